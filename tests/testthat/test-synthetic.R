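test_that("maturity profile plants exact band counts", {
  m0 <- generate_maturity_profile(50, 0, seed = 1)
  expect_true(all(m0 <= 0.25 | m0 >= 0.75))

  m <- generate_maturity_profile(100, 0.20, 0.44, seed = 2)
  expect_equal(sum(m > 0.25 & m < 0.75), 20)
  n_low <- sum(m < 0.1); n_high <- sum(m > 0.9)
  # requested 44% imbalance, up to integer rounding: 80 extremal ->
  # n_low = round(80 / 2.44) = 33, n_high = 47
  expect_equal(n_low, 33)
  expect_equal(n_high, 47)
  expect_lt(abs((n_high - n_low) / n_low - 0.44), 1 / n_low)

  expect_identical(generate_maturity_profile(40, 0.3, seed = 9),
                   generate_maturity_profile(40, 0.3, seed = 9))
  expect_error(generate_maturity_profile(50, 1.2), "intermediate_fraction")
  expect_error(generate_maturity_profile(50, 0.2, -1), "imbalance")
})

test_that("intermediate fraction round-trips across seeds", {
  fr <- vapply(1:20, function(s) {
    m <- generate_maturity_profile(100, 0.20, 0.44, seed = s)
    maturity_distribution_stats(m)$intermediate_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.20), 0.03)
})

test_that("planted network honours rates, symmetry and determinism", {
  # rate-zero between blocks: no cross edges
  pn <- generate_planted_network(20, 0.5, q_in = 3, q_out = 0, sigma = 0.3,
                                 hours = 10, seed = 4)
  W <- pn$network$W
  cross <- outer(pn$truth_membership, pn$truth_membership, "!=")
  expect_true(all(W[cross] == 0))
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(W == round(W)) && all(W >= 0))

  pn2 <- generate_planted_network(20, 0.5, 3, 0, 0.3, 10, seed = 4)
  expect_identical(W, pn2$network$W)

  expect_error(generate_planted_network(3, 0.5, 2, 0.2), "n >= 4")
  expect_error(generate_planted_network(20, 0.5, 1, 1), "q_in > q_out")
})

test_that("worker log-strengths look log-normal (small skewness)", {
  sk <- vapply(1:20, function(s) {
    pn <- generate_planted_network(100, 0.6, 2, 0.2, 0.5, 24, seed = s)
    x <- log(node_strength(pn$network))
    mean((x - mean(x))^3) / sd(x)^3
  }, numeric(1))
  expect_lt(abs(mean(sk)), 0.5)
})

test_that("trajectories: zero step keeps an ant in one hexagon", {
  ids <- c("a1", "a2")
  colony <- list(config = colony_config(detection_frames = 50, seed = 1),
                 truth_maturity = setNames(c(0.1, 0.9), ids),
                 foraging_proportion = setNames(c(0, 0), ids))
  det <- generate_trajectories(colony, step_scale_by_maturity = function(m) 0,
                               seed = 2)
  grid <- hex_grid(40, 30)
  for (id in ids) {
    d <- det[det$ant_id == id, ]
    hr <- home_range_90(d, grid)
    expect_equal(hr$n_hexes, 1)
  }
  det2 <- generate_trajectories(colony,
                                step_scale_by_maturity = function(m) 0,
                                seed = 2)
  expect_identical(det, det2)
})

test_that("trajectories stay in bounds and honour foraging proportions", {
  ids <- sprintf("b%d", 1:4)
  colony <- list(config = colony_config(detection_frames = 100, seed = 1),
                 truth_maturity = setNames(c(0.05, 0.3, 0.7, 0.95), ids),
                 foraging_proportion = setNames(c(0, 0.25, 0.5, 0.75), ids))
  det <- generate_trajectories(colony, seed = 5)
  expect_true(all(det$x >= 0 & det$x <= 40 & det$y >= 0 & det$y <= 30))
  fp <- foraging_proportion(det)
  expect_equal(unname(fp[ids]), c(0, 0.25, 0.5, 0.75), tolerance = 0.01)
})

test_that("measured home range grows with maturity cohorts", {
  mk <- function(mat, seed) {
    ids <- sprintf("c%02d", seq_along(mat))
    colony <- list(config = colony_config(detection_frames = 150,
                                          seed = seed),
                   truth_maturity = setNames(mat, ids),
                   foraging_proportion = setNames(rep(0, length(mat)), ids))
    generate_trajectories(colony, seed = seed)
  }
  grid <- hex_grid(40, 30)
  hr_mean <- function(det) {
    ids <- unique(det$ant_id)
    mean(vapply(ids, function(i) {
      home_range_90(det[det$ant_id == i, ], grid)$proportion_of_arena
    }, numeric(1)))
  }
  lo <- hr_mean(mk(rep(0.05, 20), 61))
  hi <- hr_mean(mk(rep(0.95, 20), 62))
  expect_gt(hi, lo)
})

test_that("simulated colonies satisfy their structural invariants", {
  col <- simulate_colony(colony_config(n_workers = 30, duration_hours = 6,
                                       detection_frames = 40, seed = 17))
  E <- col$edge_counts
  expect_identical(E, t(E))
  expect_true(all(diag(E) == 0))
  expect_true(all(E >= 0) && all(E == round(E)))
  expect_true(all(col$foraging_proportion >= 0 &
                    col$foraging_proportion <= 1))
  expect_true(all(unique(col$detections$ant_id) %in% rownames(E)))
  expect_equal(sum(col$network$meta$is_queen), 1)

  col2 <- simulate_colony(colony_config(n_workers = 30, duration_hours = 6,
                                        detection_frames = 40, seed = 17))
  expect_identical(col$edge_counts, col2$edge_counts)
  expect_identical(col$detections, col2$detections)
  expect_identical(col$hourly_queen_contacts, col2$hourly_queen_contacts)
})

test_that("planted low-detection ants are caught by the filter", {
  col <- simulate_colony(colony_config(n_workers = 30, duration_hours = 6,
                                       detection_frames = 100,
                                       exclusion_ants = 1, seed = 23))
  counts <- setNames(col$network$meta$detection_count,
                     col$network$meta$ant_id)
  excluded <- low_detection_filter(counts)
  expect_true("ant_001" %in% excluded)
  rep <- run_colony(col, analysis_config(k_range = 2, n_rewires = 5,
                                         n_restarts = 4,
                                         n_restarts_null = 2, seed = 1))
  expect_false("ant_001" %in% rep$per_ant$ant_id)
})

test_that("cohort generation enforces its preconditions", {
  expect_error(generate_cohort(2), ">= 3")
  coh <- generate_cohort(3, seed = 5,
                         base_config = colony_config(n_workers = 20,
                                                     duration_hours = 4,
                                                     detection_frames = 0))
  expect_length(coh, 3)
  expect_s3_class(coh[[1]], "synthetic_colony")
  # q_in varies across colonies, foraging_scale co-varies with it
  qs <- vapply(coh, function(c) c$config$q_in, numeric(1))
  expect_gt(max(qs) / min(qs), 1)
})

test_that("zero coupling slope leaves modularity and DOL unassociated", {
  # scaled-down calibration: 4 replicate cohorts of 20 small colonies
  rs <- vapply(1:4, function(rep) {
    coh <- generate_cohort(20, dol_modularity_slope = 0, seed = 700 + rep,
                           base_config = colony_config(
                             n_workers = 30, duration_hours = 8,
                             detection_frames = 0))
    Q2 <- vapply(coh, function(col) {
      suppressWarnings(fit_soft_communities(col$network, 2, n_restarts = 3,
                                            max_iter = 250,
                                            seed = 1)$Q_soft)
    }, numeric(1))
    dol <- vapply(coh, function(col) {
      division_of_labour(col$foraging_proportion[setdiff(col$ids, "queen")])
    }, numeric(1))
    cor(Q2, dol)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.5)
})

test_that("colony files round-trip through the writers", {
  col <- simulate_colony(colony_config(n_workers = 12, duration_hours = 4,
                                       detection_frames = 20, seed = 31))
  dir <- withr::local_tempdir()
  paths <- write_colony(col, dir)
  expect_true(all(file.exists(paths)))
  det <- read_detections(paths["detections"])
  expect_equal(nrow(det), nrow(col$detections))
  net <- read_edgelist(paths["edges"], metadata = col$network$meta)
  expect_equal(net$W, col$network$W)
})
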