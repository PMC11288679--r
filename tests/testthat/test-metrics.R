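test_that("node entropy matches direct formula evaluation", {
  expect_equal(as.numeric(node_entropy(c(5, 0, 0))), 0)
  expect_equal(as.numeric(node_entropy(c(1, 1, 1, 1))), log(4))
  expect_equal(as.numeric(node_entropy(c(2, 1, 1))),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  h <- node_entropy(c(0, 0, 0))
  expect_equal(as.numeric(h), 0)
  expect_true(attr(h, "isolated"))
  expect_equal(as.numeric(node_entropy(c(2, 2), base = 2)), 1)
  expect_error(node_entropy(c(1, -1)), "nonnegative")
})

test_that("entropy bounds hold and the maximum needs full uniformity", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    v <- rpois(n, 3)
    h <- as.numeric(node_entropy(v))
    expect_gte(h, 0)
    expect_lte(h, log(n) + 1e-12)
  }
  expect_lt(as.numeric(node_entropy(c(4, 4, 4, 0))), log(4))
})

test_that("z-normalisation centres and scales within groups", {
  expect_equal(z_normalize(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(z_normalize(c(2, 2, 2)), "degenerate")
  expect_error(z_normalize(c(1)), ">= 2")
  set.seed(6)
  x <- rnorm(30)
  g <- rep(1:3, each = 10)
  z <- z_normalize(x, g)
  for (k in 1:3) {
    expect_equal(mean(z[g == k]), 0)
    expect_equal(sd(z[g == k]), 1)
  }
})

test_that("division of labour is the sample sd of foraging proportions", {
  expect_equal(division_of_labour(rep(0.3, 10)), 0)
  expect_equal(division_of_labour(c(0, 1)), sd(c(0, 1)))
  expect_error(division_of_labour(0.4), ">= 2 workers")
  set.seed(7)
  x <- runif(20, 0, 0.5)
  expect_equal(division_of_labour(sample(x)), division_of_labour(x))
  expect_equal(division_of_labour(x * 0.5), 0.5 * division_of_labour(x))
})

test_that("maturity-distribution statistics", {
  s <- maturity_distribution_stats(rep(c(0, 1), 25))
  expect_equal(s$intermediate_fraction, 0)

  half <- c(runif(50, 0.3, 0.7), runif(25, 0, 0.05), runif(25, 0.95, 1))
  s2 <- maturity_distribution_stats(half)
  expect_gt(s2$prop_test_p, 0.9)

  m <- generate_maturity_profile(100, 0.20, 0.44, seed = 3)
  s3 <- maturity_distribution_stats(m)
  expect_equal(s3$intermediate_fraction, 0.20)

  s4 <- maturity_distribution_stats(runif(20, 0.95, 1))
  expect_true(is.na(s4$high_low_imbalance))
  expect_error(maturity_distribution_stats(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hex indexing: origin, centre identity, and nearest-centre oracle", {
  grid <- hex_grid(20, 15, body_length = 1, hex_size_bl = 2)
  expect_equal(hex_index(0, 0, grid), data.frame(q = 0L, r = 0L))

  set.seed(8)
  inner <- interior_hexes(grid)
  hx <- inner[sample(nrow(inner), 20), ]
  got <- hex_index(hx$cx, hx$cy, grid)
  expect_equal(got$q, hx$q)
  expect_equal(got$r, hx$r)

  # oracle: nearest hexagon centre over the full candidate set
  pts_x <- runif(200, 0, 20); pts_y <- runif(200, 0, 15)
  got <- hex_index(pts_x, pts_y, grid)
  for (i in seq_along(pts_x)) {
    d <- sqrt((grid$hexes$cx - pts_x[i])^2 + (grid$hexes$cy - pts_y[i])^2)
    j <- which.min(d)
    expect_equal(got$q[i], grid$hexes$q[j])
    expect_equal(got$r[i], grid$hexes$r[j])
  }

  expect_warning(hex_index(-5, 0, grid), "clamped")
})

test_that("hex tiling partitions detections", {
  grid <- hex_grid(20, 15)
  set.seed(9)
  x <- runif(500, 0, 20); y <- runif(500, 0, 15)
  ax <- hex_index(x, y, grid)
  # every point maps to exactly one hexagon of the grid
  key_grid <- paste(grid$hexes$q, grid$hexes$r)
  expect_true(all(paste(ax$q, ax$r) %in% key_grid))
  counts <- table(paste(ax$q, ax$r))
  expect_equal(sum(counts), 500)
})

test_that("90% home range follows the ranked-accumulation rule", {
  grid <- hex_grid(40, 30)
  centre1 <- interior_hexes(grid)[10, ]
  one <- data.frame(x = rep(centre1$cx, 7), y = rep(centre1$cy, 7))
  hr <- home_range_90(one, grid)
  expect_equal(hr$n_hexes, 1)
  expect_equal(hr$proportion_of_arena, 1 / grid$N_hex)

  # equal split over 10 hexagons: 9 cover exactly 90%
  hx <- interior_hexes(grid)[21:30, ]
  ten <- data.frame(x = rep(hx$cx, each = 4), y = rep(hx$cy, each = 4))
  expect_equal(home_range_90(ten, grid)$n_hexes, 9)
})

test_that("home range matches the brute-force prefix oracle", {
  grid <- hex_grid(40, 30)
  set.seed(10)
  for (i in 1:20) {
    hx <- interior_hexes(grid)[sample(nrow(interior_hexes(grid)), 30), ]
    counts <- rpois(30, sample(1:6, 1)) + 1
    det <- data.frame(x = rep(hx$cx, counts), y = rep(hx$cy, counts))
    hr <- home_range_90(det, grid)
    oracle <- oracle_home_range_size(
      data.frame(q = hx$q, r = hx$r, count = counts))
    expect_equal(hr$n_hexes, oracle)
    expect_gte(hr$covered, 0.9 * nrow(det))
  }
})

test_that("strength-maturity association recovers planted couplings", {
  # perfect anti-association
  m <- seq(0, 1, length.out = 10)
  a <- strength_maturity_association(m, -2 * m + 0.5)
  expect_equal(unname(a$r), -1)

  # null: independent strengths, |r| small on average over seeds
  rs <- vapply(1:20, function(s) {
    set.seed(s)
    strength_maturity_association(runif(100), rnorm(100))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)

  # planted negative coupling in the full generator
  slopes <- vapply(1:10, function(s) {
    col <- simulate_colony(colony_config(n_workers = 60,
                                         duration_hours = 12,
                                         detection_frames = 0, seed = s))
    w <- !col$network$meta$is_queen
    zs <- z_normalize(node_strength(col$network)[w])
    strength_maturity_association(
      col$truth_maturity[col$network$meta$ant_id[w]], zs)$slope
  }, numeric(1))
  expect_true(all(slopes < 0))

  expect_true(strength_maturity_association(rep(0.5, 5), rnorm(5))$degenerate)
  expect_error(strength_maturity_association(c(0.1, 0.9), c(1, 2)), ">= 3")
})
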