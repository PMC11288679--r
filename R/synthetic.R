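#' Synthetic colony configuration
#'
#' Bundles every knob of the synthetic colony generator. Defaults emulate
#' the tracked-colony regime the analysis targets: 100 workers plus one
#' queen, a forager community slightly larger than the nurse community,
#' a bimodal maturity distribution with a 20% intermediate fraction and
#' 44% more high- than low-maturity workers, log-normal activity
#' dispersion, and an hourly interaction schedule. Time is scaled down
#' (24 simulated hours rather than five days) to keep test runtimes
#' reasonable; rates are per pair per hour so structure is unaffected.
#'
#' @param n_workers workers per colony (default 100).
#' @param planted_split fraction of workers in the forager community when
#'   membership is planted directly (default 0.6; in full-colony
#'   simulation community sizes emerge from the maturity profile instead).
#' @param q_in,q_out expected within/between-community interaction events
#'   per pair per hour (defaults 2 and 0.2).
#' @param strength_lognorm_sigma dispersion of per-ant log-normal activity
#'   multipliers (default 0.5).
#' @param pair_dispersion Gamma shape of pair-level rate tilts (default 1;
#'   `Inf` = pure Poisson). See [generate_planted_network()].
#' @param intermediate_fraction fraction of workers with maturity strictly
#'   between 0.25 and 0.75 (default 0.2).
#' @param high_low_imbalance target (n_{>0.9} - n_{<0.1}) / n_{<0.1}
#'   (default 0.44).
#' @param queen_archetype one of `"specialist"`, `"hub"`, `"worker_like"`.
#' @param duration_hours simulated hours (>= 2; default 24).
#' @param arena_dims arena width x height in body lengths (default 40 x 30).
#' @param body_length body length unit (default 1).
#' @param membership_steepness slope of the logistic mapping maturity ->
#'   forager-membership probability (default 8).
#' @param strength_maturity_coupling coefficient of (maturity - 0.5) on
#'   log activity; negative means foragers interact less (default -0.8).
#' @param foraging_scale maximum foraging proportion reached by the most
#'   mature workers (default 0.5); scales division of labour.
#' @param foraging_centre,foraging_steepness logistic placement of the
#'   maturity -> foraging curve (defaults 0.8 and 10): foraging only takes
#'   off at high maturity.
#' @param detection_frames frames of trajectory per ant (default 200;
#'   0 skips trajectory generation). Frame rate is 1 frame/s, a reduced
#'   rate relative to raw tracking, scaled by this knob.
#' @param exclusion_ants number of workers planted with ~5% of normal
#'   detection counts, to exercise the low-detection filter (default 0).
#' @param colony_id,species labels.
#' @param seed integer seed; all generator output is reproducible from it.
#' @return a `colony_config` list.
#' @export
colony_config <- function(n_workers = 100, planted_split = 0.6,
                          q_in = 2, q_out = 0.2,
                          strength_lognorm_sigma = 0.5,
                          pair_dispersion = 1,
                          intermediate_fraction = 0.2,
                          high_low_imbalance = 0.44,
                          queen_archetype = c("worker_like", "specialist",
                                              "hub"),
                          duration_hours = 24,
                          arena_dims = c(40, 30), body_length = 1,
                          membership_steepness = 8,
                          strength_maturity_coupling = -0.8,
                          foraging_scale = 0.5, foraging_centre = 0.8,
                          foraging_steepness = 10,
                          detection_frames = 200, exclusion_ants = 0,
                          colony_id = "synthetic_colony_1",
                          species = "synthetic", seed = 1) {
  queen_archetype <- match.arg(queen_archetype)
  if (planted_split <= 0 || planted_split >= 1) {
    stop_invalid("planted_split must be in (0, 1)")
  }
  if (!(q_in > q_out) || q_out < 0) stop_invalid("need q_in > q_out >= 0")
  if (intermediate_fraction < 0 || intermediate_fraction >= 1) {
    stop_invalid("intermediate_fraction must be in [0, 1)")
  }
  if (duration_hours < 2) stop_invalid("duration_hours must be >= 2")
  if (any(arena_dims <= 0)) stop_invalid("arena_dims must be positive")
  cfg <- list(n_workers = n_workers, planted_split = planted_split,
              q_in = q_in, q_out = q_out,
              strength_lognorm_sigma = strength_lognorm_sigma,
              pair_dispersion = pair_dispersion,
              intermediate_fraction = intermediate_fraction,
              high_low_imbalance = high_low_imbalance,
              queen_archetype = queen_archetype,
              duration_hours = duration_hours,
              arena_dims = arena_dims, body_length = body_length,
              membership_steepness = membership_steepness,
              strength_maturity_coupling = strength_maturity_coupling,
              foraging_scale = foraging_scale,
              foraging_centre = foraging_centre,
              foraging_steepness = foraging_steepness,
              detection_frames = detection_frames,
              exclusion_ants = exclusion_ants,
              colony_id = colony_id, species = species, seed = seed)
  class(cfg) <- "colony_config"
  cfg
}

#' Generate a bimodal social-maturity profile
#'
#' Draws `n` maturities in \[0, 1\] with an exact planted intermediate
#' fraction (values strictly inside (0.25, 0.75)) and a planted
#' high:low imbalance: the extremal values split between a low band
#' (< 0.1) and a high band (> 0.9) so that
#' (n_high - n_low) / n_low matches `high_low_imbalance` up to integer
#' rounding.
#'
#' @param n number of workers.
#' @param intermediate_fraction fraction in (0.25, 0.75), in \[0, 1).
#' @param high_low_imbalance target imbalance, > -1.
#' @param seed integer seed.
#' @return numeric vector of length n (shuffled order).
#' @export
generate_maturity_profile <- function(n, intermediate_fraction,
                                      high_low_imbalance = 0.44,
                                      seed = NULL) {
  if (intermediate_fraction < 0 || intermediate_fraction >= 1) {
    stop_invalid("intermediate_fraction must be in [0, 1)")
  }
  if (high_low_imbalance <= -1) {
    stop_invalid("high_low_imbalance must exceed -1")
  }
  n_int <- round(n * intermediate_fraction)
  n_ext <- n - n_int
  n_low <- round(n_ext / (2 + high_low_imbalance))
  n_high <- n_ext - n_low
  if (n_ext > 0 && (n_low < 1 || n_high < 0)) {
    stop_invalid("infeasible intermediate_fraction / imbalance combination")
  }
  eps <- 1e-6
  with_seed(seed, {
    vals <- c(runif(n_low, 0, 0.1 - eps),
              runif(n_high, 0.9 + eps, 1),
              runif(n_int, 0.25 + eps, 0.75 - eps))
    sample(vals)
  })
}

#' Generate a planted two-community weighted network
#'
#' Workers are split into a forager and a nurse block; the interaction
#' count of pair (i, j) is Poisson with mean
#' `hours * a_i * a_j * q` where q is `q_in` within a block and `q_out`
#' between blocks, and `a_i` are log-normal activity multipliers with
#' dispersion `sigma` (mean 1). This yields heavy-tailed, approximately
#' log-normal node strengths and tunable modularity.
#'
#' @param n number of nodes (>= 4).
#' @param split fraction of nodes in the forager block.
#' @param q_in,q_out within/between-block rates (events per pair per
#'   hour), q_in > q_out >= 0.
#' @param sigma log-normal dispersion of activity multipliers.
#' @param hours scheduled hours.
#' @param pair_dispersion Gamma shape of pair-level rate tilts (mean 1):
#'   counts are negative-binomial (Poisson with Gamma-mixed rates),
#'   matching the overdispersion of real contact counts; `Inf` gives pure
#'   Poisson. Default 1.
#' @param seed integer seed.
#' @param membership optional planted labels (`"forager"`/`"nurse"`)
#'   overriding the random split.
#' @param activity optional per-node activity multipliers (overrides the
#'   log-normal draw).
#' @param ids optional node ids.
#' @return list with `network` (a `weighted_network`) and
#'   `truth_membership` (character vector).
#' @export
generate_planted_network <- function(n, split = 0.6, q_in = 2, q_out = 0.2,
                                     sigma = 0.5, hours = 24,
                                     pair_dispersion = 1, seed = NULL,
                                     membership = NULL, activity = NULL,
                                     ids = NULL) {
  if (n < 4) stop_invalid("planted network requires n >= 4")
  if (!(q_in > q_out) || q_out < 0) stop_invalid("need q_in > q_out >= 0")
  with_seed(seed, {
    if (is.null(membership)) {
      n_f <- round(n * split)
      if (n_f < 2 || n - n_f < 2) stop_invalid("split leaves a block < 2")
      membership <- sample(c(rep("forager", n_f), rep("nurse", n - n_f)))
    }
    if (is.null(activity)) {
      activity <- rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
    }
    if (is.null(ids)) ids <- sprintf("ant_%03d", seq_len(n))
    same <- outer(membership, membership, "==")
    lambda <- hours * outer(activity, activity) * ifelse(same, q_in, q_out)
    W <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- upper.tri(W)
    lam <- lambda[ut]
    if (is.finite(pair_dispersion)) {
      lam <- lam * rgamma(length(lam), shape = pair_dispersion,
                          rate = pair_dispersion)
    }
    W[ut] <- rpois(sum(ut), lam)
    W <- W + t(W)
    net <- weighted_network(W, data.frame(ant_id = ids, is_queen = FALSE))
    list(network = net, truth_membership = setNames(membership, ids))
  })
}

#' Generate random-walk trajectories for a colony
#'
#' Each ant performs a reflected Gaussian random walk inside the arena;
#' the per-frame step scale grows with maturity so that 90% home-range
#' size increases with maturity by construction. Each ant spends its
#' configured foraging proportion of frames in the foraging box (a
#' contiguous terminal block, so the per-ant proportion is exact up to
#' frame rounding); walks in the two boxes are independent.
#'
#' @param colony a `synthetic_colony` (or any list with `config`,
#'   `truth_maturity` and `foraging_proportion`).
#' @param step_scale_by_maturity function maturity -> step sd in body
#'   lengths per frame (default `0.2 + 2.3 * maturity`).
#' @param seed integer seed.
#' @param n_frames frames per ant (default `config$detection_frames`).
#' @return detection-record data.frame (see [read_detections()]).
#' @export
generate_trajectories <- function(colony, step_scale_by_maturity = NULL,
                                  seed = NULL, n_frames = NULL) {
  cfg <- colony$config
  if (is.null(step_scale_by_maturity)) {
    step_scale_by_maturity <- function(m) 0.2 + 2.3 * m
  }
  n_frames <- n_frames %||% cfg$detection_frames
  if (is.null(n_frames) || n_frames < 1) {
    return(data.frame(time_s = numeric(0), ant_id = character(0),
                      x = numeric(0), y = numeric(0),
                      angle_rad = numeric(0), arena = character(0)))
  }
  W <- cfg$arena_dims[1]
  H <- cfg$arena_dims[2]
  ids <- names(colony$truth_maturity)
  with_seed(seed, {
    recs <- lapply(ids, function(id) {
      m <- colony$truth_maturity[[id]]
      p_f <- colony$foraging_proportion[[id]]
      step <- step_scale_by_maturity(m)
      n_forage <- round(n_frames * p_f)
      arena <- c(rep("nest", n_frames - n_forage), rep("forage", n_forage))
      x <- numeric(n_frames)
      y <- numeric(n_frames)
      pos <- c(runif(1, 0, W), runif(1, 0, H))
      for (t in seq_len(n_frames)) {
        if (t > 1 && arena[t] != arena[t - 1]) {
          pos <- c(runif(1, 0, W), runif(1, 0, H))  # entered the other box
        } else if (t > 1) {
          pos <- reflect(pos + rnorm(2, 0, step), W, H)
        }
        x[t] <- pos[1]
        y[t] <- pos[2]
      }
      data.frame(time_s = seq_len(n_frames) - 1, ant_id = id, x = x, y = y,
                 angle_rad = runif(n_frames, 0, 2 * pi), arena = arena,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    # planted low-detection ants keep only ~5% of their frames
    if ((cfg$exclusion_ants %||% 0) > 0) {
      workers <- setdiff(ids, "queen")
      drop_ids <- head(workers, cfg$exclusion_ants)
      keep <- !(out$ant_id %in% drop_ids) | (out$time_s %% 20 == 0)
      out <- out[keep, , drop = FALSE]
    }
    out <- out[order(out$time_s, out$ant_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

reflect <- function(pos, W, H) {
  p <- pos
  # fold back into [0, W] x [0, H] (steps are small relative to the arena)
  for (rep in 1:3) {
    p[1] <- ifelse(p[1] < 0, -p[1], ifelse(p[1] > W, 2 * W - p[1], p[1]))
    p[2] <- ifelse(p[2] < 0, -p[2], ifelse(p[2] > H, 2 * H - p[2], p[2]))
  }
  pmin(pmax(p, 0), c(W, H))
}

#' Generate an hourly queen-contact schedule
#'
#' Emulates the three queen archetypes observed across species:
#' `"specialist"` (few fixed partners, high hour-to-hour identity
#' conservation, total strength near the worker mean), `"hub"` (broad
#' worker-typical partner spread but inflated contact frequency, queen
#' strength well above the worker mean) and `"worker_like"` (all knobs at
#' worker-typical values).
#'
#' @param archetype one of `"specialist"`, `"hub"`, `"worker_like"`.
#' @param n_workers workforce size.
#' @param hours schedule length (>= 2).
#' @param seed integer seed.
#' @param target_strength worker mean strength the schedule is calibrated
#'   to (default `8 * hours`).
#' @param strength_sd worker strength standard deviation (used by the hub
#'   archetype to push the queen >= 3 sd above the mean; default
#'   `target_strength / 4`).
#' @param partner_weights optional per-worker sampling weights (e.g.
#'   nurse-biased); default uniform.
#' @param worker_ids optional worker id labels.
#' @return an `hourly_contacts` (list of named count vectors per hour).
#' @export
generate_queen_schedule <- function(archetype, n_workers, hours,
                                    seed = NULL, target_strength = NULL,
                                    strength_sd = NULL,
                                    partner_weights = NULL,
                                    worker_ids = NULL) {
  if (!archetype %in% c("specialist", "hub", "worker_like")) {
    stop_invalid("unknown queen archetype: ", archetype)
  }
  if (hours < 2) stop_invalid("schedule requires hours >= 2")
  target_strength <- target_strength %||% (8 * hours)
  strength_sd <- strength_sd %||% (target_strength / 4)
  worker_ids <- worker_ids %||% sprintf("ant_%03d", seq_len(n_workers))
  partner_weights <- partner_weights %||% rep(1, n_workers)

  with_seed(seed, {
    if (archetype == "specialist") {
      n_partners <- max(2, round(0.04 * n_workers))
      partners <- sample(worker_ids, n_partners, prob = partner_weights)
      mu <- max(target_strength / (hours * n_partners) - 1, 0)
      out <- lapply(seq_len(hours), function(h) {
        setNames(1L + rpois(n_partners, mu), partners)
      })
    } else {
      total <- if (archetype == "hub") {
        target_strength + 3 * strength_sd
      } else {
        target_strength
      }
      per_hour <- total / hours
      out <- lapply(seq_len(hours), function(h) {
        k <- rpois(1, per_hour)
        if (k == 0) return(integer(0))
        draws <- sample(worker_ids, k, replace = TRUE,
                        prob = partner_weights)
        tab <- table(draws)
        setNames(as.integer(tab), names(tab))
      })
    }
    attr(out, "no_events") <- FALSE
    class(out) <- "hourly_contacts"
    out
  })
}

#' Simulate a full colony with known ground truth
#'
#' Assembles every synthetic ingredient into one colony: a bimodal
#' maturity profile, community membership via a logistic function of
#' maturity, a planted weighted worker network whose activity multipliers
#' couple (negatively, by default) to maturity, maturity-driven foraging
#' proportions, a queen contact schedule of the configured archetype
#' (merged into the interaction matrix), trajectories, and the hourly
#' queen-contact record.
#'
#' @param config a [colony_config()].
#' @return a `synthetic_colony`: list with `config`, `ids` (queen last,
#'   id `"queen"`), `truth_maturity`, `truth_membership`, `network`
#'   (a `weighted_network` including the queen), `edge_counts`,
#'   `foraging_proportion`, `detections`, `hourly_queen_contacts`,
#'   `truth` (activity multipliers and schedule calibration).
#' @export
simulate_colony <- function(config = colony_config()) {
  cfg <- config
  n <- cfg$n_workers
  with_seed(cfg$seed, {
    worker_ids <- sprintf("ant_%03d", seq_len(n))
    maturity <- setNames(
      generate_maturity_profile(n, cfg$intermediate_fraction,
                                cfg$high_low_imbalance, seed = NULL),
      worker_ids)
    p_forager <- stats::plogis(cfg$membership_steepness * (maturity - 0.5))
    membership <- ifelse(runif(n) < p_forager, "forager", "nurse")
    # guard: both communities need at least two members for a 2-block net
    if (sum(membership == "forager") < 2) {
      membership[order(maturity, decreasing = TRUE)[1:2]] <- "forager"
    }
    if (sum(membership == "nurse") < 2) {
      membership[order(maturity)[1:2]] <- "nurse"
    }
    sigma <- cfg$strength_lognorm_sigma
    activity <- exp(-sigma^2 / 2 + sigma * rnorm(n) +
                      cfg$strength_maturity_coupling * (maturity - 0.5))
    pn <- generate_planted_network(n, q_in = cfg$q_in, q_out = cfg$q_out,
                                   sigma = sigma,
                                   hours = cfg$duration_hours,
                                   pair_dispersion = cfg$pair_dispersion,
                                   seed = NULL,
                                   membership = membership,
                                   activity = activity, ids = worker_ids)
    foraging <- pmin(pmax(
      cfg$foraging_scale *
        stats::plogis(cfg$foraging_steepness *
                        (maturity - cfg$foraging_centre)) +
        rnorm(n, 0, 0.02), 0), 1)
    names(foraging) <- worker_ids

    ws <- node_strength(pn$network)
    # the queen samples partners with a typical nurse's expected edge
    # profile (activity x within/between rate, with the same pair-level
    # tilts as worker pairs), so a worker_like queen ends up with
    # worker-typical entropy, not an artificially even spread
    nurse_bias <- activity * ifelse(membership == "nurse", cfg$q_in, cfg$q_out)
    if (is.finite(cfg$pair_dispersion)) {
      nurse_bias <- nurse_bias * rgamma(n, shape = cfg$pair_dispersion,
                                        rate = cfg$pair_dispersion)
    }
    schedule <- generate_queen_schedule(
      cfg$queen_archetype, n, cfg$duration_hours, seed = NULL,
      target_strength = mean(ws), strength_sd = sd(ws),
      partner_weights = nurse_bias, worker_ids = worker_ids)

    queen_counts <- setNames(numeric(n), worker_ids)
    for (h in seq_along(schedule)) {
      hc <- schedule[[h]]
      if (length(hc) > 0) {
        queen_counts[names(hc)] <- queen_counts[names(hc)] + hc
      }
    }
    ids <- c(worker_ids, "queen")
    E <- matrix(0, n + 1, n + 1, dimnames = list(ids, ids))
    E[worker_ids, worker_ids] <- pn$network$W
    E["queen", worker_ids] <- queen_counts
    E[worker_ids, "queen"] <- queen_counts

    maturity_all <- c(maturity, queen = 0)
    membership_all <- c(setNames(membership, worker_ids), queen = "nurse")
    foraging_all <- c(foraging, queen = 0)

    colony <- list(config = cfg, ids = ids,
                   truth_maturity = maturity_all,
                   truth_membership = membership_all,
                   foraging_proportion = foraging_all)
    detections <- generate_trajectories(colony, seed = NULL)
    det_counts <- if (nrow(detections) > 0) {
      tab <- table(detections$ant_id)
      setNames(as.numeric(tab), names(tab))[ids]
    } else {
      setNames(rep(NA_real_, length(ids)), ids)
    }

    meta <- data.frame(ant_id = ids, is_queen = ids == "queen",
                       foraging_proportion = foraging_all[ids],
                       detection_count = as.numeric(det_counts))
    net <- weighted_network(E, meta, colony = cfg$colony_id,
                            species = cfg$species)
    structure(list(config = cfg, ids = ids,
                   truth_maturity = maturity_all,
                   truth_membership = membership_all,
                   network = net, edge_counts = E,
                   foraging_proportion = foraging_all,
                   detections = detections,
                   hourly_queen_contacts = schedule,
                   truth = list(activity = setNames(activity, worker_ids),
                                worker_strengths = ws)),
              class = "synthetic_colony")
  })
}

#' @export
print.synthetic_colony <- function(x, ...) {
  cat(sprintf(
    "<synthetic_colony> %s: %d workers + queen (%s), %d hours, %d detections\n",
    x$config$colony_id, x$config$n_workers, x$config$queen_archetype,
    x$config$duration_hours, nrow(x$detections)))
  invisible(x)
}

#' Generate a cohort of colonies with planted modularity-DOL coupling
#'
#' Colony configurations co-vary the within:between interaction ratio
#' (which drives measured modularity) and the foraging-proportion spread
#' (which drives measured division of labour). With
#' `dol_modularity_slope = 0` the two are drawn independently; positive
#' slopes plant a positive cross-colony association whose measured
#' Pearson correlation grows with the slope.
#'
#' @param n_colonies number of colonies (>= 3).
#' @param dol_modularity_slope coupling strength (default 1; 0 = none).
#' @param seed integer seed.
#' @param base_config template [colony_config()]; per-colony fields
#'   (q_in, foraging_scale, colony_id, seed) are overridden. The default
#'   template uses 40-worker colonies and no trajectories so 25-colony
#'   cohorts stay cheap.
#' @return list of `synthetic_colony` objects.
#' @export
generate_cohort <- function(n_colonies, dol_modularity_slope = 1, seed = NULL,
                            base_config = NULL) {
  if (n_colonies < 3) stop_invalid("a cohort requires >= 3 colonies")
  base_config <- base_config %||%
    colony_config(n_workers = 40, duration_hours = 12, detection_frames = 0)
  with_seed(seed, {
    u <- runif(n_colonies)                      # modularity driver
    v <- runif(n_colonies)                      # independent DOL driver
    noise <- rnorm(n_colonies, 0, 0.05)
    s <- dol_modularity_slope
    fscale <- pmin(pmax(0.3 + 0.35 * (s * (u - 0.5) +
                                        (1 - min(abs(s), 1)) * (v - 0.5)) +
                          noise, 0.02), 0.95)
    ratio <- 2 * 8^u                            # q_in/q_out in [2, 16]
    seeds <- sample.int(.Machine$integer.max, n_colonies)
    lapply(seq_len(n_colonies), function(i) {
      cfg <- base_config
      cfg$q_out <- 0.2
      cfg$q_in <- cfg$q_out * ratio[i]
      cfg$foraging_scale <- fscale[i]
      cfg$colony_id <- sprintf("synthetic_colony_%02d", i)
      cfg$species <- sprintf("group_%d", ((i - 1) %% 5) + 1)
      cfg$seed <- seeds[i]
      simulate_colony(cfg)
    })
  })
}

#' Write a synthetic colony's files
#'
#' Emits the detection CSV, the pairwise edge-count CSV and a
#' ground-truth JSON (config, maturities, memberships, foraging
#' proportions) into a directory.
#'
#' @param colony a `synthetic_colony`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_colony <- function(colony, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  det <- file.path(dir, "detections.csv")
  edg <- file.path(dir, "edges.csv")
  tru <- file.path(dir, "truth.json")
  write_detections(colony$detections, det)
  write_edgelist(colony$network, edg)
  truth <- list(config = unclass(colony$config),
                truth_maturity = as.list(colony$truth_maturity),
                truth_membership = as.list(colony$truth_membership),
                foraging_proportion = as.list(colony$foraging_proportion))
  jsonlite::write_json(truth, tru, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(detections = det, edges = edg, truth = tru))
}
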