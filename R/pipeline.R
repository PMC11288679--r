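#' Analysis configuration
#'
#' Defaults mirror the per-colony analysis: soft communities for
#' k = 2..5, a 100-rewire permutation test at k = 2, no gap closing when
#' segmenting interaction events, hexagons of two body lengths for home
#' ranges, and a fixed seed for full determinism.
#'
#' @param k_range community numbers profiled (default 2:5).
#' @param n_rewires rewired replicas in the permutation test (default 100).
#' @param n_restarts optimiser restarts per fit (default 20).
#' @param n_restarts_null restarts used for null-network fits (default 5;
#'   nulls need less polish than the observed fit and dominate runtime).
#' @param tol,max_iter optimiser stopping rule.
#' @param max_gap_frames gap closing for event segmentation (default 0).
#' @param hex_size_bl hexagon circumradius in body lengths (default 2).
#' @param n_swap_multiplier accepted swaps per edge when rewiring.
#' @param hour_length_s seconds per hour bin (default 3600).
#' @param coverage home-range coverage level (default 0.9).
#' @param seed master seed for the run.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(k_range = 2:5, n_rewires = 100, n_restarts = 20,
                            n_restarts_null = 5, tol = 1e-6, max_iter = 500,
                            max_gap_frames = 0, hex_size_bl = 2,
                            n_swap_multiplier = 10, hour_length_s = 3600,
                            coverage = 0.9, seed = 1) {
  structure(list(k_range = k_range, n_rewires = n_rewires,
                 n_restarts = n_restarts, n_restarts_null = n_restarts_null,
                 tol = tol, max_iter = max_iter,
                 max_gap_frames = max_gap_frames, hex_size_bl = hex_size_bl,
                 n_swap_multiplier = n_swap_multiplier,
                 hour_length_s = hour_length_s, coverage = coverage,
                 seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#'
#' Keys mirror [analysis_config()] arguments; unknown keys error.
#'
#' @param path JSON file.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop_invalid("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Run the full per-colony analysis
#'
#' Executes the pipeline stages in order: low-detection exclusion,
#' network construction, soft community detection across `k_range`,
#' the rewiring permutation test at k = 2, social maturity, per-ant and
#' colony-level metrics, and queen encounter kinetics. Deterministic
#' given `config$seed`.
#'
#' @param x input colony: a `synthetic_colony`, a `weighted_network`, or
#'   a list with elements `detections` and `capsules` (interactions are
#'   then inferred with [detect_interactions()]).
#' @param config an [analysis_config()].
#' @return a `colony_report` list (serialisable with [write_report()]).
#' @export
run_colony <- function(x, config = analysis_config()) {
  flags <- character(0)

  detections <- NULL
  hourly <- NULL
  events <- NULL
  if (inherits(x, "synthetic_colony")) {
    net <- x$network
    detections <- if (nrow(x$detections) > 0) x$detections else NULL
    hourly <- x$hourly_queen_contacts
    body_length <- x$config$body_length
    arena <- x$config$arena_dims
    n_hours <- x$config$duration_hours
  } else if (inherits(x, "weighted_network")) {
    net <- x
    body_length <- 1
    arena <- NULL
    n_hours <- NULL
  } else if (is.list(x) && !is.null(x$detections)) {
    capsules <- x$capsules %||% capsule_spec(unique(x$detections$ant_id))
    det <- detect_interactions(x$detections, capsules,
                               config$max_gap_frames)
    events <- det$events
    detections <- x$detections
    meta <- data.frame(ant_id = rownames(det$counts))
    meta$is_queen <- meta$ant_id %in% (x$queen_id %||% character(0))
    fp <- foraging_proportion(detections)
    meta$foraging_proportion <- as.numeric(fp[meta$ant_id])
    tab <- table(detections$ant_id)
    meta$detection_count <- as.numeric(tab[meta$ant_id])
    net <- weighted_network(det$counts, meta, colony = x$colony %||% NA,
                            species = x$species %||% NA)
    body_length <- x$body_length %||% 1
    arena <- x$arena_dims %||% NULL
    n_hours <- NULL
  } else {
    stop_invalid("unsupported input to run_colony")
  }

  # --- exclusion of poorly detected ants ------------------------------
  excluded <- character(0)
  dc <- net$meta$detection_count
  if (!all(is.na(dc))) {
    counts <- setNames(dc, net$meta$ant_id)
    counts <- counts[!is.na(counts)]
    if (length(counts) >= 2) excluded <- low_detection_filter(counts)
  }
  qid <- queen_id(net)
  queen_excluded <- !is.na(qid) && qid %in% excluded
  if (queen_excluded) flags <- c(flags, "queen_excluded")
  if (length(excluded) > 0) {
    flags <- c(flags, paste0("excluded:", length(excluded)))
    net <- build_network(net$W, net$meta, excluded,
                         colony = net$colony, species = net$species)
    qid <- queen_id(net)
  }

  with_seed(config$seed, {
    # --- communities ---------------------------------------------------
    profile <- modularity_profile(net, ks = config$k_range,
                                  n_restarts = config$n_restarts,
                                  tol = config$tol,
                                  max_iter = config$max_iter, seed = NULL)
    part2 <- profile$partitions[["2"]]
    if (!is.null(part2) && !part2$converged) flags <- c(flags, "nonconverged_k2")

    perm <- modularity_permutation_test(
      net, k = 2, n_rewires = config$n_rewires,
      n_restarts = config$n_restarts_null, tol = config$tol,
      max_iter = config$max_iter,
      n_swap_multiplier = config$n_swap_multiplier, seed = NULL)
    if (perm$degenerate) flags <- c(flags, "degenerate_network")

    fp <- setNames(net$meta$foraging_proportion, net$meta$ant_id)
    maturity <- social_maturity(
      part2, queen_id = if (!is.na(qid)) qid else NULL,
      foraging_proportion = if (is.na(qid)) fp else NULL)
    if (attr(maturity, "orientation") == "foraging_fallback") {
      flags <- c(flags, "maturity_oriented_by_foraging")
    }

    # --- per-ant metrics -----------------------------------------------
    ids <- net$meta$ant_id
    strength <- node_strength(net)
    entropy <- vapply(seq_along(ids), function(i) {
      as.numeric(node_entropy(net$W[i, -i]))
    }, numeric(1))
    z_strength <- z_normalize(strength)
    z_entropy <- z_normalize(entropy)

    homerange <- rep(NA_real_, length(ids))
    if (!is.null(detections) && !is.null(arena)) {
      grid <- hex_grid(arena[1], arena[2], body_length, config$hex_size_bl)
      nest <- detections[detections$arena == "nest", , drop = FALSE]
      for (i in seq_along(ids)) {
        d <- nest[nest$ant_id == ids[i], , drop = FALSE]
        if (nrow(d) > 0) {
          homerange[i] <- home_range_90(d, grid,
                                        config$coverage)$proportion_of_arena
        }
      }
    }

    per_ant <- data.frame(ant_id = ids,
                          is_queen = net$meta$is_queen,
                          maturity = as.numeric(maturity[ids]),
                          strength = as.numeric(strength[ids]),
                          z_strength = z_strength,
                          entropy = entropy, z_entropy = z_entropy,
                          foraging_proportion = net$meta$foraging_proportion,
                          detection_count = net$meta$detection_count,
                          homerange_prop = homerange)

    workers <- per_ant[!per_ant$is_queen, , drop = FALSE]
    dol <- if (nrow(workers) >= 2 &&
               !all(is.na(workers$foraging_proportion))) {
      division_of_labour(workers$foraging_proportion)
    } else NA_real_
    mat_stats <- maturity_distribution_stats(workers$maturity)
    sma <- strength_maturity_association(workers$maturity,
                                         workers$z_strength)

    # --- queen kinetics -------------------------------------------------
    queen <- NULL
    if (!is.na(qid)) {
      hc <- hourly
      if (is.null(hc) && !is.null(events) && nrow(events) > 0) {
        hc <- bin_queen_contacts(events, qid, config$hour_length_s,
                                 n_hours = n_hours)
      }
      kin <- if (!is.null(hc) && length(hc) >= 1) {
        queen_kinetics(hc, n_workers = nrow(workers))
      } else {
        list(workers_per_hour = NA_real_,
             contacts_per_worker_per_hour = NA_real_,
             identity_conservation = NA_real_)
      }
      queen <- c(kin, list(
        queen_z_strength = per_ant$z_strength[per_ant$is_queen],
        queen_z_entropy = per_ant$z_entropy[per_ant$is_queen]))
    } else {
      flags <- c(flags, "no_queen")
    }

    structure(list(
      colony_id = net$colony, species = net$species,
      n_nodes = length(ids), excluded = excluded,
      Q = as.list(profile$Q), best_k = profile$best_k,
      permutation = list(Q_obs = perm$Q_obs, p = perm$p,
                         n_rewires = config$n_rewires,
                         null_mean = if (length(perm$Q_null)) mean(perm$Q_null) else NA_real_,
                         null_sd = if (length(perm$Q_null) > 1) sd(perm$Q_null) else NA_real_),
      dol = dol,
      maturity_stats = mat_stats,
      strength_maturity = sma,
      queen = queen,
      per_ant = per_ant,
      flags = as.list(flags)),
      class = "colony_report")
  })
}

#' @export
print.colony_report <- function(x, ...) {
  cat(sprintf("<colony_report> %s: n=%d, best k=%d, Q2=%.3f (p=%.4g), DOL=%.3f\n",
              x$colony_id, x$n_nodes, x$best_k, x$Q[["2"]],
              x$permutation$p, x$dol))
  if (length(x$flags) > 0) cat("  flags:", unlist(x$flags), "\n")
  invisible(x)
}

#' Serialise / restore a colony report as JSON
#'
#' Round-trippable at full precision; two runs with identical config and
#' seed produce byte-identical files.
#'
#' @param report a `colony_report` (or `cohort_report`).
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "columns")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.data.frame(x)) {
    as.list(x)
  } else x
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# required fields and their predicates: the report "schema"
REPORT_SCHEMA <- list(
  colony_id = function(x) length(x) == 1,
  n_nodes = function(x) is.numeric(x) && x >= 1,
  Q = function(x) is.list(x) && length(x) >= 1 &&
    all(vapply(x, is.numeric, logical(1))),
  best_k = function(x) is.numeric(x) && x >= 1,
  permutation = function(x) is.list(x) &&
    all(c("Q_obs", "p", "n_rewires") %in% names(x)) &&
    x$p > 0 && x$p <= 1,
  dol = function(x) is.na(x) || is.finite(x),
  maturity_stats = function(x) is.list(x) &&
    all(c("intermediate_fraction", "n_high", "n_low") %in% names(x)),
  per_ant = function(x) all(c("ant_id", "maturity", "strength",
                              "z_strength", "entropy") %in% names(x)),
  flags = function(x) is.list(x) || is.character(x))

#' Validate a colony report's structure
#'
#' Checks that every required field is present and well-formed (the same
#' contract the JSON serialisation follows). Used by tests and available
#' to consumers of externally produced report files.
#'
#' @param report a `colony_report` or a list read back with
#'   [read_report()].
#' @return TRUE invisibly; errors with the offending field otherwise.
#' @export
validate_report <- function(report) {
  for (field in names(REPORT_SCHEMA)) {
    if (!field %in% names(report)) {
      stop_data("report is missing field: ", field)
    }
    if (!isTRUE(REPORT_SCHEMA[[field]](report[[field]]))) {
      stop_data("report field fails validation: ", field)
    }
  }
  invisible(TRUE)
}

#' Run the cross-colony (cohort) analysis
#'
#' Per-colony reports plus: the cross-colony Pearson correlation between
#' soft modularity at k = 2 and division of labour, and per-group Welch
#' comparisons of queen versus worker z-scores (strength and entropy).
#'
#' @param colonies list of inputs accepted by [run_colony()].
#' @param config an [analysis_config()].
#' @return a `cohort_report`.
#' @export
run_cohort <- function(colonies, config = analysis_config()) {
  reports <- lapply(colonies, run_colony, config = config)
  Q2 <- vapply(reports, function(r) r$Q[["2"]], numeric(1))
  dol <- vapply(reports, function(r) r$dol, numeric(1))
  ok <- is.finite(Q2) & is.finite(dol)
  corr <- NULL
  flags <- character(0)
  if (sum(ok) >= 3 && sd(Q2[ok]) > 0 && sd(dol[ok]) > 0) {
    ct <- cor.test(Q2[ok], dol[ok])
    corr <- list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  } else {
    flags <- c(flags, "modularity_dol_correlation_undefined")
  }

  species <- vapply(reports, function(r)
    if (is.null(r$species) || is.na(r$species)) "all" else r$species,
    character(1))
  queen_comparisons <- lapply(unique(species), function(sp) {
    idx <- which(species == sp)
    qz_s <- vapply(reports[idx], function(r)
      if (!is.null(r$queen)) r$queen$queen_z_strength else NA_real_,
      numeric(1))
    qz_e <- vapply(reports[idx], function(r)
      if (!is.null(r$queen)) r$queen$queen_z_entropy else NA_real_,
      numeric(1))
    wz <- do.call(rbind, lapply(reports[idx], function(r)
      r$per_ant[!r$per_ant$is_queen, c("z_strength", "z_entropy")]))
    welch <- function(qv, wv) {
      qv <- qv[is.finite(qv)]
      if (length(qv) < 2) return(list(t = NA_real_, p = NA_real_))
      tt <- t.test(qv, wv)
      list(t = unname(tt$statistic), p = tt$p.value)
    }
    list(group = sp, n_colonies = length(idx),
         strength = welch(qz_s, wz$z_strength),
         entropy = welch(qz_e, wz$z_entropy),
         queen_z_strength_mean = mean(qz_s, na.rm = TRUE),
         queen_z_entropy_mean = mean(qz_e, na.rm = TRUE))
  })

  structure(list(colonies = reports,
                 modularity_dol = corr,
                 queen_comparisons = queen_comparisons,
                 flags = as.list(flags)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d colonies\n", length(x$colonies)))
  if (!is.null(x$modularity_dol)) {
    cat(sprintf("  modularity~DOL: r=%.3f (p=%.4g, n=%d)\n",
                x$modularity_dol$r, x$modularity_dol$p,
                x$modularity_dol$n))
  }
  invisible(x)
}
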