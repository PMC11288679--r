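#' Shannon entropy of a node's interaction-count vector
#'
#' Computed over the counts of interactions with every *other* colony
#' member, zeros included (zeros contribute nothing to the sum but do
#' define the vector). Natural log by default, so the maximum for n - 1
#' potential partners is ln(n - 1), attained only by a uniform spread
#' across all of them.
#'
#' @param counts nonnegative vector of length n - 1 (all other ants).
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return entropy; an all-zero vector yields 0 with attribute
#'   `isolated = TRUE`.
#' @export
node_entropy <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop_data("interaction counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) {
    h <- 0
    attr(h, "isolated") <- TRUE
    return(h)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = base))
}

#' Z-normalise values within groups
#'
#' Centres and scales to unit sample standard deviation within each group
#' (e.g. within colonies, so queen/worker positions are comparable across
#' colonies of different sizes and activity levels).
#'
#' @param values numeric vector.
#' @param group grouping vector (default: one group).
#' @return numeric vector of the same length.
#' @export
z_normalize <- function(values, group = rep(1L, length(values))) {
  out <- numeric(length(values))
  for (g in unique(group)) {
    idx <- group == g
    if (sum(idx) < 2) stop_data("z-normalisation needs >= 2 values per group")
    s <- sd(values[idx])
    if (s == 0) stop_data("degenerate group (sd = 0) in z-normalisation")
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Division of labour
#'
#' Colony-level division of labour measured as the sample standard
#' deviation across workers of the proportion of time spent outside the
#' nest. 0 means every worker foraged at the same rate; larger values
#' mean foraging is concentrated in a subset of workers. Queens must be
#' excluded by the caller.
#'
#' @param foraging_proportions per-worker foraging proportions in \[0, 1\].
#' @return scalar standard deviation.
#' @export
division_of_labour <- function(foraging_proportions) {
  if (length(foraging_proportions) < 2) {
    stop_data("division of labour requires >= 2 workers")
  }
  sd(foraging_proportions)
}

#' Maturity-distribution statistics
#'
#' Summarises how workers distribute across the two communities:
#' the fraction with intermediate maturity (strictly between 0.25 and
#' 0.75), the extremal counts above 0.9 and below 0.1, the high:low
#' imbalance \eqn{(n_{>0.9} - n_{<0.1}) / n_{<0.1}}, and a one-sample
#' proportions test (with continuity correction) of the intermediate
#' count against an even split.
#'
#' @param maturities worker maturities in \[0, 1\] (queen excluded).
#' @return list: `n`, `intermediate_count`, `intermediate_fraction`,
#'   `n_high` (> 0.9), `n_low` (< 0.1), `high_low_imbalance` (NA when
#'   `n_low` is 0), `prop_test_p`.
#' @export
maturity_distribution_stats <- function(maturities) {
  if (any(maturities < 0 | maturities > 1)) {
    stop_data("maturities must lie in [0, 1]")
  }
  n <- length(maturities)
  n_int <- sum(maturities > 0.25 & maturities < 0.75)
  n_high <- sum(maturities > 0.9)
  n_low <- sum(maturities < 0.1)
  imb <- if (n_low > 0) (n_high - n_low) / n_low else NA_real_
  p <- if (n > 0) prop.test(n_int, n, p = 0.5, correct = TRUE)$p.value
       else NA_real_
  list(n = n, intermediate_count = n_int, intermediate_fraction = n_int / n,
       n_high = n_high, n_low = n_low, high_low_imbalance = imb,
       prop_test_p = p)
}

#' Association between social maturity and (normalised) node strength
#'
#' Least-squares slope and Pearson correlation of z-normalised strength on
#' maturity within one colony. The per-ant table is what cross-colony
#' mixed models are fitted on; this helper gives the per-colony summary.
#'
#' @param maturity per-ant maturity values.
#' @param z_strength per-ant z-normalised strengths (same order).
#' @return list with `slope`, `r`, `p` (correlation test), `n`; all NA
#'   with `degenerate = TRUE` when maturity is constant.
#' @export
strength_maturity_association <- function(maturity, z_strength) {
  if (length(maturity) < 3) stop_data("association requires >= 3 ants")
  if (sd(maturity) == 0) {
    return(list(slope = NA_real_, r = NA_real_, p = NA_real_,
                n = length(maturity), degenerate = TRUE))
  }
  fit <- lm(z_strength ~ maturity)
  ct <- suppressWarnings(cor.test(maturity, z_strength))
  list(slope = unname(coef(fit)[2]), r = unname(ct$estimate),
       p = ct$p.value, n = length(maturity), degenerate = FALSE)
}
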