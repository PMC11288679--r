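#' Soft modularity of a membership matrix
#'
#' Generalises Newman-Girvan modularity to soft (probabilistic) community
#' memberships. With \eqn{W} the weight matrix, \eqn{s_i} node strengths,
#' \eqn{m} the total edge weight and \eqn{S} an n-by-k row-stochastic
#' membership matrix,
#' \deqn{Q = \sum_c \sum_{ij} \left[ \frac{W_{ij}}{2m} -
#'       \frac{s_i s_j}{(2m)^2} \right] S_{ic} S_{jc}.}
#' When S is binary this is exactly hard modularity.
#'
#' @param network a `weighted_network` with positive total weight.
#' @param S numeric n-by-k matrix; rows must sum to 1.
#' @return scalar soft modularity in \[-1, 1\].
#' @export
soft_modularity <- function(network, S) {
  S <- as.matrix(S)
  m <- total_weight(network)
  if (m <= 0) stop_data("modularity undefined: network has zero total weight")
  if (nrow(S) != n_nodes(network)) stop_data("membership rows must match nodes")
  if (max(abs(rowSums(S) - 1)) > 1e-6) stop_data("membership rows must sum to 1")
  p <- rowSums(network$W) / (2 * m)
  A <- network$W / (2 * m)
  sum(diag(t(S) %*% A %*% S)) - sum((t(S) %*% p)^2)
}

#' Fit soft communities by symmetric nonnegative factorisation
#'
#' Approximates the normalised weight matrix \eqn{\tilde W = W/(2m)} by
#' \eqn{X \Lambda X^T} (columns of X and \eqn{\Lambda} on the simplex)
#' using multiplicative KL-divergence updates — the static, single-snapshot
#' case of the soft community detection family used for insect interaction
#' networks. The soft membership matrix is the row-normalised
#' \eqn{X\Lambda}. The best of `n_restarts` random starts by soft
#' modularity is returned.
#'
#' @param network a `weighted_network` with m > 0.
#' @param k number of communities.
#' @param n_restarts random restarts (default 20).
#' @param tol absolute tolerance on the KL objective change (default 1e-6).
#' @param max_iter iteration cap per restart (default 500).
#' @param seed integer seed; the fit is deterministic given (network, seed).
#' @return a `soft_partition`: list with membership matrix `S` (rows are
#'   ants, rows sum to 1), `k`, `Q_soft`, `n_restarts`, `converged`, and
#'   the factor pair (`X`, `lambda`) of the winning restart.
#' @export
fit_soft_communities <- function(network, k, n_restarts = 20, tol = 1e-6,
                                 max_iter = 500, seed = NULL) {
  if (k < 1) stop_invalid("k must be >= 1")
  m <- total_weight(network)
  if (m <= 0) stop_data("cannot fit communities: zero total weight")
  n <- n_nodes(network)
  A <- network$W / (2 * m)

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      X0 <- matrix(rgamma(n * k, shape = 1), n, k)
      X0 <- sweep(X0, 2, colSums(X0), "/")
      lam0 <- rep(1 / k, k)
      fit <- facet_fit_cpp(A, X0, lam0, tol, max_iter)
      XL <- sweep(fit$X, 2, fit$lambda, "*")
      rs <- rowSums(XL)
      S <- XL
      zero <- rs <= 0
      S[!zero, ] <- XL[!zero, , drop = FALSE] / rs[!zero]
      if (any(zero)) S[zero, ] <- 1 / k
      Q <- soft_modularity(network, S)
      if (is.null(best) || Q > best$Q_soft) {
        best <- list(S = S, k = k, Q_soft = Q, n_restarts = n_restarts,
                     converged = isTRUE(fit$converged),
                     monotone = isTRUE(fit$monotone),
                     X = fit$X, lambda = as.numeric(fit$lambda),
                     isolated = zero)
      }
    }
    rownames(best$S) <- network$meta$ant_id
    if (!best$monotone) {
      warning("objective decreased during optimisation (numerical issue)")
    }
    if (!best$converged) {
      warning("soft community fit did not converge within max_iter")
    }
    class(best) <- "soft_partition"
    best
  })
}

#' @export
print.soft_partition <- function(x, ...) {
  cat(sprintf("<soft_partition> n=%d k=%d Q_soft=%.4f (converged: %s)\n",
              nrow(x$S), x$k, x$Q_soft, x$converged))
  invisible(x)
}

#' Best soft modularity for each candidate community number
#'
#' Fits soft communities for each k (same restart budget per k) and
#' reports the achieved soft modularity, mirroring the model-selection
#' step where the score is inspected for k = 2..5.
#'
#' @inheritParams fit_soft_communities
#' @param ks integer vector of community numbers (default 2:5).
#' @return list with `Q` (named numeric, one entry per k), `best_k`
#'   (argmax), and `partitions` (list of `soft_partition`s keyed by k).
#' @export
modularity_profile <- function(network, ks = 2:5, n_restarts = 20,
                               tol = 1e-6, max_iter = 500, seed = NULL) {
  with_seed(seed, {
    fits <- lapply(ks, function(k) {
      fit_soft_communities(network, k, n_restarts, tol, max_iter, seed = NULL)
    })
    Q <- vapply(fits, function(f) f$Q_soft, numeric(1))
    names(Q) <- as.character(ks)
    names(fits) <- as.character(ks)
    list(Q = Q, best_k = ks[which.max(Q)], partitions = fits)
  })
}

#' Permutation test of community structure against rewired nulls
#'
#' Compares the observed soft modularity at a given k against the
#' distribution over degree-preserving rewired replicas. The p-value uses
#' the standard add-one permutation estimator
#' \eqn{p = (1 + \#\{Q_{null} \ge Q_{obs}\}) / (n_{rewires} + 1)}.
#'
#' @inheritParams fit_soft_communities
#' @param k community number tested (default 2).
#' @param n_rewires number of rewired replicas (default 100).
#' @param n_restarts restarts per fit (observed and null alike).
#' @param n_swap_multiplier swaps per edge passed to [rewire()].
#' @return list with `Q_obs`, `Q_null` (numeric vector), `p`, and
#'   `degenerate` flag (TRUE means the network could not be rewired and
#'   p = 1 is returned with a warning).
#' @export
modularity_permutation_test <- function(network, k = 2, n_rewires = 100,
                                        n_restarts = 20, tol = 1e-6,
                                        max_iter = 500,
                                        n_swap_multiplier = 10, seed = NULL) {
  with_seed(seed, {
    obs <- fit_soft_communities(network, k, n_restarts, tol, max_iter,
                                seed = NULL)
    if (nrow(edge_list(network)) < 2) {
      warning("degenerate network: permutation test returns p = 1")
      return(list(Q_obs = obs$Q_soft, Q_null = numeric(0), p = 1,
                  degenerate = TRUE))
    }
    Q_null <- vapply(seq_len(n_rewires), function(b) {
      null_net <- rewire(network, n_swap_multiplier, seed = NULL)
      fit_soft_communities(null_net, k, n_restarts, tol, max_iter,
                           seed = NULL)$Q_soft
    }, numeric(1))
    p <- (1 + sum(Q_null >= obs$Q_soft)) / (n_rewires + 1)
    list(Q_obs = obs$Q_soft, Q_null = Q_null, p = p, degenerate = FALSE)
  })
}

#' Social maturity from a two-community soft partition
#'
#' The forager community is identified as the one the queen is *less*
#' affiliated with; an ant's social maturity is its membership weight in
#' that community (0 = deeply embedded in the nurse community, 1 = deeply
#' embedded in the forager community).
#'
#' @param partition a `soft_partition` with k = 2 whose membership rows
#'   are named by ant id.
#' @param queen_id ant id of the queen, or NA/NULL if the queen was
#'   excluded upstream.
#' @param foraging_proportion optional named per-ant vector; used only as
#'   the orientation fallback when no queen is available (the forager
#'   community is then the one with the higher mean foraging proportion).
#' @return named numeric vector of maturities in \[0, 1\] for every ant in
#'   the partition (queen included); attributes `forager_column` and
#'   `orientation` ("queen" or "foraging_fallback").
#' @export
social_maturity <- function(partition, queen_id = NULL,
                            foraging_proportion = NULL) {
  if (!inherits(partition, "soft_partition") || partition$k != 2) {
    stop_invalid("social maturity requires a k = 2 soft partition")
  }
  S <- partition$S
  ids <- rownames(S)
  have_queen <- !is.null(queen_id) && !is.na(queen_id)
  if (have_queen) {
    if (!queen_id %in% ids) stop_data("queen id not found in partition")
    qs <- S[queen_id, ]
    if (abs(qs[1] - qs[2]) < 1e-12) {
      stop_data("queen membership is exactly tied; cannot orient communities")
    }
    forager_col <- which.min(qs)
    orientation <- "queen"
  } else {
    if (is.null(foraging_proportion)) {
      stop_invalid("no queen and no foraging proportions: cannot orient")
    }
    fp <- foraging_proportion[ids]
    mu <- c(sum(S[, 1] * fp, na.rm = TRUE) / sum(S[, 1]),
            sum(S[, 2] * fp, na.rm = TRUE) / sum(S[, 2]))
    forager_col <- which.max(mu)
    orientation <- "foraging_fallback"
  }
  maturity <- S[, forager_col]
  names(maturity) <- ids
  attr(maturity, "forager_column") <- forager_col
  attr(maturity, "orientation") <- orientation
  maturity
}

#' Write a soft partition (plus maturity) as CSV
#'
#' @param partition a `soft_partition`.
#' @param path output path.
#' @param maturity optional named maturity vector to append.
#' @export
write_partition <- function(partition, path, maturity = NULL) {
  df <- data.frame(ant_id = rownames(partition$S))
  for (c in seq_len(partition$k)) {
    df[[paste0("membership_", c)]] <- partition$S[, c]
  }
  if (!is.null(maturity)) df$maturity <- as.numeric(maturity[df$ant_id])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
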