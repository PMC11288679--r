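# fixtures are built in code; no data files

# sparse Erdos-Renyi-like weighted network
er_network <- function(seed, n = 12, p = 0.4, lam = 2) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- rbinom(sum(ut), 1, p) * (1 + rpois(sum(ut), lam))
  W <- W + t(W)
  weighted_network(W)
}

# dense unstructured count matrix (every pair gets a Poisson weight)
dense_count_network <- function(seed, n = 100, lam = 5) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- rpois(sum(ut), lam)
  W <- W + t(W)
  weighted_network(W)
}

# binary membership matrix from labels
hard_S <- function(memb, k = max(memb)) {
  S <- matrix(0, length(memb), k)
  S[cbind(seq_along(memb), memb)] <- 1
  S
}

# minimal soft_partition for unit tests of downstream consumers
fake_partition <- function(S, ids = paste0("ant_", seq_len(nrow(S)))) {
  rownames(S) <- ids
  structure(list(S = S, k = ncol(S), Q_soft = NA_real_, n_restarts = 0,
                 converged = TRUE),
            class = "soft_partition")
}

# independent per-frame scan + explicit state machine for event segmentation
brute_force_events <- function(detections, capsules, max_gap_frames = 0) {
  frames <- sort(unique(detections$time_s))
  ids <- sort(unique(detections$ant_id))
  caplist <- split(capsules, capsules$ant_id)
  pairs <- combn(ids, 2)
  events <- list()
  counts <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    overlap <- logical(length(frames))
    for (t in seq_along(frames)) {
      ra <- detections[detections$time_s == frames[t] & detections$ant_id == a, ]
      rb <- detections[detections$time_s == frames[t] & detections$ant_id == b, ]
      if (nrow(ra) == 1 && nrow(rb) == 1) {
        overlap[t] <- capsules_intersect(
          c(ra$x, ra$y, ra$angle_rad), caplist[[a]][1, ],
          c(rb$x, rb$y, rb$angle_rad), caplist[[b]][1, ])
      }
    }
    # state machine with gap counter
    in_event <- FALSE; gap <- 0; start <- NA; last <- NA; nfr <- 0
    flush <- function() {
      events[[length(events) + 1]] <<- data.frame(
        ant_i = a, ant_j = b, start_s = frames[start], end_s = frames[last],
        n_frames = nfr, stringsAsFactors = FALSE)
      counts[a, b] <<- counts[a, b] + 1
      counts[b, a] <<- counts[b, a] + 1
    }
    for (t in seq_along(frames)) {
      if (overlap[t]) {
        if (!in_event) { in_event <- TRUE; start <- t; nfr <- 0 }
        last <- t; nfr <- nfr + 1; gap <- 0
      } else if (in_event) {
        gap <- gap + 1
        if (gap > max_gap_frames) { flush(); in_event <- FALSE; gap <- 0 }
      }
    }
    if (in_event) flush()
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ant_i = character(0), ant_j = character(0),
               start_s = numeric(0), end_s = numeric(0), n_frames = integer(0))
  ev <- ev[order(ev$start_s, ev$ant_i, ev$ant_j), , drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, counts = counts)
}

# prefix oracle for the 90% home range: tries all prefix sizes of the
# ranked hexagon list and returns the smallest that reaches coverage
oracle_home_range_size <- function(counts_df, coverage = 0.9) {
  tab <- counts_df[order(-counts_df$count, counts_df$q, counts_df$r), ]
  total <- sum(tab$count)
  for (k in seq_len(nrow(tab))) {
    if (sum(tab$count[seq_len(k)]) >= coverage * total) return(k)
  }
  nrow(tab)
}

# hexagons whose centres lie inside the arena (edge hexagons belong to the
# grid but their centres would be clamped if used as detection points)
interior_hexes <- function(grid) {
  h <- grid$hexes
  h[h$cx >= 0 & h$cx <= grid$width & h$cy >= 0 & h$cy <= grid$height, ]
}

# random detection table for IO / geometry tests
random_detections <- function(seed, n_ants = 5, n_frames = 20,
                              arena = c(10, 8)) {
  set.seed(seed)
  ids <- sprintf("a%02d", seq_len(n_ants))
  df <- expand.grid(time_s = seq_len(n_frames) - 1, ant_id = ids,
                    stringsAsFactors = FALSE)
  df$x <- runif(nrow(df), 0, arena[1])
  df$y <- runif(nrow(df), 0, arena[2])
  df$angle_rad <- runif(nrow(df), 0, 2 * pi)
  df$arena <- sample(c("nest", "forage"), nrow(df), replace = TRUE)
  df <- df[order(df$time_s, df$ant_id), c("time_s", "ant_id", "x", "y",
                                          "angle_rad", "arena")]
  rownames(df) <- NULL
  df
}
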