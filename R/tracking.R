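DETECTION_COLS <- c("time_s", "ant_id", "x", "y", "angle_rad", "arena")

#' Read / write detection records
#'
#' A detection record is one tag detection: time (seconds from experiment
#' start), ant id, position (body-length units), body orientation
#' (radians) and which box the ant was in (`nest` or `forage`).
#'
#' @param path CSV path with columns `time_s, ant_id, x, y, angle_rad,
#'   arena`.
#' @return data.frame of detection records, sorted by (time_s, ant_id).
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(DETECTION_COLS, names(df))
  if (length(missing) > 0) {
    stop_data("detection file missing column(s): ",
              paste(missing, collapse = ", "))
  }
  df <- df[, DETECTION_COLS]
  df$ant_id <- as.character(df$ant_id)
  validate_detections(df)
  df[order(df$time_s, df$ant_id), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

validate_detections <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$time_s < 0)) stop_data("negative detection times")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop_data("non-finite detection positions")
  }
  if (!all(df$arena %in% c("nest", "forage"))) {
    stop_data("arena must be 'nest' or 'forage'")
  }
  if (anyDuplicated(df[, c("time_s", "ant_id")]) > 0) {
    stop_data("duplicate (time_s, ant_id) detection rows")
  }
  invisible(df)
}

#' @rdname read_detections
#' @param detections data.frame of detection records.
#' @export
write_detections <- function(detections, path) {
  df <- as.data.frame(detections)[, DETECTION_COLS, drop = FALSE]
  df <- df[order(df$time_s, df$ant_id), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Capsule specifications
#'
#' The head capsule of an ant is a 2-D capsule (a segment with a radius)
#' placed along the body axis: the segment runs from `head_offset_start`
#' to `head_offset_end` body lengths ahead of the tag centre, in the
#' direction of the body orientation. Interactions are inferred from
#' head-capsule overlap. Defaults (segment from 0.3 to 0.5 body lengths,
#' radius 0.2) approximate an annotated head region.
#'
#' @param ant_id ant identifiers.
#' @param head_offset_start,head_offset_end signed offsets along the body
#'   axis (body lengths), start < end.
#' @param radius capsule radius (body lengths), > 0.
#' @return data.frame of capsule specs, one row per ant.
#' @export
capsule_spec <- function(ant_id, head_offset_start = 0.3,
                         head_offset_end = 0.5, radius = 0.2) {
  df <- data.frame(ant_id = as.character(ant_id),
                   head_offset_start = head_offset_start,
                   head_offset_end = head_offset_end,
                   radius = radius, stringsAsFactors = FALSE)
  if (any(df$radius <= 0)) stop_invalid("capsule radius must be > 0")
  if (any(df$head_offset_start >= df$head_offset_end)) {
    stop_invalid("capsule offset_start must be < offset_end")
  }
  df
}

#' @rdname capsule_spec
#' @param path CSV path (columns ant_id, head_offset_start,
#'   head_offset_end, radius).
#' @export
read_capsules <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  capsule_spec(df$ant_id, df$head_offset_start, df$head_offset_end, df$radius)
}

#' @rdname capsule_spec
#' @param capsules capsule spec data.frame.
#' @export
write_capsules <- function(capsules, path) {
  write.csv(capsules, path, row.names = FALSE)
  invisible(path)
}

# minimum distance between 2-D segments (p1,p2) and (q1,q2); vector args
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c_ <- sum(d1 * r)
    if (e <= eps) {
      t <- 0; s <- min(max(-c_ / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      denom <- a * e - b * b
      s <- if (denom > eps) min(max((b * f - c_ * e) / denom, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c_ / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c_) / a, 0), 1) }
    }
  }
  cp <- p1 + s * d1
  cq <- q1 + t * d2
  sqrt(sum((cp - cq)^2))
}

head_segment <- function(x, y, angle, cap) {
  u <- c(cos(angle), sin(angle))
  list(a = c(x, y) + cap$head_offset_start * u,
       b = c(x, y) + cap$head_offset_end * u)
}

#' Do two ants' head capsules intersect?
#'
#' True iff the minimum distance between the two head-capsule segments
#' (each placed by its ant's position and orientation) is at most the sum
#' of the two capsule radii (boundary contact counts as intersection).
#'
#' @param pose1,pose2 numeric length-3 vectors `c(x, y, angle_rad)`.
#' @param cap1,cap2 single-row capsule specs (see [capsule_spec()]).
#' @return logical.
#' @export
capsules_intersect <- function(pose1, cap1, pose2, cap2) {
  s1 <- head_segment(pose1[1], pose1[2], pose1[3], cap1)
  s2 <- head_segment(pose2[1], pose2[2], pose2[3], cap2)
  d <- segment_distance(s1$a, s1$b, s2$a, s2$b)
  d <= cap1$radius + cap2$radius + 1e-12
}

#' Detect pairwise interaction events from detections
#'
#' An interaction event for a pair is a maximal run of frames in which
#' their head capsules intersect, allowing interruptions of at most
#' `max_gap_frames` frames (default 0, no gap closing). Frames where
#' either ant is undetected count as non-overlap frames. The count matrix
#' records the number of *events* per pair.
#'
#' @param detections detection records (one row per frame and ant).
#' @param capsules capsule specs covering every ant in `detections`.
#' @param max_gap_frames maximum tolerated interruption within one event.
#' @return list with `events` (data.frame: ant_i, ant_j with i < j by id
#'   order, start_s, end_s, n_frames) and `counts` (symmetric matrix of
#'   event counts over all ants in `detections`).
#' @export
detect_interactions <- function(detections, capsules, max_gap_frames = 0) {
  validate_detections(detections)
  ids <- sort(unique(detections$ant_id))
  unknown <- setdiff(ids, capsules$ant_id)
  if (length(unknown) > 0) {
    stop_invalid("ants without capsule specs: ", paste(unknown, collapse = ", "))
  }
  frames <- sort(unique(detections$time_s))
  fidx <- match(detections$time_s, frames)
  caplist <- split(capsules, capsules$ant_id)

  # per-frame pairwise overlap scan
  overlaps <- list()
  by_frame <- split(seq_len(nrow(detections)), fidx)
  for (f in names(by_frame)) {
    rows <- by_frame[[f]]
    if (length(rows) < 2) next
    sub <- detections[rows, , drop = FALSE]
    segs <- lapply(seq_len(nrow(sub)), function(i) {
      head_segment(sub$x[i], sub$y[i], sub$angle_rad[i],
                   caplist[[sub$ant_id[i]]][1, ])
    })
    radii <- vapply(sub$ant_id, function(a) caplist[[a]]$radius[1], numeric(1))
    for (i in seq_len(nrow(sub) - 1)) {
      for (j in seq((i + 1), nrow(sub))) {
        d <- segment_distance(segs[[i]]$a, segs[[i]]$b,
                              segs[[j]]$a, segs[[j]]$b)
        if (d <= radii[i] + radii[j] + 1e-12) {
          pr <- sort(c(sub$ant_id[i], sub$ant_id[j]))
          key <- paste(pr[1], pr[2], sep = "\r")
          overlaps[[key]] <- c(overlaps[[key]], as.integer(f))
        }
      }
    }
  }

  counts <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ev <- list()
  for (key in names(overlaps)) {
    pr <- strsplit(key, "\r", fixed = TRUE)[[1]]
    fr <- sort(overlaps[[key]])
    # split runs where the interruption exceeds max_gap_frames
    brk <- c(0, which(diff(fr) > max_gap_frames + 1), length(fr))
    for (b in seq_len(length(brk) - 1)) {
      run <- fr[(brk[b] + 1):brk[b + 1]]
      ev[[length(ev) + 1]] <- data.frame(
        ant_i = pr[1], ant_j = pr[2],
        start_s = frames[run[1]], end_s = frames[run[length(run)]],
        n_frames = length(run), stringsAsFactors = FALSE)
    }
    n_events <- length(brk) - 1
    counts[pr[1], pr[2]] <- counts[pr[1], pr[2]] + n_events
    counts[pr[2], pr[1]] <- counts[pr[2], pr[1]] + n_events
  }
  events <- if (length(ev) > 0) {
    out <- do.call(rbind, ev)
    out[order(out$start_s, out$ant_i, out$ant_j), , drop = FALSE]
  } else {
    data.frame(ant_i = character(0), ant_j = character(0),
               start_s = numeric(0), end_s = numeric(0),
               n_frames = integer(0))
  }
  rownames(events) <- NULL
  list(events = events, counts = counts)
}

#' Write / read interaction events CSV
#'
#' @param events events data.frame from [detect_interactions()].
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ant_i", "ant_j", "start_s", "end_s", "n_frames")
  if (!all(need %in% names(df))) {
    stop_data("event file must have columns ", paste(need, collapse = ", "))
  }
  df$ant_i <- as.character(df$ant_i)
  df$ant_j <- as.character(df$ant_j)
  df
}

#' Per-ant proportion of time spent in the foraging box
#'
#' @param detections detection records.
#' @return named numeric vector: fraction of each ant's detections with
#'   `arena == "forage"`.
#' @export
foraging_proportion <- function(detections) {
  if (nrow(detections) == 0) {
    warning("no detections; empty foraging proportions")
    return(setNames(numeric(0), character(0)))
  }
  tab <- tapply(detections$arena == "forage", detections$ant_id, mean)
  ids <- sort(unique(detections$ant_id))
  setNames(as.numeric(tab[ids]), ids)
}

#' Exclude ants with anomalously low detection counts
#'
#' Ants detected less than 2 sample standard deviations below the colony
#' mean detection count are excluded from all analyses (the queen is
#' subject to the same rule).
#'
#' @param detection_counts named per-ant detection counts.
#' @param n_sd threshold multiplier (default 2).
#' @return character vector of excluded ant ids (possibly empty).
#' @export
low_detection_filter <- function(detection_counts, n_sd = 2) {
  if (length(detection_counts) < 2) {
    stop_data("low-detection filter requires >= 2 ants")
  }
  threshold <- mean(detection_counts) - n_sd * sd(detection_counts)
  names(detection_counts)[detection_counts < threshold]
}
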