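#' Bin queen-worker interaction events into hours
#'
#' Each event is assigned to the hour containing its start time (hours are
#' experiment-relative, starting at t = 0). The result records, per hour,
#' which workers the queen contacted and how many events each had.
#'
#' @param events events data.frame (see [detect_interactions()]).
#' @param queen_id the queen's ant id.
#' @param hour_length_s seconds per hour bin (default 3600).
#' @param n_hours optional total number of hours; defaults to the hour of
#'   the last event + 1. Hours with no events are kept as empty bins.
#' @return an `hourly_contacts`: list of named integer vectors (worker ->
#'   event count), one per hour from hour 0; attribute `no_events` is TRUE
#'   when the queen had no events at all.
#' @export
bin_queen_contacts <- function(events, queen_id, hour_length_s = 3600,
                               n_hours = NULL) {
  if (hour_length_s <= 0) stop_invalid("hour_length_s must be > 0")
  qe <- events[events$ant_i == queen_id | events$ant_j == queen_id, ,
               drop = FALSE]
  if (nrow(qe) == 0) {
    out <- rep(list(integer(0)), max(1, n_hours %||% 1))
    attr(out, "no_events") <- TRUE
    class(out) <- "hourly_contacts"
    return(out)
  }
  partner <- ifelse(qe$ant_i == queen_id, qe$ant_j, qe$ant_i)
  hour <- floor(qe$start_s / hour_length_s)
  H <- n_hours %||% (max(hour) + 1)
  out <- lapply(seq_len(H) - 1, function(h) {
    idx <- hour == h
    if (!any(idx)) return(integer(0))
    tab <- table(partner[idx])
    setNames(as.integer(tab), names(tab))
  })
  attr(out, "no_events") <- FALSE
  class(out) <- "hourly_contacts"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean proportion of the workforce contacted per hour
#'
#' Hours in which the queen contacted nobody contribute 0 to the mean.
#'
#' @param hc an `hourly_contacts`.
#' @param n_workers workforce size.
#' @return mean over hours of (distinct workers contacted) / n_workers.
#' @export
workers_per_hour <- function(hc, n_workers) {
  if (length(hc) < 1) stop_data("need >= 1 hour")
  mean(vapply(hc, length, integer(1)) / n_workers)
}

#' Mean interactions per contacted worker per hour
#'
#' Averages the event count over all (hour, worker) pairs with at least
#' one contact; zeros never enter the mean.
#'
#' @param hc an `hourly_contacts`.
#' @return mean count; NA with flag attribute if there were no contacts.
#' @export
contacts_per_worker_per_hour <- function(hc) {
  counts <- unlist(hc, use.names = FALSE)
  if (length(counts) == 0) {
    out <- NA_real_
    attr(out, "no_contacts") <- TRUE
    return(out)
  }
  mean(counts)
}

#' Hour-to-hour conservation of contacted-worker identity
#'
#' For each hour t >= 1, the fraction of hour t-1's contact partners that
#' were contacted again in hour t; the statistic is the mean over hours.
#' Hours whose predecessor set is empty are skipped.
#'
#' @param hc an `hourly_contacts` with >= 2 hours.
#' @return mean conservation in \[0, 1\]; NA with flag attribute when every
#'   predecessor hour is empty.
#' @export
identity_conservation <- function(hc) {
  if (length(hc) < 2) stop_data("identity conservation requires >= 2 hours")
  vals <- numeric(0)
  for (t in 2:length(hc)) {
    prev <- names(hc[[t - 1]])
    if (length(prev) == 0) next
    vals <- c(vals, length(intersect(names(hc[[t]]), prev)) / length(prev))
  }
  if (length(vals) == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mean(vals)
}

#' Queen encounter-kinetics summary
#'
#' @param hc an `hourly_contacts`.
#' @param n_workers workforce size.
#' @return list with `workers_per_hour`, `contacts_per_worker_per_hour`,
#'   `identity_conservation`.
#' @export
queen_kinetics <- function(hc, n_workers) {
  list(workers_per_hour = workers_per_hour(hc, n_workers),
       contacts_per_worker_per_hour =
         as.numeric(contacts_per_worker_per_hour(hc)),
       identity_conservation =
         if (length(hc) >= 2) as.numeric(identity_conservation(hc))
         else NA_real_)
}
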