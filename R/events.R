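#' Aggregate overlapping attempts on each candidate follower into events
#'
#' Retained attempts targeting the same candidate follower are merged by a
#' chain rule over their \[t1, t3\] intervals: if A overlaps B and B
#' overlaps C, all three form one event regardless of whether A overlaps C
#' (connected components of the interval-overlap graph). Events overlapping
#' any second where the coverage mask is false are dropped entirely.
#'
#' @param attempts data.frame from [extract_attempts()]; rejected rows are
#'   ignored.
#' @param grid optional [trajectory_grid()]; required with `min_coverage`.
#' @param min_coverage optional tracked-fraction threshold (e.g. 0.5 or
#'   0.8) used to build the coverage mask.
#' @return object of class `event_set`: list with `events` (one row per
#'   event: event_id, follower, t_start, t_end, n_initiators, n_attempts,
#'   success, duration_min) and `attempts` (retained attempts with their
#'   event_id). `success` is true iff at least one attempt in the event is
#'   a pull.
#' @export
build_events <- function(attempts, grid = NULL, min_coverage = NULL) {
  at <- attempts_retained(attempts)
  at$event_id <- NA_integer_
  ev_rows <- list()
  eid <- 0L
  for (fol in sort(unique(at$follower))) {
    sel <- which(at$follower == fol)
    sel <- sel[order(at$t1[sel], at$t3[sel])]
    comp_end <- -Inf
    comp_members <- integer(0)
    flush <- function(members) {
      if (!length(members)) return(invisible(NULL))
      eid <<- eid + 1L
      at$event_id[members] <<- eid
      ev_rows[[eid]] <<- data.frame(
        event_id = eid, follower = fol,
        t_start = min(at$t1[members]), t_end = max(at$t3[members]),
        n_initiators = length(unique(at$initiator[members])),
        n_attempts = length(members),
        success = any(at$outcome[members] == "pull"),
        stringsAsFactors = FALSE)
      invisible(NULL)
    }
    for (i in sel) {
      # strict overlap: consecutive attempts on one dyad share the minimum
      # between them, and a shared endpoint alone must not chain them
      if (at$t1[i] >= comp_end) {         # disjoint from current component
        flush(comp_members)
        comp_members <- i
        comp_end <- at$t3[i]
      } else {
        comp_members <- c(comp_members, i)
        comp_end <- max(comp_end, at$t3[i])
      }
    }
    flush(comp_members)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(event_id = integer(0), follower = character(0),
               t_start = integer(0), t_end = integer(0),
               n_initiators = integer(0), n_attempts = integer(0),
               success = logical(0))
  dropped_coverage <- 0L
  if (!is.null(min_coverage)) {
    stopifnot(!is.null(grid))
    mask <- coverage_mask(grid, min_coverage)
    bad_t <- grid$times[!mask]
    if (length(bad_t) && nrow(events)) {
      overlaps <- vapply(seq_len(nrow(events)), function(i) {
        any(bad_t >= events$t_start[i] & bad_t <= events$t_end[i])
      }, logical(1))
      dropped_coverage <- sum(overlaps)
      drop_ids <- events$event_id[overlaps]
      events <- events[!overlaps, , drop = FALSE]
      at <- at[!(at$event_id %in% drop_ids), , drop = FALSE]
    }
  }
  events$duration_min <- (events$t_end - events$t_start) / 60
  structure(list(events = events, attempts = at,
                 dropped_coverage = dropped_coverage),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("event_set: %d events from %d attempts (%d follower(s); %.0f%% successful)\n",
              nrow(x$events), nrow(x$attempts), length(unique(x$events$follower)),
              if (nrow(x$events)) 100 * mean(x$events$success) else 0))
  invisible(x)
}

#' Directional agreement of co-initiators
#'
#' One minus the circular variance of the initiators' unit vectors, which
#' equals the mean resultant length: 1 when all vectors are perfectly
#' aligned, 0 when they are balanced over opposing directions.
#'
#' @param angles initiator directions in radians (>= 1).
#' @return scalar in \[0, 1\].
#' @export
agreement <- function(angles) {
  if (!length(angles)) stop("agreement: no angles supplied")
  resultant_length(angles)
}

#' Per-initiator directions for one event
#'
#' For each initiator the angle of the vector from the follower's position
#' at the attempt's t1 to the initiator's position at its t2 (the
#' maximal-separation geometry); with `reference = "t2_t2"` both positions
#' are taken at t2. An initiator with several attempts in an event
#' contributes its most recent attempt (one vector per initiator).
#' Zero-length vectors drop that initiator with a message.
#'
#' @param grid a [trajectory_grid()].
#' @param event_set an `event_set`.
#' @param event_id the event.
#' @param reference "t1_t2" (default) or "t2_t2".
#' @return named numeric vector of angles (radians) per initiator id.
#' @export
initiator_directions <- function(grid, event_set, event_id,
                                 reference = c("t1_t2", "t2_t2")) {
  reference <- match.arg(reference)
  at <- event_set$attempts
  at <- at[at$event_id == event_id, , drop = FALSE]
  stopifnot(nrow(at) > 0)
  fol <- at$follower[1]
  fi <- match(fol, grid$ids)
  out <- numeric(0)
  for (init in unique(at$initiator)) {
    rows <- at[at$initiator == init, , drop = FALSE]
    r <- rows[which.max(rows$t1), ]                 # most recent attempt
    t_fol <- if (reference == "t1_t2") r$t1 else r$t2
    cf <- match(t_fol, grid$times); ci <- match(r$t2, grid$times)
    dx <- grid$x[match(init, grid$ids), ci] - grid$x[fi, cf]
    dy <- grid$y[match(init, grid$ids), ci] - grid$y[fi, cf]
    if (is.na(dx) || (dx == 0 && dy == 0)) {
      message(sprintf("initiator_directions: zero-length vector, dropping initiator %s in event %d",
                      init, event_id))
      next
    }
    out[init] <- atan2(dy, dx)
  }
  out
}

#' Direction of the follower's movement in a successful event
#'
#' Angle of the follower's net displacement from its position at the end
#' of the earliest pull's maximal-separation plateau (t2_end) to its
#' position at that pull's t3 (the closing movement).
#'
#' @param grid a [trajectory_grid()].
#' @param event_set an `event_set`.
#' @param event_id id of a successful event (error otherwise).
#' @return angle in radians, or `NA` (with a message) for zero net
#'   displacement; such events are excluded downstream.
#' @export
follower_direction <- function(grid, event_set, event_id) {
  at <- event_set$attempts
  at <- at[at$event_id == event_id & at$outcome == "pull", , drop = FALSE]
  if (!nrow(at)) stop("follower_direction: event has no pull (unsuccessful)")
  r <- at[which.min(at$t2), ]                        # earliest pull
  fi <- match(r$follower, grid$ids)
  c2 <- match(r$t2_end, grid$times); c3 <- match(r$t3, grid$times)
  dx <- grid$x[fi, c3] - grid$x[fi, c2]
  dy <- grid$y[fi, c3] - grid$y[fi, c2]
  if (is.na(dx) || (dx == 0 && dy == 0)) {
    message(sprintf("follower_direction: zero net displacement in event %d", event_id))
    return(NA_real_)
  }
  atan2(dy, dx)
}

#' Attach directions, agreement and follower direction to events
#'
#' @param grid a [trajectory_grid()].
#' @param event_set an `event_set` from [build_events()].
#' @param reference direction reference, see [initiator_directions()].
#' @return the `event_set` with `events` gaining `agreement`,
#'   `follower_direction` (radians, NA when not pulled or degenerate),
#'   `n_pullers`, and a `directions` list column of per-initiator angles.
#' @export
event_metrics <- function(grid, event_set, reference = "t1_t2") {
  ev <- event_set$events
  n <- nrow(ev)
  dirs <- vector("list", n)
  agr <- rep(NA_real_, n)
  fdir <- rep(NA_real_, n)
  npull <- integer(n)
  for (i in seq_len(n)) {
    d <- initiator_directions(grid, event_set, ev$event_id[i], reference)
    dirs[[i]] <- d
    if (length(d)) agr[i] <- agreement(d)
    at_i <- event_set$attempts[event_set$attempts$event_id == ev$event_id[i], ]
    npull[i] <- length(unique(at_i$initiator[at_i$outcome == "pull"]))
    if (ev$success[i]) {
      fdir[i] <- follower_direction(grid, event_set, ev$event_id[i])
    }
  }
  ev$agreement <- agr
  ev$follower_direction <- fdir
  ev$n_pullers <- npull
  ev$directions <- I(dirs)
  event_set$events <- ev
  event_set
}

#' Duration and composition summary of an event set
#'
#' @param event_set an `event_set`.
#' @return list with mean/SD of attempt durations and event durations (in
#'   minutes) and the fraction of events with exactly two initiators.
#' @export
event_summary <- function(event_set) {
  at <- event_set$attempts
  ev <- event_set$events
  att_min <- (at$t3 - at$t1) / 60
  list(attempt_duration_mean = mean(att_min),
       attempt_duration_sd = stats::sd(att_min),
       event_duration_mean = mean(ev$duration_min),
       event_duration_sd = stats::sd(ev$duration_min),
       frac_two_initiators = if (nrow(ev)) mean(ev$n_initiators == 2) else NA_real_,
       n_events = nrow(ev), n_attempts = nrow(at))
}

#' Write the events table with directions JSON-encoded
#' @param event_set an `event_set` processed by [event_metrics()].
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_events <- function(event_set, path) {
  ev <- event_set$events
  df <- ev[, setdiff(names(ev), "directions")]
  df$follower_direction_deg <- ev$follower_direction * 180 / pi
  df$initiators <- vapply(ev$directions, function(d) {
    as.character(jsonlite::toJSON(as.list(round(d * 180 / pi, 3)), auto_unbox = TRUE))
  }, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
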