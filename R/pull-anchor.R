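#' Dyadic distance series
#'
#' Euclidean planar distance between two individuals at every second where
#' both have a (possibly interpolated) fix.
#'
#' @param grid a [trajectory_grid()].
#' @param id_a,id_b individual ids present in the grid.
#' @return data.frame with columns `t` and `d` (metres), `d` missing where
#'   either position is missing.
#' @export
dyadic_distance <- function(grid, id_a, id_b) {
  ia <- match(id_a, grid$ids); ib <- match(id_b, grid$ids)
  stopifnot(!is.na(ia), !is.na(ib))
  d <- sqrt((grid$x[ia, ] - grid$x[ib, ])^2 + (grid$y[ia, ] - grid$y[ib, ])^2)
  data.frame(t = grid$times, d = as.numeric(d))
}

#' Alternating minima/maxima of a distance series
#'
#' Reversal ("zigzag") filter: an extremum is emitted once the series has
#' moved more than `min_change` away from the running extremum in the
#' opposite sense, giving a strictly alternating min/max sequence in which
#' consecutive extrema differ by more than `min_change`. First and last
#' samples are eligible boundary extrema. Missing samples are skipped.
#'
#' Near-extremal plateaus (the distance sitting within `plateau_slack` of
#' the extremal value, e.g. a stationary dyad between initiations) are
#' resolved to an interval: `t_first` is the first sample after the
#' previous extremum within slack of the extremal value, `t_last` the last
#' such sample before the next extremum. Downstream, an initiation's start
#' is the near side of the preceding minimum plateau (`t_last`) and its
#' end the first arrival at the following minimum (`t_first`), so that
#' displacement windows bracket the actual movement rather than an
#' arbitrary tie-broken sample of a flat stretch. The slack defaults to
#' the reversal threshold itself: by the filter's own semantics a change
#' smaller than `min_change` does not count as movement.
#'
#' @param series data.frame from [dyadic_distance()] (columns `t`, `d`).
#' @param min_change reversal threshold in metres (> 0); 3.5 by default.
#' @param plateau_slack tolerance (m) for the plateau interval.
#' @return data.frame with `t` (extremal sample), `t_first`, `t_last`,
#'   `d` (the extremal value), `type` ("min"/"max"); empty if fewer than 3
#'   non-missing samples.
#' @export
find_extrema <- function(series, min_change = 3.5, plateau_slack = min_change) {
  stopifnot(min_change > 0)
  keep <- !is.na(series$d)
  t <- series$t[keep]; d <- series$d[keep]
  empty <- data.frame(t = integer(0), t_first = integer(0),
                      t_last = integer(0), d = numeric(0),
                      type = character(0))
  if (length(d) < 3) return(empty)
  z <- zigzag_cpp(d, min_change)
  m <- length(z$index)
  if (!m) return(empty)
  t_first <- integer(m); t_last <- integer(m)
  for (j in seq_len(m)) {
    i <- z$index[j]
    lo <- if (j == 1) 1L else z$index[j - 1]
    hi <- if (j == m) length(d) else z$index[j + 1]
    near <- if (z$type[j] < 0) d[lo:hi] <= d[i] + plateau_slack
            else d[lo:hi] >= d[i] - plateau_slack
    t_first[j] <- lo + which(near)[1] - 1L
    t_last[j] <- lo + which(near)[sum(near)] - 1L
  }
  data.frame(t = t[z$index], t_first = t[t_first], t_last = t[t_last],
             d = d[z$index], type = ifelse(z$type > 0, "max", "min"))
}

.default_thresholds <- function() {
  list(min_change = 3.5, disparity = 0.1, strength = 0.1)
}

.net_displacement <- function(grid, i, t_from, t_to) {
  c1 <- match(t_from, grid$times); c2 <- match(t_to, grid$times)
  sqrt((grid$x[i, c2] - grid$x[i, c1])^2 + (grid$y[i, c2] - grid$y[i, c1])^2)
}

#' Classify a (min, max, min) distance triple as a pull or anchor attempt
#'
#' The individual with the larger net displacement over \[t1, t2\] is the
#' initiator (it moved away). If over \[t2, t3\] the candidate follower
#' contributed the larger displacement (it closed the gap), the outcome is
#' a pull; if the initiator did (it came back), an anchor. Displacements
#' are net Euclidean (robust to GPS jitter, unlike path length).
#'
#' Disparity is the geometric mean over the two segments of
#' |da - db| / (da + db): 0 when both individuals moved equally, 1 when a
#' single individual did all of the moving. Strength is the geometric mean
#' of (d2 - d1)/d2 and (d2 - d3)/d2: near 0 for small changes relative to
#' the dyadic distance, 1 for changes spanning the full distance. Retained
#' attempts need min(d2 - d1, d2 - d3) > `min_change`, disparity and
#' strength at or above their thresholds; otherwise `reject_reason` is set.
#'
#' @param grid a [trajectory_grid()].
#' @param id_a,id_b the dyad.
#' @param t1,t2,t3 times of the extrema (t1 < t2 < t3; t2 the maximum).
#' @param t2_end optional end of the near-maximum plateau (defaults to
#'   t2): the second displacement segment is measured from `t2_end` to
#'   `t3` so that a pause at maximal separation is not charged to either
#'   individual.
#' @param d1,d2,d3 optional extremal dyadic distances; when the times come
#'   from plateau edges the true extrema can sit inside the plateaus, so
#'   [extract_attempts()] passes the extremal values here. Default:
#'   distances evaluated at t1, t2, t3.
#' @param thresholds list with `min_change` (m), `disparity`, `strength`.
#' @return one-row data.frame: initiator, follower, t1..t3, t2_end,
#'   d1..d3, min_change, disparity, strength, outcome ("pull"/"anchor"),
#'   reject_reason (NA if retained).
#' @export
classify_attempt <- function(grid, id_a, id_b, t1, t2, t3, t2_end = t2,
                             d1 = NULL, d2 = NULL, d3 = NULL,
                             thresholds = .default_thresholds()) {
  ia <- match(id_a, grid$ids); ib <- match(id_b, grid$ids)
  row <- function(initiator = NA_character_, follower = NA_character_,
                  outcome = NA_character_, disparity = NA_real_,
                  strength = NA_real_, min_change = NA_real_,
                  d1 = NA_real_, d2 = NA_real_, d3 = NA_real_,
                  reject = NA_character_) {
    data.frame(initiator = initiator, follower = follower,
               t1 = t1, t2 = t2, t2_end = t2_end, t3 = t3,
               d1 = d1, d2 = d2, d3 = d3,
               min_change = min_change, disparity = disparity,
               strength = strength, outcome = outcome,
               reject_reason = reject, stringsAsFactors = FALSE)
  }
  cols <- match(c(t1, t2, t3, t2_end), grid$times)
  if (anyNA(cols) ||
      anyNA(grid$x[ia, cols]) || anyNA(grid$x[ib, cols])) {
    return(row(reject = "missing_fix"))
  }
  d <- sqrt((grid$x[ia, cols] - grid$x[ib, cols])^2 +
            (grid$y[ia, cols] - grid$y[ib, cols])^2)
  if (is.null(d1)) d1 <- d[1]
  if (is.null(d2)) d2 <- d[2]
  if (is.null(d3)) d3 <- d[3]
  mc <- min(d2 - d1, d2 - d3)
  da1 <- .net_displacement(grid, ia, t1, t2); db1 <- .net_displacement(grid, ib, t1, t2)
  da2 <- .net_displacement(grid, ia, t2_end, t3); db2 <- .net_displacement(grid, ib, t2_end, t3)
  if (da1 == db1 || da2 == db2) {
    return(row(d1 = d1, d2 = d2, d3 = d3, min_change = mc, reject = "tie"))
  }
  if (da1 > db1) {
    init_id <- id_a; fol_id <- id_b
    init_seg2 <- da2; fol_seg2 <- db2
  } else {
    init_id <- id_b; fol_id <- id_a
    init_seg2 <- db2; fol_seg2 <- da2
  }
  outcome <- if (fol_seg2 > init_seg2) "pull" else "anchor"
  disp_seg <- function(a, b) if (a + b == 0) 0 else abs(a - b) / (a + b)
  disparity <- sqrt(disp_seg(da1, db1) * disp_seg(da2, db2))
  strength <- if (d2 <= 0) 0 else sqrt(max(d2 - d1, 0) * max(d2 - d3, 0)) / d2
  reject <- NA_character_
  if (mc <= thresholds$min_change) reject <- "min_change"
  else if (disparity < thresholds$disparity) reject <- "disparity"
  else if (strength < thresholds$strength) reject <- "strength"
  row(initiator = init_id, follower = fol_id, outcome = outcome,
      disparity = disparity, strength = strength, min_change = mc,
      d1 = d1, d2 = d2, d3 = d3, reject = reject)
}

#' Extract all candidate initiation attempts from a grid
#'
#' Scans every unordered dyad: computes the dyadic distance series, finds
#' alternating extrema with the `min_change` reversal filter, and
#' classifies every (min, max, min) triple. Rows are ordered by t1, then
#' initiator and follower ids. Rejected candidates are kept with their
#' `reject_reason`; filter with [attempts_retained()].
#'
#' @param grid a [trajectory_grid()].
#' @param thresholds list with `min_change`, `disparity`, `strength`
#'   (defaults 3.5 m, 0.1, 0.1).
#' @return data.frame of attempts (see [classify_attempt()]).
#' @export
extract_attempts <- function(grid, thresholds = .default_thresholds()) {
  ids <- grid$ids
  out <- list()
  if (length(ids) >= 2) {
    for (a in seq_len(length(ids) - 1)) {
      for (b in seq((a + 1), length(ids))) {
        ser <- dyadic_distance(grid, ids[a], ids[b])
        ex <- find_extrema(ser, thresholds$min_change)
        if (nrow(ex) < 3) next
        for (s in seq_len(nrow(ex) - 2)) {
          if (ex$type[s] == "min" && ex$type[s + 1] == "max" &&
              ex$type[s + 2] == "min") {
            t1 <- ex$t_last[s]; t2a <- ex$t_first[s + 1]
            t2b <- ex$t_last[s + 1]; t3 <- ex$t_first[s + 2]
            # for marginal amplitudes the slack bands can overlap; fall
            # back to the extremal samples to keep the windows ordered
            if (t1 >= t2a) { t1 <- ex$t[s]; t2a <- ex$t[s + 1] }
            if (t2b >= t3) { t2b <- ex$t[s + 1]; t3 <- ex$t[s + 2] }
            out[[length(out) + 1L]] <-
              classify_attempt(grid, ids[a], ids[b],
                               t1 = t1, t2 = t2a, t3 = t3, t2_end = t2b,
                               d1 = ex$d[s], d2 = ex$d[s + 1],
                               d3 = ex$d[s + 2],
                               thresholds = thresholds)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(initiator = character(0), follower = character(0),
                      t1 = integer(0), t2 = integer(0), t2_end = integer(0),
                      t3 = integer(0),
                      d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
                      min_change = numeric(0), disparity = numeric(0),
                      strength = numeric(0), outcome = character(0),
                      reject_reason = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$t1, res$initiator, res$follower), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Retained attempts (all thresholds passed)
#' @param attempts data.frame from [extract_attempts()].
#' @return subset with `reject_reason` missing.
#' @export
attempts_retained <- function(attempts) {
  attempts[is.na(attempts$reject_reason), , drop = FALSE]
}
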