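#' Dyadic influence matrix and influence ranks
#'
#' `P[i, j]` counts the events in which individual i pulled individual j
#' (once per event, however many pull attempts i contributed to it). The
#' influence index is `I[i, j] = (P[i, j] - P[j, i]) / (P[i, j] + P[j, i])`,
#' ranging from -1 (j pulled in all events) to 1 (i pulled in all events),
#' 0 meaning no difference; it is undefined (NA) for dyads with no events,
#' and such dyads are excluded from row sums rather than imputed as 0.
#' Influence ranks order individuals by the row sums of I (rank 1 = most
#' influential), average ranks on ties.
#'
#' @param event_set an `event_set` (ids taken from its attempts) or the
#'   attempts data.frame with an `event_id` column.
#' @param ids optional id universe (e.g. all group members); defaults to
#'   ids appearing in the attempts.
#' @return list with `P`, `I`, `row_sum`, `influence_rank`.
#' @export
influence_matrix <- function(event_set, ids = NULL) {
  at <- if (inherits(event_set, "event_set")) event_set$attempts else event_set
  stopifnot("event_id" %in% names(at))
  pulls <- at[at$outcome == "pull" & !is.na(at$event_id), , drop = FALSE]
  pulls <- unique(pulls[, c("event_id", "initiator", "follower")])
  if (is.null(ids)) ids <- sort(unique(c(at$initiator, at$follower)))
  n <- length(ids)
  P <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(pulls)) {
    tab <- table(factor(pulls$initiator, ids), factor(pulls$follower, ids))
    P <- P + unclass(tab)
  }
  tot <- P + t(P)
  I <- (P - t(P)) / tot
  I[tot == 0] <- NA_real_
  diag(I) <- NA_real_
  row_sum <- rowSums(I, na.rm = TRUE)
  defined <- rowSums(!is.na(I)) > 0
  row_sum[!defined] <- NA_real_
  influence_rank <- rank(-row_sum, ties.method = "average", na.last = "keep")
  list(P = P, I = I, row_sum = row_sum, influence_rank = influence_rank)
}

#' Successful initiation rates per tracked hour
#'
#' Number of events in which each individual pulled someone, divided by
#' that individual's tracked hours (seconds with a non-missing fix /
#' 3600), since tags differ in uptime. Set `denominator = "calendar"` to
#' divide instead by the grid's total span.
#'
#' @param event_set an `event_set`.
#' @param grid the [trajectory_grid()] the events came from (or a list of
#'   grids whose tracked seconds are summed).
#' @param denominator "tracked" (default) or "calendar".
#' @return data.frame with id, n_pull_events, hours, rate_per_hour, and
#'   rate_rank (1 = highest rate).
#' @export
initiation_rates <- function(event_set, grid, denominator = c("tracked", "calendar")) {
  denominator <- match.arg(denominator)
  grids <- if (inherits(grid, "trajectory_grid")) list(grid) else grid
  ids <- sort(unique(unlist(lapply(grids, `[[`, "ids"))))
  secs <- setNames(numeric(length(ids)), ids)
  for (g in grids) {
    present <- rowSums(!is.na(g$x))
    if (denominator == "calendar") present <- rep(length(g$times), length(g$ids))
    secs[g$ids] <- secs[g$ids] + present
  }
  pulls <- event_set$attempts
  pulls <- pulls[pulls$outcome == "pull", , drop = FALSE]
  pulls <- unique(pulls[, c("event_id", "initiator")])
  n_pull <- table(factor(pulls$initiator, ids))
  rate <- as.numeric(n_pull) / (secs / 3600)
  data.frame(id = ids, n_pull_events = as.integer(n_pull),
             hours = as.numeric(secs) / 3600, rate_per_hour = rate,
             rate_rank = rank(-rate, ties.method = "average"))
}

# --- dominance -------------------------------------------------------------

#' Sequential Elo scores
#'
#' Winner gains `K * (1 - expected)` where the expected score follows the
#' logistic curve with the given scale; the loser loses the same amount.
#'
#' @param interactions data.frame with columns `winner`, `loser` (in
#'   chronological order).
#' @param ids id universe; defaults to ids seen in the interactions.
#' @param K update step (default 100).
#' @param init initial score (default 1000).
#' @param scale logistic scale (default 400).
#' @return named numeric vector of final scores.
#' @export
elo_scores <- function(interactions, ids = NULL, K = 100, init = 1000,
                       scale = 400) {
  if (is.null(ids)) ids <- sort(unique(c(interactions$winner, interactions$loser)))
  s <- setNames(rep(init, length(ids)), ids)
  for (r in seq_len(nrow(interactions))) {
    w <- interactions$winner[r]; l <- interactions$loser[r]
    e_w <- 1 / (1 + 10^((s[l] - s[w]) / scale))
    s[w] <- s[w] + K * (1 - e_w)
    s[l] <- s[l] - K * (1 - e_w)
  }
  s
}

#' Randomized-Elo dominance ranks
#'
#' Elo scores averaged over many random orderings of the interaction
#' sequence, which removes the dependence of sequential Elo on the (often
#' arbitrary) observation order. Ranks are by mean score, 1 = most
#' dominant; individuals with no interactions are ranked last with a
#' warning.
#'
#' @param interactions data.frame with `winner`, `loser`.
#' @param ids optional id universe.
#' @param n_orderings number of random orderings (default 1000).
#' @param ... Elo parameters passed to [elo_scores()].
#' @return list with `score` (mean over orderings), `rank` (named,
#'   permutation of 1..N up to ties), `n_orderings`.
#' @export
elo_ranks <- function(interactions, ids = NULL, n_orderings = 1000, ...) {
  if (is.null(ids)) ids <- sort(unique(c(interactions$winner, interactions$loser)))
  seen <- ids %in% c(interactions$winner, interactions$loser)
  if (any(!seen)) {
    warning(sprintf("elo_ranks: no interactions for %s; ranked last",
                    paste(ids[!seen], collapse = ", ")))
  }
  acc <- setNames(rep(0, length(ids)), ids)
  n_int <- nrow(interactions)
  for (o in seq_len(n_orderings)) {
    ord <- sample.int(n_int)
    acc <- acc + elo_scores(interactions[ord, , drop = FALSE], ids = ids, ...)
  }
  score <- acc / n_orderings
  score[!seen] <- -Inf
  rk <- rank(-score, ties.method = "average")
  list(score = score, rank = rk, n_orderings = n_orderings)
}

#' Split-half repeatability of the dominance hierarchy
#'
#' Randomizes the interaction order, splits the data in two halves,
#' derives Elo ranks from each half and correlates them (Spearman);
#' repeated `n_rep` times to give a mean and 95% interval of the
#' correlation.
#'
#' @param interactions data.frame with `winner`, `loser`.
#' @param n_rep number of random splits (default 1000).
#' @param n_orderings orderings per half for the randomized Elo (kept
#'   moderate since each split repeats it).
#' @param ... Elo parameters.
#' @return list with `mean`, `ci` (2.5/97.5 percentiles), `rho` (all
#'   values).
#' @export
split_half_repeatability <- function(interactions, n_rep = 1000,
                                     n_orderings = 20, ...) {
  ids <- sort(unique(c(interactions$winner, interactions$loser)))
  n <- nrow(interactions)
  rho <- vapply(seq_len(n_rep), function(r) {
    ord <- sample.int(n)
    half <- ord[seq_len(floor(n / 2))]
    r1 <- elo_ranks(interactions[half, , drop = FALSE], ids = ids,
                    n_orderings = n_orderings, ...)$rank
    r2 <- elo_ranks(interactions[-half, , drop = FALSE], ids = ids,
                    n_orderings = n_orderings, ...)$rank
    suppressWarnings(stats::cor(r1, r2, method = "spearman"))
  }, numeric(1))
  list(mean = mean(rho, na.rm = TRUE),
       ci = stats::quantile(rho, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
       rho = rho)
}

# --- permutation tests -----------------------------------------------------

.perm_result <- function(observed, null_values, alpha = 0.05,
                         orientation = c("small", "large")) {
  orientation <- match.arg(orientation)
  # reported p follows the convention: proportion of randomized values
  # larger than the observed value (so p near 1 flags an observed value
  # unusually close to 0 for "small" orientation tests)
  p_larger <- mean(null_values > observed)
  significant <- if (orientation == "small") p_larger >= 1 - alpha
                 else mean(null_values >= observed) < alpha
  # tie-randomized variant: exactly uniform under the null even when the
  # statistic is discrete, used for calibration diagnostics
  n_gt <- sum(null_values > observed)
  n_eq <- sum(null_values == observed)
  p_uniform <- (n_gt + stats::runif(1) * (1 + n_eq)) / (length(null_values) + 1)
  structure(list(observed = observed, null_values = null_values,
                 null_mean = mean(null_values),
                 null_ci = stats::quantile(null_values, c(0.025, 0.975),
                                           names = FALSE),
                 p = p_larger, p_uniform = p_uniform, alpha = alpha,
                 orientation = orientation, significant = significant),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("permutation test: observed %.4f vs null %.4f [%.4f, %.4f]\n",
              x$observed, x$null_mean, x$null_ci[1], x$null_ci[2]))
  cat(sprintf("  p (share of null larger than observed) = %.3f; %s at alpha = %g\n",
              x$p, if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' Does dominance predict influence (or initiation rate)?
#'
#' Observed statistic: mean absolute difference between each individual's
#' dominance rank and its target rank (influence rank, or rank of
#' successful-initiation rate per hour). Small values mean the two
#' hierarchies align. The null is built by shuffling the pairing between
#' the two rankings `n_perm` times; the effect is significant at `alpha`
#' if the observed value is closer to 0 than `1 - alpha` of the null.
#' With `subset`, both rankings are re-ranked within the subset before
#' comparison (the within-sex variants).
#'
#' @param dominance_rank named numeric vector (1 = most dominant).
#' @param target_rank named numeric vector over the same ids.
#' @param subset optional character vector of ids to restrict to.
#' @param n_perm permutations (default 1000).
#' @param alpha significance level.
#' @return a `perm_result`.
#' @export
perm_test_dominance_vs_rank <- function(dominance_rank, target_rank,
                                        subset = NULL, n_perm = 1000,
                                        alpha = 0.05) {
  ids <- intersect(names(dominance_rank), names(target_rank))
  if (!is.null(subset)) ids <- intersect(ids, subset)
  stopifnot(length(ids) >= 3)
  a <- rank(dominance_rank[ids], ties.method = "average")
  b <- rank(target_rank[ids], ties.method = "average")
  obs <- mean(abs(a - b))
  null <- vapply(seq_len(n_perm), function(i) mean(abs(a - sample(b))),
                 numeric(1))
  .perm_result(obs, null, alpha, orientation = "small")
}

#' Are males over-represented among the top-ranked individuals?
#'
#' Builds two binary variables: membership in the top n ranks (n = number
#' of males) and being male; the statistic is the mean absolute difference
#' between them (0 when the top-n set is exactly the males). The null
#' shuffles the link between the two variables.
#'
#' @param target_rank named numeric vector (influence or rate ranks,
#'   1 = top).
#' @param sexes named character vector ("M"/"F") over the same ids.
#' @param n_perm permutations.
#' @param alpha significance level.
#' @return a `perm_result`.
#' @export
perm_test_sex_top <- function(target_rank, sexes, n_perm = 1000, alpha = 0.05) {
  ids <- intersect(names(target_rank), names(sexes))
  male <- as.integer(sexes[ids] == "M")
  n_males <- sum(male)
  stopifnot(n_males >= 1, n_males < length(ids))
  top <- as.integer(rank(target_rank[ids], ties.method = "average") <= n_males)
  obs <- mean(abs(top - male))
  null <- vapply(seq_len(n_perm), function(i) mean(abs(top - sample(male))),
                 numeric(1))
  .perm_result(obs, null, alpha, orientation = "small")
}

#' Sex effect on success in mixed-sex two-puller contests
#'
#' From events with exactly two initiators, one male and one female, in
#' which exactly one initiator pulled, computes the proportion of events
#' won by the male. The null randomizes the sexes within each event (each
#' winner male with probability 1/2); the male advantage is significant at
#' `alpha` when the observed proportion exceeds `1 - alpha` of the null.
#'
#' @param winner_is_male logical vector, one entry per mixed-sex
#'   two-puller event, or an `event_set` plus `sexes` to extract them.
#' @param sexes named "M"/"F" vector, required when an `event_set` is
#'   given.
#' @param n_perm permutations.
#' @param alpha significance level.
#' @return a `perm_result` with observed = P(male success).
#' @export
two_puller_sex_success <- function(winner_is_male, sexes = NULL,
                                   n_perm = 1000, alpha = 0.05) {
  if (inherits(winner_is_male, "event_set")) {
    stopifnot(!is.null(sexes))
    winner_is_male <- mixed_two_puller_outcomes(winner_is_male, sexes)
  }
  w <- as.logical(winner_is_male)
  n <- length(w)
  stopifnot(n >= 1)
  obs <- mean(w)
  null <- vapply(seq_len(n_perm), function(i) {
    mean(stats::runif(n) < 0.5)
  }, numeric(1))
  .perm_result(obs, null, alpha, orientation = "large")
}

#' Winner sex in mixed-sex two-initiator events
#'
#' Helper extracting, from an `event_set`, the events with exactly two
#' initiators of opposite sex in which exactly one initiator pulled, and
#' returning whether the puller was the male.
#'
#' @param event_set an `event_set`.
#' @param sexes named "M"/"F" vector.
#' @return logical vector, one entry per qualifying event.
#' @export
mixed_two_puller_outcomes <- function(event_set, sexes) {
  at <- event_set$attempts
  out <- logical(0)
  for (eid in event_set$events$event_id) {
    a <- at[at$event_id == eid, , drop = FALSE]
    inits <- unique(a$initiator)
    if (length(inits) != 2) next
    sx <- sexes[inits]
    if (anyNA(sx) || length(unique(sx)) != 2) next
    pullers <- unique(a$initiator[a$outcome == "pull"])
    if (length(pullers) != 1) next
    out <- c(out, unname(sexes[pullers] == "M"))
  }
  out
}
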