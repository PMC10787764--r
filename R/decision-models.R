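#' Follower-decision model: agreement, number of initiators, and their
#' interaction
#'
#' Binomial logit marginal model of whether the candidate follower was
#' pulled (1) or anchored (0) as a function of the number of simultaneous
#' initiators, their directional agreement, and the interaction. Fitted as
#' a marginal model with an independence working correlation, clustered on
#' follower identity: point estimates come from the ordinary binomial GLM
#' and standard errors from the cluster-robust sandwich estimator, which
#' is exactly the independence-GEE fit. No autocorrelation structure is
#' used (events already pool simultaneous initiations).
#'
#' @param events data.frame with columns `success`, `n_initiators`,
#'   `agreement`, `follower` (an `event_set`'s `events` element after
#'   [event_metrics()] works directly).
#' @param covariates optional extra column names to add as linear terms
#'   (e.g. tracked fraction, initiator-follower distance).
#' @return object of class `follow_model`: list with `coefficients`,
#'   `robust_se`, `vcov` (clustered), `z`, `p`, the underlying `glm` fit,
#'   and a `separation` flag.
#' @export
fit_follow_model <- function(events, covariates = NULL) {
  df <- as.data.frame(events[, c("success", "n_initiators", "agreement",
                                 "follower", covariates)])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  stopifnot(nrow(df) > 0)
  rhs <- "n_initiators * agreement"
  if (length(covariates)) rhs <- paste(c(rhs, covariates), collapse = " + ")
  degenerate <- length(unique(df$agreement)) == 1
  if (degenerate) {
    rhs <- sub("n_initiators \\* agreement", "n_initiators", rhs)
  }
  fit <- stats::glm(stats::as.formula(paste("success ~", rhs)),
                    family = stats::binomial(), data = df)
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 20)
  if (separation) {
    warning("fit_follow_model: possible complete separation; coefficients unreliable")
  }
  V <- sandwich::vcovCL(fit, cluster = df$follower)
  se <- sqrt(diag(V))
  z <- stats::coef(fit) / se
  structure(list(coefficients = stats::coef(fit), robust_se = se, vcov = V,
                 z = z, p = 2 * stats::pnorm(-abs(z)), glm = fit,
                 cluster = "follower", separation = separation,
                 degenerate_agreement = degenerate),
            class = "follow_model")
}

#' @export
print.follow_model <- function(x, ...) {
  cat("Binomial marginal model of following (independence working correlation,\n")
  cat(sprintf("cluster-robust SEs on %s)\n", x$cluster))
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$z, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Predicted follow probability surface
#' @param object a `follow_model`.
#' @param n_initiators,agreement vectors defining the grid.
#' @param ... unused.
#' @return data.frame with n_initiators, agreement, p_follow.
#' @export
predict_follow_surface <- function(object, n_initiators = 1:8,
                                   agreement = seq(0, 1, 0.1), ...) {
  grid <- expand.grid(n_initiators = n_initiators, agreement = agreement)
  grid$p_follow <- stats::predict(object$glm, newdata = grid, type = "response")
  grid
}

# --- compromise / choose regimes ------------------------------------------

#' Put two-initiator events into the symmetric frame
#'
#' For each successful two-initiator event with a defined follower
#' direction, rotates the frame so the two initiator directions sit at
#' +theta/2 and -theta/2 about zero (the bisector); the follower angle is
#' measured in this frame. Compromise predicts follower mass near 0,
#' choose predicts modes near the initiator directions.
#'
#' @param event_set an `event_set` processed by [event_metrics()].
#' @return data.frame with event_id, disagreement_deg (0-180), and
#'   follower_rel (radians in the symmetric frame).
#' @export
two_initiator_frame <- function(event_set) {
  ev <- event_set$events
  sel <- which(ev$n_initiators == 2 & ev$success & !is.na(ev$follower_direction))
  rows <- lapply(sel, function(i) {
    d <- ev$directions[[i]]
    if (length(d) != 2) return(NULL)
    theta <- ang_dist(d[1], d[2])
    bis <- circ_mean(d)
    s <- sign(wrap_angle(d[1] - bis))
    if (s == 0) s <- 1
    data.frame(event_id = ev$event_id[i],
               disagreement_deg = theta * 180 / pi,
               follower_rel = wrap_angle(ev$follower_direction[i] - bis) * s)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(event_id = integer(0), disagreement_deg = numeric(0),
                      follower_rel = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Converging-modes test
#'
#' Tests whether follower directions are more unimodal (converged on a
#' single central direction) than expected if followers always chose one
#' of the two initiator directions. Null model: balanced two-component von
#' Mises mixture centred at +/- theta/2 with a shared concentration fitted
#' to the observed angles by maximum likelihood. Statistic: the mean
#' resultant length of the observed angles, which is continuous, large for
#' a single converged mode, and exactly invariant under rotation and
#' mirror reflection. The p-value is the share of null simulations whose
#' resultant length reaches the observed one (small p: observed more
#' unimodal than chance).
#'
#' @param angles follower angles in the symmetric frame (radians).
#' @param theta inter-initiator angle (radians) defining the null modes.
#' @param n_sim null simulations (default 199).
#' @return list with `statistic` (mean resultant length), `p.value`,
#'   `kappa_null`.
#' @export
converging_modes_test <- function(angles, theta, n_sim = 199) {
  n <- length(angles)
  stopifnot(n >= 2)
  mu <- c(theta / 2, -theta / 2)
  nll <- function(k) {
    -sum(log(0.5 * dvonmises(angles, mu[1], k) +
             0.5 * dvonmises(angles, mu[2], k) + 1e-300))
  }
  kappa_null <- stats::optimize(nll, c(0, 200))$minimum
  obs <- resultant_length(angles)
  null <- vapply(seq_len(n_sim), function(i) {
    comp <- sample(1:2, n, replace = TRUE)
    resultant_length(rvonmises(n, 0, kappa_null) + mu[comp])
  }, numeric(1))
  list(statistic = obs,
       p.value = (1 + sum(null >= obs)) / (n_sim + 1),
       kappa_null = kappa_null)
}

#' Classify angular-disagreement bins into compromise / choose regimes
#'
#' Two-initiator successful events are grouped into bins of angular
#' disagreement (12 degrees wide by default). Each bin gets a dip test of
#' bimodality on the follower angles and a converging-modes test.
#' Compromise: not significantly bimodal (dip p >= alpha) AND more
#' unimodal than chance (converge p < alpha). Choose: significantly
#' bimodal AND not more unimodal than chance. Exactly one condition
#' holding marks a transition bin; bins with fewer than `min_events`
#' events are labelled "insufficient_data". The transition range is the
#' span between the upper edge of the last pure-compromise bin and the
#' lower edge of the first pure-choose bin (NA when no such pair exists).
#'
#' @param frame data.frame from [two_initiator_frame()] (or the synthetic
#'   equivalent) with `disagreement_deg` and `follower_rel`.
#' @param bin_width bin width in degrees (default 12).
#' @param alpha significance level for both tests (default 0.05).
#' @param dip_sims,converge_sims Monte-Carlo sizes.
#' @param min_events minimum events per bin (default 10).
#' @return list with `bins` (bin_lo_deg, bin_hi_deg, n, dip_p, converge_p,
#'   regime) and `transition` (c(lo, hi) in degrees).
#' @export
regime_classification <- function(frame, bin_width = 12, alpha = 0.05,
                                  dip_sims = 999, converge_sims = 199,
                                  min_events = 10) {
  edges <- seq(0, 180, by = bin_width)
  nb <- length(edges) - 1
  out <- data.frame(bin_lo_deg = edges[-length(edges)], bin_hi_deg = edges[-1],
                    n = 0L, dip_p = NA_real_, converge_p = NA_real_,
                    regime = "insufficient_data", stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    sel <- frame$disagreement_deg > out$bin_lo_deg[b] &
      frame$disagreement_deg <= out$bin_hi_deg[b]
    x <- frame$follower_rel[sel]
    out$n[b] <- length(x)
    if (length(x) < min_events) next
    dp <- dip_test(x, n_sim = dip_sims, null = "vonmises")$p.value
    theta_mid <- (out$bin_lo_deg[b] + out$bin_hi_deg[b]) / 2 * pi / 180
    cp <- converging_modes_test(x, theta_mid, n_sim = converge_sims)$p.value
    out$dip_p[b] <- dp
    out$converge_p[b] <- cp
    unimodal <- dp >= alpha          # not significantly bimodal
    converging <- cp < alpha         # more unimodal than the two-mode null
    out$regime[b] <- if (unimodal && converging) "compromise"
      else if (!unimodal && !converging) "choose"
      else "transition"
  }
  usable <- out$regime != "insufficient_data"
  # the transition range runs from the last pure-compromise bin to the
  # first pure-choose bin above it; choose flags below a later compromise
  # bin are isolated false positives and are ignored
  lo <- NA_real_; hi <- NA_real_
  comp <- which(out$regime == "compromise")
  if (length(comp)) {
    lo <- out$bin_hi_deg[max(comp)]
    ch <- which(out$regime == "choose" & seq_len(nb) > max(comp))
    if (length(ch)) hi <- out$bin_lo_deg[min(ch)]
  } else {
    ch <- which(out$regime == "choose")
    if (length(ch)) hi <- out$bin_lo_deg[min(ch)]
  }
  list(bins = out, transition = c(lo = lo, hi = hi),
       alpha = alpha, bin_width = bin_width, n_usable_bins = sum(usable))
}

# --- initiator direction clustering and the majority rule ------------------

#' Cluster co-initiator directions on the circle
#'
#' Von Mises mixture over the initiator directions with the number of
#' components selected by BIC among k = 1..min(k_max, n). A circular
#' mixture respects the wrap-around at +/-180 degrees, which a Euclidean
#' mixture on raw angles would split.
#'
#' @param angles initiator directions (radians), length >= 2.
#' @param k_max maximum components considered (default 3).
#' @param n_restarts EM restarts per k.
#' @param kappa_max concentration cap.
#' @return list with `k`, `means` (radians), `sizes` (per-cluster counts),
#'   `assignment`, `bic` (per candidate k).
#' @export
cluster_initiator_directions <- function(angles, k_max = 3, n_restarts = 20,
                                         kappa_max = 100) {
  n <- length(angles)
  stopifnot(n >= 2)
  ks <- seq_len(min(k_max, n))
  fits <- lapply(ks, function(k) fit_vm_mixture(angles, k,
                                                n_restarts = n_restarts,
                                                kappa_max = kappa_max))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- fits[[which.min(bics)]]
  used <- sort(unique(best$assignment))
  list(k = length(used),
       means = best$mu[used],
       sizes = as.integer(table(factor(best$assignment, used))),
       assignment = match(best$assignment, used),
       bic = setNames(bics, paste0("k", ks)))
}

#' Two-cluster events for the majority analysis
#'
#' From events with two or more pulling initiators, clusters the pullers'
#' directions and keeps the events with exactly two clusters, recording
#' the cluster sizes and which cluster the follower's direction is nearer
#' (by circular distance to the cluster mean).
#'
#' @param event_set an `event_set` processed by [event_metrics()].
#' @param ... passed to [cluster_initiator_directions()].
#' @return data.frame with event_id, n1, n2, chosen (1 or 2).
#' @export
two_cluster_events <- function(event_set, ...) {
  ev <- event_set$events
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    if (!isTRUE(ev$success[i]) || is.na(ev$follower_direction[i])) next
    at_i <- event_set$attempts[event_set$attempts$event_id == ev$event_id[i], ]
    pullers <- unique(at_i$initiator[at_i$outcome == "pull"])
    if (length(pullers) < 2) next
    d <- ev$directions[[i]][pullers]
    d <- d[!is.na(d)]
    if (length(d) < 2) next
    cl <- cluster_initiator_directions(d, ...)
    if (cl$k != 2) next
    dist_to <- vapply(cl$means, ang_dist, numeric(1), b = ev$follower_direction[i])
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = ev$event_id[i], n1 = cl$sizes[1], n2 = cl$sizes[2],
      chosen = which.min(dist_to))
  }
  if (!length(rows)) {
    return(data.frame(event_id = integer(0), n1 = integer(0), n2 = integer(0),
                      chosen = integer(0)))
  }
  do.call(rbind, rows)
}

#' Majority-rule sigmoid fit
#'
#' Randomly relabels the two clusters of each event (so "cluster 1" is an
#' arbitrary label), then fits P(choose cluster 1) as a logistic function
#' of the numerical difference n1 - n2 by nonlinear least squares on the
#' per-difference empirical probabilities (weighted by event counts). The
#' curve is constrained through (0, 0.5) by construction and is monotone
#' increasing for positive steepness. Per-difference 95% confidence
#' intervals come from the uniform-draw procedure: for each difference
#' with n events and observed probability p, draw n uniform variates,
#' record the share at or below p, repeat `n_boot` times, and take the
#' 2.5th and 97.5th percentiles.
#'
#' @param clustered data.frame from [two_cluster_events()] (columns n1,
#'   n2, chosen).
#' @param n_boot uniform-draw repetitions (default 1000).
#' @return object of class `majority_fit`: list with `beta` (steepness),
#'   `dn80` (difference at which the fitted curve reaches 0.8), `table`
#'   (delta_n, n_events, p_choose_1, ci_lo, ci_hi), and `fit`.
#'   `beta` is NA with a message when every difference is zero.
#' @export
majority_rule_fit <- function(clustered, n_boot = 1000) {
  stopifnot(nrow(clustered) > 0)
  flip <- stats::runif(nrow(clustered)) < 0.5
  n1 <- ifelse(flip, clustered$n2, clustered$n1)
  n2 <- ifelse(flip, clustered$n1, clustered$n2)
  chosen <- ifelse(flip, 3L - clustered$chosen, clustered$chosen)
  dn <- n1 - n2
  y <- as.integer(chosen == 1L)
  tab <- stats::aggregate(y, by = list(delta_n = dn),
                          FUN = function(v) c(n = length(v), p = mean(v)))
  tab <- data.frame(delta_n = tab$delta_n, n_events = tab$x[, "n"],
                    p_choose_1 = tab$x[, "p"])
  ci <- t(vapply(seq_len(nrow(tab)), function(i) {
    reps <- vapply(seq_len(n_boot), function(b) {
      mean(stats::runif(tab$n_events[i]) <= tab$p_choose_1[i])
    }, numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  }, numeric(2)))
  tab$ci_lo <- ci[, 1]; tab$ci_hi <- ci[, 2]
  if (all(dn == 0)) {
    message("majority_rule_fit: all cluster-size differences are zero; fit undefined")
    return(structure(list(beta = NA_real_, dn80 = NA_real_, table = tab,
                          fit = NULL), class = "majority_fit"))
  }
  fit <- minpack.lm::nlsLM(p_choose_1 ~ 1 / (1 + exp(-beta * delta_n)),
                           data = tab, start = list(beta = 0.3),
                           weights = tab$n_events,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  beta <- stats::coef(fit)[["beta"]]
  structure(list(beta = beta,
                 dn80 = if (beta > 0) log(0.8 / 0.2) / beta else NA_real_,
                 table = tab, fit = fit),
            class = "majority_fit")
}

#' @export
print.majority_fit <- function(x, ...) {
  cat(sprintf("majority rule: logistic steepness beta = %.3f", x$beta))
  if (is.finite(x$dn80)) {
    cat(sprintf(" (P = 0.8 reached at a difference of %.1f initiators)", x$dn80))
  }
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
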