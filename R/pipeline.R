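#' Run configuration
#'
#' Collects the thresholds and Monte-Carlo sizes of the full analysis.
#' Defaults are the study settings: 3.5 m minimum change, 0.1 disparity
#' and strength, 0.5 coverage (0.8 for the robustness variant), 12-degree
#' disagreement bins, alpha 0.05, 1000 permutations and 1000 bootstrap
#' repetitions.
#'
#' @param min_change,disparity,strength attempt-retention thresholds.
#' @param coverage tracked-fraction threshold for retaining events.
#' @param bin_deg disagreement bin width (degrees).
#' @param alpha significance level.
#' @param n_perm permutations for the rank/sex tests.
#' @param n_boot bootstrap repetitions for the majority-rule intervals.
#' @param dip_sims,converge_sims Monte-Carlo sizes for the regime tests.
#' @param direction_ref reference times for initiator directions
#'   ("t1_t2" or "t2_t2").
#' @param seed integer seed for all stochastic steps.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_change = 3.5, disparity = 0.1, strength = 0.1,
                       coverage = 0.5, bin_deg = 12, alpha = 0.05,
                       n_perm = 1000, n_boot = 1000,
                       dip_sims = 999, converge_sims = 199,
                       direction_ref = "t1_t2", seed = 1L) {
  stopifnot(min_change > 0, disparity > 0, strength > 0,
            coverage > 0, coverage <= 1, bin_deg > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on one or more trajectory grids
#'
#' Preprocesses each grid (outlier removal when an area is given, gap
#' interpolation), extracts dyadic initiation attempts, builds events with
#' the coverage filter, computes event metrics, and runs the influence,
#' dominance, follower-decision, regime and majority analyses. All
#' stochastic steps are governed by `config$seed`, so reruns are
#' reproducible. Counts at every filter stage are collected in `log`.
#'
#' @param grids a [trajectory_grid()] or list of them (e.g. one per day).
#' @param metadata data.frame with id, sex, group.
#' @param interactions optional agonistic table (time, winner, loser).
#' @param config a [run_config()].
#' @param area optional [study_area()] for outlier removal.
#' @return list with the per-stage outputs and a `log` of counts.
#' @export
run_pipeline <- function(grids, metadata, interactions = NULL,
                         config = run_config(), area = NULL) {
  set.seed(config$seed)
  if (inherits(grids, "trajectory_grid")) grids <- list(grids)
  thresholds <- list(min_change = config$min_change,
                     disparity = config$disparity,
                     strength = config$strength)
  log <- list()
  all_attempts <- list(); all_events <- list(); esets <- list()
  eid_offset <- 0L
  for (gi in seq_along(grids)) {
    g <- grids[[gi]]
    if (!is.null(area)) g <- remove_outliers(g, area)
    g <- interpolate_gaps(g)
    grids[[gi]] <- g
    at <- extract_attempts(g, thresholds)
    es <- build_events(at, g, min_coverage = config$coverage)
    es <- event_metrics(g, es, reference = config$direction_ref)
    es$events$event_id <- es$events$event_id + eid_offset
    es$attempts$event_id <- es$attempts$event_id + eid_offset
    if (nrow(es$events)) eid_offset <- max(es$events$event_id)
    log[[gi]] <- data.frame(
      grid = gi,
      candidates = nrow(at),
      retained = nrow(attempts_retained(at)),
      rejected_min_change = sum(at$reject_reason == "min_change", na.rm = TRUE),
      rejected_disparity = sum(at$reject_reason == "disparity", na.rm = TRUE),
      rejected_strength = sum(at$reject_reason == "strength", na.rm = TRUE),
      rejected_missing = sum(at$reject_reason == "missing_fix", na.rm = TRUE),
      rejected_tie = sum(at$reject_reason == "tie", na.rm = TRUE),
      events = nrow(es$events),
      dropped_coverage = es$dropped_coverage)
    all_attempts[[gi]] <- at
    esets[[gi]] <- es
  }
  events <- do.call(rbind, lapply(esets, function(e) e$events))
  attempts <- do.call(rbind, lapply(esets, function(e) e$attempts))
  eset <- structure(list(events = events, attempts = attempts,
                         dropped_coverage = sum(vapply(esets, `[[`, numeric(1),
                                                       "dropped_coverage"))),
                    class = "event_set")
  infl <- influence_matrix(eset, ids = metadata$id)
  rates <- initiation_rates(eset, grids)
  sexes <- setNames(metadata$sex, metadata$id)
  out <- list(grids = grids, attempts = do.call(rbind, all_attempts),
              event_set = eset, summary = event_summary(eset),
              influence = infl, rates = rates,
              log = do.call(rbind, log), config = config)
  if (!is.null(interactions)) {
    dom <- elo_ranks(interactions, ids = metadata$id, n_orderings = 200)
    rate_rank <- setNames(rates$rate_rank, rates$id)
    out$dominance <- dom
    out$perm <- list(
      influence_all = perm_test_dominance_vs_rank(dom$rank, infl$influence_rank,
                                                  n_perm = config$n_perm,
                                                  alpha = config$alpha),
      sex_top_influence = perm_test_sex_top(infl$influence_rank, sexes,
                                            n_perm = config$n_perm,
                                            alpha = config$alpha),
      rate_all = perm_test_dominance_vs_rank(dom$rank, rate_rank,
                                             n_perm = config$n_perm,
                                             alpha = config$alpha),
      sex_top_rate = perm_test_sex_top(rate_rank, sexes,
                                       n_perm = config$n_perm,
                                       alpha = config$alpha))
    for (sx in c("M", "F")) {
      sub <- metadata$id[metadata$sex == sx]
      if (length(sub) >= 3) {
        out$perm[[paste0("influence_", tolower(sx))]] <-
          perm_test_dominance_vs_rank(dom$rank, infl$influence_rank,
                                      subset = sub, n_perm = config$n_perm,
                                      alpha = config$alpha)
      }
    }
  }
  mixed <- mixed_two_puller_outcomes(eset, sexes)
  if (length(mixed) >= 10) {
    out$two_puller_sex <- two_puller_sex_success(mixed, n_perm = config$n_perm,
                                                 alpha = config$alpha)
  }
  ev_ok <- events[!is.na(events$agreement), , drop = FALSE]
  if (nrow(ev_ok) >= 30 && length(unique(ev_ok$agreement)) > 1) {
    out$follow_model <- fit_follow_model(ev_ok)
  }
  frame <- two_initiator_frame(eset)
  if (nrow(frame) >= 50) {
    out$regime <- regime_classification(frame, bin_width = config$bin_deg,
                                        alpha = config$alpha,
                                        dip_sims = config$dip_sims,
                                        converge_sims = config$converge_sims)
  }
  clustered <- two_cluster_events(eset)
  if (nrow(clustered) >= 20) {
    out$majority <- majority_rule_fit(clustered, n_boot = config$n_boot)
  }
  out
}

#' Write the main pipeline outputs as plain-text tables
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(result$attempts, "attempts.csv")
  ev <- result$event_set$events
  ev$directions <- NULL
  w(ev, "events.csv")
  w(result$log, "filter_log.csv")
  w(as.data.frame(as.table(result$influence$I),
                  responseName = "influence_index"), "influence_matrix.csv")
  w(result$rates, "initiation_rates.csv")
  if (!is.null(result$regime)) w(result$regime$bins, "regime_bins.csv")
  if (!is.null(result$majority)) w(result$majority$table, "majority_table.csv")
  summ <- list(event_summary = result$summary)
  if (!is.null(result$follow_model)) {
    summ$follow_model <- list(coefficients = as.list(result$follow_model$coefficients),
                              robust_se = as.list(result$follow_model$robust_se))
  }
  if (!is.null(result$perm)) {
    summ$permutation_tests <- lapply(result$perm, function(p)
      list(observed = p$observed, null_mean = p$null_mean,
           null_ci = p$null_ci, p = p$p, significant = p$significant))
  }
  if (!is.null(result$two_puller_sex)) {
    summ$two_puller_sex <- list(observed = result$two_puller_sex$observed,
                                p = result$two_puller_sex$p,
                                significant = result$two_puller_sex$significant)
  }
  if (!is.null(result$majority)) {
    summ$majority <- list(beta = result$majority$beta, dn80 = result$majority$dn80)
  }
  if (!is.null(result$regime)) summ$regime_transition <- as.list(result$regime$transition)
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
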