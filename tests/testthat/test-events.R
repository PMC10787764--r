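# attempts table stub with the columns build_events needs
attempt_rows <- function(follower, t1, t3, initiator = NULL,
                         outcome = "pull") {
  n <- length(t1)
  if (is.null(initiator)) initiator <- sprintf("I%02d", seq_len(n))
  data.frame(initiator = initiator, follower = follower,
             t1 = t1, t2 = pmin(t1 + 1, t3), t2_end = pmin(t1 + 1, t3),
             t3 = t3, d1 = 0, d2 = 10, d3 = 0, min_change = 10,
             disparity = 1, strength = 1, outcome = outcome,
             reject_reason = NA_character_)
}

test_that("the chain rule links A-B-C through pairwise overlap", {
  at <- attempt_rows("F", t1 = c(0, 8, 18), t3 = c(10, 20, 30))
  es <- build_events(at)
  expect_equal(nrow(es$events), 1)
  expect_equal(es$events$t_start, 0)
  expect_equal(es$events$t_end, 30)
  expect_equal(es$events$n_initiators, 3)

  at2 <- attempt_rows("F", t1 = c(0, 20), t3 = c(10, 30))
  expect_equal(nrow(build_events(at2)$events), 2)

  # attempts sharing only an endpoint are consecutive, not simultaneous
  at3 <- attempt_rows("F", t1 = c(0, 10), t3 = c(10, 20))
  expect_equal(nrow(build_events(at3)$events), 2)
})

test_that("chain-rule components match brute-force transitive closure", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(10:100, 1)
    s <- sample(0:500, n, replace = TRUE)
    e <- s + sample(1:60, n, replace = TRUE)
    at <- attempt_rows("F", t1 = s, t3 = e)
    es <- build_events(at)
    got <- es$attempts$event_id[order(es$attempts$t1, es$attempts$initiator)]
    ord <- order(s, at$initiator)
    want <- oracle_overlap_components(s, e)[ord]
    # same partition up to labelling
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(got, want, function(v) length(unique(v)) == 1)))
  }
})

test_that("events partition retained attempts and bound durations", {
  cfg <- sim_config(n_agents = 6, n_males = 3, episodes = 8)
  sim <- simulate_group(cfg, seed = 8)
  g <- interpolate_gaps(sim$grid)
  at <- extract_attempts(g)
  es <- build_events(at)
  expect_equal(nrow(es$attempts), nrow(attempts_retained(at)))
  expect_true(all(!is.na(es$attempts$event_id)))
  for (eid in es$events$event_id) {
    a <- es$attempts[es$attempts$event_id == eid, ]
    ev <- es$events[es$events$event_id == eid, ]
    expect_gte(ev$duration_min, max((a$t3 - a$t1) / 60))
    expect_equal(ev$success, any(a$outcome == "pull"))
  }
})

test_that("events overlapping low-coverage seconds are dropped", {
  at <- attempt_rows("F", t1 = c(100, 300), t3 = c(160, 360))
  x <- matrix(0, 4, 500); y <- matrix(0, 4, 500)
  x[1:3, 320:340] <- NA; y[1:3, 320:340] <- NA   # coverage 1/4 there
  g <- trajectory_grid(sprintf("A%d", 1:4), seq(0, 499), x, y)
  es <- build_events(at, g, min_coverage = 0.5)
  expect_equal(nrow(es$events), 1)
  expect_equal(es$events$t_start, 100)
  expect_equal(es$dropped_coverage, 1)
})

test_that("initiator directions follow the angle convention", {
  # follower at origin; initiators due east and north of it
  x <- rbind(c(0, 0, 0, 0), c(5, 9, 9, 9), c(0, 0, 0, 0))
  y <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(5, 9, 9, 9))
  g <- make_grid(x, y, ids = c("F", "E", "N"))
  at <- rbind(attempt_rows("F", 1000, 1002, initiator = "E"),
              attempt_rows("F", 1000, 1002, initiator = "N"))
  at$t2 <- 1001L; at$t2_end <- 1001L
  es <- build_events(at)
  d <- initiator_directions(g, es, es$events$event_id[1])
  expect_equal(unname(d["E"]), 0, tolerance = 1e-9)
  expect_equal(unname(d["N"]), pi / 2, tolerance = 1e-9)
})

test_that("three-initiator directions match hand-computed atan2", {
  pos <- list(F = c(1, 1), A = c(4, 5), B = c(-2, 1), C = c(1, -6))
  x <- do.call(rbind, lapply(pos, function(p) rep(p[1], 4)))
  y <- do.call(rbind, lapply(pos, function(p) rep(p[2], 4)))
  g <- make_grid(x, y, ids = names(pos))
  at <- attempt_rows("F", rep(1000L, 3), rep(1002L, 3),
                     initiator = c("A", "B", "C"))
  at$t2 <- 1001L; at$t2_end <- 1001L
  es <- build_events(at)
  d <- initiator_directions(g, es, 1)
  expect_equal(unname(d["A"]), atan2(4, 3), tolerance = 1e-9)
  expect_equal(unname(d["B"]), atan2(0, -3), tolerance = 1e-9)
  expect_equal(unname(d["C"]), atan2(-7, 0), tolerance = 1e-9)
})

test_that("follower direction comes from the earliest pull and errors otherwise", {
  g <- scripted_pull_grid(follow = TRUE)
  at <- extract_attempts(g)
  es <- event_metrics(g, build_events(at))
  expect_true(es$events$success[1])
  # follower B walks due east during the closing segment
  expect_equal(es$events$follower_direction[1], 0, tolerance = 1e-6)

  g2 <- scripted_pull_grid(follow = FALSE)
  es2 <- build_events(extract_attempts(g2))
  expect_error(follower_direction(g2, es2, es2$events$event_id[1]),
               "unsuccessful")
})

test_that("duration summaries follow the worked examples", {
  at <- attempt_rows("F", t1 = 0, t3 = 60)
  s1 <- event_summary(build_events(at))
  expect_equal(s1$event_duration_mean, 1.0)

  at2 <- attempt_rows("F", t1 = c(0, 100), t3 = c(120, 300))
  es2 <- build_events(at2)
  expect_equal(nrow(es2$events), 1)
  expect_equal(es2$events$duration_min, 5.0)
})

test_that("two-initiator frame is invariant under rotation and mirror", {
  set.seed(62)
  base_dirs <- c(0.4, 1.8)
  make_es <- function(f) {
    at <- attempt_rows("F", t1 = c(0, 2), t3 = c(30, 32),
                       initiator = c("A", "B"))
    es <- build_events(at)
    es$events$agreement <- agreement(f(base_dirs))
    es$events$follower_direction <- f(0.9)
    es$events$n_pullers <- 2L
    es$events$directions <- I(list(setNames(f(base_dirs), c("A", "B"))))
    es
  }
  fr0 <- two_initiator_frame(make_es(identity))
  frR <- two_initiator_frame(make_es(function(a) wrap_angle(a + 2.5)))
  frM <- two_initiator_frame(make_es(function(a) -a))
  expect_equal(fr0$disagreement_deg, frR$disagreement_deg, tolerance = 1e-9)
  expect_equal(fr0$follower_rel, frR$follower_rel, tolerance = 1e-9)
  expect_equal(fr0$disagreement_deg, frM$disagreement_deg, tolerance = 1e-9)
  expect_equal(fr0$follower_rel, frM$follower_rel, tolerance = 1e-9)
})
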