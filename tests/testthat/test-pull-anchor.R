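test_that("dyadic distance matches hand computation", {
  x <- rbind(c(0, 0), c(3, 0)); y <- rbind(c(0, 0), c(4, 0))
  g <- make_grid(x, y)
  d <- dyadic_distance(g, g$ids[1], g$ids[2])
  expect_equal(d$d[1], 5)                  # 3-4-5 triangle
  expect_equal(d$d[2], 0)                  # identical positions

  set.seed(51)
  x <- matrix(rnorm(40), 2); y <- matrix(rnorm(40), 2)
  g <- make_grid(x, y)
  d <- dyadic_distance(g, g$ids[1], g$ids[2])
  expect_equal(d$d, sqrt((x[1, ] - x[2, ])^2 + (y[1, ] - y[2, ])^2))
})

test_that("reversal filter handles canonical shapes", {
  mono <- data.frame(t = 1:50, d = seq(0, 20, length.out = 50))
  ex <- find_extrema(mono, 3.5)
  expect_lte(sum(ex$type == "max"), 1)
  expect_lte(sum(ex$type == "min"), 1)

  spike <- data.frame(t = 1:3, d = c(0, 5, 0))
  ex <- find_extrema(spike, 3.5)
  expect_equal(ex$type, c("min", "max", "min"))

  short <- data.frame(t = 1:2, d = c(0, 5))
  expect_equal(nrow(find_extrema(short, 3.5)), 0)
})

test_that("reversal filter emits the maximal alternating sequence (oracle)", {
  set.seed(52)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    d <- 5 * sin(seq(0, runif(1, 2, 8) * pi, length.out = n)) + rnorm(n, 0, 0.3)
    mc <- runif(1, 2, 6)
    ex <- find_extrema(data.frame(t = seq_len(n), d = d), mc,
                       plateau_slack = 0.5)
    # emitted count equals the brute-force maximum
    expect_equal(nrow(ex), oracle_max_alternating(d, mc))
    if (nrow(ex) >= 2) {
      # alternating types with gaps above threshold
      expect_true(all(ex$type[-1] != ex$type[-nrow(ex)]))
      expect_true(all(abs(diff(ex$d)) > mc))
    }
  }
})

test_that("raising min_change never increases the number of extrema", {
  set.seed(53)
  for (i in 1:20) {
    d <- 6 * sin(seq(0, 10 * pi, length.out = 300)) + rnorm(300, 0, 0.5)
    ser <- data.frame(t = 1:300, d = d)
    counts <- vapply(c(2, 3.5, 5, 7), function(mc) nrow(find_extrema(ser, mc)),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("a scripted pull classifies with disparity one", {
  g <- scripted_pull_grid(follow = TRUE)
  at <- attempts_retained(extract_attempts(g))
  expect_equal(nrow(at), 1)                # exactly one attempt
  expect_equal(at$initiator, "A")
  expect_equal(at$follower, "B")
  expect_equal(at$outcome, "pull")
  expect_equal(at$disparity, 1, tolerance = 1e-9)
  expect_gt(at$min_change, 3.5)
})

test_that("the mirror case (initiator returns) is an anchor", {
  g <- scripted_pull_grid(follow = FALSE)
  at <- attempts_retained(extract_attempts(g))
  expect_equal(nrow(at), 1)
  expect_equal(at$initiator, "A")
  expect_equal(at$outcome, "anchor")
})

test_that("near-equal movement is rejected by the disparity threshold", {
  # both individuals contribute almost equally to a 5 m swing
  n <- 60
  ramp <- pmin(pmax(seq_len(n) - 10, 0), 10) / 10
  back <- pmin(pmax(seq_len(n) - 35, 0), 10) / 10
  xa <- -2.6 * ramp + 2.6 * back
  xb <- 2.4 * ramp - 2.4 * back
  g <- make_grid(rbind(xa, xb), rbind(rep(0, n), rep(0.5, n)), ids = c("A", "B"))
  at <- extract_attempts(g)
  expect_true(nrow(at) >= 1)
  expect_true(all(at$reject_reason == "disparity"))
  expect_lt(at$disparity[1], 0.1)

  # exactly equal displacement leaves the initiator ambiguous: a tie
  xb2 <- 2.6 * ramp - 2.6 * back
  g2 <- make_grid(rbind(xa, xb2), rbind(rep(0, n), rep(0.5, n)),
                  ids = c("A", "B"))
  at2 <- extract_attempts(g2)
  expect_true(all(at2$reject_reason == "tie"))
})

test_that("missing fixes at extremum times reject the attempt", {
  g <- scripted_pull_grid(follow = TRUE)
  ex <- find_extrema(dyadic_distance(g, "A", "B"), 3.5)
  out <- classify_attempt(g, "A", "B", t1 = 9999, t2 = ex$t[2], t3 = ex$t[3])
  expect_equal(out$reject_reason, "missing_fix")
})

test_that("classification is invariant to relabelling the dyad", {
  g <- scripted_pull_grid(follow = TRUE)
  ex <- find_extrema(dyadic_distance(g, "A", "B"), 3.5)
  a1 <- classify_attempt(g, "A", "B", ex$t_last[1], ex$t_first[2],
                         ex$t_first[3], ex$t_last[2])
  a2 <- classify_attempt(g, "B", "A", ex$t_last[1], ex$t_first[2],
                         ex$t_first[3], ex$t_last[2])
  expect_equal(a1$initiator, a2$initiator)
  expect_equal(a1$outcome, a2$outcome)
  expect_equal(a1$disparity, a2$disparity)
})

test_that("a stationary group yields no attempts", {
  g <- make_grid(matrix(0, 4, 100) + runif(4), matrix(0, 4, 100) + runif(4))
  expect_equal(nrow(extract_attempts(g)), 0)
})

test_that("retained attempts respect all thresholds", {
  cfg <- sim_config(n_agents = 5, n_males = 2, episodes = 8)
  sim <- simulate_group(cfg, seed = 5)
  at <- attempts_retained(extract_attempts(interpolate_gaps(sim$grid)))
  expect_true(all(at$d2 - at$d1 > 3.5))
  expect_true(all(at$d2 - at$d3 > 3.5))
  expect_true(all(at$min_change > 3.5))
  expect_true(all(at$disparity >= 0.1))
  expect_true(all(at$strength >= 0.1))
  # deterministic ordering by t1 then ids
  expect_true(!is.unsorted(at$t1))
})

test_that("planted pulls and anchors are recovered from a scripted day", {
  sched <- data.frame(type = c("pull", "pull", "anchor", "pull", "anchor"),
                      initiators = 1L, theta_deg = NA_real_)
  cfg <- sim_config(n_agents = 5, n_males = 2, gps_noise_sd = 0,
                    missing_rate = 0, jitter_sd = 0, episodes = sched)
  sim <- simulate_group(cfg, seed = 14)
  ret <- attempts_retained(extract_attempts(sim$grid))
  expect_equal(nrow(ret), nrow(sim$truth))
  for (r in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[r, ]
    hit <- ret[ret$initiator == tr$initiator & ret$follower == tr$follower &
                 abs(ret$t2 - tr$t2) <= 8, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$outcome, tr$outcome)
    expect_lte(abs(hit$t1 - tr$t1), 8)
    expect_lte(abs(hit$t3 - tr$t3), 8)
  }
})
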