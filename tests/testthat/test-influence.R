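# helper: attempts table with event ids encoding pull counts per dyad
pull_events <- function(counts) {
  # counts: data.frame(initiator, follower, n)
  rows <- list(); eid <- 0L
  for (r in seq_len(nrow(counts))) {
    for (k in seq_len(counts$n[r])) {
      eid <- eid + 1L
      rows[[eid]] <- data.frame(initiator = counts$initiator[r],
                                follower = counts$follower[r],
                                outcome = "pull", event_id = eid)
    }
  }
  do.call(rbind, rows)
}

test_that("influence index endpoints and midpoint are exact", {
  at <- pull_events(data.frame(initiator = c("i", "j", "i", "j"),
                               follower = c("j", "i", "k", "k"),
                               n = c(5, 0, 3, 3)))
  # i pulled j five times, j never pulled i; i and j pulled k 3 times each
  infl <- influence_matrix(at, ids = c("i", "j", "k"))
  expect_identical(infl$P["i", "j"], 5L)
  expect_equal(infl$I["i", "j"], 1)
  expect_equal(infl$I["j", "i"], -1)
  expect_true(is.na(infl$I["i", "i"]))
})

test_that("equal pull counts give an influence index of zero", {
  at <- pull_events(data.frame(initiator = c("i", "j"), follower = c("j", "i"),
                               n = c(3, 3)))
  infl <- influence_matrix(at)
  expect_equal(infl$I["i", "j"], 0)
  expect_equal(infl$I["j", "i"], 0)
})

test_that("influence matrix matches a brute-force recount and is antisymmetric", {
  set.seed(81)
  ids <- c("a", "b", "c", "d")
  at <- data.frame(initiator = sample(ids, 200, TRUE),
                   follower = sample(ids, 200, TRUE),
                   outcome = sample(c("pull", "anchor"), 200, TRUE),
                   event_id = seq_len(200))
  at <- at[at$initiator != at$follower, ]
  infl <- influence_matrix(at, ids = ids)
  P_oracle <- oracle_influence(at, ids)
  expect_equal(unclass(infl$P), unclass(P_oracle), ignore_attr = TRUE)
  sym <- infl$I + t(infl$I)
  expect_true(all(abs(sym[!is.na(sym)]) < 1e-12))
  # a dyad with no events stays NA and out of the row sums
  at2 <- at[!(at$initiator %in% c("a") & at$follower == "b") &
              !(at$initiator == "b" & at$follower == "a"), ]
  infl2 <- influence_matrix(at2, ids = ids)
  expect_true(is.na(infl2$I["a", "b"]))
})

test_that("multiple pulls within one event count once", {
  at <- data.frame(initiator = "i", follower = "j", outcome = "pull",
                   event_id = c(1, 1, 2))
  infl <- influence_matrix(at)
  expect_identical(infl$P["i", "j"], 2L)
})

test_that("sequential Elo respects a perfectly transitive tournament", {
  ints <- data.frame(winner = rep(c("A", "B", "A"), 10),
                     loser = rep(c("B", "C", "C"), 10))
  er <- elo_ranks(ints, n_orderings = 50)
  expect_equal(unname(er$rank[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("Elo ranks are invariant to the initial score offset", {
  set.seed(82)
  ints <- data.frame(winner = sample(LETTERS[1:5], 60, TRUE),
                     loser = sample(LETTERS[1:5], 60, TRUE))
  ints <- ints[ints$winner != ints$loser, ]
  s1 <- elo_scores(ints, init = 1000)
  s2 <- elo_scores(ints, init = 0)
  expect_equal(rank(-s1), rank(-s2))
  expect_equal(unname(s1 - s2), rep(1000, 5), tolerance = 1e-9)
})

test_that("randomized Elo recovers a steep planted hierarchy", {
  cfg <- sim_config(n_agents = 8, n_males = 4)
  si <- simulate_interactions(cfg, n_interactions = 28 * 30, seed = 6)
  er <- elo_ranks(si$interactions, n_orderings = 100)
  rho <- cor(er$rank[names(si$latent_rank)], si$latent_rank,
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("individuals without interactions are ranked last with a warning", {
  ints <- data.frame(winner = "A", loser = "B")
  expect_warning(er <- elo_ranks(ints, ids = c("A", "B", "C"),
                                 n_orderings = 5), "C")
  expect_equal(unname(er$rank["C"]), 3)
})

test_that("split-half repeatability separates signal from noise", {
  cfg <- sim_config(n_agents = 8, n_males = 4)
  si <- simulate_interactions(cfg, n_interactions = 500, seed = 7)
  sh <- split_half_repeatability(si$interactions, n_rep = 30, n_orderings = 10)
  expect_gt(sh$mean, 0.8)

  set.seed(83)
  coin <- data.frame(winner = character(0), loser = character(0))
  pairs <- t(combn(LETTERS[1:8], 2))
  for (r in 1:300) {
    p <- pairs[sample(nrow(pairs), 1), ]
    if (runif(1) < 0.5) p <- rev(p)
    coin <- rbind(coin, data.frame(winner = p[1], loser = p[2]))
  }
  sh0 <- split_half_repeatability(coin, n_rep = 30, n_orderings = 10)
  expect_lt(abs(sh0$mean), 0.35)
})

test_that("rank-alignment permutation test behaves at its extremes", {
  r <- setNames(1:8, letters[1:8])
  same <- perm_test_dominance_vs_rank(r, r, n_perm = 500)
  expect_equal(same$observed, 0)
  expect_true(same$significant)
  rev_r <- setNames(8:1, letters[1:8])
  opp <- perm_test_dominance_vs_rank(r, rev_r, n_perm = 500)
  expect_equal(opp$observed, 4)            # mean |i - (9 - i)| over 1..8
  expect_false(opp$significant)
  expect_gte(opp$p, 0.95 - 1)              # p in [0,1]
})

test_that("sex/top-rank test matches the closed-form extremes", {
  sexes <- setNames(rep(c("M", "F"), each = 5), letters[1:10])
  top_male <- setNames(c(1:5, 6:10), letters[1:10])   # males exactly top-5
  t1 <- perm_test_sex_top(top_male, sexes, n_perm = 500)
  expect_equal(t1$observed, 0)
  expect_true(t1$significant)
  # males and the top-n disjoint: |top - male| = 1 for 2 n_m individuals
  bottom_male <- setNames(c(6:10, 1:5), letters[1:10])
  t2 <- perm_test_sex_top(bottom_male, sexes, n_perm = 500)
  expect_equal(t2$observed, 2 * 5 / 10)
})

test_that("two-puller sex test finds a planted bias and not a null one", {
  set.seed(84)
  biased <- two_puller_sex_success(sim_mixed_puller(2000, 0.55), n_perm = 500)
  expect_true(biased$significant)
  expect_equal(biased$observed, 0.55, tolerance = 0.04)

  all_male <- two_puller_sex_success(rep(TRUE, 20), n_perm = 500)
  expect_equal(all_male$observed, 1.0)

  # under a fair coin the test keeps its size
  rej <- vapply(1:40, function(i) {
    two_puller_sex_success(sim_mixed_puller(100, 0.5), n_perm = 200)$significant
  }, logical(1))
  expect_lte(mean(rej), 0.2)
})

test_that("mixed two-puller extraction picks only opposite-sex single-pull events", {
  at <- data.frame(
    initiator = c("m1", "f1", "m1", "f1", "m1", "m2"),
    follower = c("x", "x", "y", "y", "z", "z"),
    outcome = c("pull", "anchor", "pull", "pull", "pull", "anchor"),
    event_id = c(1, 1, 2, 2, 3, 3))
  es <- structure(list(events = data.frame(event_id = 1:3),
                       attempts = at), class = "event_set")
  sexes <- c(m1 = "M", m2 = "M", f1 = "F")
  out <- mixed_two_puller_outcomes(es, sexes)
  # event 1: male pulled, female anchored -> male win; event 2: both pulled
  # (excluded); event 3: same-sex pair (excluded)
  expect_equal(out, TRUE)
})
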