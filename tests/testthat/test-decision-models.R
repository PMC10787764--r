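test_that("follow model recovers planted coefficient signs", {
  ev <- sim_follow_events(3000, seed = 91)
  fm <- fit_follow_model(ev)
  truth <- c(0.6, -0.8, 0.5, 1.2)
  expect_equal(unname(sign(fm$coefficients)), sign(truth))
  expect_true(all(abs(fm$coefficients - truth) < 3 * fm$robust_se))
  p <- predict_follow_surface(fm)
  expect_true(all(p$p_follow > 0 & p$p_follow < 1))
})

test_that("fitted surface reproduces the agreement-by-numbers interaction", {
  ev <- sim_follow_events(4000, seed = 92)
  fm <- fit_follow_model(ev)
  s <- predict_follow_surface(fm, n_initiators = c(1, 6),
                              agreement = c(0.05, 0.95))
  hiA <- s[s$agreement > 0.9, ]
  loA <- s[s$agreement < 0.1, ]
  # more initiators help at high agreement and hurt at low agreement
  expect_gt(hiA$p_follow[hiA$n_initiators == 6],
            hiA$p_follow[hiA$n_initiators == 1])
  expect_lt(loA$p_follow[loA$n_initiators == 6],
            loA$p_follow[loA$n_initiators == 1])
})

test_that("constant agreement degrades gracefully to a one-predictor model", {
  ev <- sim_follow_events(500, seed = 93)
  ev$agreement <- 1
  expect_silent(fm <- fit_follow_model(ev))
  expect_true(fm$degenerate_agreement)
  expect_false("agreement" %in% names(fm$coefficients))
})

test_that("with one event per follower the fit equals a plain logistic model", {
  ev <- sim_follow_events(400, seed = 94)
  ev$follower <- sprintf("F%04d", seq_len(nrow(ev)))
  fm <- fit_follow_model(ev)
  plain <- glm(success ~ n_initiators * agreement, binomial(), data = ev)
  expect_equal(unname(fm$coefficients), unname(coef(plain)), tolerance = 1e-9)
})

test_that("regime bins classify constructed pure cases", {
  set.seed(95)
  # one bin of pure compromise at 66 degrees disagreement
  comp <- data.frame(disagreement_deg = runif(120, 60, 72),
                     follower_rel = rvonmises(120, 0, 20))
  rc <- regime_classification(comp, dip_sims = 299, converge_sims = 99)
  b <- rc$bins[rc$bins$bin_lo_deg == 60, ]
  expect_equal(b$regime, "compromise")

  # one bin of pure choose at 150 degrees, followers split at +/-75
  side <- sample(c(-1, 1), 150, TRUE)
  cho <- data.frame(disagreement_deg = runif(150, 144, 156),
                    follower_rel = side * 75 * pi / 180 +
                      rvonmises(150, 0, 30))
  rc2 <- regime_classification(cho, dip_sims = 299, converge_sims = 99)
  b2 <- rc2$bins[rc2$bins$bin_lo_deg == 144, ]
  expect_equal(b2$regime, "choose")

  # sparse bins are flagged rather than classified
  expect_true(all(rc$bins$regime[rc$bins$n < 10] == "insufficient_data"))
})

test_that("regime labels are invariant under mirror reflection of all angles", {
  set.seed(96)
  fr <- sim_two_initiator_frame(600)
  fr_m <- fr; fr_m$follower_rel <- -fr_m$follower_rel
  set.seed(1); rc <- regime_classification(fr, dip_sims = 199, converge_sims = 99)
  set.seed(1); rc_m <- regime_classification(fr_m, dip_sims = 199, converge_sims = 99)
  usable <- rc$bins$regime != "insufficient_data"
  expect_equal(rc$bins$regime[usable], rc_m$bins$regime[usable])
})

test_that("converging-modes test tells bisector mass from two-mode mass", {
  set.seed(97)
  th <- 120 * pi / 180
  uni <- rvonmises(130, 0, 12)
  cm_u <- converging_modes_test(uni, th, n_sim = 199)
  expect_lt(cm_u$p.value, 0.05)
  comp <- sample(c(-1, 1), 130, TRUE)
  bim <- comp * th / 2 + rvonmises(130, 0, 12)
  cm_b <- converging_modes_test(bim, th, n_sim = 199)
  expect_gt(cm_b$p.value, 0.05)
})

test_that("direction clustering follows the worked examples", {
  set.seed(98)
  d2r <- pi / 180
  tight <- (10 + c(-2, -1, 0, 1, 2)) * d2r
  expect_equal(cluster_initiator_directions(tight)$k, 1)

  two <- c(rnorm(3, 0, 3), rnorm(2, 120, 3)) * d2r
  cl <- cluster_initiator_directions(two)
  expect_equal(cl$k, 2)
  expect_setequal(cl$sizes, c(3, 2))

  wrap <- c(175, -175, 178, -178) * d2r
  expect_equal(cluster_initiator_directions(wrap)$k, 1)

  # k never exceeds the number of directions
  expect_lte(cluster_initiator_directions(c(0, 2))$k, 2)
})

test_that("majority fit recovers a planted rule and stays flat under the null", {
  set.seed(99)
  cl <- sim_cluster_choice(2500)
  mf <- majority_rule_fit(cl, n_boot = 200)
  expect_equal(mf$beta, log(4) / 4, tolerance = 0.06)
  expect_true(all(diff(plogis(mf$beta * (-5:5))) > 0))   # monotone curve

  # deterministic rule: always pick the larger cluster
  det <- sim_cluster_choice(800)
  det$chosen <- ifelse(det$n1 >= det$n2, 1L, 2L)
  mfd <- majority_rule_fit(det, n_boot = 100)
  p3 <- plogis(mfd$beta * 3)
  expect_gt(p3, 0.95)

  cl0 <- sim_cluster_choice(2000, beta_major = 0)
  mf0 <- majority_rule_fit(cl0, n_boot = 200)
  expect_lt(abs(mf0$beta), 0.08)
  in_ci <- mf0$table$ci_lo <= 0.5 + 0.15 & mf0$table$ci_hi >= 0.5 - 0.15
  expect_gt(mean(in_ci), 0.8)
})

test_that("relabelling clusters mirrors the majority table exactly", {
  cl <- sim_cluster_choice(500, seed = 100)
  swapped <- data.frame(n1 = cl$n2, n2 = cl$n1, chosen = 3L - cl$chosen)
  set.seed(7); a <- majority_rule_fit(cl, n_boot = 50)$table
  set.seed(7); b <- majority_rule_fit(swapped, n_boot = 50)$table
  b_m <- b[order(-b$delta_n), ]
  expect_equal(a$delta_n, -b_m$delta_n)
  expect_equal(a$n_events, b_m$n_events)
  expect_equal(a$p_choose_1, 1 - b_m$p_choose_1, tolerance = 1e-12)
})

test_that("all-zero differences leave the fit undefined", {
  cl <- data.frame(n1 = rep(2, 30), n2 = rep(2, 30),
                   chosen = sample(1:2, 30, TRUE))
  expect_message(mf <- majority_rule_fit(cl, n_boot = 50), "undefined")
  expect_true(is.na(mf$beta))
})
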