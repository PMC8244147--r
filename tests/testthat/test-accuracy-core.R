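test_that("q2_from_me evaluates the marker-capture fraction", {
  expect_equal(q2_from_me(10000, 0), 1.0)
  expect_equal(q2_from_me(5000, 5000), 0.5)
  expect_equal(q2_from_me(23356, 3727), 0.8624, tolerance = 1e-4)
  expect_error(q2_from_me(-1, 10), "M >= 1")
})

test_that("theta_from_r2 matches direct evaluation and diverges near q2", {
  expect_equal(theta_from_r2(0, 1, 0.4), 0)
  expect_equal(theta_from_r2(0.277^2, 1, 0.523), 0.07977, tolerance = 1e-4)
  expect_gt(theta_from_r2(0.9999, 1, 0.4), 1e3)
  expect_error(theta_from_r2(0.9, 0.8, 0.4), "r2 must be < q2")
  expect_error(theta_from_r2(-0.1, 1, 0.4), ">= 0")
})

test_that("information <-> accuracy conversion is an exact roundtrip", {
  for (i in seq_len(nrow(roundtrip_grid))) {
    q2 <- roundtrip_grid$q2[i]; h2 <- roundtrip_grid$h2[i]
    r2 <- seq(0.01, 0.95 * q2, length.out = 25)
    th <- theta_from_r2(r2, q2, h2)
    expect_equal(r2_from_theta(th, q2, h2), r2, tolerance = 1e-10)
    # monotone increasing in theta
    expect_true(all(diff(r2_from_theta(sort(th), q2, h2)) > 0))
  }
  expect_equal(r2_from_theta(0, 1, 0.4), 0)
  expect_equal(r2_from_theta(1e6, 0.8, 0.4), 0.8, tolerance = 1e-3)
})

test_that("Fisher information is additive and extraction inverts combination", {
  expect_equal(fisher_combine(0, 0.7), 0.7)
  expect_equal(fisher_combine(0.3, 0.5), 0.8)
  expect_equal(fisher_extract(fisher_combine(0.3, 0.5), 0.3), 0.5)
  expect_error(fisher_combine(-0.1, 0.5), ">= 0")
  expect_error(fisher_extract(0.3, 0.5), "negative deviation")
  # combining accuracies through theta can only increase accuracy
  thA <- theta_from_r2(0.5^2, 1, 0.4)
  thD <- theta_from_r2(0.4^2, 1, 0.4)
  expect_gte(r2_from_theta(fisher_combine(thA, thD), 1, 0.4), 0.25)
})

test_that("index combination dominates its inputs and extraction inverts it", {
  expect_equal(index_combine_r2(0.25, 0), 0.25)
  expect_equal(index_combine_r2(1, 0.37), 1)
  expect_equal(index_combine_r2(0.25, 0.25), 0.4)
  for (i in seq_len(nrow(roundtrip_grid))) {
    q2 <- roundtrip_grid$q2[i]
    a <- seq(0.01, 0.95 * q2, length.out = 12)
    for (d in seq(0.01, 0.9, length.out = 8)) {
      comb <- index_combine_r2(a, d)
      expect_equal(index_extract_rD2(comb, a), rep(d, length(a)),
                   tolerance = 1e-12)
      # analytic dominance gap over max(a, d)
      gap <- ifelse(a >= d, d * (1 - a)^2, a * (1 - d)^2) / (1 - a * d)
      expect_equal(comb - pmax(a, d), gap, tolerance = 1e-12)
      expect_true(all(comb >= pmax(a, d) - 1e-15))
    }
  }
  expect_equal(index_extract_rD2(0.3, 0.3), 0)
  expect_warning(out <- index_extract_rD2(0.2, 0.25), "clamping")
  expect_equal(out, 0)
  expect_error(index_extract_rD2(0.2, 0.25, policy = "strict"), "less accurate")
})

test_that("me_fisher solves the quadratic in Me and recovers a known Me", {
  Me <- me_fisher(theta_D = 0.5, h2 = 0.4, N = 1000, M = 10000)
  expect_equal(Me, 744.56, tolerance = 1e-4)
  # residual of the defining quadratic, relative scale
  resid <- 0.5 * Me^2 + 0.5 * 10000 * Me - 1000 * 10000 * 0.4
  expect_lt(abs(resid) / (1000 * 10000 * 0.4), 1e-8)
  # construct theta_D from a known Me, recover it
  Me0 <- 1000; M <- 50000; N <- 2000; h2 <- 0.4
  th_D <- N * (M / (M + Me0)) * h2 / Me0
  expect_equal(me_fisher(theta_D = th_D, h2 = h2, N = N, M = M), Me0,
               tolerance = 1e-10)
  expect_error(me_fisher(r_G = 0.5, r_A = 0.6, h2 = 0.4, N = 100, M = 100),
               "undefined")
  # infinite information limit: Me -> 0
  expect_lt(me_fisher(theta_D = 1e9, h2 = 0.4, N = 1000, M = 10000), 1e-2)
})

test_that("me_index converges to the fixed point of the q2/Me system", {
  # layer-chicken reference parameters
  out <- me_index(0.277, h2 = 0.523, N = 777, M = 23356)
  expect_equal(out$Me, 3727, tolerance = 0.01)
  expect_equal(out$q2, 23356 / (23356 + out$Me))
  # fixed-point residual
  th <- theta_from_r2(0.277^2, out$q2, 0.523)
  expect_equal(out$Me, 777 * out$q2 * 0.523 / th, tolerance = 1e-7)
  # closed form at q2 = 1
  expect_equal(me_index(sqrt(0.1), 0.4, 1000, Inf)$Me, 3750, tolerance = 1e-10)
  # both Me estimators decrease in r_G at fixed r_A
  r_Gs <- seq(0.55, 0.9, by = 0.05)
  mf <- vapply(r_Gs, function(rg) me_fisher(rg, 0.5, 0.4, 1000, 20000), 1)
  mi <- vapply(r_Gs, function(rg) {
    rD2 <- index_extract_rD2(rg^2, 0.25)
    me_index(sqrt(rD2), 0.4, 1000, 20000)$Me
  }, 1)
  expect_true(all(diff(mf) < 0))
  expect_true(all(diff(mi) < 0))
  expect_error(me_index(0, 0.4, 1000, 20000), "r_D must lie")
})

test_that("theoretical Me formulas evaluate as published", {
  expect_equal(me_theoretical(37, 1.5, 9, "plain"), 999)
  expect_equal(me_theoretical(37, 1.5, 9, "log_corrected"), 999 / log(55.5))
  expect_equal(me_theoretical(120, 1.5, 9, "plain"), 3240)
  expect_error(me_theoretical(0.5, 1, 9, "log_corrected"), "Ne \\* L > 1")
})

test_that("segment retention probability behaves as a probability", {
  expect_equal(p_rt(5000, 9, 1.5, 2, ref_distance(0, 0)), 1.0)
  expect_equal(p_rt(3705, 9, 30 / 9, 2, ref_distance(1, 1)),
               (1 - 60 / 3705)^2, tolerance = 1e-12)
  expect_equal(p_rt(3705, 9, 30 / 9, 2, ref_distance(1, 1)), 0.9679,
               tolerance = 1e-4)
  expect_warning(p0 <- p_rt(27, 9, 1.5, 2, ref_distance(1, 1)), "certainly recombined")
  expect_equal(p0, 0)
  # multiplicative over generations
  p11 <- p_rt(4000, 9, 1.5, 2, ref_distance(1, 1))
  p22 <- p_rt(4000, 9, 1.5, 2, ref_distance(2, 2))
  p33 <- p_rt(4000, 9, 1.5, 2, ref_distance(3, 3))
  expect_equal(p33, p11 * p22, tolerance = 1e-12)
  # monotone: decreasing in distance and gamma, increasing in Me
  expect_lt(p22, p11)
  expect_lt(p_rt(4000, 9, 1.5, 3, ref_distance(1, 1)), p11)
  expect_gt(p_rt(8000, 9, 1.5, 2, ref_distance(1, 1)), p11)
})

test_that("target-population prediction composes retention and combination", {
  ctx <- prediction_context(h2 = 0.4, N = 1000, M = 20000, Me = 3705,
                            k = 9, L = 30 / 9)
  # inside the reference: pure genomic carryover
  expect_equal(predict_target_accuracy(0.5, 0, ctx, ref_distance(0, 0))$r_Gt, 0.5)
  # pedigree only
  expect_equal(predict_target_accuracy(0, 0.6, ctx)$r_Gt, 0.6)
  # one generation removed: equals manual composition of the primitives
  out <- predict_target_accuracy(0.5, 0.5, ctx, ref_distance(1, 1), "index")
  p <- (1 - 2 * 30 / 3705)^2
  expect_equal(out$p_rt, p)
  expect_equal(out$r_Dt, 0.5 * p)
  expect_equal(out$r_Gt, sqrt(index_combine_r2(0.25, (0.5 * p)^2)))
  expect_gte(out$r_Gt, out$r_At)
})

test_that("selection adjustment rescales accuracy by the variance ratio", {
  expect_equal(selection_adjusted_r2(0.5, 1, 1), 0.5)
  expect_equal(selection_adjusted_r2(0.5, 1, 0.8), 0.6)
  expect_equal(selection_adjusted_r2(0.9, 1, 1e-9), 1, tolerance = 1e-6)
  expect_error(selection_adjusted_r2(0.1, 1, 2), "variance ratio")
})

test_that("reference-population prediction inverts both Me estimators", {
  h2 <- 0.4; N <- 1500; M <- 20000
  ctx <- prediction_context(h2, N, M, Me = NA)
  for (r_A in c(0.3, 0.5, 0.65)) {
    for (r_G in c(r_A + 0.1, r_A + 0.2)) {
      mef <- me_fisher(r_G, r_A, h2, N, M)
      expect_equal(predict_reference_accuracy(mef, r_A, ctx, "fisher")$r_G,
                   r_G, tolerance = 1e-8)
      rD <- sqrt(index_extract_rD2(r_G^2, r_A^2))
      mei <- me_index(rD, h2, N, M)$Me
      expect_equal(predict_reference_accuracy(mei, r_A, ctx, "index")$r_G,
                   r_G, tolerance = 1e-8)
    }
  }
})
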