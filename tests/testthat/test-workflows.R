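test_that("decline regression recovers Me from a model-exact decay table", {
  # Synthetic accuracies generated from a known (Me*, r_Dr*) with the exact
  # per-generation retention factor; both routes must recover Me*.
  h2 <- 0.45; N <- 900; M <- 18000; kL <- 13.5; gamma <- 2
  Me_star <- 2500
  ctx <- prediction_context(h2, N, M, Me = Me_star, k = 9, L = 1.5)
  ref <- predict_reference_accuracy(Me_star, r_A = 0.55, ctx, "index")
  rho <- (1 - gamma * kL / Me_star)^2
  gaps <- 1:5
  r_D <- ref$r_D * rho^gaps
  r_A_t <- 0.55 * 0.7^gaps
  tbl <- data.frame(gap = gaps,
                    r_G = sqrt(index_combine_r2(r_A_t^2, r_D^2)),
                    r_A = r_A_t)
  dr <- decline_regression(tbl, h2 = h2, N = N, M = M, kL = kL, gamma = gamma)
  expect_equal(dr$me_from_slope, Me_star, tolerance = 1e-3)
  expect_equal(dr$me_from_intercept, Me_star, tolerance = 1e-3)
  expect_equal(dr$r_Dr_hat, ref$r_D, tolerance = 1e-6)
  expect_equal(dr$decline_factor_A, 0.7, tolerance = 1e-6)
})

test_that("decline regression accepts published coefficients directly", {
  dr <- decline_regression(slope = -0.0327, intercept = -1.2855,
                           slope_A = -0.3663, h2 = 0.523, N = 777, M = 23356,
                           kL = 30, gamma = 2)
  expect_equal(dr$me_from_slope, 2 * 30 / (1 - exp(-0.0327 / 2)),
               tolerance = 1e-10)
  expect_equal(dr$r_Dr_hat, exp(-1.2855))
  expect_error(decline_regression(slope = 0.01, intercept = -1, h2 = 0.5,
                                  N = 100, M = 1000),
               "no decline")
})

test_that("decline regression drops unusable gaps and needs two points", {
  tbl <- data.frame(gap = 1:3, r_G = c(0.6, 0.5, 0.30), r_A = c(0.5, 0.45, 0.42))
  expect_warning(dr <- decline_regression(tbl, h2 = 0.4, N = 500, M = 10000),
                 "dropping")
  expect_s3_class(dr, "decline_regression")
  tbl2 <- data.frame(gap = 1:2, r_G = c(0.6, 0.3), r_A = c(0.5, 0.45))
  expect_warning(expect_error(
    decline_regression(tbl2, h2 = 0.4, N = 500, M = 10000), "2 usable"))
})

test_that("gamma calibration recovers the generating value", {
  set.seed(21)
  h2 <- 0.4; Me <- 2000
  ctx <- prediction_context(h2, 1000, 20000, Me = Me, k = 9, L = 1.5)
  r_D_ref <- 0.6
  gammas <- replicate(20, {
    gaps <- 1:4
    r_At <- 0.5 * 0.75^gaps
    obs <- vapply(gaps, function(gp)
      predict_target_accuracy(r_D_ref, r_At[gp], ctx,
                              ref_distance(gp, gp), "index")$r_Gt, 1)
    obs <- pmin(pmax(obs + rnorm(4, 0, 0.01), 0.01), 0.99)
    calibrate_gamma(data.frame(gap = gaps, r_At = r_At, r_Gt_obs = obs),
                    r_D_ref, ctx)
  })
  expect_gte(mean(gammas), 1.7)
  expect_lte(mean(gammas), 2.3)
  # single near-reference gap: nearly flat objective
  ctx_big <- prediction_context(h2, 1000, 20000, Me = 50000, k = 9, L = 1.5)
  expect_warning(
    calibrate_gamma(data.frame(gap = 1, r_At = 0.5, r_Gt_obs = 0.65),
                    r_D_ref, ctx_big),
    "nearly flat")
})

test_that("single-generation experiment erodes accuracy with the gap", {
  set.seed(31)
  cfg <- sim_config(n_sires = 5, n_dams = 20, progeny_per_dam = 8,
                    n_generations = 4, h2 = 0.4)
  res <- run_single_gen_experiment(cfg, reference_gens = 1:3, target_gen = 4,
                                   n_reps = 2,
                                   hist = hist_settings(n_loci = 1200, ne = 50,
                                                        n_gen = 50),
                                   n_markers = 500, n_qtl = 90)
  pg <- res$per_gen[order(res$per_gen$gap), ]
  expect_equal(pg$gap, c(1, 2, 3))
  # erosion is present at every gap (retention strictly below 1) and the
  # per-haplotype retention compounds with the gap for a common Me
  expect_true(all(pg$p_rt_index > 0 & pg$p_rt_index < 1))
  ctx1 <- prediction_context(0.4, pg$N_ref[1], res$n_markers,
                             Me = pg$me_index[1])
  p_common <- vapply(pg$gap, function(gp)
    p_rt(pg$me_index[1], 9, 1.5, 2, ref_distance(gp, gp)), numeric(1))
  expect_true(all(diff(p_common) < 0))
  # reference-population predictions reproduce the observed accuracies
  for (i in seq_len(nrow(pg))) {
    ctx <- prediction_context(0.4, pg$N_ref[i], res$n_markers, Me = NA)
    expect_equal(predict_reference_accuracy(pg$me_index[i], pg$r_A_ref[i],
                                            ctx, "index")$r_G,
                 pg$r_G_ref[i], tolerance = 1e-6)
    expect_equal(predict_reference_accuracy(pg$me_fisher[i], pg$r_A_ref[i],
                                            ctx, "fisher")$r_G,
                 pg$r_G_ref[i], tolerance = 1e-6)
  }
})

test_that("accumulating experiment grows pedigree accuracy with reference size", {
  set.seed(41)
  cfg <- sim_config(n_sires = 5, n_dams = 20, progeny_per_dam = 8,
                    n_generations = 4, h2 = 0.4)
  res <- run_accumulating_experiment(cfg, n_reps = 2,
                                     hist = hist_settings(n_loci = 1200, ne = 50,
                                                          n_gen = 50),
                                     n_markers = 500, n_qtl = 90, seed = 41)
  pg <- res$per_gen
  expect_equal(pg$N_ref, 160 * (1:4))
  # genomic accuracy in the reference rises as data accumulate
  expect_gt(pg$r_G_ref[4], pg$r_G_ref[1])
  expect_true(all(is.finite(pg$r_Gt_pred_index)))
})

test_that("Me estimation helper returns all routes consistently", {
  est <- estimate_me_from_accuracies(r_A = 0.5, r_G = 0.7, h2 = 0.4,
                                     N = 1000, M = 20000)
  expect_gt(est$me_fisher, est$me_index)  # Fisher exceeds Index here
  expect_equal(est$q2_index, 20000 / (20000 + est$me_index))
  expect_equal(est$r_D_index^2, index_extract_rD2(0.49, 0.25))
})
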