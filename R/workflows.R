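#' Estimate Me from reference accuracies by all implemented routes
#'
#' Convenience wrapper returning the Fisher-route and Index-route estimates
#' of the effective number of chromosome segments from observed reference
#' accuracies, together with the derived deviation accuracy.
#'
#' @param r_A,r_G Observed pedigree and genomic EBV accuracies in the
#'   reference population.
#' @param h2 Heritability, `N` reference size, `M` marker count.
#' @param N,M See above.
#' @param policy Passed to [index_extract_rD2()].
#' @return A list: `me_fisher`, `me_index`, `q2_index`, `r_D_index`
#'   (deviation accuracy on the Index route), `theta_D` (Fisher route).
#' @export
estimate_me_from_accuracies <- function(r_A, r_G, h2, N, M, policy = "clamp") {
  th_D <- theta_from_r2(r_G^2, 1, h2) - theta_from_r2(r_A^2, 1, h2)
  mef <- if (th_D > 0) me_fisher(theta_D = th_D, h2 = h2, N = N, M = M) else NA_real_
  rD2 <- index_extract_rD2(r_G^2, r_A^2, policy = policy)
  mei <- if (rD2 > 0) me_index(sqrt(rD2), h2, N, M) else list(Me = NA_real_, q2 = NA_real_)
  list(me_fisher = mef, me_index = mei$Me, q2_index = mei$q2,
       r_D_index = sqrt(rD2), theta_D = th_D)
}

# Fit one evaluation (PBLUP or GBLUP) and return reference/target accuracies.
# K covers at least ref_ids and tgt_ids; phen restricted to ref_ids.
eval_accuracies <- function(K, sim, ref_ids, tgt_ids, center_by_gen) {
  ids <- c(ref_ids, tgt_ids)
  ebv <- solve_blup(K[ids, ids], sim$phen[sim$phen$id %in% ref_ids, c("id", "value")],
                    sim$cfg$h2)
  e <- stats::setNames(ebv$ebv, ebv$id)
  gen <- stats::setNames(sim$generation, sim$phen$id)
  grp_r <- if (center_by_gen) gen[ref_ids] else NULL
  list(r_ref = population_accuracy(e[ref_ids], sim$tbv[ref_ids], grp_r),
       r_tgt = population_accuracy(e[tgt_ids], sim$tbv[tgt_ids]))
}

# Shared driver: one replicate of a simulated breeding program plus its
# relationship matrices.
simulate_replicate <- function(cfg, hist, n_markers, n_qtl, maf_min, g_method) {
  genome <- genome_spec(k = hist$k, L = hist$L, n_loci = hist$n_loci,
                        mutation_rate = hist$mutation_rate)
  pool <- simulate_historical(genome, ne = hist$ne, n_gen = hist$n_gen)
  map <- assign_loci(pool, maf_min = maf_min, n_qtl = n_qtl, n_markers = n_markers)
  sim <- simulate_breeding(cfg, pool, map)
  G <- build_G(sim$markers, method = g_method)
  A <- build_A(sim$pedigree)
  list(sim = sim, G = G, A = A)
}

#' Default desk-scale historical-phase settings
#'
#' @param k,L Genome dimensions (chromosomes, Morgan per chromosome).
#' @param n_loci Starting loci in the historical phase.
#' @param ne Historical population size.
#' @param n_gen Historical generations.
#' @param mutation_rate Per-locus per-gamete mutation rate.
#' @return A list consumed by the experiment drivers.
#' @export
hist_settings <- function(k = 9, L = 1.5, n_loci = 5000, ne = 250,
                          n_gen = 200, mutation_rate = 1e-8) {
  list(k = k, L = L, n_loci = n_loci, ne = ne, n_gen = n_gen,
       mutation_rate = mutation_rate)
}

#' Accumulating-reference experiment
#'
#' Replicates a breeding program in which the reference population
#' accumulates from generation 0 onward, each time targeting the next
#' generation: for target generation `t`, generations `0..t-1` are the
#' (phenotyped, genotyped) reference and generation `t` the selection
#' candidates. Empirical accuracies (correlations of EBV with true breeding
#' values) are averaged over replicates first; Me estimates and target
#' predictions are then derived from the averaged accuracies.
#'
#' @param cfg A [sim_config()].
#' @param n_reps Number of replicates.
#' @param target_gens Target generations to evaluate (reference accumulates
#'   up to each).
#' @param hist Historical-phase settings from [hist_settings()].
#' @param n_markers,n_qtl,maf_min Locus assignment parameters.
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @return An object of class `"experiment_result"`: `per_gen` (averaged
#'   accuracies, Me estimates, predictions per target generation), `reps`
#'   (per-replicate accuracies), plus the configuration.
#' @export
run_accumulating_experiment <- function(cfg, n_reps = 10,
                                        target_gens = seq_len(cfg$n_generations),
                                        hist = hist_settings(),
                                        n_markers = 2000, n_qtl = 270,
                                        maf_min = 0.1, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), max(target_gens) <= cfg$n_generations)
  center <- cfg$selection == "gebv"
  rows <- list()
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    r <- simulate_replicate(cfg, hist, n_markers, n_qtl, maf_min, cfg$g_method)
    sim <- r$sim
    for (t in target_gens) {
      ref_ids <- sim$phen$id[sim$generation < t]
      tgt_ids <- sim$phen$id[sim$generation == t]
      accG <- eval_accuracies(r$G, sim, ref_ids, tgt_ids, center)
      accA <- eval_accuracies(r$A, sim, ref_ids, tgt_ids, center)
      me_var <- me_from_relationship_variance(r$G[ref_ids, ref_ids],
                                              r$A[ref_ids, ref_ids])
      rows[[length(rows) + 1]] <- data.frame(
        rep = rep, target_gen = t, N_ref = length(ref_ids),
        r_G_ref = accG$r_ref, r_G_tgt = accG$r_tgt,
        r_A_ref = accA$r_ref, r_A_tgt = accA$r_tgt,
        me_var = me_var)
    }
  }
  reps <- do.call(rbind, rows)
  finish_experiment(reps, cfg, n_markers, hist, gap = 1L, n_reps = n_reps)
}

#' Single-generation reference experiment
#'
#' Each replicate uses one generation at a time as the reference population
#' and a fixed later generation as the target, probing the erosion of
#' genomic information over 1 to several generations of separation.
#'
#' @inheritParams run_accumulating_experiment
#' @param reference_gens Generations used as (single-generation) reference
#'   populations.
#' @param target_gen Target generation (must exceed all reference
#'   generations).
#' @return An `"experiment_result"` with one row of `per_gen` per reference
#'   generation; generation gap is `target_gen - reference_gen`.
#' @export
run_single_gen_experiment <- function(cfg, reference_gens, target_gen,
                                      n_reps = 10, hist = hist_settings(),
                                      n_markers = 2000, n_qtl = 270,
                                      maf_min = 0.1, seed = 1) {
  stopifnot(all(reference_gens < target_gen), target_gen <= cfg$n_generations)
  center <- cfg$selection == "gebv"
  rows <- list()
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    r <- simulate_replicate(cfg, hist, n_markers, n_qtl, maf_min, cfg$g_method)
    sim <- r$sim
    for (g in reference_gens) {
      ref_ids <- sim$phen$id[sim$generation == g]
      tgt_ids <- sim$phen$id[sim$generation == target_gen]
      accG <- eval_accuracies(r$G, sim, ref_ids, tgt_ids, center)
      accA <- eval_accuracies(r$A, sim, ref_ids, tgt_ids, center)
      me_var <- me_from_relationship_variance(r$G[ref_ids, ref_ids],
                                              r$A[ref_ids, ref_ids])
      rows[[length(rows) + 1]] <- data.frame(
        rep = rep, reference_gen = g, target_gen = target_gen,
        gap = target_gen - g, N_ref = length(ref_ids),
        r_G_ref = accG$r_ref, r_G_tgt = accG$r_tgt,
        r_A_ref = accA$r_ref, r_A_tgt = accA$r_tgt,
        me_var = me_var)
    }
  }
  reps <- do.call(rbind, rows)
  finish_experiment(reps, cfg, n_markers, hist, gap = NULL, n_reps = n_reps)
}

# Average accuracies over replicates, derive Me and target predictions.
finish_experiment <- function(reps, cfg, n_markers, hist, gap, n_reps) {
  key <- if (is.null(gap)) "reference_gen" else "target_gen"
  agg <- stats::aggregate(reps[c("N_ref", "r_G_ref", "r_G_tgt",
                                 "r_A_ref", "r_A_tgt", "me_var")],
                          by = reps[key], FUN = mean)
  agg$gap <- if (is.null(gap)) reps$gap[match(agg[[key]], reps[[key]])] else gap
  kL <- hist$k * hist$L
  pred <- lapply(seq_len(nrow(agg)), function(i) {
    a <- agg[i, ]
    est <- estimate_me_from_accuracies(a$r_A_ref, a$r_G_ref, cfg$h2,
                                       a$N_ref, n_markers)
    d <- ref_distance(a$gap, a$gap)
    out <- data.frame(me_fisher = est$me_fisher, me_index = est$me_index,
                      r_D_index = est$r_D_index,
                      p_rt_index = NA_real_, r_Gt_pred_index = NA_real_,
                      r_Gt_pred_fisher = NA_real_)
    if (is.finite(est$me_index)) {
      ctx_i <- prediction_context(cfg$h2, a$N_ref, n_markers, Me = est$me_index,
                                  k = hist$k, L = hist$L)
      pi <- predict_target_accuracy(est$r_D_index, a$r_A_tgt, ctx_i, d, "index")
      out$p_rt_index <- pi$p_rt
      out$r_Gt_pred_index <- pi$r_Gt
    }
    if (is.finite(est$me_fisher)) {
      ctx_f <- prediction_context(cfg$h2, a$N_ref, n_markers, Me = est$me_fisher,
                                  k = hist$k, L = hist$L)
      rD_f <- predict_reference_accuracy(est$me_fisher, a$r_A_ref, ctx_f,
                                         "fisher")$r_D
      pf <- predict_target_accuracy(rD_f, a$r_A_tgt, ctx_f, d, "fisher")
      out$r_Gt_pred_fisher <- pf$r_Gt
    }
    out
  })
  per_gen <- cbind(agg, do.call(rbind, pred))
  structure(list(per_gen = per_gen, reps = reps, cfg = cfg,
                 n_reps = n_reps, n_markers = n_markers, hist = hist),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d replicates, selection = %s, h2 = %g\n",
              x$n_reps, x$cfg$selection, x$cfg$h2))
  print(format(x$per_gen, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Decline regression of genomic-deviation accuracy over generations
#'
#' Estimates the effective number of chromosome segments from the decline
#' of cross-validation accuracies across validation generations. Given
#' per-gap accuracies of genomic and pedigree EBV, the deviation accuracy
#' `r_D` is extracted at each gap (selection-index route), and `ln(r_D)` is
#' regressed on the generation gap by ordinary least squares. Two Me
#' estimates follow:
#' * slope route: the squared per-generation retention factor
#'   `(1 - gamma*kL/Me)^2` (the recombination exponent grows by 2 per
#'   generation, one meiosis per parent) is equated to `exp(slope)`;
#' * intercept route: `r_Dr = exp(intercept)` is the deviation accuracy at
#'   gap 0, i.e. in the reference population, from which [me_index()]
#'   estimates Me.
#'
#' The regression coefficients can be supplied directly (e.g. published
#' estimates) instead of the accuracy table.
#'
#' @param accuracies Optional data.frame with columns `gap`, `r_G`, `r_A`.
#' @param slope,intercept Regression of `ln(r_D)` on gap, if supplied
#'   directly.
#' @param slope_A Optional slope of `ln(r_A)` on gap (computed from
#'   `accuracies` when present).
#' @param h2,N,M Reference-population parameters for the intercept route.
#' @param kL Total map length in Morgan.
#' @param gamma Segment-size inflation factor.
#' @return A list of class `"decline_regression"`: `slope`, `intercept`,
#'   `slope_A`, `decline_factor_D` (`exp(slope)`), `decline_factor_A`,
#'   `r_Dr_hat`, `me_from_slope`, `me_from_intercept`, `q2`.
#' @examples
#' decline_regression(slope = -0.0327, intercept = -1.2855,
#'                    slope_A = -0.3663, h2 = 0.523, N = 777, M = 23356)
#' @export
decline_regression <- function(accuracies = NULL, slope = NULL, intercept = NULL,
                               slope_A = NULL, h2, N, M, kL = 30, gamma = 2) {
  if (!is.null(accuracies)) {
    stopifnot(all(c("gap", "r_G", "r_A") %in% names(accuracies)))
    rD2 <- suppressWarnings(
      mapply(index_extract_rD2, accuracies$r_G^2, accuracies$r_A^2))
    usable <- rD2 > 0
    if (any(!usable))
      warning(sprintf("decline_regression(): dropping %d gap(s) with non-positive r_D",
                      sum(!usable)))
    if (sum(usable) < 2)
      stop("decline_regression(): need at least 2 usable generation gaps")
    fit <- stats::lm(log(sqrt(rD2[usable])) ~ accuracies$gap[usable])
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    if (is.null(slope_A) && all(accuracies$r_A > 0)) {
      fitA <- stats::lm(log(accuracies$r_A) ~ accuracies$gap)
      slope_A <- unname(stats::coef(fitA)[2])
    }
  }
  if (is.null(slope) || is.null(intercept))
    stop("decline_regression(): supply either an accuracy table or slope + intercept")
  retention <- exp(slope / 2)  # per-generation per-haplotype retention
  if (retention >= 1)
    stop("decline_regression(): non-negative slope; no decline to interpret")
  me_slope <- gamma * kL / (1 - retention)
  r_Dr_hat <- exp(intercept)
  if (r_Dr_hat <= 0 || r_Dr_hat >= 1)
    stop("decline_regression(): intercept implies r_Dr outside (0, 1)")
  mi <- me_index(r_Dr_hat, h2, N, M)
  structure(list(slope = slope, intercept = intercept, slope_A = slope_A,
                 decline_factor_D = exp(slope),
                 decline_factor_A = if (is.null(slope_A)) NA_real_ else exp(slope_A),
                 r_Dr_hat = r_Dr_hat,
                 me_from_slope = me_slope,
                 me_from_intercept = mi$Me, q2 = mi$q2),
            class = "decline_regression")
}

#' @export
print.decline_regression <- function(x, ...) {
  cat("Decline regression of ln(r_D) on generation gap:\n")
  cat(sprintf("  slope = %.4f (per-generation factor %.4f), intercept = %.4f\n",
              x$slope, x$decline_factor_D, x$intercept))
  if (!is.na(x$decline_factor_A))
    cat(sprintf("  pedigree accuracy decline factor = %.4f\n", x$decline_factor_A))
  cat(sprintf("  r_Dr (gap 0) = %.4f\n", x$r_Dr_hat))
  cat(sprintf("  Me from slope = %.1f, Me from intercept = %.1f (q2 = %.4f)\n",
              x$me_from_slope, x$me_from_intercept, x$q2))
  invisible(x)
}

#' Calibrate the segment-size inflation factor
#'
#' Finds the `gamma` that minimises the squared difference between
#' predicted and observed genomic EBV accuracies in target populations
#' across generation gaps. With a single gap close to the reference the
#' objective is nearly flat (predictions are robust to `gamma` there) and a
#' warning is emitted.
#'
#' @param per_gap A data.frame with columns `gap`, `r_At` (target pedigree
#'   accuracy), `r_Gt_obs` (observed target genomic accuracy).
#' @param r_D_ref Deviation accuracy in the reference population.
#' @param ctx A [prediction_context()] carrying `Me`, `k`, `L`, `h2` (its
#'   `gamma` is ignored).
#' @param combine `"index"` or `"fisher"`.
#' @return The calibrated `gamma`, bounded in `(0, Me / (kL))`.
#' @export
calibrate_gamma <- function(per_gap, r_D_ref, ctx,
                            combine = c("index", "fisher")) {
  combine <- match.arg(combine)
  stopifnot(all(c("gap", "r_At", "r_Gt_obs") %in% names(per_gap)),
            inherits(ctx, "prediction_context"))
  if (nrow(per_gap) < 1) stop("calibrate_gamma(): no generation gaps supplied")
  upper <- ctx$Me / (ctx$k * ctx$L)
  obj <- function(gamma) {
    ctx$gamma <- gamma
    pred <- vapply(seq_len(nrow(per_gap)), function(i) {
      predict_target_accuracy(r_D_ref, per_gap$r_At[i], ctx,
                              ref_distance(per_gap$gap[i], per_gap$gap[i]),
                              combine)$r_Gt
    }, numeric(1))
    sum((pred - per_gap$r_Gt_obs)^2)
  }
  if (nrow(per_gap) == 1 &&
      p_rt(ctx$Me, ctx$k, ctx$L, 2, ref_distance(per_gap$gap[1], per_gap$gap[1])) > 0.99)
    warning("calibrate_gamma(): single gap with retention near 1; objective is nearly flat")
  opt <- stats::optimize(obj, c(1e-6, upper * (1 - 1e-9)))
  if (obj(1e-6) == obj(upper / 2) && obj(upper / 2) == opt$objective)
    stop("calibrate_gamma(): flat objective; accuracies carry no information about gamma")
  opt$minimum
}
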