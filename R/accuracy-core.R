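#' Population parameters for deterministic accuracy prediction
#'
#' Bundles the scalar population parameters that the deterministic accuracy
#' formulas consume: the heritability of the training phenotypes, the size of
#' the reference population, the number of genotyped markers, the effective
#' number of chromosome segments (Me), and the genome/recombination
#' parameters used by the erosion model.
#'
#' @param h2 Narrow-sense heritability of the training phenotypes, in (0, 1].
#' @param N Reference-population size (number of phenotyped + genotyped
#'   individuals).
#' @param M Number of genotyped markers.
#' @param Me Effective number of chromosome segments in the reference
#'   population (real-valued, > 0). May be `NA` when the context is used only
#'   to estimate Me.
#' @param Ne Effective population size (optional; used only by
#'   [me_theoretical()]).
#' @param k Number of chromosomes.
#' @param L Chromosome length in Morgan (average length if chromosomes
#'   differ).
#' @param gamma Segment-size inflation factor of the erosion model. The
#'   default 2 reflects that co-segregation information is lost roughly twice
#'   as fast as linkage-disequilibrium information; see [p_rt()].
#' @param q2 Proportion of genetic variance captured by the markers for the
#'   genomic-deviation EBV. Defaults to `M / (M + Me)` when `Me` is given
#'   (see [q2_from_me()]); pedigree and full genomic EBV always carry
#'   `q2 = 1` because pedigree covers the whole genome.
#'
#' @return An object of class `"prediction_context"`: a list with the fields
#'   above.
#' @examples
#' ctx <- prediction_context(h2 = 0.4, N = 1000, M = 10000, Me = 1000)
#' ctx$q2
#' @export
prediction_context <- function(h2, N, M, Me = NA_real_, Ne = NA_real_,
                               k = 9, L = 1.5, gamma = 2,
                               q2 = if (is.na(Me)) NA_real_ else q2_from_me(M, Me)) {
  stopifnot(is.numeric(h2), h2 > 0, h2 <= 1,
            is.numeric(N), N >= 1,
            is.numeric(M), M >= 1,
            is.na(Me) || Me > 0,
            is.na(Ne) || Ne > 0,
            k >= 1, L > 0, gamma > 0,
            is.na(q2) || (q2 > 0 && q2 <= 1))
  structure(list(h2 = h2, N = N, M = M, Me = Me, Ne = Ne,
                 k = k, L = L, gamma = gamma, q2 = q2),
            class = "prediction_context")
}

#' @export
print.prediction_context <- function(x, ...) {
  cat("Prediction context:\n")
  cat(sprintf("  h2 = %.4g, N = %g, M = %g, Me = %.4g, q2 = %.4g\n",
              x$h2, x$N, x$M, x$Me, x$q2))
  cat(sprintf("  genome: k = %g chromosomes x %g Morgan, gamma = %g, Ne = %s\n",
              x$k, x$L, x$gamma, format(x$Ne)))
  invisible(x)
}

#' Proportion of genetic variance captured by markers
#'
#' When markers and QTL share the same allele-frequency distribution, the
#' proportion of genetic variance captured by `M` markers in a genome of
#' `Me` effective segments is `M / (M + Me)`.
#'
#' @param M Number of genotyped markers (>= 1).
#' @param Me Effective number of chromosome segments (>= 0).
#' @return `q2 = M / (M + Me)`, in (0, 1].
#' @examples
#' q2_from_me(23356, 3727)
#' @export
q2_from_me <- function(M, Me) {
  stopifnot(is.numeric(M), is.numeric(Me))
  if (M < 1 || Me < 0) stop("q2_from_me(): require M >= 1 and Me >= 0")
  M / (M + Me)
}

#' Fisher information of an EBV from its squared accuracy
#'
#' Converts the squared population accuracy of an EBV into its Fisher
#' information statistic, the amount of information about the true breeding
#' value contained in the EBV. The statistic is additive over EBV with
#' independent sampling errors, which is what makes it useful for combining
#' and separating pedigree and genomic information.
#'
#' @param r2 Squared accuracy, in `[0, q2)`.
#' @param q2 Proportion of genetic variance captured by the information
#'   source (1 for pedigree-based and full genomic EBV).
#' @param h2 Heritability of the training phenotypes.
#' @return The information statistic `theta = r2 (1 - r2 q2 h2) / (q2 - r2)`,
#'   >= 0, strictly increasing in `r2` and diverging as `r2` approaches `q2`.
#' @seealso [r2_from_theta()] for the exact inverse.
#' @export
theta_from_r2 <- function(r2, q2 = 1, h2) {
  stopifnot(is.numeric(r2), is.numeric(q2), is.numeric(h2))
  if (any(r2 < 0)) stop("theta_from_r2(): r2 must be >= 0")
  if (any(r2 >= q2)) stop("theta_from_r2(): r2 must be < q2 (information diverges at r2 = q2)")
  if (h2 <= 0 || h2 > 1) stop("theta_from_r2(): h2 must be in (0, 1]")
  r2 * (1 - r2 * q2 * h2) / (q2 - r2)
}

#' Squared accuracy of an EBV from its Fisher information
#'
#' Exact inverse of [theta_from_r2()]: solves the quadratic
#' `q2 h2 r^4 + (-1 - theta) r^2 + q2 theta = 0` for the squared accuracy,
#' taking the root in `[0, q2)`.
#'
#' @param theta Fisher information statistic, >= 0.
#' @inheritParams theta_from_r2
#' @return Squared accuracy in `[0, q2)`; tends to `q2` as `theta` grows.
#' @export
r2_from_theta <- function(theta, q2 = 1, h2) {
  stopifnot(is.numeric(theta), is.numeric(q2), is.numeric(h2))
  if (any(theta < 0)) stop("r2_from_theta(): theta must be >= 0")
  if (h2 <= 0 || h2 > 1) stop("r2_from_theta(): h2 must be in (0, 1]")
  # q2 holds the squared capture fraction, so the quartic coefficient is q2^2
  disc <- (1 + theta)^2 - 4 * h2 * q2^2 * theta
  # disc >= (1 - theta)^2 >= 0 for q2, h2 in (0,1]; guard rounding
  disc <- pmax(disc, 0)
  (1 + theta - sqrt(disc)) / (2 * q2 * h2)
}

#' Combine independent information sources on the Fisher scale
#'
#' Under independent sampling errors the Fisher information of the genomic
#' EBV is the sum of the information in the pedigree EBV and in the
#' genomic-deviation EBV: `theta_G = theta_A + theta_D`.
#'
#' @param theta_A,theta_D Fisher information statistics, each >= 0.
#' @return `theta_A + theta_D`.
#' @export
fisher_combine <- function(theta_A, theta_D) {
  if (any(theta_A < 0) || any(theta_D < 0))
    stop("fisher_combine(): information statistics must be >= 0")
  theta_A + theta_D
}

#' Extract the genomic-deviation information from combined information
#'
#' @param theta_G Total information of the genomic EBV.
#' @param theta_A Information of the pedigree EBV.
#' @return `theta_D = theta_G - theta_A` (must be >= 0).
#' @export
fisher_extract <- function(theta_G, theta_A) {
  if (any(theta_G < 0) || any(theta_A < 0))
    stop("fisher_extract(): information statistics must be >= 0")
  if (any(theta_G < theta_A))
    stop("fisher_extract(): theta_G < theta_A implies negative deviation information")
  theta_G - theta_A
}

#' Selection-index combination of pedigree and genomic-deviation accuracy
#'
#' Squared accuracy of the optimal index `b_A * g_A + b_D * g_D` of two EBV
#' with independent sampling errors:
#' `r_G^2 = (r_A^2 + r_D^2 - 2 r_A^2 r_D^2) / (1 - r_A^2 r_D^2)`.
#'
#' @param r_A2 Squared accuracy of the pedigree EBV, in \[0, 1\].
#' @param r_D2 Squared accuracy of the genomic-deviation EBV, in \[0, 1\].
#' @return Squared accuracy of the combined (genomic) EBV, in
#'   `[max(r_A2, r_D2), 1]`. Symmetric in its arguments; returns 1 when
#'   either input is 1.
#' @seealso [index_extract_rD2()] for the inverse.
#' @export
index_combine_r2 <- function(r_A2, r_D2) {
  if (any(r_A2 < 0 | r_A2 > 1) || any(r_D2 < 0 | r_D2 > 1))
    stop("index_combine_r2(): squared accuracies must lie in [0, 1]")
  num <- r_A2 + r_D2 - 2 * r_A2 * r_D2
  den <- 1 - r_A2 * r_D2
  out <- ifelse(den == 0, 1, num / den)
  pmin(out, 1)
}

#' Extract squared deviation accuracy from genomic and pedigree accuracy
#'
#' Inverts [index_combine_r2()] in its second argument:
#' `r_D^2 = (r_G^2 - r_A^2) / (1 + r_A^2 (r_G^2 - 2))`.
#'
#' With empirical accuracies, sampling noise can produce `r_G < r_A`, for
#' which the deviation accuracy is undefined. The default policy clamps the
#' result to 0 with a warning; `policy = "strict"` raises an error instead.
#'
#' @param r_G2 Squared accuracy of the genomic EBV.
#' @param r_A2 Squared accuracy of the pedigree EBV.
#' @param policy `"clamp"` (default) or `"strict"` for the `r_G2 < r_A2`
#'   case.
#' @return Squared accuracy of the genomic-deviation EBV.
#' @export
index_extract_rD2 <- function(r_G2, r_A2, policy = c("clamp", "strict")) {
  policy <- match.arg(policy)
  if (any(r_G2 < 0 | r_G2 > 1) || any(r_A2 < 0 | r_A2 > 1))
    stop("index_extract_rD2(): squared accuracies must lie in [0, 1]")
  if (any(r_G2 < r_A2)) {
    if (policy == "strict")
      stop("index_extract_rD2(): r_G2 < r_A2; genomic EBV cannot be less accurate than its pedigree component")
    warning("index_extract_rD2(): r_G2 < r_A2 (sampling noise?); clamping r_D2 to 0")
  }
  den <- 1 + r_A2 * (r_G2 - 2)
  out <- ifelse(r_G2 < r_A2, 0, (r_G2 - r_A2) / den)
  pmax(out, 0)
}

#' Effective number of chromosome segments from accuracies (Fisher route)
#'
#' Derives Me from the observed accuracies of genomic and pedigree EBV in
#' the reference population. On the Fisher scale (with `q2 = 1` for both
#' EBV), the deviation information is `theta_D = theta_G - theta_A`;
#' substituting `q2 = M/(M + Me)` into `theta_D = N q2 h2 / Me` yields the
#' quadratic `theta_D Me^2 + theta_D M Me - N M h2 = 0`, whose positive root
#' is returned.
#'
#' @param r_G,r_A Observed accuracies of the genomic and pedigree EBV in the
#'   reference population; require `r_G > r_A`.
#' @param h2 Heritability of the training phenotypes.
#' @param N Reference-population size.
#' @param M Number of genotyped markers.
#' @param theta_D Optionally supply the deviation information directly
#'   instead of `r_G`/`r_A`.
#' @return Me (> 0).
#' @examples
#' me_fisher(theta_D = 0.5, h2 = 0.4, N = 1000, M = 10000)
#' @export
me_fisher <- function(r_G = NULL, r_A = NULL, h2, N, M, theta_D = NULL) {
  if (is.null(theta_D)) {
    stopifnot(!is.null(r_G), !is.null(r_A))
    if (r_G <= r_A)
      stop("me_fisher(): r_G <= r_A gives non-positive deviation information; Me is undefined")
    theta_D <- theta_from_r2(r_G^2, 1, h2) - theta_from_r2(r_A^2, 1, h2)
  }
  if (theta_D <= 0) stop("me_fisher(): theta_D must be > 0")
  if (h2 <= 0 || N < 1 || M < 1) stop("me_fisher(): invalid parameters")
  (-theta_D * M + sqrt(theta_D^2 * M^2 + 4 * theta_D * N * M * h2)) / (2 * theta_D)
}

#' Effective number of chromosome segments from accuracies (Index route)
#'
#' Derives Me from the accuracy of the genomic-deviation EBV in the
#' reference population, accounting for the marker-captured variance
#' `q2 = M / (M + Me)`. Because `q2` itself depends on Me, the pair of
#' relations `Me = N q2 h2 / theta_D(r_D^2, q2, h2)` and `q2 = M/(M + Me)`
#' is solved iteratively: a damped fixed-point iteration (averaging
#' successive iterates, which suppresses the oscillation of the plain
#' iteration) with a bracketed root-finding fallback.
#'
#' @param r_D Accuracy of the genomic-deviation EBV in the reference
#'   population, in (0, 1). May instead be derived from `r_G`/`r_A` via
#'   [index_extract_rD2()] by the caller.
#' @param h2 Heritability of the training phenotypes.
#' @param N Reference-population size.
#' @param M Number of genotyped markers. `M = Inf` gives the one-shot closed
#'   form with `q2` fixed at 1.
#' @param tol Relative convergence tolerance.
#' @param max_iter Maximum damped-iteration count before falling back to
#'   bracketed root finding.
#' @return A list with fields `Me` and `q2` at the converged fixed point.
#' @examples
#' me_index(r_D = exp(-1.2855), h2 = 0.523, N = 777, M = 23356)
#' @export
me_index <- function(r_D, h2, N, M, tol = 1e-8, max_iter = 500) {
  if (r_D <= 0 || r_D >= 1) stop("me_index(): r_D must lie in (0, 1)")
  if (h2 <= 0 || h2 > 1 || N < 1 || M < 1) stop("me_index(): invalid parameters")
  step <- function(Me) {
    q2 <- if (is.infinite(M)) 1 else M / (M + Me)
    if (r_D^2 >= q2)
      stop("me_index(): r_D^2 >= q2 at an iterate; accuracy exceeds the variance markers can capture")
    th <- theta_from_r2(r_D^2, q2, h2)
    N * q2 * h2 / th
  }
  if (is.infinite(M)) {
    th <- theta_from_r2(r_D^2, 1, h2)
    return(list(Me = N * h2 / th, q2 = 1))
  }
  Me <- N * h2 / theta_from_r2(r_D^2, 1, h2)  # q2 = 1 start
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    Me_new <- (Me + step(Me)) / 2  # damped
    if (abs(Me_new - Me) / Me < tol) {
      Me <- Me_new
      converged <- TRUE
      break
    }
    Me <- Me_new
  }
  if (!converged) {
    f <- function(x) x - step(x)
    root <- tryCatch(stats::uniroot(f, c(1, 100 * M), tol = tol)$root,
                     error = function(e)
                       stop(sprintf("me_index(): no convergence after %d iterations (residual %.3g) and bracketing failed",
                                    max_iter, abs(f(Me)))))
    Me <- root
  }
  list(Me = Me, q2 = M / (M + Me))
}

#' Theoretical effective number of chromosome segments
#'
#' Population-genetic predictions of Me from effective population size and
#' genome size: `2 Ne L k` (plain) or `2 Ne L k / ln(Ne L)` (log-corrected).
#'
#' @param Ne Effective population size.
#' @param L Chromosome length in Morgan.
#' @param k Number of chromosomes.
#' @param variant `"plain"` or `"log_corrected"`.
#' @return Me.
#' @examples
#' me_theoretical(Ne = 37, L = 1.5, k = 9, variant = "plain")
#' @export
me_theoretical <- function(Ne, L, k, variant = c("plain", "log_corrected")) {
  variant <- match.arg(variant)
  if (Ne <= 0 || L <= 0 || k <= 0) stop("me_theoretical(): parameters must be positive")
  base <- 2 * Ne * L * k
  if (variant == "plain") return(base)
  if (Ne * L <= 1) stop("me_theoretical(): log_corrected variant requires Ne * L > 1")
  base / log(Ne * L)
}

#' Generation distance from a target individual to the reference
#'
#' @param l_p Generations to the closest paternal ancestor in the reference
#'   population (integer >= 0).
#' @param l_m Same on the maternal side. `(1, 1)` when the target individuals
#'   are progeny of the reference population.
#' @return A list of class `"ref_distance"`.
#' @export
ref_distance <- function(l_p = 1L, l_m = 1L) {
  if (l_p < 0 || l_m < 0 || l_p != round(l_p) || l_m != round(l_m))
    stop("ref_distance(): l_p and l_m must be non-negative integers")
  structure(list(l_p = as.integer(l_p), l_m = as.integer(l_m)),
            class = "ref_distance")
}

#' Probability that a chromosome segment survives unrecombined
#'
#' The genomic-deviation EBV is modelled as the sum of estimates for Me
#' independent chromosome segments. A segment keeps its reference-population
#' accuracy in a target individual only if both the paternal and the
#' maternal haplotype in that segment were inherited intact from the closest
#' reference ancestors; a recombined segment is assumed to contribute no
#' accuracy. With average segment size `gamma * k * L / Me` Morgan (the
#' factor `gamma` inflates segment size because within-family co-segregation
#' information erodes faster than LD information), the retention probability
#' is `p_rt = (1 - gamma k L / Me)^(l_p + l_m)`.
#'
#' @param Me Effective number of chromosome segments.
#' @param k Number of chromosomes.
#' @param L Chromosome length (Morgan).
#' @param gamma Segment-size inflation factor (default 2).
#' @param dist A [ref_distance()] object (generations to closest reference
#'   ancestors).
#' @return Retention probability in \[0, 1\]; 1 when `l_p = l_m = 0`; 0 (with
#'   a warning) when `gamma * k * L >= Me`, i.e. the average segment is
#'   certain to recombine.
#' @examples
#' p_rt(Me = 3705, k = 9, L = 30 / 9, gamma = 2, dist = ref_distance(1, 1))
#' @export
p_rt <- function(Me, k, L, gamma = 2, dist = ref_distance(1L, 1L)) {
  stopifnot(inherits(dist, "ref_distance"), Me > 0, k >= 1, L > 0, gamma > 0)
  expo <- dist$l_p + dist$l_m
  if (expo == 0) return(1)
  base <- 1 - gamma * k * L / Me
  if (base <= 0) {
    warning("p_rt(): gamma * k * L >= Me; segment certainly recombined, returning 0")
    return(0)
  }
  base^expo
}

#' Predict the accuracy of GEBV in a target population
#'
#' Propagates the genomic-deviation accuracy from the reference to the
#' target population by the segment-retention probability,
#' `r_Dt = p_rt * r_Dr`, then combines it with the target pedigree accuracy
#' on the Fisher scale or by the selection-index formula.
#'
#' @param r_D_ref Accuracy of the genomic-deviation EBV in the reference
#'   population.
#' @param r_A_target Accuracy of the pedigree EBV in the target population
#'   (from pseudoBLUP software or empirical estimation; not computed here).
#' @param ctx A [prediction_context()] carrying `Me`, `k`, `L`, `gamma`,
#'   `h2` and (for the Fisher route) `q2`.
#' @param dist A [ref_distance()].
#' @param combine `"index"` (default) or `"fisher"`.
#' @return A list with fields `r_Dr`, `p_rt`, `r_Dt`, `r_At`, `r_Gt`,
#'   `method`, and `scope = "target"`.
#' @export
predict_target_accuracy <- function(r_D_ref, r_A_target, ctx,
                                    dist = ref_distance(1L, 1L),
                                    combine = c("index", "fisher")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ctx, "prediction_context"))
  if (r_D_ref < 0 || r_D_ref > 1 || r_A_target < 0 || r_A_target > 1)
    stop("predict_target_accuracy(): accuracies must lie in [0, 1]")
  p <- p_rt(ctx$Me, ctx$k, ctx$L, ctx$gamma, dist)
  r_Dt <- p * r_D_ref
  r_Gt2 <- combine_r2(r_A_target^2, r_Dt^2, ctx, combine)
  list(r_Dr = r_D_ref, p_rt = p, r_Dt = r_Dt, r_At = r_A_target,
       r_Gt = sqrt(r_Gt2), method = combine, scope = "target")
}

# Combine squared pedigree and deviation accuracies into squared genomic
# accuracy. Fisher route converts both to information (deviation at q2 from
# ctx, pedigree at q2 = 1), adds, and converts back at q2 = 1.
combine_r2 <- function(r_A2, r_D2, ctx, combine = c("index", "fisher")) {
  combine <- match.arg(combine)
  if (combine == "index") return(index_combine_r2(r_A2, r_D2))
  q2D <- if (is.na(ctx$q2)) 1 else ctx$q2
  th_A <- theta_from_r2(r_A2, 1, ctx$h2)
  th_D <- theta_from_r2(r_D2, q2D, ctx$h2)
  r2_from_theta(fisher_combine(th_A, th_D), 1, ctx$h2)
}

#' Predict the accuracy of GEBV in the reference population from Me
#'
#' Forward direction of the Me estimators: given Me, compute the deviation
#' information `theta_D = N q2 h2 / Me` (Fisher route uses `q2` implied by
#' `Me` through `M/(M+Me)`; Index route converts to `r_D` at that `q2`),
#' then combine with the reference pedigree accuracy. When Me was estimated
#' from `(r_A, r_G)` by the matching route, this reproduces `r_G` exactly.
#'
#' @param Me Effective number of chromosome segments.
#' @param r_A Reference-population pedigree accuracy.
#' @param ctx A [prediction_context()] (`Me`/`q2` fields ignored; `Me` comes
#'   from the argument).
#' @param combine `"index"` or `"fisher"`.
#' @return A list with `r_D`, `r_G`, `q2`, `theta_D`, `method`, and
#'   `scope = "reference"`.
#' @export
predict_reference_accuracy <- function(Me, r_A, ctx, combine = c("index", "fisher")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ctx, "prediction_context"), Me > 0)
  q2 <- q2_from_me(ctx$M, Me)
  theta_D <- ctx$N * q2 * ctx$h2 / Me
  if (combine == "fisher") {
    # information adds on the whole-genome (q2 = 1) scale; the deviation
    # component's own r <-> theta mapping uses its capture fraction q2
    th_A <- theta_from_r2(r_A^2, 1, ctx$h2)
    r_G2 <- r2_from_theta(th_A + theta_D, 1, ctx$h2)
    r_D <- sqrt(r2_from_theta(theta_D, q2, ctx$h2))
  } else {
    r_D2 <- r2_from_theta(theta_D, q2, ctx$h2)
    r_D <- sqrt(r_D2)
    r_G2 <- index_combine_r2(r_A^2, r_D2)
  }
  list(r_D = r_D, r_G = sqrt(r_G2), q2 = q2, theta_D = theta_D,
       method = combine, scope = "reference")
}

#' Adjust a squared accuracy for selection (Bulmer effect)
#'
#' Under the infinitesimal model the prediction error variance of EBV is
#' unaffected by selection, so the squared correlation between EBV and true
#' breeding values in a selected population relates to the unselected
#' accuracy by `r^2 = 1 - (1 - r'^2) * sigma2_G_sel / sigma2_G`.
#'
#' @param r_prime2 Squared accuracy in the unselected population, in \[0, 1\].
#' @param sigma2_G Genetic variance in the unselected (base) population.
#' @param sigma2_G_sel Genetic variance in the selected population.
#' @return Selection-adjusted squared accuracy (<= 1). An arithmetically
#'   negative result signals inconsistent inputs and raises an error.
#' @export
selection_adjusted_r2 <- function(r_prime2, sigma2_G, sigma2_G_sel) {
  if (r_prime2 < 0 || r_prime2 > 1)
    stop("selection_adjusted_r2(): r_prime2 must lie in [0, 1]")
  if (sigma2_G <= 0 || sigma2_G_sel <= 0)
    stop("selection_adjusted_r2(): variances must be positive")
  out <- 1 - (1 - r_prime2) * sigma2_G_sel / sigma2_G
  if (out < 0)
    stop(sprintf("selection_adjusted_r2(): inconsistent inputs; variance ratio %.3g drives r2 below 0",
                 sigma2_G_sel / sigma2_G))
  out
}
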