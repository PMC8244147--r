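#' Leave-one-out EBV
#'
#' For each phenotyped individual, the EBV computed with that individual's
#' phenotype removed from the data. The overall mean is estimated once by
#' GLS on the full data and phenotypes are pre-adjusted by it (the only
#' fixed effect); leave-one-out then applies to the random part of the
#' model. For the pure random-effect predictor `g_hat = K V^-1 y*` with
#' `V = K_oo + lambda I`, the leave-one-out value satisfies the downdating
#' identity `g_loo_i = (g_hat_i - H_ii y*_i) / (1 - H_ii)` with
#' `H = K_oo V^-1`, which equals the naive refit that drops row/column `i`.
#' Below `n_naive` individuals the naive refit loop is used directly.
#'
#' @param K Relationship matrix over (at least) the phenotyped individuals.
#' @param phen Phenotype data.frame with columns `id`, `value`.
#' @param h2 Heritability used for evaluation.
#' @param n_naive Below this many phenotyped individuals, compute by naive
#'   refits instead of the downdating identity (both give the same result;
#'   kept as an oracle path).
#' @return An `"ebv_table"` data.frame (`id`, `ebv`) for the phenotyped
#'   individuals, with attribute `mu`.
#' @export
loo_ebv <- function(K, phen, h2, n_naive = 3) {
  stopifnot(is.matrix(K), !is.null(rownames(K)))
  n <- nrow(phen)
  if (n < 3) stop("loo_ebv(): need at least 3 phenotyped individuals")
  if (h2 <= 0 || h2 >= 1) stop("loo_ebv(): h2 must lie strictly in (0, 1)")
  obs <- as.character(phen$id)
  o <- match(obs, rownames(K))
  if (anyNA(o)) stop("loo_ebv(): phenotyped ids missing from K")
  lambda <- (1 - h2) / h2
  Koo <- K[o, o, drop = FALSE]
  V <- Koo + diag(lambda, n)
  Vinv <- chol2inv(chol(V))
  one <- rep(1, n)
  mu <- sum(Vinv %*% phen$value) / sum(Vinv %*% one)
  ys <- phen$value - mu
  if (n < n_naive) {
    g <- vapply(seq_len(n), function(i) {
      Vi <- Koo[-i, -i, drop = FALSE] + diag(lambda, n - 1)
      as.numeric(Koo[i, -i, drop = FALSE] %*% solve(Vi, ys[-i]))
    }, numeric(1))
  } else {
    H <- Koo %*% Vinv
    hii <- diag(H)
    ghat <- as.numeric(H %*% ys)
    g <- (ghat - hii * ys) / (1 - hii)
  }
  out <- data.frame(id = obs, ebv = g, stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  attr(out, "h2") <- h2
  class(out) <- c("ebv_table", "data.frame")
  out
}

#' Leave-one-out cross-validation accuracy
#'
#' Accuracy of EBV estimated as the correlation between leave-one-out EBV
#' and pre-adjusted phenotypes, divided by the square root of heritability.
#' Optionally computed within subgroups (e.g. generations) to reflect
#' heterogeneity of information.
#'
#' @param loo Leave-one-out EBV table from [loo_ebv()], or a numeric vector.
#' @param y_adj Pre-adjusted phenotypes (fixed effects removed), same order.
#' @param h2 Heritability.
#' @param group Optional grouping factor; when given, a data.frame of
#'   per-group accuracies is returned alongside the pooled estimate.
#' @param cap Estimated accuracies > 1 are capped at 1 with a warning
#'   (`cap = FALSE` raises instead).
#' @return Pooled accuracy (numeric), with per-group accuracies as attribute
#'   `"by_group"` when `group` is given.
#' @export
loo_accuracy <- function(loo, y_adj, h2, group = NULL, cap = TRUE) {
  g <- if (is.data.frame(loo)) loo$ebv else loo
  stopifnot(length(g) == length(y_adj))
  if (h2 <= 0 || h2 > 1) stop("loo_accuracy(): h2 must lie in (0, 1]")
  acc1 <- function(gg, yy) {
    if (stats::sd(gg) == 0 || stats::sd(yy) == 0)
      stop("loo_accuracy(): zero variance")
    r <- stats::cor(gg, yy) / sqrt(h2)
    if (r > 1) {
      if (!cap) stop(sprintf("loo_accuracy(): estimated accuracy %.3f > 1", r))
      warning(sprintf("loo_accuracy(): estimated accuracy %.3f > 1; capped at 1", r))
      r <- 1
    }
    r
  }
  pooled <- acc1(g, y_adj)
  if (!is.null(group)) {
    by <- vapply(split(seq_along(g), group),
                 function(ix) acc1(g[ix], y_adj[ix]), numeric(1))
    attr(pooled, "by_group") <- data.frame(group = names(by), r = unname(by))
  }
  pooled
}

#' Add own-phenotype information to a leave-one-out accuracy
#'
#' The leave-one-out accuracy underestimates the reference-population
#' accuracy because the individual's own phenotype is excluded. Modelling
#' the full EBV as a selection index of the leave-one-out EBV and the own
#' (adjusted) phenotype gives index weights
#' `b_LOO = (1 - h2) / (1 - h2 r_loo^2)`,
#' `b_y = h2 (1 - r_loo^2) / (1 - h2 r_loo^2)` and squared accuracy
#' `r^2 = (r_loo^2 + h2 - 2 h2 r_loo^2) / (1 - h2 r_loo^2)`.
#'
#' @param r_loo Leave-one-out cross-validation accuracy, in \[0, 1\].
#' @param h2 Heritability, in (0, 1).
#' @return A list with `r` (combined accuracy), `b_loo`, `b_y`.
#' @examples
#' add_own_phenotype(r_loo = 0.5, h2 = 0.4)
#' @export
add_own_phenotype <- function(r_loo, h2) {
  if (r_loo < 0 || r_loo > 1) stop("add_own_phenotype(): r_loo must lie in [0, 1]")
  if (h2 <= 0 || h2 >= 1) stop("add_own_phenotype(): h2 must lie strictly in (0, 1)")
  r2l <- r_loo^2
  den <- 1 - h2 * r2l
  r2 <- (r2l + h2 - 2 * h2 * r2l) / den
  list(r = sqrt(r2),
       b_loo = (1 - h2) / den,
       b_y = h2 * (1 - r2l) / den)
}

#' LR (part-whole) estimate of genomic accuracy
#'
#' The correlation between EBV from partial information (pedigree) and whole
#' information (genomic) equals the ratio of their accuracies, so the
#' genomic accuracy can be estimated as
#' `r_G_hat = r_A_hat / cor(g_A_hat, g_G_hat)`.
#'
#' @param r_A_hat Estimated accuracy of the pedigree EBV, in (0, 1].
#' @param cor_AG Correlation between pedigree and genomic EBV in the same
#'   population, in (0, 1].
#' @return Estimated genomic accuracy; an implied accuracy > 1 raises an
#'   error (inconsistent inputs).
#' @export
lr_accuracy <- function(r_A_hat, cor_AG) {
  if (cor_AG <= 0 || cor_AG > 1)
    stop("lr_accuracy(): cor_AG must lie in (0, 1]")
  if (r_A_hat <= 0 || r_A_hat > 1)
    stop("lr_accuracy(): r_A_hat must lie in (0, 1]")
  out <- r_A_hat / cor_AG
  if (out > 1)
    stop(sprintf("lr_accuracy(): implied accuracy %.3f > 1; r_A_hat and cor_AG are inconsistent", out))
  out
}
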