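#' Single-trait animal-model BLUP with an arbitrary relationship matrix
#'
#' Solves the animal model `y = 1*mu + g + e` with `var(g) = K * sigma2_G`
#' and `var(e) = I * sigma2_E`, i.e. PBLUP when `K` is a pedigree matrix and
#' GBLUP when `K` is genomic. The overall mean is the only fixed effect.
#' Individuals in `K` without a phenotype receive EBV through their
#' relationships with phenotyped individuals.
#'
#' Computation is in the covariance (GLS) form rather than the
#' mixed-model-equation form: with `V = K_oo + lambda * I` over the
#' phenotyped set `o` and `lambda = (1 - h2) / h2`,
#' `mu_hat = (1' V^-1 y) / (1' V^-1 1)` and
#' `g_hat = K[, o] V^-1 (y - mu_hat)`. This is algebraically identical to
#' the MME solution but needs no inverse of `K`, so singular genomic
#' matrices are handled directly.
#'
#' @param K Relationship matrix over all individuals to evaluate (dimnames
#'   required).
#' @param phen A data.frame with columns `id` and `value` (one record per
#'   individual; additional columns ignored).
#' @param h2 Heritability used for evaluation, in (0, 1).
#' @return A data.frame of class `"ebv_table"` with columns `id`, `ebv`, and
#'   attributes `mu` (fixed-effect estimate) and `h2`.
#' @export
solve_blup <- function(K, phen, h2) {
  stopifnot(is.matrix(K), !is.null(rownames(K)))
  if (h2 <= 0 || h2 >= 1) stop("solve_blup(): h2 must lie strictly in (0, 1)")
  if (anyDuplicated(phen$id)) stop("solve_blup(): one phenotype record per id")
  ids <- rownames(K)
  obs <- as.character(phen$id)
  if (!all(obs %in% ids)) stop("solve_blup(): phenotyped ids missing from K")
  y <- phen$value
  lambda <- (1 - h2) / h2
  o <- match(obs, ids)
  V <- K[o, o, drop = FALSE] + diag(lambda, length(o))
  R <- tryCatch(chol(V), error = function(e)
    stop("solve_blup(): phenotyped block of K + lambda*I is not positive definite"))
  Vinv_y <- backsolve(R, forwardsolve(t(R), y))
  Vinv_1 <- backsolve(R, forwardsolve(t(R), rep(1, length(o))))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  w <- Vinv_y - mu * Vinv_1            # V^-1 (y - mu)
  g <- as.numeric(K[, o, drop = FALSE] %*% w)
  out <- data.frame(id = ids, ebv = g, stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  attr(out, "h2") <- h2
  class(out) <- c("ebv_table", "data.frame")
  out
}

#' Population accuracy of EBV
#'
#' Pearson correlation between EBV and true breeding values, optionally
#' centering both within groups (e.g. generations) before pooling, so that a
#' genetic trend does not inflate the correlation in populations under
#' selection.
#'
#' @param ebv Numeric vector of EBV.
#' @param tbv Numeric vector of true breeding values, same order.
#' @param group Optional grouping factor for within-group centering
#'   (`NULL` = no centering).
#' @return The correlation (population accuracy).
#' @export
population_accuracy <- function(ebv, tbv, group = NULL) {
  stopifnot(length(ebv) == length(tbv))
  if (!is.null(group)) {
    stopifnot(length(group) == length(ebv))
    if (any(table(group) < 3))
      stop("population_accuracy(): need >= 3 individuals per centering group")
    ebv <- ebv - stats::ave(ebv, group)
    tbv <- tbv - stats::ave(tbv, group)
  }
  if (stats::sd(ebv) == 0 || stats::sd(tbv) == 0)
    stop("population_accuracy(): zero variance in EBV or TBV")
  stats::cor(ebv, tbv)
}

#' Read / write EBV tables
#'
#' TSV with columns `id`, `ebv`, `kind`.
#'
#' @param path File path.
#' @return `read_ebv_table()`: a data.frame.
#' @export
read_ebv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_ebv_table
#' @param ebv A data.frame with columns `id`, `ebv` and optionally `kind`.
#' @param kind EBV kind label written when `ebv` lacks a `kind` column
#'   (`"A"`, `"G"`, `"LOO_A"`, `"LOO_G"`).
#' @export
write_ebv_table <- function(ebv, path, kind = "G") {
  out <- as.data.frame(ebv)[, c("id", "ebv")]
  out$kind <- if ("kind" %in% names(ebv)) ebv$kind else kind
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
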