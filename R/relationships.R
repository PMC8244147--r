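#' Read a pedigree from CSV
#'
#' Expected columns: `id`, `sire`, `dam`, and optionally `generation`.
#' Unknown parents are coded 0 or empty.
#'
#' @param path Path to a CSV file.
#' @return A validated pedigree `data.frame` (see [as_pedigree()]).
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_pedigree(ped)
}

#' Validate a pedigree table
#'
#' Checks id uniqueness, that parents appear before their offspring, and
#' recodes unknown parents (0, "", NA) to NA.
#'
#' @param ped A data.frame with columns `id`, `sire`, `dam`, optionally
#'   `generation`.
#' @return The pedigree with class `c("pedigree_df", "data.frame")`, parents
#'   as NA where unknown, ordered so that parents precede offspring.
#' @export
as_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA") | is.na(x)] <- NA
    x
  }
  ped$id <- as.character(ped$id)
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  if (anyDuplicated(ped$id)) stop("as_pedigree(): duplicated ids")
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (col in c("sire", "dam")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (!all(p[known] %in% ped$id))
      stop("as_pedigree(): parent ids missing from the id column: ",
           paste(utils::head(setdiff(p[known], ped$id)), collapse = ", "))
    if (any(pos[p[known]] >= pos[known]))
      stop("as_pedigree(): individuals must not precede their parents (cyclic or unsorted pedigree)")
  }
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

#' Write a pedigree to CSV
#'
#' @param ped A pedigree data.frame.
#' @param path Output path. Unknown parents are written as 0.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pedigree (numerator) relationship matrix
#'
#' Builds the additive relationship matrix A by the tabular method:
#' `A[j, i] = (A[j, s] + A[j, d]) / 2` for j before i, and
#' `A[i, i] = 1 + A[s, d] / 2` (diagonal 1 + inbreeding coefficient).
#'
#' @param ped A pedigree from [as_pedigree()]/[read_pedigree()].
#' @return A symmetric matrix with dimnames the pedigree ids and attribute
#'   `provenance = "A"`.
#' @examples
#' ped <- as_pedigree(data.frame(id = c("s", "d", "x"),
#'                               sire = c(0, 0, "s"), dam = c(0, 0, "d")))
#' build_A(ped)
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(as.data.frame(ped))
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row_s <- if (s > 0) A[j, s] else 0
      row_d <- if (d > 0) A[j, d] else 0
      aij <- (row_s + row_d) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) A[s, d] / 2 else 0
  }
  attr(A, "provenance") <- "A"
  A
}

#' Genomic relationship matrix (VanRaden methods 1 and 2)
#'
#' Method 1 scales the centered cross-product matrix by the total expected
#' heterozygosity `2 * sum(p_j (1 - p_j))`; method 2 weights each locus by
#' its own `2 p_j (1 - p_j)` and averages over loci, which gives rare
#' alleles more weight. Monomorphic loci contribute nothing to method 1 and
#' are excluded from the method-2 average.
#'
#' @param genotypes Numeric matrix of allele dosages in \{0, 1, 2\}, one row
#'   per individual, one column per locus; rownames are individual ids.
#'   Missing dosages are not supported.
#' @param method 1 or 2.
#' @param p Optional vector of allele frequencies used for centering and
#'   scaling (e.g. base-population frequencies); defaults to frequencies
#'   observed in `genotypes`.
#' @return A symmetric matrix with attribute `provenance` `"G_method1"` or
#'   `"G_method2"`.
#' @export
build_G <- function(genotypes, method = 1, p = NULL) {
  stopifnot(is.matrix(genotypes), method %in% c(1, 2))
  if (anyNA(genotypes)) stop("build_G(): missing dosages are not supported")
  if (is.null(p)) p <- colMeans(genotypes) / 2
  het <- 2 * p * (1 - p)
  poly <- het > 0
  if (!any(poly)) stop("build_G(): all loci are monomorphic")
  W <- sweep(genotypes, 2, 2 * p)
  if (method == 1) {
    G <- tcrossprod(W) / sum(het)
  } else {
    Wp <- W[, poly, drop = FALSE]
    Ws <- sweep(Wp, 2, sqrt(het[poly]), "/")
    G <- tcrossprod(Ws) / sum(poly)
  }
  dimnames(G) <- list(rownames(genotypes), rownames(genotypes))
  attr(G, "provenance") <- paste0("G_method", method)
  G
}

#' Effective number of segments from relationship variance
#'
#' Me estimated as the reciprocal of the variance of genomic minus pedigree
#' relationships among all pairs of individuals in the reference population
#' (off-diagonal elements of G - A; unbiased variance over the unique
#' pairs).
#'
#' @param G,A Conformable genomic and pedigree relationship matrices over
#'   the same individuals (same order).
#' @return Me = 1 / var(offdiag(G - A)).
#' @export
me_from_relationship_variance <- function(G, A) {
  stopifnot(is.matrix(G), is.matrix(A), all(dim(G) == dim(A)))
  n <- nrow(G)
  if (n < 2) stop("me_from_relationship_variance(): need at least 2 individuals")
  if (!is.null(rownames(G)) && !is.null(rownames(A)) &&
      !identical(rownames(G), rownames(A)))
    stop("me_from_relationship_variance(): G and A cover different individuals")
  D <- G - A
  offd <- D[upper.tri(D)]
  v <- stats::var(offd)
  if (v == 0) stop("me_from_relationship_variance(): zero relationship variance")
  1 / v
}

#' Partition GEBV into pedigree-tracked and deviation components
#'
#' Following the equivalent-model decomposition of GBLUP, the part of the
#' GEBV vector that pedigree relationships can carry is
#' `g_A_star = A G^-1 g_G`, and the genomic-deviation part is the remainder
#' `g_D = g_G - g_A_star`, so the two components sum to the input exactly.
#'
#' @param gebv Numeric vector of GEBV, aligned with the rows of `A` and `G`.
#' @param A,G Pedigree and genomic relationship matrices over the same
#'   individuals.
#' @param ridge Diagonal ridge added to `G` when it is numerically singular
#'   (default `1e-6`); set to 0 to forbid regularisation.
#' @return A list with components `g_A_star` and `g_D`.
#' @export
decompose_gebv <- function(gebv, A, G, ridge = 1e-6) {
  stopifnot(length(gebv) == nrow(G), all(dim(G) == dim(A)))
  solve_G <- function(Gm) solve(Gm, gebv)
  x <- tryCatch(solve_G(G), error = function(e) {
    if (ridge <= 0) stop("decompose_gebv(): G is singular and ridge = 0")
    message(sprintf("decompose_gebv(): G near-singular; adding ridge %.1g to the diagonal", ridge))
    solve_G(G + diag(ridge, nrow(G)))
  })
  g_A_star <- as.numeric(A %*% x)
  list(g_A_star = g_A_star, g_D = as.numeric(gebv) - g_A_star)
}

#' Read / write genotype dosage tables
#'
#' `read_dosages()` accepts a PLINK `.raw`-style whitespace-delimited table
#' (recognised by the leading `FID IID ... PHENOTYPE` columns) or a plain
#' TSV with a header of locus ids and an `id` first column.
#' `write_dosages()` writes the plain TSV form.
#'
#' @param path File path.
#' @return `read_dosages()`: a numeric matrix of dosages with individual ids
#'   as rownames.
#' @export
read_dosages <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  if (identical(toupper(hdr[1:2]), c("FID", "IID"))) {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(tab))
    m <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
    rownames(m) <- as.character(tab$IID)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- as.character(tab[[1]])
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!m %in% c(0, 1, 2)))
    stop("read_dosages(): dosages must be 0/1/2 with no missing values")
  m
}

#' @rdname read_dosages
#' @param genotypes Dosage matrix with rownames.
#' @export
write_dosages <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a relationship matrix as TSV
#'
#' Square TSV with an `id` header column; values are relationship
#' coefficients.
#'
#' @param path File path.
#' @return `read_relationship_matrix()`: a symmetric numeric matrix with ids
#'   as dimnames.
#' @export
read_relationship_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' @rdname read_relationship_matrix
#' @param K Relationship matrix with dimnames.
#' @export
write_relationship_matrix <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
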