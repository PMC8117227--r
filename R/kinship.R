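# Relationship matrices and their adjustments: pedigree A and A22, the two
# genomic G constructions, blending, base tuning, the base-difference scalar
# delta, and the combined single-step inverse H^-1.

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Recursive (tabular) construction; the diagonal is 1 plus the inbreeding
#' coefficient.  Dense, intended for desk-scale pedigrees; use
#' \code{\link{ainverse_sparse}} for large systems.
#'
#' @param pedigree data frame with integer \code{id}, \code{sire}, \code{dam}
#'   (0 = unknown), topologically ordered (parents before offspring) with
#'   \code{id} equal to the row number.
#' @return Dense symmetric matrix A.
#' @export
build_A <- function(pedigree) {
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  n <- nrow(pedigree)
  if (any(s >= seq_len(n)) || any(d >= seq_len(n)))
    stop("pedigree is not topologically ordered (a parent follows its offspring)")
  A <- cpp_A_tabular(s, d)
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A
}

#' Genotyped-animal submatrix of A
#'
#' @param A pedigree relationship matrix.
#' @param idx indices (or names) of the genotyped animals.
#' @return The principal submatrix A22.
#' @export
subset_A22 <- function(A, idx) {
  if (length(idx) == 0) stop("empty genotyped-animal index")
  A[idx, idx, drop = FALSE]
}

#' Genomic relationship matrix, allele-frequency centered
#'
#' \deqn{G_0 = \frac{M M'}{2 \sum_i p_i (1 - p_i)}}
#' with \eqn{M} the dosage matrix centered by twice the allele frequencies of
#' the current genotyped animals (VanRaden's first method).
#'
#' @param dosage animals x SNPs matrix of 0/1/2 dosages.
#' @param p optional allele frequencies; computed from \code{dosage} when
#'   missing ("current" frequencies).
#' @return List-free dense matrix \code{G0} with attributes \code{p} and
#'   \code{sum2pq} (the denominator), needed later for back-solving SNP
#'   effects.
#' @export
build_G_vanraden <- function(dosage, p = NULL) {
  p <- p %||% colMeans(dosage) / 2
  s2pq <- 2 * sum(p * (1 - p))
  if (s2pq <= 0)
    stop("all SNPs are monomorphic; the VanRaden denominator is zero")
  M <- sweep(dosage, 2, 2 * p, check.margin = FALSE)
  G <- tcrossprod(M) / s2pq
  attr(G, "p") <- p
  attr(G, "sum2pq") <- s2pq
  G
}

#' Genomic relationship matrix, sample-mean centered
#'
#' \deqn{G = \frac{1}{k} \sum_i (x_i - \bar x_i)(x_i - \bar x_i)'}
#' i.e. the average over SNPs of outer products of marker columns centered by
#' their sample means (the kinship used by the EMMAX-style scan).
#'
#' @param dosage animals x SNPs matrix of 0/1/2 dosages.
#' @return Dense genomic relationship matrix.
#' @export
build_G_gemma <- function(dosage) {
  k <- ncol(dosage)
  if (k == 0) stop("no SNPs")
  M <- sweep(dosage, 2, colMeans(dosage), check.margin = FALSE)
  tcrossprod(M) / k
}

#' Blend a genomic matrix with the identity
#'
#' \eqn{G = \lambda G_0 + \beta I}, the standard guard against singular G.
#'
#' @param G0 raw genomic matrix.
#' @param lambda,beta blending weights (presets 0.95 and 0.05).
#' @return Blended matrix (attributes of \code{G0} are preserved).
#' @export
blend_G <- function(G0, lambda = 0.95, beta = 0.05) {
  G <- lambda * G0
  diag(G) <- diag(G) + beta
  attr(G, "p") <- attr(G0, "p")
  attr(G, "sum2pq") <- attr(G0, "sum2pq")
  attr(G, "lambda") <- lambda
  attr(G, "beta") <- beta
  G
}

#' Tune G to the genetic base of A22
#'
#' Solves the two-coefficient adjustment \eqn{a + b\,G} such that the mean
#' diagonal and mean off-diagonal of the tuned matrix equal those of A22
#' exactly, aligning the genomic and pedigree genetic bases.
#'
#' @param G genomic matrix (typically blended).
#' @param A22 pedigree relationships among the genotyped animals.
#' @return Tuned matrix with attributes \code{a} and \code{b}.
#' @export
tune_G_to_A22 <- function(G, A22) {
  stopifnot(all(dim(G) == dim(A22)))
  n <- nrow(G)
  md_G <- mean(diag(G)); mo_G <- (sum(G) - sum(diag(G))) / (n * (n - 1))
  md_A <- mean(diag(A22)); mo_A <- (sum(A22) - sum(diag(A22))) / (n * (n - 1))
  if (abs(md_G - mo_G) < 1e-12)
    stop("degenerate tuning system: G has equal mean diagonal and off-diagonal")
  b <- (md_A - mo_A) / (md_G - mo_G)
  a <- mo_A - b * mo_G
  Gt <- a + b * G
  attr(Gt, "p") <- attr(G, "p")
  attr(Gt, "sum2pq") <- attr(G, "sum2pq")
  attr(Gt, "a") <- a
  attr(Gt, "b") <- b
  Gt
}

#' Genetic-base difference between A22 and G
#'
#' \deqn{\delta = 1 - \frac{0.5}{n^2}\Big(\sum_{ij} A_{22}(i,j) -
#'   \sum_{ij} G(i,j)\Big)}
#' the scalar accounting for the difference in genetic base between pedigree
#' and genomic relationships in the single-step back-solving.
#'
#' @param A22,G matrices of equal dimension \eqn{n}.
#' @return The scalar \eqn{\delta}.
#' @export
compute_delta <- function(A22, G) {
  stopifnot(all(dim(A22) == dim(G)))
  n <- nrow(A22)
  1 - (0.5 / n^2) * (sum(A22) - sum(G))
}

#' Combined single-step relationship inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\
#'   0 & G^{-1} - A_{22}^{-1} \end{bmatrix}}
#' the correction applying only to the genotyped block.
#'
#' @param Ainv pedigree relationship inverse for all animals (dense or
#'   sparse).
#' @param A22inv inverse of the genotyped-animal pedigree submatrix.
#' @param Ginv inverse of the (blended, tuned) genomic matrix.
#' @param idx positions of the genotyped animals within the pedigree.
#' @return H-inverse, sparse when \code{Ainv} is sparse.
#' @export
build_Hinv <- function(Ainv, A22inv, Ginv, idx) {
  if (length(idx) == 0) return(Ainv)
  stopifnot(nrow(A22inv) == length(idx), nrow(Ginv) == length(idx))
  corr <- Ginv - A22inv
  if (is(Ainv, "Matrix")) {
    n <- nrow(Ainv)
    Cs <- Matrix::sparseMatrix(i = rep(idx, times = length(idx)),
                               j = rep(idx, each = length(idx)),
                               x = as.numeric(corr), dims = c(n, n))
    Matrix::forceSymmetric(Ainv + Cs)
  } else {
    H <- Ainv
    H[idx, idx] <- H[idx, idx] + corr
    H
  }
}

# Inverse of a dense symmetric PD matrix via Cholesky, with a usable error.
pd_solve <- function(M, what = "matrix") {
  R <- tryCatch(chol(M), error = function(e)
    stop("singular ", what, ": ", conditionMessage(e),
         " (blend G with the identity first)", call. = FALSE))
  chol2inv(R)
}
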