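# Animal-model machinery: Henderson's mixed-model equations (dense or
# sparse), exact REML variance components via the spectral profile
# likelihood, prediction-error variances and reliabilities.

#' Sparse pedigree A-inverse
#'
#' Henderson's rules with inbreeding (Meuwissen-Luo coefficients), returning
#' a sparse symmetric matrix ordered like the pedigree.
#'
#' @param sire,dam integer parent codes (0 = unknown), parents before
#'   offspring.
#' @param F optional inbreeding coefficients; computed if missing.
#' @return A \code{dsCMatrix} of dimension \code{length(sire)}.
#' @export
ainverse_sparse <- function(sire, dam, F = NULL) {
  F <- F %||% cpp_inbreeding(as.integer(sire), as.integer(dam))
  tr <- cpp_ainverse_triplets(as.integer(sire), as.integer(dam), F)
  M <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(length(sire), length(sire)))
  Matrix::forceSymmetric(M)
}

#' Inbreeding coefficients from a pedigree
#'
#' @inheritParams ainverse_sparse
#' @return Numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(sire, dam) {
  cpp_inbreeding(as.integer(sire), as.integer(dam))
}

# records -> animals incidence
incidence_sparse <- function(animal_idx, n_animals) {
  Matrix::sparseMatrix(i = seq_along(animal_idx), j = animal_idx, x = 1,
                       dims = c(length(animal_idx), n_animals))
}

#' Solve the mixed-model equations
#'
#' Solves the single-trait animal-model system
#' \deqn{\begin{bmatrix} X'X & X'Z \\ Z'X & Z'Z + K^{-1}\lambda \end{bmatrix}
#'       \begin{bmatrix} \hat\mu \\ \hat a \end{bmatrix} =
#'       \begin{bmatrix} X'y \\ Z'y \end{bmatrix}}
#' with \eqn{\lambda = \sigma^2_e/\sigma^2_a} and \eqn{K^{-1}} a pedigree,
#' genomic, or combined relationship inverse.  Dense inputs are solved by
#' Cholesky factorization; sparse inputs through the \pkg{Matrix} package.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (default a column of ones).
#' @param Z record-to-animal incidence (dense or sparse); default identity.
#' @param Kinv relationship inverse (dense matrix or sparse Matrix).
#' @param vc list with \code{sigma2_a} and \code{sigma2_e}.
#' @param c22 \code{"none"}, \code{"diag"} or \code{"full"}: how much of the
#'   animal block of the coefficient-matrix inverse to return.  The returned
#'   \code{C22} is scaled by \eqn{\sigma^2_e}, i.e. it is the prediction-error
#'   (co)variance of the animal solutions.
#' @param c22_idx animal indices for which the \code{C22} block is wanted
#'   (defaults to all animals; with many animals prefer a subset).
#' @return An object of class \code{mme_fit}: \code{beta}, \code{u},
#'   \code{C22} (or NULL), \code{pev}, the indices the block refers to, and
#'   the variance components used.
#' @export
solve_mme <- function(y, X = NULL, Z = NULL, Kinv, vc,
                      c22 = c("none", "diag", "full"), c22_idx = NULL) {
  c22 <- match.arg(c22)
  n <- length(y)
  X <- X %||% matrix(1, n, 1)
  q <- nrow(Kinv)
  Z <- Z %||% incidence_sparse(seq_len(n), q)
  stopifnot(nrow(X) == n, nrow(Z) == n, ncol(Z) == q,
            vc$sigma2_a > 0, vc$sigma2_e > 0)
  lambda <- vc$sigma2_e / vc$sigma2_a
  p <- ncol(X)
  sparse <- is(Kinv, "Matrix") || is(Z, "Matrix")
  if (sparse) {
    X <- as(X, "CsparseMatrix"); Z <- as(Z, "CsparseMatrix")
    Kinv <- as(Kinv, "CsparseMatrix")
    LHS <- rbind(cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z)),
                 cbind(Matrix::crossprod(Z, X),
                       Matrix::crossprod(Z) + Kinv * lambda))
    rhs <- rbind(Matrix::crossprod(X, y), Matrix::crossprod(Z, y))
    LHS <- Matrix::forceSymmetric(LHS)
    ch <- tryCatch(Matrix::Cholesky(LHS, LDL = FALSE, perm = TRUE),
                   error = function(e)
                     stop("singular mixed-model coefficient matrix: ",
                          conditionMessage(e)))
    sol <- as.numeric(Matrix::solve(ch, rhs))
    C22 <- NULL; pev <- NULL; idx <- NULL
    if (c22 != "none") {
      idx <- c22_idx %||% seq_len(q)
      E <- Matrix::sparseMatrix(i = p + idx, j = seq_along(idx), x = 1,
                                dims = c(p + q, length(idx)))
      V <- as.matrix(Matrix::solve(ch, E))
      C22 <- V[p + idx, , drop = FALSE] * vc$sigma2_e
      C22 <- (C22 + t(C22)) / 2
      pev <- diag(C22)
      if (c22 == "diag") C22 <- NULL
    }
  } else {
    Z <- as.matrix(Z)
    LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                 cbind(crossprod(Z, X), crossprod(Z) + Kinv * lambda))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    R <- tryCatch(chol(LHS), error = function(e)
      stop("singular mixed-model coefficient matrix: ", conditionMessage(e)))
    sol <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    C22 <- NULL; pev <- NULL; idx <- NULL
    if (c22 != "none") {
      Cinv <- chol2inv(R)
      idx <- c22_idx %||% seq_len(q)
      C22 <- Cinv[p + idx, p + idx, drop = FALSE] * vc$sigma2_e
      pev <- diag(C22)
      if (c22 == "diag") C22 <- NULL
    }
  }
  structure(list(beta = sol[seq_len(p)], u = sol[-seq_len(p)],
                 C22 = C22, pev = pev, c22_idx = idx,
                 vc = vc, lambda = lambda),
            class = "mme_fit")
}

#' @export
print.mme_fit <- function(x, ...) {
  cat("Mixed-model fit:", length(x$u), "animal effects,",
      length(x$beta), "fixed effect(s); lambda =", format(x$lambda), "\n")
  cat("  mu-hat:", format(x$beta), "\n")
  invisible(x)
}

#' REML variance components for the animal model
#'
#' Exact single-trait REML through the spectral decomposition of the
#' relationship matrix among recorded animals: with
#' \eqn{K = U D U'}, the restricted likelihood is profiled down to a
#' one-dimensional function of the heritability \eqn{h^2}, maximized by
#' golden-section/Brent search.  This avoids iterative EM updates and cannot
#' produce negative components; boundary cases (pure noise or no residual)
#' land on the interval ends.
#'
#' @param y phenotypes.
#' @param X fixed-effect design (default intercept).
#' @param K relationship matrix among the recorded animals (A, G or H
#'   submatrix).
#' @param interval search interval for \eqn{h^2}.
#' @return A list of class \code{varcomp}: \code{sigma2_a}, \code{sigma2_e},
#'   \code{h2}, restricted log-likelihood and the source tag \code{"REML"}.
#' @export
reml_estimate <- function(y, X = NULL, K, interval = c(1e-4, 1 - 1e-4)) {
  n <- length(y)
  stopifnot(n >= 2, nrow(K) == n)
  X <- X %||% matrix(1, n, 1)
  p <- qr(X)$rank
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  ty <- crossprod(ev$vectors, y)
  tX <- crossprod(ev$vectors, X)
  nloglik <- function(h2) {
    w <- h2 * d + (1 - h2)
    iw <- 1 / w
    XtWX <- crossprod(tX, tX * iw)
    XtWy <- crossprod(tX, ty * iw)
    bh <- solve(XtWX, XtWy)
    r <- ty - tX %*% bh
    rss <- sum(r^2 * iw)
    s2 <- max(rss / (n - p), 1e-300)
    0.5 * ((n - p) * log(s2) + sum(log(w)) +
             determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- optimize(nloglik, interval = interval)
  h2 <- opt$minimum
  w <- h2 * d + (1 - h2); iw <- 1 / w
  XtWX <- crossprod(tX, tX * iw)
  bh <- solve(XtWX, crossprod(tX, ty * iw))
  r <- ty - tX %*% bh
  s2 <- max(sum(r^2 * iw) / (n - p), 1e-300)
  structure(list(sigma2_a = h2 * s2, sigma2_e = (1 - h2) * s2, h2 = h2,
                 logLik = -opt$objective, source = "REML"),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Variance components (", x$source, "): sigma2_a =",
      format(x$sigma2_a, digits = 4), " sigma2_e =",
      format(x$sigma2_e, digits = 4), " h2 =",
      format(x$sigma2_a / (x$sigma2_a + x$sigma2_e), digits = 4), "\n")
  invisible(x)
}

#' EBV reliability from prediction-error variance
#'
#' \eqn{rel_i = 1 - PEV_i / (K_{ii}\,\sigma^2_a)}; the diagonal of the
#' relationship matrix accounts for inbreeding.
#'
#' @param pev per-animal prediction-error variance.
#' @param sigma2_a additive variance.
#' @param diagK diagonal of the relationship matrix (default 1).
#' @return Reliabilities in \eqn{[0, 1]}.
#' @export
reliability <- function(pev, sigma2_a, diagK = 1) {
  if (any(sigma2_a <= 0) || any(diagK <= 0))
    stop("reliability undefined for non-positive variance")
  pmin(pmax(1 - pev / (diagK * sigma2_a), 0), 1)
}

#' Parent average of breeding values
#'
#' @param pedigree data frame with \code{id}, \code{sire}, \code{dam}
#'   (0 = unknown, contributing 0 to the average).
#' @param ebv vector of breeding values indexed by animal id.
#' @return Per-animal parent average \eqn{(EBV_{sire} + EBV_{dam})/2}.
#' @export
parent_average <- function(pedigree, ebv) {
  g <- function(par) ifelse(par > 0, ebv[pmax(par, 1)], 0)
  (g(pedigree$sire) + g(pedigree$dam)) / 2
}
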