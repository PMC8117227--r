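# The four association methods.  All return the common per-SNP record
# (effect, standard error, p-value, flag) so that the evaluation layer can
# treat them interchangeably.

#' Two-sided p-value from an effect and its standard error
#'
#' \eqn{p_i = 2\,(1 - \Phi(|\hat g_i / sd(\hat g_i)|))} with \eqn{\Phi} the
#' standard normal CDF.  Used for every method so that cross-method
#' comparisons are like-for-like.
#'
#' @param effect estimated allele-substitution effect(s).
#' @param se standard error(s); must be strictly positive.
#' @return p-values in \eqn{[0, 1]}.
#' @export
pvalue_from_effect <- function(effect, se) {
  if (any(se <= 0, na.rm = TRUE))
    stop("standard error must be strictly positive")
  2 * (1 - pnorm(abs(effect / se)))
}

assoc_frame <- function(map, effect, se, flag, method, n, vc = NULL) {
  p <- rep(1, length(effect))
  ok <- !is.na(effect) & !is.na(se) & se > 0
  p[ok] <- pvalue_from_effect(effect[ok], se[ok])
  out <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                    pos_cM = map$pos_cM, effect = effect, se = se,
                    pvalue = p, flag = flag)
  attr(out, "method") <- method
  attr(out, "n") <- n
  attr(out, "vc") <- vc
  class(out) <- c("gwas_scan", "data.frame")
  out
}

default_map <- function(dosage) {
  data.frame(snp_id = colnames(dosage) %||% paste0("snp", seq_len(ncol(dosage))),
             chrom = 1L, pos_cM = seq_len(ncol(dosage)))
}

#' Single-SNP least squares without relatedness correction
#'
#' Ordinary least squares of the phenotype on each SNP dosage (plus an
#' intercept), one SNP at a time; no correction for population structure.
#' P-values use the normal reference for comparability with the mixed-model
#' methods.
#'
#' @param y phenotypes (or deregressed proofs) of the genotyped animals.
#' @param dosage animals x SNPs dosage matrix aligned with \code{y}.
#' @param map optional SNP map (\code{snp_id}, \code{chrom}, \code{pos_cM}).
#' @return A \code{gwas_scan} data frame; SNPs monomorphic in the analysis
#'   set are flagged and assigned p = 1.
#' @export
ssa_nocor <- function(y, dosage, map = NULL) {
  stopifnot(length(y) == nrow(dosage))
  map <- map %||% default_map(dosage)
  n <- length(y)
  yc <- y - mean(y)
  xbar <- colMeans(dosage)
  Sxx <- colSums(dosage * dosage) - n * xbar^2
  Sxy <- drop(crossprod(dosage, yc))
  Syy <- sum(yc^2)
  mono <- Sxx <= .Machine$double.eps * n
  b <- ifelse(mono, NA_real_, Sxy / Sxx)
  rss <- pmax(Syy - b * Sxy, 0)
  s2 <- rss / (n - 2)
  se <- ifelse(mono, NA_real_, sqrt(s2 / Sxx))
  flag <- ifelse(mono, "monomorphic", "")
  assoc_frame(map, b, se, flag, "SSA-NoCor", n)
}

#' EMMAX-style mixed-model association
#'
#' Generalized least squares of the phenotype on each SNP under
#' \eqn{V = G\sigma^2_a + I\sigma^2_e}, with the variance components
#' estimated once on the null model (no SNP) and reused for every SNP — the
#' defining EMMAX approximation.  The kinship is the sample-mean-centered
#' genomic matrix (\code{\link{build_G_gemma}}) unless supplied.
#'
#' @inheritParams ssa_nocor
#' @param G genomic relationship among the animals; built from \code{dosage}
#'   when missing.
#' @param vc variance components (list with \code{sigma2_a},
#'   \code{sigma2_e}); REML-estimated on the null model when missing.
#' @return A \code{gwas_scan} data frame.
#' @export
emmax <- function(y, dosage, G = NULL, vc = NULL, map = NULL) {
  stopifnot(length(y) == nrow(dosage))
  map <- map %||% default_map(dosage)
  n <- length(y)
  G <- G %||% build_G_gemma(dosage)
  vc <- vc %||% reml_estimate(y, K = G)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  w <- vc$sigma2_a * pmax(ev$values, 0) + vc$sigma2_e
  if (any(w <= 0)) stop("phenotypic covariance V is singular")
  iw <- 1 / w
  U <- ev$vectors
  t1 <- colSums(U)                      # U' 1
  ty <- drop(crossprod(U, y))
  TX <- crossprod(U, dosage)            # U' x_i for every SNP
  a11 <- sum(iw * t1 * t1)
  a1y <- sum(iw * t1 * ty)
  a1x <- drop(crossprod(TX, iw * t1))
  axy <- drop(crossprod(TX, iw * ty))
  axx <- colSums(TX * TX * iw)
  det <- a11 * axx - a1x^2
  bad <- det <= .Machine$double.eps * a11
  b <- ifelse(bad, NA_real_, (a11 * axy - a1x * a1y) / det)
  se <- ifelse(bad, NA_real_, sqrt(a11 / det))
  flag <- ifelse(bad, "monomorphic", "")
  assoc_frame(map, b, se, flag, "EMMAX", n, vc)
}

# shared back-solving of SNP effects and their variances from animal
# solutions: g-hat = s * M' Ginv a, Var(g)_i = s^2 [M'Ginv (G sa2 - C22)
# Ginv M]_ii, with s the lambda (and delta) scaled VanRaden denominator.
backsolve_snp <- function(M, Ginv, G, ahat, C22, sigma2_a, s) {
  W <- Ginv %*% M
  ghat <- s * drop(crossprod(M, Ginv %*% ahat))
  mid <- G * sigma2_a - C22
  vg <- s^2 * colSums(W * (mid %*% W))
  list(ghat = ghat, vg = vg)
}

#' GBLUP association by back-solving SNP effects
#'
#' Fits the GBLUP animal model by the mixed-model equations, back-solves all
#' SNP effects simultaneously from the breeding-value solutions,
#' \deqn{\hat g = \lambda \tfrac{1}{2\sum p q} M' G^{-1} \hat a,}
#' and obtains per-SNP prediction-error variances from the animal block of
#' the MME inverse:
#' \deqn{Var(\hat g) = \left(\lambda\tfrac{1}{2\sum pq}\right)^2
#'   M' G^{-1} (G\hat\sigma^2_a - C^{22}) G^{-1} M.}
#' Every phenotyped animal must be genotyped (supply deregressed proofs
#' otherwise).
#'
#' @inheritParams emmax
#' @param G blended genomic matrix (VanRaden, \eqn{\lambda G_0 + \beta I});
#'   built from \code{dosage} when missing.
#' @param lambda,beta blending weights used when \code{G} is built here; the
#'   back-solving \eqn{\lambda} is taken from the blend.
#' @return A \code{gwas_scan} data frame.  Non-positive back-solved
#'   variances (floating-point cancellation) are clamped to a tiny positive
#'   value and flagged \code{"var_clamped"}.
#' @export
gblup_gwas <- function(y, dosage, G = NULL, vc = NULL, lambda = 0.95,
                       beta = 0.05, map = NULL) {
  stopifnot(length(y) == nrow(dosage))
  map <- map %||% default_map(dosage)
  n <- length(y)
  if (is.null(G)) G <- blend_G(build_G_vanraden(dosage), lambda, beta)
  lam <- attr(G, "lambda") %||% lambda
  p <- attr(G, "p") %||% (colMeans(dosage) / 2)
  s2pq <- attr(G, "sum2pq") %||% (2 * sum(p * (1 - p)))
  vc <- vc %||% reml_estimate(y, K = G)
  Ginv <- pd_solve(G, "genomic relationship matrix")
  fit <- solve_mme(y, Kinv = Ginv, vc = vc, c22 = "full")
  M <- sweep(dosage, 2, 2 * p, check.margin = FALSE)
  bs <- backsolve_snp(M, Ginv, G, fit$u, fit$C22, vc$sigma2_a, lam / s2pq)
  clamp <- bs$vg <= 0
  vg <- ifelse(clamp, .Machine$double.eps, bs$vg)
  if (any(clamp))
    warning(sum(clamp), " SNP variance(s) clamped to a tiny positive value")
  assoc_frame(map, bs$ghat, sqrt(vg),
              ifelse(clamp, "var_clamped", ""), "GBLUP-GWAS", n, vc)
}

#' Single-step GWAS
#'
#' Solves the single-step mixed-model equations in which \eqn{G^{-1}} is
#' replaced by \eqn{H^{-1}} combining pedigree and genomic relationships, so
#' phenotypes of non-genotyped relatives contribute.  SNP effects are
#' back-solved from the genomic EBV of the genotyped animals,
#' \deqn{\hat g = \lambda\,\delta\, \tfrac{1}{2\sum pq} M' G^{-1} \hat
#'   a_{22},}
#' with \eqn{\delta} the genetic-base adjustment
#' (\code{\link{compute_delta}}, evaluated between A22 and the blended G
#' before base tuning) and variances from the genotyped block \eqn{C^{22}} of
#' the single-step MME inverse.
#'
#' @param y phenotypes of the recorded animals (any animals in the
#'   pedigree).
#' @param pheno_idx positions of the recorded animals in the pedigree.
#' @param pedigree data frame (\code{id}, \code{sire}, \code{dam}),
#'   topologically ordered, id = row number.
#' @param dosage genotyped-animal dosage matrix.
#' @param geno_idx positions of the genotyped animals in the pedigree,
#'   aligned with the rows of \code{dosage}.
#' @param vc variance components; REML on the genotyped animals with own
#'   records when missing, or the model's known values.
#' @param lambda,beta blending weights for G.
#' @param map optional SNP map.
#' @param G optional pre-built (blended, tuned) genomic matrix override.
#' @return A \code{gwas_scan} data frame.
#' @export
ssgwas <- function(y, pheno_idx, pedigree, dosage, geno_idx, vc = NULL,
                   lambda = 0.95, beta = 0.05, map = NULL, G = NULL) {
  stopifnot(length(y) == length(pheno_idx),
            nrow(dosage) == length(geno_idx))
  if (max(pheno_idx) > nrow(pedigree) || max(geno_idx) > nrow(pedigree))
    stop("pedigree/genotype index mismatch")
  map <- map %||% default_map(dosage)
  n_anim <- nrow(pedigree)
  F <- cpp_inbreeding(as.integer(pedigree$sire), as.integer(pedigree$dam))
  Ainv <- ainverse_sparse(pedigree$sire, pedigree$dam, F)
  # A22 via sparse solves of A columns for the genotyped animals
  ch <- Matrix::Cholesky(Ainv, LDL = FALSE, perm = TRUE)
  E <- Matrix::sparseMatrix(i = geno_idx, j = seq_along(geno_idx), x = 1,
                            dims = c(n_anim, length(geno_idx)))
  A22 <- as.matrix(Matrix::solve(ch, E))[geno_idx, , drop = FALSE]
  A22 <- (A22 + t(A22)) / 2
  if (is.null(G)) {
    Gb <- blend_G(build_G_vanraden(dosage), lambda, beta)
    delta <- compute_delta(A22, Gb)
    Gt <- tune_G_to_A22(Gb, A22)
  } else {
    Gt <- G
    delta <- compute_delta(A22, G)
  }
  lam <- attr(Gt, "lambda") %||% lambda
  p <- attr(Gt, "p") %||% (colMeans(dosage) / 2)
  s2pq <- attr(Gt, "sum2pq") %||% (2 * sum(p * (1 - p)))
  if (is.null(vc)) {
    own <- intersect(geno_idx, pheno_idx)
    if (length(own) >= 10) {
      rows <- match(own, geno_idx)
      vc <- reml_estimate(y[match(own, pheno_idx)],
                          K = Gt[rows, rows, drop = FALSE])
    } else stop("supply variance components: no genotyped animals with ",
                "own records to estimate them from")
  }
  Ginv <- pd_solve(Gt, "genomic relationship matrix")
  A22inv <- pd_solve(A22, "pedigree submatrix A22")
  Hinv <- build_Hinv(Ainv, A22inv, Ginv, geno_idx)
  Z <- incidence_sparse(pheno_idx, n_anim)
  fit <- solve_mme(y, Z = Z, Kinv = Hinv, vc = vc, c22 = "full",
                   c22_idx = geno_idx)
  a22 <- fit$u[geno_idx]
  M <- sweep(dosage, 2, 2 * p, check.margin = FALSE)
  bs <- backsolve_snp(M, Ginv, Gt, a22, fit$C22, vc$sigma2_a,
                      lam * delta / s2pq)
  clamp <- bs$vg <= 0
  vg <- ifelse(clamp, .Machine$double.eps, bs$vg)
  if (any(clamp))
    warning(sum(clamp), " SNP variance(s) clamped to a tiny positive value")
  out <- assoc_frame(map, bs$ghat, sqrt(vg),
                     ifelse(clamp, "var_clamped", ""), "ssGWAS", length(y), vc)
  attr(out, "delta") <- delta
  out
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("Association scan (", attr(x, "method"), "): ", nrow(x), " SNPs, ",
      attr(x, "n"), " records\n", sep = "")
  thr <- bonferroni_threshold(nrow(x))
  cat("  significant at Bonferroni 0.05 (p < ", format(thr, digits = 3),
      "): ", sum(x$pvalue < thr), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gwas_scan <- function(object, alpha = 0.05, ...) {
  thr <- bonferroni_threshold(nrow(object), alpha)
  sig <- object[object$pvalue < thr, ]
  sig <- sig[order(sig$pvalue), ]
  out <- list(method = attr(object, "method"), n = attr(object, "n"),
              n_snps = nrow(object), threshold = thr,
              n_significant = nrow(sig),
              top = utils::head(sig, 10),
              vc = attr(object, "vc"))
  class(out) <- "summary.gwas_scan"
  out
}

#' @export
print.summary.gwas_scan <- function(x, ...) {
  cat("Method:", x$method, "-", x$n_snps, "SNPs on", x$n, "records\n")
  cat("Bonferroni threshold:", format(x$threshold, digits = 3),
      "->", x$n_significant, "significant SNPs\n")
  if (nrow(x$top)) {
    cat("Strongest associations:\n")
    print(x$top[, c("snp_id", "chrom", "pos_cM", "effect", "se", "pvalue")],
          row.names = FALSE, digits = 3)
  }
  if (!is.null(x$vc))
    cat("Variance components:", format(x$vc$sigma2_a, digits = 3), "(additive),",
        format(x$vc$sigma2_e, digits = 3), "(residual)\n")
  invisible(x)
}

#' @export
coef.gwas_scan <- function(object, ...) {
  setNames(object$effect, object$snp_id)
}

#' Manhattan plot of an association scan
#'
#' \eqn{-\log_{10} p} against cumulative map position, with the Bonferroni
#' rejection line and (optionally) the true QTN positions overlaid.
#'
#' @param x a \code{gwas_scan}.
#' @param qtn optional QTN registry (\code{chrom}, \code{pos_cM}).
#' @param alpha family-wise significance level for the threshold line.
#' @param ... passed to \code{plot}.
#' @export
plot.gwas_scan <- function(x, qtn = NULL, alpha = 0.05, ...) {
  off <- c(0, cumsum(tapply(x$pos_cM, x$chrom, max)))
  xs <- x$pos_cM + off[match(x$chrom, sort(unique(x$chrom)))]
  thr <- bonferroni_threshold(nrow(x), alpha)
  lp <- -log10(pmax(x$pvalue, 1e-300))
  graphics::plot(xs, lp, pch = 16, cex = 0.4,
                 col = ifelse(x$pvalue < thr, "red", "grey40"),
                 xlab = "cumulative position (cM)",
                 ylab = expression(-log[10](p)),
                 main = attr(x, "method"), ...)
  graphics::abline(h = -log10(thr), col = "blue")
  if (!is.null(qtn)) {
    qx <- qtn$pos_cM + off[match(qtn$chrom, sort(unique(x$chrom)))]
    graphics::abline(v = qx, col = grDevices::grey(0.75))
  }
  invisible(x)
}
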