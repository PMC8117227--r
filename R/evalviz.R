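# Results layer: significance thresholding, true/false-positive accounting
# in QTN windows, ROC curves, LD decay, PCA of G, and effective population
# size from the inbreeding trend.

#' Bonferroni rejection threshold
#'
#' @param n_snps number of tested SNPs.
#' @param alpha family-wise significance level.
#' @return \code{alpha / n_snps}.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.05) {
  if (n_snps < 1) stop("no SNPs to correct for")
  alpha / n_snps
}

#' Classify significant SNPs as true or false positives
#'
#' A significant SNP (p below the threshold) is a true positive if it lies
#' within \code{window_cM} of a QTN on the same chromosome (boundary
#' inclusive), otherwise a false positive.  Counting is per significant SNP,
#' not per QTN window.
#'
#' @param scan a \code{gwas_scan} (or data frame with \code{chrom},
#'   \code{pos_cM}, \code{pvalue}).
#' @param qtn QTN registry with \code{chrom} and \code{pos_cM}.
#' @param threshold rejection threshold; Bonferroni 0.05 by default.
#' @param window_cM half-width of the QTN window.
#' @return An object of class \code{eval_summary}: TP and FP counts, the
#'   threshold and window, and the per-SNP classification.
#' @export
classify_tp_fp <- function(scan, qtn, threshold = NULL, window_cM = 2.0) {
  threshold <- threshold %||% bonferroni_threshold(nrow(scan))
  if (!all(scan$chrom %in% c(qtn$chrom, scan$chrom)) || nrow(qtn) == 0)
    stop("empty QTN registry")
  if (!all(qtn$chrom %in% scan$chrom))
    stop("QTN registry names chromosomes absent from the SNP map")
  near <- snp_near_qtn(scan, qtn, window_cM)
  sig <- scan$pvalue < threshold
  cls <- rep("ns", nrow(scan))
  cls[sig & near] <- "TP"
  cls[sig & !near] <- "FP"
  structure(list(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
                 n_significant = sum(sig), threshold = threshold,
                 window_cM = window_cM, classification = cls,
                 method = attr(scan, "method")),
            class = "eval_summary")
}

# TRUE for SNPs within window_cM (inclusive) of any same-chromosome QTN
snp_near_qtn <- function(scan, qtn, window_cM) {
  near <- logical(nrow(scan))
  for (c in unique(qtn$chrom)) {
    i <- scan$chrom == c
    qp <- qtn$pos_cM[qtn$chrom == c]
    if (!any(i)) next
    dmin <- do.call(pmin, lapply(qp, function(q) abs(scan$pos_cM[i] - q)))
    near[i] <- dmin <= window_cM
  }
  near
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("Significance accounting", if (!is.null(x$method)) paste0("(", x$method, ")"),
      ": threshold", format(x$threshold, digits = 3),
      "window +/-", x$window_cM, "cM\n")
  cat("  TP", x$tp, "| FP", x$fp, "| significant", x$n_significant, "\n")
  invisible(x)
}

#' ROC curve for an association scan against the QTN windows
#'
#' Sweeps the rejection threshold over the sorted p-values; a SNP within
#' \code{window_cM} of a QTN is a positive.  The area under the curve is the
#' trapezoidal area, which equals the Mann-Whitney statistic of the p-values
#' grouped by label.
#'
#' @inheritParams classify_tp_fp
#' @return List of class \code{roc_curve}: \code{fpr}, \code{tpr} (one point
#'   per distinct threshold, including the end points) and \code{auc}.
#' @export
roc_curve <- function(scan, qtn, window_cM = 2.0) {
  lab <- snp_near_qtn(scan, qtn, window_cM)
  nP <- sum(lab); nN <- sum(!lab)
  if (nP == 0 || nN == 0)
    stop("ROC undefined: need both positive and negative SNPs")
  o <- order(scan$pvalue)
  lab <- lab[o]; pv <- scan$pvalue[o]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(pv[-1] != pv[-length(pv)], TRUE)   # one point per threshold
  tpr <- c(0, tp[keep] / nP); fpr <- c(0, fp[keep] / nN)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = nP, n_neg = nN, method = attr(scan, "method")),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC", if (!is.null(x$method)) paste0("(", x$method, ")"), ":",
      x$n_pos, "positives,", x$n_neg, "negatives, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = paste0("ROC", if (!is.null(x$method))
                   paste0(" (", x$method, ")"), ", AUC = ",
                   format(x$auc, digits = 3)), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Linkage-disequilibrium decay curve
#'
#' Mean squared genotypic correlation (\eqn{r^2} of dosages) of
#' same-chromosome SNP pairs, binned by map distance.  Pairs are subsampled
#' when a chromosome carries more pairs than \code{max_pairs_per_chrom}.
#'
#' @param dosage animals x SNPs dosage matrix.
#' @param map SNP map with \code{chrom} and \code{pos_cM} matching the
#'   columns.
#' @param max_dist_cM largest pair distance retained.
#' @param bin_width bin width in cM.
#' @param max_pairs_per_chrom subsampling cap per chromosome.
#' @return List of class \code{ld_decay}: bin midpoints, mean r2, pair
#'   counts.
#' @export
ld_decay <- function(dosage, map, max_dist_cM = 50, bin_width = 1,
                     max_pairs_per_chrom = 20000) {
  stopifnot(ncol(dosage) == nrow(map))
  breaks <- seq(0, max_dist_cM, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  sums <- counts <- numeric(length(mids))
  for (c in unique(map$chrom)) {
    i <- which(map$chrom == c)
    if (length(i) < 2) next
    pr <- utils::combn(length(i), 2)
    if (ncol(pr) > max_pairs_per_chrom)
      pr <- pr[, sample.int(ncol(pr), max_pairs_per_chrom), drop = FALSE]
    d <- abs(map$pos_cM[i[pr[1, ]]] - map$pos_cM[i[pr[2, ]]])
    keep <- d <= max_dist_cM & d > 0
    if (!any(keep)) next
    pr <- pr[, keep, drop = FALSE]; d <- d[keep]
    X <- dosage[, i, drop = FALSE]
    sds <- apply(X, 2, sd)
    poly <- sds[pr[1, ]] > 0 & sds[pr[2, ]] > 0   # skip monomorphic pairs
    pr <- pr[, poly, drop = FALSE]; d <- d[poly]
    if (!length(d)) next
    Xc <- scale(X)
    r <- colSums(Xc[, pr[1, ], drop = FALSE] * Xc[, pr[2, ], drop = FALSE]) /
      (nrow(X) - 1)
    b <- findInterval(d, breaks, left.open = TRUE, rightmost.closed = TRUE)
    ok <- b >= 1 & b <= length(mids)
    sums <- sums + tapply_sum(r[ok]^2, b[ok], length(mids))
    counts <- counts + tapply_sum(rep(1, sum(ok)), b[ok], length(mids))
  }
  structure(list(dist_cM = mids, mean_r2 = ifelse(counts > 0, sums / counts,
                                                  NA_real_),
                 n_pairs = counts, bin_width = bin_width),
            class = "ld_decay")
}

tapply_sum <- function(x, g, nbins) {
  out <- numeric(nbins)
  s <- tapply(x, factor(g, levels = seq_len(nbins)), sum)
  out[!is.na(s)] <- s[!is.na(s)]
  out
}

#' @export
plot.ld_decay <- function(x, ...) {
  graphics::plot(x$dist_cM, x$mean_r2, type = "b", pch = 16, cex = 0.5,
                 xlab = "distance (cM)", ylab = expression(mean ~ r^2),
                 main = "LD decay", ...)
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G; scores are eigenvectors scaled by the square
#' roots of their eigenvalues, the standard view of population structure.
#'
#' @param G symmetric genomic relationship matrix.
#' @param n_pc how many components to return scores for.
#' @return List of class \code{g_pca}: \code{scores} (animals x n_pc),
#'   \code{var_explained} over all components, eigenvalues.
#' @export
pca_of_G <- function(G, n_pc = 2) {
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric")
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  n_pc <- min(n_pc, ncol(G))
  scores <- sweep(ev$vectors[, seq_len(n_pc), drop = FALSE], 2,
                  sqrt(lam[seq_len(n_pc)]), `*`)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(scores = scores, var_explained = lam / sum(lam),
                 values = lam),
            class = "g_pca")
}

#' @export
plot.g_pca <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2], pch = 16, cex = 0.6,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$var_explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$var_explained[2]),
                 main = "PCA of G", ...)
  invisible(x)
}

#' Effective population size from a rate of inbreeding
#'
#' The closed form \eqn{N_e = 1/(2\,\overline{\Delta F})} over the supplied
#' per-generation rates.
#'
#' @param delta_F per-generation rate(s) of inbreeding, averaged
#'   arithmetically (truncating non-positive spans would bias the rate
#'   upward in small populations).
#' @return The effective population size (NA when the mean rate is not
#'   positive).
#' @export
ne_from_deltaF <- function(delta_F) {
  m <- mean(delta_F)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  1 / (2 * m)
}

#' Effective population size from the pedigree inbreeding trend
#'
#' Per-generation mean inbreeding \eqn{F_n} from the pedigree, the rate
#' \deqn{\Delta F = \frac{F_n - F_{n-1}}{1 - F_{n-1}}}
#' and \deqn{N_e = \frac{1}{2\,\overline{\Delta F}}.}
#' The first span is excluded from the average when more are available:
#' pedigree founders are assumed unrelated, so \eqn{\Delta F} of the first
#' span is structurally zero (a truncation artifact, not a property of the
#' breeding design).
#'
#' @param pedigree data frame with \code{sire}, \code{dam}, \code{gen}.
#' @return List of class \code{inbreeding_trend}: per-generation mean F,
#'   per-span \eqn{\Delta F} (all spans), and \code{Ne} (NA when the mean
#'   rate is not positive).
#' @export
effective_population_size <- function(pedigree) {
  F <- cpp_inbreeding(as.integer(pedigree$sire), as.integer(pedigree$dam))
  gens <- sort(unique(pedigree$gen))
  if (length(gens) < 2) stop("need at least two generations")
  Fbar <- vapply(gens, function(g) mean(F[pedigree$gen == g]), numeric(1))
  dF <- diff(Fbar) / (1 - Fbar[-length(Fbar)])
  use <- if (length(dF) >= 2) dF[-1] else dF
  Ne <- ne_from_deltaF(use)
  structure(list(generation = gens, mean_F = Fbar, delta_F = dF, Ne = Ne),
            class = "inbreeding_trend")
}

#' @export
print.inbreeding_trend <- function(x, ...) {
  cat("Inbreeding trend over", length(x$generation), "generations: mean F",
      format(x$mean_F[length(x$mean_F)], digits = 4), "in the last\n")
  cat("  mean delta-F (post-founder spans) =",
      format(mean(x$delta_F[-1]), digits = 4),
      "-> Ne =", format(x$Ne, digits = 4), "\n")
  invisible(x)
}
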