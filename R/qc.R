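# Genotype quality control applied before association analysis.

#' Quality-control filter for a genotype panel
#'
#' Applies, in order: (1) removal of monomorphic SNPs; (2) removal of SNPs
#' with minor allele frequency strictly below \code{maf_min}; (3) removal of
#' SNPs whose observed heterozygote frequency deviates from the
#' Hardy-Weinberg expectation \eqn{2pq} by more than \code{dev_max} in
#' absolute value.  Thresholds are strict ("lower than", "greater than"), so
#' MAF exactly \code{maf_min} is kept and a deviation exactly \code{dev_max}
#' is kept.
#'
#' @param panel a \code{gwas_panel} (list with \code{dosage}, \code{ids},
#'   \code{map}) or a bare dosage matrix.
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @param dev_max heterozygosity-deviation threshold (default 0.15).
#' @return List with the filtered \code{panel} and a \code{report} of class
#'   \code{qc_report} (per-rule removal counts and the retained index).
#' @export
qc_filter <- function(panel, maf_min = 0.05, dev_max = 0.15) {
  bare <- is.matrix(panel)
  dosage <- if (bare) panel else panel$dosage
  rg <- range(dosage)
  if (rg[1] < 0 || rg[2] > 2) stop("dosages must be 0, 1 or 2")
  k <- ncol(dosage)
  p <- colMeans(dosage) / 2
  maf <- pmin(p, 1 - p)
  het_obs <- colMeans(dosage == 1)
  het_exp <- 2 * p * (1 - p)
  mono <- maf == 0
  lowmaf <- !mono & maf < maf_min
  dev <- !mono & !lowmaf & abs(het_obs - het_exp) > dev_max
  keep <- which(!(mono | lowmaf | dev))
  if (length(keep) == 0)
    stop("quality control removed every SNP (", sum(mono), " monomorphic, ",
         sum(lowmaf), " below MAF ", maf_min, ", ", sum(dev),
         " heterozygosity deviants)")
  report <- structure(list(n_input = k,
                           removed = c(monomorphic = sum(mono),
                                       low_maf = sum(lowmaf),
                                       freq_deviation = sum(dev)),
                           n_retained = length(keep),
                           retained = keep,
                           maf_min = maf_min, dev_max = dev_max),
                      class = "qc_report")
  if (bare) return(list(panel = dosage[, keep, drop = FALSE], report = report))
  out <- panel
  out$dosage <- panel$dosage[, keep, drop = FALSE]
  out$map <- panel$map[keep, , drop = FALSE]
  rownames(out$map) <- NULL
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC:", x$n_input, "SNPs in,", x$n_retained, "retained\n")
  cat("  removed: monomorphic", x$removed[["monomorphic"]],
      "| MAF <", x$maf_min, ":", x$removed[["low_maf"]],
      "| het-vs-2pq deviation >", x$dev_max, ":",
      x$removed[["freq_deviation"]], "\n")
  invisible(x)
}
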