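# User-level fitting front end: one call taking a simulated scenario to a
# per-SNP association result with any of the four methods.

#' Run an association method on a simulated scenario
#'
#' Applies genotype quality control, resolves the analysis set (genotyped
#' animals with own records, or deregressed sire proofs when the trait is
#' sex-limited and the genotyped animals carry no records), obtains variance
#' components, and dispatches to one of the four methods:
#' \code{"ssa"} (single-SNP least squares, no relatedness correction),
#' \code{"emmax"}, \code{"gblup"} (back-solved GBLUP effects) or
#' \code{"ssgwas"} (single-step, all phenotypes and the full pedigree; never
#' uses deregressed proofs).
#'
#' @param sim a \code{gwas_sim} from \code{\link{sim_scenario}} or
#'   \code{\link{simulate_recent}}.
#' @param method association method.
#' @param vc \code{"reml"} (estimate on the null model of the analysis set)
#'   or \code{"true"} (the simulation's generating values).
#' @param qc apply \code{\link{qc_filter}} first.
#' @param maf_min,dev_max QC thresholds.
#' @param lambda,beta blending weights for the genomic matrix of the
#'   BLUP-based methods.
#' @return A \code{gwas_scan} data frame with one row per retained SNP and
#'   attributes recording the method, sample size, variance components, QC
#'   report and whether deregressed proofs were used.
#' @export
gwas_scan <- function(sim, method = c("ssa", "emmax", "gblup", "ssgwas"),
                      vc = c("reml", "true"), qc = TRUE,
                      maf_min = 0.05, dev_max = 0.15,
                      lambda = 0.95, beta = 0.05) {
  method <- match.arg(method)
  vc <- match.arg(vc)
  stopifnot(inherits(sim, "gwas_sim"))
  qcr <- NULL
  panel <- sim$panel
  if (qc) {
    f <- qc_filter(panel, maf_min, dev_max)
    panel <- f$panel
    qcr <- f$report
  }
  ped <- sim$pedigree
  own <- panel$ids[ped$phenotyped[panel$ids]]
  map <- panel$map
  if (method == "ssgwas") {
    pheno_idx <- sim$phenotypes$id
    y <- sim$phenotypes$value
    vcv <- if (vc == "true") sim$vc_true else
      if (length(own) >= 10) NULL else sim$vc_true
    res <- ssgwas(y, pheno_idx, ped, panel$dosage,
                  geno_idx = panel$ids, vc = vcv,
                  lambda = lambda, beta = beta, map = map)
    drp_used <- FALSE
  } else {
    drp_used <- length(own) == 0
    if (drp_used) {
      dr <- drp_for_genotyped(sim)
      rows <- match(dr$id, panel$ids)
      y <- dr$drp
      dosage <- panel$dosage[rows, , drop = FALSE]
    } else {
      y <- sim$phenotypes$value[match(own, sim$phenotypes$id)]
      dosage <- panel$dosage[match(own, panel$ids), , drop = FALSE]
    }
    vcv <- if (vc == "true") sim$vc_true else NULL
    res <- switch(method,
                  ssa = ssa_nocor(y, dosage, map = map),
                  emmax = emmax(y, dosage, vc = vcv, map = map),
                  gblup = gblup_gwas(y, dosage, vc = vcv,
                                     lambda = lambda, beta = beta, map = map))
  }
  attr(res, "qc") <- qcr
  attr(res, "drp_used") <- drp_used
  attr(res, "scenario") <- sim$meta[c("design", "preset", "scale",
                                      "scaled_down", "seed")]
  res
}
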