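# Deregressed proofs: projecting progeny phenotypes onto genotyped parents
# so that sires of a sex-limited trait can enter methods that require the
# analysed animals to carry both genotype and phenotype.

#' Deregressed proofs from EBV, parent averages and reliabilities
#'
#' Daughter equivalents are \eqn{DE_{PA} = rel_{PA}/(1 - rel_{PA})} and
#' \eqn{DE_{prog} = rel_{EBV}/(1 - rel_{EBV}) - DE_{PA}}; the deregressed
#' proof removes the parent-average shrinkage:
#' \deqn{DRP = PA + (EBV - PA)\,\frac{DE_{prog} + DE_{PA} + 1}{DE_{prog}}.}
#' Animals whose EBV carries no progeny information beyond the parent
#' average (\eqn{DE_{prog} \le 0}) are excluded with a warning.
#'
#' @param ebv_table data frame with columns \code{id}, \code{ebv},
#'   \code{ebv_rel}, \code{pa}, \code{pa_rel} (see
#'   \code{\link{drp_for_genotyped}} for the pipeline that builds it).
#' @return Data frame of class \code{drp_records}: id, pa, ebv,
#'   reliabilities, daughter equivalents and drp, one row per retained
#'   animal.
#' @export
compute_drp <- function(ebv_table) {
  need <- c("id", "ebv", "ebv_rel", "pa", "pa_rel")
  stopifnot(all(need %in% names(ebv_table)))
  t <- ebv_table
  if (any(t$ebv_rel < 0 | t$ebv_rel >= 1 | t$pa_rel < 0 | t$pa_rel >= 1))
    stop("reliabilities must lie in [0, 1)")
  de_pa <- t$pa_rel / (1 - t$pa_rel)
  de_prog <- t$ebv_rel / (1 - t$ebv_rel) - de_pa
  ok <- de_prog > 0
  if (any(!ok))
    warning(sum(!ok), " animal(s) without progeny information beyond the ",
            "parent average excluded from deregression")
  drp <- t$pa + (t$ebv - t$pa) * (de_prog + de_pa + 1) / de_prog
  out <- data.frame(id = t$id, pa = t$pa, ebv = t$ebv,
                    ebv_rel = t$ebv_rel, pa_rel = t$pa_rel,
                    de_prog = de_prog, de_pa = de_pa, drp = drp)[ok, ]
  rownames(out) <- NULL
  class(out) <- c("drp_records", "data.frame")
  out
}

#' Deregressed proofs for the genotyped animals of a simulated scenario
#'
#' Runs the pedigree BLUP (all records, relationship inverse from the full
#' pedigree), extracts EBV, prediction-error variances and reliabilities for
#' the genotyped animals and their parents, forms parent averages and parent
#' -average reliabilities (\eqn{rel_{PA} = (rel_{sire} + rel_{dam})/4}), and
#' deregresses.
#'
#' @param sim a \code{gwas_sim}.
#' @param vc variance components for the BLUP; defaults to the simulation's
#'   true values.
#' @return A \code{drp_records} data frame (see \code{\link{compute_drp}}).
#' @export
drp_for_genotyped <- function(sim, vc = NULL) {
  vc <- vc %||% sim$vc_true
  ped <- sim$pedigree
  gid <- ped$id[ped$genotyped]
  par_ids <- setdiff(unique(c(ped$sire[gid], ped$dam[gid])), 0L)
  want <- sort(unique(c(gid, par_ids)))
  rec <- which(ped$phenotyped)
  y <- sim$phenotypes$value[match(ped$id[rec], sim$phenotypes$id)]
  Kinv <- ainverse_sparse(ped$sire, ped$dam)
  fit <- solve_mme(y, Z = incidence_sparse(rec, nrow(ped)), Kinv = Kinv,
                   vc = vc, c22 = "diag", c22_idx = want)
  F <- cpp_inbreeding(as.integer(ped$sire), as.integer(ped$dam))
  rel <- reliability(fit$pev, vc$sigma2_a, 1 + F[want])
  names(rel) <- want
  ebv <- fit$u
  relv <- rep(0, nrow(ped)); relv[want] <- rel
  pa <- parent_average(ped[gid, ], ebv)
  pa_rel <- (ifelse(ped$sire[gid] > 0, relv[pmax(ped$sire[gid], 1)], 0) +
               ifelse(ped$dam[gid] > 0, relv[pmax(ped$dam[gid], 1)], 0)) / 4
  compute_drp(data.frame(id = gid, ebv = ebv[gid],
                         ebv_rel = relv[gid], pa = pa, pa_rel = pa_rel))
}
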