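# Study orchestrator: simulate -> QC -> (DRP where needed) -> methods ->
# evaluate, across replicates, with the mean (SD) accounting and the paired
# significance comparisons between methods.

#' Run a replicated association study on a preset scenario
#'
#' For each replicate: simulate the scenario, run the requested methods
#' (deregressed proofs are substituted automatically for non-single-step
#' methods when the genotyped animals carry no own records), and count
#' significant SNPs inside (TP) and outside (FP) the \eqn{\pm}\code{window_cM}
#' QTN windows at the Bonferroni threshold.
#'
#' @inheritParams sim_scenario
#' @param n_rep number of replicates.
#' @param methods subset of \code{c("ssa", "emmax", "gblup", "ssgwas")}.
#' @param vc variance-component source passed to \code{\link{gwas_scan}}.
#' @param alpha family-wise significance level.
#' @param window_cM QTN window half-width.
#' @param out_dir optional directory; per-replicate association tables and
#'   the aggregate summary are written as TSV when given.
#' @param overrides optional preset parameter patches, see
#'   \code{\link{sim_scenario}}.
#' @param keep_scans retain the per-SNP scans in the returned object.
#' @return An object of class \code{gwas_study}: per-replicate counts,
#'   aggregate mean/SD per method, and paired t-test p-values between
#'   methods for TP and FP counts.
#' @export
run_study <- function(preset = c("fish", "beef", "dairy"),
                      scale = c("small", "large"), scaled_down = TRUE,
                      n_rep = 5, methods = c("ssa", "emmax", "gblup",
                                             "ssgwas"),
                      vc = "reml", seed = 1L, alpha = 0.05, window_cM = 2,
                      out_dir = NULL, keep_scans = FALSE, overrides = NULL) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  methods <- match.arg(methods, several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, n_rep)
  rows <- list(); scans <- list()
  for (r in seq_len(n_rep)) {
    sim <- sim_scenario(preset, scale, scaled_down, seed = rep_seeds[r],
                        overrides = overrides)
    for (m in methods) {
      sc <- gwas_scan(sim, method = m, vc = vc)
      thr <- bonferroni_threshold(nrow(sc), alpha)
      ev <- classify_tp_fp(sc, sim$qtn, threshold = thr,
                           window_cM = window_cM)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = r, method = attr(sc, "method"), tp = ev$tp,
                   fp = ev$fp, n_snps = nrow(sc), threshold = thr,
                   drp = attr(sc, "drp_used"))
      if (keep_scans) scans[[paste(r, m, sep = ".")]] <- sc
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write.table(sc, file.path(out_dir,
                                  sprintf("assoc_%s_rep%d.tsv", m, r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  agg <- aggregate(cbind(tp, fp) ~ method, data = res,
                   FUN = function(v) c(mean = mean(v), sd = sd(v)))
  agg <- data.frame(method = agg$method,
                    tp_mean = agg$tp[, "mean"], tp_sd = agg$tp[, "sd"],
                    fp_mean = agg$fp[, "mean"], fp_sd = agg$fp[, "sd"])
  cmp <- method_comparisons(res)
  out <- structure(list(results = res, aggregate = agg, comparisons = cmp,
                        preset = preset, scale = scale,
                        scaled_down = scaled_down, n_rep = n_rep,
                        alpha = alpha, window_cM = window_cM, seed = seed,
                        scans = if (keep_scans) scans else NULL),
                   class = "gwas_study")
  if (!is.null(out_dir))
    write.table(agg, file.path(out_dir, "eval_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  out
}

# paired t-tests across replicates between every method pair, for TP and FP
method_comparisons <- function(res) {
  ms <- unique(res$method)
  if (length(ms) < 2) return(NULL)
  pairs <- utils::combn(ms, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- res[res$method == pairs[1, k], ]
    b <- res[res$method == pairs[2, k], ]
    a <- a[order(a$replicate), ]; b <- b[order(b$replicate), ]
    pt <- function(x, y) {
      if (all(x == y)) return(1)       # identical counts: no difference
      tryCatch(t.test(x, y, paired = TRUE)$p.value,
               error = function(e) NA_real_)
    }
    data.frame(method_a = pairs[1, k], method_b = pairs[2, k],
               p_tp = pt(a$tp, b$tp), p_fp = pt(a$fp, b$fp))
  })
  do.call(rbind, out)
}

#' @export
print.gwas_study <- function(x, ...) {
  cat("Association study:", x$preset, paste0("(", x$scale,
      if (x$scaled_down) ", desk scale" else "", ")"), "-", x$n_rep,
      "replicates\n")
  cat("Mean (SD) significant SNPs inside / outside the +/-", x$window_cM,
      "cM QTN windows:\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-11s TP %6.2f (%5.2f)   FP %6.2f (%5.2f)\n",
                a$method[i], a$tp_mean[i], a$tp_sd[i], a$fp_mean[i],
                a$fp_sd[i]))
  invisible(x)
}

#' @export
summary.gwas_study <- function(object, ...) {
  cat("Per-replicate counts:\n")
  print(object$results, row.names = FALSE)
  if (!is.null(object$comparisons)) {
    cat("\nPaired t-tests across replicates (p-values):\n")
    print(object$comparisons, row.names = FALSE, digits = 3)
  }
  invisible(object)
}
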