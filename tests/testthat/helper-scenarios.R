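# Replicated desk-scale study scenarios shared by the acceptance-style
# tests.  Each scenario is simulated and analysed once per session and the
# per-replicate summaries cached, so several criteria can read from the same
# five replicates.

acc_env <- new.env(parent = emptyenv())

acc_scenario <- function(name) {
  got <- get0(name, envir = acc_env)
  if (!is.null(got)) return(got)
  cfg <- switch(name,
    beef  = list(preset = "beef", scale = "small", seed = 101,
                 methods = c("emmax", "gblup", "ssgwas")),
    dairy = list(preset = "dairy", scale = "small", seed = 102,
                 methods = c("emmax", "gblup", "ssgwas")),
    fishL = list(preset = "fish", scale = "large", seed = 103,
                 methods = c("ssa", "emmax", "gblup", "ssgwas")))
  seeds <- gwasim:::derive_seeds(cfg$seed, 5)
  reps <- lapply(seq_len(5), function(r) {
    sim <- sim_scenario(cfg$preset, cfg$scale, scaled_down = TRUE,
                        seed = seeds[r])
    out <- list(counts = list(), retention = NA_real_, lp = NULL)
    for (m in cfg$methods) {
      sc <- gwas_scan(sim, m, vc = "reml")
      ev <- classify_tp_fp(sc, sim$qtn)
      out$counts[[m]] <- c(tp = ev$tp, fp = ev$fp)
      if (r == 1 && m %in% c("emmax", "gblup"))
        out$lp[[m]] <- -log10(pmax(sc$pvalue, 1e-300))
      if (m == cfg$methods[1])
        out$retention <- attr(sc, "qc")$n_retained / attr(sc, "qc")$n_input
    }
    out
  })
  assign(name, reps, envir = acc_env)
  reps
}

acc_counts <- function(name, method, what = c("tp", "fp")) {
  what <- match.arg(what)
  vapply(acc_scenario(name), function(r) r$counts[[method]][[what]],
         numeric(1))
}
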