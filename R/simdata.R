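# Forward-in-time breeding simulator: a historical phase generates linkage
# disequilibrium and mutation-drift equilibrium; species-specific recent
# designs (fish / beef / dairy) then build the structured study populations.

map_arrays <- function(genome) {
  list(chrom = as.integer(genome$map$chrom),
       pos = genome$map$pos_cM,
       len = genome$chrom_length_cM)
}

#' Simulate the historical population
#'
#' Random union of gametes along a population-size trajectory, with recurrent
#' mutation, to generate linkage disequilibrium and mutation-drift
#' equilibrium before the recent breeding designs start.  Founder haplotypes
#' carry exactly \code{round(2N * founder_freq)} copies of the allele at
#' every locus, so with zero generations the allele frequencies equal
#' \code{founder_freq} exactly.
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param sizes integer vector of population sizes per generation, starting
#'   with the founder generation; \code{length(sizes) - 1} generations of
#'   mating are simulated.
#' @param prop_male proportion of males in every historical generation.
#' @param seed optional integer seed.
#' @return An object of class \code{founder_pool}: diploid haplotypes of the
#'   final generation plus the genome and the male/female split (by
#'   convention the first \code{n_male} individuals are male).
#' @export
simulate_historical <- function(genome, sizes, prop_male = 0.5, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), length(sizes) >= 1,
            all(sizes >= 2), prop_male > 0, prop_male < 1)
  if (!is.null(seed)) set.seed(seed)
  ma <- map_arrays(genome)
  founders <- cpp_founders(nrow(genome$map), as.integer(sizes[1]),
                           genome$founder_freq)
  hap <- if (length(sizes) == 1) founders else
    cpp_historical(founders, as.integer(sizes), ma$chrom, ma$pos, ma$len,
                   prop_male, genome$mutation_rate)
  n <- sizes[length(sizes)]
  structure(list(hap = hap, genome = genome, n = n,
                 n_male = max(1L, round(prop_male * n)),
                 sizes = sizes, prop_male = prop_male),
            class = "founder_pool")
}

#' @export
print.founder_pool <- function(x, ...) {
  cat("Founder pool:", x$n, "individuals (", x$n_male, "male ) after",
      length(x$sizes) - 1, "historical generations;",
      nrow(x$genome$map), "loci\n")
  invisible(x)
}

#' Meiosis: one gamete from a parental haplotype pair
#'
#' Crossover counts per chromosome are Poisson(length_cM / 100) with
#' uniformly placed positions and no interference; the gamete is a mosaic of
#' the two parental haplotypes.
#'
#' @param h1,h2 the parent's two haplotypes, 0/1 vectors over the loci of
#'   \code{genome$map}.
#' @param genome a \code{\link{genome_spec}} supplying the genetic map.
#' @return Integer 0/1 gamete of the same length.
#' @export
meiosis <- function(h1, h2, genome) {
  stopifnot(inherits(genome, "genome_spec"),
            length(h1) == nrow(genome$map), length(h2) == length(h1))
  ma <- map_arrays(genome)
  as.integer(cpp_gamete(as.raw(h1), as.raw(h2), ma$chrom, ma$pos, ma$len))
}

#' Draw and scale QTN effects
#'
#' Absolute effects are gamma(shape, 1) draws with random sign, rescaled so
#' that the realized variance of the total QTN contribution (the true
#' breeding value) among the founders of the recent population equals
#' \eqn{h^2/(1-h^2)} times the residual variance (fixed at 1).
#'
#' @param genome a \code{\link{genome_spec}}.
#' @param trait a \code{\link{trait_spec}}.
#' @param qtn_dosage founder QTN dosage matrix (founders x QTN, values 0/1/2).
#' @param seed optional integer seed.
#' @return List with signed scaled \code{effects}, the target additive
#'   variance \code{sigma2_a}, per-QTN \code{founder_freq}, and the scaling
#'   factor applied.
#' @export
assign_qtn_effects <- function(genome, trait, qtn_dosage, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"), inherits(trait, "trait_spec"),
            is.matrix(qtn_dosage))
  if (!is.null(seed)) set.seed(seed)
  nq <- ncol(qtn_dosage)
  raw <- rgamma(nq, shape = trait$qtn_effect_shape, rate = 1)
  sgn <- sample(c(-1, 1), nq, replace = TRUE)
  eff <- raw * sgn
  tbv <- drop(qtn_dosage %*% eff)
  v <- mean((tbv - mean(tbv))^2)         # population variance among founders
  if (v <= 0)
    stop("all QTN are monomorphic among recent-population founders; ",
         "cannot scale effects to the target genetic variance")
  sigma2_a <- trait$heritability / (1 - trait$heritability)  # sigma2_e = 1
  sc <- sqrt(sigma2_a / v)
  list(effects = eff * sc, sigma2_a = sigma2_a,
       founder_freq = colMeans(qtn_dosage) / 2, scale = sc)
}

# ---- internal machinery shared by the recent-population designs ------------

# Balanced randomized sexes: as close to 50/50 as the count allows.
balanced_sexes <- function(n) sample(rep_len(c("M", "F"), n))

new_sim_state <- function(pool, trait, seed_stage) {
  genome <- pool$genome
  ma <- map_arrays(genome)
  qtn_idx <- which(genome$map$type == "qtn")
  snp_idx <- which(genome$map$type == "snp")
  env <- new.env(parent = emptyenv())
  env$genome <- genome; env$trait <- trait; env$ma <- ma
  env$qtn_idx <- qtn_idx - 1L; env$snp_idx <- snp_idx - 1L
  env$id <- integer(0); env$sire <- integer(0); env$dam <- integer(0)
  env$sex <- character(0); env$gen <- integer(0)
  env$genotyped <- logical(0); env$phenotyped <- logical(0)
  env$tbv <- numeric(0); env$y <- numeric(0)   # y drawn for every animal
  env$geno <- list()                           # SNP dosage blocks (genotyped)
  env$cur_ids <- integer(0); env$cur_hap <- NULL
  env$effects <- rep(0, length(qtn_idx))   # replaced once scaled effects exist
  env$seed_stage <- seed_stage
  env
}

# Append one cohort.  sire/dam are ids (0 = unknown founder parents);
# parent haplotypes must be the current generation's matrix.
add_cohort <- function(st, hap, sex, sire, dam, gen) {
  n <- length(sex)
  ids <- seq_along(sex) + length(st$id)
  st$id <- c(st$id, ids)
  st$sire <- c(st$sire, sire); st$dam <- c(st$dam, dam)
  st$sex <- c(st$sex, sex); st$gen <- c(st$gen, rep.int(gen, n))
  st$genotyped <- c(st$genotyped, rep.int(FALSE, n))
  st$phenotyped <- c(st$phenotyped, rep.int(FALSE, n))
  qd <- cpp_dosage(hap, seq_len(n) - 1L, st$qtn_idx)
  tbv <- drop(qd %*% st$effects)
  st$tbv <- c(st$tbv, tbv)
  st$y <- c(st$y, st$trait$overall_mean + tbv + rnorm(n))
  st$cur_ids <- ids
  st$cur_hap <- hap
  invisible(ids)
}

# Breed offspring from the current generation given parent ids per offspring.
breed <- function(st, off_sire, off_dam, gen, sex = NULL) {
  si <- match(off_sire, st$cur_ids) - 1L
  di <- match(off_dam, st$cur_ids) - 1L
  if (anyNA(si) || anyNA(di))
    stop("parents must belong to the current generation")
  hap <- cpp_offspring(st$cur_hap, as.integer(si), as.integer(di),
                       st$ma$chrom, st$ma$pos, st$ma$len,
                       st$genome$mutation_rate)
  if (is.null(sex)) sex <- balanced_sexes(length(off_sire))
  add_cohort(st, hap, sex, off_sire, off_dam, gen)
}

# Record SNP dosages for a set of current-generation animals.
flag_genotyped <- function(st, ids) {
  idx <- match(ids, st$cur_ids) - 1L
  if (anyNA(idx)) stop("can only genotype animals of the current generation")
  g <- cpp_dosage(st$cur_hap, as.integer(idx), st$snp_idx)
  rownames(g) <- as.character(ids)
  st$geno[[length(st$geno) + 1L]] <- g
  st$genotyped[ids] <- TRUE
  invisible(NULL)
}

# Pedigree BLUP with the true variance ratio, used for within-simulation
# EBV selection.  Uses all female (or all, if not sex-limited) records so far.
ebv_for_selection <- function(st) {
  h2 <- st$trait$heritability
  rec <- if (st$trait$sex_limited) which(st$sex == "F") else seq_along(st$id)
  if (length(rec) < 2) stop("EBV selection requested with no records")
  vc <- list(sigma2_a = h2 / (1 - h2), sigma2_e = 1, source = "true")
  F <- cpp_inbreeding(st$sire, st$dam)
  Kinv <- ainverse_sparse(st$sire, st$dam, F)
  fit <- solve_mme(y = st$y[rec],
                   X = matrix(1, length(rec), 1),
                   Z = incidence_sparse(rec, length(st$id)),
                   Kinv = Kinv, vc = vc)
  drop(fit$u)
}

founders_from_pool <- function(st, pool, n_sires, n_dams, gen = 0L) {
  if (pool$n_male < n_sires || (pool$n - pool$n_male) < n_dams)
    stop("founder pool too small for the requested sires and dams")
  males <- sample.int(pool$n_male, n_sires)
  females <- pool$n_male + sample.int(pool$n - pool$n_male, n_dams)
  idx <- c(males, females)
  hap <- pool$hap[, as.vector(rbind(2L * idx - 1L, 2L * idx)), drop = FALSE]
  add_cohort(st, hap, c(rep("M", n_sires), rep("F", n_dams)),
             sire = rep.int(0L, n_sires + n_dams),
             dam = rep.int(0L, n_sires + n_dams), gen = gen)
}

# Random mating: each dam is paired with one uniformly drawn sire and
# produces `off_per_dam` offspring.
random_matings <- function(sires, dams, off_per_dam) {
  mate <- sample(sires, length(dams), replace = TRUE)
  list(sire = rep(mate, each = off_per_dam),
       dam = rep(dams, each = off_per_dam))
}

# Random union of gametes: both parents drawn independently per offspring,
# so per-parent offspring numbers are near-Poisson and the nucleus realizes
# the idealized Ne = 4 Nm Nf / (Nm + Nf).
random_union_matings <- function(sires, dams, n_off) {
  list(sire = sample(sires, n_off, replace = TRUE),
       dam = sample(dams, n_off, replace = TRUE))
}

finish_sim <- function(st, pool, design, params, eff_info, seed) {
  ped <- data.frame(id = st$id, sire = st$sire, dam = st$dam, sex = st$sex,
                    gen = st$gen, genotyped = st$genotyped,
                    phenotyped = st$phenotyped)
  geno <- do.call(rbind, st$geno)
  geno <- geno[order(as.integer(rownames(geno))), , drop = FALSE]
  snp_map <- st$genome$map[st$genome$map$type == "snp",
                           c("locus_id", "chrom", "pos_cM")]
  names(snp_map)[1] <- "snp_id"
  rownames(snp_map) <- NULL
  colnames(geno) <- snp_map$snp_id
  panel <- structure(list(dosage = geno, ids = as.integer(rownames(geno)),
                          map = snp_map),
                     class = "gwas_panel")
  qtn_map <- st$genome$map[st$genome$map$type == "qtn", ]
  qtn <- data.frame(qtn_id = qtn_map$locus_id, chrom = qtn_map$chrom,
                    pos_cM = qtn_map$pos_cM, effect = eff_info$effects,
                    founder_freq = eff_info$founder_freq)
  rownames(qtn) <- NULL
  ph <- which(ped$phenotyped)
  phen <- data.frame(id = ped$id[ph], value = st$y[ph], tbv = st$tbv[ph])
  structure(list(pedigree = ped, panel = panel, phenotypes = phen, qtn = qtn,
                 tbv = st$tbv, genome = st$genome, trait = st$trait,
                 vc_true = list(sigma2_a = eff_info$sigma2_a, sigma2_e = 1,
                                source = "true"),
                 meta = list(design = design, params = params, seed = seed)),
            class = "gwas_sim")
}

# ---- the three recent-population designs -----------------------------------

sim_fish_recent <- function(pool, trait, params, seed) {
  p <- params
  seeds <- derive_seeds(seed, 2)
  set.seed(seeds[1])
  st <- new_sim_state(pool, trait, seeds)
  fid <- founders_from_pool(st, pool, p$n_sires, p$n_dams)
  # effects scaled on the founders of the recent population
  qd <- cpp_dosage(st$cur_hap, seq_along(fid) - 1L, st$qtn_idx)
  eff <- assign_qtn_effects(st$genome, trait, qd, seed = seeds[2])
  st$effects <- eff$effects
  st$tbv <- drop(qd %*% eff$effects)
  st$y <- trait$overall_mean + st$tbv + rnorm(length(fid))
  # five generations of random selection, culling and mating (random union
  # of gametes, off_per_dam offspring per dam on average)
  for (g in seq_len(p$n_gen_random)) {
    cur <- st$cur_ids
    sires <- sample(cur[st$sex[cur] == "M"], p$n_sires)
    dams <- sample(cur[st$sex[cur] == "F"], p$n_dams)
    m <- random_union_matings(sires, dams, p$off_per_dam * p$n_dams)
    breed(st, m$sire, m$dam, gen = g)
  }
  # the new line: n_sires x n_dams from the last generation, full litters
  cur <- st$cur_ids
  sires <- sample(cur[st$sex[cur] == "M"], p$n_sires)
  dams <- sample(cur[st$sex[cur] == "F"], p$n_dams)
  parent_ids <- c(sires, dams)
  m <- random_matings(sires, dams, p$litter)
  # parents are genotyped and phenotyped together with the new line
  flag_genotyped(st, parent_ids)
  st$phenotyped[parent_ids] <- TRUE
  off <- breed(st, m$sire, m$dam, gen = p$n_gen_random + 1L)
  st$phenotyped[off] <- TRUE
  n_geno_off <- round(p$geno_frac * length(off))
  flag_genotyped(st, sample(off, n_geno_off))
  finish_sim(st, pool, "fish", p, eff, seed)
}

sim_beef_recent <- function(pool, trait, params, seed) {
  p <- params
  seeds <- derive_seeds(seed, 2)
  set.seed(seeds[1])
  st <- new_sim_state(pool, trait, seeds)
  fid <- founders_from_pool(st, pool, p$n_sires, p$n_dams)
  qd <- cpp_dosage(st$cur_hap, seq_along(fid) - 1L, st$qtn_idx)
  eff <- assign_qtn_effects(st$genome, trait, qd, seed = seeds[2])
  st$effects <- eff$effects
  st$tbv <- drop(qd %*% eff$effects)
  st$y <- trait$overall_mean + st$tbv + rnorm(length(fid))
  gen <- 0L
  # phase A: random mating at full size
  for (g in seq_len(p$n_gen_random)) {
    cur <- st$cur_ids
    sires <- sample(cur[st$sex[cur] == "M"], p$n_sires)
    dams <- sample(cur[st$sex[cur] == "F"], p$n_dams)
    m <- random_matings(sires, dams, p$off_per_dam)
    gen <- gen + 1L
    breed(st, m$sire, m$dam, gen = gen)
  }
  # phase B: five EBV-selected lines; block assignment of ranked candidates
  # differentiates the lines, within-line truncation selection maintains it
  ebv <- ebv_for_selection(st)
  cur <- st$cur_ids
  males <- cur[st$sex[cur] == "M"]; females <- cur[st$sex[cur] == "F"]
  top_m <- males[order(ebv[males], decreasing = TRUE)][
    seq_len(p$n_lines * p$line_sires)]
  top_f <- females[order(ebv[females], decreasing = TRUE)][
    seq_len(p$n_lines * p$line_dams)]
  line_s <- split(top_m, rep(seq_len(p$n_lines), each = p$line_sires))
  line_d <- split(top_f, rep(seq_len(p$n_lines), each = p$line_dams))
  for (g in seq_len(p$line_gens)) {
    ms <- mapply(function(s, d) random_matings(s, d, p$line_off_per_dam),
                 line_s, line_d, SIMPLIFY = FALSE)
    sizes <- vapply(ms, function(m) length(m$sire), 1L)
    line_of <- rep(seq_len(p$n_lines), sizes)
    gen <- gen + 1L
    # sexes balanced within each line so every line can supply its quota of
    # sires and dams
    off <- breed(st, unlist(lapply(ms, `[[`, "sire")),
                 unlist(lapply(ms, `[[`, "dam")), gen = gen,
                 sex = unlist(lapply(sizes, balanced_sexes)))
    ebv <- ebv_for_selection(st)
    line_s <- line_d <- vector("list", p$n_lines)
    for (l in seq_len(p$n_lines)) {
      ol <- off[line_of == l]
      olm <- ol[st$sex[ol] == "M"]; olf <- ol[st$sex[ol] == "F"]
      line_s[[l]] <- olm[order(ebv[olm], decreasing = TRUE)][
        seq_len(p$line_sires)]
      line_d[[l]] <- olf[order(ebv[olf], decreasing = TRUE)][
        seq_len(p$line_dams)]
    }
  }
  # phase C: pool the lines, random mating
  sires <- unlist(line_s); dams <- unlist(line_d)
  for (g in seq_len(p$pool_gens)) {
    m <- random_matings(sires, dams, p$pool_off_per_dam)
    if (g == p$pool_gens)                  # parents of the final generation:
      flag_genotyped(st, c(sires, dams))   # record dosages while still current
    gen <- gen + 1L
    off <- breed(st, m$sire, m$dam, gen = gen)
    if (g == p$pool_gens) {
      flag_genotyped(st, off)
    } else {
      sires <- sample(off[st$sex[off] == "M"], length(sires))
      dams <- sample(off[st$sex[off] == "F"], length(dams))
    }
  }
  # records: females of the last two pooled generations
  st$phenotyped[st$sex == "F" & st$gen >= gen - 1L] <- TRUE
  finish_sim(st, pool, "beef", p, eff, seed)
}

sim_dairy_recent <- function(pool, trait, params, seed) {
  p <- params
  seeds <- derive_seeds(seed, 2)
  set.seed(seeds[1])
  st <- new_sim_state(pool, trait, seeds)
  fid <- founders_from_pool(st, pool, p$n_sires, p$n_dams)
  qd <- cpp_dosage(st$cur_hap, seq_along(fid) - 1L, st$qtn_idx)
  eff <- assign_qtn_effects(st$genome, trait, qd, seed = seeds[2])
  st$effects <- eff$effects
  st$tbv <- drop(qd %*% eff$effects)
  st$y <- trait$overall_mean + st$tbv + rnorm(length(fid))
  st$phenotyped[fid[st$sex[fid] == "F"]] <- TRUE
  sires <- fid[st$sex[fid] == "M"]; dams <- fid[st$sex[fid] == "F"]
  # coancestry among current parents, for inbreeding-minimizing matings
  K <- diag(0.5, length(fid)); par_ids <- c(sires, dams)
  dimnames(K) <- list(par_ids, par_ids)
  dams_per_sire <- length(dams) / length(sires)
  for (g in seq_len(p$n_gens)) {
    if (g == p$geno_gen) flag_genotyped_noncurrent(st, sires)
    mate <- greedy_mate(K[as.character(sires), as.character(dams),
                          drop = FALSE], dams_per_sire)
    off_sire <- rep(sires[mate], each = p$off_per_dam)
    off_dam <- rep(dams, each = p$off_per_dam)
    off <- breed(st, off_sire, off_dam, gen = g)
    st$phenotyped[off[st$sex[off] == "F"]] <- TRUE
    ebv <- ebv_for_selection(st)
    om <- off[st$sex[off] == "M"]; of <- off[st$sex[off] == "F"]
    new_sires <- om[order(ebv[om], decreasing = TRUE)][seq_len(p$n_sires)]
    new_dams <- of[order(ebv[of], decreasing = TRUE)][
      seq_len(min(p$n_dams, length(of)))]
    K <- propagate_coancestry(K, par_ids, st, c(new_sires, new_dams))
    sires <- new_sires; dams <- new_dams; par_ids <- c(sires, dams)
  }
  finish_sim(st, pool, "dairy", p, eff, seed)
}

# genotype animals that are parents (previous generation) of the current
# matings: their haplotypes are still in cur_hap only while current, so this
# must be called before breeding replaces cur_hap.
flag_genotyped_noncurrent <- function(st, ids) flag_genotyped(st, ids)

# Greedy mate allocation: dams in random order, each assigned to the sire
# with the smallest coancestry among sires with remaining capacity.
greedy_mate <- function(Ksd, dams_per_sire) {
  n_s <- nrow(Ksd); n_d <- ncol(Ksd)
  cap <- rep(ceiling(dams_per_sire), n_s)
  mate <- integer(n_d)
  for (j in sample.int(n_d)) {
    open <- which(cap > 0)
    mate[j] <- open[which.min(Ksd[open, j])]
    cap[mate[j]] <- cap[mate[j]] - 1L
  }
  mate
}

# Coancestry among the selected offspring from coancestry among parents.
propagate_coancestry <- function(K, par_ids, st, sel) {
  S <- match(as.character(st$sire[sel]), as.character(par_ids))
  D <- match(as.character(st$dam[sel]), as.character(par_ids))
  Kn <- 0.25 * (K[S, S, drop = FALSE] + K[S, D, drop = FALSE] +
                  K[D, S, drop = FALSE] + K[D, D, drop = FALSE])
  diag(Kn) <- 0.5 * (1 + K[cbind(S, D)])
  dimnames(Kn) <- list(sel, sel)
  Kn
}

#' Simulate a recent breeding population
#'
#' Realizes one of the three study designs on top of a historical founder
#' pool: \describe{
#'   \item{fish}{random selection and mating of a small nucleus for five
#'     generations, then one large full-sib line (large litters); both sexes
#'     genotyped and phenotyped.}
#'   \item{beef}{random mating at scale, then five EBV-selected lines bred
#'     separately and pooled into one randomly mated line; the last
#'     generation and its parents are genotyped, females carry records.}
#'   \item{dairy}{EBV selection with inbreeding-minimizing mate allocation
#'     for ten generations; only the sires of one generation are genotyped,
#'     females carry records (each genotyped sire has phenotyped daughters).}
#' }
#'
#' @param design \code{"fish"}, \code{"beef"} or \code{"dairy"}.
#' @param founders a \code{founder_pool} from
#'   \code{\link{simulate_historical}}.
#' @param trait a \code{\link{trait_spec}}.
#' @param params design parameters; defaults are the full-size presets (see
#'   \code{\link{scenario_params}}).
#' @param seed integer seed; fixed seeds reproduce the pedigree and genotypes
#'   exactly.
#' @return A \code{gwas_sim} object: pedigree, genotype panel of genotyped
#'   animals, phenotype table (with true breeding values retained for
#'   validation), the QTN registry, and the true variance components.
#' @export
simulate_recent <- function(design = c("fish", "beef", "dairy"), founders,
                            trait, params = NULL, seed = 1L) {
  design <- match.arg(design)
  stopifnot(inherits(founders, "founder_pool"), inherits(trait, "trait_spec"))
  params <- params %||% scenario_params(design, scaled_down = FALSE)$recent
  switch(design,
         fish = sim_fish_recent(founders, trait, params, seed),
         beef = sim_beef_recent(founders, trait, params, seed),
         dairy = sim_dairy_recent(founders, trait, params, seed))
}

#' @export
print.gwas_sim <- function(x, ...) {
  cat("Simulated", x$meta$design, "population:",
      nrow(x$pedigree), "animals,",
      sum(x$pedigree$genotyped), "genotyped,",
      nrow(x$phenotypes), "records;",
      ncol(x$panel$dosage), "SNPs,", nrow(x$qtn), "QTN\n")
  cat("  trait h2 =", x$trait$heritability,
      if (x$trait$sex_limited) "(sex-limited)" else "", "\n")
  invisible(x)
}

#' @export
summary.gwas_sim <- function(object, ...) {
  ped <- object$pedigree
  ph <- object$phenotypes
  r2 <- if (nrow(ph) > 2) summary(stats::lm(value ~ tbv, data = ph))$r.squared
        else NA_real_
  out <- list(design = object$meta$design,
              n_animals = nrow(ped),
              n_genotyped = sum(ped$genotyped),
              n_records = nrow(ph),
              n_snps = ncol(object$panel$dosage),
              n_qtn = nrow(object$qtn),
              h2_target = object$trait$heritability,
              h2_realized = r2,
              by_gen = table(ped$gen))
  class(out) <- "summary.gwas_sim"
  out
}

#' @export
print.summary.gwas_sim <- function(x, ...) {
  cat("Design:", x$design, "-", x$n_animals, "animals,", x$n_genotyped,
      "genotyped,", x$n_records, "records\n")
  cat("Panel:", x$n_snps, "SNPs,", x$n_qtn, "QTN\n")
  cat("Heritability: target", x$h2_target, "- realized (R2 of y on TBV)",
      round(x$h2_realized, 3), "\n")
  cat("Animals per generation:\n")
  print(x$by_gen)
  invisible(x)
}
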