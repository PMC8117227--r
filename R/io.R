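# Plain-text persistence of simulated scenarios, and PLINK export.

#' Write a simulated scenario to tab-separated files
#'
#' Emits \code{pedigree.tsv}, \code{genotypes.tsv} (id plus one dosage
#' column per SNP), \code{map.tsv}, \code{phenotypes.tsv} and
#' \code{qtn.tsv}; \code{\link{read_scenario}} restores them losslessly.
#'
#' @param sim a \code{gwas_sim}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_scenario <- function(sim, dir) {
  stopifnot(inherits(sim, "gwas_sim"))
  if (nrow(sim$pedigree) == 0) stop("empty pedigree")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    path <- file.path(dir, f)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  ped <- sim$pedigree
  ped$genotyped <- as.integer(ped$genotyped)
  ped$phenotyped <- as.integer(ped$phenotyped)
  p1 <- w(ped, "pedigree.tsv")
  geno <- data.frame(id = sim$panel$ids, sim$panel$dosage,
                     check.names = FALSE)
  p2 <- w(geno, "genotypes.tsv")
  p3 <- w(sim$panel$map, "map.tsv")
  p4 <- w(sim$phenotypes, "phenotypes.tsv")
  p5 <- w(sim$qtn, "qtn.tsv")
  invisible(c(p1, p2, p3, p4, p5))
}

#' Read a scenario written by \code{\link{write_scenario}}
#'
#' @param dir directory containing the TSV files.
#' @return List with \code{pedigree}, \code{panel} (a \code{gwas_panel}),
#'   \code{phenotypes} and \code{qtn} matching the in-memory originals.
#' @export
read_scenario <- function(dir) {
  rd <- function(f) read.table(file.path(dir, f), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE)
  ped <- rd("pedigree.tsv")
  ped$genotyped <- as.logical(ped$genotyped)
  ped$phenotyped <- as.logical(ped$phenotyped)
  geno <- rd("genotypes.tsv")
  ids <- as.integer(geno$id)
  dosage <- as.matrix(geno[, -1, drop = FALSE])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- as.character(ids)
  panel <- structure(list(dosage = dosage, ids = ids, map = rd("map.tsv")),
                     class = "gwas_panel")
  list(pedigree = ped, panel = panel, phenotypes = rd("phenotypes.tsv"),
       qtn = rd("qtn.tsv"))
}

#' Export genotyped animals in PLINK .ped/.map format
#'
#' Alleles are coded 1/2 (dosage counts allele 2); the .map file carries the
#' genetic distance in cM and a base-pair proxy of 10 kb per 0.01 cM.
#'
#' @param sim a \code{gwas_sim}.
#' @param prefix output path prefix (writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}).
#' @return Invisibly, the two file paths.
#' @export
export_plink <- function(sim, prefix) {
  stopifnot(inherits(sim, "gwas_sim"))
  ped <- sim$pedigree
  ids <- sim$panel$ids
  d <- sim$panel$dosage
  al <- matrix("", nrow(d), 2 * ncol(d))
  al[, seq(1, 2 * ncol(d), 2)] <- ifelse(d >= 1, "2", "1")
  al[, seq(2, 2 * ncol(d), 2)] <- ifelse(d == 2, "2", "1")
  ph <- sim$phenotypes$value[match(ids, sim$phenotypes$id)]
  ph[is.na(ph)] <- -9
  pedf <- data.frame(fid = 1L, iid = ids,
                     pid = ped$sire[ids], mid = ped$dam[ids],
                     sex = ifelse(ped$sex[ids] == "M", 1L, 2L),
                     pheno = ph, al, check.names = FALSE)
  pp <- paste0(prefix, ".ped")
  write.table(pedf, pp, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  m <- sim$panel$map
  mapf <- data.frame(chrom = m$chrom, id = m$snp_id, cm = m$pos_cM,
                     bp = round(m$pos_cM * 1e6))
  mp <- paste0(prefix, ".map")
  write.table(mapf, mp, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(pp, mp))
}
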