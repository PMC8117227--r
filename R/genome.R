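#' Genome specification
#'
#' Defines the simulated genome: number of chromosomes, map length, an evenly
#' spaced SNP panel, one (or more) causal QTN per chromosome placed at evenly
#' spaced interior positions (the single-QTN default sits at the chromosome
#' midpoint), a recurrent mutation rate, and the founder allele frequency.
#'
#' SNP positions on a chromosome of length \eqn{L} are \eqn{j L/(m+1)} for
#' \eqn{j = 1, \dots, m}; the per-chromosome SNP count \eqn{m} is rounded to
#' an even number so that no SNP coincides with the midpoint QTN.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM map length of each chromosome in centimorgans
#'   (scalar, recycled).
#' @param n_snps total SNP count across the genome (rounded to an even
#'   per-chromosome count).
#' @param n_qtn_per_chrom causal loci per chromosome.
#' @param mutation_rate recurrent allele-flip rate per locus (haplotype copy)
#'   per generation.
#' @param founder_freq allele frequency at every locus in the first
#'   historical generation.
#' @return An object of class \code{genome_spec}: the arguments plus a locus
#'   map (\code{data.frame} with \code{locus}, \code{chrom}, \code{pos_cM},
#'   \code{type}) ordered by chromosome and position.
#' @export
genome_spec <- function(n_chromosomes = 29, chrom_length_cM = 100,
                        n_snps = 35000, n_qtn_per_chrom = 1,
                        mutation_rate = 2.5e-5, founder_freq = 0.5) {
  stopifnot(n_chromosomes >= 1, chrom_length_cM > 0, n_snps >= n_chromosomes,
            n_qtn_per_chrom >= 0, mutation_rate >= 0,
            founder_freq > 0, founder_freq < 1)
  len <- rep_len(chrom_length_cM, n_chromosomes)
  m <- round(n_snps / n_chromosomes)
  m <- m - m %% 2L                       # even: midpoint never on the grid
  if (m < 2) stop("fewer than two SNPs per chromosome")
  maps <- vector("list", n_chromosomes)
  for (c in seq_len(n_chromosomes)) {
    snp_pos <- seq_len(m) * len[c] / (m + 1)
    qtn_pos <- if (n_qtn_per_chrom > 0)
      seq_len(n_qtn_per_chrom) * len[c] / (n_qtn_per_chrom + 1) else numeric(0)
    if (any(qtn_pos %in% snp_pos))
      stop("QTN position collides with the SNP grid")
    pos <- c(snp_pos, qtn_pos)
    type <- c(rep("snp", m), rep("qtn", n_qtn_per_chrom))
    o <- order(pos)
    maps[[c]] <- data.frame(chrom = c, pos_cM = pos[o], type = type[o])
  }
  map <- do.call(rbind, maps)
  map$locus <- seq_len(nrow(map))
  snp_i <- map$type == "snp"
  map$locus_id <- NA_character_
  map$locus_id[snp_i] <- paste0("snp", seq_len(sum(snp_i)))
  map$locus_id[!snp_i] <- paste0("qtn", seq_len(sum(!snp_i)))
  map <- map[, c("locus", "locus_id", "chrom", "pos_cM", "type")]
  rownames(map) <- NULL
  structure(list(n_chromosomes = n_chromosomes, chrom_length_cM = len,
                 n_snps = m * n_chromosomes, n_qtn_per_chrom = n_qtn_per_chrom,
                 mutation_rate = mutation_rate, founder_freq = founder_freq,
                 map = map),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome:", x$n_chromosomes, "chromosomes x",
      format(x$chrom_length_cM[1]), "cM;",
      x$n_snps, "SNPs,", x$n_qtn_per_chrom * x$n_chromosomes, "QTN\n")
  cat("  mutation rate", format(x$mutation_rate),
      "/locus/generation; founder allele frequency",
      format(x$founder_freq), "\n")
  invisible(x)
}

#' Trait specification
#'
#' @param heritability narrow-sense heritability of the simulated trait; the
#'   preset scenarios use 0.25 (fish), 0.30 (beef) and 0.35 (dairy).
#' @param overall_mean trait mean added to every phenotype.
#' @param qtn_effect_shape shape of the gamma distribution of absolute QTN
#'   effects (0.40 in all presets: few large, many small effects).
#' @param sex_limited if \code{TRUE}, phenotypes are recorded on females only.
#' @return An object of class \code{trait_spec}.
#' @export
trait_spec <- function(heritability = 0.25, overall_mean = 1.0,
                       qtn_effect_shape = 0.40, sex_limited = FALSE) {
  stopifnot(heritability > 0, heritability < 1, qtn_effect_shape > 0)
  structure(list(heritability = heritability, overall_mean = overall_mean,
                 qtn_effect_shape = qtn_effect_shape,
                 sex_limited = sex_limited),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  cat("Trait: h2 =", x$heritability, "mean =", x$overall_mean,
      if (x$sex_limited) "(sex-limited, female records only)" else
        "(recorded on both sexes)", "\n")
  invisible(x)
}
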