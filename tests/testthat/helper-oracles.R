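# Independent oracles used against the package implementations.

# Wright's kinship by recursion (memoised), independent of the tabular
# construction: f(i,j) = 0.5 f(s_i, j) + 0.5 f(d_i, j) for i > j,
# f(i,i) = 0.5 (1 + f(s_i, d_i)).  A = 2 f.
oracle_A <- function(sire, dam) {
  n <- length(sire)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    val <- if (i == j)
      0.5 * (1 + f(sire[i], dam[i]))
    else
      0.5 * f(sire[i], j) + 0.5 * f(dam[i], j)
    assign(key, val, envir = memo)
    val
  }
  outer(seq_len(n), seq_len(n), Vectorize(function(i, j) 2 * f(i, j)))
}

# Brute-force mixed-model solutions and PEV block by direct inversion of the
# assembled coefficient matrix.
oracle_mme <- function(y, X, Z, Kinv, sigma2_a, sigma2_e) {
  lambda <- sigma2_e / sigma2_a
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Kinv * lambda))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Ci <- solve(C)
  sol <- Ci %*% rhs
  p <- ncol(X)
  list(beta = sol[seq_len(p)], u = sol[-seq_len(p)],
       C22 = Ci[-seq_len(p), -seq_len(p), drop = FALSE] * sigma2_e)
}

# H assembled from its partitioned definition (genotyped block replaced by
# G, non-genotyped blocks projected through the pedigree), inverted directly.
oracle_Hinv <- function(A, G, idx) {
  n <- nrow(A)
  ng <- setdiff(seq_len(n), idx)
  A22 <- A[idx, idx, drop = FALSE]
  A22i <- solve(A22)
  H <- A
  H[idx, idx] <- G
  if (length(ng)) {
    A12 <- A[ng, idx, drop = FALSE]
    H[ng, idx] <- A12 %*% A22i %*% G
    H[idx, ng] <- t(H[ng, idx])
    H[ng, ng] <- A[ng, ng] - A12 %*% A22i %*% (A22 - G) %*% A22i %*% t(A12)
  }
  solve(H)
}

# small deterministic dosage matrix with all three genotype classes
toy_dosage <- function(n = 12, k = 8, seed = 99) {
  set.seed(seed)
  matrix(sample(0:2, n * k, replace = TRUE, prob = c(.3, .4, .3)), n, k)
}

# pedigree data frame helper
ped_df <- function(sire, dam, sex = NULL, gen = NULL) {
  n <- length(sire)
  data.frame(id = seq_len(n), sire = sire, dam = dam,
             sex = sex %||% rep("M", n),
             gen = gen %||% rep(0L, n),
             genotyped = FALSE, phenotyped = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one tiny fish scenario reused by several unit files (fast: ~1 s)
tiny_fish <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- genome_spec(n_chromosomes = 4, n_snps = 120)
      pool <- simulate_historical(g, sizes = rep(150, 16), prop_male = 0.4,
                                  seed = 11)
      cache <<- simulate_recent("fish", pool, trait_spec(0.25),
                                params = list(n_sires = 8, n_dams = 8,
                                              n_gen_random = 3,
                                              off_per_dam = 2, litter = 25,
                                              geno_frac = 0.5),
                                seed = 5)
    }
    cache
  }
})
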