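# Shared fixtures: everything is generated in code at test time.

# Small non-negative fragprint-like feature matrix with no all-zero rows.
tiny_features <- function(n, d = 24, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rbinom(n * (d - 4), 1, 0.2), n),
             matrix(rpois(n * 4, 0.5), n))
  zero <- rowSums(x) == 0
  x[zero, 1] <- 1
  x
}

# A few SMILES spellings of azobenzene (same molecule, different atom orders).
azobenzene_spellings <- c(
  "c1ccc(cc1)/N=N/c1ccccc1",
  "C1=CC=C(C=C1)/N=N/C1=CC=CC=C1",
  "c1ccc(/N=N/c2ccccc2)cc1"
)

# Small, valid screening library of azoarene-flavoured molecules.
demo_smiles <- c(
  "c1ccc(cc1)/N=N/c1ccccc1",                # azobenzene
  "Cc1ccc(cc1)/N=N/c1ccccc1",               # 4-methyl
  "Oc1ccc(cc1)/N=N/c1ccccc1",               # 4-hydroxy
  "Nc1ccc(cc1)/N=N/c1ccccc1",               # 4-amino
  "CN(C)c1ccc(cc1)/N=N/c1ccccc1",           # 4-dimethylamino
  "COc1ccc(cc1)/N=N/c1ccc(cc1)[N+](=O)[O-]" # push-pull
)

# Write a temporary dataset CSV (default column map) and return its path.
write_demo_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "smiles,e_iso_pi,e_iso_n,z_iso_pi,z_iso_n,solvent"
  writeLines(c(header, rows), path)
  path
}

# Dense multivariate-normal log density computed without Cholesky (solve +
# LU determinant): the independent oracle for the GP marginal likelihood.
dense_mvn_logdensity <- function(K, y) {
  n <- length(y)
  ld <- determinant(K, logarithm = TRUE)
  stopifnot(ld$sign == 1)
  -0.5 * drop(t(y) %*% solve(K, y)) - 0.5 * as.numeric(ld$modulus) -
    0.5 * n * log(2 * pi)
}

# The jitter the package adds to keep covariances positive definite; the
# oracles must describe the same covariance.
oracle_jitter <- function(K) 1e-6 * mean(diag(K))
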