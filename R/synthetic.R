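# Synthetic multitask datasets with known ground truth. The generator
# emulates the statistical structure the multioutput GP assumes: sparse
# fragprint-like features organised in scaffold families (curated azoswitch
# sets are families of decorated scaffolds, so Tanimoto similarities are
# far from orthogonal), latent task values drawn jointly from the ICM prior
# (shared Tanimoto input kernel times a task covariance B = LL'),
# homoscedastic Gaussian observation noise, and per-task label missingness
# matching the curated data's label availability.

#' Specification of a synthetic multitask dataset
#'
#' Defaults emulate the curated photoswitch data: 405 molecules; a signal
#' standard deviation of 40 nm per task (task covariance `B` with diagonal
#' 1600 nm^2) with strong cross-task correlation 0.7; observation noise of
#' sd ~17 nm (`sigma_y2 = 300`), large because solvent effects are absorbed
#' into the noise rather than the representation; task means around the
#' typical band positions of azoswitches; per-task label missingness
#' reproducing the 392/141/93/123 labels available out of 405 molecules;
#' and features drawn as decorated scaffold families, so that molecular
#' similarities span the range a curated family of azoswitches shows rather
#' than being near-orthogonal.
#'
#' @param n_molecules Number of molecules.
#' @param feature_length Total fragprint length; 80% Bernoulli(0.05) bits,
#'   20% Poisson(0.3) counts, mimicking fragprint sparsity.
#' @param n_scaffolds Number of scaffold families; each molecule copies a
#'   scaffold's feature vector and resamples a fraction of positions.
#' @param decoration_rate Fraction of feature positions resampled per
#'   molecule (0 = identical within family, 1 = independent molecules).
#' @param true_sigma_f2 Signal variance multiplier of the shared kernel.
#' @param true_L Lower-triangular 4 x 4 Cholesky factor of the task
#'   covariance `B = L %*% t(L)`; diagonal must be strictly positive.
#' @param true_sigma_y2 Observation-noise variance (nm^2), >= 0.
#' @param task_means Per-task mean wavelengths (nm).
#' @param label_missingness Per-task probability in \[0, 1\] that a label is
#'   masked.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 405L,
                           feature_length = 512L,
                           n_scaffolds = 12L,
                           decoration_rate = 0.2,
                           true_sigma_f2 = 1,
                           true_L = default_true_L(),
                           true_sigma_y2 = 300,
                           task_means = c(350, 440, 320, 430),
                           label_missingness = c(0.032, 0.652, 0.770, 0.696),
                           seed = 0L) {
  true_L <- as.matrix(true_L)
  stopifnot(n_molecules >= 1, feature_length >= 2,
            n_scaffolds >= 1, decoration_rate >= 0, decoration_rate <= 1,
            true_sigma_f2 > 0, true_sigma_y2 >= 0,
            nrow(true_L) == 4, ncol(true_L) == 4,
            all(true_L[upper.tri(true_L)] == 0),
            all(diag(true_L) > 0),
            length(task_means) == 4,
            length(label_missingness) == 4,
            all(label_missingness >= 0), all(label_missingness <= 1))
  structure(
    list(n_molecules = as.integer(n_molecules),
         feature_length = as.integer(feature_length),
         n_scaffolds = as.integer(n_scaffolds),
         decoration_rate = decoration_rate,
         true_sigma_f2 = true_sigma_f2, true_L = true_L,
         true_sigma_y2 = true_sigma_y2, task_means = task_means,
         label_missingness = label_missingness, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Default ground-truth task Cholesky factor
#'
#' Lower Cholesky factor of `B = 1600 * R` where `R` has unit diagonal and
#' off-diagonal correlation 0.7: equal 40 nm signal scales across the four
#' wavelength tasks with strong shared structure, the regime in which
#' multitask learning pays off.
#'
#' @return A 4 x 4 lower-triangular matrix.
#' @export
default_true_L <- function() {
  R <- matrix(0.7, 4, 4); diag(R) <- 1
  t(chol(1600 * R))
}

#' Generate a synthetic multitask dataset
#'
#' Draws sparse binary/count feature vectors, latent task values jointly from
#' the ICM GP prior `sigma_f2 * B[t, s] * tanimoto(x_i, x_j)`, adds Gaussian
#' observation noise, and masks labels per task. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `features` (n x d matrix), `observations` (n x 4
#'   matrix of wavelengths, `NA` where masked), `latent` (noise-free n x 4
#'   matrix) and `ground_truth` (list of `sigma_f2`, `sigma_y2`, `L`, `B`,
#'   `task_means`).
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  d <- spec$feature_length
  n_bits <- ceiling(0.8 * d)
  n_counts <- d - n_bits

  draw_features <- function(m) {
    bits <- matrix(stats::rbinom(m * n_bits, 1L, 0.05), nrow = m)
    counts <- matrix(stats::rpois(m * n_counts, 0.3), nrow = m)
    cbind(bits, counts)
  }
  # decorated scaffold families: each molecule copies its family's feature
  # vector and resamples a fraction of positions from the marginals
  scaffolds <- draw_features(spec$n_scaffolds)
  family <- sample.int(spec$n_scaffolds, n, replace = TRUE)
  X <- scaffolds[family, , drop = FALSE]
  for (i in seq_len(n)) {
    flip <- which(stats::runif(d) < spec$decoration_rate)
    if (length(flip)) X[i, flip] <- draw_features(1L)[flip]
  }
  # all-zero rows have undefined Tanimoto similarity; redraw them
  for (k in 1:100) {
    zero <- rowSums(X != 0) == 0
    if (!any(zero)) break
    X[zero, ] <- draw_features(sum(zero))
  }
  if (any(rowSums(X != 0) == 0)) stop("could not draw non-zero feature vectors")

  B <- spec$true_L %*% t(spec$true_L)
  Tm <- tanimoto_gram(X, sigma_f2 = spec$true_sigma_f2)
  Lt <- chol_with_jitter(Tm)$L
  Lb <- t(chol(B + diag(1e-10 * mean(diag(B)), 4)))
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  # Cov(latent[i,t], latent[j,s]) = sigma_f2 * T[i,j] * B[t,s]
  latent <- sweep(Lt %*% Z %*% t(Lb), 2, spec$task_means, `+`)

  Y <- latent + matrix(stats::rnorm(n * 4, sd = sqrt(spec$true_sigma_y2)), n, 4)
  mask <- sapply(seq_len(4), function(t) {
    stats::rbinom(n, 1L, spec$label_missingness[t]) == 1L
  })
  Y[mask] <- NA_real_
  colnames(Y) <- colnames(latent) <- .TASKS

  list(features = X, observations = Y, latent = latent, family = family,
       ground_truth = list(sigma_f2 = spec$true_sigma_f2,
                           sigma_y2 = spec$true_sigma_y2,
                           L = spec$true_L, B = B,
                           task_means = spec$task_means))
}

#' Flatten a label matrix to task observations
#'
#' Turns an n x 4 wavelength matrix with `NA` gaps into the long observation
#' format [mogp_fit()] consumes: one row per observed (molecule, task) pair.
#'
#' @param labels n x 4 matrix with columns in [azogp_tasks()] order.
#' @return Data.frame with columns `molecule`, `task`, `value`.
#' @export
labels_to_observations <- function(labels) {
  labels <- as.matrix(labels)
  stopifnot(ncol(labels) == 4)
  obs <- do.call(rbind, lapply(seq_len(4), function(t) {
    ix <- which(!is.na(labels[, t]))
    if (!length(ix)) return(NULL)
    data.frame(molecule = ix, task = .TASKS[t], value = labels[ix, t],
               stringsAsFactors = FALSE)
  }))
  rownames(obs) <- NULL
  obs
}
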