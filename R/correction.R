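# Data-driven correction of physics-based (TD-DFT) wavelength predictions:
# a sparse linear (Lasso) model of the residual r = experimental - computed
# on fragprint features, evaluated under leave-one-out validation. The L1
# penalty induces sparsity over the high-dimensional fragprint vector; the
# penalised objective is (1/2n) * RSS + l1 * ||beta||_1 with the intercept
# unpenalised and features standardised internally (L1 is scale-sensitive).

#' Fit a sparse residual-correction model
#'
#' Lasso regression of the residuals `experimental - computed` (nm) on
#' fragprint features, at a single fixed L1 multiplier (default 0.1).
#' Deterministic given the data: the solution is computed by coordinate
#' descent at exactly the requested penalty.
#'
#' @param features Feature matrix (n x (F+G) fragprints).
#' @param computed_nm Physics-based predicted wavelengths (nm).
#' @param experimental_nm Experimental wavelengths (nm).
#' @param l1_multiplier L1 penalty (default 0.1); `Inf` gives the
#'   intercept-only model (mean residual).
#' @return An object of class `residual_model`: list with `coefficients`
#'   (length F+G), `intercept`, `l1_multiplier`, `n_features`, `n_nonzero`.
#' @export
fit_residual_model <- function(features, computed_nm, experimental_nm,
                               l1_multiplier = 0.1) {
  features <- as.matrix(features)
  stopifnot(length(computed_nm) == length(experimental_nm),
            nrow(features) == length(computed_nm),
            l1_multiplier >= 0)
  if (nrow(features) < 2L) stop("need at least 2 paired observations")
  r <- experimental_nm - computed_nm
  if (is.infinite(l1_multiplier) || stats::sd(r) == 0) {
    beta <- numeric(ncol(features))
    intercept <- mean(r)
  } else {
    fit <- glmnet::glmnet(features, r, alpha = 1, lambda = l1_multiplier,
                          standardize = TRUE, intercept = TRUE,
                          thresh = 1e-10, maxit = 1e6)
    beta <- as.numeric(fit$beta)
    intercept <- as.numeric(fit$a0)
  }
  structure(
    list(coefficients = beta, intercept = intercept,
         l1_multiplier = l1_multiplier,
         n_features = ncol(features), n_nonzero = sum(beta != 0)),
    class = "residual_model"
  )
}

#' @export
print.residual_model <- function(x, ...) {
  cat(sprintf("Sparse residual correction: intercept %.3f nm, %d/%d non-zero coefficients (l1 = %g)\n",
              x$intercept, x$n_nonzero, x$n_features, x$l1_multiplier))
  invisible(x)
}

#' @export
coef.residual_model <- function(object, ...) {
  c(intercept = object$intercept, object$coefficients)
}

#' Apply a residual correction to computed wavelengths
#'
#' `corrected = computed + predicted residual`; affine in the computed values
#' for a fixed model.
#'
#' @param model A fitted [fit_residual_model()].
#' @param features Feature matrix with the model's feature dimension.
#' @param computed_nm Physics-based predictions to correct (nm).
#' @return Corrected wavelengths (nm).
#' @export
apply_correction <- function(model, features, computed_nm) {
  stopifnot(inherits(model, "residual_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features) {
    stop(sprintf("feature configuration mismatch: model has %d features, input has %d",
                 model$n_features, ncol(features)))
  }
  stopifnot(nrow(features) == length(computed_nm))
  computed_nm + model$intercept + drop(features %*% model$coefficients)
}

#' Leave-one-out evaluation of the residual correction
#'
#' For each paired molecule, fits the residual model on the other n - 1
#' pairs and corrects the held-out computed value; reports uncorrected and
#' corrected error metrics over the held-out predictions.
#'
#' @inheritParams fit_residual_model
#' @return A list with `uncorrected` and `corrected` ([metric_suite()]
#'   reports) and `corrected_nm` (the per-fold corrected predictions).
#' @export
loo_corrected_eval <- function(features, computed_nm, experimental_nm,
                               l1_multiplier = 0.1) {
  features <- as.matrix(features)
  n <- length(computed_nm)
  stopifnot(length(experimental_nm) == n, nrow(features) == n)
  if (n < 3L) stop("need at least 3 paired observations")
  corrected <- vapply(seq_len(n), function(i) {
    m <- fit_residual_model(features[-i, , drop = FALSE],
                            computed_nm[-i], experimental_nm[-i],
                            l1_multiplier)
    apply_correction(m, features[i, , drop = FALSE], computed_nm[i])
  }, numeric(1))
  list(uncorrected = metric_suite(computed_nm, experimental_nm),
       corrected = metric_suite(corrected, experimental_nm),
       corrected_nm = corrected)
}
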