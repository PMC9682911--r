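# Benchmarking harness: error metrics, repeated random 80/20 splits,
# leave-one-out validation, confidence-error curves and paired Wilcoxon
# model comparison.
#
# Model factories: a model_factory is a function(x_train, y_train) returning
# a prediction function(x_test) -> list/data.frame with at least $mean (and
# optionally $var). gp_factory() adapts gp_fit() to this interface.

#' Error metrics for wavelength predictions
#'
#' Mean absolute error, mean signed error (prediction minus truth, to
#' diagnose systematic bias), RMSE, and the standard error of the absolute
#' errors. Pairs with an absent truth are dropped and counted.
#'
#' @param predictions,truths Equal-length numeric vectors (nm); `NA` truths
#'   are dropped.
#' @return An object of class `eval_report`: list with `mae`, `signed_me`,
#'   `rmse`, `stderr_mae`, `n`, `n_dropped`, `per_item_errors`
#'   (prediction - truth for the retained pairs).
#' @export
#' @examples
#' metric_suite(c(455, 465), c(450, 470)) # mae 5, signed_me 0
metric_suite <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (length(predictions) < 1L) stop("need at least one pair")
  keep <- !is.na(truths) & !is.na(predictions)
  if (!any(keep)) stop("no valid prediction/truth pairs")
  err <- predictions[keep] - truths[keep]
  n <- length(err)
  structure(
    list(mae = mean(abs(err)),
         signed_me = mean(err),
         rmse = sqrt(mean(err^2)),
         stderr_mae = if (n > 1) stats::sd(abs(err)) / sqrt(n) else NA_real_,
         n = n, n_dropped = sum(!keep),
         per_item_errors = unname(err)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d (dropped %d): MAE %.2f nm (se %.2f), signed ME %.2f nm, RMSE %.2f nm\n",
              x$n, x$n_dropped, x$mae,
              if (is.na(x$stderr_mae)) NA else x$stderr_mae, x$signed_me, x$rmse))
  invisible(x)
}

#' GP model factory
#'
#' Adapts [gp_fit()] to the model-factory interface used by the benchmark
#' drivers.
#'
#' @param ... Arguments forwarded to [gp_fit()] (e.g. `n_restarts`, `seed`).
#' @return A `function(x_train, y_train)` returning a
#'   `function(x_test) -> data.frame(mean, var)`.
#' @export
gp_factory <- function(...) {
  args <- list(...)
  function(x_train, y_train) {
    fit <- do.call(gp_fit, c(list(x = x_train, y = y_train), args))
    function(x_test) predict(fit, x_test)
  }
}

#' Repeated random train/test split benchmark
#'
#' Evaluates a model over `n_splits` random splits of the labelled molecules
#' in a `1 - test_fraction` / `test_fraction` ratio (default 80/20). Split k
#' is drawn with seed `seed + k` (a counter scheme, so extending `n_splits`
#' keeps earlier splits identical), which also makes split indices identical
#' across model factories for paired comparison.
#'
#' @param x Feature matrix.
#' @param y Targets (nm); `NA` rows are excluded. At least 10 labels.
#' @param model_factory See [gp_factory()].
#' @param n_splits Number of random splits (default 20).
#' @param test_fraction Held-out fraction (default 0.2).
#' @param seed Base seed of the counter scheme.
#' @return A list with `reports` (one [metric_suite()] report per split),
#'   `mae` (vector of per-split MAEs) and `splits` (list of held-out index
#'   vectors, positions within the labelled subset of rows of `x`).
#' @export
random_split_benchmark <- function(x, y, model_factory, n_splits = 20L,
                                   test_fraction = 0.2, seed = 0L) {
  x <- as.matrix(x)
  lab <- which(!is.na(y))
  if (length(lab) < 10L) stop("need at least 10 labelled molecules")
  n_test <- max(1L, round(test_fraction * length(lab)))
  splits <- lapply(seq_len(n_splits), function(k) {
    set.seed(as.integer(seed) + k)
    sort(sample(seq_along(lab), n_test))
  })
  reports <- lapply(splits, function(te) {
    tr <- setdiff(seq_along(lab), te)
    pred_fun <- model_factory(x[lab[tr], , drop = FALSE], y[lab[tr]])
    p <- pred_fun(x[lab[te], , drop = FALSE])
    metric_suite(p$mean, y[lab[te]])
  })
  list(reports = reports,
       mae = vapply(reports, `[[`, numeric(1), "mae"),
       splits = splits)
}

#' Leave-one-out benchmark
#'
#' For each labelled molecule, fits the model on the remaining labelled
#' molecules (plus an optional extra training pool) and predicts the
#' held-out one; prediction errors are averaged and the standard error
#' reported. If the held-out molecule also appears in the extra pool
#' (matched by `ids`), it is removed from the pool for that fold so the
#' answer cannot leak into training.
#'
#' @param x Feature matrix.
#' @param y Targets (nm); `NA` rows are excluded from the folds.
#' @param model_factory See [gp_factory()].
#' @param ids Optional identifiers (e.g. canonical SMILES) for the rows of
#'   `x`, used by the leakage guard.
#' @param extra Optional list with `x`, `y` and optionally `ids`: additional
#'   training records available to every fold.
#' @return A list with `report` (the [metric_suite()] over the held-out
#'   predictions) and `predictions` (vector aligned with the labelled rows).
#' @export
loo_benchmark <- function(x, y, model_factory, ids = NULL, extra = NULL) {
  x <- as.matrix(x)
  lab <- which(!is.na(y))
  if (length(lab) < 3L) stop("need at least 3 labelled molecules")
  if (!is.null(extra)) stopifnot(is.list(extra), !is.null(extra$x), !is.null(extra$y))
  preds <- vapply(seq_along(lab), function(i) {
    tr <- lab[-i]
    x_tr <- x[tr, , drop = FALSE]
    y_tr <- y[tr]
    if (!is.null(extra)) {
      keep <- rep(TRUE, length(extra$y))
      if (!is.null(ids) && !is.null(extra$ids)) {
        keep <- extra$ids != ids[lab[i]]
      }
      x_tr <- rbind(x_tr, as.matrix(extra$x)[keep, , drop = FALSE])
      y_tr <- c(y_tr, extra$y[keep])
    }
    pred_fun <- model_factory(x_tr, y_tr)
    pred_fun(x[lab[i], , drop = FALSE])$mean[1]
  }, numeric(1))
  list(report = metric_suite(preds, y[lab]), predictions = preds)
}

#' Confidence-error curve
#'
#' Ranks predictions by confidence (ascending predictive variance) and
#' reports the MAE over the most-confident fraction of the data for each
#' grid point. A model whose uncertainty is informative shows MAE decreasing
#' as the retained fraction shrinks; the fraction-1.0 point is the overall
#' MAE by construction. A group of predictions tied at the retention
#' boundary is included whole, so the curve is invariant to input order and
#' all-equal variances give a curve flat at the overall MAE.
#'
#' @param predictions,variances,truths Equal-length vectors; variances >= 0.
#' @param fractions Retained-fraction grid in (0, 1]; retained count is
#'   `ceiling(fraction * n)`, enlarged only by boundary ties.
#' @return An object of class `confidence_curve`: data.frame with columns
#'   `fraction`, `n_retained`, `mae`.
#' @export
confidence_error_curve <- function(predictions, variances, truths,
                                   fractions = seq(0.05, 1, by = 0.05)) {
  stopifnot(length(predictions) == length(variances),
            length(predictions) == length(truths))
  if (length(predictions) == 0L) stop("empty input")
  if (any(variances < 0)) stop("variances must be non-negative")
  err <- abs(predictions - truths)
  n <- length(err)
  sorted_var <- sort(variances)
  ks <- pmin(n, ceiling(fractions * n))
  retained <- lapply(ks, function(k) which(variances <= sorted_var[k]))
  out <- data.frame(fraction = fractions,
                    n_retained = lengths(retained))
  out$mae <- vapply(retained, function(ix) mean(err[ix]), numeric(1))
  class(out) <- c("confidence_curve", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank comparison of two models' paired errors (paired by
#' split or molecule). The null distribution is exact for n <= 25 (absent
#' ties), normal approximation with continuity correction otherwise. Zero
#' differences are discarded before ranking (classic Wilcoxon policy); the
#' Pratt variant, which ranks zeros and then drops their contribution, is
#' available via `zero_policy = "pratt"`.
#'
#' @param errors_a,errors_b Equal-length paired numeric vectors, n >= 5.
#' @param zero_policy `"discard"` (default) or `"pratt"`.
#' @return A list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_effective` and `method`.
#' @export
wilcoxon_paired <- function(errors_a, errors_b,
                            zero_policy = c("discard", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(errors_a) == length(errors_b))
  if (length(errors_a) < 5L) stop("need at least 5 pairs")
  d <- errors_a - errors_b
  if (all(d == 0)) {
    warning("all paired differences are zero; degenerate comparison")
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  if (zero_policy == "discard") {
    dd <- d[d != 0]
    n <- length(dd)
    wt <- suppressWarnings(
      stats::wilcox.test(dd, exact = (n <= 25L), correct = TRUE)
    )
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n_effective = n, method = wt$method)
  } else {
    # Pratt: rank |d| including zeros, drop the zeros' rank contribution,
    # normal approximation with the matching mean/variance adjustment.
    r <- rank(abs(d))
    nz <- d != 0
    Vp <- sum(r[nz & d > 0])
    n <- length(d)
    n0 <- sum(!nz)
    mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
    # tie/zero-adjusted variance of the positive-rank sum
    ties <- table(r[nz])
    sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    zstat <- (Vp - mu) / sqrt(sig2)
    list(statistic = Vp,
         p_value = min(1, 2 * stats::pnorm(-abs(zstat))),
         n_effective = sum(nz),
         method = "Wilcoxon signed rank, Pratt zero handling (normal approx.)")
  }
}
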