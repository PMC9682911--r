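# Multioutput GP over the four transition-wavelength tasks via the intrinsic
# model of coregionalisation: covariance between observation (molecule i,
# task t) and (molecule j, task s) is sigma_f2 * tanimoto(x_i, x_j) * B[t, s]
# with B = L L' parametrised through its Cholesky factor. Observed
# (molecule, task) pairs are stacked into one exact GP; molecules missing a
# task's label simply contribute no row for that task. Targets are z-scored
# per task; noise is one shared homoscedastic sigma_y2 on that scale.
#
# sigma_f2 is fixed at 1 by default: under the ICM kernel only the product
# sigma_f2 * B is identifiable, so B carries the per-task signal amplitudes.
# Set fit_sigma_f = TRUE to optimise it jointly anyway.

# Free-parameter layout helpers for the lower-triangular L (diagonal stored
# on the log scale for positivity).
lt_index <- function(P) which(lower.tri(diag(P), diag = TRUE), arr.ind = TRUE)

theta_to_L <- function(th, P) {
  idx <- lt_index(P)
  L <- matrix(0, P, P)
  L[idx] <- ifelse(idx[, 1] == idx[, 2], exp(th), th)
  L
}

L_to_theta <- function(L) {
  idx <- lt_index(nrow(L))
  ifelse(idx[, 1] == idx[, 2], log(L[idx]), L[idx])
}

make_mogp_objective <- function(Tsub, Zt, z, fit_sigma_f, fixed_sy2, fix_L, L_fixed) {
  n <- length(z)
  P <- ncol(Zt)
  ti <- max.col(Zt)  # task index per observation
  cache <- new.env(parent = emptyenv())
  unpack <- function(theta) {
    k <- 0L
    sf2 <- if (fit_sigma_f) { k <- k + 1L; exp(theta[k]) } else 1
    sy2 <- if (is.null(fixed_sy2)) { k <- k + 1L; exp(theta[k]) } else fixed_sy2
    L <- if (fix_L) L_fixed else theta_to_L(theta[(k + 1L):length(theta)], P)
    list(sf2 = sf2, sy2 = sy2, L = L)
  }
  compute <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    p <- unpack(theta)
    B <- p$L %*% t(p$L)
    Ksig <- p$sf2 * Tsub * B[ti, ti]
    pieces <- gauss_lml_pieces(Ksig + diag(p$sy2, n), z)
    Kinv <- chol2inv(t(pieces$chL))
    A <- tcrossprod(pieces$alpha) - Kinv
    g <- numeric(0)
    if (fit_sigma_f) g <- c(g, 0.5 * sum(A * Ksig))
    if (is.null(fixed_sy2)) g <- c(g, 0.5 * p$sy2 * sum(diag(A)))
    if (!fix_L) {
      M <- 0.5 * p$sf2 * (A * Tsub)
      G <- crossprod(Zt, M %*% Zt)
      dL <- (G + t(G)) %*% p$L
      idx <- lt_index(P)
      gL <- ifelse(idx[, 1] == idx[, 2], dL[idx] * diag(p$L)[idx[, 1]], dL[idx])
      g <- c(g, gL)
    }
    val <- list(nll = -pieces$lml, grad = -g, pieces = pieces, params = p)
    cache$key <- key
    cache$val <- val
    val
  }
  list(fn = function(th) compute(th)$nll,
       gr = function(th) compute(th)$grad,
       at = compute)
}

#' Fit a multioutput (ICM) Tanimoto-kernel GP
#'
#' Joint exact GP regression over the four transition-wavelength tasks.
#' Observed (molecule, task) pairs are stacked into a single GP whose kernel
#' is the shared Tanimoto input kernel times a task covariance `B = L L'`
#' learned through its Cholesky factor; cross-task correlations let sparsely
#' labelled tasks borrow strength from densely labelled ones. Targets are
#' standardised per task (a task observed with fewer than 2 values, or with
#' zero variance, is an error); noise is a single homoscedastic variance on
#' the standardised scale. Hyperparameters are fitted by multi-restart
#' L-BFGS with analytic gradients, deterministic for a given `seed`.
#'
#' @param x Feature matrix, one row per molecule.
#' @param observations Data.frame with columns `molecule` (row index into
#'   `x`), `task` (name in [azogp_tasks()] or index 1..4) and `value` (nm).
#'   See [labels_to_observations()].
#' @param n_restarts Optimiser restarts (first start: `L = I`, noise 0.1).
#' @param seed Integer seed for restart draws.
#' @param fit_sigma_f Optimise the redundant overall signal variance as well
#'   (default `FALSE`; `B` then carries the task amplitudes).
#' @param sigma_y2 Optional fixed noise variance on the standardised-target
#'   scale (`NULL` = optimise).
#' @param L Optional 4 x 4 lower-triangular starting value (or fixed value,
#'   with `fix_L = TRUE`) for the task Cholesky factor.
#' @param fix_L Hold `L` fixed instead of optimising it.
#' @return An object of class `tanimoto_mogp` with `print`, `summary`,
#'   `predict`, `coef`, `simulate` and `logLik` methods.
#' @seealso [predict.tanimoto_mogp()], [gp_fit()]
#' @export
mogp_fit <- function(x, observations, n_restarts = 5L, seed = 0L,
                     fit_sigma_f = FALSE, sigma_y2 = NULL,
                     L = NULL, fix_L = FALSE) {
  x <- as.matrix(x)
  obs <- as.data.frame(observations)
  stopifnot(all(c("molecule", "task", "value") %in% names(obs)))
  if (nrow(obs) < 2L) stop("need at least 2 observations")
  mi <- as.integer(obs$molecule)
  if (any(mi < 1L | mi > nrow(x))) stop("molecule index out of range")
  ti <- vapply(obs$task, function(t) match(match_task(t), .TASKS), integer(1))
  yv <- as.numeric(obs$value)
  if (any(!is.finite(yv))) stop("observation values must be finite")

  P <- 4L
  task_means <- task_sds <- rep(NA_real_, P)
  for (t in sort(unique(ti))) {
    vals <- yv[ti == t]
    if (length(vals) < 2L) {
      stop(sprintf("task %s has fewer than 2 observations", .TASKS[t]))
    }
    s <- stats::sd(vals)
    if (s == 0) stop(sprintf("degenerate target: task %s has zero variance", .TASKS[t]))
    task_means[t] <- mean(vals)
    task_sds[t] <- s
  }
  z <- (yv - task_means[ti]) / task_sds[ti]

  Tmol <- tanimoto_gram(x)
  Tsub <- Tmol[mi, mi, drop = FALSE]
  Zt <- matrix(0, length(z), P)
  Zt[cbind(seq_along(z), ti)] <- 1

  L_init <- if (is.null(L)) diag(P) else as.matrix(L)
  stopifnot(all(L_init[upper.tri(L_init)] == 0), all(diag(L_init) > 0))
  obj <- make_mogp_objective(Tsub, Zt, z, fit_sigma_f, sigma_y2, fix_L, L_init)

  n_free_L <- if (fix_L) 0L else P * (P + 1L) / 2L
  base_theta <- c(if (fit_sigma_f) 0,
                  if (is.null(sigma_y2)) log(0.1),
                  if (!fix_L) L_to_theta(L_init))
  if (length(base_theta) == 0L) {
    # everything fixed: nothing to optimise
    at <- obj$at(numeric(0))
    best <- list(par = numeric(0), convergence = 0L)
  } else {
    set.seed(as.integer(seed))
    inits <- c(list(base_theta),
               lapply(seq_len(max(0L, n_restarts - 1L)), function(i) {
                 th <- c(if (fit_sigma_f) stats::runif(1, -1, 1),
                         if (is.null(sigma_y2)) log(stats::runif(1, 1e-3, 1)),
                         if (!fix_L) {
                           idx <- lt_index(P)
                           ifelse(idx[, 1] == idx[, 2],
                                  stats::runif(P * (P + 1) / 2, -0.5, 0.5),
                                  stats::rnorm(P * (P + 1) / 2, 0, 0.3))[seq_len(n_free_L)]
                         })
                 th
               }))
    best <- NULL
    for (init in inits) {
      res <- tryCatch(
        stats::optim(init, obj$fn, obj$gr, method = "L-BFGS-B",
                     lower = rep(-15, length(init)), upper = rep(15, length(init)),
                     control = list(maxit = 500L, factr = 1e9)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value - 1e-9) {
        best <- list(value = res$value, par = res$par, convergence = res$convergence)
      }
    }
    if (is.null(best)) stop("hyperparameter optimisation failed in every restart")
    if (best$convergence != 0L) {
      warning("optimiser did not fully converge; returning best parameters found")
    }
    at <- obj$at(best$par)
  }

  p <- at$params
  B <- p$L %*% t(p$L)
  B_nm2 <- B * outer(task_sds, task_sds)          # NA rows for unobserved tasks
  sigma_y2_nm2 <- p$sy2 * task_sds^2

  structure(
    list(x = x, molecule = mi, task_index = ti, value = yv, z = z,
         task_means = task_means, task_sds = task_sds,
         sigma_f2 = p$sf2, sigma_y2 = p$sy2, L = p$L, B = B,
         B_nm2 = B_nm2, sigma_y2_nm2 = sigma_y2_nm2,
         chol = at$pieces$chL, alpha = at$pieces$alpha,
         jitter = at$pieces$jitter,
         log_marginal_likelihood = at$pieces$lml,
         convergence = best$convergence, n_obs = length(z),
         call = match.call()),
    class = "tanimoto_mogp"
  )
}

#' Predict one task from a multioutput Tanimoto GP
#'
#' Exact ICM-GP posterior for the requested task at new feature vectors.
#' Inference is the vanilla-GP posterior with the multitask kernel
#' `sigma_f2 * tanimoto(x, x') * B[t, s]` substituted; results are
#' de-standardised to nm using the task's own constants.
#'
#' @param object A fitted `tanimoto_mogp`.
#' @param newdata Feature matrix with the training feature dimension.
#' @param task Task name (see [azogp_tasks()]) or index 1..4; must have
#'   training observations.
#' @param include_noise Add the observation-noise variance to the reported
#'   variance.
#' @param ... Unused.
#' @return A data.frame with columns `mean` (nm) and `var` (nm^2).
#' @export
predict.tanimoto_mogp <- function(object, newdata, task, include_noise = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x)) {
    stop(sprintf("feature dimension mismatch: model has %d, newdata has %d",
                 ncol(object$x), ncol(newdata)))
  }
  t_star <- match(match_task(task), .TASKS)
  if (is.na(object$task_sds[t_star])) {
    stop(sprintf("task %s has no training observations", .TASKS[t_star]))
  }
  Tcross <- tanimoto_gram(newdata, object$x, sigma_f2 = object$sigma_f2)
  Ks <- Tcross[, object$molecule, drop = FALSE] *
    matrix(object$B[t_star, object$task_index], nrow(newdata), object$n_obs,
           byrow = TRUE)
  mu <- drop(Ks %*% object$alpha)
  v <- forwardsolve(object$chol, t(Ks))
  s2 <- pmax(object$sigma_f2 * object$B[t_star, t_star] - colSums(v^2), 0)
  if (include_noise) s2 <- s2 + object$sigma_y2
  data.frame(mean = mu * object$task_sds[t_star] + object$task_means[t_star],
             var = s2 * object$task_sds[t_star]^2)
}

#' Posterior draws from a multioutput Tanimoto GP, one task at a time
#'
#' @inheritParams predict.tanimoto_mogp
#' @param nsim Number of posterior function draws.
#' @param seed Optional integer seed.
#' @return A matrix (`nrow(newdata)` x `nsim`) of sampled wavelengths (nm).
#' @export
simulate.tanimoto_mogp <- function(object, nsim = 1, seed = NULL,
                                   newdata = object$x, task = "E_PI_PI", ...) {
  if (!is.null(seed)) set.seed(seed)
  newdata <- as.matrix(newdata)
  t_star <- match(match_task(task), .TASKS)
  if (is.na(object$task_sds[t_star])) {
    stop(sprintf("task %s has no training observations", .TASKS[t_star]))
  }
  Tcross <- tanimoto_gram(newdata, object$x, sigma_f2 = object$sigma_f2)
  Ks <- Tcross[, object$molecule, drop = FALSE] *
    matrix(object$B[t_star, object$task_index], nrow(newdata), object$n_obs,
           byrow = TRUE)
  mu <- drop(Ks %*% object$alpha)
  v <- forwardsolve(object$chol, t(Ks))
  Kss <- tanimoto_gram(newdata, sigma_f2 = object$sigma_f2) *
    object$B[t_star, t_star]
  Sigma <- Kss - crossprod(v)
  Lp <- chol_with_jitter((Sigma + t(Sigma)) / 2)$L
  zm <- matrix(stats::rnorm(nrow(newdata) * nsim), nrow(newdata), nsim)
  (mu + Lp %*% zm) * object$task_sds[t_star] + object$task_means[t_star]
}

#' @export
coef.tanimoto_mogp <- function(object, ...) {
  list(B = object$B_nm2, sigma_y2 = object$sigma_y2_nm2,
       sigma_f2 = object$sigma_f2)
}

#' @export
logLik.tanimoto_mogp <- function(object, ...) {
  df <- 11L + as.integer(!is.null(object$call$fit_sigma_f) &&
                           isTRUE(eval(object$call$fit_sigma_f)))
  structure(object$log_marginal_likelihood, df = df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
print.tanimoto_mogp <- function(x, ...) {
  obs_tasks <- .TASKS[!is.na(x$task_sds)]
  cat("Multioutput (ICM) Tanimoto-kernel Gaussian process\n")
  cat(sprintf("  %d observations over %d task(s): %s\n",
              x$n_obs, length(obs_tasks), paste(obs_tasks, collapse = ", ")))
  cat(sprintf("  shared noise sd (standardised) = %.4f\n", sqrt(x$sigma_y2)))
  cat("  task covariance B (nm^2):\n")
  Bp <- round(x$B_nm2)
  dimnames(Bp) <- list(.TASKS, .TASKS)
  print(Bp)
  invisible(x)
}

#' @export
summary.tanimoto_mogp <- function(object, ...) {
  s <- sqrt(pmax(diag(object$B_nm2), 0))
  Bc <- object$B_nm2 / outer(s, s)
  structure(list(model = object, task_correlation = Bc), class = "summary.tanimoto_mogp")
}

#' @export
print.summary.tanimoto_mogp <- function(x, ...) {
  print(x$model)
  cat("  implied task correlations:\n")
  Bc <- round(x$task_correlation, 2)
  dimnames(Bc) <- list(.TASKS, .TASKS)
  print(Bc)
  invisible(x)
}
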