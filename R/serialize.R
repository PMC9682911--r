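# Plain-text (JSON) model bundles: everything needed to reconstruct a fitted
# GP - training features, targets, standardisation constants, kernel
# hyperparameters and the coregionalisation factor - is stored; Cholesky
# factors are rebuilt on load rather than serialised. Versioned so stale
# bundles fail loudly.

BUNDLE_FORMAT_VERSION <- "azogp-bundle-1"

#' Save a fitted GP model to a JSON bundle
#'
#' Works for both [gp_fit()] and [mogp_fit()] objects. The bundle is plain
#' JSON (portable, diffable); covariance factorisations are recomputed on
#' load.
#'
#' @param model A `tanimoto_gp` or `tanimoto_mogp`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gp_save <- function(model, path) {
  if (inherits(model, "tanimoto_gp")) {
    payload <- list(format = BUNDLE_FORMAT_VERSION, class = "tanimoto_gp",
                    x = model$x, y = model$y,
                    sigma_f2 = model$sigma_f2, sigma_y2 = model$sigma_y2)
  } else if (inherits(model, "tanimoto_mogp")) {
    payload <- list(format = BUNDLE_FORMAT_VERSION, class = "tanimoto_mogp",
                    x = model$x,
                    molecule = model$molecule,
                    task = .TASKS[model$task_index],
                    value = model$value,
                    sigma_f2 = model$sigma_f2, sigma_y2 = model$sigma_y2,
                    L = model$L)
  } else {
    stop("model must be a tanimoto_gp or tanimoto_mogp")
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a fitted GP model from a JSON bundle
#'
#' @param path Bundle written by [gp_save()].
#' @return The reconstructed `tanimoto_gp` or `tanimoto_mogp` (numerically
#'   identical predictions to the saved model, up to jitter).
#' @export
gp_load <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(b$format, BUNDLE_FORMAT_VERSION)) {
    stop(sprintf("unsupported bundle format: %s", b$format %||% "missing"))
  }
  if (identical(b$class, "tanimoto_gp")) {
    gp_fit(as.matrix(b$x), b$y, sigma_f2 = b$sigma_f2, sigma_y2 = b$sigma_y2)
  } else if (identical(b$class, "tanimoto_mogp")) {
    obs <- data.frame(molecule = b$molecule, task = b$task, value = b$value,
                      stringsAsFactors = FALSE)
    # fold any fitted overall signal variance into L (only sigma_f2 * B is
    # identifiable, so this reproduces the saved covariance exactly)
    mogp_fit(as.matrix(b$x), obs, sigma_y2 = b$sigma_y2,
             L = sqrt(b$sigma_f2) * as.matrix(b$L), fix_L = TRUE,
             fit_sigma_f = FALSE)
  } else {
    stop(sprintf("unknown bundle class: %s", b$class))
  }
}
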