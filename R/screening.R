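# Criterion-based virtual screening: apply the photophysical criteria to
# model-predicted E/Z pi-pi* wavelengths over a SMILES library, rank the
# passing candidates, and summarise screening outcomes against experiment.
#
# Criterion 1: E-isomer pi-pi* maximum inside a window (default 450-600 nm,
#   inclusive boundary - red-shifted enough to limit UV damage and improve
#   tissue penetration).
# Criterion 2: separation between the E and Z pi-pi* bands above a threshold
#   (default 40 nm - enough band separation for selective LED addressing of
#   either isomer).

#' Screening criteria
#'
#' @param e_pipi_window Two-element window (nm) for the E-isomer pi-pi*
#'   maximum; default `c(450, 600)`.
#' @param min_separation Required separation (nm) between the E and Z
#'   pi-pi* bands; a candidate passes when the separation *exceeds* this.
#' @param boundary_inclusive Treat window endpoints as passing (default
#'   `TRUE`: a band at exactly 450 nm satisfies criterion 1).
#' @param absolute_separation Use `|E - Z|` instead of the signed `E - Z`
#'   (default `FALSE`: for azoswitches the E band lies red of the Z band,
#'   so the signed difference is the physically meaningful one).
#' @return An object of class `screening_criteria`.
#' @export
screening_criteria <- function(e_pipi_window = c(450, 600),
                               min_separation = 40,
                               boundary_inclusive = TRUE,
                               absolute_separation = FALSE) {
  stopifnot(length(e_pipi_window) == 2, e_pipi_window[1] < e_pipi_window[2],
            min_separation > 0)
  structure(list(e_pipi_window = as.numeric(e_pipi_window),
                 min_separation = as.numeric(min_separation),
                 boundary_inclusive = isTRUE(boundary_inclusive),
                 absolute_separation = isTRUE(absolute_separation)),
            class = "screening_criteria")
}

#' @export
print.screening_criteria <- function(x, ...) {
  cat(sprintf("Screening criteria: E pi-pi* in [%g, %g] nm (%s); E-Z separation > %g nm%s\n",
              x$e_pipi_window[1], x$e_pipi_window[2],
              if (x$boundary_inclusive) "inclusive" else "exclusive",
              x$min_separation,
              if (x$absolute_separation) " (absolute)" else ""))
  invisible(x)
}

#' Apply the screening criteria to wavelength pairs
#'
#' Vectorised verdicts: criterion 1 is the window test on the E-isomer
#' pi-pi* wavelength; criterion 2 is the band-separation test, failed (not
#' an error) when the Z value is absent - screening must be total over a
#' library.
#'
#' @param e_pipi E-isomer pi-pi* wavelengths (nm), finite.
#' @param z_pipi Z-isomer pi-pi* wavelengths (nm); may contain `NA`.
#' @param criteria A [screening_criteria()].
#' @return Data.frame with logical columns `passes_c1`, `passes_c2`,
#'   `passes_both` and numeric `separation` (nm, `NA` when Z absent).
#' @export
#' @examples
#' check_criteria(c(450, 399), c(370, 331)) # first passes both
check_criteria <- function(e_pipi, z_pipi = rep(NA_real_, length(e_pipi)),
                           criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"),
            length(e_pipi) == length(z_pipi), all(is.finite(e_pipi)))
  w <- criteria$e_pipi_window
  c1 <- if (criteria$boundary_inclusive) {
    e_pipi >= w[1] & e_pipi <= w[2]
  } else {
    e_pipi > w[1] & e_pipi < w[2]
  }
  sep <- e_pipi - z_pipi
  if (criteria$absolute_separation) sep <- abs(sep)
  c2 <- !is.na(z_pipi) & sep > criteria$min_separation
  data.frame(passes_c1 = c1, passes_c2 = c2, passes_both = c1 & c2,
             separation = sep)
}

#' Screen a SMILES library with a multitask GP
#'
#' Featurises the library, predicts the E and Z pi-pi* wavelengths with the
#' fitted multitask model, applies the screening criteria and ranks the
#' passing candidates: descending predicted E pi-pi* within the window,
#' ties broken by descending predicted band separation. Invalid SMILES are
#' skipped with a logged reason. Deterministic.
#'
#' @param model A fitted [mogp_fit()] with observations for `E_PI_PI` and
#'   `Z_PI_PI`.
#' @param smiles_list Character vector of candidate SMILES.
#' @param criteria A [screening_criteria()].
#' @param config The [fragprint_config()] the model was trained with.
#' @param mode Representation used at training time.
#' @return An object of class `screening_verdicts`: data.frame with columns
#'   `smiles`, `pred_e`, `pred_z`, `var_e`, `var_z`, `separation`,
#'   `passes_c1`, `passes_c2`, `passes_both`, `rank` (1..k for passing
#'   candidates, `NA` otherwise), ordered passing-first; attribute `rejects`
#'   logs skipped input rows.
#' @export
screen_library <- function(model, smiles_list, criteria = screening_criteria(),
                           config = fragprint_config(),
                           mode = "fragprints") {
  stopifnot(inherits(model, "tanimoto_mogp"))
  if (length(smiles_list) == 0L) stop("empty library")
  lib <- featurize_library(smiles_list, mode = mode, config = config)
  pe <- predict(model, lib$features, task = "E_PI_PI")
  pz <- predict(model, lib$features, task = "Z_PI_PI")
  v <- check_criteria(pe$mean, pz$mean, criteria)
  out <- data.frame(smiles = lib$canonical,
                    pred_e = pe$mean, pred_z = pz$mean,
                    var_e = pe$var, var_z = pz$var,
                    separation = v$separation,
                    passes_c1 = v$passes_c1, passes_c2 = v$passes_c2,
                    passes_both = v$passes_both,
                    stringsAsFactors = FALSE)
  ord <- order(!out$passes_both, -out$pred_e, -out$separation)
  out <- out[ord, , drop = FALSE]
  out$rank <- NA_integer_
  if (any(out$passes_both)) out$rank[out$passes_both] <- seq_len(sum(out$passes_both))
  rownames(out) <- NULL
  attr(out, "rejects") <- lib$rejects
  class(out) <- c("screening_verdicts", "data.frame")
  out
}

#' Screening report: predicted versus experimental wavelengths
#'
#' Summarises a prospective screen: model MAEs on the E and Z pi-pi* bands
#' (the Z MAE is computed over exactly the candidates with an experimental Z
#' value) and criteria pass counts evaluated on the *experimental* values.
#'
#' @param predicted Data.frame/list with `e_pipi` and `z_pipi` (nm), the
#'   model predictions per candidate.
#' @param experimental Same shape, the measured values; `z_pipi` may contain
#'   `NA` (e.g. a candidate that did not photoswitch).
#' @param criteria A [screening_criteria()].
#' @return An object of class `screening_report`: list with `mae_e`,
#'   `mae_z`, `n_e`, `n_z`, `counts` (named vector `c1`, `c2`, `both`),
#'   `n_candidates`, `verdicts` (per-candidate experimental verdicts).
#' @export
screening_report <- function(predicted, experimental,
                             criteria = screening_criteria()) {
  pe <- predicted$e_pipi; pz <- predicted$z_pipi
  xe <- experimental$e_pipi; xz <- experimental$z_pipi
  if (length(pe) != length(xe) || length(pz) != length(xz)) {
    stop("predicted and experimental candidate lists differ in length")
  }
  rep_e <- metric_suite(pe, xe)
  rep_z <- metric_suite(pz, xz)
  verdicts <- check_criteria(xe, xz, criteria)
  structure(
    list(mae_e = rep_e$mae, mae_z = rep_z$mae,
         n_e = rep_e$n, n_z = rep_z$n,
         counts = c(c1 = sum(verdicts$passes_c1),
                    c2 = sum(verdicts$passes_c2),
                    both = sum(verdicts$passes_both)),
         n_candidates = length(xe),
         verdicts = verdicts),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report over %d candidates\n", x$n_candidates))
  cat(sprintf("  model MAE, E pi-pi*: %.1f nm (n = %d)\n", x$mae_e, x$n_e))
  cat(sprintf("  model MAE, Z pi-pi*: %.1f nm (n = %d)\n", x$mae_z, x$n_z))
  cat(sprintf("  experimental criteria: %d pass criterion 1, %d pass criterion 2, %d pass both\n",
              x$counts["c1"], x$counts["c2"], x$counts["both"]))
  invisible(x)
}
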