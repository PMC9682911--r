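# Dataset IO for the curated-photoswitch CSV schema: SMILES plus up to four
# experimental transition wavelengths (nm), optional solvent and TD-DFT
# columns. Missing entries are permitted; solvent repeats of the same
# molecule are collapsed by random choice (solvent effects are absorbed into
# the observation noise).

default_column_map <- function() {
  list(smiles = "smiles",
       E_PI_PI = "e_iso_pi", E_N_PI = "e_iso_n",
       Z_PI_PI = "z_iso_pi", Z_N_PI = "z_iso_n",
       solvent = "solvent")
}

# "", NA, "NaN" -> NA; anything else must be numeric.
parse_wavelength <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NAN" | toupper(x) == "NA"] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Load a photoswitch dataset from CSV
#'
#' Reads a comma-separated, UTF-8, headered CSV of molecules into a tidy
#' data.frame: one row per retained molecule, with canonical SMILES and the
#' four wavelength labels (`E_PI_PI`, `E_N_PI`, `Z_PI_PI`, `Z_N_PI`, in nm;
#' `NA` = label absent). Rows whose SMILES cannot be parsed, or that carry a
#' non-positive wavelength (physically impossible), are rejected with a
#' logged reason rather than aborting the load. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param column_map Named list mapping the internal field names (`smiles`,
#'   the four task names, optionally `solvent` and TD-DFT columns) to the
#'   file's column names. Defaults: `smiles`, `e_iso_pi`, `e_iso_n`,
#'   `z_iso_pi`, `z_iso_n`, `solvent`.
#' @return A data.frame with columns `smiles`, the four tasks, `solvent`
#'   (NA if the file has none) and `source_id` (original row number), plus
#'   attribute `rejects` (data.frame of `source_id`, `smiles`, `reason`).
#' @export
load_dataset <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  cm <- utils::modifyList(default_column_map(), as.list(column_map))
  if (!cm$smiles %in% names(raw)) {
    stop(sprintf("schema error: SMILES column '%s' not found", cm$smiles))
  }
  n <- nrow(raw)
  labels <- sapply(.TASKS, function(t) {
    col <- cm[[t]]
    if (!is.null(col) && col %in% names(raw)) parse_wavelength(raw[[col]])
    else rep(NA_real_, n)
  })
  labels <- matrix(labels, nrow = n, dimnames = list(NULL, .TASKS))
  solvent <- if (!is.null(cm$solvent) && cm$solvent %in% names(raw)) {
    s <- trimws(raw[[cm$solvent]]); s[s == ""] <- NA_character_; s
  } else rep(NA_character_, n)

  can <- canonicalize_all(raw[[cm$smiles]])
  reasons <- can$reason
  nonpos <- apply(labels, 1, function(r) any(!is.na(r) & r <= 0))
  reasons[is.na(reasons) & nonpos] <- "non-positive wavelength (physically impossible)"
  keep <- is.na(reasons)

  rejects <- data.frame(source_id = which(!keep),
                        smiles = raw[[cm$smiles]][!keep],
                        reason = reasons[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) stop("empty dataset: no valid rows")

  out <- data.frame(smiles = can$canonical[keep],
                    labels[keep, , drop = FALSE],
                    solvent = solvent[keep],
                    source_id = which(keep),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a photoswitch dataset to CSV
#'
#' Inverse of [load_dataset()] under the default column map: absent labels
#' are written as empty cells, so a load/write round trip preserves records
#' and missingness exactly.
#'
#' @param records Data.frame as returned by [load_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  cm <- default_column_map()
  out <- data.frame(smiles = records$smiles, stringsAsFactors = FALSE)
  for (t in .TASKS) out[[cm[[t]]]] <- records[[t]]
  out$solvent <- records$solvent
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Collapse solvent duplicates
#'
#' The curated data contain measurements of the same molecule in different
#' solvents. The solvent is not part of the molecular representation (its
#' effect is absorbed into the observation noise), so exactly one record per
#' canonical SMILES is retained, chosen uniformly at random among the
#' duplicates. Reproducible for a given seed; idempotent; the identity on
#' duplicate-free input.
#'
#' @param records Data.frame as returned by [load_dataset()].
#' @param seed Integer seed for the uniform choice.
#' @return The deduplicated data.frame, in first-occurrence order.
#' @export
deduplicate_solvent <- function(records, seed = 0L) {
  stopifnot(is.data.frame(records), "smiles" %in% names(records))
  set.seed(as.integer(seed))
  groups <- split(seq_len(nrow(records)), records$smiles)
  chosen <- vapply(groups, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1))
  out <- records[sort(chosen), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged screening-benchmark fixture
#'
#' The 11 commercially available azoswitches from the prospective screening
#' experiment: model-predicted and experimentally determined pi-pi*
#' wavelengths (nm) for the E and Z isomers. Switch 7 did not photoswitch
#' under irradiation, so its experimental Z value is absent.
#'
#' @return A data.frame with columns `switch`, `model_e_pipi`, `model_z_pipi`,
#'   `exp_e_pipi`, `exp_z_pipi` (11 rows; `exp_z_pipi` is `NA` for switch 7).
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_screen.csv", package = "azogp")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
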