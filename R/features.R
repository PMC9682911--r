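# Molecular featurisation: canonical SMILES, circular fingerprints, fragment
# counts, and their concatenation ("fragprints", the count vectors the
# Tanimoto kernel operates on). Chemistry is delegated to OpenBabel via
# ChemmineOB.

FRAG_CATALOGUE_VERSION <- "1.0"

#' Canonicalise a SMILES string
#'
#' Converts any valid SMILES spelling of a molecule to its unique canonical
#' form (OpenBabel canonical SMILES). Idempotent; unparseable input raises an
#' error.
#'
#' @param smiles A single non-empty SMILES string.
#' @return The canonical SMILES string.
#' @export
#' @examples
#' canonicalize("C1=CC=CC=C1") == canonicalize("c1ccccc1")
canonicalize <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("invalid molecule: empty or non-string SMILES")
  }
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(trimws(smiles), "\n")),
    error = function(e) ""
  )
  # OpenBabel appends a title field after a tab and a trailing newline.
  out <- sub("[ \t\r\n].*$", "", out)
  if (!nzchar(out)) stop(sprintf("invalid molecule: cannot parse SMILES '%s'", smiles))
  out
}

# Vectorised canonicalisation that collects failures instead of stopping.
# Returns list(canonical = chr (NA where invalid), reason = chr).
canonicalize_all <- function(smiles) {
  res <- lapply(smiles, function(s) {
    tryCatch(list(ok = canonicalize(s), reason = NA_character_),
             error = function(e) list(ok = NA_character_,
                                      reason = conditionMessage(e)))
  })
  list(
    canonical = vapply(res, `[[`, character(1), "ok"),
    reason = vapply(res, `[[`, character(1), "reason")
  )
}

#' The frozen fragment catalogue
#'
#' An ordered table of named functional-group substructure patterns (SMARTS)
#' whose per-molecule unique match counts form the fragment block of the
#' fragprint representation. The catalogue ships with the package and its
#' ordering is frozen (version `"1.0"`) so that feature vectors are
#' reproducible independently of chemistry-toolkit version drift.
#'
#' @return A data.frame with columns `name` and `smarts`, plus attribute
#'   `version`.
#' @export
fragment_catalogue <- function() {
  path <- system.file("extdata", "fragment_catalogue.csv", package = "azogp")
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(cat, "version") <- FRAG_CATALOGUE_VERSION
  cat
}

#' Fragprint configuration
#'
#' Fixes the featurisation hyperparameters: the circular-fingerprint type and
#' folded bit length, and the fragment catalogue. The circular fingerprint is
#' ECFP with radius 3 (`"ECFP6"` in diameter naming), natively 4096 bits,
#' folded by OR-ing halves down to `n_bits`.
#'
#' @param n_bits Folded fingerprint length; must divide 4096 by a power of
#'   two. Default 2048.
#' @param fp_type OpenBabel fingerprint type; default `"ECFP6"` (radius 3).
#' @param catalogue Fragment catalogue data.frame; default [fragment_catalogue()].
#' @return A list of class `fragprint_config`.
#' @export
fragprint_config <- function(n_bits = 2048L, fp_type = "ECFP6",
                             catalogue = fragment_catalogue()) {
  n_bits <- as.integer(n_bits)
  if (n_bits < 1L || 4096L %% n_bits != 0L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("n_bits must be a power of two dividing 4096")
  }
  stopifnot(is.data.frame(catalogue), all(c("name", "smarts") %in% names(catalogue)))
  structure(
    list(n_bits = n_bits, fp_type = fp_type, catalogue = catalogue,
         catalogue_version = attr(catalogue, "version") %||% "unversioned"),
    class = "fragprint_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse canonical SMILES into OpenBabel molecule references.
ob_parse <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

# Fold a binary fingerprint matrix down to n_bits by OR-ing halves.
fold_bits <- function(m, n_bits) {
  while (ncol(m) > n_bits) {
    half <- ncol(m) / 2
    m <- pmax(m[, seq_len(half), drop = FALSE],
              m[, half + seq_len(half), drop = FALSE])
  }
  m
}

# Core batch featuriser over already-canonical SMILES. Returns a matrix.
featurize_canonical <- function(canonical, mode, config) {
  mols <- ob_parse(canonical)
  n <- length(canonical)
  blocks <- list()
  if (mode %in% c("fingerprint", "fragprints")) {
    fp <- as.matrix(ChemmineOB::fingerprint_OB(mols, config$fp_type))
    # a single molecule comes back column-oriented
    if (n == 1L && nrow(fp) > 1L) fp <- t(fp)
    fp <- fold_bits(fp, config$n_bits)
    colnames(fp) <- paste0("fp_", seq_len(ncol(fp)))
    blocks$fp <- fp
  }
  if (mode %in% c("fragments", "fragprints")) {
    counts <- vapply(
      config$catalogue$smarts,
      function(p) as.numeric(ChemmineOB::smartsSearch_OB(mols, p, uniqueMatches = TRUE)),
      numeric(n)
    )
    counts <- matrix(counts, nrow = n,
                     dimnames = list(NULL, paste0("frag_", config$catalogue$name)))
    blocks$frag <- counts
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Featurise a molecule
#'
#' Converts a SMILES string into one of the three molecular representations:
#' `"fingerprint"` (binary circular-fingerprint bits, length F),
#' `"fragments"` (non-negative functional-group match counts, length G), or
#' `"fragprints"` (their concatenation, length F + G). The input is
#' canonicalised first, so any SMILES spelling of the same molecule yields an
#' identical vector.
#'
#' @param smiles A single SMILES string.
#' @param mode Representation; one of `"fragprints"`, `"fingerprint"`,
#'   `"fragments"`.
#' @param config A [fragprint_config()].
#' @return A named numeric vector.
#' @export
featurize <- function(smiles, mode = c("fragprints", "fingerprint", "fragments"),
                      config = fragprint_config()) {
  mode <- match.arg(mode)
  can <- canonicalize(smiles)
  drop(featurize_canonical(can, mode, config))
}

#' Featurise a SMILES library
#'
#' Batch version of [featurize()] with partial-failure semantics: invalid
#' SMILES are rejected with a reason and do not abort the run. Duplicate
#' SMILES are kept (no silent deduplication). Rows whose feature vector is
#' all-zero are flagged with a warning (a silent featurisation failure would
#' otherwise poison the Tanimoto kernel).
#'
#' @param smiles_list Character vector of SMILES.
#' @param mode Representation, as in [featurize()].
#' @param config A [fragprint_config()].
#' @return A list with `features` (matrix, one row per kept molecule),
#'   `kept_indices` (positions in the input), `canonical` (canonical SMILES of
#'   kept rows) and `rejects` (data.frame of `index`, `smiles`, `reason`).
#' @export
featurize_library <- function(smiles_list,
                              mode = c("fragprints", "fingerprint", "fragments"),
                              config = fragprint_config()) {
  mode <- match.arg(mode)
  if (length(smiles_list) == 0L) stop("empty library")
  can <- canonicalize_all(smiles_list)
  keep <- !is.na(can$canonical)
  rejects <- data.frame(index = which(!keep),
                        smiles = smiles_list[!keep],
                        reason = can$reason[!keep],
                        stringsAsFactors = FALSE)
  if (!any(keep)) stop("empty library: no valid SMILES")
  feats <- featurize_canonical(can$canonical[keep], mode, config)
  zero_rows <- rowSums(feats != 0) == 0
  if (any(zero_rows)) {
    warning(sprintf("%d molecule(s) produced an all-zero feature vector: %s",
                    sum(zero_rows),
                    paste(utils::head(can$canonical[keep][zero_rows], 5), collapse = ", ")))
  }
  list(features = feats,
       kept_indices = which(keep),
       canonical = can$canonical[keep],
       rejects = rejects)
}
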