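# Feed/diet/excreta chemical composition tables.
#
# Percentages are stored on the 0-100 scale (as in proximate-analysis
# tables), never as fractions. Every table carries a 'basis' attribute:
# "dm" (per kg dry matter) or "as_fed". Hemicellulose is never stored;
# derive it as NDF - ADF where needed.

# canonical analyte name -> accepted header synonyms (matched case-insensitively
# after squashing non-alphanumerics)
.analyte_synonyms <- list(
  sample_id = c("sample_id", "sample", "id", "ingredient", "ingredient_id"),
  dm     = c("dm", "dry_matter", "dm_pct"),
  ge     = c("ge", "gross_energy", "ge_mj_kg", "ge_mj_kg_dm"),
  cp     = c("cp", "crude_protein"),
  ndf    = c("ndf", "andf", "a_ndf"),
  adf    = c("adf"),
  ash    = c("ash"),
  ee     = c("ee", "ether_extract", "fat", "crude_fat"),
  starch = c("starch"),
  idf    = c("idf", "insoluble_dietary_fiber", "insoluble_dietary_fibre"),
  sdf    = c("sdf", "soluble_dietary_fiber", "soluble_dietary_fibre"),
  tdf    = c("tdf", "total_dietary_fiber", "total_dietary_fibre"),
  ca     = c("ca", "calcium"),
  p      = c("p", "phosphorus")
)

.squash <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

.canonical_analyte <- function(header) {
  h <- .squash(header)
  for (canon in names(.analyte_synonyms)) {
    if (h %in% .analyte_synonyms[[canon]]) return(canon)
  }
  NA_character_
}

# percentage-scale analytes subject to the [0, 100] range check
.pct_analytes <- c("cp", "ndf", "adf", "ash", "ee", "starch",
                   "idf", "sdf", "tdf", "ca", "p")

#' Read a chemical composition table
#'
#' Reads a CSV of feed, diet, or excreta composition (one sample per row)
#' into a `feed_composition` data frame. Header names are matched
#' case-insensitively against a synonym table (e.g. `aNDF` maps to `ndf`);
#' unknown columns are carried through unchanged, never dropped.
#'
#' Invariant violations -- percentages outside \[0, 100\], `tdf` differing
#' from `idf + sdf` by more than 0.5 percentage points (the analytical
#' tolerance of the fibre assay), or `ndf < adf` -- are reported as
#' warnings naming the offending row, not repaired.
#'
#' @param path path to a CSV file with a header row.
#' @param basis basis on which the analytes are expressed: `"dm"` or
#'   `"as_fed"`.
#' @return A data frame of class `feed_composition` with canonical analyte
#'   columns (`sample_id`, `dm`, `cp`, ...) first and any extra columns
#'   after, and attribute `basis`.
#' @seealso [convert_basis()]
#' @examples
#' path <- system.file("extdata", "barley10.csv", package = "sowcal")
#' comp <- read_composition_table(path, basis = "dm")
#' comp[comp$sample_id == "Barley-2", c("cp", "adf", "tdf")]
#' @export
read_composition_table <- function(path, basis = c("dm", "as_fed")) {
  basis <- match.arg(basis)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  canon <- vapply(names(raw), .canonical_analyte, character(1))
  dup <- canon[!is.na(canon)][duplicated(canon[!is.na(canon)])]
  if (length(dup)) stop("duplicate analyte columns after synonym mapping: ",
                        paste(unique(dup), collapse = ", "))
  names(raw)[!is.na(canon)] <- canon[!is.na(canon)]
  if (!"sample_id" %in% names(raw)) stop("missing mandatory column: sample_id")
  if (!"dm" %in% names(raw)) stop("missing mandatory column: dm (dry matter)")

  raw$sample_id <- as.character(raw$sample_id)
  num_cols <- setdiff(names(raw), "sample_id")
  for (cl in num_cols) {
    v <- raw[[cl]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                     v[bad[1]], cl, bad[1]))
      }
      raw[[cl]] <- conv
    }
  }

  known <- intersect(names(.analyte_synonyms), names(raw))
  out <- raw[, c(known, setdiff(names(raw), known)), drop = FALSE]
  attr(out, "basis") <- basis
  class(out) <- c("feed_composition", "data.frame")
  for (msg in validate_composition(out)) warning(msg, call. = FALSE)
  out
}

#' Validate composition invariants
#'
#' Returns (rather than signals) the list of invariant violations in a
#' composition table, one message per offence, naming the sample.
#' Checked: `dm > 0`; percentage analytes within \[0, 100\];
#' `|tdf - (idf + sdf)| <= 0.5` when all three fibre fractions are
#' present; `ndf >= adf`.
#'
#' @param x a `feed_composition` data frame (or compatible).
#' @return Character vector of messages; empty when all invariants hold.
#' @export
validate_composition <- function(x) {
  msgs <- character(0)
  id <- if ("sample_id" %in% names(x)) x$sample_id else as.character(seq_len(nrow(x)))
  if ("dm" %in% names(x)) {
    bad <- which(!is.na(x$dm) & x$dm <= 0)
    for (i in bad) msgs <- c(msgs, sprintf("sample '%s': dm must be > 0", id[i]))
  }
  for (an in intersect(c("dm", .pct_analytes), names(x))) {
    v <- x[[an]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    for (i in bad) {
      msgs <- c(msgs, sprintf("sample '%s': %s = %g outside [0, 100]",
                              id[i], an, v[i]))
    }
  }
  if (all(c("idf", "sdf", "tdf") %in% names(x))) {
    gap <- abs(x$tdf - (x$idf + x$sdf))
    bad <- which(!is.na(gap) & gap > 0.5)
    for (i in bad) {
      msgs <- c(msgs, sprintf(
        "sample '%s': TDF != IDF+SDF (|%g - %g| = %.2f > 0.5 pct points)",
        id[i], x$tdf[i], x$idf[i] + x$sdf[i], gap[i]))
    }
  }
  if (all(c("ndf", "adf") %in% names(x))) {
    bad <- which(!is.na(x$ndf) & !is.na(x$adf) & x$ndf < x$adf)
    for (i in bad) {
      msgs <- c(msgs, sprintf("sample '%s': ndf (%g) < adf (%g)",
                              id[i], x$ndf[i], x$adf[i]))
    }
  }
  msgs
}

#' Convert a composition table between dry-matter and as-fed bases
#'
#' Rescales every numeric analyte except `dm` itself by `100 / dm`
#' (as-fed to DM) or `dm / 100` (DM to as-fed), row by row. Gross energy
#' is rescaled identically. Converting to the table's current basis is the
#' identity; a round trip reproduces the input to within 1e-12.
#'
#' @param x a `feed_composition` data frame with a `basis` attribute.
#' @param target `"dm"` or `"as_fed"`.
#' @return The converted table with its `basis` attribute updated.
#' @examples
#' path <- system.file("extdata", "barley10.csv", package = "sowcal")
#' comp <- read_composition_table(path, basis = "dm")
#' af <- convert_basis(comp, "as_fed")
#' af$cp[1] # 10.87 * 0.8930
#' @export
convert_basis <- function(x, target = c("dm", "as_fed")) {
  target <- match.arg(target)
  basis <- attr(x, "basis")
  if (is.null(basis)) stop("'x' has no basis attribute; read it with read_composition_table()")
  if (!"dm" %in% names(x)) stop("'x' has no dm column")
  if (any(!is.na(x$dm) & x$dm == 0)) stop("dm of 0 cannot be rebased")
  if (basis == target) return(x)
  f <- if (target == "dm") 100 / x$dm else x$dm / 100
  for (cl in setdiff(names(x), c("sample_id", "dm"))) {
    if (is.numeric(x[[cl]])) x[[cl]] <- x[[cl]] * f
  }
  attr(x, "basis") <- target
  x
}

#' @export
print.feed_composition <- function(x, ...) {
  cat(sprintf("Feed composition: %d sample(s), basis = %s\n",
              nrow(x), attr(x, "basis")))
  print(as.data.frame(x), ...)
  invisible(x)
}
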