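# Pearson correlation screening of chemical composition against energy
# values, with two-sided significance from the t transform.

#' Pearson correlation matrix with significance
#'
#' Pairwise Pearson correlations among the selected numeric variables,
#' with two-sided p-values from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. When both `ndf` and `adf` are present,
#' hemicellulose (`ndf - adf`) can be derived on the fly; it is never
#' stored in composition tables.
#'
#' A zero-variance column yields `NA` correlations and a warning.
#'
#' @param data data frame (e.g. a `feed_composition` table, possibly
#'   merged with energy values).
#' @param variables variables to correlate; default all numeric columns.
#' @param derive_hemicellulose add a `hemicellulose = ndf - adf` column
#'   when possible.
#' @return Object of class `correlation_matrix`: list with `variables`,
#'   `r`, `p` (symmetric matrices), and `n`.
#' @examples
#' path <- system.file("extdata", "barley10.csv", package = "sowcal")
#' comp <- read_composition_table(path, basis = "dm")
#' cm <- pearson_matrix(comp, variables = c("adf", "idf", "tdf"))
#' round(cm$r["idf", "tdf"], 2)
#' @export
pearson_matrix <- function(data, variables = NULL, derive_hemicellulose = TRUE) {
  df <- as.data.frame(data)
  if (derive_hemicellulose && all(c("ndf", "adf") %in% names(df)) &&
      !"hemicellulose" %in% names(df)) {
    df$hemicellulose <- df$ndf - df$adf
  }
  if (is.null(variables)) {
    variables <- names(df)[vapply(df, is.numeric, logical(1))]
  } else {
    miss <- setdiff(variables, names(df))
    if (length(miss)) stop("variables not found: ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(df[, variables, drop = FALSE])
  if (anyNA(m)) stop("missing values in the correlated columns")
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples for correlation p-values")

  zero_var <- apply(m, 2, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance column(s): ",
            paste(variables[zero_var], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(m))
  r[zero_var, ] <- NA_real_
  r[, zero_var] <- NA_real_
  diag(r)[!zero_var] <- 1

  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0

  structure(list(variables = variables, r = r, p = p, n = n),
            class = "correlation_matrix")
}

#' Significance stars for a correlation matrix
#'
#' @param x a `correlation_matrix`.
#' @return Character matrix: `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise.
#' @export
correlation_stars <- function(x) {
  stopifnot(inherits(x, "correlation_matrix"))
  s <- ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))
  s[is.na(x$p)] <- ""
  diag(s) <- ""
  s
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlations (n = %d); * p < 0.05, ** p < 0.01\n", x$n))
  txt <- matrix(paste0(formatC(x$r, format = "f", digits = digits),
                       correlation_stars(x)),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  txt[upper.tri(txt)] <- ""
  print(txt, quote = FALSE, ...)
  invisible(x)
}

#' Write a correlation matrix as CSV
#'
#' Writes the coefficient matrix as a square CSV and, alongside it, a
#' star-annotated text report (`<path>` and `<path base>_stars.csv`).
#'
#' @param x a `correlation_matrix`.
#' @param path output CSV path for the coefficients.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(x, path) {
  stopifnot(inherits(x, "correlation_matrix"))
  utils::write.csv(as.data.frame(x$r), path, row.names = TRUE)
  star_path <- sub("(\\.[^.]*)?$", "_stars\\1", path)
  ann <- matrix(paste0(formatC(x$r, format = "f", digits = 2),
                       correlation_stars(x)),
                nrow = nrow(x$r), dimnames = dimnames(x$r))
  utils::write.csv(as.data.frame(ann), star_path, row.names = TRUE)
  invisible(path)
}
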