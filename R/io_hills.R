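# Readers and writers for the PLUMED-style HILLS / COLVAR whitespace dialects.
#
# A HILLS file is whitespace-delimited with an optional "#! FIELDS ..." comment
# header naming the columns. Each non-comment line records one deposited
# Gaussian: time (ps), the two hill centers in normalized CV coordinates, the
# two widths sigma, the height (kJ/mol), and optionally the bias factor.

parse_fields_header <- function(lines) {
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(hdr) == 0) return(NULL)
  strsplit(sub("^#!\\s*FIELDS\\s+", "", hdr[[1]]), "\\s+")[[1]]
}

read_whitespace_table <- function(path, what = "file") {
  if (!file.exists(path)) abort(sprintf("%s not found: %s", what, path))
  lines <- readLines(path, warn = FALSE)
  fields <- parse_fields_header(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- seq_along(lines)[keep]
  if (length(data_lines) == 0) {
    return(list(fields = fields, values = matrix(numeric(0), nrow = 0, ncol = 0)))
  }
  parsed <- strsplit(trimws(data_lines), "\\s+")
  ncols <- lengths(parsed)
  if (length(unique(ncols)) != 1) {
    bad <- line_no[which(ncols != ncols[1])[1]]
    abort(sprintf("malformed line %d in %s: expected %d columns, got %d",
                  bad, path, ncols[1], ncols[ncols != ncols[1]][1]))
  }
  values <- suppressWarnings(
    matrix(as.numeric(unlist(parsed)), nrow = length(parsed), byrow = TRUE)
  )
  if (anyNA(values)) {
    bad <- line_no[which(rowSums(is.na(values)) > 0)[1]]
    abort(sprintf("malformed line %d in %s: non-numeric field", bad, path))
  }
  list(fields = fields, values = values)
}

#' Read a metadynamics HILLS file
#'
#' Parses a PLUMED-dialect HILLS text file into one row per deposited Gaussian
#' hill. Columns are mapped from the `#! FIELDS` comment header when present;
#' headerless files are read in the fixed order
#' `time, center1, center2, sigma1, sigma2, height[, biasf]`.
#'
#' @param path Path to the HILLS file.
#' @param default_bias_factor Bias factor assumed when the file has no `biasf`
#'   column. Default 30.
#' @param validate Check hill invariants (positive widths, non-negative
#'   heights, centers inside the normalized range \[-0.5, 0.5\]). Default TRUE.
#'
#' @return A tibble with columns `time` (ps), `center1`, `center2` (normalized
#'   CV coordinates), `sigma1`, `sigma2`, `height` (kJ/mol), `bias_factor`.
#' @export
read_hills <- function(path, default_bias_factor = 30, validate = TRUE) {
  tab <- read_whitespace_table(path, "HILLS file")
  if (nrow(tab$values) == 0) {
    return(tibble(time = numeric(0), center1 = numeric(0), center2 = numeric(0),
                  sigma1 = numeric(0), sigma2 = numeric(0), height = numeric(0),
                  bias_factor = numeric(0)))
  }
  v <- tab$values
  if (!is.null(tab$fields)) {
    f <- tab$fields
    if (length(f) != ncol(v)) {
      abort(sprintf("HILLS header names %d fields but rows have %d columns",
                    length(f), ncol(v)))
    }
    ht_col <- which(f == "height")
    bf_col <- which(f == "biasf")
    sig_cols <- grep("^sigma_", f)
    time_col <- which(f == "time")
    if (length(ht_col) != 1) abort("HILLS format error: no `height` column")
    if (length(sig_cols) < 2) abort("HILLS format error: need two `sigma_*` columns")
    cv_names <- sub("^sigma_", "", f[sig_cols[1:2]])
    cv_cols <- match(cv_names, f)
    if (anyNA(cv_cols)) abort("HILLS format error: sigma columns without matching CV columns")
    hills <- tibble(
      time = if (length(time_col) == 1) v[, time_col] else seq_len(nrow(v)),
      center1 = v[, cv_cols[1]], center2 = v[, cv_cols[2]],
      sigma1 = v[, sig_cols[1]], sigma2 = v[, sig_cols[2]],
      height = v[, ht_col],
      bias_factor = if (length(bf_col) == 1) v[, bf_col] else default_bias_factor
    )
  } else {
    if (ncol(v) < 6) {
      abort(sprintf(
        "HILLS format error: headerless file needs >= 6 columns (time, 2 centers, 2 sigmas, height), got %d",
        ncol(v)))
    }
    hills <- tibble(
      time = v[, 1], center1 = v[, 2], center2 = v[, 3],
      sigma1 = v[, 4], sigma2 = v[, 5], height = v[, 6],
      bias_factor = if (ncol(v) >= 7) v[, 7] else default_bias_factor
    )
  }
  if (validate) validate_hills(hills)
  hills
}

validate_hills <- function(hills) {
  if (any(hills$sigma1 <= 0) || any(hills$sigma2 <= 0)) {
    abort("invalid hills: sigma must be > 0")
  }
  if (any(hills$height < 0)) abort("invalid hills: height must be >= 0")
  rng <- range(hills$center1, hills$center2)
  if (rng[1] < -0.5 - 1e-9 || rng[2] > 0.5 + 1e-9) {
    abort("invalid hills: normalized centers must lie in [-0.5, 0.5]")
  }
  invisible(hills)
}

#' Write hills in the PLUMED HILLS dialect
#'
#' @param hills Tibble as returned by [read_hills()] or [gen_hills_from_fes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(hills, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#! FIELDS time cv1 cv2 sigma_cv1 sigma_cv2 height biasf", con)
  if (nrow(hills) > 0) {
    writeLines(sprintf("%.10g %.12g %.12g %.12g %.12g %.12g %.10g",
                       hills$time, hills$center1, hills$center2,
                       hills$sigma1, hills$sigma2, hills$height,
                       hills$bias_factor), con)
  }
  invisible(path)
}

#' Read a COLVAR time series
#'
#' Reads a PLUMED-dialect COLVAR file (whitespace columns, `#! FIELDS` header)
#' into a tibble, one row per record.
#'
#' @param path Path to the COLVAR file.
#' @return A tibble whose columns follow the FIELDS header (or `time`, `V1`,
#'   ... for headerless files).
#' @export
read_colvar <- function(path) {
  tab <- read_whitespace_table(path, "COLVAR file")
  v <- tab$values
  if (nrow(v) == 0) return(tibble(time = numeric(0)))
  nm <- tab$fields
  if (is.null(nm) || length(nm) != ncol(v)) {
    nm <- c("time", paste0("V", seq_len(max(0, ncol(v) - 1))))[seq_len(ncol(v))]
  }
  as_tibble(setNames(as.data.frame(v), nm))
}
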