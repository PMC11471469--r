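.dataset_registry <- list(
  precipitation_hinkley = list(
    file = "precipitation_hinkley.csv",
    citation = paste("Thirty successive March daily precipitation totals",
                     "(inches), Minneapolis/St Paul; Hinkley (1977)."),
    n = 30L),
  leukaemia_saudi = list(
    file = "leukaemia_saudi.csv",
    citation = paste("Survival times (years) of 40 leukaemia patients,",
                     "Saudi Arabian Ministry of Health hospitals;",
                     "Abouammoh et al. (2000)."),
    n = 40L)
)

#' Embedded lifetime datasets
#'
#' Two positive-valued samples commonly used to benchmark one-parameter
#' lifetime models: `"precipitation_hinkley"` (30 daily March
#' precipitation totals, in inches) and `"leukaemia_saudi"` (survival
#' times of 40 leukaemia patients, in years). Values are stored verbatim
#' in their published order; the leukaemia series contains one adjacent
#' non-ascending pair which is deliberately not re-sorted.
#'
#' @param name dataset name, `"precipitation_hinkley"` or
#'   `"leukaemia_saudi"`.
#' @return a tibble with a single `value` column and attributes
#'   `dataset_name` and `citation`.
#' @examples
#' precip <- load_dataset("precipitation_hinkley")
#' nrow(precip)
#' @export
load_dataset <- function(name) {
  if (length(name) != 1L || !name %in% names(.dataset_registry)) {
    stop("unknown dataset; available: ",
         paste(names(.dataset_registry), collapse = ", "), call. = FALSE)
  }
  info <- .dataset_registry[[name]]
  path <- system.file("extdata", info$file, package = "duslindley",
                      mustWork = TRUE)
  out <- tibble::tibble(value = utils::read.csv(path)$value)
  stopifnot(nrow(out) == info$n)
  attr(out, "dataset_name") <- name
  attr(out, "citation") <- info$citation
  out
}

#' @rdname load_dataset
#' @export
dus_datasets <- function() names(.dataset_registry)

#' Read a positive sample from delimited text
#'
#' Reads a one-value-per-line or delimiter-separated text file into a
#' validated sample. Values must be strictly positive and finite;
#' offending entries are reported with their line numbers. Order is
#' preserved. A message logs the sample size and range.
#'
#' @param path path to the text file.
#' @param column optional column name (files with a header row) or index;
#'   by default the first column is used and a bare numeric file (no
#'   header) is accepted.
#' @return a tibble with a single `value` column.
#' @seealso [write_sample()] for the full-precision inverse.
#' @export
read_sample <- function(path, column = NULL) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,;\t ]+")[[1]][1])))
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE,
                          blank.lines.skip = FALSE)
  if (grepl(",", first, fixed = TRUE)) {
    df <- utils::read.csv(path, header = has_header,
                          blank.lines.skip = FALSE)
  }
  col <- if (is.null(column)) 1L else column
  if (is.character(col) && !col %in% names(df)) {
    stop("column `", col, "` not found in ", path, call. = FALSE)
  }
  raw <- df[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  line_offset <- if (has_header) 1L else 0L
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad) > 0L) {
    stop("invalid (non-numeric, non-finite or non-positive) values at ",
         "line(s) ", paste(bad + line_offset, collapse = ", "), " of ",
         path, call. = FALSE)
  }
  message(sprintf("read_sample: n = %d, min = %g, max = %g",
                  length(vals), min(vals), max(vals)))
  tibble::tibble(value = vals)
}

#' Write a positive sample as one value per line
#'
#' Full-precision (17 significant digits) text output so that
#' `read_sample(write_sample(x, path))` reproduces `x` exactly.
#'
#' @param x numeric vector or data frame with a `value` column.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_sample <- function(x, path) {
  vals <- as_sample(x, min_n = 1L)
  writeLines(format(vals, digits = 17, scientific = FALSE, trim = TRUE),
             path)
  invisible(x)
}
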