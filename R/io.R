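#' Read a sample of positive observations from a text file
#'
#' Accepts one value per line or a single-column delimited file (an
#' optional one-line header is detected and skipped).  Comma-decimal input
#' (e.g. `0,105`) is supported via `decimal_comma = TRUE`.  Any
#' non-numeric or non-positive entry aborts with the offending line
#' number — silent dropping of bad records would bias every downstream
#' estimate.
#'
#' @param path file to read.
#' @param decimal_comma logical; interpret `,` as the decimal separator.
#' @return numeric vector of strictly positive values.
#' @examples
#' f <- tempfile()
#' writeLines(c("1.0", "2.5", "0.3"), f)
#' read_sample(f)
#' @export
read_sample <- function(path, decimal_comma = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- !(lines == "" | startsWith(lines, "#"))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  if (decimal_comma) lines <- gsub(",", ".", lines, fixed = TRUE)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1L]) && length(lines) > 1L) {   # header line
    lines <- lines[-1L]; line_no <- line_no[-1L]
    vals <- suppressWarnings(as.numeric(lines))
  }
  if (anyNA(vals))
    stop("non-numeric entry at line ", line_no[which(is.na(vals))[1L]],
         " of ", path, call. = FALSE)
  if (any(vals <= 0))
    stop("non-positive value at line ", line_no[which(vals <= 0)[1L]],
         " of ", path, call. = FALSE)
  vals
}
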