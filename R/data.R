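#' Bundled COVID-19 case fatality rate samples
#'
#' Cumulative COVID-19 case fatality rates (confirmed deaths / confirmed
#' cases, in percent, one value per country) aggregated by WHO region —
#' African (AFR, n = 42), Eastern Mediterranean (EMR, n = 21), European
#' (EUR, n = 50), Americas (AMR, n = 35), South-East Asian (SEAR, n = 8),
#' Western Pacific (WPR, n = 18) — plus the OECD members (n = 36).  Values
#' are bundled verbatim as printed in the source publication's data table
#' (the OECD column's decimal commas are normalised to dots at packaging
#' time) and are used exactly as printed, in percent.
#'
#' @param code region code, one of `iep_regions()`.
#' @return `iep_region`: a data frame with the single column `cfr`, plus
#'   attributes `region` and `n`.  `iep_regions`: the vector of available
#'   codes.
#' @examples
#' iep_regions()
#' nrow(iep_region("AFR"))   # 42
#' @export
iep_region <- function(code) {
  code <- toupper(code)
  if (!code %in% iep_regions())
    stop("unknown region '", code, "'; available: ",
         paste(iep_regions(), collapse = ", "), call. = FALSE)
  cached <- .region_cache[[code]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", paste0("cfr_", tolower(code), ".csv"),
                      package = "iepfit", mustWork = TRUE)
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  .check_positive(d$cfr, paste0(code, " cfr"))
  attr(d, "region") <- code
  attr(d, "n") <- nrow(d)
  .region_cache[[code]] <- d
  d
}

#' @rdname iep_region
#' @export
iep_regions <- function() c("AFR", "EMR", "EUR", "AMR", "SEAR", "WPR", "OECD")

.region_cache <- new.env(parent = emptyenv())
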