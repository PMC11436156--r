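# Packaged 2021 Canadian census populations per jurisdiction, with pooling.
#
# The registry ships as a plain CSV under extdata (columns jurisdiction,
# abbrev, stratum, population, basis) and is loaded once per session. The
# territorial 18-39 counts are not published at that stratification; they
# are a synthetic proportional split of the national 18-39 residual
# (flagged basis = "synthetic") constrained to sum to it exactly, so that
# nation-wide pooled throughput can be assembled from all 13 jurisdictions.

the_registry <- new.env(parent = emptyenv())

#' The packaged census population registry
#'
#' 2021 Canadian census population counts for the 10 provinces, 3
#' territories and Canada, in strata `"total"` and `"18-39"`.
#'
#' @return A data frame with columns `jurisdiction`, `abbrev`, `stratum`,
#'   `population` (integer persons) and `basis` (`"census"` for published
#'   census counts, `"synthetic"` for the constructed territorial 18-39
#'   split).
#' @examples
#' head(census_registry())
#' @export
census_registry <- function() {
  if (is.null(the_registry$data)) {
    path <- system.file("extdata", "census_2021.csv", package = "sccspool",
                        mustWork = TRUE)
    reg <- utils::read.csv(path, stringsAsFactors = FALSE)
    reg$population <- as.integer(reg$population)
    the_registry$data <- reg
  }
  the_registry$data
}

#' Names of the packaged jurisdictions
#'
#' @param stratum Restrict to jurisdictions with a count in this stratum.
#' @param include_national Include the `"Canada"` aggregate row.
#' @return Character vector of jurisdiction names.
#' @export
jurisdiction_names <- function(stratum = "total", include_national = FALSE) {
  reg <- census_registry()
  nm <- unique(reg$jurisdiction[reg$stratum == stratum])
  if (!include_national) nm <- setdiff(nm, "Canada")
  nm
}

#' Look up one jurisdiction's census record
#'
#' @param name One of the 10 provinces, 3 territories, or `"Canada"` (the
#'   published national totals).
#' @return An object of class `"jurisdiction_record"`: a list with `name`,
#'   `abbrev`, and `strata` (named numeric vector of person counts).
#' @examples
#' get_jurisdiction("Ontario")$strata[["total"]]  # 14,223,942
#' @export
get_jurisdiction <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  reg <- census_registry()
  rows <- reg[reg$jurisdiction == name, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("unknown jurisdiction '", name, "'; valid names: ",
         paste(unique(reg$jurisdiction), collapse = ", "), call. = FALSE)
  }
  strata <- stats::setNames(as.numeric(rows$population), rows$stratum)
  structure(list(name = name, abbrev = rows$abbrev[1], strata = strata),
            class = "jurisdiction_record")
}

#' @export
print.jurisdiction_record <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$name, x$abbrev))
  for (s in names(x$strata))
    cat(sprintf("  %-6s : %s\n", s, format(x$strata[[s]], big.mark = ",")))
  invisible(x)
}

stratum_count <- function(name, stratum) {
  rec <- get_jurisdiction(name)
  if (!stratum %in% names(rec$strata))
    stop("jurisdiction '", name, "' has no '", stratum, "' stratum",
         call. = FALSE)
  rec$strata[[stratum]]
}

#' Pool jurisdictions' populations within a stratum
#'
#' @param names Non-empty character vector of jurisdiction names, without
#'   duplicates.
#' @param stratum Stratum label available for every member.
#' @return An object of class `"pooled_population"`: a list with `members`,
#'   `stratum` and `population` (the exact sum of member counts).
#' @examples
#' pool(c("Ontario", "Quebec"))$population  # 22,725,775
#' @export
pool <- function(names, stratum = "total") {
  stopifnot(is.character(names), length(names) >= 1)
  if (anyDuplicated(names))
    stop("duplicate jurisdiction in pool: ",
         paste(unique(names[duplicated(names)]), collapse = ", "),
         call. = FALSE)
  counts <- vapply(names, stratum_count, numeric(1), stratum = stratum)
  structure(list(members = names, stratum = stratum,
                 population = sum(counts)),
            class = "pooled_population")
}

#' @export
print.pooled_population <- function(x, ...) {
  cat(sprintf("Pooled population [%s]: %s\n  %s\n", x$stratum,
              format(x$population, big.mark = ","),
              paste(x$members, collapse = " + ")))
  invisible(x)
}
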