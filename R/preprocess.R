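#' AnalysisMatrix: zero-filled, optionally log-transformed values
#'
#' The working matrix for statistics: samples x compounds, with censored
#' cells replaced by 0 and an optional natural-log transform
#' \code{ln(x + offset)} applied. The transform tag and offset are carried
#' so the transform can be inverted exactly.
#'
#' @slot values numeric matrix, samples x compounds, no missing cells.
#' @slot transform "raw" or "log".
#' @slot offset log offset (ng/g); 0 when raw.
#' @seealso [replaceCensored()], [logTransform()], [prevalenceFilter()]
#' @export
setClass("AnalysisMatrix",
  representation(values = "matrix", transform = "character",
                 offset = "numeric"))

setValidity("AnalysisMatrix", function(object) {
  if (anyNA(object@values)) return("values must have no missing cells")
  if (!object@transform %in% c("raw", "log"))
    return("transform must be 'raw' or 'log'")
  if (object@transform == "raw" && any(object@values < 0))
    return("raw values must be >= 0")
  TRUE
})

setMethod("show", "AnalysisMatrix", function(object) {
  cat("AnalysisMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "compounds [", object@transform, "]\n")
})

#' @describeIn AnalysisMatrix-class the numeric matrix (samples x
#'   compounds)
#' @param x an \code{AnalysisMatrix}
#' @export
values <- function(x) x@values

#' Replace censored cells with zero
#'
#' The censored-value convention used before all downstream statistics:
#' every below-LOQ cell becomes 0; uncensored values are unchanged.
#'
#' @param x a [MossExperiment-class].
#' @return an [AnalysisMatrix-class] (samples x compounds, transform
#'   "raw").
#' @export
replaceCensored <- function(x) {
  stopifnot(is(x, "MossExperiment"))
  v <- concMatrix(x)
  v[censoredMatrix(x)] <- 0
  new("AnalysisMatrix", values = v, transform = "raw", offset = 0)
}

#' Prevalence filter
#'
#' Retains compounds detected (non-zero) in at least \code{min_nonzero}
#' samples. The default threshold scales the published 20-of-42 rule to
#' the actual sample count: \code{ceiling(fraction * n)} with
#' \code{fraction = 20/42}. An explicit \code{min_nonzero} wins over the
#' fraction.
#'
#' @param x an [AnalysisMatrix-class] (raw scale).
#' @param min_nonzero absolute detection threshold; overrides
#'   \code{fraction}.
#' @param fraction detection fraction used when \code{min_nonzero} is
#'   NULL.
#' @return character vector of retained compound names (possibly empty,
#'   with a warning).
#' @export
prevalenceFilter <- function(x, min_nonzero = NULL, fraction = 20 / 42) {
  stopifnot(is(x, "AnalysisMatrix"))
  n <- nrow(x@values)
  if (is.null(min_nonzero)) min_nonzero <- ceiling(fraction * n)
  nz <- colSums(x@values != 0)
  keep <- names(nz)[nz >= min_nonzero]
  if (!length(keep))
    warning("prevalence filter retained no compounds (threshold ",
            min_nonzero, " of ", n, ")")
  keep
}

#' Natural-log transform
#'
#' \code{ln(value + offset)}. The published workflow log-transforms the
#' zero-filled matrix to approximate normality before ANOVA; with the
#' default offset of 1 ng/g zeros map to zero and ordering is preserved.
#'
#' @param x an [AnalysisMatrix-class] with transform "raw".
#' @param offset added before the log; must be > 0 when zeros are
#'   present.
#' @return an [AnalysisMatrix-class] with transform "log".
#' @export
logTransform <- function(x, offset = 1) {
  stopifnot(is(x, "AnalysisMatrix"))
  if (x@transform != "raw") stop("matrix is already log-transformed")
  if (offset == 0 && any(x@values == 0))
    stop("offset must be > 0 when zeros are present")
  if (offset < 0) stop("offset must be >= 0")
  new("AnalysisMatrix", values = log(x@values + offset),
      transform = "log", offset = offset)
}

#' Invert the log transform
#' @param x an [AnalysisMatrix-class] with transform "log".
#' @return an [AnalysisMatrix-class] on the raw scale.
#' @export
invTransform <- function(x) {
  stopifnot(is(x, "AnalysisMatrix"))
  if (x@transform != "log") stop("matrix is not log-transformed")
  v <- exp(x@values) - x@offset
  v[abs(v) < 1e-12] <- 0   # clean tiny negatives from rounding
  new("AnalysisMatrix", values = v, transform = "raw", offset = 0)
}

#' Decade bin of a collection year
#'
#' Decades run 1920s--1970s; the sparse 1930s are merged into the 1920s
#' bin, matching the survey design. Years outside 1900--1999 need an
#' explicit mapping.
#'
#' @param year integer vector of collection years.
#' @param extra_map optional named character vector mapping years (as
#'   character) outside 1900--1999 to decade labels.
#' @return character vector of decade labels.
#' @examples
#' decadeOf(1932)  # "1920s"
#' @export
decadeOf <- function(year, extra_map = NULL) {
  out <- rep(NA_character_, length(year))
  in_range <- !is.na(year) & year >= 1900 & year <= 1999
  out[in_range] <- paste0(floor(year[in_range] / 10) * 10, "s")
  out[out %in% "1930s"] <- "1920s"
  if (any(!in_range)) {
    if (is.null(extra_map))
      stop("year(s) outside 1900-1999 need an explicit mapping: ",
           paste(unique(year[!in_range]), collapse = ", "))
    mapped <- extra_map[as.character(year[!in_range])]
    if (anyNA(mapped))
      stop("no mapping for year(s): ",
           paste(unique(year[!in_range][is.na(mapped)]), collapse = ", "))
    out[!in_range] <- mapped
  }
  out
}

#' Fuel era of a decade bin
#'
#' Coal was the dominant fuel through the 1940s, oil from the 1950s on:
#' decades 1920s--1940s map to "coal", 1950s--1970s to "oil".
#'
#' @param decade character vector of decade labels.
#' @return character vector "coal"/"oil".
#' @export
eraOf <- function(decade) {
  era <- rep(NA_character_, length(decade))
  era[decade %in% c("1900s", "1910s", "1920s", "1930s", "1940s")] <- "coal"
  era[decade %in% c("1950s", "1960s", "1970s", "1980s", "1990s")] <- "oil"
  if (anyNA(era))
    stop("no era defined for decade(s): ",
         paste(unique(decade[is.na(era)]), collapse = ", "))
  era
}

#' Assign decade bins and fuel eras
#'
#' Adds/overwrites \code{decade} and \code{era} columns derived from the
#' collection year. Total: every sample receives exactly one decade and
#' one era.
#'
#' @param x a [MossExperiment-class] or a data.frame with a \code{year}
#'   column.
#' @param extra_map see [decadeOf()].
#' @return the input with \code{decade} and \code{era} set.
#' @export
assignGroups <- function(x, extra_map = NULL) {
  if (is(x, "MossExperiment")) {
    cd <- colData(x)
    cd$decade <- decadeOf(cd$year, extra_map)
    cd$era <- eraOf(cd$decade)
    colData(x) <- cd
    return(x)
  }
  x$decade <- decadeOf(x$year, extra_map)
  x$era <- eraOf(x$decade)
  x
}
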