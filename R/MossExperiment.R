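#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData colData<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MossExperiment: censored PAH concentrations for a herbarium study
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} with compounds as rows and herbarium
#' samples as columns, holding two assays:
#' \describe{
#'   \item{\code{conc}}{concentrations in ng per g dry weight; \code{NA}
#'     where the measurement is censored (below LOQ).}
#'   \item{\code{censored}}{logical; \code{TRUE} exactly where \code{conc}
#'     is \code{NA}.}
#' }
#' Row metadata carries the panel fields (benzene rings, weight class,
#' LOQ, ...); column metadata carries the sample sheet (species, collection
#' year, decade bin, fuel era, locality, dry mass). The originating
#' [PAHPanel-class] is kept in \code{metadata(x)$panel}.
#'
#' @seealso [MossExperiment()], [concMatrix()], [censoredMatrix()],
#'   [replaceCensored()]
#' @export
setClass("MossExperiment", contains = "SummarizedExperiment")

setValidity("MossExperiment", function(object) {
  an <- assayNames(object)
  if (!all(c("conc", "censored") %in% an))
    return("assays 'conc' and 'censored' are required")
  conc <- assay(object, "conc")
  cen <- assay(object, "censored")
  if (!is.logical(cen))
    return("'censored' assay must be logical")
  if (anyNA(cen))
    return("'censored' assay must not contain NA")
  if (!identical(unname(is.na(conc)), unname(cen == TRUE)))
    return("conc must be NA exactly where censored is TRUE")
  if (any(conc < 0, na.rm = TRUE))
    return("uncensored concentrations must be >= 0")
  if (!is(metadata(object)$panel, "PAHPanel"))
    return("metadata$panel must be a PAHPanel")
  if (!all(rownames(object) %in% names(metadata(object)$panel)))
    return("row names must be compounds of the panel")
  TRUE
})

#' Construct a MossExperiment
#'
#' @param conc numeric matrix, compounds x samples, NA where censored.
#' @param censored logical matrix of the same shape; if \code{NULL},
#'   derived as \code{is.na(conc)}.
#' @param colData data.frame / DataFrame of per-sample metadata (one row
#'   per column of \code{conc}); typically columns \code{species},
#'   \code{year}, \code{locality}, \code{dry_mass_g}.
#' @param panel the [PAHPanel-class] the rows belong to.
#' @return a [MossExperiment-class].
#' @export
MossExperiment <- function(conc, censored = NULL, colData = NULL, panel) {
  if (is.null(censored)) censored <- is.na(conc)
  mode(censored) <- "logical"
  idx <- panelIndex(panel, rownames(conc))
  rd <- DataFrame(panel@compounds[idx, , drop = FALSE])
  rownames(rd) <- rownames(conc)
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(conc))
  se <- SummarizedExperiment(
    assays = list(conc = conc, censored = censored),
    colData = colData, rowData = rd)
  metadata(se)$panel <- panel
  new("MossExperiment", se)
}

#' @describeIn MossExperiment-class concentration matrix (samples x
#'   compounds), \code{NA} where censored.
#' @param x a \code{MossExperiment}
#' @export
concMatrix <- function(x) t(assay(x, "conc"))

#' @describeIn MossExperiment-class logical censoring matrix
#'   (samples x compounds).
#' @export
censoredMatrix <- function(x) t(assay(x, "censored"))

#' @describeIn MossExperiment-class the panel the experiment was built on.
#' @export
panelOf <- function(x) metadata(x)$panel

#' @describeIn MossExperiment-class sample metadata as a plain data.frame.
#' @export
sampleMeta <- function(x) {
  df <- as.data.frame(colData(x))
  df$sample_id <- colnames(x)
  df[, c("sample_id", setdiff(names(df), "sample_id")), drop = FALSE]
}

setMethod("show", "MossExperiment", function(object) {
  cat("MossExperiment:", nrow(object), "compounds x", ncol(object),
      "samples\n")
  cen <- assay(object, "censored")
  cat(sprintf("  censored cells: %d/%d (%.0f%%)\n", sum(cen), length(cen),
              100 * mean(cen)))
  if ("decade" %in% names(colData(object)))
    cat("  decades:", paste(names(table(colData(object)$decade)),
                            table(colData(object)$decade),
                            sep = ":", collapse = " "), "\n")
  cat("  panel:", panelOf(object)@name, "\n")
})

#' Fraction of samples detecting each compound
#' @param x a [MossExperiment-class]
#' @return named integer vector of detection counts per compound
#' @export
detectionCounts <- function(x) {
  cen <- assay(x, "censored")
  rowSums(!cen)
}
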