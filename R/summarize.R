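#' Period summary of PAH concentrations
#'
#' Builds the per-decade summary used in survey report tables: for each
#' compound, the number of detections and the conditional mean and range
#' over uncensored values only; a compound's mean is reported only when it
#' was detected in at least two samples in that period. The aggregate rows
#' (LMW, HMW and total PAH) use a different convention, forced by the way
#' such tables are assembled: each sample's LMW/HMW/total sums are formed
#' with censored cells as 0, then averaged over all samples in the period
#' -- which makes the identity total = LMW + HMW exact, per sample and per
#' period.
#'
#' @param x a [MossExperiment-class] with decade bins assigned.
#' @return object of class \code{PeriodSummary}: a list with
#'   \describe{
#'     \item{compounds}{data.frame: period, compound, n_detected, mean,
#'       min, max, reported (mean suppressed when n_detected < 2).}
#'     \item{aggregates}{data.frame: period, class (LMW/HMW/SigmaPAH),
#'       mean, min, max over per-sample zero-filled sums.}
#'   }
#' @export
periodSummary <- function(x) {
  stopifnot(is(x, "MossExperiment"))
  meta <- sampleMeta(x)
  if (is.null(meta$decade)) stop("assign decade bins first (assignGroups)")
  conc <- concMatrix(x)              # samples x compounds, NA censored
  panel <- panelOf(x)
  periods <- sort(unique(meta$decade))
  empty <- setdiff(periods, meta$decade)
  if (length(empty)) warning("empty period(s) omitted: ",
                             paste(empty, collapse = ", "))

  comp_rows <- list(); agg_rows <- list()
  wc <- weightClass(panel, colnames(conc))
  for (p in periods) {
    sel <- meta$decade == p
    sub <- conc[sel, , drop = FALSE]
    nd <- colSums(!is.na(sub))
    cmean <- suppressWarnings(colMeans(sub, na.rm = TRUE))
    cmin <- suppressWarnings(apply(sub, 2, min, na.rm = TRUE))
    cmax <- suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
    cmin[!is.finite(cmin)] <- NA; cmax[!is.finite(cmax)] <- NA
    reported <- nd >= 2
    cmean[!reported] <- NA           # < 2 detections: mean suppressed
    cmin[nd == 0] <- NA
    comp_rows[[p]] <- data.frame(
      period = p, compound = colnames(sub), n_total = sum(sel),
      n_detected = unname(nd), mean = unname(cmean), min = unname(cmin),
      max = unname(cmax), reported = unname(reported),
      stringsAsFactors = FALSE)

    zf <- sub; zf[is.na(zf)] <- 0    # zero-filled for aggregates
    lmw <- rowSums(zf[, wc == "LMW", drop = FALSE])
    hmw <- rowSums(zf[, wc == "HMW", drop = FALSE])
    tot <- lmw + hmw
    agg_rows[[p]] <- data.frame(
      period = p,
      class = c("LMW", "HMW", "SigmaPAH"),
      mean = c(mean(lmw), mean(hmw), mean(tot)),
      min = c(min(lmw), min(hmw), min(tot)),
      max = c(max(lmw), max(hmw), max(tot)), stringsAsFactors = FALSE)
  }
  structure(list(compounds = do.call(rbind, c(comp_rows,
                                              make.row.names = FALSE)),
                 aggregates = do.call(rbind, c(agg_rows,
                                               make.row.names = FALSE))),
            class = "PeriodSummary")
}

#' Format a period summary as a report table
#'
#' One row per compound plus LMW/HMW/SigmaPAH aggregate rows, one column
#' per period, cells "mean (min-max)" rounded to 1 decimal. Compounds
#' detected once show "<LOQ (<LOQ-max)"; never-detected compounds show
#' "<LOQ". Compounds never detected in any period are dropped.
#'
#' @param ps a \code{PeriodSummary} from [periodSummary()].
#' @param digits decimals for concentrations (default 1).
#' @return character data.frame (compound x period).
#' @export
formatPeriodTable <- function(ps, digits = 1) {
  stopifnot(inherits(ps, "PeriodSummary"))
  fmt <- function(v) formatC(round(v, digits), format = "f",
                             digits = digits)
  cell <- function(mean, min, max, nd, nt) {
    if (nd == 0) return("<LOQ")
    lo <- if (nd < nt) "<LOQ" else fmt(min)  # range dips below LOQ
    if (nd == 1) return(paste0("<LOQ (", lo, "-", fmt(max), ")"))
    paste0(fmt(mean), " (", lo, "-", fmt(max), ")")
  }
  cc <- ps$compounds
  keep <- unique(cc$compound[cc$n_detected > 0])
  cc <- cc[cc$compound %in% keep, , drop = FALSE]
  periods <- unique(cc$period)
  rows <- lapply(split(cc, factor(cc$compound, levels = unique(cc$compound))),
    function(d) vapply(periods, function(p) {
      r <- d[d$period == p, ]
      cell(r$mean, r$min, r$max, r$n_detected, r$n_total)
    }, character(1)))
  agg <- lapply(split(ps$aggregates,
                      factor(ps$aggregates$class,
                             levels = c("LMW", "HMW", "SigmaPAH"))),
    function(d) vapply(periods, function(p) {
      r <- d[d$period == p, ]
      paste0(fmt(r$mean), " (", fmt(r$min), "-", fmt(r$max), ")")
    }, character(1)))
  out <- as.data.frame(do.call(rbind, c(rows, agg)),
                       stringsAsFactors = FALSE)
  names(out) <- periods
  out
}

#' Column Z-score matrix
#'
#' Standardizes each compound column to mean 0, sd 1 -- the normalization
#' behind the survey heat maps, where each cell is the number of standard
#' deviations a sample sits above or below the compound mean. Constant
#' columns (sd 0) are set to 0 and flagged.
#'
#' @param x an [AnalysisMatrix-class] or plain numeric matrix (samples x
#'   compounds).
#' @param grouping optional per-sample annotation (e.g. decade or
#'   species) stored as an attribute for plotting.
#' @return numeric matrix with attributes \code{constant} (logical per
#'   column) and \code{grouping}.
#' @export
zscoreMatrix <- function(x, grouping = NULL) {
  v <- if (is(x, "AnalysisMatrix")) x@values else x
  if (nrow(v) < 2) stop("need at least 2 samples")
  mu <- colMeans(v)
  sdv <- apply(v, 2, sd)
  constant <- sdv == 0
  z <- sweep(v, 2, mu, `-`)
  z[, !constant] <- sweep(z[, !constant, drop = FALSE], 2,
                          sdv[!constant], `/`)
  z[, constant] <- 0
  attr(z, "constant") <- constant
  attr(z, "grouping") <- grouping
  z
}

#' Heat map of a Z-score matrix
#'
#' Thin wrapper over \pkg{pheatmap} with rows ordered by the grouping
#' annotation; requires the suggested \pkg{pheatmap} package.
#'
#' @param z matrix from [zscoreMatrix()].
#' @param filename optional PNG path; NULL draws to the active device.
#' @param ... passed to \code{pheatmap::pheatmap}.
#' @return the pheatmap object, invisibly.
#' @export
plotZscoreHeatmap <- function(z, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plotZscoreHeatmap needs the 'pheatmap' package")
  grouping <- attr(z, "grouping")
  ann <- NULL
  if (!is.null(grouping)) {
    ord <- order(grouping)
    z <- z[ord, , drop = FALSE]
    ann <- data.frame(group = grouping[ord], row.names = rownames(z))
  }
  invisible(pheatmap::pheatmap(z, cluster_rows = FALSE,
                               cluster_cols = FALSE,
                               annotation_row = ann,
                               filename = filename, ...))
}
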