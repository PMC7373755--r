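#' Fit 6-point internal-standard calibration curves
#'
#' Classical internal-standard calibration: for each compound, ordinary
#' least squares of the area ratio (analyte area / IS area) on the amount
#' ratio (analyte ng / IS ng). Unweighted by default; \code{weighting =
#' "1/x"} weights each point by the inverse amount ratio, a common choice
#' when calibration spans orders of magnitude.
#'
#' @param calibration data.frame with columns \code{compound},
#'   \code{analyte_ng}, \code{is_ng}, \code{analyte_area}, \code{is_area}
#'   (and optionally \code{level}).
#' @param weighting "none" (default) or "1/x".
#' @return data.frame, one row per compound: \code{compound},
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{n_points}.
#' @examples
#' cal <- data.frame(compound = "pyrene", analyte_ng = 1:6 * 100,
#'                   is_ng = 1600, analyte_area = 2 * (1:6 * 100) / 1600,
#'                   is_area = 1)
#' fitCalibration(cal)   # slope 2, intercept 0, r^2 = 1
#' @export
fitCalibration <- function(calibration, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  needed <- c("compound", "analyte_ng", "is_ng", "analyte_area", "is_area")
  if (!all(needed %in% names(calibration)))
    stop("calibration table needs columns: ",
         paste(setdiff(needed, names(calibration)), collapse = ", "))
  if (any(calibration$analyte_ng <= 0) || any(calibration$is_ng <= 0))
    stop("calibration amounts must be > 0")
  out <- lapply(split(calibration, calibration$compound), function(d) {
    x <- d$analyte_ng / d$is_ng
    y <- d$analyte_area / d$is_area
    if (length(unique(x)) < 2)
      stop("calibration for ", d$compound[1],
           ": need >= 2 distinct amount ratios")
    w <- if (weighting == "1/x") 1 / x else NULL
    fit <- lm(y ~ x, weights = w)
    ss_res <- sum((y - fitted(fit))^2)
    ss_tot <- sum((y - mean(y))^2)
    data.frame(compound = d$compound[1],
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
               n_points = length(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Quantify peak areas to ng per g dry weight
#'
#' Back-calculates through the calibration: amount ratio =
#' (area ratio - intercept) / slope; analyte mass = amount ratio x IS
#' spike; concentration = analyte mass / dry mass. Concentrations below
#' the compound LOQ -- including negative back-calculated amounts -- are
#' reported as censored (no numeric value); a value exactly at the LOQ is
#' retained.
#'
#' @param areas data.frame with columns \code{sample_id}, \code{compound},
#'   \code{analyte_area}, \code{is_area}.
#' @param models calibration fits from [fitCalibration()].
#' @param dry_mass_g named numeric vector of sample dry masses (g), names
#'   = sample_id.
#' @param is_spike_ng internal-standard mass spiked per sample (ng);
#'   default 1600 ng = 200 ul of an 8 ug/ml mix.
#' @param loq named numeric LOQ per compound (ng/g), or a
#'   [PAHPanel-class]; default LOQ 0 disables censoring.
#' @return data.frame: \code{sample_id}, \code{compound},
#'   \code{concentration} (NA when censored), \code{censored}.
#' @export
quantifyAreas <- function(areas, models, dry_mass_g, is_spike_ng = 1600,
                          loq = NULL) {
  if (is(loq, "PAHPanel")) loq <- panelLOQ(loq)
  if (any(models$slope <= 0))
    stop("invalid calibration model: slope must be > 0 (",
         paste(models$compound[models$slope <= 0], collapse = ", "), ")")
  m <- match(areas$compound, models$compound)
  if (anyNA(m))
    stop("no calibration model for: ",
         paste(unique(areas$compound[is.na(m)]), collapse = ", "))
  dm <- dry_mass_g[areas$sample_id]
  if (anyNA(dm))
    stop("no dry mass for sample(s): ",
         paste(unique(areas$sample_id[is.na(dm)]), collapse = ", "))
  if (any(dm <= 0)) stop("dry mass must be > 0")
  area_ratio <- areas$analyte_area / areas$is_area
  amount_ratio <- (area_ratio - models$intercept[m]) / models$slope[m]
  conc <- amount_ratio * is_spike_ng / dm
  lq <- if (is.null(loq)) 0 else {
    v <- loq[areas$compound]
    if (anyNA(v)) stop("no LOQ for: ",
                       paste(unique(areas$compound[is.na(v)]), collapse = ", "))
    v
  }
  cen <- conc < lq | conc < 0
  conc[cen] <- NA_real_
  data.frame(sample_id = areas$sample_id, compound = areas$compound,
             concentration = unname(conc), censored = unname(cen),
             stringsAsFactors = FALSE)
}

#' Apply recovery-standard correction
#'
#' The recovery fraction of a deuterated standard is its measured amount
#' divided by the spiked amount; each analyte concentration is divided by
#' the recovery fraction of its paired internal standard. A fraction of 1
#' leaves results unchanged; 0.5 doubles them.
#'
#' @param quant quantified long table from [quantifyAreas()].
#' @param recovery data.frame with columns \code{sample_id},
#'   \code{standard} and either \code{fraction} or both
#'   \code{measured_ng} and \code{spiked_ng}.
#' @param panel a [PAHPanel-class] supplying the compound-to-standard
#'   pairing (\code{is_partner}).
#' @return \code{quant} with corrected concentrations and a
#'   \code{recovery} column.
#' @export
recoveryCorrect <- function(quant, recovery, panel) {
  if (!"fraction" %in% names(recovery))
    recovery$fraction <- recovery$measured_ng / recovery$spiked_ng
  if (any(recovery$fraction <= 0) || anyNA(recovery$fraction))
    stop("recovery fractions must be > 0")
  idx <- panelIndex(panel, quant$compound)
  partner <- panel@compounds$is_partner[idx]
  key <- paste(quant$sample_id, partner)
  rkey <- paste(recovery$sample_id, recovery$standard)
  frac <- recovery$fraction[match(key, rkey)]
  if (anyNA(frac))
    stop("missing recovery fraction for sample/standard pair(s): ",
         paste(unique(key[is.na(frac)]), collapse = "; "))
  quant$concentration <- quant$concentration / frac
  quant$recovery <- frac
  quant
}

#' Quantify a simulated or imported area study into a MossExperiment
#'
#' Fits the calibration, quantifies every sample area, and assembles a
#' [MossExperiment-class] with decade/era grouping applied.
#'
#' @param areas,calibration tables as produced by [simulatePeakAreas()]
#'   or read from CSV.
#' @param meta sample sheet with \code{sample_id}, \code{dry_mass_g} (and
#'   usually \code{species}, \code{year}, \code{locality}).
#' @param panel a [PAHPanel-class]; its LOQs drive censoring unless
#'   \code{loq} is given.
#' @param loq optional named LOQ overrides (ng/g).
#' @param is_spike_ng internal-standard spike (ng).
#' @param weighting calibration weighting, see [fitCalibration()].
#' @return a [MossExperiment-class].
#' @export
quantifyStudy <- function(areas, calibration, meta, panel = defaultPanel(),
                          loq = NULL, is_spike_ng = 1600,
                          weighting = "none") {
  models <- fitCalibration(calibration, weighting = weighting)
  dm <- setNames(meta$dry_mass_g, meta$sample_id)
  if (is.null(loq)) loq <- panelLOQ(panel)
  quant <- quantifyAreas(areas, models, dm, is_spike_ng = is_spike_ng,
                         loq = loq)
  longToExperiment(quant, meta, panel)
}

# long (sample_id, compound, concentration, censored) -> MossExperiment
longToExperiment <- function(quant, meta, panel) {
  samples <- meta$sample_id
  compounds <- unique(quant$compound)
  idx <- panelIndex(panel, compounds)   # errors on unknowns
  compounds <- panel@compounds$name[idx]
  conc <- matrix(NA_real_, length(compounds), length(samples),
                 dimnames = list(compounds, samples))
  cen <- matrix(TRUE, length(compounds), length(samples),
                dimnames = list(compounds, samples))
  i <- cbind(match(panel@compounds$name[panelIndex(panel, quant$compound)],
                   compounds),
             match(quant$sample_id, samples))
  if (anyNA(i[, 2]))
    stop("area table contains sample(s) absent from metadata: ",
         paste(unique(quant$sample_id[is.na(i[, 2])]), collapse = ", "))
  conc[i] <- quant$concentration
  cen[i] <- quant$censored
  cd <- meta
  rownames(cd) <- cd$sample_id
  me <- MossExperiment(conc, cen,
                       colData = cd[, setdiff(names(cd), "sample_id"),
                                    drop = FALSE],
                       panel = panel)
  if (all(c("year") %in% names(meta))) me <- assignGroups(me)
  me
}
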