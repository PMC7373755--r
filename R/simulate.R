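#' @title Synthetic herbarium study generator
#' @description Seeded generators that emulate a multi-decade herbarium
#'   moss survey: sample metadata, "true" tissue concentrations following
#'   per-decade trends, censoring at compound LOQs, and GC-MS peak-area
#'   tables with internal-standard calibration series. Everything flows
#'   from one user-supplied seed.
#' @name synthetic
NULL

# run expr with a local RNG state seeded by `seed`; global stream restored
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.DECADES <- c("1920s", "1940s", "1950s", "1960s", "1970s")

#' Study design for the synthetic generator
#'
#' Defaults mirror a 42-specimen herbarium survey: three moss species
#' (Dicranum scoparium 13, Hylocomium splendens 15, Racomitrium
#' lanuginosum 14 samples) collected in roughly triplicate per species
#' across five decade bins, 1920s through 1970s (no 1930s bin: the single
#' 1930s specimen is booked under the 1920s).
#'
#' @param species_by_decade integer matrix, species x decade, of sample
#'   counts. Default rows sum to 13/15/14 and columns to the decade sizes.
#' @param seed integer seed driving all randomness downstream.
#' @param dry_mass_range sampled dry mass per specimen, g (uniform).
#' @return an object of class \code{StudyDesign} (a validated list).
#' @export
studyDesign <- function(species_by_decade = NULL, seed = 1L,
                        dry_mass_range = c(0.38, 1.64)) {
  if (is.null(species_by_decade)) {
    species_by_decade <- rbind(
      "Dicranum scoparium"      = c(3, 3, 3, 2, 2),
      "Hylocomium splendens"    = c(3, 3, 3, 3, 3),
      "Racomitrium lanuginosum" = c(3, 3, 3, 3, 2))
    colnames(species_by_decade) <- .DECADES
  }
  if (is.null(rownames(species_by_decade)) ||
      is.null(colnames(species_by_decade)))
    stop("species_by_decade needs species row names and decade column names")
  if (any(species_by_decade < 0) ||
      any(species_by_decade != round(species_by_decade)))
    stop("sample counts must be non-negative integers")
  if (any(colSums(species_by_decade) == 0))
    stop("every decade bin must contain at least one sample")
  if (length(dry_mass_range) != 2 || any(dry_mass_range <= 0))
    stop("dry_mass_range must be two positive numbers")
  structure(list(species_by_decade = species_by_decade,
                 n_samples = sum(species_by_decade),
                 seed = as.integer(seed),
                 dry_mass_range = sort(dry_mass_range)),
            class = "StudyDesign")
}

#' Concentration trend model for the synthetic generator
#'
#' True tissue concentration of compound c in sample i is
#' \code{baseline_c * decade_factor * species_factor * exp(N(0, sigma^2))}.
#' Defaults emulate the published Greenland survey: LMW-dominated
#' baselines (naphthalene and phenanthrene in the hundreds of ng/g),
#' decade factors declining from 1 in the 1920s to about 0.3 in the 1970s
#' with a 1960s uptick, a heavier-accumulating Dicranum scoparium, and
#' compound LOQs that leave four compounds (naphthalene, phenanthrene,
#' fluoranthene, pyrene) ubiquitously detected, seven more intermittently
#' detected, and the remaining eight effectively never detected.
#'
#' @param baseline named numeric, 1920s deposition level per compound
#'   (ng per g dry weight); names must resolve in the panel.
#' @param decade_factors named numeric multiplier per decade bin.
#' @param species_factors named numeric multiplier per species.
#' @param sigma lognormal noise sd on the log scale (default 0.4).
#' @param loq named numeric LOQ per compound; defaults to the panel LOQs
#'   with method-specific overrides for the intermittently detected
#'   compounds.
#' @param panel the [PAHPanel-class] the compounds live in.
#' @return an object of class \code{TrendModel} (a validated list).
#' @export
trendModel <- function(baseline = NULL, decade_factors = NULL,
                       species_factors = NULL, sigma = 0.4, loq = NULL,
                       panel = defaultPanel()) {
  if (is.null(baseline))
    baseline <- c(naphthalene = 370, phenanthrene = 260, fluoranthene = 80,
                  pyrene = 55, "benz[a]anthracene" = 10, chrysene = 40,
                  "benzo[b]fluoranthene" = 8, "benzo[k]fluoranthene" = 8,
                  "benzo[ghi]perylene" = 8, anthracene = 6,
                  "benzo[a]pyrene" = 6,
                  acenaphthylene = 0.5, acenaphthene = 0.5, fluorene = 0.5,
                  "indeno[1,2,3-cd]pyrene" = 0.5,
                  "dibenz[a,h]anthracene" = 0.5, retene = 0.5,
                  "benzo[e]pyrene" = 0.5, perylene = 0.5)
  if (is.null(decade_factors))
    decade_factors <- c("1920s" = 1.00, "1940s" = 0.59, "1950s" = 0.47,
                        "1960s" = 0.55, "1970s" = 0.31)
  if (is.null(species_factors))
    species_factors <- c("Dicranum scoparium" = 1.30,
                         "Hylocomium splendens" = 0.85,
                         "Racomitrium lanuginosum" = 0.85)
  if (is.null(loq)) {
    loq <- panelLOQ(panel)
    overrides <- c(chrysene = 35, "benz[a]anthracene" = 8,
                   "benzo[b]fluoranthene" = 12, "benzo[k]fluoranthene" = 12,
                   "benzo[ghi]perylene" = 10, "benzo[a]pyrene" = 6)
    loq[names(overrides)] <- overrides
  }
  idx <- panelIndex(panel, names(baseline))  # errors on unknowns
  names(baseline) <- panel@compounds$name[idx]
  if (any(baseline <= 0)) stop("baselines must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(decade_factors <= 0) || any(species_factors <= 0))
    stop("trend and species factors must be > 0")
  structure(list(baseline = baseline, decade_factors = decade_factors,
                 species_factors = species_factors, sigma = sigma,
                 loq = loq, panel = panel),
            class = "TrendModel")
}

#' Simulate a herbarium study
#'
#' Draws sample metadata and true (pre-censoring) tissue concentrations
#' from a [studyDesign()] and [trendModel()]. Years are uniform within
#' each decade; one 1920s-bin sample is given the year 1932 when the bin
#' holds more than one sample, mirroring a merged 1930s specimen. Dry
#' masses are uniform on the design range.
#'
#' @param design a \code{StudyDesign}.
#' @param trend a \code{TrendModel}.
#' @return list with \code{meta} (data.frame: sample_id, species, year,
#'   decade, locality, dry_mass_g) and \code{truth} (matrix, samples x
#'   compounds, ng per g dry weight).
#' @export
simulateStudy <- function(design, trend) {
  stopifnot(inherits(design, "StudyDesign"), inherits(trend, "TrendModel"))
  grid <- design$species_by_decade
  missing_dec <- setdiff(colnames(grid), names(trend$decade_factors))
  if (length(missing_dec))
    stop("trend model lacks decade factors for: ",
         paste(missing_dec, collapse = ", "))
  missing_sp <- setdiff(rownames(grid), names(trend$species_factors))
  if (length(missing_sp))
    stop("trend model lacks species factors for: ",
         paste(missing_sp, collapse = ", "))

  species <- rep(rep(rownames(grid), ncol(grid)), as.vector(grid))
  decade <- rep(rep(colnames(grid), each = nrow(grid)), as.vector(grid))
  n <- length(species)
  compounds <- names(trend$baseline)

  withSeed(design$seed, {
    start <- as.integer(substr(decade, 1, 4))
    year <- start + sample(0:9, n, replace = TRUE)
    in20s <- which(decade == "1920s")
    if (length(in20s) > 1) year[in20s[length(in20s)]] <- 1932L
    meta <- data.frame(
      sample_id = sprintf("MOSS%02d", seq_len(n)),
      species = species, year = year, decade = decade,
      locality = sprintf("site-%02d", sample(seq_len(n))),
      dry_mass_g = round(runif(n, design$dry_mass_range[1],
                               design$dry_mass_range[2]), 3),
      stringsAsFactors = FALSE)
    mu <- outer(trend$decade_factors[meta$decade] *
                  trend$species_factors[meta$species],
                trend$baseline)
    noise <- matrix(exp(rnorm(n * length(compounds), 0, trend$sigma)),
                    nrow = n)
    truth <- mu * noise
    dimnames(truth) <- list(meta$sample_id, compounds)
    list(meta = meta, truth = truth)
  })
}

#' Censor a true concentration matrix at compound LOQs
#'
#' Values strictly below the LOQ are censored (ties at the LOQ are
#' retained); censored cells carry no numeric value.
#'
#' @param truth matrix, samples x compounds.
#' @param loq named numeric LOQ per compound, or a [PAHPanel-class]
#'   (its LOQ column is used).
#' @return list with \code{conc} (matrix with NA at censored cells) and
#'   \code{censored} (logical matrix).
#' @export
censorMatrix <- function(truth, loq) {
  if (is(loq, "PAHPanel")) loq <- panelLOQ(loq)
  missing <- setdiff(colnames(truth), names(loq))
  if (length(missing))
    stop("no LOQ defined for: ", paste(missing, collapse = ", "))
  cen <- sweep(truth, 2, loq[colnames(truth)], `<`)
  conc <- truth
  conc[cen] <- NA_real_
  list(conc = conc, censored = cen)
}

#' Simulate a full study as a MossExperiment
#'
#' Convenience wrapper: [simulateStudy()] then [censorMatrix()] then
#' [assignGroups()], packed into a [MossExperiment-class].
#'
#' @param design a \code{StudyDesign}
#' @param trend a \code{TrendModel}
#' @return a [MossExperiment-class] with decade and era columns set.
#' @export
simulateMossExperiment <- function(design = studyDesign(),
                                   trend = trendModel()) {
  sim <- simulateStudy(design, trend)
  obs <- censorMatrix(sim$truth, trend$loq)
  cd <- sim$meta
  rownames(cd) <- cd$sample_id
  me <- MossExperiment(conc = t(obs$conc), censored = t(obs$censored),
                       colData = cd[, setdiff(names(cd), "sample_id")],
                       panel = trend$panel)
  assignGroups(me)
}

#' Simulate GC-MS peak-area tables with a calibration series
#'
#' Emulates internal-standard GC-MS output at the integrated-peak level:
#' for each sample and compound the analyte/IS area ratio is
#' \code{rf * (analyte ng in extract / IS ng) * (1 + eps)} with
#' \code{eps ~ N(0, noise_cv^2)}; the analyte mass is tissue concentration
#' times dry mass. The IS spike defaults to 1600 ng (200 ul of an
#' 8 ug/ml mix). A 6-level calibration series per compound spans the
#' simulated amount-ratio range.
#'
#' @param truth matrix, samples x compounds, ng per g dry weight.
#' @param meta data.frame with \code{sample_id} and \code{dry_mass_g}.
#' @param rf named (or scalar) response factor per compound, > 0.
#' @param is_spike_ng internal-standard mass spiked per sample, ng.
#' @param noise_cv relative area noise (fraction; 0 = noise-free).
#' @param n_levels calibration levels per compound (default 6).
#' @param seed integer seed for the area noise.
#' @return list with \code{areas} (sample_id, compound, analyte_area,
#'   is_area) and \code{calibration} (compound, level, analyte_ng, is_ng,
#'   analyte_area, is_area).
#' @export
simulatePeakAreas <- function(truth, meta, rf = 1, is_spike_ng = 1600,
                              noise_cv = 0, n_levels = 6, seed = 1L) {
  if (any(meta$dry_mass_g <= 0)) stop("dry mass must be positive")
  compounds <- colnames(truth)
  if (length(rf) == 1) rf <- setNames(rep(rf, length(compounds)), compounds)
  if (any(rf[compounds] <= 0) || anyNA(rf[compounds]))
    stop("response factors must be > 0 for every compound")
  dm <- setNames(meta$dry_mass_g, meta$sample_id)[rownames(truth)]
  rfv <- rf[compounds]

  withSeed(seed, {
    analyte_ng <- truth * dm            # dm recycles down rows = samples
    ratio_true <- sweep(analyte_ng, 2, rfv, `*`) / is_spike_ng
    eps <- matrix(rnorm(length(ratio_true), 0, noise_cv), nrow(ratio_true))
    is_area <- 1e5
    areas <- data.frame(
      sample_id = rep(rownames(truth), times = ncol(truth)),
      compound = rep(compounds, each = nrow(truth)),
      analyte_area = as.vector(ratio_true * (1 + eps)) * is_area,
      is_area = is_area,
      stringsAsFactors = FALSE)

    cal <- do.call(rbind, lapply(compounds, function(cc) {
      amt <- analyte_ng[, cc]
      lo <- max(min(amt) / 2, 1e-3)
      hi <- max(max(amt) * 2, lo * 10)
      lv <- exp(seq(log(lo), log(hi), length.out = n_levels))
      r <- rf[cc] * lv / is_spike_ng
      data.frame(compound = cc, level = seq_len(n_levels),
                 analyte_ng = lv, is_ng = is_spike_ng,
                 analyte_area = r * (1 + rnorm(n_levels, 0, noise_cv)) *
                   is_area,
                 is_area = is_area, stringsAsFactors = FALSE)
    }))
    rownames(cal) <- NULL
    list(areas = areas, calibration = cal)
  })
}
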