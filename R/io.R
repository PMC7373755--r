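#' Published Greenland survey summaries
#'
#' Accessors for the published period-level summary tables shipped with
#' the package: conditional period means and ranges of PAH
#' concentrations in Greenland herbarium mosses (1920s-1970s), and the
#' corresponding published diagnostic-ratio table. These are the natural
#' inputs to the ratio-of-means engine ([ratiosFromMeans()]) and the
#' reference for the classification checks.
#'
#' @return data.frame; see the column comments in the underlying CSVs.
#' @export
publishedPeriodMeans <- function() {
  read.csv(system.file("extdata", "greenland_period_means.csv",
                       package = "mossPAH", mustWork = TRUE),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname publishedPeriodMeans
#' @export
publishedPeriodRatios <- function() {
  read.csv(system.file("extdata", "greenland_period_ratios.csv",
                       package = "mossPAH", mustWork = TRUE),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a concentration study from CSV
#'
#' Canonical exchange format: a metadata CSV (columns \code{sample_id},
#' \code{species}, \code{year}, \code{locality}, \code{dry_mass_g}) and a
#' long concentration CSV (columns \code{sample_id}, \code{compound},
#' \code{value}, \code{censored}; censored cells have an empty value,
#' never a sentinel number). Unknown compounds and duplicate
#' (sample, compound) cells are errors naming the offenders.
#'
#' @param meta_path,conc_path CSV paths; lines starting with \code{#}
#'   are treated as comments.
#' @param panel a [PAHPanel-class] to validate compounds against.
#' @return a [MossExperiment-class] with decade/era assigned.
#' @export
readConcentrations <- function(meta_path, conc_path,
                               panel = defaultPanel()) {
  meta <- read.csv(meta_path, comment.char = "#",
                   stringsAsFactors = FALSE)
  long <- read.csv(conc_path, comment.char = "#",
                   stringsAsFactors = FALSE)
  need_m <- c("sample_id", "dry_mass_g")
  if (!all(need_m %in% names(meta)))
    stop("metadata CSV lacks column(s): ",
         paste(setdiff(need_m, names(meta)), collapse = ", "))
  need_c <- c("sample_id", "compound", "value", "censored")
  if (!all(need_c %in% names(long)))
    stop("concentration CSV lacks column(s): ",
         paste(setdiff(need_c, names(long)), collapse = ", "))
  dup <- duplicated(long[, c("sample_id", "compound")])
  if (any(dup)) {
    off <- long[dup, c("sample_id", "compound")]
    stop("duplicate (sample, compound) rows (first at data line ",
         which(dup)[1], "): ",
         paste(off$sample_id[1], off$compound[1]))
  }
  panelIndex(panel, unique(long$compound))   # unknown compounds -> error
  long$censored <- as.logical(long$censored)
  bad <- !long$censored & is.na(long$value)
  if (any(bad))
    stop("uncensored rows without a value at data line(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  long$value[long$censored] <- NA_real_
  quant <- data.frame(sample_id = long$sample_id,
                      compound = long$compound,
                      concentration = long$value,
                      censored = long$censored, stringsAsFactors = FALSE)
  longToExperiment(quant, meta, panel)
}

# write a data.frame as CSV under a provenance header
writeWithHeader <- function(df, path, provenance) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance, con)
  write.csv(df, con, row.names = FALSE, na = "")
}

provenanceHeader <- function(seed, config) {
  cfg_hash <- substr(digestConfig(config), 1, 12)
  c(sprintf("# mossPAH %s", as.character(packageVersion("mossPAH"))),
    sprintf("# seed=%s config=%s", seed, cfg_hash))
}

# stable hash of the config list (md5 of its deparsed canonical form);
# output location does not affect analytical identity
digestConfig <- function(config) {
  config <- config[setdiff(names(config), "outdir")]
  config <- config[order(names(config))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a MossExperiment to the exchange CSVs
#'
#' @param x a [MossExperiment-class].
#' @param meta_path,conc_path output CSV paths.
#' @param provenance optional character vector of header comment lines.
#' @return invisibly, the two paths.
#' @export
writeConcentrations <- function(x, meta_path, conc_path,
                                provenance = character()) {
  meta <- sampleMeta(x)
  conc <- concMatrix(x)
  cen <- censoredMatrix(x)
  long <- data.frame(
    sample_id = rep(rownames(conc), times = ncol(conc)),
    compound = rep(colnames(conc), each = nrow(conc)),
    value = as.vector(conc),
    censored = as.vector(cen), stringsAsFactors = FALSE)
  writeWithHeader(meta, meta_path, provenance)
  writeWithHeader(long, conc_path, provenance)
  invisible(c(meta_path, conc_path))
}

#' Default pipeline configuration
#'
#' @param seed integer seed for the synthetic stage.
#' @param outdir output directory.
#' @param ... overrides for any config entry (prevalence_min_nonzero,
#'   prevalence_fraction, log_offset, alpha, alpha_relaxed, noise_cv,
#'   quantify_from_areas).
#' @return named list.
#' @export
pipelineConfig <- function(seed = 1L, outdir = tempfile("mossPAH-run"),
                           ...) {
  cfg <- list(seed = as.integer(seed), outdir = outdir,
              prevalence_min_nonzero = NULL,
              prevalence_fraction = 20 / 42,
              log_offset = 1, alpha = 0.05, alpha_relaxed = 0.1,
              noise_cv = 0.05, quantify_from_areas = TRUE)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Run the full analysis pipeline on a synthetic or imported study
#'
#' Executes, in order: simulate (or ingest) -> peak-area quantification
#' -> censored-zero replacement, prevalence filter, log transform ->
#' period summary and Z-scores -> decade/era ANOVA with Tukey and FDR ->
#' Bray-Curtis dissimilarity -> diagnostic-ratio apportionment; then
#' writes the report CSVs plus a markdown report. All outputs carry a
#' provenance header (package version, config hash, seed) and contain no
#' timestamps, so the same config and seed give byte-identical files.
#'
#' @param config list from [pipelineConfig()].
#' @param experiment optional [MossExperiment-class]; when supplied the
#'   synthetic stage is skipped.
#' @return invisibly, a list with every intermediate result and
#'   \code{files} (the written paths).
#' @export
runPipeline <- function(config = pipelineConfig(), experiment = NULL) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- provenanceHeader(config$seed, config)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    writeWithHeader(df, p, prov)
    paths[[name]] <<- p
  }

  if (is.null(experiment)) {
    design <- studyDesign(seed = config$seed)
    trend <- trendModel()
    sim <- simulateStudy(design, trend)
    if (isTRUE(config$quantify_from_areas)) {
      pk <- simulatePeakAreas(sim$truth, sim$meta, rf = 1.5,
                              noise_cv = config$noise_cv,
                              seed = config$seed + 1L)
      experiment <- quantifyStudy(pk$areas, pk$calibration, sim$meta,
                                  panel = trend$panel, loq = trend$loq)
    } else {
      obs <- censorMatrix(sim$truth, trend$loq)
      quant <- data.frame(
        sample_id = rep(rownames(obs$conc), ncol(obs$conc)),
        compound = rep(colnames(obs$conc), each = nrow(obs$conc)),
        concentration = as.vector(obs$conc),
        censored = as.vector(obs$censored), stringsAsFactors = FALSE)
      experiment <- longToExperiment(quant, sim$meta, trend$panel)
    }
  }
  meta <- sampleMeta(experiment)
  writeConcentrations(experiment,
                      file.path(config$outdir, "sample_metadata.csv"),
                      file.path(config$outdir, "concentrations.csv"),
                      provenance = prov)
  paths[["sample_metadata.csv"]] <-
    file.path(config$outdir, "sample_metadata.csv")
  paths[["concentrations.csv"]] <-
    file.path(config$outdir, "concentrations.csv")

  am <- replaceCensored(experiment)
  retained <- prevalenceFilter(am,
                               min_nonzero = config$prevalence_min_nonzero,
                               fraction = config$prevalence_fraction)
  lg <- logTransform(am, offset = config$log_offset)

  ps <- periodSummary(experiment)
  emit(ps$compounds, "period_summary_compounds.csv")
  emit(ps$aggregates, "period_summary_aggregates.csv")
  z <- zscoreMatrix(am, grouping = meta$decade)
  emit(data.frame(sample_id = rownames(z), as.data.frame(unclass(z)),
                  check.names = FALSE), "zscore_matrix.csv")

  stats_decade <- anovaPerCompound(lg, meta$decade, compounds = retained)
  stats_era <- anovaPerCompound(lg, meta$era, compounds = retained)
  emit(stats_decade, "anova_decade.csv")
  emit(stats_era, "anova_era.csv")
  tukey <- lapply(setNames(retained, retained), function(cc)
    tukeyHsd(lg@values[, cc], meta$decade, alpha = config$alpha))
  letters_tab <- do.call(rbind, lapply(names(tukey), function(cc)
    data.frame(compound = cc, group = names(tukey[[cc]]$letters),
               letters = unname(tukey[[cc]]$letters),
               stringsAsFactors = FALSE)))
  emit(letters_tab, "tukey_letters_decade.csv")

  bc <- brayCurtis(am)
  dis <- dissimilarityByDecade(bc, meta$decade, alpha = config$alpha)
  emit(dis$categories, "dissimilarity_categories.csv")

  ratios <- apportion(experiment)
  emit(ratios, "diagnostic_ratios.csv")

  report <- c(prov,
    "# Pipeline report", "",
    sprintf("Samples: %d; compounds: %d; retained after prevalence filter: %s",
            ncol(experiment), nrow(experiment),
            paste(retained, collapse = ", ")),
    "",
    "## Period summary (conditional means, ng/g dry weight)", "",
    knitTable(formatPeriodTable(ps)),
    "",
    "## Diagnostic ratios (ratio-of-means)", "",
    knitTable(ratios[ratios$method == "ratio-of-means" &
                       !is.na(ratios$value),
                     c("period", "rule", "value", "label")]))
  rp <- file.path(config$outdir, "report.md")
  writeLines(report, rp)
  paths[["report.md"]] <- rp

  invisible(list(experiment = experiment, analysis = am, log = lg,
                 retained = retained, period_summary = ps, zscore = z,
                 stats_decade = stats_decade, stats_era = stats_era,
                 tukey = tukey, dissimilarity = dis, ratios = ratios,
                 files = paths, config = config))
}

# minimal markdown table writer (no extra dependency)
knitTable <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "f",
                                                 digits = 2))
  df[] <- lapply(df, as.character)
  if (!is.null(rownames(df)) && !identical(rownames(df),
                                           as.character(seq_len(nrow(df)))))
    df <- cbind(" " = rownames(df), df)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, unname(rows))
}
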