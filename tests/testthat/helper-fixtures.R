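# shared fixtures: everything built in code, nothing read from disk

# four-compound mini panel covering both weight classes
miniPanel <- function(loq = c(2, 2, 2, 2)) {
  PAHPanel(data.frame(
    name = c("phenanthrene", "anthracene", "fluoranthene", "pyrene"),
    abbreviation = c("Phe", "Ant", "Flt", "Pyr"),
    benzene_rings = c(3, 3, 3, 4),
    mw = c(178.23, 178.23, 202.25, 202.25),
    is_partner = "phenanthrene-d10",
    loq = loq), name = "mini")
}

# experiment from an explicit samples x compounds matrix (NA = censored)
makeExperiment <- function(conc, years = NULL, panel = defaultPanel()) {
  if (is.null(years)) years <- rep(1925, nrow(conc))
  meta <- data.frame(sample_id = rownames(conc),
                     species = "Dicranum scoparium", year = years,
                     locality = "x", dry_mass_g = 1)
  rownames(meta) <- meta$sample_id
  me <- MossExperiment(t(conc), colData = meta[, -1], panel = panel)
  assignGroups(me)
}

# deterministic noise-free study: 4 ubiquitous compounds, rest censored
noiselessStudy <- function(seed = 1) {
  simulateStudy(studyDesign(seed = seed),
                trendModel(sigma = 0))
}
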