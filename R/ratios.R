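.SOURCE_LABELS <- c("Petroleum", "Combustion",
                    "Liquid fossil fuel combustion",
                    "Coal, wood or grass combustion",
                    "Petrogenic", "Pyrogenic",
                    "Fuel combustion (vehicle and crude oil)",
                    "Fuel combustion (vehicle)",
                    "Petroleum or combustion")

#' RatioRuleSet: diagnostic-ratio definitions
#'
#' A validated collection of PAH diagnostic-ratio rules. Each rule names
#' a numerator and denominator -- a single compound, a sum of compounds,
#' or the LMW/HMW weight-class aggregates -- plus an ordered list of
#' threshold intervals mapping the ratio value to an emission-source
#' label (petrogenic vs pyrogenic families). Rules are data, not code:
#' the default set ships as a YAML file and custom sets load via
#' [readRatioRules()].
#'
#' @slot rules list of rule definitions (name, numerator, denominator,
#'   intervals data.frame with lower/upper bounds, strictness flags and
#'   label; optional amended flag and note).
#' @seealso [ratioRules()], [computeRatio()], [classifyRatio()],
#'   [apportion()]
#' @export
setClass("RatioRuleSet", representation(rules = "list"))

setValidity("RatioRuleSet", function(object) {
  for (r in object@rules) {
    if (is.null(r$name) || is.null(r$numerator) || is.null(r$denominator))
      return("every rule needs name, numerator, denominator")
    iv <- r$intervals
    if (!is.data.frame(iv) || !all(c("lower", "upper", "lower_strict",
                                     "upper_strict", "label") %in% names(iv)))
      return(paste(r$name, ": malformed intervals"))
    if (!all(iv$label %in% .SOURCE_LABELS))
      return(paste(r$name, ": unknown source label",
                   setdiff(iv$label, .SOURCE_LABELS)[1]))
    if (any(iv$lower > iv$upper))
      return(paste(r$name, ": interval with lower > upper"))
    # pairwise overlap check under the open/closed convention
    if (nrow(iv) > 1) {
      for (i in seq_len(nrow(iv) - 1)) for (j in (i + 1):nrow(iv)) {
        lo <- max(iv$lower[i], iv$lower[j])
        hi <- min(iv$upper[i], iv$upper[j])
        if (lo < hi) return(paste(r$name, ": overlapping intervals"))
        if (lo == hi) {
          closed_i <- (iv$lower[i] == lo & !iv$lower_strict[i]) |
            (iv$upper[i] == lo & !iv$upper_strict[i])
          closed_j <- (iv$lower[j] == lo & !iv$lower_strict[j]) |
            (iv$upper[j] == lo & !iv$upper_strict[j])
          if (closed_i && closed_j)
            return(paste(r$name, ": intervals share a closed boundary"))
        }
      }
    }
  }
  TRUE
})

setMethod("show", "RatioRuleSet", function(object) {
  cat("RatioRuleSet:", length(object@rules), "diagnostic ratios\n")
  for (r in object@rules)
    cat(" -", r$name, if (isTRUE(r$amended)) "[amended]" else "", "\n")
})

#' @describeIn RatioRuleSet-class number of rules
#' @param x a \code{RatioRuleSet}
#' @export
setMethod("length", "RatioRuleSet", function(x) length(x@rules))

#' @describeIn RatioRuleSet-class rule names
#' @export
setMethod("names", "RatioRuleSet", function(x)
  vapply(x@rules, `[[`, "", "name"))

#' Read diagnostic-ratio rules from YAML
#'
#' @param path YAML file; see the packaged
#'   \code{extdata/diagnostic_ratios.yaml} for the schema.
#' @return a [RatioRuleSet-class].
#' @export
readRatioRules <- function(path) {
  raw <- yaml::read_yaml(path)$rules
  rules <- lapply(raw, function(r) {
    iv <- do.call(rbind, lapply(r$intervals, function(v) data.frame(
      lower = if (is.null(v$lower)) -Inf else v$lower,
      upper = if (is.null(v$upper)) Inf else v$upper,
      lower_strict = isTRUE(v$lower_strict),
      upper_strict = isTRUE(v$upper_strict),
      label = v$label, stringsAsFactors = FALSE)))
    list(name = r$name, numerator = unlist(r$numerator),
         denominator = unlist(r$denominator),
         intervals = iv, amended = isTRUE(r$amended),
         note = r$note)
  })
  names(rules) <- vapply(rules, `[[`, "", "name")
  new("RatioRuleSet", rules = rules)
}

#' The default nine-ratio rule set
#'
#' The nine diagnostic ratios conventionally used to separate petrogenic
#' from pyrogenic PAH signatures (anthracene, fluoranthene,
#' benz[a]anthracene shares; phenanthrene/anthracene;
#' indeno[1,2,3-cd]pyrene/benzo[ghi]perylene; benzo[a]pyrene ratios;
#' fluoranthene/pyrene; and the HMW/LMW aggregate ratio).
#'
#' @return a [RatioRuleSet-class] with 9 rules.
#' @export
ratioRules <- function() {
  readRatioRules(system.file("extdata", "diagnostic_ratios.yaml",
                             package = "mossPAH", mustWork = TRUE))
}

# evaluate one side (numerator or denominator) of a rule on a profile.
# conc: named numeric with NA at censored cells. Aggregate sides (LMW /
# HMW) use censored = 0 but need >= 1 uncensored member; compound sides
# need every member uncensored. Returns NA when undefined.
.evalSide <- function(tokens, conc, panel) {
  if (length(tokens) == 1 && tokens %in% c("LMW", "HMW")) {
    members <- intersect(compoundsByClass(panel, tokens), names(conc))
    if (!length(members) || all(is.na(conc[members]))) return(NA_real_)
    return(sum(conc[members], na.rm = TRUE))
  }
  idx <- panelIndex(panel, tokens)   # errors on unknown compound
  nm <- panel@compounds$name[idx]
  if (!all(nm %in% names(conc)) || anyNA(conc[nm])) return(NA_real_)
  sum(conc[nm])
}

#' Evaluate a diagnostic ratio on one profile
#'
#' Ratios are computed from uncensored values only: the ratio is
#' undefined (NA) when any required single compound is censored or the
#' denominator is zero. LMW/HMW aggregates treat censored cells as 0 but
#' require at least one uncensored member on each side.
#'
#' @param conc named numeric vector of concentrations for one sample
#'   (or one period's means), NA where censored/suppressed.
#' @param rule one rule from a [RatioRuleSet-class] (element of
#'   \code{ruleset@rules}).
#' @param panel a [PAHPanel-class].
#' @return the ratio value, or NA when undefined.
#' @export
computeRatio <- function(conc, rule, panel) {
  num <- .evalSide(rule$numerator, conc, panel)
  den <- .evalSide(rule$denominator, conc, panel)
  if (is.na(num) || is.na(den) || den == 0) return(NA_real_)
  num / den
}

#' Classify a ratio value to a source label
#'
#' Applies the rule's threshold intervals under the boundary convention:
#' strict bounds ("<a", ">b") exclude the bound, printed ranges are
#' closed, so a tie lands in the range interval. A defined value falling
#' in no interval returns "indeterminate".
#'
#' @param rule one rule from a [RatioRuleSet-class].
#' @param value numeric ratio value (NA allowed, returns NA).
#' @return source label, "indeterminate", or NA.
#' @export
classifyRatio <- function(rule, value) {
  if (is.na(value)) return(NA_character_)
  iv <- rule$intervals
  ok <- (value > iv$lower | (!iv$lower_strict & value == iv$lower)) &
        (value < iv$upper | (!iv$upper_strict & value == iv$upper))
  if (!any(ok)) return("indeterminate")
  iv$label[which(ok)[1]]
}

#' Diagnostic ratios from period mean concentrations
#'
#' The ratio-of-means engine: evaluates every rule on a table of period
#' mean concentrations (for example a published summary table). Rows
#' named \code{LMW} and \code{HMW} supply the aggregate sides; rules
#' whose inputs are absent or suppressed come back NA.
#'
#' @param means data.frame with columns \code{period}, \code{compound}
#'   (canonical name, abbreviation, or "LMW"/"HMW"), \code{mean} (NA
#'   where the period mean is suppressed/censored).
#' @param rules a [RatioRuleSet-class].
#' @param panel a [PAHPanel-class].
#' @return data.frame: period, rule, value (NA = not computable),
#'   label.
#' @export
ratiosFromMeans <- function(means, rules, panel = defaultPanel()) {
  stopifnot(is(rules, "RatioRuleSet"))
  is_agg <- means$compound %in% c("LMW", "HMW", "SigmaPAH")
  means$compound[!is_agg] <-
    panel@compounds$name[panelIndex(panel, means$compound[!is_agg])]
  out <- list()
  for (p in unique(means$period)) {
    sub <- means[means$period == p, ]
    conc <- setNames(sub$mean, sub$compound)
    for (r in rules@rules) {
      # aggregate sides: use the table's own LMW/HMW rows when present
      val <- local({
        num_t <- rule_side(r$numerator, conc)
        den_t <- rule_side(r$denominator, conc)
        if (is.na(num_t) || is.na(den_t) || den_t == 0) NA_real_
        else num_t / den_t
      })
      out[[length(out) + 1]] <- data.frame(
        period = p, rule = r$name, value = val,
        label = classifyRatio(r, val), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# side evaluation against a means table: LMW/HMW rows used verbatim;
# compound sides need every mean present and unsuppressed
rule_side <- function(tokens, conc) {
  if (length(tokens) == 1 && tokens %in% c("LMW", "HMW")) {
    v <- conc[tokens]
    return(if (is.null(v) || is.na(v)) NA_real_ else unname(v))
  }
  if (!all(tokens %in% names(conc)) || anyNA(conc[tokens]))
    return(NA_real_)
  sum(conc[tokens])
}

#' Period source apportionment
#'
#' Computes every diagnostic ratio for every period by both conventions
#' and classifies each value:
#' \describe{
#'   \item{ratio-of-means}{the rule evaluated on the period's conditional
#'     compound means (means suppressed below 2 detections) and the
#'     period LMW/HMW aggregate means.}
#'   \item{per-sample-mean}{the rule evaluated per sample, then averaged
#'     over samples where it is defined, with the observed range.}
#' }
#' Both are reported because summary tables built on period averages and
#' per-sample ratio ranges answer slightly different questions; values
#' that cannot be computed are NA (printed as "-").
#'
#' @param x a [MossExperiment-class] with decade bins assigned.
#' @param rules a [RatioRuleSet-class]; default [ratioRules()].
#' @return data.frame: period, rule, method, value, min, max,
#'   n_defined, label.
#' @export
apportion <- function(x, rules = ratioRules()) {
  stopifnot(is(x, "MossExperiment"), is(rules, "RatioRuleSet"))
  panel <- panelOf(x)
  ps <- periodSummary(x)
  agg <- ps$aggregates[ps$aggregates$class != "SigmaPAH", ]
  means <- rbind(
    data.frame(period = ps$compounds$period,
               compound = ps$compounds$compound,
               mean = ps$compounds$mean, stringsAsFactors = FALSE),
    data.frame(period = agg$period, compound = agg$class,
               mean = agg$mean, stringsAsFactors = FALSE))
  rom <- ratiosFromMeans(means, rules, panel)
  rom$method <- "ratio-of-means"
  rom$min <- NA_real_; rom$max <- NA_real_; rom$n_defined <- NA_integer_

  meta <- sampleMeta(x)
  conc <- concMatrix(x)
  psm <- list()
  for (p in unique(meta$decade)) {
    sel <- which(meta$decade == p)
    for (r in rules@rules) {
      vals <- vapply(sel, function(i)
        computeRatio(conc[i, ], r, panel), numeric(1))
      vals <- vals[!is.na(vals)]
      psm[[length(psm) + 1]] <- data.frame(
        period = p, rule = r$name,
        value = if (length(vals)) mean(vals) else NA_real_,
        label = classifyRatio(r, if (length(vals)) mean(vals)
                              else NA_real_),
        method = "per-sample-mean",
        min = if (length(vals)) min(vals) else NA_real_,
        max = if (length(vals)) max(vals) else NA_real_,
        n_defined = length(vals), stringsAsFactors = FALSE)
    }
  }
  out <- rbind(rom, do.call(rbind, c(psm, make.row.names = FALSE)))
  out <- out[order(match(out$rule, names(rules)), out$period,
                   out$method), ]
  rownames(out) <- NULL
  out[, c("period", "rule", "method", "value", "min", "max",
          "n_defined", "label")]
}
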