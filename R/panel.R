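#' @import methods
#' @importFrom utils read.csv write.csv packageVersion modifyList
#' @importFrom stats aov anova TukeyHSD p.adjust lm coef fitted rnorm
#'   runif sd setNames shapiro.test ptukey pf
#' @importFrom vegan vegdist
NULL

.WEIGHT_CLASSES <- c("LMW", "HMW")

#' PAHPanel: the targeted compound panel
#'
#' An S4 container describing the panel of polycyclic aromatic hydrocarbons
#' (PAHs) targeted by a GC-MS method. Each compound carries its canonical
#' name, a short abbreviation, the number of benzene rings (the basis of the
#' low/high-molecular-weight split), molecular weight, an optional IARC
#' carcinogenicity label, the deuterated internal-standard partner used for
#' quantification, and the limit of quantification (LOQ, ng per g dry
#' weight) below which measurements are censored.
#'
#' The weight class is derived, never stored independently: a compound is
#' low molecular weight (LMW) when it has fewer than four benzene rings and
#' high molecular weight (HMW) otherwise. Note the count is of benzene
#' (six-membered aromatic) rings, so fluoranthene -- three benzene rings
#' fused around a five-membered ring -- is LMW even though it has four
#' fused rings in total.
#'
#' @slot compounds data.frame with columns \code{name},
#'   \code{abbreviation}, \code{benzene_rings}, \code{mw}, \code{iarc},
#'   \code{is_partner}, \code{loq} and the derived \code{weight_class}.
#' @slot name single character label for the panel.
#'
#' @seealso [defaultPanel()], [readPanel()], [weightClass()]
#' @export
setClass("PAHPanel",
  representation(compounds = "data.frame", name = "character"))

setValidity("PAHPanel", function(object) {
  cmp <- object@compounds
  needed <- c("name", "abbreviation", "benzene_rings", "mw", "iarc",
              "is_partner", "loq", "weight_class")
  if (!all(needed %in% names(cmp)))
    return(paste("compounds must have columns:",
                 paste(setdiff(needed, names(cmp)), collapse = ", ")))
  if (anyDuplicated(cmp$name))
    return("compound names must be unique")
  if (anyDuplicated(cmp$abbreviation))
    return("compound abbreviations must be unique")
  if (any(cmp$benzene_rings < 2 | cmp$benzene_rings != round(cmp$benzene_rings)))
    return("benzene_rings must be integers >= 2")
  if (any(!is.finite(cmp$loq)) || any(cmp$loq <= 0))
    return("loq must be finite and > 0")
  derived <- ifelse(cmp$benzene_rings < 4, "LMW", "HMW")
  if (!identical(as.character(cmp$weight_class), derived))
    return("weight_class must equal LMW iff benzene_rings < 4")
  TRUE
})

#' Construct a PAH panel
#'
#' @param compounds data.frame with columns \code{name},
#'   \code{abbreviation}, \code{benzene_rings}, \code{mw}; optional columns
#'   \code{iarc}, \code{is_partner}, \code{loq} (LOQ defaults to 5 ng/g).
#'   The \code{weight_class} column is always (re)derived from
#'   \code{benzene_rings}.
#' @param name label for the panel.
#' @return a [PAHPanel-class] object.
#' @export
PAHPanel <- function(compounds, name = "custom") {
  compounds <- as.data.frame(compounds)
  if (is.null(compounds$iarc)) compounds$iarc <- NA_character_
  if (is.null(compounds$is_partner)) compounds$is_partner <- NA_character_
  if (is.null(compounds$loq)) compounds$loq <- 5
  compounds$weight_class <- ifelse(compounds$benzene_rings < 4, "LMW", "HMW")
  rownames(compounds) <- NULL
  new("PAHPanel", compounds = compounds, name = name)
}

#' The default 19-compound panel
#'
#' The 16 US-EPA priority PAHs plus three further compounds commonly
#' targeted in atmospheric deposition work (retene, benzo[e]pyrene,
#' perylene). LOQs default to 5 ng per g dry weight and are meant to be
#' overridden with method-specific values via [readPanel()] or by editing
#' the returned object.
#'
#' @param loq optional named numeric vector of LOQ overrides
#'   (names = compound names or abbreviations).
#' @return a [PAHPanel-class] with 19 compounds.
#' @examples
#' p <- defaultPanel()
#' weightClass(p, "fluoranthene")   # "LMW": three benzene rings
#' weightClass(p, "pyrene")         # "HMW"
#' @export
defaultPanel <- function(loq = NULL) {
  path <- system.file("extdata", "pah_panel.csv", package = "mossPAH",
                      mustWork = TRUE)
  panel <- readPanel(path, name = "epa16+3")
  if (!is.null(loq)) {
    cmp <- panel@compounds
    idx <- match(names(loq), cmp$name)
    idx2 <- match(names(loq), cmp$abbreviation)
    idx[is.na(idx)] <- idx2[is.na(idx)]
    if (anyNA(idx))
      stop("unknown compound in loq overrides: ",
           paste(names(loq)[is.na(idx)], collapse = ", "))
    cmp$loq[idx] <- unname(loq)
    panel <- PAHPanel(cmp, name = panel@name)
  }
  panel
}

#' Read a panel definition from CSV or YAML
#'
#' @param path file with columns/keys \code{name}, \code{abbreviation},
#'   \code{benzene_rings}, \code{mw}, and optionally \code{iarc},
#'   \code{is_partner}, \code{loq}.
#' @param name panel label; defaults to the file name.
#' @return a [PAHPanel-class].
#' @export
readPanel <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  tab <- if (ext %in% c("yml", "yaml")) {
    do.call(rbind, lapply(yaml::read_yaml(path)$compounds, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
  } else {
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  PAHPanel(tab, name = name)
}

#' @describeIn PAHPanel-class number of compounds
#' @param x,object a \code{PAHPanel}
#' @export
setMethod("length", "PAHPanel", function(x) nrow(x@compounds))

#' @describeIn PAHPanel-class canonical compound names
#' @export
setMethod("names", "PAHPanel", function(x) x@compounds$name)

setMethod("show", "PAHPanel", function(object) {
  cmp <- object@compounds
  cat("PAHPanel '", object@name, "': ", nrow(cmp), " compounds (",
      sum(cmp$weight_class == "LMW"), " LMW, ",
      sum(cmp$weight_class == "HMW"), " HMW)\n", sep = "")
  cat(" ", paste(cmp$abbreviation, collapse = " "), "\n")
})

#' Resolve compound identifiers against a panel
#'
#' Accepts canonical names or abbreviations; errors on anything unknown.
#' @param panel a [PAHPanel-class]
#' @param compounds character vector of names or abbreviations
#' @return integer row indices into the panel
#' @keywords internal
panelIndex <- function(panel, compounds) {
  cmp <- panel@compounds
  idx <- match(compounds, cmp$name)
  idx2 <- match(compounds, cmp$abbreviation)
  idx[is.na(idx)] <- idx2[is.na(idx)]
  if (anyNA(idx))
    stop("compound(s) not in panel '", panel@name, "': ",
         paste(unique(compounds[is.na(idx)]), collapse = ", "))
  idx
}

#' Weight class of panel compounds
#'
#' Low molecular weight (LMW) for fewer than four benzene rings, high
#' molecular weight (HMW) otherwise.
#'
#' @param panel a [PAHPanel-class]
#' @param compounds compound names or abbreviations; default all.
#' @return character vector of "LMW"/"HMW", named by compound.
#' @export
weightClass <- function(panel, compounds = names(panel)) {
  idx <- panelIndex(panel, compounds)
  setNames(panel@compounds$weight_class[idx], compounds)
}

#' Limits of quantification
#' @param panel a [PAHPanel-class]
#' @return named numeric vector (ng per g dry weight), names = compound names
#' @export
panelLOQ <- function(panel) {
  setNames(panel@compounds$loq, panel@compounds$name)
}

#' Compounds of one weight class
#' @param panel a [PAHPanel-class]
#' @param class "LMW" or "HMW"
#' @return character vector of compound names
#' @export
compoundsByClass <- function(panel, class = c("LMW", "HMW")) {
  class <- match.arg(class)
  panel@compounds$name[panel@compounds$weight_class == class]
}
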