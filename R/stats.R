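#' Per-compound one-way ANOVA across decades or eras
#'
#' For each retained compound (and optionally the per-sample total PAH
#' sum) a one-way ANOVA of log-scale concentration on the grouping
#' factor, with Benjamini-Hochberg FDR correction across the compound
#' family. Two-group contrasts (coal vs oil era) run through the same
#' machinery; there F equals the squared pooled two-sample t statistic.
#' Groups with fewer than 2 samples are dropped with a warning.
#'
#' @param x an [AnalysisMatrix-class], normally log-transformed.
#' @param groups character/factor per sample (decade or era labels).
#' @param compounds columns to test; default all columns of \code{x}.
#' @param include_total also test the per-sample total (computed on the
#'   raw scale, then re-transformed like \code{x}).
#' @return data.frame: response, grouping arity, F, df_between,
#'   df_within, p, p_adj (BH across compound rows only; the total row is
#'   reported unadjusted alongside).
#' @export
anovaPerCompound <- function(x, groups, compounds = NULL,
                             include_total = TRUE) {
  stopifnot(is(x, "AnalysisMatrix"))
  v <- x@values
  if (length(groups) != nrow(v))
    stop("groups must have one label per sample")
  if (is.null(compounds)) compounds <- colnames(v)
  compounds <- intersect(compounds, colnames(v))
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("group(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    v <- v[keep, , drop = FALSE]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 2 samples")
  g <- factor(groups)

  responses <- lapply(compounds, function(cc) v[, cc])
  names(responses) <- compounds
  if (include_total) {
    raw <- if (x@transform == "log") invTransform(x) else x
    tot <- rowSums(raw@values)
    responses$SigmaPAH <- if (x@transform == "log")
      log(tot + x@offset) else tot
  }
  rows <- lapply(names(responses), function(nm) {
    a <- anova(aov(responses[[nm]] ~ g))
    data.frame(response = nm, grouping = nlevels(g),
               F = a[1, "F value"], df_between = a[1, "Df"],
               df_within = a[2, "Df"], p = a[1, "Pr(>F)"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  is_cmp <- out$response != "SigmaPAH"
  out$p_adj <- NA_real_
  out$p_adj[is_cmp] <- fdrAdjust(out$p[is_cmp])
  out$p_adj[!is_cmp] <- out$p[!is_cmp]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate correction across a family of p values
#' (a thin, named wrapper over \code{p.adjust(method = "BH")} so the
#' adjustment used throughout the package is a single auditable choice).
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, same order.
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must be in [0,1]")
  p.adjust(p, method = "BH")
}

#' Tukey HSD pairwise contrasts with compact letters
#'
#' All-pairs comparison of group means by the studentized range
#' (Tukey-Kramer for unbalanced groups), plus a compact letter display:
#' groups sharing a letter are not significantly different at
#' \code{alpha}.
#'
#' @param values numeric response vector.
#' @param groups group labels, at least 2 groups.
#' @param alpha family-wise significance level for the letters.
#' @return list: \code{pairs} (data.frame group_a, group_b, diff, lwr,
#'   upr, p_adj), \code{letters} (named character per group).
#' @export
tukeyHsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  tk <- TukeyHSD(aov(values ~ g), conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(group_a = vapply(nm, `[`, "", 1),
                      group_b = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       letters = compactLetters(pairs, levels(g), alpha))
}

# insert-absorb compact letter display: groups sharing a letter are not
# significantly different (pairs with p_adj < alpha must not share one)
compactLetters <- function(pairs, groups, alpha = 0.05) {
  sig <- pairs[!is.na(pairs$p_adj) & pairs$p_adj < alpha, , drop = FALSE]
  sets <- list(groups)                      # start: one letter for all
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    both <- vapply(sets, function(s) all(c(a, b) %in% s), logical(1))
    for (j in which(both)) {
      s <- sets[[j]]
      sets[[j]] <- setdiff(s, a)
      sets[[length(sets) + 1]] <- setdiff(s, b)
    }
    # absorb: drop sets contained in another
    keep <- !vapply(seq_along(sets), function(j)
      any(vapply(seq_along(sets), function(k)
        k != j && all(sets[[j]] %in% sets[[k]]), logical(1))), logical(1))
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) min(match(s, groups)), 1L))]
  lab <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(sets))
    lab[sets[[j]]] <- paste0(lab[sets[[j]]], letters[j])
  lab
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over compounds, computed
#' with \code{vegan::vegdist}. A pair of all-zero profiles has an
#' undefined quotient; it is reported as 0 and flagged via the
#' \code{allzero_pairs} attribute.
#'
#' @param x an [AnalysisMatrix-class] (raw scale) or nonnegative matrix,
#'   samples x compounds.
#' @return symmetric matrix in [0, 1] with zero diagonal.
#' @export
brayCurtis <- function(x) {
  v <- if (is(x, "AnalysisMatrix")) x@values else x
  if (any(v < 0)) stop("Bray-Curtis requires nonnegative values")
  # vegdist warns on all-zero pairs; those cells are defined below
  d <- as.matrix(suppressWarnings(vegan::vegdist(v, method = "bray")))
  zero_rows <- rowSums(v) == 0
  nz <- outer(zero_rows, zero_rows, `&`)
  if (any(nz)) d[nz] <- 0                    # both profiles empty
  diag(d) <- 0
  attr(d, "allzero_pairs") <- sum(nz[upper.tri(nz)])
  d
}

#' Dissimilarity trends across decades
#'
#' Groups the pairwise Bray-Curtis values by unordered decade-pair
#' category (within-1920s, 1920s vs 1940s, ...; 5 decades give 15
#' categories) and runs ANOVA plus Tukey HSD across the categories. The
#' pairs are not independent observations -- each sample enters many
#' pairs -- so the result carries an explicit caveat flag.
#'
#' @param d dissimilarity matrix from [brayCurtis()].
#' @param decades decade label per sample (matrix row).
#' @param alpha significance level for the letter display.
#' @return list: \code{categories} (category, n_pairs, mean_dissimilarity),
#'   \code{anova} (F, df, p), \code{tukey} (pairs + letters),
#'   \code{caveat} = TRUE (non-independent pairs).
#' @export
dissimilarityByDecade <- function(d, decades, alpha = 0.05) {
  stopifnot(nrow(d) == length(decades))
  n <- nrow(d)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  a <- decades[ij[, 1]]; b <- decades[ij[, 2]]
  cat_ <- ifelse(a == b, a,
                 paste(pmin(a, b), pmax(a, b), sep = " vs "))
  val <- d[upper.tri(d)]
  tab <- table(cat_)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("pair categor(ies) with < 2 pairs excluded: ",
            paste(small, collapse = ", "))
    keep <- !cat_ %in% small
    cat_ <- cat_[keep]; val <- val[keep]
  }
  g <- factor(cat_)
  av <- anova(aov(val ~ g))
  categories <- data.frame(category = levels(g),
                           n_pairs = as.integer(table(g)),
                           mean_dissimilarity =
                             as.numeric(tapply(val, g, mean)),
                           stringsAsFactors = FALSE)
  list(categories = categories,
       anova = data.frame(F = av[1, "F value"], df_between = av[1, "Df"],
                          df_within = av[2, "Df"], p = av[1, "Pr(>F)"]),
       tukey = tukeyHsd(val, cat_, alpha = alpha),
       caveat = TRUE)
}
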