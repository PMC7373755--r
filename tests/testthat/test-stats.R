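# brute-force BH step-up, written from the definition: adjusted p of the
# i-th smallest is min over j >= i of p_(j) * m / j, capped at 1
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

test_that("BH adjustment matches a brute-force oracle", {
  expect_equal(fdrAdjust(0.03), 0.03)                    # single p
  expect_equal(fdrAdjust(rep(0.2, 5)), rep(0.2, 5))      # all equal
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(fdrAdjust(p), bruteForceBH(p))
  }
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("BH is monotone in raw p and idempotent", {
  set.seed(18)
  p <- runif(25)
  adj <- fdrAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_equal(fdrAdjust(adj) >= adj, rep(TRUE, 25))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(21)
  v <- matrix(rnorm(30, 10), 30, 1, dimnames = list(NULL, "phenanthrene"))
  am <- new("AnalysisMatrix", values = v, transform = "raw", offset = 0)
  g <- rep(c("coal", "oil"), each = 15)
  res <- anovaPerCompound(am, g, include_total = FALSE)
  tt <- t.test(v[g == "coal", 1], v[g == "oil", 1], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df_between, 1)
})

test_that("vanishing effects drive p toward 1", {
  v0 <- rep(c(1, 2, 3), 4)
  am <- new("AnalysisMatrix",
            values = matrix(v0 + c(1e-9, 0), 12, 1,
                            dimnames = list(NULL, "pyrene")),
            transform = "raw", offset = 0)
  res <- anovaPerCompound(am, rep(c("a", "b"), each = 6),
                          include_total = FALSE)
  expect_lt(res$F, 1e-10)
  expect_gt(res$p, 0.999)
})

test_that("undersized groups are dropped with a warning", {
  set.seed(22)
  am <- new("AnalysisMatrix",
            values = matrix(rnorm(9, 10), 9, 1,
                            dimnames = list(NULL, "pyrene")),
            transform = "raw", offset = 0)
  g <- c(rep("a", 4), rep("b", 4), "c")
  expect_warning(res <- anovaPerCompound(am, g, include_total = FALSE),
                 "excluded")
  expect_equal(res$df_between, 1)
  expect_error(suppressWarnings(
    anovaPerCompound(am, c(rep("a", 8), "c"), include_total = FALSE)),
    "2 groups")
})

test_that("two-group Tukey equals the pooled t-test", {
  set.seed(23)
  x <- rnorm(12, 5); y <- rnorm(14, 5.5)
  tk <- tukeyHsd(c(x, y), rep(c("a", "b"), c(12, 14)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$pairs$p_adj, tt$p.value, tolerance = 1e-6)
  # identical groups: p ~ 1, shared letter
  tk2 <- tukeyHsd(rep(c(1, 2, 3), 4), rep(c("a", "b"), 6))
  expect_gt(tk2$pairs$p_adj, 0.9)
  expect_equal(unname(tk2$letters["a"]), unname(tk2$letters["b"]))
})

test_that("a strongly shifted group always earns a unique letter", {
  unique_letter <- 0
  for (i in 1:100) {
    set.seed(300 + i)
    v <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 5))  # 5-sigma shift
    g <- rep(c("a", "b", "c"), each = 10)
    lt <- tukeyHsd(v, g)$letters
    unique_letter <- unique_letter +
      (!lt["c"] %in% lt[c("a", "b")] && nchar(lt["c"]) == 1)
  }
  expect_equal(unique_letter, 100)
  expect_error(tukeyHsd(rnorm(5), rep("a", 5)), "2 groups")
})

test_that("Bray-Curtis matches hand arithmetic and its axioms", {
  x <- rbind(s1 = c(1, 2), s2 = c(3, 0), s3 = c(1, 2))
  expect_equal(brayCurtis(x)["s1", "s2"], 4 / 6, tolerance = 1e-12)
  expect_equal(brayCurtis(x)["s1", "s3"], 0)             # identical
  disj <- rbind(a = c(1, 0), b = c(0, 2))
  expect_equal(brayCurtis(disj)["a", "b"], 1)            # disjoint
  expect_error(brayCurtis(rbind(c(-1, 2), c(1, 1))), "nonnegative")
  set.seed(41)
  for (i in 1:10) {
    m <- matrix(rexp(60), 10, 6)
    d <- brayCurtis(m)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_true(all(diag(d) == 0))
  }
  withzero <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  dz <- brayCurtis(withzero)
  expect_equal(dz["a", "b"], 0)
  expect_equal(attr(dz, "allzero_pairs"), 1)
})

test_that("decade-pair dissimilarity categories behave as designed", {
  # 5 decades, 3 identical samples each: 15 categories, all-zero means
  decs <- rep(c("1920s", "1940s", "1950s", "1960s", "1970s"), each = 3)
  m <- matrix(rep(c(5, 3), each = 15), 15, 2)
  d0 <- brayCurtis(m)
  res <- suppressWarnings(dissimilarityByDecade(d0, decs))
  expect_equal(nrow(res$categories), 15)     # 5 within + 10 between
  expect_true(all(res$categories$mean_dissimilarity == 0))
  expect_true(res$caveat)
  # scaling one decade tenfold raises its between-decade dissimilarity
  m2 <- m
  m2[decs == "1920s", ] <- m2[decs == "1920s", ] * 10
  res2 <- suppressWarnings(dissimilarityByDecade(brayCurtis(m2), decs))
  cats <- res2$categories
  between20 <- grepl("1920s vs", cats$category)
  within <- !grepl(" vs ", cats$category)
  expect_gt(min(cats$mean_dissimilarity[between20]),
            max(cats$mean_dissimilarity[within]))
})

test_that("coal-era enrichment is detected through the era contrast", {
  # a doubled coal-era fluoranthene signal should reach p < 0.001
  grid <- matrix(c(11, 10, 11, 10), 1, 4,
                 dimnames = list("Hylocomium splendens",
                                 c("1920s", "1940s", "1950s", "1970s")))
  tm <- trendModel(baseline = c(fluoranthene = 160),
                   decade_factors = c("1920s" = 1, "1940s" = 1,
                                      "1950s" = 0.5, "1970s" = 0.5),
                   sigma = 0.4)
  sim <- simulateStudy(studyDesign(species_by_decade = grid, seed = 77),
                       tm)
  meta <- assignGroups(sim$meta)
  am <- new("AnalysisMatrix", values = sim$truth, transform = "raw",
            offset = 0)
  res <- anovaPerCompound(logTransform(am), meta$era,
                          include_total = FALSE)
  expect_lt(res$p, 0.001)
})
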