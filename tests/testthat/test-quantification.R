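test_that("calibration recovers an exact line", {
  cal <- data.frame(compound = "pyrene", analyte_ng = (1:6) * 100,
                    is_ng = 1600,
                    analyte_area = 2 * (1:6) * 100 / 1600, is_area = 1)
  m <- fitCalibration(cal)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1)
  expect_equal(m$n_points, 6)
})

test_that("degenerate calibrations error", {
  one <- data.frame(compound = "pyrene", analyte_ng = 100, is_ng = 1600,
                    analyte_area = 1, is_area = 1)
  expect_error(fitCalibration(one), "distinct amount ratios")
  flat <- one[c(1, 1), ]
  expect_error(fitCalibration(flat), "distinct amount ratios")
})

test_that("noisy calibration slope lands within 3 standard errors", {
  set.seed(7)
  ok <- 0
  for (i in 1:20) {
    x <- (1:6) * 100 / 1600
    y <- 1.8 * x * (1 + rnorm(6, 0, 0.05))
    cal <- data.frame(compound = "flt", analyte_ng = (1:6) * 100,
                      is_ng = 1600, analyte_area = y, is_area = 1)
    m <- fitCalibration(cal)
    se <- summary(lm(y ~ x))$coefficients["x", "Std. Error"]
    ok <- ok + (abs(m$slope - 1.8) <= 3 * se)
  }
  expect_gte(ok, 17)   # per-replicate coverage well above 90%
})

test_that("quantification arithmetic and censoring conventions hold", {
  m <- data.frame(compound = "pyrene", slope = 1, intercept = 0,
                  r_squared = 1, n_points = 6)
  areas <- data.frame(sample_id = "s1", compound = "pyrene",
                      analyte_area = 0.5, is_area = 1)
  q <- quantifyAreas(areas, m, c(s1 = 1.0))
  expect_equal(q$concentration, 800)       # 0.5 * 1600 / 1.0
  q2 <- quantifyAreas(areas, m, c(s1 = 2.0))
  expect_equal(q2$concentration, 400)      # inverse in dry mass
  # at-LOQ value retained, below-LOQ censored, negative censored
  q3 <- quantifyAreas(areas, m, c(s1 = 1.0), loq = c(pyrene = 800))
  expect_false(q3$censored)
  q4 <- quantifyAreas(areas, m, c(s1 = 1.0), loq = c(pyrene = 800.1))
  expect_true(q4$censored)
  expect_true(is.na(q4$concentration))
  neg <- data.frame(sample_id = "s1", compound = "pyrene",
                    analyte_area = -0.1, is_area = 1)
  expect_true(quantifyAreas(neg, m, c(s1 = 1))$censored)
  bad <- m; bad$slope <- -1
  expect_error(quantifyAreas(areas, bad, c(s1 = 1)), "slope")
  expect_error(quantifyAreas(areas, m, c(s1 = -1)), "dry mass")
})

test_that("concentrations are invariant to a global area rescaling", {
  sim <- noiselessStudy(seed = 4)
  pk <- simulatePeakAreas(sim$truth, sim$meta, rf = 1.5, noise_cv = 0)
  dm <- setNames(sim$meta$dry_mass_g, sim$meta$sample_id)
  q1 <- quantifyAreas(pk$areas, fitCalibration(pk$calibration), dm)
  pk2 <- pk
  pk2$areas$analyte_area <- pk2$areas$analyte_area * 7
  pk2$calibration$analyte_area <- pk2$calibration$analyte_area * 7
  q2 <- quantifyAreas(pk2$areas, fitCalibration(pk2$calibration), dm)
  expect_equal(q2$concentration, q1$concentration, tolerance = 1e-9)
})

test_that("noise-free simulate-then-quantify recovers truth cellwise", {
  sim <- noiselessStudy(seed = 6)
  pk <- simulatePeakAreas(sim$truth, sim$meta, rf = 2.2, noise_cv = 0)
  dm <- setNames(sim$meta$dry_mass_g, sim$meta$sample_id)
  q <- quantifyAreas(pk$areas, fitCalibration(pk$calibration), dm)
  got <- matrix(q$concentration, nrow(sim$truth),
                dimnames = dimnames(sim$truth))
  expect_equal(got, sim$truth, tolerance = 1e-9)
})

test_that("recovery correction rescales by the paired standard", {
  panel <- miniPanel()
  q <- data.frame(sample_id = "s1",
                  compound = c("phenanthrene", "pyrene"),
                  concentration = c(100, 50), censored = FALSE)
  rec1 <- data.frame(sample_id = "s1", standard = "phenanthrene-d10",
                     fraction = 1)
  expect_equal(recoveryCorrect(q, rec1, panel)$concentration,
               q$concentration)
  rec05 <- transform(rec1, fraction = 0.5)
  expect_equal(recoveryCorrect(q, rec05, panel)$concentration,
               c(200, 100))
  rec_meas <- data.frame(sample_id = "s1",
                         standard = "phenanthrene-d10",
                         measured_ng = 1280, spiked_ng = 1600)
  expect_equal(recoveryCorrect(q, rec_meas, panel)$recovery,
               c(0.8, 0.8))
  expect_error(recoveryCorrect(q, transform(rec1, fraction = 0), panel),
               "recovery")
})

test_that("simulated extraction loss is undone by recovery correction", {
  sim <- noiselessStudy(seed = 9)
  pk <- simulatePeakAreas(sim$truth, sim$meta, rf = 1, noise_cv = 0)
  pk$areas$analyte_area <- pk$areas$analyte_area * 0.8   # 80% recovery
  dm <- setNames(sim$meta$dry_mass_g, sim$meta$sample_id)
  q <- quantifyAreas(pk$areas, fitCalibration(pk$calibration), dm)
  panel <- defaultPanel()
  rec <- expand.grid(sample_id = sim$meta$sample_id,
                     standard = unique(panel@compounds$is_partner),
                     stringsAsFactors = FALSE)
  rec$fraction <- 0.8
  qc <- recoveryCorrect(q, rec, panel)
  got <- matrix(qc$concentration, nrow(sim$truth),
                dimnames = dimnames(sim$truth))
  expect_equal(got, sim$truth, tolerance = 0.02)
})
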