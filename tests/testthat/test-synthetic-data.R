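test_that("feature tables are reproducible and honor the generative model", {
  bd <- batch_design(20, list(
    list(name = "b", levels = c("A", "B"), gamma = c(0, 1), delta = c(1, 2))))
  pd <- phenotype_design(effect_size = 0, affected_fraction = 0)
  s1 <- simulate_feature_table(200, 20, bd, pd, seed = 42)
  s2 <- simulate_feature_table(200, 20, bd, pd, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_feature_table(200, 20, bd, pd, seed = 43)
  expect_false(identical(s1$features, s3$features))

  # no planted batch effect: per-batch means differ only by sampling noise
  bd0 <- batch_design(20, list(list(name = "b", levels = c("A", "B"))))
  s0 <- simulate_feature_table(500, 20, bd0, pd, seed = 7)
  p <- t.test(s0$features[, 1] ~ s0$cohort$b)$p.value
  expect_gt(p, 0.001)

  # law of large numbers: planted gamma = 1, delta = 2 recovered
  # (n chosen so the +/-0.15 band is ~4 standard errors of each gap)
  sL <- simulate_feature_table(8000, 20, bd, pd, seed = 9)
  b <- sL$cohort$b
  gaps <- colMeans(sL$features[b == "B", ]) - colMeans(sL$features[b == "A", ])
  rats <- apply(sL$features[b == "B", ], 2, sd) /
    apply(sL$features[b == "A", ], 2, sd)
  expect_true(all(abs(gaps - 1) < 0.15))
  expect_true(all(abs(rats - 2) < 0.2))
})

test_that("planted effects are recoverable by OLS within 3 SE at n = 1000", {
  bd <- batch_design(10, list(
    list(name = "b", levels = c("A", "B"), gamma = c(0, 0.7),
         delta = c(1, 1.5))))
  pd <- phenotype_design(effect_size = 0, affected_fraction = 0)
  s <- simulate_feature_table(1000, 10, bd, pd, seed = 5)
  ind <- as.integer(s$cohort$b == "B")
  for (g in c(1, 4, 10)) {
    fit <- summary(lm(s$features[, g] ~ ind))$coefficients
    expect_lt(abs(fit["ind", "Estimate"] - 0.7), 3 * fit["ind", "Std. Error"])
  }
})

test_that("batch levels with < 2 patients error; invalid designs rejected", {
  bd <- batch_design(5, list(
    list(name = "b", levels = c("A", "B"), probs = c(0.999, 0.001))))
  pd <- phenotype_design()
  expect_error(simulate_feature_table(20, 5, bd, pd, seed = 1),
               "< 2 patients")
  expect_error(batch_design(5, list(list(name = "b", levels = c("A", "B"),
                                         delta = c(1, -1)))),
               "strictly positive")
  expect_error(batch_design(5, list(list(name = "b", levels = c("A", "B"),
                                         probs = c(0.4, 0.4)))),
               "sum to 1")
  expect_error(phenotype_design(class_proportions = c(0.2, 0.3)), "sum to 1")
})

test_that("confounding knob tilts the phenotype-batch odds ratio", {
  bd <- batch_design(5, list(list(name = "b", levels = c("A", "B"))))
  pd <- phenotype_design()
  s <- simulate_feature_table(4000, 5, bd, pd, seed = 3, confounding_or = 4)
  tab <- table(s$cohort$phenotype, s$cohort$b)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or, 2.5)
  expect_lt(or, 6)
})

test_that("survival generator matches its closed-form behavior", {
  bd <- batch_design(5, list(list(name = "b", levels = c("A", "B"))))
  co <- simulate_feature_table(500, 5, bd, phenotype_design(), seed = 2)$cohort

  # no censoring: every patient has an event
  d0 <- survival_design(baseline_rate = 0.2, phenotype_loghr = 0,
                        covariate_loghr = c(covar1 = 0), censoring_rate = 0)
  expect_true(all(simulate_survival(co, d0, seed = 1)$event == 1))

  # censoring fraction matches the competing-exponentials formula at n=2000
  co2 <- simulate_feature_table(2000, 5, bd, phenotype_design(
    effect_size = 0, affected_fraction = 0), seed = 4)$cohort
  dc <- survival_design(baseline_rate = 0.1, phenotype_loghr = 0,
                        covariate_loghr = c(covar1 = 0),
                        censoring_rate = 0.05)
  sv <- simulate_survival(co2, dc, seed = 6)
  expect_lt(abs(mean(sv$event == 0) - 0.05 / 0.15), 0.05)

  # phenotype log-HR = 1: event-rate ratio between classes near e
  de <- survival_design(baseline_rate = 0.1, phenotype_loghr = 1,
                        covariate_loghr = c(covar1 = 0), censoring_rate = 0)
  co3 <- simulate_feature_table(1000, 5, bd, phenotype_design(
    effect_size = 0, affected_fraction = 0), seed = 8)$cohort
  sv3 <- simulate_survival(co3, de, seed = 9)
  mt <- tapply(sv3$time, sv3$phenotype, mean)
  ratio <- mt[["1"]] / mt[["2"]]   # mean time inversely prop. to rate
  expect_lt(abs(ratio - exp(1)), 0.4)

  # all-censored output warns and is flagged
  dall <- survival_design(baseline_rate = 1e-6, phenotype_loghr = 0,
                          covariate_loghr = c(covar1 = 0),
                          censoring_rate = 10)
  expect_warning(svc <- simulate_survival(co, dall, seed = 1),
                 "censored")
  expect_true(isTRUE(attr(svc, "all_censored")))
})

test_that("downstream C on a no-signal cohort is near 0.5", {
  bd <- batch_design(5, list(list(name = "b", levels = c("A", "B"))))
  co <- simulate_feature_table(500, 5, bd, phenotype_design(
    effect_size = 0, affected_fraction = 0), seed = 12)$cohort
  d <- survival_design(baseline_rate = 0.1, phenotype_loghr = 0,
                       covariate_loghr = c(covar1 = 0),
                       censoring_rate = 0.03)
  sv <- simulate_survival(co, d, seed = 13)
  risk <- rnorm(500)   # arbitrary risk, no signal
  expect_gt(c_statistic(risk, sv$time, sv$event), 0.45)
  expect_lt(c_statistic(risk, sv$time, sv$event), 0.55)
})

test_that("image generator plants acquisition effects and texture classes", {
  sim <- simulate_images(30, seed = 3)
  expect_length(sim$images, 30)
  expect_true(all(vapply(sim$images, function(im) sum(im$mask), 0) >= 50))
  # spacing metadata carried per image
  sp <- t(vapply(sim$images, function(im) im$spacing, numeric(3)))
  expect_setequal(unique(sp[, 1]), c(0.7, 1.0))

  # contrast-enhancement offset approximately +100 in ROI means
  roi_means <- vapply(seq_len(30), function(i)
    mean(sim$images[[i]]$intensities[sim$images[[i]]$mask]), 0)
  dm <- diff(tapply(roi_means, sim$cohort$contrast, mean))
  expect_lt(abs(abs(dm) - 100), 5)

  # identical seed reproduces everything bit for bit
  sim2 <- simulate_images(30, seed = 3)
  expect_identical(sim, sim2)

  # degenerate ellipsoid: a semi-axis below 2 voxels errors
  expect_error(simulate_images(2, base_shape = c(24, 24, 4), seed = 1),
               "degenerate ellipsoid")
})

test_that("planted texture classes separate on NGTDM coarseness (pinned)", {
  sim <- simulate_images(40, seed = 3)
  fx <- extract_cohort_features(sim$images,
                                extraction_params(families = c("ngtdm")),
                                ids = sim$cohort$patient_id)
  v <- split(fx[, "ngtdm_coarseness"], sim$cohort$phenotype)
  es <- abs(diff(vapply(v, mean, 0))) / sqrt(mean(vapply(v, var, 0)))
  expect_gt(es, 1)
})
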