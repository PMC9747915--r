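sim_surv <- function(n, beta_x = 0, seed = 1, censor = 0.05) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- rexp(n, rate = 0.1 * exp(beta_x * x))
  t_c <- if (censor > 0) rexp(n, censor) else rep(Inf, n)
  list(x = x, time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

test_that("group_by_batch dichotomizes with the >= boundary rule", {
  co <- data.frame(patient_id = 1:4,
                   pixel_spacing = c(0.7, 0.8, 0.78, 1.1),
                   kernel = factor(c("soft", "sharp", "soft", "sharp")))
  g <- group_by_batch(co, "pixel_spacing", threshold = 0.78)
  expect_identical(as.character(g$groups),
                   c("<0.78", ">=0.78", ">=0.78", ">=0.78"))
  g2 <- group_by_batch(co, "kernel")
  expect_identical(levels(g2$groups), c("sharp", "soft"))
  expect_error(group_by_batch(co, "pixel_spacing", threshold = 5), "empty")
  expect_error(group_by_batch(co, "nope"), "not in cohort")
})

test_that("c_statistic matches its definition and the enumeration oracle", {
  expect_equal(c_statistic(c(2, 1), c(1, 2), c(1, 1)), 1)
  expect_equal(c_statistic(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)

  # 6-patient fixture with censoring vs brute force
  risk <- c(0.3, -1, 2, 0.5, 0, 1)
  time <- c(5, 3, 9, 1, 7, 4)
  event <- c(1, 0, 1, 1, 0, 1)
  expect_identical(c_statistic(risk, time, event),
                   cstat_oracle(risk, time, event))

  # tied times and tied risks against the oracle
  set.seed(21)
  for (i in 1:20) {
    n <- 15
    r <- sample(1:4, n, TRUE); tm <- sample(1:6, n, TRUE)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    got <- tryCatch(c_statistic(r, tm, ev), error = function(e) NA)
    want <- tryCatch(cstat_oracle(r, tm, ev), error = function(e) NA)
    if (!is.na(got) || !is.na(want)) expect_equal(got, want)
  }

  expect_error(c_statistic(1:3, 3:1, c(0, 0, 0)), "comparable")
})

test_that("C is invariant to monotone risk transforms and complements", {
  s <- sim_surv(80, beta_x = 0.8, seed = 3)
  c1 <- c_statistic(s$x, s$time, s$event)
  expect_equal(c_statistic(exp(3 * s$x), s$time, s$event), c1)
  expect_equal(c_statistic(s$x, s$time, s$event) +
                 c_statistic(-s$x, s$time, s$event), 1)
})

test_that("fit_cox recovers planted effects and matches the likelihood
           oracle", {
  # null covariate: small coefficient
  s0 <- sim_surv(500, beta_x = 0, seed = 5)
  f0 <- fit_cox(data.frame(x = s0$x), s0$time, s0$event)
  expect_lt(abs(f0$coefficients[["x"]]), 0.2)

  # planted log-HR 1 recovered
  s1 <- sim_surv(1000, beta_x = 1, seed = 6)
  f1 <- fit_cox(data.frame(x = s1$x), s1$time, s1$event)
  expect_gt(f1$coefficients[["x"]], 0.8)
  expect_lt(f1$coefficients[["x"]], 1.2)

  # 8-patient no-ties fixture: matches grid-search partial likelihood
  x8 <- c(0.1, -0.4, 1.2, 0.8, -1.0, 0.3, -0.2, 0.6)
  t8 <- c(3.1, 5.2, 1.4, 2.2, 8.0, 4.4, 6.1, 0.9)
  e8 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  f8 <- fit_cox(data.frame(x = x8), t8, e8)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, cox_loglik_oracle, 0, x = x8, time = t8, event = e8)
  expect_lt(abs(f8$coefficients[["x"]] - grid[which.max(ll)]), 1e-4 + 1e-4)

  expect_error(fit_cox(data.frame(x = 1:3), 1:3, c(1, 0, 0)), "2 events")
  expect_error(fit_cox(data.frame(x = rep(1, 20)), 1:20, rep(1, 20)),
               "constant")
})

test_that("cross-validated C behaves at the null and under signal", {
  s0 <- sim_surv(150, beta_x = 0, seed = 8)
  cv0 <- cv_c_statistic(data.frame(x = s0$x), s0$time, s0$event,
                        n_iterations = 10, seed = 9)
  expect_gt(cv0$mean, 0.42)
  expect_lt(cv0$mean, 0.58)

  s1 <- sim_surv(300, beta_x = 1, seed = 10)
  full <- c_statistic(fit_cox(data.frame(x = s1$x), s1$time, s1$event)$risk,
                      s1$time, s1$event)
  cv1 <- cv_c_statistic(data.frame(x = s1$x), s1$time, s1$event,
                        n_iterations = 10, seed = 11)
  expect_lt(abs(cv1$mean - full), 0.05)
  expect_true(cv1$ci[1] <= cv1$mean && cv1$mean <= cv1$ci[2])

  cv2 <- cv_c_statistic(data.frame(x = s1$x), s1$time, s1$event,
                        n_iterations = 10, seed = 11)
  expect_identical(cv1$values, cv2$values)
})

test_that("nmi matches contingency arithmetic and its conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)   # permutation invariant
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)   # independent split
  expect_equal(nmi(rep(1, 6), c(1, 1, 1, 2, 2, 2)), 0) # single-cluster rule
  expect_equal(nmi(c(1, 2, 1, 2), c(1, 2, 1, 2)),
               nmi(c(2, 1, 2, 1), c(1, 2, 1, 2)))      # symmetry
  expect_error(nmi(1:3, 1:4), "equal length")
})

test_that("covariate_association is plain Pearson chi-square", {
  lab <- rep(1:2, each = 10)
  cov <- rep(c("a", "b"), each = 10)
  r <- covariate_association(lab, cov)
  expect_equal(r$statistic, 20)
  expect_lt(r$p.value, 1e-4)

  # perfect-independence counts: statistic 0
  r0 <- covariate_association(rep(1:2, 10), rep(c("a", "b"), each = 10))
  expect_equal(r0$statistic, 0)

  expect_error(covariate_association(rep(1, 20), cov), "degenerate")
})

test_that("build_report assembles per-group c-scores that recompute", {
  sim <- radbatch:::simulate_confounded_cohort(seed = 31)
  co <- sim$cohort
  grouping <- group_by_batch(co, "spacing_group")
  set.seed(32)
  labs <- setNames(as.integer(co$phenotype), co$patient_id)
  phen <- list()
  for (sc in c("original", "3"))
    phen[[sc]] <- list(spacing_group = list(
      small = labs[co$patient_id[grouping$groups == "small"]],
      large = labs[co$patient_id[grouping$groups == "large"]]))
  rep_out <- build_report(phen, co, list(spacing_group = grouping),
                          covariate_cols = "covar1", reference = "3")
  cs <- rep_out$cscores
  expect_setequal(unique(cs$scenario), c("original", "3"))
  # group sizes partition the cohort
  expect_equal(sum(unique(cs[, c("group", "n")])$n), nrow(co))
  # report values equal independently recomputed c-scores
  for (gl in c("small", "large")) {
    sel <- grouping$groups == gl
    x <- data.frame(phenotype = as.integer(co$phenotype[sel] == 2),
                    covar1 = co$covar1[sel])
    fit <- fit_cox(x, co$time[sel], co$event[sel])
    want <- c_statistic(fit$risk, co$time[sel], co$event[sel])
    got <- cs$c[cs$group == gl & cs$scenario == "3"]
    expect_equal(got, want, tolerance = 1e-12)
  }
  # identical labelings: NMI vs reference is 1
  expect_equal(rep_out$nmi$nmi_vs_reference,
               rep(1, nrow(rep_out$nmi)), tolerance = 1e-12)
})
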