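# Two-group person-time data with known totals, used for the analytic
# rate-ratio oracle.
two_group_rows <- function(d1 = 30L, t1 = 400, d0 = 50L, t0 = 1200,
                           cell = 10) {
  grp <- function(d, t, x) {
    k <- cell
    data.frame(event = c(rep(1L, d), rep(0L, k)),
               time = c(rep(t / (2 * d), d), rep(t / (2 * k), k)),
               exposure = x)
  }
  rbind(grp(d1, t1, 1), grp(d0, t0, 0))
}

test_that("covariate-free Poisson fit equals the closed-form rate ratio", {
  d1 <- 37L; t1 <- 512.5; d0 <- 211L; t0 <- 3100.25
  rows <- two_group_rows(d1, t1, d0, t0)
  fit <- cits(rows, variant = "hes", formula = event ~ exposure,
              rare_threshold = 0L)
  oracle <- crude_rate_ratio(d1, t1, d0, t0)
  expect_equal(fit$effect, oracle, tolerance = 1e-8)
  # Wald interval on the log scale with z = 1.959964
  se <- sqrt(1 / d1 + 1 / d0)
  expect_equal(fit$ci95,
               oracle * exp(c(-1, 1) * stats::qnorm(0.975) * se),
               tolerance = 1e-6)
})

test_that("the IRR is invariant to rescaling person-time (offset correctness)", {
  rows <- two_group_rows()
  f1 <- cits(rows, variant = "hes", formula = event ~ exposure,
             rare_threshold = 0L)
  rows2 <- rows
  rows2$time <- rows2$time * 3.7
  f2 <- cits(rows2, variant = "hes", formula = event ~ exposure,
             rare_threshold = 0L)
  expect_equal(f1$effect, f2$effect, tolerance = 1e-10)
  expect_equal(f1$ci95, f2$ci95, tolerance = 1e-10)
})

test_that("degenerate designs are flagged rather than reported", {
  rows <- two_group_rows()
  rows$exposure <- 0
  expect_warning(fit <- cits(rows, variant = "hes",
                             formula = event ~ exposure,
                             rare_threshold = 0L), "inestimable")
  expect_false(fit$estimable)
  expect_true(is.na(fit$effect))
  rows_bad <- two_group_rows()
  rows_bad$time[1] <- 0
  expect_error(cits(rows_bad, variant = "hes", rare_threshold = 0L),
               "positive")
  rows_bad2 <- two_group_rows()
  rows_bad2$exposure[1] <- 1.5
  expect_error(cits(rows_bad2, variant = "hes", rare_threshold = 0L),
               "\\[0, 1\\]")
})

test_that("the rare-outcome guard uses the fewer-than-200 rule", {
  expect_true(rare_guard(199))
  expect_false(rare_guard(200))
  expect_true(rare_guard(0))
  expect_error(rare_guard(-1))

  # a sparse outcome short-circuits the fit and reports counts only
  rows <- two_group_rows(d1 = 20L, d0 = 30L)
  fit <- cits(rows, variant = "hes", formula = event ~ exposure)
  expect_true(fit$rare_flag)
  expect_null(fit$fit)
  expect_true(is.na(fit$effect))
  expect_equal(fit$n_events, 50L)
  expect_output(print(fit), "Rare outcome")
})

test_that("maternal Poisson risk model matches the crude risk ratio and recovers a simulated effect", {
  # closed form on a 2x2 table
  tab <- data.frame(
    flag = c(rep(1L, 40), rep(0L, 360), rep(1L, 90), rep(0L, 510)),
    exposure = c(rep(1, 400), rep(0, 600)))
  fit <- cits(tab, variant = "maternal", outcome = "flag",
              formula = flag ~ exposure, rare_threshold = 0L)
  expect_equal(fit$effect, (40 / 400) / (90 / 600), tolerance = 1e-8)

  # generator scenario at the composite-morbidity scale with a true
  # risk ratio of 0.70 under exposure
  cfg <- quick_config(n_children = 60000, seed = 14)
  hosp <- generate_hospitals(cfg)
  coh <- generate_cohort(cfg, hosp)
  mat <- generate_maternal(cfg, coh)
  mat$exposure <- as.numeric(mat$truly_exposed)
  fit2 <- cits(mat, variant = "maternal", outcome = "composite_infection")
  se <- (log(fit2$ci95[2]) - log(fit2$ci95[1])) / (2 * stats::qnorm(0.975))
  expect_lt(abs(log(fit2$effect) - log(0.70)), 3 * se)

  # an outcome with no events is caught by the rare guard
  mat0 <- mat
  mat0$composite_infection <- 0L
  fit0 <- cits(mat0, variant = "maternal", outcome = "composite_infection")
  expect_true(fit0$rare_flag)
})

test_that("linear model recovers mean differences for continuous outcomes", {
  # identical groups: difference exactly zero
  d <- data.frame(y = rep(c(2, 3, 4), 2), exposure = rep(c(0, 1), each = 3),
                  delivery_year = 2010,
                  delivery_type = factor("caesarean",
                                         levels = c("vaginal", "caesarean")))
  f0 <- cits(d, variant = "continuous", outcome = "y",
             formula = y ~ exposure)
  expect_equal(f0$effect, 0, tolerance = 1e-12)

  # constructed shift with no confounding is recovered exactly
  set.seed(1)
  base <- rnorm(200)
  d2 <- data.frame(y = c(base, base - 0.23),
                   exposure = rep(c(0, 1), each = 200))
  f2 <- cits(d2, variant = "continuous", outcome = "y",
             formula = y ~ exposure)
  expect_equal(f2$effect, -0.23, tolerance = 1e-10)

  # generator scenario: length of stay shifted by -0.23 days under
  # exposure, recovered within 3 SE by the adjusted model
  cfg <- quick_config(n_children = 60000, seed = 15)
  coh <- generate_cohort(cfg, generate_hospitals(cfg))
  mat <- generate_maternal(cfg, coh)
  mat$exposure <- as.numeric(mat$truly_exposed)
  f3 <- cits(mat, variant = "continuous", outcome = "length_of_stay")
  se <- (f3$ci95[2] - f3$ci95[1]) / (2 * stats::qnorm(0.975))
  expect_lt(abs(f3$effect - (-0.23)), 3 * se)
})

# Aggregated Lexis-style cells with subgroup-specific exposure effects;
# event counts are Poisson draws at the cell rates.
subgroup_cells <- function(irr_elective, irr_emergency, seed,
                           py = 40000, rate = 0.02) {
  set.seed(seed)
  grid <- expand.grid(birth_year = 2006:2018,
                      cs_group = c("vaginal", "elective", "emergency"),
                      stringsAsFactors = FALSE)
  grid$delivery_type <- factor(
    ifelse(grid$cs_group == "vaginal", "vaginal", "caesarean"),
    levels = c("vaginal", "caesarean"))
  grid$caesarean_type <- factor(
    ifelse(grid$cs_group == "vaginal", NA, grid$cs_group),
    levels = c("elective", "emergency"))
  grid$exposure <- as.numeric(grid$delivery_type == "caesarean" &
                                grid$birth_year > 2011)
  irr <- ifelse(grid$cs_group == "elective", irr_elective,
                ifelse(grid$cs_group == "emergency", irr_emergency, 1))
  grid$time <- ifelse(grid$delivery_type == "vaginal", py, py / 2)
  mu <- grid$time * rate * 1.02^(grid$birth_year - 2006) *
    ifelse(grid$delivery_type == "caesarean", 1.2, 1) *
    irr^grid$exposure
  grid$event <- rpois(nrow(grid), mu)
  grid$age_year <- 0L
  grid
}

test_that("subgroup interaction by caesarean type recovers differential effects", {
  # identical subgroup IRRs: interaction consistent with zero
  cells <- subgroup_cells(1.1, 1.1, seed = 4)
  res0 <- subgroup_interaction(cells, variant = "hes", coding = "linear")
  expect_lt(abs(log(res0$interaction_ratio)), 3 * res0$interaction_se)

  # elective IRR 1.2 vs emergency 0.8: ratio 1.5 recovered within 3 SE
  cells2 <- subgroup_cells(1.2, 0.8, seed = 9)
  res <- subgroup_interaction(cells2, variant = "hes", coding = "linear")
  expect_lt(abs(log(res$interaction_ratio) - log(1.5)),
            3 * res$interaction_se)
  expect_true(res$irr_elective[["estimate"]] > res$irr_emergency[["estimate"]])

  # vaginal rows only: undefined
  vag <- cells[cells$delivery_type == "vaginal", ]
  expect_error(subgroup_interaction(vag, variant = "hes"),
               "no caesarean rows")
})

test_that("quasipoisson option scales intervals without moving the estimate", {
  rows <- two_group_rows(d1 = 300L, t1 = 4000, d0 = 500L, t0 = 12000)
  f1 <- cits(rows, variant = "hes", formula = event ~ exposure)
  f2 <- cits(rows, variant = "hes", formula = event ~ exposure,
             dispersion = "quasipoisson")
  expect_equal(f1$effect, f2$effect, tolerance = 1e-10)
  expect_true(diff(f2$ci95) > 0)
})
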