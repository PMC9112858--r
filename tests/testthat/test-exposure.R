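test_that("uptake curve is the birth-weighted fraction under pre-incision policy", {
  # all hospitals change in 2009: step function with p = 0 before,
  # 1 strictly after
  hosp <- data.frame(hospital_id = c("A", "B"),
                     policy_change_year = c(2009L, 2009L),
                     policy_status = "changed")
  cu <- estimate_uptake(hosp, equal_births(c("A", "B"), 2008:2010))
  expect_equal(cu$p_preincision[cu$year == 2008], 0)
  expect_equal(cu$p_preincision[cu$year == 2009], 0)
  expect_equal(cu$p_preincision[cu$year == 2010], 1)

  # two equal-size hospitals changing 2009 and 2011: p(2010) = 0.5
  hosp2 <- data.frame(hospital_id = c("A", "B"),
                      policy_change_year = c(2009L, 2011L),
                      policy_status = "changed")
  cu2 <- estimate_uptake(hosp2, equal_births(c("A", "B"), 2010))
  expect_equal(cu2$p_preincision, 0.5)

  # birth-count weighting: a hospital with three times the births
  # dominates the curve
  b <- rbind(data.frame(hospital_id = "A", year = 2010, n_caesarean = 300),
             data.frame(hospital_id = "B", year = 2010, n_caesarean = 100))
  expect_equal(estimate_uptake(hosp2, b)$p_preincision, 0.75)

  # unknown-policy hospitals drop out of numerator and denominator
  cu3 <- estimate_uptake(five_hospital_survey(),
                         equal_births(paste0("H", 1:5), 2011))
  expect_equal(cu3$p_preincision, 2 / 4)  # H1, H5 pre of 4 known; H4 out
  expect_equal(cu3$n_denominator, 400)
})

test_that("degenerate and undefined uptake cases are flagged, not zeroed", {
  all_unknown <- data.frame(hospital_id = c("A", "B"),
                            policy_change_year = NA_integer_,
                            policy_status = "unknown")
  expect_error(estimate_uptake(all_unknown, equal_births(c("A", "B"), 2010)),
               "known policy")

  # a year whose caesarean births all fall at unknown-policy hospitals
  mixed <- data.frame(hospital_id = c("A", "U"),
                      policy_change_year = c(2009L, NA),
                      policy_status = c("changed", "unknown"))
  b <- rbind(data.frame(hospital_id = "A", year = 2010, n_caesarean = 50),
             data.frame(hospital_id = "U", year = 2011, n_caesarean = 50))
  cu <- estimate_uptake(mixed, b)
  expect_true(cu$defined[cu$year == 2010])
  expect_false(cu$defined[cu$year == 2011])
  expect_true(is.na(cu$p_preincision[cu$year == 2011]))

  expect_error(estimate_uptake(mixed, data.frame(
    hospital_id = "X", year = 2010, n_caesarean = 1)), "unknown hospital_id")
  expect_error(estimate_uptake(mixed, data.frame(
    hospital_id = "A", year = 2010, n_caesarean = -1)), ">= 0")
})

test_that("uptake is non-decreasing when hospitals switch at most once", {
  for (seed in 1:5) {
    set.seed(seed)
    ids <- sprintf("H%02d", 1:30)
    hosp <- data.frame(
      hospital_id = ids,
      policy_change_year = sample(2007:2015, 30, replace = TRUE),
      policy_status = "changed")
    cu <- estimate_uptake(hosp, equal_births(ids, 2006:2018))
    expect_true(all(diff(cu$p_preincision) >= 0))
  }
})

test_that("national regime assigns the uptake probability to caesarean births only", {
  curve <- data.frame(year = 2008:2012,
                      p_preincision = c(0, 0.25, 0.5, 0.75, 1),
                      n_denominator = 100, defined = TRUE)
  kids <- make_children("H1", c(2008, 2010, 2010, 2012),
                        c("caesarean", "caesarean", "vaginal", "vaginal"))
  out <- assign_exposure(kids, "national", curve = curve)
  expect_equal(out$exposure, c(0, 0.5, 0, 0))
  expect_true(all(out$exposure_status == "included"))

  # caesarean birth year missing from the curve is an explicit error
  kids2 <- make_children("H1", 2013, "caesarean")
  expect_error(assign_exposure(kids2, "national", curve = curve),
               "not defined")
  # but a vaginal birth outside the curve is fine (always unexposed)
  kids3 <- make_children("H1", 2013, "vaginal")
  expect_equal(assign_exposure(kids3, "national", curve = curve)$exposure, 0)
})

test_that("hospital regime applies change-year and unknown-policy exclusions", {
  hosp <- five_hospital_survey()
  kids <- make_children(
    hospital_id = c("H1", "H1", "H1", "H4", "H3", "H1", "H2"),
    birth_year = c(2013, 2009, 2008, 2013, 2013, 2009, 2011),
    delivery_type = c("caesarean", "caesarean", "caesarean", "caesarean",
                      "caesarean", "vaginal", "vaginal"))
  out <- assign_exposure(kids, "hospital", hospitals = hosp)
  # born 2013 at H1 (change 2009): exposed
  expect_equal(out$exposure[1], 1)
  expect_equal(as.character(out$exposure_status[1]), "included")
  # born in the change year: excluded
  expect_equal(as.character(out$exposure_status[2]), "excluded_change_year")
  expect_true(is.na(out$exposure[2]))
  # born strictly before the change: unexposed, included
  expect_equal(out$exposure[3], 0)
  # unknown policy: excluded
  expect_equal(as.character(out$exposure_status[4]),
               "excluded_unknown_policy")
  # never-changed hospital: unexposed, included
  expect_equal(out$exposure[5], 0)
  expect_equal(as.character(out$exposure_status[5]), "included")
  # vaginal births: unexposed and retained, even in a change year
  expect_equal(out$exposure[6:7], c(0, 0))
  expect_true(all(out$exposure_status[6:7] == "included"))

  # config switch: drop the whole hospital-year instead
  out2 <- assign_exposure(kids, "hospital", hospitals = hosp,
                          exclude_vaginal_change_year = TRUE)
  expect_equal(as.character(out2$exposure_status[7]),
               "excluded_change_year")

  expect_error(assign_exposure(make_children("NOPE", 2010, "caesarean"),
                               "hospital", hospitals = hosp),
               "unknown hospital_id")
})

test_that("national and hospital regimes agree under a degenerate survey", {
  cfg <- quick_config(n_children = 3000, seed = 77,
                      change_year_distribution = c("2011" = 1))
  hosp <- generate_hospitals(cfg)
  coh <- generate_cohort(cfg, hosp)
  curve <- estimate_uptake(hosp, caesarean_births_by_hospital_year(coh))
  nat <- assign_exposure(coh, "national", curve = curve)
  hs <- assign_exposure(coh, "hospital", hospitals = hosp)
  keep <- hs$exposure_status == "included"
  expect_equal(nat$exposure[keep], hs$exposure[keep])
  # the only excluded births are caesareans in the shared change year
  expect_true(all(coh$birth_year[!keep] == 2011))
  expect_true(all(coh$delivery_type[!keep] == "caesarean"))
})
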