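# Shared fixtures built in code.

# Five-hospital survey covering all policy states used by the
# change-year and unknown-policy exclusion rules.
five_hospital_survey <- function() {
  data.frame(
    hospital_id = c("H1", "H2", "H3", "H4", "H5"),
    policy_change_year = c(2009L, 2011L, NA, NA, 2010L),
    policy_status = factor(
      c("changed", "changed", "never", "unknown", "changed"),
      levels = c("changed", "never", "unknown")),
    size_weight = rep(0.2, 5),
    stringsAsFactors = FALSE)
}

# Equal caesarean birth counts for every hospital-year combination.
equal_births <- function(hospital_ids, years, n = 100) {
  b <- expand.grid(hospital_id = hospital_ids, year = years,
                   stringsAsFactors = FALSE)
  b$n_caesarean <- n
  b
}

# Minimal child records for exposure assignment.
make_children <- function(hospital_id, birth_year, delivery_type,
                          caesarean_type = NA) {
  n <- max(length(hospital_id), length(birth_year), length(delivery_type))
  data.frame(
    child_id = sprintf("C%02d", seq_len(n)),
    hospital_id = rep_len(hospital_id, n),
    birth_year = rep_len(birth_year, n),
    delivery_type = factor(rep_len(delivery_type, n),
                           levels = c("vaginal", "caesarean")),
    caesarean_type = factor(rep_len(caesarean_type, n),
                            levels = c("elective", "emergency")),
    stringsAsFactors = FALSE)
}

# Small generator configuration with log-linear trends, under which the
# linear-coded models are exactly specified.
quick_config <- function(n_children = 5000, true_irr = 1,
                         baseline = c(asthma = 20), seed = 1, ...) {
  sim_config(n_children = n_children, baseline_rate = baseline,
             age_rate_multipliers = rep(1, 5), year_trend = 1.02,
             delivery_rr = 1.2, true_irr = true_irr, seed = seed, ...)
}

# Closed-form rate ratio from a two-group person-time split; the
# analytic oracle the covariate-free Poisson fit must match.
crude_rate_ratio <- function(d1, t1, d0, t0) (d1 / t1) / (d0 / t0)
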