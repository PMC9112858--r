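#' Simulation configuration for the synthetic mother-baby cohort
#'
#' Bundles every parameter of the synthetic electronic-health-record
#' generator into a validated configuration object.  The defaults describe
#' the study conditions the package emulates: a UK-scale linked
#' primary-care cohort of 515,945 children born 2006-2018, a caesarean
#' section fraction of 28.1%, hospital policy-change years spread around
#' the 2011 national recommendation with a sizeable unknown-policy mass
#' (about 55% of births occur at hospitals with a known change year), and
#' first-event hazards on the events-per-1000-person-years scale.
#'
#' @param n_children number of retained children (one per pregnancy after
#'   random selection from multiple births).
#' @param birth_year_range integer vector \code{c(first, last)} of calendar
#'   birth years; must lie within 2005-2018.
#' @param caesarean_fraction probability that a birth is by caesarean
#'   section.
#' @param elective_fraction_of_cs probability that a caesarean is elective
#'   (rather than emergency).
#' @param n_hospitals number of hospitals undertaking caesarean sections.
#' @param change_year_distribution named numeric vector of probabilities
#'   over policy-change years, plus optional \code{"never"} and
#'   \code{"unknown"} masses; must sum to 1.  Year names must fall inside
#'   the study period.
#' @param baseline_rate named numeric vector, one element per outcome, of
#'   first-event rates per 1000 person-years at the reference age/year in
#'   unexposed vaginal births.
#' @param age_rate_multipliers positive multiplicative factors for years of
#'   life 0-4 (length 5); the first element is conventionally 1.
#' @param year_trend multiplicative change in outcome rates per calendar
#'   year (secular diagnosis trend shared by both delivery types).
#' @param delivery_rr rate ratio, caesarean versus vaginal birth.
#' @param true_irr incidence rate ratio attached to true fetal exposure to
#'   pre-incision antibiotics; the quantity the CITS models try to recover.
#' @param compliance probability that a caesarean birth after the
#'   hospital's policy change is truly exposed (hospital audits reported
#'   70-100% of women receiving pre-incision antibiotics; 1 means
#'   deterministic policy adherence).
#' @param ltfu_annual_prob per-year probability of loss to follow-up
#'   (geometric hazard, independent of outcomes).
#' @param multiple_birth_prob probability that a pregnancy is a multiple
#'   birth (one child is later retained at random).
#' @param maternal_risk named list, one element per maternal outcome, each
#'   a numeric vector with elements \code{risk_cs}, \code{risk_vaginal}
#'   (six-week postpartum risks in unexposed deliveries) and
#'   \code{exposure_rr} (risk ratio under pre-incision exposure).
#' @param los_mean_cs,los_mean_vaginal mean maternal length of stay (days)
#'   by delivery type in unexposed deliveries.
#' @param los_exposure_delta additive shift (days) in mean caesarean length
#'   of stay under pre-incision exposure.
#' @param los_shape gamma shape parameter for length of stay.
#' @param study_end administrative end of follow-up (\code{Date}).
#' @param seed integer seed making all generated tables reproducible.
#'
#' @return an object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(n_children = 1000, seed = 42)
#' cfg$caesarean_fraction
#' @export
sim_config <- function(n_children = 515945,
                       birth_year_range = c(2006L, 2018L),
                       caesarean_fraction = 0.281,
                       elective_fraction_of_cs = 0.4,
                       n_hospitals = 180L,
                       change_year_distribution = c(
                         "2008" = 0.05, "2009" = 0.10, "2010" = 0.15,
                         "2011" = 0.15, "2012" = 0.10, "2013" = 0.05,
                         "unknown" = 0.40),
                       baseline_rate = c(asthma = 9.9, eczema = 71.9),
                       age_rate_multipliers = c(1.0, 1.2, 1.1, 0.9, 0.8),
                       year_trend = 1.02,
                       delivery_rr = 1.2,
                       true_irr = 1.0,
                       compliance = 1.0,
                       ltfu_annual_prob = 0.05,
                       multiple_birth_prob = 0.015,
                       maternal_risk = list(
                         composite_infection = c(risk_cs = 0.0861,
                                                 risk_vaginal = 0.0143,
                                                 exposure_rr = 0.70),
                         wound_infection = c(risk_cs = 0.0809,
                                             risk_vaginal = 0.0102,
                                             exposure_rr = 0.62)),
                       los_mean_cs = 3.2,
                       los_mean_vaginal = 1.5,
                       los_exposure_delta = -0.23,
                       los_shape = 4,
                       study_end = as.Date("2018-12-31"),
                       seed = 1L) {
  cfg <- list(
    n_children = as.integer(n_children),
    birth_year_range = as.integer(birth_year_range),
    caesarean_fraction = caesarean_fraction,
    elective_fraction_of_cs = elective_fraction_of_cs,
    n_hospitals = as.integer(n_hospitals),
    change_year_distribution = change_year_distribution,
    baseline_rate = baseline_rate,
    age_rate_multipliers = age_rate_multipliers,
    year_trend = year_trend,
    delivery_rr = delivery_rr,
    true_irr = true_irr,
    compliance = compliance,
    ltfu_annual_prob = ltfu_annual_prob,
    multiple_birth_prob = multiple_birth_prob,
    maternal_risk = maternal_risk,
    los_mean_cs = los_mean_cs,
    los_mean_vaginal = los_mean_vaginal,
    los_exposure_delta = los_exposure_delta,
    los_shape = los_shape,
    study_end = as.Date(study_end),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_children < 1L) stop("n_children must be >= 1", call. = FALSE)
  if (cfg$n_hospitals < 1L) stop("n_hospitals must be >= 1", call. = FALSE)
  byr <- cfg$birth_year_range
  if (length(byr) != 2L || byr[1] > byr[2] || byr[1] < 2005L || byr[2] > 2018L)
    stop("birth_year_range must be [first, last] within 2005-2018",
         call. = FALSE)
  probs <- c(cfg$caesarean_fraction, cfg$elective_fraction_of_cs,
             cfg$compliance, cfg$ltfu_annual_prob, cfg$multiple_birth_prob)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  dist <- cfg$change_year_distribution
  if (length(dist) == 0L)
    stop("change_year_distribution must be non-empty", call. = FALSE)
  if (is.null(names(dist)) || any(!nzchar(names(dist))))
    stop("change_year_distribution must be a named vector", call. = FALSE)
  if (any(dist < 0) || abs(sum(dist) - 1) > 1e-8)
    stop("change_year_distribution must be non-negative and sum to 1",
         call. = FALSE)
  yr_names <- setdiff(names(dist), c("never", "unknown"))
  yrs <- suppressWarnings(as.integer(yr_names))
  if (any(is.na(yrs)))
    stop("change_year_distribution names must be years, 'never' or 'unknown'",
         call. = FALSE)
  if (length(yrs) && (min(yrs) < byr[1] - 1L || max(yrs) > byr[2]))
    stop("policy change years must lie inside the study period",
         call. = FALSE)
  if (length(cfg$baseline_rate) == 0L || is.null(names(cfg$baseline_rate)))
    stop("baseline_rate must be a named vector of outcome rates",
         call. = FALSE)
  if (any(cfg$baseline_rate <= 0) || any(cfg$age_rate_multipliers <= 0) ||
      cfg$year_trend <= 0 || cfg$delivery_rr <= 0 || cfg$true_irr <= 0)
    stop("hazard parameters must be strictly positive", call. = FALSE)
  if (length(cfg$age_rate_multipliers) != 5L)
    stop("age_rate_multipliers must have length 5 (years of life 0-4)",
         call. = FALSE)
  for (nm in names(cfg$maternal_risk)) {
    mr <- cfg$maternal_risk[[nm]]
    if (!all(c("risk_cs", "risk_vaginal", "exposure_rr") %in% names(mr)))
      stop("maternal_risk entries need risk_cs, risk_vaginal, exposure_rr",
           call. = FALSE)
    if (mr[["risk_cs"]] < 0 || mr[["risk_cs"]] > 1 ||
        mr[["risk_vaginal"]] < 0 || mr[["risk_vaginal"]] > 1 ||
        mr[["exposure_rr"]] < 0 ||
        mr[["risk_cs"]] * mr[["exposure_rr"]] > 1)
      stop("maternal risks (including exposed risk) must lie in [0, 1]",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  children: %d, hospitals: %d, births %d-%d\n",
              x$n_children, x$n_hospitals,
              x$birth_year_range[1], x$birth_year_range[2]))
  cat(sprintf("  caesarean fraction: %.3f (elective %.2f of CS)\n",
              x$caesarean_fraction, x$elective_fraction_of_cs))
  cat(sprintf("  outcomes: %s\n",
              paste(sprintf("%s=%.2f/1000py", names(x$baseline_rate),
                            x$baseline_rate), collapse = ", ")))
  cat(sprintf("  true exposure IRR: %.3f, compliance: %.2f, seed: %d\n",
              x$true_irr, x$compliance, x$seed))
  invisible(x)
}
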