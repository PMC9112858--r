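#' Generate a synthetic hospital policy survey
#'
#' Draws one row per hospital, with the year of switching from
#' post-cord-clamping to pre-incision antibiotic prophylaxis sampled
#' i.i.d. from \code{config$change_year_distribution}.  The special
#' categories \code{"never"} (policy never changed) and \code{"unknown"}
#' (survey non-response / year not recalled) are carried in
#' \code{policy_status}; both leave \code{policy_change_year} as
#' \code{NA}, but only \code{"unknown"} hospitals are dropped from
#' uptake-curve denominators downstream.  A log-normal relative size
#' weight governs how many births each hospital receives.
#'
#' An \code{"unknown"} status masks the survey report only: such a
#' hospital still follows a true policy, with \code{true_change_year}
#' drawn from the distribution of the known categories, so its births
#' can genuinely be exposed even though the hospital is excluded from
#' uptake estimation and from the hospital-regime analysis.  This is
#' what survey non-response looks like in reality, and it is what makes
#' unknown-policy hospitals a source of exposure misclassification
#' rather than a pocket of truly unexposed births.
#'
#' @param config a [sim_config()] object.
#' @return data frame with columns \code{hospital_id},
#'   \code{policy_change_year} (the survey report: integer, \code{NA}
#'   when never/unknown), \code{policy_status} (\code{"changed"},
#'   \code{"never"}, \code{"unknown"}), \code{true_change_year} (the
#'   policy actually applied at the hospital) and \code{size_weight}.
#' @examples
#' h <- generate_hospitals(sim_config(n_children = 100, seed = 3))
#' table(h$policy_status)
#' @export
generate_hospitals <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_hospitals
  dist <- config$change_year_distribution
  cat_draw <- sample(names(dist), n, replace = TRUE, prob = dist)
  status <- ifelse(cat_draw == "unknown", "unknown",
                   ifelse(cat_draw == "never", "never", "changed"))
  year <- suppressWarnings(as.integer(cat_draw))
  true_year <- year
  unk <- status == "unknown"
  resp <- dist[setdiff(names(dist), "unknown")]
  if (any(unk) && length(resp) > 0) {
    true_cat <- sample(names(resp), sum(unk), replace = TRUE, prob = resp)
    true_year[unk] <- suppressWarnings(as.integer(true_cat))
  }
  w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.6)
  data.frame(
    hospital_id = sprintf("H%03d", seq_len(n)),
    policy_change_year = year,
    policy_status = factor(status, levels = c("changed", "never", "unknown")),
    true_change_year = true_year,
    size_weight = w / sum(w),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic mother-baby cohort
#'
#' Simulates one pregnancy per retained child.  Multiple-birth
#' pregnancies produce sibling records sharing mother, hospital, birth
#' date and delivery type; exactly one child per multiple-birth group is
#' then retained at random, mirroring the independence rule used when
#' analysing linked records.  First-event times per outcome follow a
#' piecewise-constant hazard over years of life 0-4,
#' \deqn{\lambda(a, y) = \textrm{baseline} \times \textrm{agemult}_a
#'   \times \textrm{trend}^{(y - y_0)} \times \textrm{RR}_{CS}^{[CS]}
#'   \times \textrm{IRR}^{[exposed]},}
#' with the calendar year for age \eqn{a} taken as birth year + \eqn{a}.
#' A child is truly exposed when born by caesarean section in a year
#' strictly after its hospital's policy-change year, thinned by the
#' compliance probability.  Loss to follow-up has a geometric per-year
#' hazard independent of outcomes; birth dates are uniform within the
#' birth year.  Generated event and loss dates may fall after the study
#' end; censoring is applied downstream by [person_year_table()].
#'
#' @param config a [sim_config()] object.
#' @param hospitals data frame from [generate_hospitals()].
#' @return data frame with one row per retained child: identifiers,
#'   \code{birth_date}, \code{birth_year}, \code{delivery_type}
#'   (factor, vaginal = reference), \code{caesarean_type} (\code{NA} for
#'   vaginal births), \code{truly_exposed}, \code{ltfu_date},
#'   \code{multiple_birth_group} and one \code{<outcome>_date} column
#'   per configured outcome (\code{NA} when no event by age 5).
#' @examples
#' cfg <- sim_config(n_children = 500, seed = 7)
#' coh <- generate_cohort(cfg, generate_hospitals(cfg))
#' mean(coh$delivery_type == "caesarean")
#' @export
generate_cohort <- function(config, hospitals) {
  validate_sim_config(config)
  if (NROW(hospitals) == 0L) stop("hospitals must be non-empty", call. = FALSE)
  set.seed(config$seed + 1L)

  n_preg <- config$n_children
  twin <- stats::rbinom(n_preg, 1L, config$multiple_birth_prob) == 1L
  n_sib <- ifelse(twin, 2L, 1L)

  ## pregnancy-level attributes (shared by siblings)
  years <- config$birth_year_range[1]:config$birth_year_range[2]
  birth_year <- sample(years, n_preg, replace = TRUE)
  year_start <- as.Date(paste0(birth_year, "-01-01"))
  ndays <- as.integer(as.Date(paste0(birth_year, "-12-31")) - year_start) + 1L
  birth_date <- year_start + floor(stats::runif(n_preg) * ndays)
  hosp_idx <- sample.int(nrow(hospitals), n_preg, replace = TRUE,
                         prob = hospitals$size_weight)
  hospital_id <- hospitals$hospital_id[hosp_idx]
  ## truth follows the policy actually applied, not the survey report
  true_col <- if ("true_change_year" %in% names(hospitals))
    "true_change_year" else "policy_change_year"
  change_year <- hospitals[[true_col]][hosp_idx]
  cs <- stats::runif(n_preg) < config$caesarean_fraction
  cs_type <- rep(NA_character_, n_preg)
  cs_type[cs] <- ifelse(
    stats::runif(sum(cs)) < config$elective_fraction_of_cs,
    "elective", "emergency")
  post_change <- !is.na(change_year) & birth_year > change_year
  exposed <- cs & post_change &
    stats::runif(n_preg) < config$compliance

  ## expand to child rows (twin pregnancies contribute two candidates)
  preg <- rep.int(seq_len(n_preg), n_sib)
  nc <- length(preg)
  group <- rep(NA_character_, nc)
  group[twin[preg]] <- sprintf("G%06d", preg[twin[preg]])

  ## child-level loss to follow-up: geometric year count + uniform offset
  if (config$ltfu_annual_prob > 0) {
    lyr <- stats::rgeom(nc, config$ltfu_annual_prob) + stats::runif(nc)
    ltfu_date <- birth_date[preg] + floor(lyr * 365.25)
    ltfu_date[lyr > 6] <- NA
  } else {
    ltfu_date <- birth_date[preg] + NA_real_
  }

  ## child-level first-event dates per outcome
  byr <- birth_year[preg]
  base_mult <- config$delivery_rr^cs[preg] * config$true_irr^exposed[preg]
  out_dates <- list()
  for (nm in names(config$baseline_rate)) {
    base <- config$baseline_rate[[nm]] / 1000
    lam <- matrix(0, nc, 5L)
    for (a in 0:4) {
      lam[, a + 1L] <- base * config$age_rate_multipliers[a + 1L] *
        config$year_trend^(byr + a - years[1]) * base_mult
    }
    waits <- matrix(stats::rexp(nc * 5L), nc, 5L) / lam
    hit <- waits < 1
    has_event <- rowSums(hit) > 0L
    first <- max.col(hit, ties.method = "first")
    etime <- ifelse(has_event,
                    (first - 1L) + waits[cbind(seq_len(nc), first)], NA_real_)
    d <- birth_date[preg] + floor(etime * 365.25)
    d[!has_event] <- NA
    out_dates[[paste0(nm, "_date")]] <- d
  }

  children <- data.frame(
    pregnancy = preg,
    mother_id = sprintf("M%07d", preg),
    hospital_id = hospital_id[preg],
    birth_date = birth_date[preg],
    birth_year = byr,
    delivery_type = factor(ifelse(cs[preg], "caesarean", "vaginal"),
                           levels = c("vaginal", "caesarean")),
    caesarean_type = factor(cs_type[preg],
                            levels = c("elective", "emergency")),
    truly_exposed = exposed[preg],
    ltfu_date = ltfu_date,
    multiple_birth_group = group,
    stringsAsFactors = FALSE)
  for (nm in names(out_dates)) children[[nm]] <- out_dates[[nm]]

  ## retain exactly one child per multiple-birth group
  sib_index <- stats::ave(children$pregnancy, children$pregnancy,
                          FUN = seq_along)
  pick <- ifelse(twin, 1L + (stats::runif(n_preg) < 0.5), 1L)
  keep <- sib_index == pick[children$pregnancy]
  children <- children[keep, , drop = FALSE]
  children$child_id <- sprintf("C%07d", seq_len(nrow(children)))
  children$pregnancy <- NULL
  rownames(children) <- NULL
  cols <- c("child_id", "mother_id", "hospital_id", "birth_date",
            "birth_year", "delivery_type", "caesarean_type",
            "truly_exposed", "ltfu_date", "multiple_birth_group",
            names(out_dates))
  children[, cols]
}

#' Generate maternal six-week postpartum outcomes
#'
#' One row per delivery (the mother of each retained child).  Each
#' configured maternal outcome is a Bernoulli indicator of occurrence
#' within 42 days of delivery, with risk depending on delivery type and,
#' for truly exposed caesarean deliveries, multiplied by the outcome's
#' \code{exposure_rr}.  Length of stay is gamma distributed with a mean
#' set by delivery type and shifted additively by
#' \code{los_exposure_delta} under exposure, so an ordinary linear model
#' recovers the shift as a difference in means.
#'
#' @param config a [sim_config()] object.
#' @param cohort data frame from [generate_cohort()].
#' @return data frame with \code{mother_id}, \code{delivery_year},
#'   \code{delivery_type}, \code{truly_exposed}, one binary column per
#'   maternal outcome, and \code{length_of_stay} (days).
#' @export
generate_maternal <- function(config, cohort) {
  validate_sim_config(config)
  if (NROW(cohort) == 0L) stop("cohort must be non-empty", call. = FALSE)
  set.seed(config$seed + 2L)
  n <- nrow(cohort)
  cs <- cohort$delivery_type == "caesarean"
  exposed <- cohort$truly_exposed
  out <- data.frame(
    mother_id = cohort$mother_id,
    delivery_year = cohort$birth_year,
    delivery_type = cohort$delivery_type,
    truly_exposed = exposed,
    stringsAsFactors = FALSE)
  for (nm in names(config$maternal_risk)) {
    mr <- config$maternal_risk[[nm]]
    risk <- ifelse(cs, mr[["risk_cs"]], mr[["risk_vaginal"]]) *
      ifelse(exposed, mr[["exposure_rr"]], 1)
    out[[nm]] <- stats::rbinom(n, 1L, risk)
  }
  los_mean <- ifelse(cs, config$los_mean_cs, config$los_mean_vaginal) +
    config$los_exposure_delta * exposed
  out$length_of_stay <- stats::rgamma(n, shape = config$los_shape,
                                      scale = los_mean / config$los_shape)
  out
}

#' Write the synthetic tables to CSV
#'
#' Generates hospitals, cohort and maternal tables from a configuration
#' and writes \code{hospitals.csv}, \code{cohort.csv} and
#' \code{maternal.csv} into \code{dir}.  Identical configurations
#' (including the seed) produce byte-identical files.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_synthetic_data <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hospitals <- generate_hospitals(config)
  cohort <- generate_cohort(config, hospitals)
  maternal <- generate_maternal(config, cohort)
  paths <- c(hospitals = file.path(dir, "hospitals.csv"),
             cohort = file.path(dir, "cohort.csv"),
             maternal = file.path(dir, "maternal.csv"))
  utils::write.csv(hospitals, paths[["hospitals"]], row.names = FALSE)
  utils::write.csv(cohort, paths[["cohort"]], row.names = FALSE)
  utils::write.csv(maternal, paths[["maternal"]], row.names = FALSE)
  invisible(paths)
}
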