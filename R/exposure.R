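#' Estimate the national policy-uptake curve
#'
#' Computes, for each calendar year, the probability that a caesarean
#' birth in that year occurred under a pre-incision antibiotic policy:
#' the caesarean births at hospitals whose policy-change year is strictly
#' before the birth year, divided by the caesarean births at all
#' hospitals with a known policy (a known change year, or a policy that
#' never changed).  Hospitals with unknown policy are excluded from both
#' numerator and denominator, so the curve is weighted by where caesarean
#' births actually happen rather than by a raw hospital fraction.  Years
#' with an empty denominator get \code{NA} with \code{defined = FALSE}
#' rather than a silent zero.
#'
#' @param hospitals data frame with \code{hospital_id},
#'   \code{policy_change_year} and \code{policy_status} (as produced by
#'   [generate_hospitals()]).
#' @param births_by_hospital_year data frame with columns
#'   \code{hospital_id}, \code{year} and \code{n_caesarean}; see
#'   [caesarean_births_by_hospital_year()].
#' @return an object of class \code{"uptake_curve"}: a data frame with
#'   columns \code{year}, \code{p_preincision}, \code{n_denominator} and
#'   \code{defined}.
#' @examples
#' hosp <- data.frame(hospital_id = c("A", "B"),
#'                    policy_change_year = c(2009L, 2011L),
#'                    policy_status = "changed")
#' births <- expand.grid(hospital_id = c("A", "B"), year = 2008:2012)
#' births$n_caesarean <- 100
#' estimate_uptake(hosp, births)
#' @export
estimate_uptake <- function(hospitals, births_by_hospital_year) {
  b <- births_by_hospital_year
  stopifnot(all(c("hospital_id", "year", "n_caesarean") %in% names(b)))
  if (any(b$n_caesarean < 0)) stop("birth counts must be >= 0", call. = FALSE)
  idx <- match(b$hospital_id, hospitals$hospital_id)
  if (anyNA(idx)) stop("unknown hospital_id in birth counts", call. = FALSE)
  status <- as.character(hospitals$policy_status)[idx]
  if (!any(status != "unknown"))
    stop("no hospital with a known policy", call. = FALSE)
  change <- hospitals$policy_change_year[idx]
  known <- status != "unknown"
  pre <- known & !is.na(change) & change < b$year
  years <- sort(unique(b$year))
  num <- vapply(years, function(y)
    sum(b$n_caesarean[pre & b$year == y]), numeric(1))
  den <- vapply(years, function(y)
    sum(b$n_caesarean[known & b$year == y]), numeric(1))
  curve <- data.frame(
    year = as.integer(years),
    p_preincision = ifelse(den > 0, num / den, NA_real_),
    n_denominator = den,
    defined = den > 0)
  class(curve) <- c("uptake_curve", "data.frame")
  curve
}

#' Tabulate caesarean births by hospital and year
#'
#' Helper building the denominator table for [estimate_uptake()] from a
#' cohort.
#'
#' @param cohort data frame with \code{hospital_id}, \code{birth_year}
#'   and \code{delivery_type}.
#' @return data frame with \code{hospital_id}, \code{year},
#'   \code{n_caesarean}.
#' @export
caesarean_births_by_hospital_year <- function(cohort) {
  cs <- cohort[cohort$delivery_type == "caesarean", , drop = FALSE]
  if (nrow(cs) == 0L)
    return(data.frame(hospital_id = character(), year = integer(),
                      n_caesarean = numeric()))
  agg <- stats::aggregate(
    list(n_caesarean = rep(1, nrow(cs))),
    by = list(hospital_id = cs$hospital_id, year = cs$birth_year),
    FUN = sum)
  agg[order(agg$hospital_id, agg$year), ]
}

#' Assign exposure to pre-incision antibiotics
#'
#' Attaches an exposure value and inclusion status to every child under
#' one of the two regimes used in the analysis:
#' \describe{
#'   \item{\code{"national"}}{caesarean births receive the national
#'     uptake probability for their birth year (a value in \[0, 1\]);
#'     vaginal births are classified as unexposed (0).  All births are
#'     included.  A missing or undefined curve year for a caesarean birth
#'     is an error.}
#'   \item{\code{"hospital"}}{caesarean births receive an indicator: 1 if
#'     the birth year is strictly after the hospital's policy-change
#'     year, 0 if strictly before; births in the change year itself are
#'     excluded (\code{excluded_change_year}), and births at hospitals
#'     with unknown policy are excluded
#'     (\code{excluded_unknown_policy}).  Vaginal births are unexposed
#'     controls and retained by default even at a hospital in its change
#'     year; set \code{exclude_vaginal_change_year = TRUE} to drop the
#'     whole hospital-year instead.}
#' }
#'
#' @param cohort data frame of children (see [generate_cohort()]).
#' @param regime \code{"national"} or \code{"hospital"}.
#' @param curve an \code{uptake_curve} (required for the national
#'   regime).
#' @param hospitals hospital survey table (required for the hospital
#'   regime).
#' @param exclude_vaginal_change_year logical; hospital regime only, see
#'   above.
#' @return the cohort with two added columns: \code{exposure} (numeric,
#'   \code{NA} for excluded births) and \code{exposure_status} (factor:
#'   \code{included}, \code{excluded_change_year},
#'   \code{excluded_unknown_policy}).
#' @examples
#' cfg <- sim_config(n_children = 300, seed = 11)
#' hosp <- generate_hospitals(cfg)
#' coh <- generate_cohort(cfg, hosp)
#' he <- assign_exposure(coh, "hospital", hospitals = hosp)
#' table(he$exposure_status)
#' @export
assign_exposure <- function(cohort,
                            regime = c("national", "hospital"),
                            curve = NULL, hospitals = NULL,
                            exclude_vaginal_change_year = FALSE) {
  regime <- match.arg(regime)
  n <- nrow(cohort)
  cs <- cohort$delivery_type == "caesarean"
  exposure <- numeric(n)
  status <- rep("included", n)

  if (regime == "national") {
    if (is.null(curve)) stop("national regime needs an uptake curve",
                             call. = FALSE)
    idx <- match(cohort$birth_year, curve$year)
    need <- cs
    if (anyNA(idx[need]))
      stop("uptake curve not defined for some birth years: ",
           paste(sort(unique(cohort$birth_year[need & is.na(idx)])),
                 collapse = ", "), call. = FALSE)
    p <- curve$p_preincision[idx]
    if (anyNA(p[need]))
      stop("uptake probability undefined (empty denominator) for years: ",
           paste(sort(unique(cohort$birth_year[need & is.na(p)])),
                 collapse = ", "), call. = FALSE)
    exposure[cs] <- p[cs]
  } else {
    if (is.null(hospitals)) stop("hospital regime needs the survey table",
                                 call. = FALSE)
    hidx <- match(cohort$hospital_id, hospitals$hospital_id)
    if (anyNA(hidx)) stop("unknown hospital_id in cohort", call. = FALSE)
    hstatus <- as.character(hospitals$policy_status)[hidx]
    change <- hospitals$policy_change_year[hidx]
    unknown <- hstatus == "unknown"
    in_change_year <- !is.na(change) & cohort$birth_year == change
    post <- !is.na(change) & cohort$birth_year > change
    exposure[cs] <- as.numeric(post[cs])
    status[cs & unknown] <- "excluded_unknown_policy"
    status[cs & !unknown & in_change_year] <- "excluded_change_year"
    if (exclude_vaginal_change_year) {
      status[!cs & unknown] <- "excluded_unknown_policy"
      status[!cs & !unknown & in_change_year] <- "excluded_change_year"
    }
    exposure[status != "included"] <- NA_real_
  }

  cohort$exposure <- exposure
  cohort$exposure_status <- factor(
    status, levels = c("included", "excluded_change_year",
                       "excluded_unknown_policy"))
  cohort
}
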