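#' Follow-up end under the earliest-of censoring rule
#'
#' For each child and one outcome, follow-up runs from birth to the
#' earliest of: the fifth birthday, the date of loss to follow-up, the
#' administrative study end, and the date the outcome was first
#' diagnosed.  The event indicator is 1 exactly when the diagnosis date
#' attains that minimum (ties in favour of the event, since the first
#' diagnosis defines the outcome).  Durations are measured as plain date
#' differences in days divided by 365.25.
#'
#' @param birth_date,ltfu_date,outcome_date \code{Date} vectors
#'   (recycled); \code{ltfu_date} and \code{outcome_date} may be
#'   \code{NA}.
#' @param study_end a single \code{Date}.
#' @return data frame with columns \code{fu_years} (length of follow-up
#'   in years) and \code{event} (integer 0/1).
#' @examples
#' follow_up_end(as.Date("2014-06-01"), as.Date(NA), as.Date(NA),
#'               as.Date("2018-12-31"))
#' @export
follow_up_end <- function(birth_date, ltfu_date, outcome_date, study_end) {
  n <- max(length(birth_date), length(ltfu_date), length(outcome_date))
  birth_date <- rep_len(birth_date, n)
  ltfu_date <- rep_len(ltfu_date, n)
  outcome_date <- rep_len(outcome_date, n)
  if (any(!is.na(outcome_date) & outcome_date < birth_date))
    stop("diagnosis date before birth date", call. = FALSE)
  if (any(!is.na(ltfu_date) & ltfu_date < birth_date))
    stop("loss to follow-up date before birth date", call. = FALSE)
  to_years <- function(d) as.numeric(d - birth_date) / 365.25
  cand <- cbind(fifth = 5,
                ltfu = to_years(ltfu_date),
                end = to_years(study_end),
                diag = to_years(outcome_date))
  fu <- do.call(pmin, c(as.data.frame(cand), na.rm = TRUE))
  event <- as.integer(!is.na(cand[, "diag"]) & cand[, "diag"] <= fu)
  data.frame(fu_years = fu, event = event)
}

#' Expand follow-up into person-year rows
#'
#' Splits one child's follow-up into one row per year of life lived
#' under observation: full years carry time 1, the final partial year
#' carries the fractional remainder, and the event indicator (if any)
#' sits on the final row only.  Ages use half-open intervals
#' \eqn{[a, a+1)}, so follow-up of exactly 5.0 years yields five rows of
#' time 1 and no row has \code{age_year >= 5}.
#'
#' @param fu_years follow-up length in years (scalar, > 0 expected; 0
#'   returns an empty frame with a warning).
#' @param event 0/1 event indicator for the end of follow-up.
#' @return data frame with columns \code{age_year}, \code{time} and
#'   \code{event}.
#' @examples
#' expand_person_years(4.583, event = 0)
#' @export
expand_person_years <- function(fu_years, event = 0L) {
  if (fu_years <= 0) {
    warning("zero follow-up: returning no person-year rows")
    return(data.frame(age_year = integer(), time = numeric(),
                      event = integer()))
  }
  k <- ceiling(fu_years - 1e-12)
  time <- rep(1, k)
  time[k] <- fu_years - (k - 1)
  data.frame(age_year = 0:(k - 1L), time = time,
             event = c(rep(0L, k - 1L), as.integer(event)))
}

#' Build the person-year analysis table for one outcome
#'
#' Applies [follow_up_end()] to every child and expands the result into
#' per-year-of-life rows (one observation per child per year of life in
#' the study), carrying the covariates the CITS models need.  Children
#' must already hold an \code{exposure} column (see [assign_exposure()]);
#' excluded children (\code{exposure_status != "included"}) are dropped.
#'
#' @param cohort data frame of children with exposure assigned.
#' @param outcome outcome name; the column \code{<outcome>_date} must
#'   exist.
#' @param study_end administrative study end date.
#' @return data frame with columns \code{child_id}, \code{birth_year},
#'   \code{age_year}, \code{delivery_type}, \code{caesarean_type},
#'   \code{exposure}, \code{time} and \code{event}.
#' @examples
#' cfg <- sim_config(n_children = 200, seed = 5)
#' hosp <- generate_hospitals(cfg)
#' coh <- assign_exposure(generate_cohort(cfg, hosp), "hospital",
#'                        hospitals = hosp)
#' rows <- person_year_table(coh, "asthma", cfg$study_end)
#' head(rows)
#' @export
person_year_table <- function(cohort, outcome, study_end) {
  dcol <- paste0(outcome, "_date")
  if (!dcol %in% names(cohort))
    stop("no such outcome column: ", dcol, call. = FALSE)
  if (!"exposure" %in% names(cohort))
    stop("cohort has no exposure column; run assign_exposure() first",
         call. = FALSE)
  if ("exposure_status" %in% names(cohort))
    cohort <- cohort[cohort$exposure_status == "included", , drop = FALSE]
  fe <- follow_up_end(cohort$birth_date, cohort$ltfu_date,
                      cohort[[dcol]], study_end)
  pos <- fe$fu_years > 0
  if (!all(pos)) {
    warning(sum(!pos), " children with zero follow-up dropped")
    cohort <- cohort[pos, , drop = FALSE]
    fe <- fe[pos, , drop = FALSE]
  }
  k <- pmin(ceiling(fe$fu_years - 1e-12), 5L)
  idx <- rep.int(seq_len(nrow(cohort)), k)
  age <- sequence(k) - 1L
  last <- cumsum(k)
  time <- rep(1, length(idx))
  time[last] <- fe$fu_years - (k - 1)
  event <- integer(length(idx))
  event[last] <- fe$event
  data.frame(
    child_id = cohort$child_id[idx],
    birth_year = cohort$birth_year[idx],
    age_year = age,
    delivery_type = cohort$delivery_type[idx],
    caesarean_type = cohort$caesarean_type[idx],
    exposure = cohort$exposure[idx],
    time = time,
    event = event,
    stringsAsFactors = FALSE)
}

#' Collapse person-year rows into covariate cells
#'
#' Sums events and person-time within cells defined by the analysis
#' covariates.  The Poisson log-likelihood with a log person-time offset
#' is invariant to this collapse, so model fits on the collapsed table
#' are identical to fits on the child-level rows while being much
#' faster; it is the standard aggregation for piecewise-constant rate
#' models.
#'
#' @param rows person-year table from [person_year_table()].
#' @param by covariate columns defining the cells.
#' @return data frame with the \code{by} columns plus summed
#'   \code{event} and \code{time}.
#' @export
collapse_person_years <- function(rows,
                                  by = c("birth_year", "age_year",
                                         "delivery_type",
                                         "caesarean_type", "exposure")) {
  by <- intersect(by, names(rows))
  key <- do.call(paste, c(rows[by], list(sep = "\r")))
  ev <- rowsum(cbind(event = rows$event, time = rows$time), key)
  u <- !duplicated(key)
  first <- rows[u, by, drop = FALSE]
  first <- first[match(rownames(ev), key[u]), , drop = FALSE]
  out <- cbind(first, as.data.frame(ev))
  rownames(out) <- NULL
  out
}

#' Total events and person-years
#'
#' @param rows a person-year table (see [person_year_table()]).
#' @return named numeric vector \code{c(n_events, person_years)}.
#' @export
total_person_years <- function(rows) {
  if (NROW(rows) == 0L) stop("empty person-year table", call. = FALSE)
  c(n_events = sum(rows$event), person_years = sum(rows$time))
}
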