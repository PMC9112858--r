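#' Round half away from zero
#'
#' Display rounding for rates and percentages.  Base R's \code{round()}
#' rounds half to even; published tables conventionally round half up,
#' so 72.355 displays as 72.36 rather than 72.35 (at magnitudes where
#' floating point representation does not already decide the tie).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Event rate per 1000 person-years with log-normal confidence interval
#'
#' The rate is \code{1000 * n_events / person_years}; the 95% interval
#' multiplies and divides the rate by \code{exp(z / sqrt(n_events))}
#' (a Wald interval for the log rate with Poisson variance
#' \code{1/n_events}).  The interval is undefined at zero events.
#'
#' @param n_events number of individuals with the outcome.
#' @param person_years total time at risk in years (> 0).
#' @param conf_level confidence level (default 0.95).
#' @param digits display rounding (default 2 decimals, half up).
#' @return object of class \code{"rate_summary"}: list with
#'   \code{n_events}, \code{person_years}, \code{rate} (full precision),
#'   \code{rate_display}, \code{ci95}, \code{ci95_display}.
#' @examples
#' rate_per_1000(16540, 1670173)   # 9.90 (9.75 to 10.06)
#' rate_per_1000(102888, 1430708)  # 71.91 (71.48 to 72.35)
#' @export
rate_per_1000 <- function(n_events, person_years, conf_level = 0.95,
                          digits = 2) {
  if (person_years <= 0) stop("person_years must be > 0", call. = FALSE)
  if (n_events < 0) stop("n_events must be >= 0", call. = FALSE)
  rate <- 1000 * n_events / person_years
  if (n_events > 0) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    f <- exp(z / sqrt(n_events))
    ci <- c(rate / f, rate * f)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(n_events = n_events, person_years = person_years,
                 rate = rate, rate_display = round_half_up(rate, digits),
                 ci95 = ci, ci95_display = round_half_up(ci, digits)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  ci <- if (anyNA(x$ci95)) "CI undefined (no events)" else
    sprintf("%.2f to %.2f", x$ci95_display[1], x$ci95_display[2])
  cat(sprintf("%d events / %.0f person-years: %.2f per 1000 (%s)\n",
              x$n_events, x$person_years, x$rate_display, ci))
  invisible(x)
}

#' Percentage of a denominator
#'
#' @param n numerator count.
#' @param denom denominator count (> 0).
#' @param digits display rounding (half up).
#' @return list with \code{percent} (full precision) and
#'   \code{percent_display}.
#' @examples
#' proportion(12466, 144861)$percent_display   # 8.61
#' proportion(144861, 515945, digits = 1)$percent_display  # 28.1
#' @export
proportion <- function(n, denom, digits = 2) {
  if (denom <= 0) stop("denominator must be > 0", call. = FALSE)
  pct <- 100 * n / denom
  list(percent = pct, percent_display = round_half_up(pct, digits))
}

#' Build report tables for a cohort and its model results
#'
#' Produces the two table layouts of the evaluation: births by calendar
#' year and delivery type (with a totals row), and a per-outcome results
#' table combining event counts, person-years, rates per 1000
#' person-years with confidence intervals, and the model's rate ratio,
#' interval and p-value.  Rare outcomes appear with their counts and
#' \code{NA} in the model columns (rendered as a dash in the text
#' output); outcomes requested but missing from \code{results} are
#' listed with a \code{missing} status rather than silently dropped.
#' Counts of 5 or fewer can be masked.
#'
#' @param cohort child cohort data frame.
#' @param results named list: per outcome, a list with elements
#'   \code{rate} (a \code{rate_summary}) and \code{model} (a \code{cits}
#'   object), or \code{NULL} for a missing outcome.
#' @param dir optional output directory; when given,
#'   \code{births_by_year.csv}, \code{outcome_results.csv} and a
#'   human-readable \code{outcome_results.txt} are written.
#' @param mask_small logical; mask counts <= 5 as \code{"<=5"} in the
#'   text rendering.
#' @return invisibly, list with data frames \code{births_by_year} and
#'   \code{outcomes}.
#' @export
build_tables <- function(cohort, results, dir = NULL, mask_small = FALSE) {
  if (nrow(cohort) > 0) {
    tab <- table(factor(cohort$birth_year),
                 factor(cohort$delivery_type,
                        levels = c("caesarean", "vaginal")))
    births <- data.frame(year = rownames(tab),
                         caesarean = as.integer(tab[, "caesarean"]),
                         vaginal = as.integer(tab[, "vaginal"]),
                         stringsAsFactors = FALSE)
    births <- rbind(births,
                    data.frame(year = "Total",
                               caesarean = sum(births$caesarean),
                               vaginal = sum(births$vaginal)))
  } else {
    births <- data.frame(year = character(), caesarean = integer(),
                         vaginal = integer())
  }

  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    if (is.null(r))
      return(data.frame(outcome = nm, status = "missing",
                        n_events = NA_integer_, person_years = NA_real_,
                        rate = NA_real_, rate_low = NA_real_,
                        rate_high = NA_real_, irr = NA_real_,
                        irr_low = NA_real_, irr_high = NA_real_,
                        p_value = NA_real_))
    rare <- isTRUE(r$model$rare_flag)
    data.frame(
      outcome = nm,
      status = if (rare) "rare" else "modelled",
      n_events = r$rate$n_events,
      person_years = r$rate$person_years,
      rate = r$rate$rate_display,
      rate_low = r$rate$ci95_display[1],
      rate_high = r$rate$ci95_display[2],
      irr = if (rare) NA_real_ else r$model$effect,
      irr_low = if (rare) NA_real_ else r$model$ci95[1],
      irr_high = if (rare) NA_real_ else r$model$ci95[2],
      p_value = if (rare) NA_real_ else r$model$p_value)
  })
  outcomes <- do.call(rbind, rows)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(births, file.path(dir, "births_by_year.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes, file.path(dir, "outcome_results.csv"),
                     row.names = FALSE)
    writeLines(render_outcome_table(outcomes, mask_small),
               file.path(dir, "outcome_results.txt"))
  }
  invisible(list(births_by_year = births, outcomes = outcomes))
}

render_outcome_table <- function(outcomes, mask_small = FALSE) {
  if (nrow(outcomes) == 0L)
    return("Outcome | N (person-years) | Rate/1000py (95% CI) | IRR (95% CI) | P")
  fmt_n <- function(n) {
    if (is.na(n)) return("-")
    if (mask_small && n <= 5) return("<=5")
    format(n, big.mark = " ")
  }
  lines <- apply(outcomes, 1, function(r) {
    if (r[["status"]] == "missing")
      return(sprintf("%s | absent from results", r[["outcome"]]))
    n <- as.integer(r[["n_events"]])
    py <- as.numeric(r[["person_years"]])
    rate_txt <- sprintf("%s (%s to %s)", r[["rate"]], r[["rate_low"]],
                        r[["rate_high"]])
    irr_txt <- if (r[["status"]] == "rare") "- | -"
      else sprintf("%.2f (%.2f to %.2f) | %.3g",
                   as.numeric(r[["irr"]]), as.numeric(r[["irr_low"]]),
                   as.numeric(r[["irr_high"]]), as.numeric(r[["p_value"]]))
    sprintf("%s | %s (%.0f) | %s | %s", r[["outcome"]], fmt_n(n), py,
            rate_txt, irr_txt)
  })
  c("Outcome | N (person-years) | Rate/1000py (95% CI) | IRR (95% CI) | P",
    lines)
}

#' Published UK births by year and delivery type
#'
#' Reads the bundled table of births with known delivery type by
#' calendar year in the two UK cohorts the synthetic generator emulates:
#' the linked primary-care cohort and the English hospital-admissions
#' cohort (full, and restricted to hospitals with known antibiotic
#' policy).  Dashes in the published table are \code{NA}.
#'
#' @return data frame with columns \code{year},
#'   \code{primary_care_caesarean}, \code{primary_care_vaginal},
#'   \code{hes_caesarean}, \code{hes_vaginal},
#'   \code{hes_known_policy_caesarean}, \code{hes_known_policy_vaginal}.
#' @export
uk_births_by_year <- function() {
  utils::read.csv(system.file("extdata", "uk_births_by_year.csv",
                              package = "citsepi"))
}
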