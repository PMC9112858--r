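#' Rare-outcome guard
#'
#' Model fitting is suppressed for outcomes with fewer than 200 affected
#' individuals over the study period; only summary counts are reported
#' for such outcomes.
#'
#' @param n_events number of individuals with the outcome.
#' @param threshold minimum count at which models are fitted (default
#'   200).
#' @return \code{TRUE} when the outcome is too rare to model.
#' @examples
#' rare_guard(199)  # TRUE
#' rare_guard(200)  # FALSE
#' @export
rare_guard <- function(n_events, threshold = 200L) {
  stopifnot(n_events >= 0)
  n_events < threshold
}

cits_covariates <- function(variant, coding, interaction = FALSE) {
  yr <- switch(variant,
               maternal = "delivery_year",
               continuous = "delivery_year",
               "birth_year")
  yr_t <- if (coding == "categorical") paste0("factor(", yr, ")") else yr
  age_t <- if (coding == "categorical") "factor(age_year)" else "age_year"
  base <- switch(variant,
    primary_care = c(yr_t, age_t, paste0(yr_t, ":", age_t), "delivery_type"),
    hes = c(yr_t, "delivery_type"),
    maternal = c(yr_t, "delivery_type"),
    continuous = c(yr_t, "delivery_type"))
  exp_t <- if (interaction) c("exposure:cs_group") else "exposure"
  c(base, exp_t)
}

#' Fit a controlled interrupted time series model
#'
#' The single fitting front end for the four model variants used in the
#' policy evaluation.  All variants share the design logic of a
#' controlled interrupted time series: vaginal deliveries form a control
#' series absorbing secular trends, and the exposure term carries the
#' policy effect.
#'
#' \describe{
#'   \item{\code{"primary_care"}}{Poisson regression on per-year-of-life
#'     person-time rows with a \code{log(time)} offset and covariates for
#'     year of birth, age (year of life), their interaction, delivery
#'     type, and exposure.  Exposure may be a probability in \[0, 1\]
#'     (national uptake regime): it enters linearly on the log-rate
#'     scale, so \code{exp(beta)} is interpreted as fully exposed versus
#'     unexposed.}
#'   \item{\code{"hes"}}{as above with covariates for year of birth,
#'     delivery type and exposure (an indicator under the hospital
#'     change-year regime).}
#'   \item{\code{"maternal"}}{Poisson regression with log link on a
#'     binary six-week postpartum outcome (one row per delivery, no
#'     offset), estimating a risk ratio, with covariates for year of
#'     delivery and delivery type.  A log-link Poisson fit is used
#'     instead of logistic regression so the effect is a rate/risk ratio
#'     rather than an odds ratio.}
#'   \item{\code{"continuous"}}{ordinary least squares for continuous
#'     outcomes (e.g. length of stay), estimating an adjusted difference
#'     in means, with covariates for year of delivery and delivery
#'     type.}
#' }
#'
#' Effects are reported with Wald 95% confidence intervals, computed on
#' the log scale for the ratio models (\code{exp(beta +/- 1.96 se)}).
#' Outcomes affecting fewer than \code{rare_threshold} individuals are
#' not modelled: the returned object carries counts only, with
#' \code{rare_flag = TRUE}.
#'
#' @param data a person-year table ([person_year_table()]) for the
#'   \code{"primary_care"}/\code{"hes"} variants, or a deliveries table
#'   ([generate_maternal()]) for \code{"maternal"}/\code{"continuous"}.
#'   Maternal variants require \code{exposure} and \code{delivery_year}
#'   columns.
#' @param variant model variant, see above.
#' @param outcome outcome column name (maternal and continuous variants
#'   only).
#' @param coding \code{"categorical"} (default: year and age as factors
#'   with the earliest level as reference, flexible trends) or
#'   \code{"linear"} (log-linear trends).
#' @param rare_threshold rare-outcome guard threshold (default 200).
#' @param dispersion \code{"poisson"} (default) or
#'   \code{"quasipoisson"} for an overdispersion-scaled variance.
#' @param formula optional model formula overriding the variant's
#'   covariate set; the exposure term must still be named
#'   \code{exposure}.
#' @param control a [stats::glm.control()] list; default tolerance 1e-12
#'   and up to 100 iterations.
#' @return an object of class \code{"cits"}: a list with the fitted
#'   model (\code{fit}), \code{effect} (IRR, risk ratio, or mean
#'   difference), \code{ci95}, \code{p_value}, \code{n_events},
#'   \code{rare_flag}, \code{converged}, \code{estimable} and
#'   bookkeeping fields.  Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{vcov}, \code{confint}, \code{predict},
#'   \code{residuals}, \code{simulate}, \code{plot}.
#' @examples
#' cfg <- sim_config(n_children = 2000, baseline_rate = c(asthma = 40),
#'                   seed = 2)
#' hosp <- generate_hospitals(cfg)
#' coh <- assign_exposure(generate_cohort(cfg, hosp), "hospital",
#'                        hospitals = hosp)
#' rows <- person_year_table(coh, "asthma", cfg$study_end)
#' fit <- cits(rows, variant = "hes", coding = "linear")
#' fit
#' @export
cits <- function(data,
                 variant = c("primary_care", "hes", "maternal",
                             "continuous"),
                 outcome = NULL,
                 coding = c("categorical", "linear"),
                 rare_threshold = 200L,
                 dispersion = c("poisson", "quasipoisson"),
                 formula = NULL,
                 control = stats::glm.control(epsilon = 1e-12,
                                              maxit = 100L)) {
  variant <- match.arg(variant)
  coding <- match.arg(coding)
  dispersion <- match.arg(dispersion)
  cl <- match.call()

  is_rate <- variant %in% c("primary_care", "hes")
  if (is_rate) {
    stopifnot(all(c("event", "time", "exposure") %in% names(data)))
    if (any(data$time <= 0)) stop("person-time must be positive",
                                  call. = FALSE)
    ok <- !is.na(data$exposure)
    if (any(data$exposure[ok] < 0 | data$exposure[ok] > 1))
      stop("exposure must lie in [0, 1]", call. = FALSE)
    response <- "event"
    n_events <- sum(data$event)
  } else {
    if (is.null(outcome))
      stop("maternal and continuous variants need `outcome`",
           call. = FALSE)
    if (!outcome %in% names(data))
      stop("no such outcome column: ", outcome, call. = FALSE)
    stopifnot("exposure" %in% names(data))
    response <- outcome
    n_events <- if (variant == "maternal") sum(data[[outcome]])
                else sum(!is.na(data[[outcome]]))
  }

  res <- structure(list(
    call = cl, variant = variant, coding = coding, outcome = outcome,
    effect_scale = if (variant == "continuous") "difference" else "ratio",
    n_events = n_events, n_obs = nrow(data),
    rare_flag = FALSE, converged = NA, estimable = NA,
    effect = NA_real_, ci95 = c(NA_real_, NA_real_),
    p_value = NA_real_, fit = NULL, dispersion = dispersion),
    class = "cits")

  if (variant != "continuous" && rare_guard(n_events, rare_threshold)) {
    res$rare_flag <- TRUE
    return(res)
  }

  if (is.null(formula)) {
    rhs <- paste(cits_covariates(variant, coding), collapse = " + ")
    formula <- stats::as.formula(paste(response, "~", rhs))
  }

  if (variant == "continuous") {
    fit <- stats::lm(formula, data = data)
  } else {
    fam <- if (dispersion == "poisson") stats::poisson(link = "log")
           else stats::quasipoisson(link = "log")
    if (is_rate) {
      data$.log_time <- log(data$time)
      formula <- stats::update(formula, . ~ . + offset(.log_time))
    }
    fit <- stats::glm(formula, family = fam, data = data,
                      control = control)
  }

  res$fit <- fit
  res$converged <- if (inherits(fit, "glm")) fit$converged else TRUE

  cf <- stats::coef(fit)
  if (!"exposure" %in% names(cf) || is.na(cf[["exposure"]])) {
    res$estimable <- FALSE
    warning("exposure coefficient inestimable (degenerate design)")
    return(res)
  }
  se <- sqrt(diag(stats::vcov(fit))[["exposure"]])
  beta <- cf[["exposure"]]
  ## crude separation screen: absurd coefficient or exploding SE
  if (!is.finite(se) || se > 100 || abs(beta) > 15) {
    res$estimable <- FALSE
    res$converged <- FALSE
    warning("exposure effect unstable (possible complete separation)")
    return(res)
  }
  res$estimable <- TRUE
  z <- stats::qnorm(0.975)
  if (res$effect_scale == "ratio") {
    res$effect <- exp(beta)
    res$ci95 <- exp(beta + c(-1, 1) * z * se)
  } else {
    res$effect <- beta
    res$ci95 <- beta + c(-1, 1) * z * se
  }
  res$p_value <- 2 * stats::pnorm(-abs(beta / se))
  res
}

effect_label <- function(x) {
  switch(x$variant,
         maternal = "Risk ratio (Poisson, log link)",
         continuous = "Adjusted mean difference",
         "Incidence rate ratio")
}

#' @export
print.cits <- function(x, digits = 3, ...) {
  cat(sprintf("Controlled interrupted time series fit (variant: %s)\n",
              x$variant))
  if (!is.null(x$outcome)) cat(sprintf("Outcome: %s\n", x$outcome))
  cat(sprintf("Observations: %d; individuals with event: %d\n",
              x$n_obs, x$n_events))
  if (x$rare_flag) {
    cat("Rare outcome: summary counts only, no model fitted.\n")
  } else if (!isTRUE(x$estimable)) {
    cat("Exposure effect not estimable (degenerate design or separation).\n")
  } else {
    cat(sprintf("%s: %.*f (95%% CI %.*f to %.*f), p = %s\n",
                effect_label(x), digits, x$effect, digits, x$ci95[1],
                digits, x$ci95[2], format.pval(x$p_value, digits = 2)))
    if (!isTRUE(x$converged)) cat("Warning: fit did not converge.\n")
  }
  invisible(x)
}

#' @export
summary.cits <- function(object, ...) {
  out <- list(cits = object,
              fit_summary = if (!is.null(object$fit)) summary(object$fit))
  class(out) <- "summary.cits"
  out
}

#' @export
print.summary.cits <- function(x, ...) {
  print(x$cits)
  if (!is.null(x$fit_summary)) {
    cat("\nUnderlying model fit:\n")
    print(x$fit_summary)
  }
  invisible(x)
}

#' @export
coef.cits <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::coef(object$fit)
}

#' @export
vcov.cits <- function(object, ...) {
  if (is.null(object$fit)) return(NULL)
  stats::vcov(object$fit)
}

#' Wald confidence intervals for a CITS fit
#'
#' Intervals are computed as \code{estimate +/- z * se} on the linear
#' predictor scale (the log-rate scale for the ratio variants).
#'
#' @param object a \code{cits} object.
#' @param parm coefficients to include (default all).
#' @param level confidence level.
#' @param ... unused.
#' @export
confint.cits <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$fit)) return(NULL)
  cf <- stats::coef(object$fit)
  se <- sqrt(diag(stats::vcov(object$fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2), digits = 3),
                        "%")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.cits <- function(object, ...) {
  if (is.null(object$fit)) stop("no fitted model (rare outcome?)",
                                call. = FALSE)
  stats::predict(object$fit, ...)
}

#' @export
residuals.cits <- function(object, ...) {
  if (is.null(object$fit)) stop("no fitted model (rare outcome?)",
                                call. = FALSE)
  stats::residuals(object$fit, ...)
}

#' @export
simulate.cits <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fit)) stop("no fitted model (rare outcome?)",
                                call. = FALSE)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Plot observed and fitted event rates over time
#'
#' Draws the observed yearly event rate per 1000 person-years for each
#' delivery type together with the model's fitted rates, the visual
#' summary of a controlled interrupted time series.  Only meaningful for
#' the rate variants.
#'
#' @param x a \code{cits} object fitted to a person-year table.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cits <- function(x, ...) {
  if (is.null(x$fit) || !x$variant %in% c("primary_care", "hes"))
    stop("plotting is defined for fitted rate models only", call. = FALSE)
  d <- x$fit$model
  yr <- d[["factor(birth_year)"]]
  if (is.null(yr)) yr <- d[["birth_year"]]
  yr <- as.integer(as.character(yr))
  grp <- d$delivery_type
  t_obs <- exp(x$fit$offset)
  obs <- 1000 * tapply(d$event, list(yr, grp), sum) /
    tapply(t_obs, list(yr, grp), sum)
  fitted_ev <- stats::fitted(x$fit)
  fit <- 1000 * tapply(fitted_ev, list(yr, grp), sum) /
    tapply(t_obs, list(yr, grp), sum)
  yrs <- as.integer(rownames(obs))
  graphics::matplot(yrs, obs, pch = c(1, 16), col = c("grey40", "black"),
                    xlab = "Year of birth",
                    ylab = "Events per 1000 person-years", ...)
  graphics::matlines(yrs, fit, lty = c(2, 1), col = c("grey40", "black"))
  graphics::legend("topleft", bty = "n",
                   legend = paste(colnames(obs), c("(control)", "")),
                   pch = c(1, 16), lty = c(2, 1),
                   col = c("grey40", "black"))
  invisible(x)
}

#' Exploratory subgroup analysis by caesarean type
#'
#' Refits the CITS model with the exposure term split by caesarean type
#' (elective versus emergency) via an interaction, returning per-subgroup
#' incidence rate ratios and a Wald p-value for the difference between
#' them.
#'
#' @param rows person-year table including \code{caesarean_type}.
#' @param variant \code{"primary_care"} or \code{"hes"}.
#' @param coding year/age coding, as in [cits()].
#' @return list with \code{irr_elective}, \code{irr_emergency} (each a
#'   vector of estimate, lower, upper), \code{interaction_ratio},
#'   \code{interaction_p}, and the underlying \code{fit}.
#' @export
subgroup_interaction <- function(rows,
                                 variant = c("primary_care", "hes"),
                                 coding = c("categorical", "linear")) {
  variant <- match.arg(variant)
  coding <- match.arg(coding)
  cs <- rows$delivery_type == "caesarean"
  if (!any(cs)) stop("no caesarean rows: interaction undefined",
                     call. = FALSE)
  if (any(cs & is.na(rows$caesarean_type)))
    stop("caesarean rows with missing caesarean_type", call. = FALSE)
  rows$exp_elective <- rows$exposure *
    (cs & rows$caesarean_type == "elective")
  rows$exp_emergency <- rows$exposure *
    (cs & rows$caesarean_type == "emergency")
  for (v in c("exp_elective", "exp_emergency")) {
    if (sum(rows[[v]], na.rm = TRUE) == 0)
      stop("subgroup with no exposed person-time: ", v, call. = FALSE)
  }
  base <- setdiff(cits_covariates(variant, coding), "exposure")
  f <- stats::as.formula(paste(
    "event ~", paste(c(base, "exp_elective", "exp_emergency"),
                     collapse = " + ")))
  fit <- stats::glm(f, family = stats::poisson(), data = rows,
                    offset = log(rows$time),
                    control = stats::glm.control(epsilon = 1e-12,
                                                 maxit = 100L))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  z <- stats::qnorm(0.975)
  one <- function(term) {
    b <- cf[[term]]; se <- sqrt(V[term, term])
    c(estimate = exp(b), lower = exp(b - z * se), upper = exp(b + z * se))
  }
  db <- cf[["exp_elective"]] - cf[["exp_emergency"]]
  dse <- sqrt(V["exp_elective", "exp_elective"] +
                V["exp_emergency", "exp_emergency"] -
                2 * V["exp_elective", "exp_emergency"])
  list(irr_elective = one("exp_elective"),
       irr_emergency = one("exp_emergency"),
       interaction_ratio = exp(db),
       interaction_se = dse,
       interaction_p = 2 * stats::pnorm(-abs(db / dse)),
       fit = fit)
}
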