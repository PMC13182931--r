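#' The 19-variable confounder adjustment set
#'
#' Default confounders for per-nutrient Cox models: serum chloride, carbon
#' dioxide combining power, white blood cells, hemoglobin, urea, serum
#' calcium, potassium, sodium, creatinine, phosphorus, albumin,
#' high-sensitivity C-reactive protein, glucose, weight, systolic and
#' diastolic blood pressure, diabetes, body-mass index, and glomerular
#' filtration rate. Serum electrolytes are distinct measurements from the
#' dietary mineral intakes and remain in the set even when the nutrient
#' under study is the matching dietary mineral; albumin stays in the set
#' even within albumin strata, where it still varies.
#'
#' @return Character vector of profile column names.
#' @export
default_confounders <- function() {
  c("serum_cl", "co2cp", "wbc", "hb", "urea", "serum_ca", "serum_k",
    "serum_na", "scr", "serum_p", "albumin", "hs_crp", "glucose",
    "weight", "sbp", "dbp", "diabetes", "bmi", "gfr")
}

#' Per-unit scalings used for reporting hazard ratios
#'
#' Conventional reporting scale per nutrient (e.g. water per 100 g/d, fat
#' per 10 g/d, DPI per 0.1 g/kg/d); nutrients not listed are reported per
#' single unit.
#'
#' @return Named numeric vector of divisors.
#' @export
unit_scales <- function() {
  c(water = 100, fat = 10, calories = 10, k = 10, na = 100, mg = 10,
    ca = 100, p = 10, retinol = 10, vitamin_a = 100, carotene = 100,
    dpi = 0.1)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood with the Efron tie correction
#' (via \pkg{survival}). The thin wrapper enforces this package's input
#' contracts and returns the pieces downstream stages consume.
#'
#' @param time Follow-up times, > 0.
#' @param status Event indicator (1 = event).
#' @param x Numeric covariate matrix or data frame, no constant column.
#' @return A list of class \code{"cox_fit"}: \code{coef}, \code{vcov},
#'   \code{loglik} (maximised partial log-likelihood), and the underlying
#'   \code{model}.
#' @examples
#' set.seed(1)
#' d <- data.frame(z = rnorm(40))
#' t <- rexp(40, exp(0.5 * d$z))
#' fit_cox(t, rep(1, 40), d)$coef
#' @export
fit_cox <- function(time, status, x) {
  x <- as.matrix(x)
  if (sum(status) < 1) stop("fit_cox: no events in the data")
  if (any(!is.finite(x))) stop("fit_cox: covariates must be finite")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("fit_cox: constant covariate column(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  fit <- survival::coxph(survival::Surv(time, status) ~ x, ties = "efron")
  if (any(!is.finite(fit$coefficients)) || any(!is.finite(diag(fit$var))))
    stop("fit_cox: fit did not converge (possible separation)")
  cf <- stats::setNames(fit$coefficients, colnames(x))
  vc <- fit$var
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(coef = cf, vcov = vc, loglik = fit$loglik[2], model = fit),
            class = "cox_fit")
}

#' Confounder-adjusted hazard ratio for one nutrient
#'
#' Fits one multivariate Cox model per nutrient -- the scaled nutrient plus
#' the confounder set -- on all patients or one stratum, and reports the
#' hazard ratio per \code{unit_scale} units with its Wald 95% CI and P.
#'
#' @param profiles A \code{diet_profiles} data frame.
#' @param nutrient Nutrient column name.
#' @param confounders Confounder column names (default
#'   [default_confounders()]).
#' @param unit_scale Report the HR per this many intake units (default from
#'   [unit_scales()], else 1).
#' @param subset Optional logical/integer row subset (e.g. one albumin
#'   stratum).
#' @param group Label stored in the result.
#' @return A list of class \code{"cox_result"}: \code{hr}, \code{ci95},
#'   \code{p_wald}, \code{coef}, \code{vcov}, the fitted \code{"cox_fit"}
#'   and bookkeeping fields.
#' @export
nutrient_hr <- function(profiles, nutrient, confounders = default_confounders(),
                        unit_scale = NULL, subset = NULL, group = "all") {
  need <- c(nutrient, confounders, "time", "status")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop(sprintf("nutrient_hr: missing column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(unit_scale)) {
    us <- unit_scales()
    unit_scale <- if (nutrient %in% names(us)) us[[nutrient]] else 1
  }
  d <- if (is.null(subset)) profiles else profiles[subset, , drop = FALSE]
  d <- d[stats::complete.cases(d[, need, drop = FALSE]), , drop = FALSE]
  p <- length(confounders) + 1L
  if (nrow(d) <= p + 1L)
    stop(sprintf(paste("nutrient_hr: group '%s' has %d complete rows for %d",
                       "covariates; reduce the confounder set"),
                 group, nrow(d), p))
  xm <- cbind(d[[nutrient]] / unit_scale,
              as.matrix(d[, confounders, drop = FALSE]))
  colnames(xm) <- c(nutrient, confounders)
  fit <- fit_cox(d$time, d$status, xm)
  b <- fit$coef[[nutrient]]
  se <- sqrt(fit$vcov[nutrient, nutrient])
  structure(list(
    nutrient = nutrient, group = group, unit_scale = unit_scale,
    hr = exp(b), ci95 = exp(b + c(-1, 1) * 1.96 * se),
    p_wald = 2 * stats::pnorm(-abs(b / se)),
    coef = fit$coef, vcov = fit$vcov, fit = fit,
    n = nrow(d), n_events = sum(d$status),
    data = d
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> %s (%s, per %g unit): HR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$nutrient, x$group, x$unit_scale, x$hr,
              x$ci95[1], x$ci95[2], x$p_wald))
  invisible(x)
}

#' Per-patient risk scores from a fitted Cox model
#'
#' \code{s_i = exp(eta_i - mean(eta))} where \code{eta_i} is the full linear
#' predictor (nutrient terms plus confounders); the geometric mean of the
#' scores is exactly 1, so \code{s < 1} reads "below the group's average
#' predicted risk".
#'
#' @param coefs Named coefficient vector.
#' @param x Covariate matrix with matching column names.
#' @return Positive numeric vector of scores.
#' @export
risk_scores <- function(coefs, x) {
  x <- as.matrix(x)
  miss <- setdiff(names(coefs), colnames(x))
  if (length(miss))
    stop(sprintf("risk_scores: covariate(s) %s absent from data",
                 paste(miss, collapse = ", ")))
  eta <- drop(x[, names(coefs), drop = FALSE] %*% coefs)
  exp(eta - mean(eta))
}

#' Intake-score pairs for one nutrient
#'
#' One \code{(intake, score)} pair per included patient, no resampling.
#'
#' @param intake Nutrient intakes.
#' @param scores Risk scores aligned with \code{intake}.
#' @param nutrient,group Labels.
#' @return A data frame of class \code{"risk_pairs"} with columns \code{t}
#'   (intake) and \code{s} (score).
#' @export
build_risk_pairs <- function(intake, scores, nutrient = "", group = "all") {
  if (length(intake) == 0L) stop("build_risk_pairs: empty group")
  if (length(intake) != length(scores))
    stop("build_risk_pairs: intake and scores must align")
  res <- data.frame(t = intake, s = scores)
  attr(res, "nutrient") <- nutrient
  attr(res, "group") <- group
  class(res) <- c("risk_pairs", "data.frame")
  res
}

#' Table of adjusted hazard ratios across nutrients and groups
#'
#' One [nutrient_hr()] fit per (nutrient, group) combination, including the
#' pooled cohort, assembled in the conventional report shape.
#'
#' @param profiles A \code{diet_profiles} data frame.
#' @param assignment Optional [tertile_split()] result; when supplied, each
#'   stratum is fitted in addition to the pooled cohort.
#' @param nutrients Nutrient column names (default: the profile's nutrient
#'   columns).
#' @param confounders Confounder column names.
#' @return Data frame: nutrient, unit_scale, group, hr, ci_lo, ci_hi, p.
#' @export
hr_table <- function(profiles, assignment = NULL,
                     nutrients = attr(profiles, "nutrient_cols"),
                     confounders = default_confounders()) {
  groups <- list(all = NULL)
  if (!is.null(assignment)) {
    m <- match(profiles$patient_id, assignment$patient_id)
    for (g in levels(assignment$group))
      groups[[g]] <- which(assignment$group[m] == g)
  }
  rows <- list()
  for (nm in nutrients) for (g in names(groups)) {
    cr <- nutrient_hr(profiles, nm, confounders,
                      subset = groups[[g]], group = g)
    rows[[length(rows) + 1L]] <- data.frame(
      nutrient = nm, unit_scale = cr$unit_scale, group = g,
      hr = cr$hr, ci_lo = cr$ci95[1], ci_hi = cr$ci95[2], p = cr$p_wald,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
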