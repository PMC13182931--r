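#' Two-stage nonlinear diet-mortality dose-response fit
#'
#' The package's core estimator for one nutrient in one patient set.
#' Stage 1 fits a confounder-adjusted Cox proportional-hazards model of
#' all-cause mortality in which the nutrient enters through a restricted
#' cubic spline basis (Efron ties), and converts each patient's full linear
#' predictor into a risk score \code{s = exp(eta - mean(eta))} with
#' geometric mean 1. Stage 2 regresses \code{log(s)} on the same spline
#' basis of intake by ordinary least squares, tests overall association and
#' nonlinearity with nested F-tests, and extracts the intake ranges where
#' the centred fitted hazard-ratio curve lies below 1.
#'
#' With \code{nutrient_form = "linear"} the stage-1 model uses the nutrient
#' as a single linear term (the form behind conventional per-nutrient HR
#' tables); its scores carry no curvature information, so stage 2 can then
#' only delineate a monotone threshold.
#'
#' @param profiles A [build_profiles()] data frame (needs \code{time},
#'   \code{status}, the nutrient and the confounders).
#' @param nutrient Nutrient column name.
#' @param confounders Confounder column names (default
#'   [default_confounders()]).
#' @param subset Optional row subset (e.g. one albumin stratum).
#' @param group Label for the subset.
#' @param k Number of spline knots (3-5, default 4), placed by
#'   [choose_knots()].
#' @param nutrient_form \code{"spline"} (default) or \code{"linear"}
#'   stage-1 nutrient term.
#' @return An object of class \code{"diet_response"} with print, summary,
#'   coef, predict, plot and residuals methods. Key fields: \code{cox}
#'   (stage-1 fit), \code{spline} (stage-2 fit), \code{p_overall},
#'   \code{p_nonlinear}, \code{ranges} (a [extract_ranges()] result) and
#'   \code{linear_hr} (the conventional linear-Cox hazard ratio for the
#'   same data).
#' @examples
#' ch <- generate_cohort(cohort_config(
#'   n_patients = 250, seed = 3,
#'   effect_specs = list(effect_spec("zn", "quadratic",
#'                                   center = 8.18, curvature = 0.06))))
#' pr <- build_profiles(ch)
#' fit <- diet_response(pr, "zn")
#' fit
#' @export
diet_response <- function(profiles, nutrient,
                          confounders = default_confounders(),
                          subset = NULL, group = "all", k = 4,
                          nutrient_form = c("spline", "linear")) {
  nutrient_form <- match.arg(nutrient_form)
  need <- c(nutrient, confounders, "time", "status")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop(sprintf("diet_response: missing column(s): %s",
                 paste(miss, collapse = ", ")))
  d <- if (is.null(subset)) profiles else profiles[subset, , drop = FALSE]
  d <- d[stats::complete.cases(d[, need, drop = FALSE]), , drop = FALSE]
  x <- d[[nutrient]]
  knots <- choose_knots(x, k)

  nut_X <- if (nutrient_form == "spline") {
    B <- rcs_basis(x, knots)
    colnames(B) <- c(nutrient, paste0(nutrient, "_", colnames(B)[-1]))
    B
  } else {
    matrix(x, ncol = 1, dimnames = list(NULL, nutrient))
  }
  conf_X <- as.matrix(d[, confounders, drop = FALSE])
  X <- cbind(nut_X, conf_X)
  cox <- fit_cox(d$time, d$status, X)
  s <- risk_scores(cox$coef, X)

  pairs <- build_risk_pairs(x, s, nutrient, group)
  spl <- fit_spline(pairs, knots)
  tests <- anova_nonlinearity(pairs, knots)
  rng <- extract_ranges(spl)

  lin <- nutrient_hr(profiles, nutrient, confounders,
                     subset = subset, group = group)

  structure(list(
    nutrient = nutrient, group = group, confounders = confounders,
    nutrient_form = nutrient_form, knots = knots,
    n = nrow(d), n_events = sum(d$status),
    cox = cox, scores = s, pairs = pairs, spline = spl,
    p_overall = tests$p_overall, p_nonlinear = tests$p_nonlinear,
    ranges = rng, linear_hr = lin, data = d,
    call = match.call()
  ), class = "diet_response")
}

#' @export
print.diet_response <- function(x, ...) {
  cat(sprintf("Two-stage dose-response fit: %s (%s group)\n",
              x$nutrient, x$group))
  cat(sprintf("  n = %d (%d deaths); %d knots; stage-1 nutrient term: %s\n",
              x$n, x$n_events, length(x$knots), x$nutrient_form))
  cat(sprintf("  P (overall) = %.3g, P (nonlinear) = %.3g\n",
              x$p_overall, x$p_nonlinear))
  print(x$ranges)
  invisible(x)
}

#' @export
summary.diet_response <- function(object, ...) {
  out <- list(
    nutrient = object$nutrient, group = object$group,
    n = object$n, n_events = object$n_events,
    knots = object$knots,
    linear_hr = object$linear_hr$hr, linear_ci = object$linear_hr$ci95,
    linear_p = object$linear_hr$p_wald, unit_scale = object$linear_hr$unit_scale,
    p_overall = object$p_overall, p_nonlinear = object$p_nonlinear,
    A = object$ranges$A, B = object$ranges$B, C = object$ranges$C
  )
  class(out) <- "summary.diet_response"
  out
}

#' @export
print.summary.diet_response <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  cat(sprintf("Nutrient %s, group %s: n = %d, deaths = %d\n",
              x$nutrient, x$group, x$n, x$n_events))
  cat(sprintf("  Linear Cox HR per %g unit: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$unit_scale, x$linear_hr, x$linear_ci[1], x$linear_ci[2],
              x$linear_p))
  cat(sprintf("  Spline: knots at %s\n",
              paste(signif(x$knots, 4), collapse = ", ")))
  cat(sprintf("  P = %.3g, P-NL = %.3g; protective points A = %s, B = %s, C = %s\n",
              x$p_overall, x$p_nonlinear, fmt(x$A), fmt(x$B), fmt(x$C)))
  invisible(x)
}

#' @export
coef.diet_response <- function(object, stage = c("spline", "cox"), ...) {
  stage <- match.arg(stage)
  if (stage == "spline") object$spline$coefficients else object$cox$coef
}

#' Predict the centred hazard-ratio curve at new intakes
#'
#' @param object A \code{"diet_response"} fit.
#' @param newx Intake values (default: the 200-point grid over the observed
#'   domain).
#' @param type \code{"hr"} (centred hazard ratio, reference = cohort mean
#'   curve level), \code{"log_hr"}, or \code{"score"} (uncentred fitted
#'   score).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.diet_response <- function(object, newx = NULL,
                                  type = c("hr", "log_hr", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newx))
    newx <- seq(object$spline$domain[1], object$spline$domain[2],
                length.out = 200)
  g <- predict.rcs_fit(object$spline, newx)
  switch(type,
         score = exp(g),
         log_hr = g - object$ranges$reference,
         hr = exp(g - object$ranges$reference))
}

#' @export
residuals.diet_response <- function(object, ...) {
  stats::residuals(object$spline$lm)
}

#' Plot the fitted dose-response curve
#'
#' Centred hazard-ratio curve with a pointwise 95% band from the stage-2
#' regression, the HR = 1 reference line, shaded protective ranges and an
#' intake rug.
#'
#' @param x A \code{"diet_response"} fit.
#' @param ... Passed to [plot.default()].
#' @return \code{x}, invisibly.
#' @export
plot.diet_response <- function(x, ...) {
  crv <- x$ranges$curve
  Xg <- rcs_basis(crv$x, x$spline$knots)
  pr <- stats::predict(x$spline$lm,
                       newdata = data.frame(Xg), se.fit = TRUE)
  lo <- exp(pr$fit - 1.96 * pr$se.fit - x$ranges$reference)
  hi <- exp(pr$fit + 1.96 * pr$se.fit - x$ranges$reference)
  plot(crv$x, crv$hr, type = "n",
       ylim = range(c(lo, hi, 1)),
       xlab = sprintf("%s intake", x$nutrient),
       ylab = "Hazard ratio", ...)
  if (nrow(x$ranges$components))
    for (i in seq_len(nrow(x$ranges$components)))
      graphics::rect(x$ranges$components[i, 1], graphics::par("usr")[3],
                     x$ranges$components[i, 2], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("palegreen", 0.3),
                     border = NA)
  graphics::polygon(c(crv$x, rev(crv$x)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("grey60", 0.35), border = NA)
  graphics::lines(crv$x, crv$hr, lwd = 2)
  graphics::abline(h = 1, lty = 2, col = "firebrick")
  graphics::rug(x$pairs$t)
  invisible(x)
}

#' Protective intake range of a fitted dose-response
#'
#' @param fit A \code{"diet_response"}.
#' @param scaled Report A/B/C divided by the nutrient's conventional
#'   reporting scale ([unit_scales()])?
#' @return One-row data frame: nutrient, group, A, B, C, p, p_nl.
#' @export
protective_range <- function(fit, scaled = FALSE) {
  sc <- if (scaled) fit$linear_hr$unit_scale else 1
  data.frame(nutrient = fit$nutrient, group = fit$group,
             A = fit$ranges$A / sc, B = fit$ranges$B / sc,
             C = fit$ranges$C / sc,
             p = fit$p_overall, p_nl = fit$p_nonlinear,
             stringsAsFactors = FALSE)
}

#' Protective-range table across nutrients and groups
#'
#' One [diet_response()] fit per (nutrient, group), pooled cohort included,
#' assembled in the conventional report shape with A/B/C on each nutrient's
#' reporting scale.
#'
#' @inheritParams hr_table
#' @param k Number of spline knots.
#' @return Data frame: nutrient, unit_scale, group, A, B, C, p, p_nl.
#' @export
range_table <- function(profiles, assignment = NULL,
                        nutrients = attr(profiles, "nutrient_cols"),
                        confounders = default_confounders(), k = 4) {
  groups <- list(all = NULL)
  if (!is.null(assignment)) {
    m <- match(profiles$patient_id, assignment$patient_id)
    for (g in levels(assignment$group))
      groups[[g]] <- which(assignment$group[m] == g)
  }
  us <- unit_scales()
  rows <- list()
  for (nm in nutrients) for (g in names(groups)) {
    fit <- diet_response(profiles, nm, confounders,
                         subset = groups[[g]], group = g, k = k)
    sc <- if (nm %in% names(us)) us[[nm]] else 1
    rows[[length(rows) + 1L]] <- data.frame(
      nutrient = nm, unit_scale = sc, group = g,
      A = fit$ranges$A / sc, B = fit$ranges$B / sc, C = fit$ranges$C / sc,
      p = fit$p_overall, p_nl = fit$p_nonlinear, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
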