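#' Default dietary nutrient panel
#'
#' The 24 recorded daily nutrient intakes used throughout the package, with
#' their units and the cohort-level means and standard deviations used as
#' marginals by the synthetic generator. Protein and energy intake normalised
#' by ideal body weight (DPI, DEI) are derived during preprocessing rather
#' than recorded, which completes the conventional 26-nutrient panel.
#'
#' @return A data frame with columns \code{name}, \code{unit}, \code{mean},
#'   \code{sd}.
#' @export
nutrient_panel <- function() {
  data.frame(
    name = c("water", "protein", "fat", "carbohydrate", "calories", "df",
             "k", "na", "mg", "ca", "p", "fe", "zn", "cu", "mn", "se",
             "retinol", "vitamin_a", "carotene", "vitamin_e", "thiamine",
             "riboflavin", "nicotinic", "ascorbic"),
    unit = c("g/d", "g/d", "g/d", "g/d", "kcal/d", "g/d",
             "mg/d", "mg/d", "mg/d", "mg/d", "mg/d", "mg/d", "mg/d", "mg/d",
             "mg/d", "ug/d", "ug/d", "ug RAE/d", "ug/d", "ug/d", "mg/d",
             "mg/d", "mgNE/d", "mg/d"),
    mean = c(1512.00, 52.52, 61.28, 215.34, 1582.30, 10.18,
             1493.33, 2595.51, 253.39, 437.14, 799.52, 15.70, 8.18, 1.26,
             3.92, 35.71, 166.44, 469.28, 1705.64, 21.99, 1.24, 1.32,
             12.45, 88.43),
    sd = c(522.61, 15.78, 17.76, 68.68, 450.26, 3.75,
           481.10, 925.01, 80.37, 168.42, 244.67, 5.17, 2.87, 0.44,
           1.56, 11.36, 152.01, 272.27, 1228.01, 9.31, 3.73, 3.58,
           5.15, 48.69),
    stringsAsFactors = FALSE
  )
}

#' Default laboratory/vital confounder panel
#'
#' Per-visit clinical features simulated by the generator: cohort mean, SD,
#' per-feature missingness fraction, loading on the shared latent health
#' factor, and log-hazard coefficient (applied to mean-centred values).
#' Together with the baseline diabetes flag and derived body-mass index these
#' form the 19-variable confounder adjustment set.
#'
#' @return A data frame with columns \code{name}, \code{mean}, \code{sd},
#'   \code{missing_rate}, \code{load}, \code{gamma}.
#' @export
lab_panel <- function() {
  df <- data.frame(
    name = c("albumin", "hb", "urea", "scr", "serum_k", "serum_na",
             "serum_cl", "serum_ca", "serum_p", "hs_crp", "glucose",
             "co2cp", "wbc", "gfr", "sbp", "dbp", "weight"),
    mean = c(37.15, 108.11, 21.26, 720.38, 4.33, 139.17,
             101.48, 2.24, 1.61, 5.66, 6.19,
             25.87, 6.88, 0.06, 135.65, 78.97, 61.17),
    sd = c(4.90, 21.78, 6.54, 254.87, 0.78, 4.87,
           6.33, 0.84, 0.49, 13.29, 2.94,
           4.44, 2.28, 0.60, 21.38, 14.20, 11.95),
    missing_rate = c(0.22, 0.09, 0.10, 0.10, 0.11, 0.12,
                     0.06, 0.11, 0.12, 0.29, 0.28,
                     0.07, 0.09, 0.05, 0.05, 0.05, 0.05),
    stringsAsFactors = FALSE
  )
  df$load <- ifelse(df$name == "albumin", 0.6, 0.3)
  df$gamma <- 0
  df$gamma[df$name == "albumin"] <- -0.04
  df$gamma[df$name == "hb"] <- -0.004
  df$gamma[df$name == "hs_crp"] <- 0.005
  df
}

#' Specify a ground-truth nutrient effect on the log hazard
#'
#' Declares how one nutrient's long-run intake enters the true log relative
#' hazard of the synthetic cohort: not at all (\code{"null"}), linearly
#' (\code{beta} per intake unit), or as a U-shape
#' (\code{curvature * (x - center)^2}, \code{curvature > 0}).
#'
#' @param nutrient Nutrient name (must match a generator panel column).
#' @param kind One of \code{"null"}, \code{"linear"}, \code{"quadratic"}.
#' @param beta Log-hazard slope per intake unit (linear kind only).
#' @param center Intake at minimum log hazard (quadratic kind only).
#' @param curvature Second-order coefficient per squared unit, \code{> 0}
#'   (quadratic kind only).
#' @return An object of class \code{"effect_spec"}.
#' @examples
#' effect_spec("zn", "quadratic", center = 8, curvature = 0.05)
#' @export
effect_spec <- function(nutrient, kind = c("null", "linear", "quadratic"),
                        beta = NULL, center = NULL, curvature = NULL) {
  kind <- match.arg(kind)
  if (!is.character(nutrient) || length(nutrient) != 1L || !nzchar(nutrient))
    stop("effect_spec: 'nutrient' must be a single non-empty name")
  if (kind == "linear") {
    if (is.null(beta) || !is.finite(beta))
      stop("effect_spec: linear kind requires a finite 'beta'")
    if (!is.null(center) || !is.null(curvature))
      stop("effect_spec: linear kind takes only 'beta'")
  } else if (kind == "quadratic") {
    if (is.null(center) || !is.finite(center))
      stop("effect_spec: quadratic kind requires a finite 'center'")
    if (is.null(curvature) || !is.finite(curvature) || curvature <= 0)
      stop("effect_spec: quadratic kind requires 'curvature' > 0")
    if (!is.null(beta))
      stop("effect_spec: quadratic kind takes 'center' and 'curvature' only")
  } else {
    if (!is.null(beta) || !is.null(center) || !is.null(curvature))
      stop("effect_spec: null kind takes no parameters")
  }
  structure(list(nutrient = nutrient, kind = kind, beta = beta,
                 center = center, curvature = curvature),
            class = "effect_spec")
}

#' @export
print.effect_spec <- function(x, ...) {
  desc <- switch(x$kind,
    null = "no effect",
    linear = sprintf("linear, beta = %g per unit", x$beta),
    quadratic = sprintf("U-shaped, center = %g, curvature = %g per unit^2",
                        x$center, x$curvature))
  cat(sprintf("<effect_spec> %s: %s\n", x$nutrient, desc))
  invisible(x)
}

.check_rate <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("cohort_config: '%s' must lie in [0, 1]", field))
  x
}

#' Configure a synthetic dialysis cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size,
#' follow-up design (visit renewal process, horizon, averaging window),
#' missingness rates, the lab/nutrient panels, the shared latent health
#' factor linking labs, diet and hazard, ground-truth nutrient effects, the
#' Weibull baseline hazard and the independent exponential censoring rate.
#' Defaults emulate a peritoneal-dialysis cohort followed quarterly for up
#' to 12 years with roughly 45% observed mortality.
#'
#' @param n_patients Number of patients (>= 3 so tertiles are nonempty).
#' @param n_nutrients How many nutrients of the panel to simulate (first
#'   \code{n_nutrients} rows of \code{nutrients}).
#' @param follow_up_horizon Administrative censoring time, months.
#' @param visit_interval_mean Mean of the per-patient visit renewal
#'   intervals, months (Normal, SD \code{visit_interval_sd}, truncated at
#'   0.5).
#' @param visit_interval_sd SD of the renewal intervals, months.
#' @param window_length Averaging window used downstream, months; must be
#'   smaller than the horizon.
#' @param diet_missing_rate Fraction of whole diet records dropped.
#' @param nutrients Nutrient panel data frame (see [nutrient_panel()]).
#' @param labs Lab panel data frame (see [lab_panel()]); its
#'   \code{missing_rate} column holds the per-feature lab missingness.
#' @param diet_load Loading of nutrient intake on the latent health factor
#'   (confounder-diet correlation).
#' @param effect_specs List of [effect_spec()] objects (ground truth).
#' @param baseline_hazard List with Weibull \code{shape} and \code{scale}
#'   (months); shape 1 gives an exponential baseline.
#' @param censor_rate Monthly rate of the independent exponential censoring
#'   process (0 disables random censoring; administrative censoring at the
#'   horizon always applies).
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#' @return An object of class \code{"cohort_config"}.
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 7)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 656,
                          n_nutrients = NULL,
                          follow_up_horizon = 144,
                          visit_interval_mean = 3,
                          visit_interval_sd = 1,
                          window_length = 6,
                          diet_missing_rate = 0.20,
                          nutrients = nutrient_panel(),
                          labs = lab_panel(),
                          diet_load = 0.3,
                          effect_specs = list(),
                          baseline_hazard = list(shape = 1, scale = 125),
                          censor_rate = 0.008,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 3)
    stop("cohort_config: 'n_patients' must be >= 3 (tertiles must be nonempty)")
  if (is.null(n_nutrients)) n_nutrients <- nrow(nutrients)
  if (n_nutrients < 1 || n_nutrients > nrow(nutrients))
    stop("cohort_config: 'n_nutrients' must be between 1 and nrow(nutrients)")
  if (!is.numeric(follow_up_horizon) || follow_up_horizon <= window_length)
    stop("cohort_config: 'follow_up_horizon' must exceed 'window_length'")
  if (window_length <= 0)
    stop("cohort_config: 'window_length' must be positive")
  if (visit_interval_mean <= 0)
    stop("cohort_config: 'visit_interval_mean' must be positive")
  .check_rate(diet_missing_rate, "diet_missing_rate")
  .check_rate(labs$missing_rate, "labs$missing_rate")
  .check_rate(diet_load, "diet_load")
  if (!is.list(baseline_hazard) || is.null(baseline_hazard$shape) ||
      is.null(baseline_hazard$scale) || baseline_hazard$shape <= 0 ||
      baseline_hazard$scale <= 0)
    stop("cohort_config: 'baseline_hazard' needs positive 'shape' and 'scale'")
  if (censor_rate < 0)
    stop("cohort_config: 'censor_rate' must be >= 0")
  for (es in effect_specs) {
    if (!inherits(es, "effect_spec"))
      stop("cohort_config: 'effect_specs' must be a list of effect_spec objects")
    if (!es$nutrient %in% nutrients$name[seq_len(n_nutrients)])
      stop(sprintf("cohort_config: effect_specs nutrient '%s' not in the simulated panel",
                   es$nutrient))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_nutrients = as.integer(n_nutrients),
    follow_up_horizon = follow_up_horizon,
    visit_interval_mean = visit_interval_mean,
    visit_interval_sd = visit_interval_sd,
    window_length = window_length,
    diet_missing_rate = diet_missing_rate,
    nutrients = nutrients[seq_len(n_nutrients), , drop = FALSE],
    labs = labs,
    diet_load = diet_load,
    effect_specs = effect_specs,
    baseline_hazard = baseline_hazard,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d patients, %d nutrients, horizon %g mo, seed %d\n",
              x$n_patients, x$n_nutrients, x$follow_up_horizon, x$seed))
  cat(sprintf("  visits ~ N(%g, %g) mo; window %g mo; diet records missing %g%%\n",
              x$visit_interval_mean, x$visit_interval_sd, x$window_length,
              100 * x$diet_missing_rate))
  cat(sprintf("  baseline hazard Weibull(shape %g, scale %g mo); censor rate %g/mo\n",
              x$baseline_hazard$shape, x$baseline_hazard$scale, x$censor_rate))
  if (length(x$effect_specs))
    for (es in x$effect_specs) print(es)
  invisible(x)
}
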