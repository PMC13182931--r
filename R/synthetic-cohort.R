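# Truncated-normal draws by inverse CDF; lower bound only (physiological >= 0).
.rtnorm <- function(n, mean, sd, lower = 0) {
  p0 <- stats::pnorm((lower - mean) / sd)
  u <- stats::runif(n, p0, 1)
  mean + sd * stats::qnorm(u)
}

#' True log relative hazard of a synthetic patient
#'
#' Additive ground-truth log hazard: a linear combination of (centred)
#' confounder values plus one term per nutrient effect -- \code{beta * x}
#' for a linear effect, \code{curvature * (x - center)^2} for a U-shape,
#' nothing for a null effect.
#'
#' @param baseline_covariates Named numeric vector of confounder values
#'   (the generator passes mean-centred lab setpoints).
#' @param nutrient_intakes Named numeric vector of long-run nutrient intakes.
#' @param effect_specs List of [effect_spec()] objects.
#' @param confounder_betas Named numeric vector of log-hazard coefficients;
#'   names must be a subset of \code{names(baseline_covariates)}.
#' @return A single finite number, the log relative hazard.
#' @examples
#' log_hazard(c(alb = -2), c(zn = 3),
#'            list(effect_spec("zn", "quadratic", center = 5, curvature = 0.2)),
#'            c(alb = 0))
#' @export
log_hazard <- function(baseline_covariates, nutrient_intakes,
                       effect_specs, confounder_betas) {
  lhr <- 0
  if (length(confounder_betas)) {
    miss <- setdiff(names(confounder_betas), names(baseline_covariates))
    if (length(miss))
      stop(sprintf("log_hazard: covariate(s) %s not supplied",
                   paste(miss, collapse = ", ")))
    lhr <- lhr + sum(confounder_betas * baseline_covariates[names(confounder_betas)])
  }
  for (es in effect_specs) {
    if (es$kind == "null") next
    if (!es$nutrient %in% names(nutrient_intakes))
      stop(sprintf("log_hazard: unknown nutrient '%s' in effect_specs", es$nutrient))
    x <- nutrient_intakes[[es$nutrient]]
    lhr <- lhr + if (es$kind == "linear") es$beta * x
                 else es$curvature * (x - es$center)^2
  }
  unname(lhr)
}

#' Draw an event or censoring time under a Weibull baseline hazard
#'
#' Inverse-CDF sampling from the hazard
#' \code{h(t) = (shape/scale) * (t/scale)^(shape-1) * exp(log_hr)}, competing
#' with an independent exponential censoring time (rate \code{censor_rate}
#' per month) and administrative censoring at \code{horizon}. Vectorised
#' over \code{log_hr}.
#'
#' @param log_hr Finite log relative hazard(s).
#' @param baseline_hazard List with positive Weibull \code{shape} and
#'   \code{scale} (months).
#' @param horizon Administrative censoring time, months (may be \code{Inf}).
#' @param censor_rate Monthly exponential censoring rate (0 disables).
#' @return A data frame with columns \code{time} (> 0, months) and
#'   \code{status} (1 = death, 0 = censored).
#' @examples
#' set.seed(1)
#' sample_event_time(0, list(shape = 1, scale = 12), horizon = 60)
#' @export
sample_event_time <- function(log_hr, baseline_hazard, horizon = Inf,
                              censor_rate = 0) {
  if (any(!is.finite(log_hr)))
    stop("sample_event_time: 'log_hr' must be finite")
  shape <- baseline_hazard$shape
  scale <- baseline_hazard$scale
  if (is.null(shape) || is.null(scale) || shape <= 0 || scale <= 0)
    stop("sample_event_time: baseline hazard shape and scale must be positive")
  n <- length(log_hr)
  # S(t) = exp(-(t/scale)^shape * exp(log_hr)); invert at U ~ Unif(0,1)
  t_event <- scale * (-log(stats::runif(n)) / exp(log_hr))^(1 / shape)
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, horizon)
  time <- pmin(t_event, t_cens)
  time <- pmax(time, .Machine$double.eps)
  data.frame(time = time, status = as.integer(t_event <= t_cens))
}

#' Analytic protective intake interval of a ground-truth effect
#'
#' For a nutrient effect f on the log hazard and an intake distribution X,
#' returns the set \code{\{x : f(x) < E[f(X)]\}} -- the intakes whose hazard
#' contribution is below the cohort-average contribution, the synthetic
#' analogue of "fitted hazard ratio below 1". The expectation is computed by
#' numeric integration over a normal intake marginal truncated at
#' \code{lower}. A quadratic effect yields one finite interval containing
#' its center, a linear effect a half-line, a null effect nothing.
#'
#' @param spec An [effect_spec()].
#' @param intake_mean,intake_sd Parameters of the (truncated) normal intake
#'   marginal.
#' @param lower Truncation bound of the intake support (default 0).
#' @return \code{NULL} for a null effect, else \code{c(lo, hi)} clipped to
#'   \code{[lower, Inf)}; half-lines use \code{Inf}/\code{lower} endpoints.
#' @examples
#' true_protective_interval(
#'   effect_spec("x", "quadratic", center = 5, curvature = 0.2),
#'   intake_mean = 5, intake_sd = 1, lower = -Inf)  # ~ (4, 6)
#' @export
true_protective_interval <- function(spec, intake_mean, intake_sd, lower = 0) {
  if (spec$kind == "null") return(NULL)
  if (spec$kind == "linear") {
    mu <- .tnorm_mean(intake_mean, intake_sd, lower)
    return(if (spec$beta > 0) c(max(lower, -Inf), mu) else c(mu, Inf))
  }
  # quadratic: threshold tau = E[curvature * (X - center)^2]
  dens <- function(x) stats::dnorm(x, intake_mean, intake_sd)
  z <- if (is.finite(lower)) 1 - stats::pnorm((lower - intake_mean) / intake_sd) else 1
  lo_int <- if (is.finite(lower)) lower else intake_mean - 10 * intake_sd
  m2 <- stats::integrate(function(x) (x - spec$center)^2 * dens(x),
                         lo_int, intake_mean + 10 * intake_sd,
                         rel.tol = 1e-10)$value / z
  half <- sqrt(m2)
  c(max(lower, spec$center - half), spec$center + half)
}

.tnorm_mean <- function(mean, sd, lower) {
  if (!is.finite(lower)) return(mean)
  a <- (lower - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Generate a synthetic longitudinal dialysis cohort
#'
#' Draws a complete four-table cohort (baseline, visits, diets, outcomes)
#' under the configured ground truth. One latent health factor per patient
#' links lab setpoints, nutrient intake and mortality hazard, so diet-outcome
#' associations are confounded by construction. Event times come from the
#' Weibull baseline hazard scaled by [log_hazard()]; visits follow a
#' per-patient renewal process; per-feature lab missingness and whole-record
#' diet missingness are applied at the configured rates. Identical
#' configurations (including seed) give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return An object of class \code{"diet_cohort"}: a list of data frames
#'   \code{baseline}, \code{visits}, \code{diets}, \code{outcomes} plus a
#'   \code{truth} list (effect specs, analytic protective intervals, latent
#'   factor and true log hazards).
#' @examples
#' ch <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' nrow(ch$baseline)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop("generate_cohort: 'config' must be a cohort_config object")
  set.seed(config$seed)
  n <- config$n_patients
  labs <- config$labs
  nut <- config$nutrients
  id <- sprintf("P%04d", seq_len(n))

  u <- stats::rnorm(n)  # latent health factor (higher = healthier)

  # static baseline attributes
  age <- pmin(pmax(stats::rnorm(n, 59.11, 15.78), 16), 97)
  gender <- ifelse(stats::runif(n) < 0.50, "F", "M")
  height <- .rtnorm(n, 162.60, 9.46, lower = 120)
  diabetes <- as.integer(stats::runif(n) < 0.37)

  # per-patient lab setpoints: shared-factor Gaussian structure, floored at 0
  nlab <- nrow(labs)
  setp <- matrix(0, n, nlab, dimnames = list(NULL, labs$name))
  for (j in seq_len(nlab)) {
    e <- stats::rnorm(n)
    raw <- labs$mean[j] + labs$sd[j] *
      (labs$load[j] * u + sqrt(1 - labs$load[j]^2) * e)
    setp[, j] <- pmax(raw, 0)
  }

  # per-patient long-run nutrient intakes, truncated at 0
  nnut <- nrow(nut)
  imean <- matrix(0, n, nnut, dimnames = list(NULL, nut$name))
  for (k in seq_len(nnut)) {
    e <- stats::rnorm(n)
    shifted_mean <- nut$mean[k] + nut$sd[k] * config$diet_load * u
    resid_sd <- nut$sd[k] * sqrt(1 - config$diet_load^2)
    imean[, k] <- .qtnorm_vec(stats::runif(n), shifted_mean, resid_sd, 0)
  }

  # true hazard per patient: centred lab setpoints + nutrient effects
  centred <- sweep(setp, 2, labs$mean)
  gam <- stats::setNames(labs$gamma, labs$name)
  gam <- gam[gam != 0]
  lhr <- vapply(seq_len(n), function(i)
    log_hazard(centred[i, ], imean[i, ], config$effect_specs, gam),
    numeric(1))

  ev <- sample_event_time(lhr, config$baseline_hazard,
                          horizon = config$follow_up_horizon,
                          censor_rate = config$censor_rate)

  outcomes <- data.frame(patient_id = id, t0 = 0,
                         tend = ev$time, omega = ev$status,
                         stringsAsFactors = FALSE)

  # visit schedule: renewal process from month 0 until exit
  sched <- lapply(seq_len(n), function(i) {
    t <- 0
    out <- 0
    repeat {
      step <- max(0.5, stats::rnorm(1, config$visit_interval_mean,
                                    config$visit_interval_sd))
      t <- t + step
      if (t >= ev$time[i]) break
      out <- c(out, t)
    }
    out
  })
  vis_id <- rep(id, lengths(sched))
  vis_idx <- rep(seq_len(n), lengths(sched))
  vis_month <- unlist(sched)
  nv <- length(vis_month)

  visits <- data.frame(patient_id = vis_id, month = vis_month,
                       stringsAsFactors = FALSE)
  for (j in seq_len(nlab)) {
    val <- pmax(setp[vis_idx, j] + stats::rnorm(nv, 0, 0.15 * labs$sd[j]), 0)
    drop <- vis_month > 0 & stats::runif(nv) < labs$missing_rate[j]
    val[drop] <- NA_real_
    visits[[labs$name[j]]] <- val
  }

  keep <- stats::runif(nv) >= config$diet_missing_rate
  diets <- data.frame(patient_id = vis_id[keep], month = vis_month[keep],
                      stringsAsFactors = FALSE)
  nd <- sum(keep)
  for (k in seq_len(nnut)) {
    diets[[nut$name[k]]] <-
      pmax(imean[vis_idx[keep], k] + stats::rnorm(nd, 0, 0.25 * nut$sd[k]), 0)
  }

  baseline <- data.frame(patient_id = id, age = age, gender = gender,
                         height_cm = height, weight_kg = setp[, "weight"],
                         diabetes = diabetes, stringsAsFactors = FALSE)
  for (j in which(labs$name != "weight"))
    baseline[[labs$name[j]]] <-
      pmax(setp[, j] + stats::rnorm(n, 0, 0.15 * labs$sd[j]), 0)

  truth <- list(
    effect_specs = config$effect_specs,
    protective_intervals = lapply(config$effect_specs, function(es) {
      k <- match(es$nutrient, nut$name)
      list(nutrient = es$nutrient,
           interval = true_protective_interval(es, nut$mean[k], nut$sd[k]))
    }),
    latent = u, log_hazard = lhr, intake_mean = imean
  )

  structure(list(baseline = baseline, visits = visits, diets = diets,
                 outcomes = outcomes, truth = truth, config = config),
            class = "diet_cohort")
}

# vectorised truncated-normal quantile with elementwise means
.qtnorm_vec <- function(u, mean, sd, lower) {
  p0 <- stats::pnorm((lower - mean) / sd)
  mean + sd * stats::qnorm(p0 + u * (1 - p0))
}

#' @export
print.diet_cohort <- function(x, ...) {
  cat(sprintf("<diet_cohort> %d patients, %d visits, %d diet records, %d deaths\n",
              nrow(x$baseline), nrow(x$visits), nrow(x$diets),
              sum(x$outcomes$omega)))
  invisible(x)
}

#' Write a synthetic cohort to CSV
#'
#' Writes \code{baseline.csv}, \code{visits.csv}, \code{diets.csv},
#' \code{outcomes.csv} and \code{truth.json} into \code{dir}.
#'
#' @param cohort A \code{diet_cohort}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("baseline", "visits", "diets", "outcomes"))
    utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  truth <- list(
    effect_specs = lapply(cohort$truth$effect_specs, unclass),
    protective_intervals = cohort$truth$protective_intervals
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir Directory holding the four CSV tables.
#' @return A \code{diet_cohort} (without ground-truth metadata unless
#'   \code{truth.json} is present).
#' @export
read_cohort <- function(dir) {
  tbs <- lapply(c("baseline", "visits", "diets", "outcomes"), function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) stop(sprintf("read_cohort: missing %s", f))
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(tbs) <- c("baseline", "visits", "diets", "outcomes")
  tf <- file.path(dir, "truth.json")
  tbs$truth <- if (file.exists(tf)) jsonlite::fromJSON(tf, simplifyVector = FALSE)
               else NULL
  structure(tbs, class = "diet_cohort")
}
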