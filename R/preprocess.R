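#' Last observation carried forward
#'
#' Fills each missing value with the most recent earlier non-missing value
#' of the same feature. Values before the first observation stay missing;
#' observed values are never altered. Applied to lab features only -- diet
#' records have no within-record missingness, whole records are simply
#' absent.
#'
#' @param x Numeric vector ordered by time.
#' @param months Optional vector of record times used to verify ordering.
#' @return \code{x} with gaps filled forward.
#' @examples
#' locf_impute(c(5, NA, NA))   # 5 5 5
#' locf_impute(c(NA, 7))       # NA 7
#' @export
locf_impute <- function(x, months = NULL) {
  if (!is.null(months) && is.unsorted(months))
    stop("locf_impute: records must be sorted by time")
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- c(NA, x[ok])[idx + 1L]
  filled
}

#' Per-window means of a longitudinal feature
#'
#' Splits follow-up into half-open windows \code{[0, w), [w, 2w), ...}
#' anchored at the patient's own entry, and averages the non-missing values
#' falling in each window. Windows with no records are omitted entirely
#' rather than zero-filled.
#'
#' @param months Record times in months since entry (>= 0).
#' @param values Feature values (may contain \code{NA}).
#' @param window_length Window length in months, > 0.
#' @return Named numeric vector of window means (names are window indices,
#'   0-based); empty records give an empty result.
#' @examples
#' window_average(c(1, 2, 8), c(10, 20, 30), 6)  # 15, 30
#' @export
window_average <- function(months, values, window_length) {
  if (window_length <= 0) stop("window_average: 'window_length' must be > 0")
  if (length(months) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(months < 0)) stop("window_average: months must be >= 0")
  win <- floor(months / window_length)
  keep <- !is.na(values)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  wm <- tapply(values[keep], win[keep], mean)
  stats::setNames(as.numeric(wm), names(wm))
}

#' Overall time average of per-window means
#'
#' The two-level estimator: an unweighted mean of the window means, not the
#' pooled mean of the raw records, so densely sampled periods do not
#' dominate.
#'
#' @param window_means Numeric vector of window means.
#' @return Their mean, or \code{NA} when empty.
#' @examples
#' patient_time_average(c(15, 30))  # 22.5
#' @export
patient_time_average <- function(window_means) {
  if (length(window_means) == 0L) return(NA_real_)
  mean(window_means)
}

#' Ideal body weight (modified Broca)
#'
#' Height in centimetres minus 105.
#'
#' @param height_cm Height, > 105 cm.
#' @return Ideal body weight in kg.
#' @examples
#' ideal_body_weight(160)  # 55
#' @export
ideal_body_weight <- function(height_cm) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 105))
    stop("ideal_body_weight: height must exceed 105 cm")
  height_cm - 105
}

#' Normalise protein and energy intake by ideal body weight
#'
#' @param avg_protein Time-averaged protein intake, g/d.
#' @param avg_calories Time-averaged energy intake, kcal/d.
#' @param ibw Ideal body weight, kg, > 0.
#' @return List with \code{dpi} (g/kg/d) and \code{dei} (kcal/kg/d).
#' @examples
#' derive_dpi_dei(55, 1650, 55)  # dpi 1, dei 30
#' @export
derive_dpi_dei <- function(avg_protein, avg_calories, ibw) {
  if (any(!is.finite(ibw)) || any(ibw <= 0))
    stop("derive_dpi_dei: ideal body weight must be positive")
  list(dpi = avg_protein / ibw, dei = avg_calories / ibw)
}

# two-level average of one feature column over (patient, month) rows
.two_level <- function(pid, months, values, w) {
  win <- floor(months / w)
  keep <- !is.na(values)
  if (!any(keep)) return(stats::setNames(rep(NA_real_, 0), character(0)))
  g1 <- paste(pid[keep], win[keep], sep = "\r")
  wm <- tapply(values[keep], g1, mean)
  wpid <- sub("\r.*$", "", names(wm))
  tapply(as.numeric(wm), wpid, mean)
}

#' Build one time-averaged profile per patient
#'
#' Turns the longitudinal tables of a cohort into the per-patient analysis
#' table: lab features are LOCF-imputed within patient, then averaged within
#' half-open windows and across windows; nutrient intakes are window-averaged
#' without imputation; DPI and DEI are appended using the modified-Broca
#' ideal body weight. Patients without any diet record, any visit, or with
#' height at or below 105 cm are excluded with a recorded reason.
#'
#' @param cohort A \code{diet_cohort} (or a list with \code{baseline},
#'   \code{visits}, \code{diets}, \code{outcomes} data frames).
#' @param window_length Averaging window in months (default 6).
#' @return A data frame of class \code{"diet_profiles"}, one row per
#'   retained patient: id, static baseline fields, time-averaged labs and
#'   nutrients, \code{dpi}, \code{dei}, \code{bmi}, follow-up \code{time}
#'   and event \code{status}. Exclusions are in \code{attr(, "excluded")}.
#' @examples
#' ch <- generate_cohort(cohort_config(n_patients = 30, seed = 1))
#' pr <- build_profiles(ch)
#' names(pr)[1:8]
#' @export
build_profiles <- function(cohort, window_length = 6) {
  bl <- cohort$baseline
  vis <- cohort$visits
  diet <- cohort$diets
  out <- cohort$outcomes

  for (tb in list(vis, diet, out))
    if (!all(tb$patient_id %in% bl$patient_id))
      stop("build_profiles: table references a patient id absent from baseline")

  excluded <- data.frame(patient_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop <- function(ids, why) {
    if (length(ids))
      excluded <<- rbind(excluded,
                         data.frame(patient_id = ids, reason = why,
                                    stringsAsFactors = FALSE))
  }
  drop(setdiff(bl$patient_id, unique(diet$patient_id)), "no diet records")
  drop(setdiff(setdiff(bl$patient_id, excluded$patient_id),
               unique(vis$patient_id)), "no visits")
  short <- bl$patient_id[bl$height_cm <= 105]
  drop(setdiff(short, excluded$patient_id), "height <= 105 cm")
  keep_ids <- setdiff(bl$patient_id, excluded$patient_id)
  if (!length(keep_ids)) stop("build_profiles: no patients left after exclusions")
  if (nrow(excluded))
    warning(sprintf("build_profiles: excluded %d patient(s): %s",
                    nrow(excluded),
                    paste(unique(excluded$reason), collapse = "; ")))

  vis <- vis[vis$patient_id %in% keep_ids, , drop = FALSE]
  diet <- diet[diet$patient_id %in% keep_ids, , drop = FALSE]
  vis <- vis[order(vis$patient_id, vis$month), , drop = FALSE]
  diet <- diet[order(diet$patient_id, diet$month), , drop = FALSE]

  lab_cols <- setdiff(names(vis), c("patient_id", "month"))
  nut_cols <- setdiff(names(diet), c("patient_id", "month"))

  prof <- data.frame(patient_id = keep_ids, stringsAsFactors = FALSE)

  # labs: LOCF within patient (records already time-ordered), then two-level
  vsplit <- split(seq_len(nrow(vis)), vis$patient_id)
  for (cl in lab_cols) {
    v <- vis[[cl]]
    for (ix in vsplit) v[ix] <- locf_impute(v[ix], vis$month[ix])
    avg <- .two_level(vis$patient_id, vis$month, v, window_length)
    prof[[cl]] <- as.numeric(avg[prof$patient_id])
  }
  # nutrients: no imputation, two-level average of available records
  for (cl in nut_cols) {
    avg <- .two_level(diet$patient_id, diet$month, diet[[cl]], window_length)
    prof[[cl]] <- as.numeric(avg[prof$patient_id])
  }

  m <- match(prof$patient_id, bl$patient_id)
  prof$age <- bl$age[m]
  prof$gender <- bl$gender[m]
  prof$diabetes <- bl$diabetes[m]
  prof$height_cm <- bl$height_cm[m]
  prof$baseline_albumin <- if ("albumin" %in% names(bl)) bl$albumin[m] else NA_real_

  ibw <- ideal_body_weight(prof$height_cm)
  dd <- derive_dpi_dei(prof$protein, prof$calories, ibw)
  prof$dpi <- dd$dpi
  prof$dei <- dd$dei
  prof$bmi <- if ("weight" %in% names(prof))
    prof$weight / (prof$height_cm / 100)^2 else NA_real_

  mo <- match(prof$patient_id, out$patient_id)
  prof$time <- out$tend[mo] - out$t0[mo]
  prof$status <- out$omega[mo]
  if (any(!is.finite(prof$time)) || any(prof$time <= 0))
    stop("build_profiles: nonpositive or missing follow-up time")

  attr(prof, "excluded") <- excluded
  attr(prof, "window_length") <- window_length
  attr(prof, "lab_cols") <- lab_cols
  attr(prof, "nutrient_cols") <- c(nut_cols, "dpi", "dei")
  class(prof) <- c("diet_profiles", "data.frame")
  prof
}
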