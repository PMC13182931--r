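#' Tertile subtyping on a baseline biomarker
#'
#' Splits patients into low / medium / high groups at the empirical 1/3 and
#' 2/3 quantiles (linear-interpolation quantiles): value strictly below the
#' lower cutpoint is \code{low}, at or below the upper cutpoint \code{medium},
#' above it \code{high}. Ties at a cutpoint all fall on the lower-boundary
#' side, deterministically.
#'
#' @param values Numeric biomarker values (baseline serum albumin, g/l, in
#'   the intended use), at least 3 finite values.
#' @param ids Optional patient ids (defaults to the value order).
#' @return A data frame of class \code{"subtype_assignment"} with
#'   \code{patient_id} and factor \code{group}; cutpoints in
#'   \code{attr(, "cutpoints")}.
#' @examples
#' tertile_split(1:9)
#' @export
tertile_split <- function(values, ids = NULL) {
  if (sum(is.finite(values)) < 3)
    stop("tertile_split: need at least 3 finite values")
  if (is.null(ids)) ids <- seq_along(values)
  q <- stats::quantile(values, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  if (q[1] == q[2]) {
    warning("tertile_split: degenerate cutpoints; assigning all patients to 'medium'")
    grp <- rep("medium", length(values))
  } else {
    grp <- ifelse(values < q[1], "low",
                  ifelse(values <= q[2], "medium", "high"))
  }
  res <- data.frame(patient_id = ids,
                    group = factor(grp, levels = c("low", "medium", "high")),
                    stringsAsFactors = FALSE)
  attr(res, "cutpoints") <- q
  class(res) <- c("subtype_assignment", "data.frame")
  res
}

#' Compare a variable across patient groups
#'
#' Continuous variables: one-way ANOVA with Tukey HSD pairwise comparisons.
#' Categorical variables: chi-square test on the contingency table. All
#' tests two-tailed; no multiple-testing correction is applied across
#' variables.
#'
#' @param profiles A \code{diet_profiles} data frame (or any data frame).
#' @param assignment A [tertile_split()] result aligned by \code{patient_id}.
#' @param variable Column name to compare.
#' @param type \code{"auto"} (factor/character/logical treated as
#'   categorical), \code{"continuous"} or \code{"categorical"}.
#' @return A list of class \code{"group_comparison"}: per-group summaries,
#'   overall \code{p}, and Tukey pairwise p-values (continuous) or the
#'   chi-square table (categorical).
#' @export
compare_groups <- function(profiles, assignment, variable,
                           type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  if (!variable %in% names(profiles))
    stop(sprintf("compare_groups: variable '%s' not found", variable))
  m <- match(profiles$patient_id, assignment$patient_id)
  grp <- droplevels(assignment$group[m])
  x <- profiles[[variable]]
  ok <- !is.na(x) & !is.na(grp)
  x <- x[ok]; grp <- droplevels(grp[ok])
  if (nlevels(grp) < 2)
    stop("compare_groups: need at least 2 nonempty groups")
  if (type == "auto")
    type <- if (is.numeric(x)) "continuous" else "categorical"

  if (type == "continuous") {
    wvar <- tapply(x, grp, stats::var)
    if (all(!is.na(wvar) & wvar == 0) &&
        length(unique(tapply(x, grp, mean))) == 1L) {
      warning("compare_groups: no variance anywhere; reporting p = 1")
      return(structure(list(variable = variable, type = type,
                            means = tapply(x, grp, mean),
                            sds = tapply(x, grp, stats::sd),
                            statistic = 0, p = 1, pairwise = NULL),
                       class = "group_comparison"))
    }
    fit <- stats::aov(x ~ grp)
    tab <- summary(fit)[[1]]
    p <- tab[["Pr(>F)"]][1]
    fstat <- tab[["F value"]][1]
    tk <- stats::TukeyHSD(fit)$grp
    structure(list(variable = variable, type = type,
                   means = tapply(x, grp, mean),
                   sds = tapply(x, grp, stats::sd),
                   statistic = fstat, p = p,
                   pairwise = stats::setNames(tk[, "p adj"], rownames(tk))),
              class = "group_comparison")
  } else {
    tabx <- table(x, grp)
    ct <- suppressWarnings(stats::chisq.test(tabx))
    structure(list(variable = variable, type = type,
                   counts = tabx, statistic = unname(ct$statistic),
                   p = ct$p.value, pairwise = NULL),
              class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): p = %.4g\n",
              x$variable, x$type, x$p))
  invisible(x)
}

#' Kaplan-Meier curves and k-sample log-rank test by group
#'
#' Product-limit survival estimate per group and the k-sample log-rank
#' statistic for differences between the curves.
#'
#' @param time Follow-up times, > 0 (months).
#' @param status Event indicator, 1 = death, 0 = censored.
#' @param group Group labels aligned with \code{time}.
#' @return A list of class \code{"km_logrank"}: \code{fit} (a
#'   [survival::survfit] object), \code{curves} (data frame time /
#'   survival / group), \code{chisq}, \code{df} and \code{p}.
#' @export
km_logrank <- function(time, status, group) {
  if (any(time <= 0)) stop("km_logrank: follow-up times must be positive")
  if (!all(status %in% c(0, 1))) stop("km_logrank: status must be 0/1")
  group <- as.factor(group)
  empty <- levels(group)[tabulate(group, nlevels(group)) == 0]
  if (length(empty)) {
    warning(sprintf("km_logrank: dropping empty group(s): %s",
                    paste(empty, collapse = ", ")))
    group <- droplevels(group)
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ group)
  curves <- data.frame(
    time = fit$time, survival = fit$surv,
    group = if (is.null(fit$strata)) rep(levels(group), length(fit$time))
            else rep(sub("^group=", "", names(fit$strata)), fit$strata),
    stringsAsFactors = FALSE)
  if (nlevels(group) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, status) ~ group)
    chisq <- sd$chisq
    df <- length(sd$n) - 1
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; df <- NA_integer_; p <- NA_real_
  }
  structure(list(fit = fit, curves = curves, chisq = chisq, df = df, p = p),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("<km_logrank> chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Descriptive comparison table across groups
#'
#' Applies [compare_groups()] to a set of variables and assembles the usual
#' per-group mean (SD) + overall P table.
#'
#' @param profiles A \code{diet_profiles} data frame.
#' @param assignment A [tertile_split()] result.
#' @param variables Character vector of columns to compare.
#' @return A data frame: variable, per-group mean and SD columns, \code{p}.
#' @export
comparison_table <- function(profiles, assignment, variables) {
  rows <- lapply(variables, function(v) {
    cmp <- compare_groups(profiles, assignment, v)
    if (cmp$type == "continuous") {
      out <- data.frame(variable = v, stringsAsFactors = FALSE)
      for (g in names(cmp$means)) {
        out[[paste0(g, "_mean")]] <- unname(cmp$means[g])
        out[[paste0(g, "_sd")]] <- unname(cmp$sds[g])
      }
      out$p <- cmp$p
      out
    } else {
      data.frame(variable = v, p = cmp$p, stringsAsFactors = FALSE)
    }
  })
  cont <- rows[vapply(rows, function(r) ncol(r) > 2, logical(1))]
  cat_ <- rows[vapply(rows, function(r) ncol(r) == 2, logical(1))]
  out <- if (length(cont)) do.call(rbind, cont) else NULL
  if (length(cat_)) {
    cat_df <- do.call(rbind, cat_)
    if (is.null(out)) out <- cat_df
    else {
      for (cl in setdiff(names(out), names(cat_df))) cat_df[[cl]] <- NA_real_
      out <- rbind(out, cat_df[, names(out)])
    }
  }
  out
}
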