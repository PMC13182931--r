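#' Place spline knots at conventional quantiles
#'
#' Harrell's convention: for k = 3 knots the 10th/50th/90th percentiles,
#' k = 4 the 5th/35th/65th/95th, k = 5 the 5th/27.5th/50th/72.5th/95th.
#' Falls back to equally spaced quantiles if the conventional set is not
#' strictly increasing.
#'
#' @param x Intake values, at least 10 distinct.
#' @param k Number of knots, 3, 4 or 5 (default 4).
#' @return Strictly increasing numeric vector of knots.
#' @examples
#' choose_knots(0:100, k = 4)  # 5 35 65 95
#' @export
choose_knots <- function(x, k = 4) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 10)
    stop("choose_knots: need at least 10 distinct values")
  if (!k %in% 3:5) stop("choose_knots: 'k' must be 3, 4 or 5")
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95))
  kn <- stats::quantile(x, probs, names = FALSE)
  if (any(diff(kn) <= 0))
    kn <- stats::quantile(x, seq(0.05, 0.95, length.out = k), names = FALSE)
  if (any(diff(kn) <= 0))
    stop("choose_knots: could not place strictly increasing knots")
  kn
}

#' Restricted cubic spline design columns
#'
#' Truncated-power restricted cubic basis: \code{[x, C_1(x), ...,
#' C_{k-2}(x)]} with
#' \deqn{C_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k -
#'   t_{k-1}) + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k -
#'   t_1)^2.}
#' The resulting fit is a cubic spline with continuous first and second
#' derivatives, constrained to be exactly linear below the first and above
#' the last knot; a fit to a linear target therefore has all nonlinear
#' coefficients equal to zero.
#'
#' @param x Finite numeric vector.
#' @param knots Strictly increasing knots, length >= 3.
#' @return Matrix with columns \code{x}, \code{c1}, ..., \code{c(k-2)}.
#' @export
rcs_basis <- function(x, knots) {
  if (any(!is.finite(x))) stop("rcs_basis: 'x' must be finite")
  k <- length(knots)
  if (k < 3 || any(diff(knots) <= 0))
    stop("rcs_basis: knots must be strictly increasing, length >= 3")
  pos3 <- function(u) pmax(u, 0)^3
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                     pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                     pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("c", seq_len(k - 2)))
  out
}

#' Fit the log risk score on a restricted cubic spline of intake
#'
#' Ordinary least squares of \code{log(s)} on the RCS basis of intake,
#' yielding the fitted log-hazard-ratio curve of the second stage.
#'
#' @param pairs A [build_risk_pairs()] data frame (columns \code{t},
#'   \code{s}).
#' @param knots Knot vector (default chosen by [choose_knots()]).
#' @return A list of class \code{"rcs_fit"}: \code{knots},
#'   \code{coefficients} (intercept, linear, nonlinear terms),
#'   \code{domain} (observed intake range), \code{sigma}, the underlying
#'   \code{lm} object, and the training pairs.
#' @export
fit_spline <- function(pairs, knots = NULL) {
  t <- pairs$t; s <- pairs$s
  if (any(s <= 0)) stop("fit_spline: scores must be positive")
  if (is.null(knots)) knots <- choose_knots(t)
  if (length(t) < length(knots) + 2)
    stop("fit_spline: need at least k + 2 pairs")
  X <- rcs_basis(t, knots)
  df <- data.frame(y = log(s), X)
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("fit_spline: rank-deficient design")
  structure(list(knots = knots, coefficients = stats::coef(fit),
                 domain = range(t),
                 sigma = suppressWarnings(summary(fit)$sigma),
                 lm = fit, pairs = pairs),
            class = "rcs_fit")
}

#' Evaluate a fitted spline curve
#'
#' @param object An \code{"rcs_fit"}.
#' @param newx Intake values at which to evaluate the fitted log curve.
#' @param ... Unused.
#' @return Fitted values of \code{log(s)} at \code{newx}.
#' @export
predict.rcs_fit <- function(object, newx, ...) {
  X <- rcs_basis(newx, object$knots)
  drop(cbind(1, X) %*% object$coefficients)
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat(sprintf("<rcs_fit> %d knots at %s; domain [%.3g, %.3g]\n",
              length(x$knots), paste(signif(x$knots, 4), collapse = ", "),
              x$domain[1], x$domain[2]))
  invisible(x)
}

#' Overall and nonlinearity F-tests for the spline fit
#'
#' Nested-model ANOVA: the overall P compares the full RCS model against
#' the intercept-only model; the nonlinearity P compares it against the
#' linear-only model, so a small value flags curvature beyond a straight
#' line.
#'
#' @param pairs A [build_risk_pairs()] data frame.
#' @param knots Knot vector (default [choose_knots()]).
#' @return List with \code{p_overall}, \code{p_nonlinear}, and the two F
#'   statistics.
#' @export
anova_nonlinearity <- function(pairs, knots = NULL) {
  t <- pairs$t; s <- pairs$s
  if (is.null(knots)) knots <- choose_knots(t)
  X <- rcs_basis(t, knots)
  df <- data.frame(y = log(s), X)
  full <- stats::lm(y ~ ., data = df)
  lin <- stats::lm(y ~ x, data = df)
  null <- stats::lm(y ~ 1, data = df)
  a_nl <- stats::anova(lin, full)
  a_ov <- stats::anova(null, full)
  f_nl <- a_nl$F[2]; p_nl <- a_nl[["Pr(>F)"]][2]
  # a linear model that already fits to numerical precision leaves the
  # nested comparison 0/0; by construction that is no nonlinearity at all
  tss <- sum((df$y - mean(df$y))^2)
  if (stats::deviance(lin) <= 1e-12 * max(tss, .Machine$double.eps)) {
    f_nl <- 0; p_nl <- 1
  }
  list(p_overall = a_ov[["Pr(>F)"]][2], p_nonlinear = p_nl,
       f_overall = a_ov$F[2], f_nonlinear = f_nl)
}

#' Extract protective intake ranges from a fitted spline
#'
#' Centres the fitted log curve to mean zero over the group's empirical
#' intake distribution (the same reference as the stage-1 score centring),
#' evaluates it on a uniform grid over the observed domain, and reports the
#' interval decomposition of the protective set \code{\{x : exp(g(x)) < 1\}}
#' as points A, B, C: the set is \code{[A, B]} plus optionally
#' \code{[C, domain max]}; B is absent when the first component runs to the
#' domain maximum. Crossings are located by linear interpolation between
#' grid nodes; components narrower than 2% of the domain are suppressed as
#' grid noise, and if more than two components remain the two widest are
#' kept with a warning.
#'
#' @param model An \code{"rcs_fit"}.
#' @param grid_size Number of grid points (default 200).
#' @return A list of class \code{"range_points"}: \code{A}, \code{B},
#'   \code{C} (\code{NA} when absent), the protective \code{components}
#'   matrix, and the centred curve as a data frame (\code{x}, \code{log_hr},
#'   \code{hr}).
#' @export
extract_ranges <- function(model, grid_size = 200) {
  dom <- model$domain
  if (diff(dom) <= 0) stop("extract_ranges: degenerate intake domain")
  gx <- seq(dom[1], dom[2], length.out = grid_size)
  ref <- mean(predict.rcs_fit(model, model$pairs$t))
  gy <- predict.rcs_fit(model, gx) - ref

  below <- gy < 0
  comps <- list()
  i <- 1L
  while (i <= grid_size) {
    if (below[i]) {
      j <- i
      while (j < grid_size && below[j + 1L]) j <- j + 1L
      lo <- if (i == 1L) gx[1] else .xing(gx[i - 1L], gx[i], gy[i - 1L], gy[i])
      hi <- if (j == grid_size) gx[grid_size]
            else .xing(gx[j], gx[j + 1L], gy[j], gy[j + 1L])
      comps[[length(comps) + 1L]] <- c(lo, hi)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(comps)) {
    cm <- do.call(rbind, comps)
    wide <- cm[, 2] - cm[, 1] >= 0.02 * diff(dom)
    cm <- cm[wide, , drop = FALSE]
    if (nrow(cm) > 2) {
      warning("extract_ranges: >2 protective components; keeping the 2 widest")
      ord <- order(cm[, 2] - cm[, 1], decreasing = TRUE)[1:2]
      cm <- cm[sort(ord), , drop = FALSE]
    }
  } else cm <- matrix(numeric(0), 0, 2)

  A <- B <- C <- NA_real_
  if (nrow(cm) >= 1) {
    A <- cm[1, 1]
    if (cm[1, 2] < gx[grid_size]) B <- cm[1, 2]
  }
  if (nrow(cm) == 2) C <- cm[2, 1]

  structure(list(A = A, B = B, C = C, components = cm,
                 curve = data.frame(x = gx, log_hr = gy, hr = exp(gy)),
                 reference = ref),
            class = "range_points")
}

.xing <- function(x0, x1, y0, y1) x0 - y0 * (x1 - x0) / (y1 - y0)

#' @export
print.range_points <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  cat(sprintf("<range_points> A = %s, B = %s, C = %s\n",
              fmt(x$A), fmt(x$B), fmt(x$C)))
  invisible(x)
}
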