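# shared fixtures built in code

# 3-patient toy cohort with hand-computable two-level averages
toy_cohort <- function() {
  baseline <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(60, 55, 70), gender = c("F", "M", "F"),
    height_cm = c(160, 170, 155), weight_kg = c(60, 70, 50),
    diabetes = c(0L, 1L, 0L), albumin = c(35, 40, 30),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    month = c(0, 2, 8, 0, 1, 0),
    albumin = c(30, NA, 40, NA, 36, 33),
    stringsAsFactors = FALSE)
  diets <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2"),
    month = c(0, 2, 8, 0),
    protein = c(50, 70, 90, 66),
    calories = c(1500, 1700, 1900, 1650),
    stringsAsFactors = FALSE)
  outcomes <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    t0 = 0, tend = c(10, 12, 6), omega = c(1L, 0L, 1L),
    stringsAsFactors = FALSE)
  list(baseline = baseline, visits = visits, diets = diets,
       outcomes = outcomes)
}

# direct proportional-hazards simulator: one exposure x, one confounder z,
# exponential event times, optional quadratic exposure effect
sim_surv <- function(n, beta_x = 0, quad = NULL, gamma_z = 0.5, rho = 0.3,
                     rate = 0.05, cens = 0.02, horizon = 120,
                     x_mean = 0, x_sd = 1) {
  x <- rnorm(n, x_mean, x_sd)
  z <- rho * scale(x)[, 1] + sqrt(1 - rho^2) * rnorm(n)
  lhr <- beta_x * x + gamma_z * z
  if (!is.null(quad)) lhr <- lhr + quad$curvature * (x - quad$center)^2
  te <- rexp(n, rate * exp(lhr))
  tc <- pmin(if (cens > 0) rexp(n, cens) else Inf, horizon)
  data.frame(x = x, z = z, time = pmin(te, tc),
             status = as.integer(te <= tc))
}

# brute-force Cox partial log-likelihood (Breslow form; exact for
# distinct event times) -- independent oracle for small instances
brute_pl <- function(beta, time, status, x) {
  ev <- which(status == 1)
  sum(vapply(ev, function(i) {
    at_risk <- time >= time[i]
    beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }, numeric(1)))
}

# protective interval of a centred curve on a grid: first contiguous run
# of hr < 1 (helper for Jaccard comparisons)
grid_interval <- function(gx, ghr) {
  below <- ghr < 1
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  widest <- runs[which.max(r$lengths[runs])]
  c(gx[starts[widest]], gx[ends[widest]])
}

jaccard <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0)
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  if (uni <= 0) 0 else inter / uni
}
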