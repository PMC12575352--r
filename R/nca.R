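#' Construct a concentration-time profile
#'
#' @param time Strictly increasing sampling times, h (`time[1] >= 0`).
#' @param conc Concentrations, pg/mL, nonnegative, same length as `time`.
#' @param dose Administered dose, µg (needed for clearance-scale NCA).
#' @param label Compartment or compound label.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(time, conc, dose = NA_real_, label = "plasma") {
  if (length(time) != length(conc)) stop("time and conc lengths differ", call. = FALSE)
  if (length(time) < 2L) stop("insufficient data: need >= 2 points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (time[1] < 0) stop("time must start at or after 0", call. = FALSE)
  if (any(conc < 0)) stop("concentrations must be nonnegative", call. = FALSE)
  structure(list(time = as.numeric(time), conc = as.numeric(conc),
                 dose = dose, label = label),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> %s: %d points over %.3g h, Cmax %.4g pg/mL\n",
              x$label, length(x$time), max(x$time), max(x$conc)))
  invisible(x)
}

#' Trapezoidal area under the curve over the observed span
#'
#' `"linear"` uses the linear trapezoid on every interval;
#' `"linear_up_log_down"` (default) switches to the log trapezoid on
#' intervals where the concentration declines between two positive values.
#'
#' @param profile A [conc_profile()].
#' @param method `"linear_up_log_down"` or `"linear"`.
#' @return AUC(0-t) in pg·h/mL.
#' @export
auc_trapezoid <- function(profile, method = c("linear_up_log_down", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_profile"))
  sum(segment_areas(profile$time, profile$conc, method)$auc)
}

# per-interval AUC and AUMC contributions
segment_areas <- function(t, c, method) {
  n <- length(t)
  i1 <- seq_len(n - 1L)
  i2 <- i1 + 1L
  dt <- t[i2] - t[i1]
  auc <- (c[i1] + c[i2]) / 2 * dt
  aumc <- (t[i1] * c[i1] + t[i2] * c[i2]) / 2 * dt
  if (method == "linear_up_log_down") {
    logdown <- c[i2] < c[i1] & c[i2] > 0
    if (any(logdown)) {
      k <- log(c[i1][logdown] / c[i2][logdown]) / dt[logdown]
      dck <- (c[i1][logdown] - c[i2][logdown]) / k
      auc[logdown] <- dck
      aumc[logdown] <- (t[i1][logdown] * c[i1][logdown] -
                          t[i2][logdown] * c[i2][logdown]) / k + dck / k
    }
  }
  list(auc = auc, aumc = aumc)
}

#' Terminal elimination rate constant
#'
#' Log-linear regression on the terminal phase. Candidate windows are all
#' contiguous tails of >= `min_points` positive observations after (and
#' excluding) the observed Cmax; the window maximizing adjusted R-squared is
#' selected, ties (within 1e-4) going to the window with more points. A
#' nonnegative slope or no admissible window yields `failed = TRUE` rather
#' than a silent estimate.
#'
#' @param profile A [conc_profile()].
#' @param min_points Minimum points in the regression window (>= 3).
#' @return List with `lambda_z` (1/h), `n_points`, `adj_r2`, `intercept`
#'   (log pg/mL), `failed` flag.
#' @export
lambda_z <- function(profile, min_points = 3) {
  stopifnot(inherits(profile, "conc_profile"), min_points >= 3)
  t <- profile$time
  c <- profile$conc
  i_cmax <- which.max(c)
  idx <- seq_along(t) > i_cmax & c > 0
  t_tail <- t[idx]
  c_tail <- c[idx]
  n <- length(t_tail)
  failed <- list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_,
                 intercept = NA_real_, failed = TRUE)
  if (n < min_points) return(failed)

  best <- NULL
  for (k in seq(min_points, n)) {
    sel <- seq(n - k + 1L, n)
    if (c_tail[sel[1]] <= c_tail[sel[length(sel)]]) next   # tail must decline
    fit <- stats::lm(log(c_tail[sel]) ~ t_tail[sel])
    slope <- unname(stats::coef(fit)[2])
    if (!is.finite(slope) || slope >= 0) next
    # exact mono-exponential tails fit perfectly; silence the lm notice
    adj <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || adj > best$adj_r2 + 1e-4 ||
        (abs(adj - best$adj_r2) <= 1e-4 && k > best$n_points)) {
      best <- list(lambda_z = -slope, n_points = k, adj_r2 = adj,
                   intercept = unname(stats::coef(fit)[1]), failed = FALSE)
    }
  }
  if (is.null(best)) return(failed)
  best
}

#' Non-compartmental analysis of an intravenous profile
#'
#' Derives AUC(0-t), AUC(0-inf), AUMC, terminal rate constant and half-life,
#' clearance `CL = dose / AUC(0-inf)`, mean residence time
#' `MRT = AUMC/AUC - infusion_duration/2`, and `Vss = CL * MRT`. For bolus
#' profiles whose first record is zero or starts after time zero, C(0) is
#' back-extrapolated log-linearly from the first two positive declining
#' observations (standard IV-bolus convention).
#'
#' @param profile A [conc_profile()] in pg/mL.
#' @param dose Dose in µg (defaults to the profile's dose).
#' @param method AUC method, see [auc_trapezoid()].
#' @param infusion_duration_h Infusion duration (0 for bolus).
#' @param back_extrapolate_c0 Back-extrapolate C(0) for bolus profiles.
#' @return An object of class `nca_result` with fields `auc_0_t`,
#'   `auc_0_inf` (pg·h/mL), `aumc` (pg·h²/mL), `cl` (L/h), `vss` (L),
#'   `t_half` (h), `mrt` (h), `cmax` (pg/mL), `tmax` (h), `lambda_z` (1/h),
#'   `lambda_z_n`, `lambda_z_adj_r2`, `extrap_frac`, and flags
#'   `lambda_z_failed`, `high_extrapolation` (tail > 20% of AUC(0-inf)).
#' @export
nca_iv <- function(profile, dose = profile$dose,
                   method = c("linear_up_log_down", "linear"),
                   infusion_duration_h = 0, back_extrapolate_c0 = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "conc_profile"))
  if (!is.finite(dose) || dose <= 0) stop("a positive dose (ug) is required", call. = FALSE)

  t <- profile$time
  c <- profile$conc
  bolus <- infusion_duration_h == 0
  if (back_extrapolate_c0 && bolus) {
    pos <- which(c > 0)
    if (length(pos) >= 2L) {
      p1 <- pos[1]; p2 <- pos[2]
      c0 <- if (c[p2] < c[p1]) {
        exp(log(c[p1]) - t[p1] * (log(c[p2]) - log(c[p1])) / (t[p2] - t[p1]))
      } else {
        c[p1]
      }
      if (t[1] > 0) {
        t <- c(0, t); c <- c(c0, c)
      } else if (c[1] == 0) {
        c[1] <- c0
      }
    }
  }

  seg <- segment_areas(t, c, method)
  auc_t <- sum(seg$auc)
  aumc_t <- sum(seg$aumc)

  lz <- lambda_z(conc_profile(t, c, dose, profile$label))
  c_last <- c[length(c)]
  t_last <- t[length(t)]
  if (!lz$failed && c_last > 0) {
    auc_tail <- c_last / lz$lambda_z
    aumc_tail <- c_last * t_last / lz$lambda_z + c_last / lz$lambda_z^2
  } else {
    auc_tail <- 0
    aumc_tail <- 0
  }
  auc_inf <- auc_t + auc_tail
  aumc_inf <- aumc_t + aumc_tail

  cl <- 1000 * dose / auc_inf                 # ug / (pg.h/mL) -> L/h
  mrt <- aumc_inf / auc_inf - infusion_duration_h / 2
  vss <- cl * mrt
  extrap <- auc_tail / auc_inf

  structure(
    list(auc_0_t = auc_t, auc_0_inf = auc_inf, aumc = aumc_inf,
         cl = cl, vss = vss,
         t_half = if (lz$failed) NA_real_ else log(2) / lz$lambda_z,
         mrt = mrt, cmax = max(c), tmax = t[which.max(c)],
         lambda_z = lz$lambda_z, lambda_z_n = lz$n_points,
         lambda_z_adj_r2 = lz$adj_r2, extrap_frac = extrap,
         lambda_z_failed = lz$failed,
         high_extrapolation = is.finite(extrap) && extrap > 0.2,
         dose = dose, method = method),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "<nca_result> AUC0-t %.4g, AUC0-inf %.4g pg.h/mL; CL %.4g L/h; Vss %.4g L; T1/2 %.4g h; Cmax %.4g pg/mL%s\n",
    x$auc_0_t, x$auc_0_inf, x$cl, x$vss, x$t_half, x$cmax,
    if (isTRUE(x$high_extrapolation)) " [extrapolated tail > 20%]" else ""))
  invisible(x)
}

#' Per-tissue exposure summary and brain/plasma ratios
#'
#' One row per tissue compartment with Cmax, Tmax, AUC(0-t) (linear
#' trapezoid on the simulation grid), and the ratios to the plasma series on
#' both the Cmax and AUC bases. The Cmax basis is the headline
#' CNS-penetration metric; the AUC basis is always co-reported.
#'
#' @param sim A `simulation_result`.
#' @return data.frame with columns `tissue`, `cmax`, `tmax`, `auc_0_t`,
#'   `cmax_ratio`, `auc_ratio`.
#' @export
tissue_ratios <- function(sim) {
  stopifnot(inherits(sim, "simulation_result"))
  if (!"plasma" %in% rownames(sim$conc)) stop("missing plasma series", call. = FALSE)
  plasma <- sim$conc["plasma", ]
  auc_pl <- sum(segment_areas(sim$time, plasma, "linear")$auc)
  cmax_pl <- max(plasma)
  rows <- lapply(kp_tissues(), function(tt) {
    cc <- sim$conc[tt, ]
    auc <- sum(segment_areas(sim$time, cc, "linear")$auc)
    data.frame(tissue = tt, cmax = max(cc), tmax = sim$time[which.max(cc)],
               auc_0_t = auc, cmax_ratio = max(cc) / cmax_pl,
               auc_ratio = auc / auc_pl)
  })
  do.call(rbind, rows)
}
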