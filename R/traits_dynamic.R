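#' Fit an offset Gaussian growth curve
#'
#' Nonlinear least squares of `f(t) = d + a exp(-(t - b)^2 / (2 c^2))` to
#' a single plot's trait series: `a` is the seasonal amplitude above the
#' baseline `d`, `b` the peak day (DAS) and `c` the width in days. The
#' bell shape captures the rise to a seasonal maximum and the late-season
#' decline typical of canopy height and greenness. Initialization:
#' `a0 = max - min`, `b0` = day of the maximum, `c0` = span/4, `d0 = min`;
#' bounds `a > 0`, `c` in [1, 200], `b` in domain +/- 30 days.
#'
#' @param das sample days (days after sowing), strictly increasing, or a
#'   data frame with columns `das` and `value`.
#' @param value trait values (omit when `das` is a data frame).
#' @return a `growth_curve`: list with `a`, `b`, `c`, `d`, `domain`,
#'   `rss`, `converged` and `warning` (non-`NULL` when the optimizer hit
#'   a bound or failed to converge cleanly).
#' @export
fit_growth_curve <- function(das, value = NULL) {
  if (is.data.frame(das)) { value <- das$value; das <- das$das }
  ok <- !is.na(das) & !is.na(value)
  das <- das[ok]; value <- value[ok]
  if (length(das) < 5) stop("growth-curve fit needs at least 5 samples", call. = FALSE)
  if (is.unsorted(das, strictly = TRUE)) stop("sample days must be strictly increasing", call. = FALSE)
  if (diff(range(value)) == 0) stop("fit error: all trait values are equal", call. = FALSE)
  span <- diff(range(das))
  start <- c(a = max(value) - min(value), b = das[which.max(value)],
             c = span / 4, d = min(value))
  lower <- c(a = 1e-8, b = min(das) - 30, c = 1, d = -Inf)
  upper <- c(a = Inf, b = max(das) + 30, c = 200, d = Inf)
  model <- function(p, t) p[4] + p[1] * exp(-(t - p[2])^2 / (2 * p[3]^2))
  rss_fn <- function(p) sum((value - model(p, das))^2)
  fit <- tryCatch(suppressWarnings(
    stats::nls(value ~ d + a * exp(-(t - b)^2 / (2 * c^2)),
               data = list(value = value, t = das),
               start = as.list(start), lower = lower, upper = upper,
               algorithm = "port",
               control = stats::nls.control(maxiter = 500, tol = 1e-10, warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)[c("a", "b", "c", "d")]
    converged <- fit$convInfo$isConv
  } else {
    p <- start; converged <- FALSE
  }
  # polish (and rescue a failed nls) with bounded quasi-Newton on the RSS
  op <- stats::optim(p, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500, factr = 10))
  if (op$value < rss_fn(p)) { p <- op$par; converged <- TRUE }
  warning_msg <- NULL
  if (!converged) warning_msg <- "optimizer did not report clean convergence"
  if (abs(p["c"] - lower["c"]) < 1e-8 || abs(p["c"] - upper["c"]) < 1e-8) {
    warning_msg <- c(warning_msg, "width parameter c at its bound")
  }
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 d = unname(p["d"]), domain = range(das), rss = rss_fn(p),
                 converged = converged, warning = warning_msg),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> f(t) = %.4g + %.4g exp(-(t - %.4g)^2 / (2 %.4g^2)), DAS %g..%g, rss %.3g\n",
              x$d, x$a, x$b, x$c, x$domain[1], x$domain[2], x$rss))
  invisible(x)
}

#' Evaluate a growth curve and its derivatives
#'
#' @param curve a `growth_curve`.
#' @param t days after sowing.
#' @param deriv 0, 1 or 2.
#' @return f(t), f'(t) or f''(t).
#' @export
eval_growth_curve <- function(curve, t, deriv = 0) {
  u <- (t - curve$b) / curve$c
  g <- curve$a * exp(-u^2 / 2)
  switch(as.character(deriv),
         "0" = curve$d + g,
         "1" = -u / curve$c * g,
         "2" = (u^2 - 1) / curve$c^2 * g,
         stop("deriv must be 0, 1 or 2", call. = FALSE))
}

curve_grid <- function(curve, step) seq(curve$domain[1], curve$domain[2], by = step)

#' Growth-difference curve
#'
#' The analytic first derivative of the fitted curve sampled on a regular
#' grid over its domain: the instantaneous growth rate in trait units per
#' day, positive while the trait rises and zero at the seasonal peak.
#'
#' @param curve a `growth_curve`.
#' @param step grid step in days (default 0.1).
#' @return data frame with columns `das` and `rate`.
#' @export
growth_difference_curve <- function(curve, step = 0.1) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  t <- curve_grid(curve, step)
  data.frame(das = t, rate = eval_growth_curve(curve, t, deriv = 1))
}

#' Knee points and the rapid growth phase
#'
#' The knee points of the growth-difference curve are its stationary
#' days, i.e. the inflection days of the fitted curve; for the offset
#' Gaussian these are `b - c` and `b + c` in closed form. The interval
#' between them is the rapid growth phase (RGP). Endpoints outside the
#' observed domain are clipped and flagged; if both fall outside, the RGP
#' is undefined.
#'
#' @param curve a `growth_curve`.
#' @return list with `kp1`, `kp2` (sorted ascending), `rgp_days`,
#'   `clipped` (logical) and `defined` (logical).
#' @export
locate_knee_points <- function(curve) {
  if (curve$c <= 0) stop("curve width must be positive", call. = FALSE)
  kp <- sort(c(curve$b - curve$c, curve$b + curve$c))
  dom <- curve$domain
  if (kp[2] <= dom[1] || kp[1] >= dom[2]) {
    return(list(kp1 = NA_real_, kp2 = NA_real_, rgp_days = NA_real_,
                clipped = FALSE, defined = FALSE))
  }
  clipped <- kp[1] < dom[1] || kp[2] > dom[2]
  kp <- pmin(pmax(kp, dom[1]), dom[2])
  list(kp1 = kp[1], kp2 = kp[2], rgp_days = kp[2] - kp[1],
       clipped = clipped, defined = TRUE)
}

#' Fastest growth rate within the rapid growth phase
#'
#' Argmax of the growth-difference curve over the RGP (over the full
#' domain, flagged, when the RGP is undefined). For a rising Gaussian
#' this is the RGP's start `b - c` with rate `(a / c) exp(-1/2)`.
#'
#' @param curve a `growth_curve`.
#' @param rgp result of [locate_knee_points()] (computed if missing).
#' @param step grid step in days (default 0.1).
#' @return list with `fgr_day`, `fgr_value` and `flagged`.
#' @export
fastest_growth_rate <- function(curve, rgp = NULL, step = 0.1) {
  if (is.null(rgp)) rgp <- locate_knee_points(curve)
  window <- if (isTRUE(rgp$defined)) c(rgp$kp1, rgp$kp2) else curve$domain
  t <- seq(window[1], window[2], by = step)
  rate <- eval_growth_curve(curve, t, deriv = 1)
  i <- which.max(rate)
  list(fgr_day = t[i], fgr_value = rate[i], flagged = !isTRUE(rgp$defined))
}

#' Average growth rate over an interval
#'
#' `AGR = 100 (f(t_end) - f(t_start)) / ((t_end - t_start) max_value)`:
#' the percentage of the seasonal maximum gained per day between the two
#' days. With `normalize = FALSE` the rate is returned in absolute trait
#' units per day instead.
#'
#' @param curve a `growth_curve`.
#' @param t_start,t_end interval endpoints in DAS, `t_start < t_end`.
#' @param normalize divide by the seasonal maximum `d + a` (default TRUE).
#' @return rate in %/day (or units/day), `NA` if the maximum is <= 0.
#' @export
average_growth_rate <- function(curve, t_start, t_end, normalize = TRUE) {
  if (t_start >= t_end) stop("t_start must be before t_end", call. = FALSE)
  gain <- eval_growth_curve(curve, t_end) - eval_growth_curve(curve, t_start)
  rate <- gain / (t_end - t_start)
  if (!normalize) return(rate)
  max_value <- curve$d + curve$a
  if (max_value <= 0) return(NA_real_)
  100 * rate / max_value
}

#' Normalized curvature curve
#'
#' `kappa(t) = |f''(t)| / (1 + f'(t)^2)^(3/2)` sampled on a regular grid
#' and divided by its maximum so the peak is 1. A straight-line curve has
#' zero curvature everywhere; normalization is then skipped and flagged.
#'
#' @param curve a `growth_curve`.
#' @param step grid step in days (default 0.1).
#' @return data frame (`das`, `curvature`, normalized) with attributes
#'   `max_curvature` (unnormalized peak) and `flat` (logical).
#' @export
curvature_curve <- function(curve, step = 0.1) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  t <- curve_grid(curve, step)
  k <- curvature_values(curve, t)
  kmax <- max(k)
  flat <- kmax <= 0
  out <- data.frame(das = t, curvature = if (flat) k else k / kmax)
  attr(out, "max_curvature") <- kmax
  attr(out, "flat") <- flat
  out
}

curvature_values <- function(curve, t) {
  d1 <- eval_growth_curve(curve, t, deriv = 1)
  d2 <- eval_growth_curve(curve, t, deriv = 2)
  abs(d2) / (1 + d1^2)^(3 / 2)
}

#' Growth-stage days from the curvature curve
#'
#' The day of maximum curvature marks the seasonal trait maximum; the
#' beginning of ripening is the first local minimum of the normalized
#' curvature strictly after it (undefined when no interior local minimum
#' exists, e.g. for a still-rising curve).
#'
#' @param fxcuv curvature samples from [curvature_curve()].
#' @return list with `max_trait_day` and `ripening_day` (`NA` when
#'   undefined).
#' @export
estimate_stage_days <- function(fxcuv) {
  k <- fxcuv$curvature
  t <- fxcuv$das
  i_max <- which.max(k)
  ripening <- NA_real_
  n <- length(k)
  if (i_max < n - 1) {
    after <- (i_max + 1):(n - 1)
    is_min <- k[after] <= k[after - 1] & k[after] <= k[after + 1] &
      (k[after] < k[after - 1] | k[after] < k[after + 1])
    hit <- after[which(is_min)]
    if (length(hit)) ripening <- t[hit[1]]
  }
  list(max_trait_day = t[i_max], ripening_day = ripening)
}

#' Dynamic phenotypes of one trait series
#'
#' Fits the growth curve and composes the full dynamic-trait set: rapid
#' growth phase (KP1/KP2 and its length), fastest growth rate day and
#' value, average growth rates over [0, FGR day], [0, max day] and the
#' RGP, the seasonal maximum (day and value, optionally clamped for
#' range-bounded traits such as CCI), and the beginning of ripening.
#'
#' @param das,value the trait series (or a data frame via `das`).
#' @param step sampling grid in days (default 0.1).
#' @param value_cap optional upper clamp for `max_value` (e.g. 1 for CCI).
#' @return list of class `dynamic_phenotypes`.
#' @export
dynamic_phenotypes <- function(das, value = NULL, step = 0.1, value_cap = NULL) {
  curve <- fit_growth_curve(das, value)
  rgp <- locate_knee_points(curve)
  fgr <- fastest_growth_rate(curve, rgp, step)
  fxcuv <- curvature_curve(curve, step)
  stages <- estimate_stage_days(fxcuv)
  max_day <- curve$b
  if (abs(stages$max_trait_day - max_day) > step &&
      max_day >= curve$domain[1] && max_day <= curve$domain[2]) {
    warning("curvature peak and fitted peak disagree by more than one grid step")
  }
  max_value <- curve$d + curve$a
  if (!is.null(value_cap)) max_value <- min(max_value, value_cap)
  agr0 <- function(t_end) {
    if (is.na(t_end) || t_end <= 0) return(NA_real_)
    average_growth_rate(curve, 0, t_end)
  }
  structure(list(
    curve = curve,
    rgp_start = rgp$kp1, rgp_end = rgp$kp2, rgp_days = rgp$rgp_days,
    rgp_clipped = rgp$clipped,
    fgr_day = fgr$fgr_day, fgr_value = fgr$fgr_value, fgr_flagged = fgr$flagged,
    agr_to_fgr = agr0(fgr$fgr_day),
    agr_to_max = agr0(max_day),
    agr_in_rgp = if (isTRUE(rgp$defined)) average_growth_rate(curve, rgp$kp1, rgp$kp2) else NA_real_,
    max_day = max_day, max_value = max_value,
    curvature_max_day = stages$max_trait_day,
    ripening_day = stages$ripening_day,
    rss = curve$rss, converged = curve$converged
  ), class = "dynamic_phenotypes")
}

#' @export
print.dynamic_phenotypes <- function(x, ...) {
  cat(sprintf("<dynamic_phenotypes> RGP [%.1f, %.1f] (%.1f d), FGR %.4g/day at %.1f DAS,\n",
              x$rgp_start, x$rgp_end, x$rgp_days, x$fgr_value, x$fgr_day))
  cat(sprintf("  max %.4g at %.1f DAS, ripening %.1f DAS, AGR(0..FGR) %.4g %%/day\n",
              x$max_value, x$max_day, x$ripening_day, x$agr_to_fgr))
  invisible(x)
}

#' Dynamic phenotypes for every (plot, trait) series in a trait table
#'
#' @param records data frame with columns `plot_id`, `das`, `trait`,
#'   `value` (as written by [write_trait_table()]).
#' @param step grid step in days.
#' @param value_caps named numeric vector of per-trait upper clamps
#'   (default caps `cci` at 1).
#' @return data frame, one row per (plot, trait), with all phenotype
#'   fields plus fit diagnostics; series that fail to fit get `NA` fields
#'   and the error message in `fit_error`.
#' @export
dynamic_phenotype_table <- function(records, step = 0.1, value_caps = c(cci = 1)) {
  keys <- unique(records[, c("plot_id", "trait")])
  keys <- keys[order(keys$plot_id, keys$trait), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- records$plot_id == keys$plot_id[i] & records$trait == keys$trait[i]
    ser <- records[sel, ]
    ser <- ser[order(ser$das), ]
    cap <- unname(value_caps[keys$trait[i]])
    if (length(cap) != 1) cap <- NA_real_
    base <- data.frame(plot_id = keys$plot_id[i], trait = keys$trait[i])
    res <- tryCatch(
      dynamic_phenotypes(ser$das, ser$value, step = step,
                         value_cap = if (is.null(cap) || is.na(cap)) NULL else cap),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(cbind(base, data.frame(
        rgp_start = NA, rgp_end = NA, rgp_days = NA, fgr_day = NA, fgr_value = NA,
        agr_to_fgr = NA, agr_to_max = NA, agr_in_rgp = NA, max_day = NA,
        max_value = NA, ripening_day = NA, rss = NA, converged = FALSE,
        fit_error = conditionMessage(res))))
    }
    cbind(base, data.frame(
      rgp_start = round(res$rgp_start, 1), rgp_end = round(res$rgp_end, 1),
      rgp_days = round(res$rgp_days, 1), fgr_day = round(res$fgr_day, 1),
      fgr_value = res$fgr_value, agr_to_fgr = res$agr_to_fgr,
      agr_to_max = res$agr_to_max, agr_in_rgp = res$agr_in_rgp,
      max_day = round(res$max_day, 1), max_value = res$max_value,
      ripening_day = round(res$ripening_day, 1), rss = res$rss,
      converged = res$converged, fit_error = ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
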