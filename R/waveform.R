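#' Periodic pressure waveform
#'
#' A waveform is a set of samples on a uniform time grid over one cardiac
#' period, evaluated by periodic piecewise-linear interpolation. Pressures are
#' stored in mmHg at the interface; the solver converts to CGS internally.
#'
#' @param time sample times in s, strictly increasing, spanning `[0, period)`.
#' @param pressure sample values in mmHg.
#' @param period cardiac period T in s.
#' @param notch dicrotic-notch time in s (end of systole), used by the cardiac
#'   phase map; `NA` if unknown.
#' @return An object of class `waveform`.
#' @export
waveform <- function(time, pressure, period, notch = NA_real_) {
  stopifnot(length(time) == length(pressure), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("waveform times must be strictly increasing")
  if (time[1] < 0 || time[length(time)] >= period) {
    stop("waveform times must span [0, period)")
  }
  structure(list(time = as.numeric(time), pressure = as.numeric(pressure),
                 period = period, notch = notch),
            class = "waveform")
}

#' Evaluate a waveform
#'
#' Periodic piecewise-linear evaluation: `wf_eval(wf, t + k*T)` equals
#' `wf_eval(wf, t)` for any integer k.
#'
#' @param wf a [waveform()].
#' @param t times in s (vectorised).
#' @return pressure in mmHg.
#' @export
wf_eval <- function(wf, t) {
  tm <- t %% wf$period
  # closing sample: wrap the first value to t = period for continuity
  tt <- c(wf$time, wf$period)
  pp <- c(wf$pressure, wf$pressure[1])
  stats::approx(tt, pp, xout = tm, rule = 2)$y
}

#' @rdname wf_eval
#' @export
wf_mean <- function(wf) {
  # time average over one period (trapezoid on the closed grid)
  tt <- c(wf$time, wf$period)
  pp <- c(wf$pressure, wf$pressure[1])
  sum(diff(tt) * (pp[-1] + pp[-length(pp)]) / 2) / wf$period
}

#' Scale a waveform by a constant factor
#' @param wf a [waveform()].
#' @param factor multiplicative factor.
#' @export
wf_scale <- function(wf, factor) {
  waveform(wf$time, wf$pressure * factor, wf$period, wf$notch)
}

#' Constant waveform
#' @param value pressure in mmHg.
#' @param period cardiac period in s.
#' @param n number of samples.
#' @export
wf_constant <- function(value, period, n = 100) {
  waveform(seq(0, period, length.out = n + 1)[1:n], rep(value, n), period)
}

#' External (extravascular) pressure by myocardial class
#'
#' Terminal vascular beds feel an external pressure according to where they are
#' embedded: left-ventricular beds feel the full LV transient, right-ventricular
#' beds 0.2 x LV, septal beds 0.6 x LV, and systemic (non-cardiac) beds a
#' constant venous pressure.
#'
#' @param class one of `"LV"`, `"RV"`, `"septal"`, `"systemic"`.
#' @param t times in s.
#' @param lv the left-ventricular external-pressure [waveform()].
#' @param venous constant systemic venous pressure in mmHg.
#' @return external pressure in mmHg at times `t`.
#' @export
external_pressure <- function(class, t, lv, venous = 1) {
  switch(class,
    LV       = wf_eval(lv, t),
    RV       = 0.2 * wf_eval(lv, t),
    septal   = 0.6 * wf_eval(lv, t),
    systemic = rep(venous, length(t)),
    stop("unknown external-pressure class: ", class)
  )
}

#' @rdname external_pressure
#' @details `external_pressure_waveform()` returns the class waveform itself
#'   (sampled on the LV grid) rather than point evaluations.
#' @export
external_pressure_waveform <- function(class, lv, venous = 1) {
  switch(class,
    LV       = lv,
    RV       = wf_scale(lv, 0.2),
    septal   = wf_scale(lv, 0.6),
    systemic = wf_constant(venous, lv$period),
    stop("unknown external-pressure class: ", class)
  )
}

#' Read and write two-column waveform files
#'
#' Plain-text format: comment headers `# period: <s>` and `# notch: <s>`
#' followed by two whitespace-separated columns (time s, pressure mmHg).
#'
#' @param path file path.
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0("^#\\s*", key, ":\\s*"), "", m[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("time", "pressure"))
  waveform(dat$time, dat$pressure, period = getv("period"), notch = getv("notch"))
}

#' @rdname read_waveform
#' @param wf a [waveform()].
#' @export
write_waveform <- function(wf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period: %.17g", wf$period), con)
  if (!is.na(wf$notch)) writeLines(sprintf("# notch: %.17g", wf$notch), con)
  utils::write.table(data.frame(time = wf$time, pressure = wf$pressure),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parameters for synthetic pressure waveforms
#'
#' Defaults describe a resting adult: period 0.917 s (about 65 bpm), diastolic
#' aortic pressure 76.41 mmHg, systolic peak 120 mmHg, dicrotic notch at 38% of
#' the cycle, diastolic pressure decay time constant 1.25 s, peak LV
#' extravascular pressure 100 mmHg and venous offset 1 mmHg.
#'
#' @param period cardiac period T, s.
#' @param diastolic diastolic (minimum) aortic pressure, mmHg.
#' @param systolic systolic peak aortic pressure, mmHg.
#' @param notch_frac dicrotic-notch time as a fraction of the period, in (0,1).
#' @param tau diastolic decay time constant, s.
#' @param lv_peak peak left-ventricular external pressure, mmHg.
#' @param venous systemic venous offset, mmHg.
#' @param n samples per period.
#' @export
waveform_params <- function(period = 0.917, diastolic = 76.41, systolic = 120,
                            notch_frac = 0.38, tau = 1.25, lv_peak = 100,
                            venous = 1, n = 100) {
  if (notch_frac <= 0 || notch_frac >= 1) stop("notch_frac must be in (0, 1)")
  stopifnot(period > 0, tau > 0, systolic >= diastolic)
  list(period = period, diastolic = diastolic, systolic = systolic,
       notch_frac = notch_frac, tau = tau, lv_peak = lv_peak,
       venous = venous, n = n)
}

#' Synthetic aortic-root inlet pressure waveform
#'
#' Systole: a smooth rise from the diastolic foot to the systolic peak and fall
#' to the dicrotic-notch pressure. Diastole: exponential decay with time
#' constant `tau` toward an asymptote chosen so the end-of-cycle pressure
#' returns exactly to the diastolic value; the minimum of the generated
#' waveform therefore equals `diastolic` and the diastolic tail refits `tau`.
#'
#' @param params a [waveform_params()] list.
#' @return a [waveform()] carrying the notch time.
#' @export
generate_inlet_pressure <- function(params = waveform_params()) {
  p <- params
  tn <- p$notch_frac * p$period
  # notch pressure: between diastolic and peak
  p_notch <- p$diastolic + 0.35 * (p$systolic - p$diastolic)
  tgrid <- seq(0, p$period, length.out = p$n + 1)[1:p$n]
  # systolic shape: linear foot-to-notch ramp plus a sine bump whose
  # amplitude is solved so the maximum lands exactly on the systolic value
  sgrid <- seq(0, 1, length.out = 2001)
  ramp <- (p_notch - p$diastolic) * sgrid
  pulse <- p$systolic - p$diastolic
  amp <- if (pulse > 0) {
    stats::uniroot(function(a) max(ramp + a * sin(pi * sgrid)) - pulse,
                   c(0, pulse), tol = 1e-12)$root
  } else 0
  # diastolic asymptote solving P(T) = diastolic for the exponential tail
  e <- exp(-(p$period - tn) / p$tau)
  p_out <- (p$diastolic - p_notch * e) / (1 - e)
  val <- ifelse(tgrid <= tn,
    {
      s <- tgrid / tn
      p$diastolic + (p_notch - p$diastolic) * s + amp * sin(pi * s)
    },
    p_out + (p_notch - p_out) * exp(-(tgrid - tn) / p$tau)
  )
  waveform(tgrid, val, p$period, notch = tn)
}

#' Synthetic left-ventricular external-pressure waveform
#'
#' A squared-sine contraction bump over systole (synchronised with the inlet
#' waveform: systole spans `[0, notch_frac * period]`) on top of the constant
#' venous offset; in diastole the waveform is the venous plateau.
#'
#' @param params a [waveform_params()] list.
#' @return a [waveform()].
#' @export
generate_lv_external_pressure <- function(params = waveform_params()) {
  p <- params
  tn <- p$notch_frac * p$period
  tgrid <- seq(0, p$period, length.out = p$n + 1)[1:p$n]
  val <- p$venous + ifelse(tgrid <= tn,
                           p$lv_peak * sin(pi * tgrid / tn)^2, 0)
  waveform(tgrid, val, p$period, notch = tn)
}

#' Fit the diastolic decay time constant
#'
#' Least-squares fit of P(t) = Pout + (P(t0) - Pout) exp(-(t - t0)/tau) to the
#' diastolic tail of an inlet waveform, where t0 is the start of the decay
#' window (the dicrotic notch unless given). Both `tau` and the outflow
#' asymptote `Pout` are fitted unless `pout` is supplied.
#'
#' @param wf inlet pressure [waveform()]; must carry a notch time if `window`
#'   is not given.
#' @param window decay window `c(t_start, t_end)` in s; default notch-to-period.
#' @param pout optional fixed outflow pressure, mmHg.
#' @return fitted time constant tau in s, with attributes `pout` and `p0`.
#' @export
fit_time_constant <- function(wf, window = NULL, pout = NULL) {
  if (is.null(window)) {
    if (is.na(wf$notch)) stop("waveform has no notch time; supply a window")
    window <- c(wf$notch, wf$period)
  }
  # fit on the waveform's own samples inside the window (no resampling
  # error); fall back to a dense grid for coarsely sampled waveforms
  tt <- wf$time[wf$time >= window[1] & wf$time <= window[2]]
  if (length(tt) < 10) tt <- seq(window[1], window[2], length.out = 200)
  pp <- wf_eval(wf, pmin(tt, wf$period * (1 - 1e-12)))
  if (any(diff(pp) > 1e-9 * max(abs(pp)))) {
    warning("decay window is not monotone decreasing; fit may be poor")
  }
  t0 <- tt[1]
  p0 <- pp[1]
  obj <- function(par) {
    tau <- par[1]
    po <- if (is.null(pout)) par[2] else pout
    sum((po + (p0 - po) * exp(-(tt - t0) / tau) - pp)^2)
  }
  start <- if (is.null(pout)) c(1, min(pp) - 10) else 1
  fit <- stats::optim(start, obj, method = if (is.null(pout)) "Nelder-Mead" else "Brent",
                      lower = if (is.null(pout)) -Inf else 1e-3,
                      upper = if (is.null(pout)) Inf else 100,
                      control = list(reltol = 1e-14, maxit = 5000))
  if (is.null(pout)) {  # quasi-Newton polish
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(reltol = 1e-15, maxit = 500))
  }
  tau <- fit$par[1]
  structure(tau,
            pout = if (is.null(pout)) fit$par[2] else pout,
            p0 = p0)
}
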