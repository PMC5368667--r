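#' Melt-analysis settings
#'
#' @param baseline_frac Fraction of the temperature span used to seed the
#'   folded (lowest) and unfolded (highest) baseline windows.
#' @param baseline_tol Final guard: a window is shrunk while the mean
#'   fraction folded inside it departs from 1 (folded) or 0 (unfolded) by
#'   more than this.
#' @param plateau_tol Windows auto-extend toward the transition while the
#'   fraction folded stays within this tolerance of its plateau value
#'   (1 folded, 0 unfolded); extending the baseline fit over the full
#'   plateau minimizes the extrapolation error at the transition.
#' @param window_margin Safety margin (deg C) kept between a baseline
#'   window's inner edge and the detected end of its plateau.
#' @param f_lo,f_hi Fraction-folded band defining the transition region
#'   (central, near-linear part of a two-state sigmoid).
#' @param regress_on `"fraction"` (default) regresses fraction folded on
#'   temperature; `"ellipticity"` regresses the raw signal and solves for
#'   the midpoint between the baselines.
#' @param min_transition_points Minimum points used in the transition
#'   regression; when the band holds fewer, the nearest points around the
#'   f = 0.5 crossing complete it.
#' @return List of settings.
#' @export
melt_config <- function(baseline_frac = 0.15,
                        baseline_tol = 0.05,
                        plateau_tol = 0.05,
                        window_margin = 3,
                        f_lo = 0.35,
                        f_hi = 0.65,
                        regress_on = c("fraction", "ellipticity"),
                        min_transition_points = 4L) {
  list(baseline_frac = baseline_frac,
       baseline_tol = baseline_tol,
       plateau_tol = plateau_tol,
       window_margin = window_margin,
       f_lo = f_lo,
       f_hi = f_hi,
       regress_on = match.arg(regress_on),
       min_transition_points = min_transition_points)
}

check_melt_curve <- function(curve) {
  stopifnot(all(c("temp", "signal") %in% names(curve)))
  if (is.unsorted(curve$temp, strictly = TRUE)) {
    stop("melt temperatures must be strictly increasing")
  }
  invisible(curve)
}

#' Fit linear folded/unfolded baselines
#'
#' Ordinary least-squares lines through the pre- and post-transition
#' segments of a thermal scan; the folded and unfolded ellipticities are
#' treated as linear functions of temperature.
#'
#' @param curve Data frame with `temp` (deg C, strictly increasing) and
#'   `signal` (ellipticity).
#' @param folded_window,unfolded_window `c(lo, hi)` temperature ranges;
#'   the folded window must lie below the unfolded window, each must
#'   contain at least 4 points, and they must not overlap.
#' @return Object of class `baseline_pair`: `folded` and `unfolded` each
#'   `c(slope, intercept)`, plus the `windows` used.
#' @export
fit_baselines <- function(curve, folded_window, unfolded_window) {
  check_melt_curve(curve)
  if (folded_window[2] >= unfolded_window[1]) {
    stop("baseline windows overlap or are out of order")
  }
  rng <- range(curve$temp)
  if (folded_window[1] < rng[1] - 1e-9 || unfolded_window[2] > rng[2] + 1e-9) {
    stop("baseline window outside the scanned temperature range")
  }
  line_in <- function(w) {
    sel <- curve$temp >= w[1] & curve$temp <= w[2]
    if (sum(sel) < 4L) stop("baseline window contains fewer than 4 points")
    b <- stats::coef(stats::lm(signal ~ temp, data = curve[sel, ]))
    c(slope = unname(b[2]), intercept = unname(b[1]))
  }
  structure(list(folded = line_in(folded_window),
                 unfolded = line_in(unfolded_window),
                 windows = list(folded = folded_window,
                                unfolded = unfolded_window)),
            class = "baseline_pair")
}

baseline_eval <- function(line, temp) line[["intercept"]] + line[["slope"]] * temp

#' Fraction folded from a melt curve and baselines
#'
#' `f(T) = (theta(T) - theta_U(T)) / (theta_F(T) - theta_U(T))`. Values may
#' slightly exceed `[0, 1]` from noise and are not clipped.
#'
#' @param curve Melt data frame (`temp`, `signal`).
#' @param baselines `baseline_pair` from [fit_baselines()].
#' @return Data frame (`temp`, `fraction`).
#' @export
fraction_folded <- function(curve, baselines) {
  check_melt_curve(curve)
  thf <- baseline_eval(baselines$folded, curve$temp)
  thu <- baseline_eval(baselines$unfolded, curve$temp)
  denom <- thf - thu
  if (any(denom == 0) || any(sign(denom) != sign(denom[1]))) {
    stop("folded and unfolded baselines cross inside the scan; ",
         "fraction folded is undefined")
  }
  data.frame(temp = curve$temp, fraction = (curve$signal - thu) / denom)
}

# Automatic baseline-window selection. Windows seed at the outer
# baseline_frac of the span and auto-extend over the folded/unfolded
# plateaus (points whose fraction folded stays within plateau_tol of 1/0,
# minus a safety margin), iterating fit -> transform -> re-select to
# convergence; fitting the whole plateau minimizes baseline extrapolation
# error at the transition. The mean-departure shrink guard runs last.
autoshrink_baselines <- function(curve, config) {
  temp <- curve$temp
  rng <- range(temp)
  span <- diff(rng)
  fw <- c(rng[1], rng[1] + config$baseline_frac * span)
  uw <- c(rng[2] - config$baseline_frac * span, rng[2])
  # fit baselines; when a window overlaps the transition the fitted lines
  # can cross inside the scan - shrink both windows toward the scan edges
  # until the fraction folded is defined
  fit_f <- function(fw, uw) {
    for (k in 1:8) {
      bl <- fit_baselines(curve, fw, uw)
      f <- tryCatch(fraction_folded(curve, bl)$fraction,
                    error = function(e) NULL)
      if (!is.null(f)) return(list(bl = bl, f = f, fw = fw, uw = uw))
      fw[2] <- fw[1] + 0.75 * (fw[2] - fw[1])
      uw[1] <- uw[2] - 0.75 * (uw[2] - uw[1])
      if (sum(temp >= fw[1] & temp <= fw[2]) < 4L ||
          sum(temp >= uw[1] & temp <= uw[2]) < 4L) break
    }
    stop("folded and unfolded baselines cross inside the scan; ",
         "fraction folded is undefined")
  }
  for (pass in 1:8) {
    ft <- fit_f(fw, uw)
    bl <- ft$bl
    f <- ft$f
    fw <- ft$fw
    uw <- ft$uw
    # plateau-edge detection runs on a lightly smoothed f (5-point running
    # mean) so single noisy excursions do not truncate a window; a plateau
    # ends where smoothed f leaves its tolerance band for 2 consecutive
    # points
    n <- length(f)
    f_sm <- as.numeric(stats::filter(f, rep(1 / 5, 5), sides = 2))
    f_sm[is.na(f_sm)] <- f[is.na(f_sm)]
    bad_f <- f_sm < 1 - config$plateau_tol
    dep_f <- which(bad_f[-n] & bad_f[-1])
    end_f <- if (length(dep_f)) temp[dep_f[1]] - config$window_margin else
      rng[2] - config$baseline_frac * span
    bad_u <- f_sm > config$plateau_tol
    dep_u <- which(bad_u[-n] & bad_u[-1]) + 1L
    start_u <- if (length(dep_u)) temp[dep_u[length(dep_u)]] + config$window_margin else
      rng[1] + config$baseline_frac * span
    # window edges follow the detected plateaus, clamped to keep >= 4 points
    fw_new <- c(rng[1], min(max(end_f, temp[4L]), temp[n - 7L]))
    uw_new <- c(max(min(start_u, temp[n - 3L]), temp[8L]), rng[2])
    if (fw_new[2] >= uw_new[1]) break # degenerate; keep previous windows
    if (isTRUE(all.equal(fw_new, fw)) && isTRUE(all.equal(uw_new, uw))) break
    fw <- fw_new
    uw <- uw_new
  }
  # final guard: shrink while the window-mean fraction departs from 1/0
  for (pass in 1:6) {
    ft <- fit_f(fw, uw)
    bl <- ft$bl
    f <- ft$f
    fw <- ft$fw
    uw <- ft$uw
    dev_f <- abs(mean(f[temp >= fw[1] & temp <= fw[2]]) - 1)
    dev_u <- abs(mean(f[temp >= uw[1] & temp <= uw[2]]))
    ok_f <- dev_f <= config$baseline_tol
    ok_u <- dev_u <= config$baseline_tol
    if (ok_f && ok_u) break
    if (!ok_f) fw[2] <- fw[1] + 0.75 * (fw[2] - fw[1])
    if (!ok_u) uw[1] <- uw[2] - 0.75 * (uw[2] - uw[1])
    if (sum(temp >= fw[1] & temp <= fw[2]) < 4L ||
        sum(temp >= uw[1] & temp <= uw[2]) < 4L) break
  }
  bl
}

#' Estimate the apparent melting temperature from one melt
#'
#' Pipeline: fit linear folded/unfolded baselines (initial windows are the
#' lowest/highest `baseline_frac` of the span, auto-shrunk while the
#' fraction folded inside them departs from 1/0 by more than
#' `baseline_tol`), transform to fraction folded, select the contiguous
#' transition region with `f_lo <= f <= f_hi`, and place the apparent
#' melting temperature where the least-squares line through that region
#' crosses `f = 0.5`. No reversibility is assumed, so the estimate is an
#' apparent (not equilibrium) melting temperature; no enthalpy is
#' extracted.
#'
#' @param curve Melt data frame (`temp`, `signal`), first heating scan.
#' @param config See [melt_config()].
#' @return Object of class `tm_estimate`: `tm_app` (deg C),
#'   `transition_window`, `regression_r2`, `baselines`, `n_replicates = 1`,
#'   `sd = 0`, `reversibility = NA`.
#' @export
estimate_tm <- function(curve, config = melt_config()) {
  check_melt_curve(curve)
  bl <- autoshrink_baselines(curve, config)
  f <- fraction_folded(curve, bl)

  # transition region: the dominant contiguous run of points inside the
  # fraction-folded band; for near-step transitions that leave the band
  # empty, fall back to the points flanking the f = 0.5 sign change
  in_band <- f$fraction >= config$f_lo & f$fraction <= config$f_hi
  sel <- integer(0)
  if (any(in_band)) {
    runs <- rle(in_band)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cand <- which(runs$values)
    mid_dev <- vapply(cand, function(k) {
      abs(stats::median(f$fraction[starts[k]:ends[k]]) - 0.5)
    }, numeric(1))
    k <- cand[order(-runs$lengths[cand], mid_dev)][1]
    sel <- starts[k]:ends[k]
    center <- stats::median(f$temp[sel])
  } else {
    sgn <- sign(f$fraction - 0.5)
    cross <- which(sgn[-length(sgn)] * sgn[-1] < 0 | sgn[-length(sgn)] == 0)
    if (length(cross) == 0L) stop("fraction folded never crosses 0.5")
    center <- f$temp[cross[ceiling(length(cross) / 2)]]
  }
  if (length(sel) < config$min_transition_points) {
    # complete the regression with the points nearest the transition center
    extra <- setdiff(order(abs(f$temp - center)), sel)
    sel <- sort(c(sel, extra[seq_len(config$min_transition_points -
                                       length(sel))]))
  }

  tf <- f$temp[sel]
  ff <- f$fraction[sel]
  if (any(diff(ff) > 0.15)) {
    warning("fraction folded is non-monotone in the transition region")
  }
  if (config$regress_on == "fraction") {
    reg <- stats::lm(ff ~ tf)
    b <- stats::coef(reg)
    tm <- (0.5 - b[[1]]) / b[[2]]
  } else {
    reg <- stats::lm(curve$signal[sel] ~ tf)
    b <- stats::coef(reg)
    # midpoint signal between the two baselines, evaluated at the solution
    mid <- function(t) {
      0.5 * (baseline_eval(bl$folded, t) + baseline_eval(bl$unfolded, t))
    }
    tm <- stats::uniroot(function(t) b[[1]] + b[[2]] * t - mid(t),
                         range(tf), extendInt = "yes")$root
  }
  rng <- range(curve$temp)
  if (tm < rng[1] || tm > rng[2]) {
    stop("apparent Tm (", format(tm), ") falls outside the scanned range")
  }
  structure(list(tm_app = unname(tm),
                 transition_window = range(tf),
                 regression_r2 = summary(reg)$r.squared,
                 baselines = bl,
                 reversibility = NA_real_,
                 n_replicates = 1L,
                 sd = 0),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("<tm_estimate: Tm* %.2f C (n=%d, sd %.2f, r2 %.3f)>\n",
              x$tm_app, x$n_replicates, x$sd,
              if (is.null(x$regression_r2)) NA else x$regression_r2))
  invisible(x)
}

#' Reversibility of unfolding from repeated melts
#'
#' Ratio of the folded-baseline-window signal amplitude (relative to the
#' first melt's unfolded baseline) in the second heating scan versus the
#' first. A fully reversible melt returns ~1; a second scan flat at the
#' unfolded baseline returns ~0.
#'
#' @param first,second Melt data frames (`temp`, `signal`); the second is
#'   interpolated onto the first scan's grid.
#' @param config See [melt_config()].
#' @return Reversible fraction (numeric scalar).
#' @export
check_reversibility <- function(first, second, config = melt_config()) {
  check_melt_curve(first)
  check_melt_curve(second)
  lo <- max(min(first$temp), min(second$temp))
  hi <- min(max(first$temp), max(second$temp))
  if (hi <= lo) stop("melt temperature grids do not overlap")
  bl <- autoshrink_baselines(first, config)
  fw <- bl$windows$folded
  fw[1] <- max(fw[1], lo)
  if (fw[2] <= fw[1]) stop("folded window not covered by both melts")
  grid <- first$temp[first$temp >= fw[1] & first$temp <= fw[2]]
  s1 <- first$signal[first$temp >= fw[1] & first$temp <= fw[2]]
  s2 <- stats::approx(second$temp, second$signal, xout = grid)$y
  thu <- baseline_eval(bl$unfolded, grid)
  amp1 <- mean(s1 - thu)
  amp2 <- mean(s2 - thu)
  if (amp1 == 0) stop("first melt has zero folded amplitude")
  amp2 / amp1
}

#' Mean residue ellipticity
#'
#' Standard convention
#' `MRE = theta[mdeg] * MRW / (10 * pathlength[cm] * conc[g/L])`
#' in deg cm^2 dmol^-1, linear in the raw signal. The convention is
#' attached to the result as the `"convention"` attribute so reports are
#' self-describing.
#'
#' @param theta Ellipticity (mdeg).
#' @param conc Protein concentration (g/L), `> 0`.
#' @param pathlength Cuvette path (cm), `> 0`.
#' @param mean_residue_weight Mean residue weight (g/mol), `> 0`.
#' @return Mean residue ellipticity (deg cm^2 dmol^-1).
#' @export
mean_residue_ellipticity <- function(theta, conc, pathlength,
                                     mean_residue_weight = 110) {
  if (conc <= 0 || pathlength <= 0 || mean_residue_weight <= 0) {
    stop("concentration, pathlength and mean residue weight must be positive")
  }
  structure(theta * mean_residue_weight / (10 * pathlength * conc),
            convention = "MRE = theta[mdeg]*MRW/(10*l[cm]*c[g/L])")
}

#' Average replicate Tm estimates
#'
#' Mean and sample standard deviation of the apparent melting temperature
#' over independent melts.
#'
#' @param estimates List of `tm_estimate`s (or numeric Tm values).
#' @param reversibility Optional reversible fraction to attach.
#' @return A `tm_estimate` whose `tm_app` is the replicate mean, with
#'   `n_replicates`, `sd` and per-replicate `values`.
#' @export
summarize_tm <- function(estimates, reversibility = NA_real_) {
  if (length(estimates) == 0L) stop("no Tm estimates supplied")
  tms <- vapply(estimates, function(e) {
    if (inherits(e, "tm_estimate")) e$tm_app else as.numeric(e)
  }, numeric(1))
  structure(list(tm_app = mean(tms),
                 transition_window = NULL,
                 regression_r2 = NULL,
                 baselines = NULL,
                 reversibility = reversibility,
                 n_replicates = length(tms),
                 sd = if (length(tms) > 1L) stats::sd(tms) else 0,
                 values = tms),
            class = "tm_estimate")
}

#' Read melt curves from CSV
#'
#' Expected columns: `variant`, `scan` (1 = first heating, 2 = repeat),
#' `replicate`, `temp_C`, `signal`.
#'
#' @param path CSV file.
#' @return Nested list `[[variant]][[replicate]]` of lists with `first`
#'   and (optionally) `second` melt data frames.
#' @export
read_melts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "scan", "replicate", "temp_C", "signal") %in%
                  names(df)))
  out <- list()
  for (v in unique(df$variant)) {
    sub <- df[df$variant == v, ]
    out[[v]] <- lapply(split(sub, sub$replicate), function(r) {
      res <- list(first = data.frame(temp = r$temp_C[r$scan == 1],
                                     signal = r$signal[r$scan == 1]))
      if (any(r$scan == 2)) {
        res$second <- data.frame(temp = r$temp_C[r$scan == 2],
                                 signal = r$signal[r$scan == 2])
      }
      res
    })
  }
  out
}

#' Estimate and summarize Tm for every variant in a melt table
#'
#' Only the first heating scan feeds the Tm estimate; the repeat scan, when
#' present, feeds the reversibility check.
#'
#' @param melts As returned by [read_melts()] (or [gen_pseries_bundle()]).
#' @param config See [melt_config()].
#' @return Named list of summarized `tm_estimate`s (with `variant` field).
#' @export
fit_all_melts <- function(melts, config = melt_config()) {
  stats::setNames(
    lapply(names(melts), function(v) {
      reps <- melts[[v]]
      ests <- lapply(reps, function(r) estimate_tm(r$first, config))
      rev <- vapply(reps, function(r) {
        if (is.null(r$second)) NA_real_
        else check_reversibility(r$first, r$second, config)
      }, numeric(1))
      out <- summarize_tm(ests, reversibility = mean(rev, na.rm = TRUE))
      out$variant <- v
      out
    }),
    names(melts))
}
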