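#' Saturation-plus-nonspecific fluorescence binding model
#'
#' Mean-fluorescence model for yeast-display titrations:
#' `APC(c) = APC_min + APC_sat * c / (c + K_D) + APC_ns * c`,
#' a one-site saturation isotherm on top of a linear nonspecific component.
#' Monotone nondecreasing in concentration when `apc_sat, apc_ns >= 0`.
#'
#' @param conc Antigen concentration(s), molar, `>= 0`.
#' @param apc_min Baseline fluorescence (a.u.).
#' @param apc_sat Saturation amplitude (a.u.).
#' @param apc_ns Nonspecific slope (a.u. per molar).
#' @param kd Equilibrium dissociation constant (molar, `> 0`).
#' @return Predicted fluorescence (a.u.).
#' @export
binding_model <- function(conc, apc_min, apc_sat, apc_ns, kd) {
  if (any(conc < 0)) stop("negative concentration")
  if (kd <= 0) stop("kd must be positive")
  apc_min + apc_sat * conc / (conc + kd) + apc_ns * conc
}

#' Fit settings for the binding isotherm
#'
#' @param n_starts Number of K_D starting values on a log grid spanning
#'   `[min conc / 100, max conc * 100]`.
#' @param kd_bounds_factor K_D is constrained to
#'   `[min conc / f, max conc * f]`.
#' @param unmeasurable_kd_factor Flag the fit unmeasurable when the fitted
#'   K_D exceeds this multiple of the highest tested concentration.
#' @param unmeasurable_sat_factor Flag unmeasurable when the fitted
#'   saturation amplitude is at or below this multiple of the residual RMS.
#' @param saturation_f_alpha Significance level of the partial F-test of
#'   the full isotherm against the nested linear (no-saturation) model; a
#'   fit whose saturable component does not improve on the straight line
#'   at this level is flagged unmeasurable (a K_D far above the tested
#'   ladder is indistinguishable from the linear nonspecific term). Set
#'   `NULL` to disable.
#' @return List of settings.
#' @export
binding_config <- function(n_starts = 7L,
                           kd_bounds_factor = 1000,
                           unmeasurable_kd_factor = 10,
                           unmeasurable_sat_factor = 3,
                           saturation_f_alpha = 0.01) {
  list(n_starts = n_starts,
       kd_bounds_factor = kd_bounds_factor,
       unmeasurable_kd_factor = unmeasurable_kd_factor,
       unmeasurable_sat_factor = unmeasurable_sat_factor,
       saturation_f_alpha = saturation_f_alpha)
}

# Linear-subproblem initialization: for fixed kd the model is linear in
# (apc_min, apc_sat, apc_ns); solve by OLS and clamp the bounded terms.
linear_params_at_kd <- function(conc, signal, kd) {
  sat_frac <- conc / (conc + kd)
  fit <- stats::lm(signal ~ sat_frac + conc)
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  c(apc_min = unname(b[1]),
    apc_sat = max(0, unname(b[2])),
    apc_ns = max(0, unname(b[3])))
}

#' Fit a titration to the binding isotherm
#'
#' Multi-start bounded nonlinear least squares minimizing the mean squared
#' error between observed and predicted fluorescence. K_D starts on a log
#' grid; at each start the three linear parameters are initialized by
#' ordinary least squares, then all four parameters are refined with
#' bounded Levenberg-Marquardt ([minpack.lm::nlsLM]) using log10 K_D and a
#' concentration-scaled nonspecific slope for conditioning. The association
#' constant is the inverse of the fitted K_D.
#'
#' A fit is flagged unmeasurable (low-affinity convention) when the fitted
#' K_D exceeds 10x the highest tested concentration or the saturation
#' amplitude is at or below 3x the residual RMS; both thresholds sit in
#' [binding_config()].
#'
#' @param data Data frame with columns `conc` (molar) and `signal` (a.u.);
#'   one replicate. At least 5 distinct concentrations spanning at least
#'   2 decades (among positive concentrations) are required.
#' @param config See [binding_config()].
#' @return Object of class `binding_fit`: list with `apc_min`, `apc_sat`,
#'   `apc_ns`, `kd`, `ka`, `mse`, `measurable`, `n_points`.
#' @export
fit_isotherm <- function(data, config = binding_config()) {
  stopifnot(all(c("conc", "signal") %in% names(data)))
  conc <- as.numeric(data$conc)
  signal <- as.numeric(data$signal)
  if (any(conc < 0)) stop("negative concentration in titration")
  pos <- conc[conc > 0]
  if (length(unique(conc)) < 5L) {
    stop("unfit titration: fewer than 5 distinct concentrations")
  }
  if (length(pos) == 0L || max(pos) / min(pos) < 100) {
    stop("unfit titration: concentrations span fewer than 2 decades")
  }
  cmin <- min(pos)
  cmax <- max(pos)
  cscale <- cmax # nonspecific slope fitted as apc_ns * cmax (a.u. scale)
  lkd_lo <- log10(cmin / config$kd_bounds_factor)
  lkd_hi <- log10(cmax * config$kd_bounds_factor)
  starts <- seq(log10(cmin / 100), log10(cmax * 100),
                length.out = config$n_starts)
  cs <- conc / cscale

  resid_fn <- function(p) {
    signal - (p[1] + p[2] * conc / (conc + 10^p[4]) + p[3] * cs)
  }
  best <- NULL
  best_sse <- Inf
  for (lkd0 in starts) {
    lin <- linear_params_at_kd(conc, signal, 10^lkd0)
    # a zero saturation start makes the K_D gradient vanish; floor it
    sat0 <- max(lin[["apc_sat"]], 0.05 * diff(range(signal)), 1e-9)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(apc_min = lin[["apc_min"]], apc_sat = sat0,
                ans = lin[["apc_ns"]] * cscale, lkd = lkd0),
        lower = c(-Inf, 0, 0, lkd_lo),
        upper = c(Inf, Inf, Inf, lkd_hi),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- fit$deviance
    if (sse < best_sse) {
      best_sse <- sse
      best <- fit$par
    }
  }
  if (is.null(best)) {
    # fall back to the pure grid optimum so the error can report a residual
    grid <- vapply(starts, function(l) {
      p <- linear_params_at_kd(conc, signal, 10^l)
      sum((signal - binding_model(conc, p[1], p[2], p[3], 10^l))^2)
    }, numeric(1))
    stop("isotherm fit failed to converge from any start (best grid SSE ",
         format(min(grid)), ")")
  }

  kd <- 10^best[["lkd"]]
  apc_sat <- best[["apc_sat"]]
  n <- length(conc)
  mse <- best_sse / n
  rms <- sqrt(mse)
  measurable <- kd <= config$unmeasurable_kd_factor * cmax &&
    apc_sat > config$unmeasurable_sat_factor * rms
  if (measurable && !is.null(config$saturation_f_alpha) && n > 4L) {
    sse_lin <- sum(stats::residuals(stats::lm(signal ~ conc))^2)
    f_stat <- if (best_sse == 0) {
      if (sse_lin > 0) Inf else 0
    } else {
      ((sse_lin - best_sse) / 2) / (best_sse / (n - 4))
    }
    measurable <- f_stat > stats::qf(1 - config$saturation_f_alpha, 2, n - 4)
  }
  structure(list(apc_min = best[["apc_min"]],
                 apc_sat = apc_sat,
                 apc_ns = best[["ans"]] / cscale,
                 kd = kd,
                 ka = 1 / kd,
                 mse = mse,
                 measurable = measurable,
                 n_points = length(conc)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit: KD %.3g M (KA %.3g /M), APCmin %.3g, APCsat %.3g, APCns %.3g, mse %.3g%s>\n",
              x$kd, x$ka, x$apc_min, x$apc_sat, x$apc_ns, x$mse,
              if (x$measurable) "" else ", UNMEASURABLE"))
  invisible(x)
}

#' Summarize replicate binding fits for one variant
#'
#' Mean and sample (n-1) standard deviation of K_A over the measurable
#' replicates. The variant is flagged unmeasurable when more than half its
#' replicates are; an unmeasurable summary carries `NA` mean/sd (the
#' low-affinity dagger convention).
#'
#' @param fits List of `binding_fit`s for one variant.
#' @param variant Variant label.
#' @return Object of class `affinity_summary`: `variant`, `mean_ka`,
#'   `sd_ka`, `n` (measurable replicates used), `n_total`, `measurable`,
#'   `values` (per-replicate K_A, measurable only).
#' @export
summarize_affinity <- function(fits, variant) {
  if (length(fits) == 0L) stop("no fits supplied for '", variant, "'")
  meas <- vapply(fits, function(f) isTRUE(f$measurable), logical(1))
  kas <- vapply(fits[meas], function(f) f$ka, numeric(1))
  variant_measurable <- sum(!meas) <= length(fits) / 2
  if (!variant_measurable || length(kas) == 0L) {
    out <- list(variant = variant, mean_ka = NA_real_, sd_ka = NA_real_,
                n = 0L, n_total = length(fits), measurable = FALSE,
                values = numeric(0))
  } else {
    out <- list(variant = variant,
                mean_ka = mean(kas),
                sd_ka = if (length(kas) > 1L) stats::sd(kas) else 0,
                n = length(kas),
                n_total = length(fits),
                measurable = TRUE,
                values = kas)
  }
  structure(out, class = "affinity_summary")
}

#' @export
print.affinity_summary <- function(x, ...) {
  if (x$measurable) {
    cat(sprintf("<affinity %s: KA %.3g +/- %.3g /M (n=%d)>\n",
                x$variant, x$mean_ka, x$sd_ka, x$n))
  } else {
    cat(sprintf("<affinity %s: unmeasurable (n=%d)>\n", x$variant, x$n_total))
  }
  invisible(x)
}

#' Read titrations from CSV
#'
#' Expected columns: `variant`, `replicate`, `conc_M`, `signal`.
#'
#' @param path CSV file.
#' @return Nested list: `[[variant]][[replicate]]` data frames with
#'   `conc`, `signal`.
#' @export
read_titrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "replicate", "conc_M", "signal") %in% names(df)))
  out <- list()
  for (v in unique(df$variant)) {
    sub <- df[df$variant == v, ]
    out[[v]] <- lapply(split(sub, sub$replicate), function(r) {
      data.frame(conc = r$conc_M, signal = r$signal)
    })
  }
  out
}

#' Fit every replicate of every variant in a titration table
#'
#' @param titrations As returned by [read_titrations()] (or
#'   [gen_pseries_bundle()]).
#' @param config See [binding_config()].
#' @return Named list of `affinity_summary` objects.
#' @export
fit_all_titrations <- function(titrations, config = binding_config()) {
  stats::setNames(
    lapply(names(titrations), function(v) {
      fits <- lapply(titrations[[v]], fit_isotherm, config = config)
      summarize_affinity(fits, v)
    }),
    names(titrations))
}
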