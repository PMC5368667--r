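test_that("baselines recover exact lines and reject bad windows", {
  temp <- seq(25, 95, by = 0.5)
  curve <- data.frame(temp = temp, signal = -0.01 * temp - 3)
  bl <- fit_baselines(curve, c(25, 40), c(80, 95))
  expect_equal(unname(bl$folded["slope"]), -0.01, tolerance = 1e-12)
  expect_equal(unname(bl$folded["intercept"]), -3, tolerance = 1e-12)

  flat <- data.frame(temp = temp, signal = rep(5, length(temp)))
  blf <- fit_baselines(flat, c(25, 40), c(80, 95))
  expect_equal(unname(blf$folded["slope"]), 0, tolerance = 1e-12)
  expect_equal(unname(blf$unfolded["slope"]), 0, tolerance = 1e-12)

  expect_error(fit_baselines(curve, c(25, 60), c(50, 95)), "overlap")
  expect_error(fit_baselines(curve, c(10, 40), c(80, 95)), "outside")
  expect_error(fit_baselines(curve, c(25, 26), c(80, 95)), "fewer than 4")
})

test_that("baselines from a synthetic two-state curve match the truth", {
  truth <- melt_truth(tm = 66, noise_sd = 0, seed = 1)
  curve <- gen_melt(truth)[[1]]$first
  bl <- fit_baselines(curve, c(25, 40), c(85, 95))
  expect_equal(unname(bl$folded["slope"]), truth$folded_baseline[1],
               tolerance = 0.02)
  expect_equal(unname(bl$unfolded["slope"]), truth$unfolded_baseline[1],
               tolerance = 0.02)
  expect_equal(unname(bl$unfolded["intercept"]), truth$unfolded_baseline[2],
               tolerance = 0.02)
})

test_that("fraction folded hits 1, 0 and 1/2 on the baselines and midway", {
  temp <- seq(30, 90, by = 1)
  bl <- structure(list(folded = c(slope = -0.01, intercept = -2),
                       unfolded = c(slope = -0.002, intercept = -14),
                       windows = list(folded = c(30, 40),
                                      unfolded = c(80, 90))),
                  class = "baseline_pair")
  thf <- -2 - 0.01 * temp
  thu <- -14 - 0.002 * temp
  f1 <- fraction_folded(data.frame(temp = temp, signal = thf), bl)
  expect_equal(f1$fraction, rep(1, length(temp)))
  f0 <- fraction_folded(data.frame(temp = temp, signal = thu), bl)
  expect_equal(f0$fraction, rep(0, length(temp)))
  fm <- fraction_folded(data.frame(temp = temp, signal = (thf + thu) / 2), bl)
  expect_equal(fm$fraction, rep(0.5, length(temp)))

  crossing <- structure(list(folded = c(slope = -1, intercept = 30),
                             unfolded = c(slope = 0, intercept = -20),
                             windows = bl$windows), class = "baseline_pair")
  expect_error(fraction_folded(data.frame(temp = temp, signal = thf), crossing),
               "cross")
})

test_that("fraction folded is invariant under joint affine signal transforms", {
  truth <- melt_truth(tm = 66, noise_sd = 0, seed = 1)
  curve <- gen_melt(truth)[[1]]$first
  bl <- fit_baselines(curve, c(25, 40), c(85, 95))
  f0 <- fraction_folded(curve, bl)
  curve2 <- data.frame(temp = curve$temp, signal = 3 * curve$signal + 7)
  bl2 <- fit_baselines(curve2, c(25, 40), c(85, 95))
  f2 <- fraction_folded(curve2, bl2)
  expect_equal(f2$fraction, f0$fraction, tolerance = 1e-9)
})

test_that("an ideal step melt yields its step temperature", {
  temp <- seq(25, 95, by = 0.25)
  thf <- -2 - 0.01 * temp
  thu <- -14 - 0.002 * temp
  sig <- ifelse(temp < 70, thf, thu)
  est <- estimate_tm(data.frame(temp = temp, signal = sig))
  expect_equal(est$tm_app, 70, tolerance = 0.25)
})

test_that("apparent Tm recovery: noiseless within 0.1, noisy within 0.5", {
  truth0 <- melt_truth(tm = 66, noise_sd = 0, seed = 1)
  est0 <- estimate_tm(gen_melt(truth0)[[1]]$first)
  expect_lt(abs(est0$tm_app - 66), 0.1)
  expect_gt(est0$regression_r2, 0.99)
  expect_true(est0$tm_app >= est0$transition_window[1] - 0.5 &&
                est0$tm_app <= est0$transition_window[2] + 0.5)

  truth <- melt_truth(tm = 66, noise_sd = 0.3, seed = 1)
  for (rep_ in gen_melt(truth, replicate_seeds = c(1, 2))) {
    est <- estimate_tm(rep_$first)
    expect_lt(abs(est$tm_app - 66), 0.5)
  }
})

test_that("Tm estimates are stable under temperature-grid refinement", {
  t_coarse <- melt_truth(tm = 66, noise_sd = 0, seed = 1,
                         temp_grid = seq(25, 95, by = 0.5))
  t_fine <- melt_truth(tm = 66, noise_sd = 0, seed = 1,
                       temp_grid = seq(25, 95, by = 0.1))
  e1 <- estimate_tm(gen_melt(t_coarse)[[1]]$first)
  e2 <- estimate_tm(gen_melt(t_fine)[[1]]$first)
  expect_lt(abs(e1$tm_app - e2$tm_app), 0.05)
})

test_that("random truths are recovered with small mean error", {
  set.seed(42)
  errs <- replicate(20, {
    tm <- runif(1, 55, 85)
    dh <- runif(1, 250, 600)
    # scan extends past the hottest transition so both plateaus are sampled
    truth <- melt_truth(tm = tm, dh = dh, noise_sd = 0.3,
                        temp_grid = seq(25, 105, by = 0.5),
                        seed = sample.int(1e6, 1))
    ests <- vapply(gen_melt(truth),
                   function(r) suppressWarnings(estimate_tm(r$first))$tm_app,
                   numeric(1))
    abs(mean(ests) - tm)
  })
  expect_lt(mean(errs), 0.3)
})

test_that("reversibility is the second-scan amplitude fraction", {
  truth <- melt_truth(tm = 66, noise_sd = 0, seed = 1)
  first <- gen_melt(truth)[[1]]$first
  expect_equal(check_reversibility(first, first), 1.0, tolerance = 1e-9)

  thu <- truth$unfolded_baseline[2] + truth$unfolded_baseline[1] * first$temp
  flat <- data.frame(temp = first$temp, signal = thu)
  # the fitted unfolded baseline differs from the generating line by the
  # residual folded tail, so "fully unfolded" lands near but not at 0
  expect_equal(check_reversibility(first, flat), 0.0, tolerance = 0.05)

  scaled <- data.frame(temp = first$temp,
                       signal = thu + 0.6 * (first$signal - thu))
  expect_equal(check_reversibility(first, scaled), 0.6, tolerance = 0.05)

  shifted <- data.frame(temp = first$temp + 200, signal = first$signal)
  expect_error(check_reversibility(first, shifted), "overlap")
})

test_that("mean residue ellipticity follows the stated convention", {
  expect_equal(as.numeric(mean_residue_ellipticity(0, 0.2, 0.1, 110)), 0)
  # hand evaluation: -10 * 110 / (10 * 0.1 * 0.2) = -5500
  expect_equal(as.numeric(mean_residue_ellipticity(-10, 0.2, 0.1, 110)), -5500)
  # doubling concentration halves the value
  expect_equal(as.numeric(mean_residue_ellipticity(-10, 0.4, 0.1, 110)), -2750)
  expect_error(mean_residue_ellipticity(-10, 0, 0.1, 110), "positive")
})

test_that("replicate Tm summaries give mean and sample SD", {
  s <- summarize_tm(list(66.1, 65.9))
  expect_equal(s$tm_app, 66.0)
  expect_equal(s$sd, sd(c(66.1, 65.9)))
  expect_equal(s$n_replicates, 2L)

  s1 <- summarize_tm(list(70))
  expect_equal(s1$sd, 0)
  expect_equal(s1$n_replicates, 1L)

  s3 <- summarize_tm(list(70, 70, 70))
  expect_equal(s3$tm_app, 70)
  expect_equal(s3$sd, 0)

  expect_error(summarize_tm(list()), "no Tm")
})

test_that("melt CSV round-trips and the pipeline consumes it", {
  truth <- melt_truth(tm = 66, noise_sd = 0.3, reversibility = 0.9,
                      n_replicates = 2, seed = 3)
  reps <- gen_melt(truth)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  df <- do.call(rbind, lapply(seq_along(reps), function(r) {
    rbind(data.frame(variant = "v", scan = 1, replicate = r,
                     temp_C = reps[[r]]$first$temp,
                     signal = reps[[r]]$first$signal),
          data.frame(variant = "v", scan = 2, replicate = r,
                     temp_C = reps[[r]]$second$temp,
                     signal = reps[[r]]$second$signal))
  }))
  write.csv(df, f, row.names = FALSE)
  back <- read_melts(f)
  expect_equal(back$v[[1]]$first$signal, reps[[1]]$first$signal)
  summ <- fit_all_melts(back)$v
  expect_equal(summ$n_replicates, 2L)
  expect_lt(abs(summ$tm_app - 66), 0.5)
  expect_equal(summ$reversibility, 0.9, tolerance = 0.05)
})
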