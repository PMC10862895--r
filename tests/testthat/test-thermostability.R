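# Boltzmann melt fitting, triplicate aggregation, phenotype classification.

test_that("noiseless sigmoid is recovered to >= 6 s.f. with free normalization", {
  x <- seq(25, 89, 1)
  y <- 0.1 + (0.9 - 0.1) / (1 + exp((50 - x) / 2))
  fit <- fit_melting_curve(melting_curve(x, y))
  expect_equal(fit$v50, 50, tolerance = 1e-7)
  expect_equal(fit$slope, 2, tolerance = 1e-7)
  expect_equal(fit$top, 0.9, tolerance = 1e-7)
  expect_equal(fit$bottom, 0.1, tolerance = 1e-7)
  expect_true(fit$converged)
})

test_that("temperature-mirrored (decreasing) curve is rejected as non-converged", {
  x <- seq(25, 89, 1)
  y <- 1 / (1 + exp((50 - x) / 2))
  fit <- fit_melting_curve(melting_curve(x, rev(y)))
  expect_false(fit$converged)
})

test_that("input contracts: short curves and flat signals error", {
  expect_error(melting_curve(1:5, rnorm(5)), class = "ss_input_error")
  x <- seq(25, 89, 1)
  set.seed(1)
  flat <- 0.5 + rnorm(length(x), sd = 0.01)
  expect_error(fit_melting_curve(melting_curve(x, flat)),
               class = "ss_no_transition_error")
  expect_error(melting_curve(c(x[-1], 89), rep(0.5, 65)),
               class = "ss_validation_error")  # non-increasing temperature
})

test_that("synthetic replicates refit within 0.5 degC; grid oracle concurs", {
  curves <- generate_melting_curves(
    melt_gen_spec(55, 2, noise_sd = 0.02, replicates = 3, seed = 11))
  for (cv in curves) {
    fit <- fit_melting_curve(cv, fix_normalization = TRUE)
    expect_true(fit$converged)
    expect_lt(abs(fit$v50 - 55), 0.5)
    oracle <- oracle_melt_grid(cv$temperature, cv$signal)
    expect_equal(fit$v50, oracle$v50, tolerance = 0.02)
  }
})

test_that("Tm estimate is invariant under affine signal rescaling (free Top/Bottom)", {
  cv <- generate_melting_curves(melt_gen_spec(60, 3, noise_sd = 0.01,
                                              seed = 2))[[1]]
  f1 <- fit_melting_curve(cv)
  f2 <- fit_melting_curve(melting_curve(cv$temperature,
                                        -5000 + 12000 * cv$signal))
  expect_equal(f1$v50, f2$v50, tolerance = 1e-6)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-6)
})

test_that("summarize_tm does triplicate arithmetic and skips non-converged fits", {
  mk <- function(v50, conv = TRUE)
    structure(list(v50 = v50, converged = conv,
                   meta = list(variant = "WT", nucleotide = "GDP")),
              class = "melting_fit")
  s <- summarize_tm(list(mk(60), mk(60), mk(60)))
  expect_equal(s$tm_mean, 60)
  expect_equal(s$tm_sd, 0)
  s2 <- summarize_tm(list(mk(59), mk(60), mk(61)))
  expect_equal(s2$tm_mean, 60)
  expect_equal(s2$tm_sd, 1)
  s3 <- summarize_tm(list(mk(59), mk(100, conv = FALSE), mk(61)))
  expect_equal(s3$n_replicates, 2)
  expect_true(is.na(summarize_tm(list(mk(60)))$tm_sd))
  expect_error(summarize_tm(list(mk(60, conv = FALSE))),
               class = "ss_aggregation_error")
})

test_that("replicate Tm spread is consistent with a Monte-Carlo envelope", {
  # 1000-seed Monte-Carlo: distribution of per-curve Tm error at 2% noise
  errs <- vapply(1:1000, function(s) {
    cv <- generate_melting_curves(melt_gen_spec(55, 2, noise_sd = 0.02,
                                                seed = s))[[1]]
    fit_melting_curve(cv, fix_normalization = TRUE)$v50 - 55
  }, numeric(1))
  mc_sd <- sd(errs)
  s <- summarize_tm(lapply(
    generate_melting_curves(melt_gen_spec(55, 2, noise_sd = 0.02,
                                          replicates = 3, seed = 5)),
    fit_melting_curve, fix_normalization = TRUE))
  # a 3-replicate sd lies inside the 2.5/97.5% envelope of chi-distributed sd
  lo <- mc_sd * sqrt(qchisq(0.025, 2) / 2)
  hi <- mc_sd * sqrt(qchisq(0.975, 2) / 2)
  expect_gt(s$tm_sd, lo)
  expect_lt(s$tm_sd, hi)
})

mk_sum <- function(mean, sd = 0.5, n = 3)
  structure(list(tm_mean = mean, tm_sd = sd, n_replicates = n),
            class = "tm_summary")

test_that("thermal phenotype classification follows the reference logic", {
  wt_gdp <- mk_sum(56.2); wt_gtp <- mk_sum(65.2)
  # WT-like ~9 degC shift -> nucleotide responsive
  ph <- classify_thermal_phenotype(mk_sum(56.2), mk_sum(65.2),
                                   wt_gdp, wt_gtp, threshold = 3)
  expect_equal(ph$category, "nucleotide_responsive")
  expect_equal(ph$delta_tm, 9)
  # coincident with the GDP reference -> gdp_like
  ph2 <- classify_thermal_phenotype(mk_sum(56.2), mk_sum(56.2),
                                    wt_gdp, wt_gtp, threshold = 3)
  expect_equal(ph2$category, "gdp_like")
  # near the GTP reference -> gtp_like
  ph3 <- classify_thermal_phenotype(mk_sum(64.8), mk_sum(65.0),
                                    wt_gdp, wt_gtp, threshold = 3)
  expect_equal(ph3$category, "gtp_like")
  # equidistant midpoint with a small threshold -> indeterminate
  mid <- (56.2 + 65.2) / 2
  ph4 <- classify_thermal_phenotype(mk_sum(mid), mk_sum(mid),
                                    wt_gdp, wt_gtp, threshold = 0.5)
  expect_equal(ph4$category, "indeterminate")
  # contradictory references are a configuration error
  expect_error(classify_thermal_phenotype(mk_sum(60), mk_sum(60),
                                          wt_gtp, wt_gdp),
               class = "ss_config_error")
})

test_that("classification is monotone in delta_tm", {
  wt_gdp <- mk_sum(56.2); wt_gtp <- mk_sum(65.2)
  cats <- vapply(seq(0, 15, by = 0.5), function(d) {
    classify_thermal_phenotype(mk_sum(56), mk_sum(56 + d),
                               wt_gdp, wt_gtp, threshold = 3)$category
  }, character(1))
  first_resp <- match("nucleotide_responsive", cats)
  expect_false(is.na(first_resp))
  # once responsive, always responsive as delta grows
  expect_true(all(cats[first_resp:length(cats)] == "nucleotide_responsive"))
})

test_that("melting CSV round-trips through read/write", {
  curves <- generate_melting_curves(
    melt_gen_spec(60, 2, noise_sd = 0.01, replicates = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_melting_csv(curves, path)
  back <- read_melting_csv(path)
  expect_length(back, 2)
  got <- back[[1]]
  expect_equal(got$temperature, curves[[1]]$temperature)
  expect_equal(got$signal, curves[[1]]$signal)
})
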