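noiseless_trace <- function(truth = wt_s2_truth(), protocol = s2_protocol(),
                            scale_34 = 1, scale_36 = 1) {
  simulate_mims(truth, wt_enrichment(), protocol,
                scale_34 = scale_34, scale_36 = scale_36)
}

test_that("preprocess removes baseline and residual-O2 step", {
  # explicit step removal reproduces the artifact-free twin exactly
  with_step <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                             residual_o2_step = 0.05, noise_sigma = 0)
  twin <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol())
  corrected <- preprocess_mims(with_step, residual = 0.05)
  expect_equal(corrected$mz34, twin$mz34, tolerance = 1e-12)
  expect_equal(corrected$mz36, twin$mz36, tolerance = 1e-12)

  # auto mode: first post-injection sample early enough that genuine signal
  # is negligible relative to the step
  slow <- exchange_params(5, 0.2)
  grid <- mims_time_grid(n_post = 80, t_min = 1e-4)
  noisy <- simulate_mims(slow, wt_enrichment(), s3_protocol(), time_grid = grid,
                         residual_o2_step = 0.08, noise_sigma = 0.002, seed = 21)
  clean <- simulate_mims(slow, wt_enrichment(), s3_protocol(), time_grid = grid,
                         residual_o2_step = 0, noise_sigma = 0.002, seed = 21)
  corrected <- preprocess_mims(noisy, residual = "auto")
  post <- corrected$t > 0
  expect_lt(max(abs(corrected$mz34[post] - clean$mz34[post])), 6 * 0.002)
  # post-correction baseline is centred on zero
  expect_lt(abs(mean(corrected$mz34[corrected$t < 0])), 3 * 0.002)

  # time is re-zeroed to injection
  shifted <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                           injection_time = 5,
                           time_grid = mims_time_grid(injection_time = 5))
  out <- preprocess_mims(shifted, residual = 0)
  expect_equal(injection_time(out), 0)
  expect_equal(min(out$t), -0.2, tolerance = 1e-9)

  expect_error(preprocess_mims(
    simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                  time_grid = mims_time_grid(n_pre = 0)), residual = "auto"),
    "pre-injection")
})

test_that("noiseless global fit recovers generating parameters to 1e-6", {
  cases <- list(
    list(truth = exchange_params(111, 0.93), protocol = s2_protocol(), s = c(1, 1)),
    list(truth = exchange_params(29, 0.85), protocol = s3_protocol(), s = c(2.5, 0.4)),
    list(truth = exchange_params(55, 0.67), protocol = s2_protocol(42), s = c(0.1, 7)))
  for (cs in cases) {
    tr <- noiseless_trace(cs$truth, cs$protocol, cs$s[1], cs$s[2])
    fit <- fit_exchange(tr, wt_enrichment(), cs$protocol)
    est <- tidy(fit)
    expect_true(fit$converged)
    expect_equal(est$estimate[est$term == "k_f"], cs$truth$k_f, tolerance = 1e-6)
    expect_equal(est$estimate[est$term == "k_s"], cs$truth$k_s, tolerance = 1e-6)
    expect_equal(est$estimate[est$term == "scale_34"], cs$s[1], tolerance = 1e-6)
    expect_equal(est$estimate[est$term == "scale_36"], cs$s[2], tolerance = 1e-6)
  }
  # grid initialization converges to the same optimum
  tr <- noiseless_trace()
  fit_g <- fit_exchange(tr, wt_enrichment(), s2_protocol(), init = "grid")
  expect_equal(glance(fit_g)$k_f, 111, tolerance = 1e-6)
})

test_that("rate estimates are invariant to overall signal scale", {
  tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                      noise_sigma = 0.01, seed = 31)
  fit1 <- fit_exchange(tr, wt_enrichment(), s2_protocol())
  big <- tr
  big$mz34 <- big$mz34 * 137.5
  big$mz36 <- big$mz36 * 137.5
  fit2 <- fit_exchange(big, wt_enrichment(), s2_protocol())
  expect_equal(glance(fit2)$k_f, glance(fit1)$k_f, tolerance = 1e-9)
  expect_equal(glance(fit2)$k_s, glance(fit1)$k_s, tolerance = 1e-9)
  expect_equal(tidy(fit2)$estimate[3:4] / tidy(fit1)$estimate[3:4], c(137.5, 137.5),
               tolerance = 1e-9)
})

test_that("the slow rate is a single shared parameter and a is fixed from enrichment", {
  fit <- fit_exchange(noiseless_trace(), wt_enrichment(), s2_protocol())
  expect_equal(sum(tidy(fit)$term == "k_s"), 1L)
  expect_identical(fit$a, fast_fraction_a(wt_enrichment()))
  expect_identical(fit$b, interflash_b(s2_protocol()))
  # both channels' fitted values are computed from the same k_s: perturbing
  # nothing, the m/z 36 fitted curve equals the monophasic model at k_s
  ks <- glance(fit)$k_s
  m36 <- fit$residuals[fit$residuals$channel == "mz36", ]
  s36 <- tidy(fit)$estimate[tidy(fit)$term == "scale_36"]
  expect_equal(m36$fitted, s36 * mz36_model(m36$t, exchange_params(111, ks)),
               tolerance = 1e-9)
  # free-a fit recovers the generating a on noiseless data
  fit_free <- fit_exchange(noiseless_trace(), wt_enrichment(), s2_protocol(),
                           fix_a = FALSE)
  expect_equal(tidy(fit_free)$estimate[tidy(fit_free)$term == "a"],
               fast_fraction_a(wt_enrichment()), tolerance = 1e-4)
})

test_that("ignoring the inter-flash correction biases the fast phase", {
  # traces simulated WITH S3-dwell exchange, fitted with and without b
  kf_b <- kf_nob <- numeric(20)
  for (s in 1:20) {
    tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(29),
                        noise_sigma = 0.01, seed = 400 + s)
    kf_b[s] <- glance(fit_exchange(tr, wt_enrichment(), s2_protocol(29)))$k_f
    kf_nob[s] <- glance(fit_exchange(tr, wt_enrichment(), s2_protocol(29),
                                     b_override = 1))$k_f
  }
  expect_lt(abs(median(kf_b) / 111 - 1), 0.05)
  # the uncorrected fit systematically overestimates k_f
  expect_gt(median(kf_nob), median(kf_b) * 1.3)
})

test_that("poorly separated rates trigger the degeneracy path", {
  truth <- exchange_params(1.5, 1)
  tr <- simulate_mims(truth, wt_enrichment(), s3_protocol(),
                      noise_sigma = 0.005, seed = 77)
  expect_warning(fit <- fit_exchange(tr, wt_enrichment(), s3_protocol()),
                 "poorly separated")
  expect_true(fit$degenerate)
  expect_false(is.null(fit$monophasic))
  expect_true(fit$monophasic$converged)
  # monophasic comparison lands between the two generating rates
  expect_gt(fit$monophasic$k, 0.8)
  expect_lt(fit$monophasic$k, 2)
})

test_that("fit validates its inputs", {
  short <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                         time_grid = mims_time_grid(n_post = 5))
  expect_error(fit_exchange(short, wt_enrichment(), s2_protocol()), ">= 8")
  expect_error(fit_exchange(noiseless_trace(), wt_enrichment(),
                            flash_protocol("S2")), "k_f_s3")
  expect_error(fit_exchange(noiseless_trace(), wt_enrichment(), s2_protocol(),
                            b_override = 1.5), "b_override")
})

test_that("jackknife SEs are exactly the textbook formula over leave-one-out refits", {
  tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                      time_grid = mims_time_grid(n_post = 30),
                      noise_sigma = 0.01, seed = 55)
  fit <- fit_exchange(tr, wt_enrichment(), s2_protocol())
  jf <- jackknife_errors(fit)
  # brute-force enumeration of the leave-one-out estimates via the same
  # warm-started refit used internally
  n <- length(fit$data$t)
  loo <- vapply(seq_len(n), function(i)
    trmims:::refit_exchange_subset(fit, setdiff(seq_len(n), i))$estimate["k_s"],
    numeric(1))
  se_expected <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  se_reported <- tidy(jf)$std.error[tidy(jf)$term == "k_s"]
  expect_equal(se_reported, se_expected, tolerance = 1e-12)
  expect_identical(unique(tidy(jf)$se_method), "jackknife")
  expect_equal(jf$jackknife$n_replicates, n)
})

test_that("jackknife of a noiseless fit gives (near) zero standard errors", {
  tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                      time_grid = mims_time_grid(n_post = 25))
  fit <- fit_exchange(tr, wt_enrichment(), s2_protocol())
  jf <- jackknife_errors(fit)
  expect_true(all(tidy(jf)$std.error < 1e-5 * abs(tidy(jf)$estimate)))
})

test_that("jackknife refuses unusable bases", {
  tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                      time_grid = mims_time_grid(n_post = 9, n_pre = 0))
  fit <- fit_exchange(tr, wt_enrichment(), s2_protocol())
  expect_error(jackknife_errors(fit), ">= 10")
})
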