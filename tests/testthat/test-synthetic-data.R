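test_that("artifact-free generator collapses to the analytic forward models", {
  truth <- wt_s2_truth()
  tr <- simulate_mims(truth, wt_enrichment(), s2_protocol(),
                      noise_sigma = 0, mixing_tau = 0, residual_o2_step = 0)
  a <- fast_fraction_a(wt_enrichment())
  b <- interflash_b(s2_protocol())
  post <- tr$t >= 0
  expect_identical(tr$mz34[post], mz34_model(tr$t[post], truth, a = a, b = b))
  expect_identical(tr$mz36[post], mz36_model(tr$t[post], truth))
  expect_true(all(tr$mz34[!post] == 0 & tr$mz36[!post] == 0))
})

test_that("identical seeds give bit-identical traces, different seeds differ", {
  args <- list(wt_s2_truth(), wt_enrichment(), s2_protocol(), noise_sigma = 0.01)
  t1 <- do.call(simulate_mims, c(args, seed = 123))
  t2 <- do.call(simulate_mims, c(args, seed = 123))
  t3 <- do.call(simulate_mims, c(args, seed = 124))
  expect_identical(t1$mz34, t2$mz34)
  expect_identical(t1$mz36, t2$mz36)
  expect_false(identical(t1$mz34, t3$mz34))
  # seeding is local: the ambient RNG stream is untouched
  set.seed(99); before <- .Random.seed
  invisible(do.call(simulate_mims, c(args, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("ensemble mean of noisy traces converges to the noiseless kernel", {
  grid <- mims_time_grid(n_post = 30)
  noiseless <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                             time_grid = grid, noise_sigma = 0)
  sigma <- 0.02
  n_rep <- 200
  acc34 <- acc36 <- 0
  for (s in seq_len(n_rep)) {
    tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                        time_grid = grid, noise_sigma = sigma, seed = s)
    acc34 <- acc34 + tr$mz34
    acc36 <- acc36 + tr$mz36
  }
  tol <- 3 * sigma / sqrt(n_rep)
  expect_true(all(abs(acc34 / n_rep - noiseless$mz34) < tol))
  expect_true(all(abs(acc36 / n_rep - noiseless$mz36) < tol))
})

test_that("residual-O2 step and baseline behave as an injection artifact", {
  tr <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                      residual_o2_step = 0.05, noise_sigma = 0)
  twin <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                        residual_o2_step = 0, noise_sigma = 0)
  pre <- tr$t < 0
  expect_true(all(tr$mz34[pre] == 0))                    # baseline unaffected
  expect_equal(tr$mz34[!pre], twin$mz34[!pre] + 0.05)    # constant offset after
  expect_equal(tr$mz36[!pre], twin$mz36[!pre] + 0.05)
  # per-channel amplitudes
  tr2 <- simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                       residual_o2_step = c(0.03, 0.08))
  expect_equal(tr2$mz34[!pre] - twin$mz34[!pre], rep(0.03, sum(!pre)))
  expect_equal(tr2$mz36[!pre] - twin$mz36[!pre], rep(0.08, sum(!pre)))
})

test_that("first-order mixing smooths the enrichment rise correctly", {
  # closed-form kernel vs numerical convolution of the step model with
  # h(s) = exp(-s/tau)/tau
  truth <- exchange_params(20, 0.5)
  tau <- 0.05
  a <- fast_fraction_a(wt_enrichment()); b <- 1
  t_eval <- c(0.01, 0.05, 0.2, 1, 5)
  sim <- simulate_mims(truth, wt_enrichment(), s3_protocol(),
                       time_grid = t_eval, mixing_tau = tau)
  numconv <- vapply(t_eval, function(tt) {
    f <- function(s) mz34_model(tt - s, truth, a = a, b = b) * exp(-s / tau) / tau
    stats::integrate(f, 0, tt, rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(sim$mz34, numconv, tolerance = 1e-7)
  # mixing delays the rise but not the plateau
  step <- simulate_mims(truth, wt_enrichment(), s3_protocol(),
                        time_grid = t_eval, mixing_tau = 0)
  expect_true(all(sim$mz34[1:3] < step$mz34[1:3]))
  expect_equal(sim$mz34[5], step$mz34[5], tolerance = 1e-2)
})

test_that("generator validates its configuration", {
  expect_error(simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                             time_grid = c(0.1, 0.1, 0.2)), "strictly increasing")
  expect_error(simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                             time_grid = c(-2, -1), injection_time = 0),
               "injection")
  expect_error(simulate_mims(wt_s2_truth(), wt_enrichment(), s2_protocol(),
                             noise_sigma = -1), "noise_sigma")
  expect_error(exchange_params(-1, 0.5), "k_f")
  expect_error(exchange_params(1, 0), "k_s")
})

test_that("fluorescence generator evaluates the decay model exactly", {
  p <- wt_fluor_truth()
  tr <- simulate_fluorescence(p, noise_sigma = 0)
  expect_identical(tr$fv_norm, fluor_decay_model(tr$t, p))
  # offset survives at long times
  expect_equal(fluor_decay_model(1e6, p), p$A0, tolerance = 1e-12)
  # value near t = 0 approaches the full amplitude sum
  expect_equal(fluor_decay_model(0, p), p$A0 + p$A1 + p$A2 + p$A3)
  # determinism
  n1 <- simulate_fluorescence(p, noise_sigma = 0.01, seed = 8)
  n2 <- simulate_fluorescence(p, noise_sigma = 0.01, seed = 8)
  expect_identical(n1$fv_norm, n2$fv_norm)
  # unordered time constants rejected at construction
  expect_error(fluor_decay_params(0, 0.1, 0.2, 0.3, 0.5, 0.2, 1), "ordered")
})

test_that("default grids have the documented shape", {
  g <- mims_time_grid()
  expect_equal(sum(g < 0), 10)
  expect_equal(min(g[g > 0]), 0.002, tolerance = 1e-12)
  expect_equal(max(g), 20, tolerance = 1e-12)
  fg <- fluor_time_grid()
  expect_equal(min(fg), 150e-6, tolerance = 1e-12)
  expect_equal(max(fg), 100, tolerance = 1e-12)
  # ~8 points per decade
  expect_equal((length(fg) - 1) / log10(max(fg) / min(fg)), 8, tolerance = 0.1)
})
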