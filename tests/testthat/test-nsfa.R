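test_that("stable-stretch selection matches an exhaustive scan", {
  # [100, 95, 200, 101, 99, 98]: the trailing run of three qualifies
  blk <- make_scaled_block(c(100, 95, 200, 101, 99, 98) / 100)
  expect_equal(select_stable_stretch(blk, 0.10), 4:6)
  # identical peaks: the whole block
  blk2 <- make_scaled_block(rep(1, 5))
  expect_equal(select_stable_stretch(blk2, 0.10), 1:5)
  # zero tolerance with distinct peaks: no qualifying run
  blk3 <- make_scaled_block(c(1, 1.05, 1.1))
  expect_error(select_stable_stretch(blk3, 0), "more data")

  # randomized agreement with a brute-force scan over all contiguous runs
  set.seed(31)
  for (rep in 1:20) {
    peaks <- stats::runif(12, 80, 130)
    blk <- make_scaled_block(peaks / 100)
    got <- select_stable_stretch(blk, 0.10)
    best <- NULL
    for (i in 1:11) for (j in (i + 1):12) {
      pp <- peaks[i:j]
      if (max(pp) / min(pp) <= 1.10 + 1e-12 &&
          (is.null(best) || j - i > best[2] - best[1])) best <- c(i, j)
    }
    if (is.null(best)) {
      expect_error(select_stable_stretch(blk, 0.10))
    } else {
      expect_equal(got, best[1]:best[2])
    }
  }
})

test_that("artifact exclusion flags only the contaminated sweep", {
  blk <- make_scaled_block(rep(1, 10), dt = 1e-3)
  # clean block: nothing excluded
  expect_equal(exclude_artifact_sweeps(blk), 1:10)
  # inject a 50 pA single-sample spike into sweep 4
  blk$sweeps[[4]]$current[200] <- blk$sweeps[[4]]$current[200] + 50
  expect_equal(exclude_artifact_sweeps(blk), setdiff(1:10, 4))
  # disabled filter keeps everything
  expect_equal(exclude_artifact_sweeps(blk, Inf), 1:10)
})

test_that("pairwise variance implements the successive-difference estimator", {
  prot <- application_protocol()
  time <- seq(0, 0.95, by = 1e-3)
  meta <- recording_meta(sample_interval = 1e-3)
  mk <- function(vals) {
    sweep_block(lapply(seq_along(vals), function(k) {
      patch_sweep(time, rep(vals[k], length(time)),
                  protocol_to_stimulus(prot, time), meta, k)
    }), prot)
  }
  # identical sweeps: zero variance
  vt0 <- pairwise_variance(mk(c(3, 3)))
  expect_true(all(vt0$ensemble_variance == 0))
  # constant sweeps at 0 and 2 pA: (2-0)^2/2 = 2 pA^2 everywhere
  vt <- pairwise_variance(mk(c(0, 2)))
  expect_true(all(vt$ensemble_variance == 2))
  expect_equal(attr(vt, "n_pairs"), 1L)
  expect_error(pairwise_variance(mk(c(0, 2)), use = 1L), ">= 2 sweeps")

  # iid Gaussian sweeps: estimator is unbiased for stationary noise
  set.seed(17)
  sigma <- 1.5
  M <- 500
  cur <- matrix(stats::rnorm(length(time) * M, 0, sigma), ncol = M)
  blk <- sweep_block(lapply(1:M, function(k) {
    patch_sweep(time, cur[, k], protocol_to_stimulus(prot, time), meta, k)
  }), prot)
  vt2 <- pairwise_variance(blk)
  vbar <- mean(vt2$ensemble_variance)
  # variance of the pairwise estimator mean over time points (correlated
  # across pairs); generous 3-sigma Monte-Carlo band via per-point spread
  se <- stats::sd(vt2$ensemble_variance) / sqrt(length(time))
  expect_lt(abs(vbar - sigma^2), 3 * se * 3)
})

test_that("pairwise variance is first-order insensitive to linear rundown", {
  prot <- application_protocol()
  time <- seq(0, 0.95, by = 1e-3)
  meta <- recording_meta(sample_interval = 1e-3)
  shape <- -100 * asic_popen(time)
  mk_scaled <- function(eps) {
    sweep_block(lapply(0:2, function(k) {
      patch_sweep(time, shape * (1 + k * eps),
                  protocol_to_stimulus(prot, time), meta, k + 1)
    }), prot)
  }
  # noiseless: scaling sweep k by (1 + k eps) leaves only O(eps^2) variance
  for (eps in c(0.01, 0.005)) {
    vt <- pairwise_variance(mk_scaled(eps))
    v_lin <- max(vt$ensemble_variance)
    expect_lt(v_lin, (max(abs(shape)) * eps)^2)  # bounded by (peak*eps)^2
  }
  # and it scales ~quadratically in eps
  v1 <- max(pairwise_variance(mk_scaled(0.01))$ensemble_variance)
  v2 <- max(pairwise_variance(mk_scaled(0.005))$ensemble_variance)
  expect_equal(v1 / v2, 4, tolerance = 0.01)
})

test_that("baseline variance is measured from the pre-application window", {
  prot <- application_protocol(baseline = 0.1)
  time <- seq(0, 0.95, by = 1e-3)
  meta <- recording_meta(sample_interval = 1e-3)
  # noiseless block: zero
  blk0 <- make_scaled_block(rep(1, 4))
  expect_equal(baseline_variance(blk0), 0)
  expect_error(baseline_variance(blk0, window = 0), "> 0")
  expect_error(baseline_variance(blk0, window = 0.2), "extends into")
  # Gaussian sigma = 2: ~4 pA^2 at 200 sweeps
  set.seed(29)
  blk <- sweep_block(lapply(1:200, function(k) {
    patch_sweep(time, stats::rnorm(length(time), 0, 2),
                protocol_to_stimulus(prot, time), meta, k)
  }), prot)
  expect_equal(baseline_variance(blk), 4, tolerance = 0.15)
})

test_that("current binning covers the decay with ordered non-empty bins", {
  prot <- application_protocol(duration = 0.8, baseline = 0.1)
  time <- seq(0, 0.95, by = 1e-3)
  meta <- recording_meta(sample_interval = 1e-3)
  # monotone noiseless decay into 5 bins: 5 ordered pairs
  decay <- ifelse(time >= 0.1, -100 * exp(-(time - 0.1) / 0.2), 0)
  blk <- sweep_block(lapply(1:3, function(k) {
    patch_sweep(time, decay, protocol_to_stimulus(prot, time), meta, k)
  }), prot)
  vt <- pairwise_variance(blk)
  w <- epoch_index_window(prot$epochs[[1]], time)
  b <- bin_current_variance(vt, w, n_bins = 5)
  expect_equal(nrow(b), 5L)
  expect_true(all(diff(abs(b$binned_current)) > 0))
  # all-zero current: no dynamic range
  blk0 <- sweep_block(lapply(1:3, function(k) {
    patch_sweep(time, numeric(length(time)),
                protocol_to_stimulus(prot, time), meta, k)
  }), prot)
  vt0 <- pairwise_variance(blk0)
  expect_error(bin_current_variance(vt0, w), "dynamic range")
})

test_that("parabola fit inverts exact points and honours the vertex algebra", {
  # exact points from i = 1, N = 100, baseline 0
  i <- 1; N <- 100
  I <- seq(2, 80, length.out = 12)
  V <- i * I - I^2 / N
  binned <- data.frame(binned_current = I, binned_variance = V,
                       n_samples = 1L)
  fit <- fit_current_variance(binned, baseline = 0,
                              meta = recording_meta(holding_potential = -60,
                                                    reversal_potential = 0))
  expect_equal(fit$i_single, 1, tolerance = 1e-10)
  expect_equal(fit$n_channels, 100, tolerance = 1e-8)
  # vertex: max-variance current at iN/2, max variance baseline + i^2 N/4
  vertex_I <- fit$i_single * fit$n_channels / 2
  expect_equal(vertex_I, i * N / 2, tolerance = 1e-8)
  expect_equal(fit$i_single * vertex_I - vertex_I^2 / fit$n_channels,
               i^2 * N / 4, tolerance = 1e-8)
  # negative-going currents keep the sign of i
  fitn <- fit_current_variance(
    data.frame(binned_current = -I, binned_variance = V, n_samples = 1L),
    baseline = 0, meta = recording_meta())
  expect_equal(fitn$i_single, -1, tolerance = 1e-10)
  # low-confidence flag when P_open stays below 0.5 (rising limb only)
  I2 <- seq(2, 40, length.out = 8)
  fit2 <- fit_current_variance(
    data.frame(binned_current = I2, binned_variance = i * I2 - I2^2 / N,
               n_samples = 1L), baseline = 0, meta = recording_meta())
  expect_true(fit2$low_confidence)
  expect_false(fit$low_confidence)
})

test_that("conductance conversion follows g = 1000 i / (Vh - Erev)", {
  binned <- data.frame(binned_current = -seq(2, 50, length.out = 8),
                       binned_variance = NA, n_samples = 1L)
  binned$binned_variance <- -0.6 * binned$binned_current -
    binned$binned_current^2 / 100
  fit <- fit_current_variance(binned, 0,
                              recording_meta(holding_potential = -60,
                                             reversal_potential = 0))
  expect_equal(fit$conductance_pS, 10, tolerance = 1e-8)
})

test_that("full pipeline recovers generator truth near the reported regime", {
  # p_peak 0.86, g 10 pS at -60 mV (i = -0.6 pA), N = 100, 70 sweeps
  time <- seq(0, 1.0, by = 1e-4)
  prot <- application_protocol(duration = 0.8, baseline = 0.1)
  p <- asic_popen(time)
  spec <- ensemble_spec(popen = p, n_channels = 100,
                        single_channel_current = -0.6)
  blk <- generate_nsfa_block(spec, prot, n_sweeps = 70,
                             noise = noise_model(0.3), seed = 42,
                             time = time,
                             meta = recording_meta(reversal_potential = 0))
  res <- nsfa(blk)
  expect_lt(abs(res$peak_open_probability - 0.86), 0.05)
  expect_lt(abs(res$conductance_pS - 10) / 10, 0.15)
})

test_that("parameter recovery holds across the N x p x i grid", {
  # median relative error on N below 15%, absolute error on p below 0.05
  time <- seq(0, 0.7, by = 2e-4)
  prot <- application_protocol(duration = 0.5, baseline = 0.1)
  errs_N <- c(); errs_p <- c()
  for (N in c(50, 100, 500)) {
    for (p_pk in c(0.3, 0.6, 0.86)) {
      for (i_sc in c(0.5, 1)) {
        p <- asic_popen(time, p_peak = p_pk, tau_des = 0.12)
        spec <- ensemble_spec(popen = p, n_channels = N,
                              single_channel_current = -i_sc)
        blk <- generate_nsfa_block(spec, prot, n_sweeps = 200,
                                   noise = noise_model(0.2),
                                   seed = derive_seed(1000, sprintf("g%d-%g-%g", N, p_pk, i_sc)),
                                   time = time)
        res <- tryCatch(nsfa(blk), error = function(e) NULL)
        if (is.null(res)) { errs_N <- c(errs_N, Inf); errs_p <- c(errs_p, Inf); next }
        errs_N <- c(errs_N, abs(res$n_channels / N - 1))
        errs_p <- c(errs_p, abs(res$peak_open_probability - p_pk))
      }
    }
  }
  expect_lte(stats::median(errs_N), 0.15)
  expect_lte(stats::median(errs_p), 0.05)
})
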