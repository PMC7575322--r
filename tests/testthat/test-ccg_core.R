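test_that("single spike pairs land in the correct half-open lag bin", {
  pre <- spike_train("p", "a", "pyramidal", 1.0)
  post <- spike_train("i", "a", "interneuron", 1.0015)
  cg <- compute_ccg(pre, post, c(0, 10))
  expect_equal(cg$raw[cg$lag_ms == 2], 1L)    # lag 1.5 ms is in [1.5, 2.5)
  expect_equal(sum(cg$raw), 1L)
  expect_equal(cg$n_ref, 1L)
  expect_equal(sum(cg$prob), 1)
})

test_that("identical spike times count fully for distinct cells, never as self-pairs", {
  t <- sort(runif(50, 0, 60))
  a <- spike_train("A", "x", "pyramidal", t)
  b <- spike_train("B", "x", "interneuron", t)
  cg <- compute_ccg(a, b, c(0, 60))
  expect_equal(cg$raw[cg$lag_ms == 0], 50L)
  cg_self <- compute_ccg(a, a, c(0, 60))
  # autocorrelogram: own-spike pairings removed from the zero-lag bin
  expect_equal(cg_self$raw[cg_self$lag_ms == 0], 0L)
})

test_that("CCG counts equal the all-pairs brute force on random trains", {
  set.seed(31)
  for (rep in 1:3) {
    a <- poisson_train(8, 0, 500, "p", type = "pyramidal")
    b <- poisson_train(10, 0, 500, "i", type = "interneuron")
    cg <- compute_ccg(a, b, c(0, 500))
    expect_identical(cg$raw, brute_ccg_counts(a$spikes, b$spikes))
  }
})

test_that("reversing the pair reverses the correlogram (antisymmetry)", {
  set.seed(37)
  for (rep in 1:3) {
    a <- poisson_train(5, 0, 300, "p"); b <- poisson_train(12, 0, 300, "i")
    expect_identical(compute_ccg(a, b, c(0, 300))$raw,
                     rev(compute_ccg(b, a, c(0, 300))$raw))
  }
})

test_that("missing reference spikes signal a missing CCG", {
  a <- spike_train("p", "x", "pyramidal", numeric())
  b <- spike_train("i", "x", "interneuron", c(1, 2))
  expect_null(compute_ccg(a, b, c(0, 10)))
  expect_true(is.na(transmission_probability(NULL)))
  expect_false(detect_monosynaptic(NULL)$significant)
})

test_that("chance level is the mean flank probability", {
  cg <- make_ccg(rep(7L, 101), n_ref = 100L)
  expect_equal(chance_level(cg), 0.07)        # uniform histogram
  cg0 <- make_ccg(c(rep(0L, 45), rep(3L, 11), rep(0L, 45)), n_ref = 10L)
  expect_equal(chance_level(cg0), 0)          # empty flanks

  # independent Poisson pair: chance ~ r_post * bin width
  set.seed(41)
  ch <- vapply(1:10, function(i) {
    a <- poisson_train(1, 0, 1500, "p"); b <- poisson_train(15, 0, 1500, "i")
    chance_level(compute_ccg(a, b, c(0, 1500)))
  }, numeric(1))
  expect_equal(mean(ch), 15 * 0.001, tolerance = 0.02)
})

test_that("flat histograms are never declared monosynaptic", {
  flat <- make_ccg(rep(5L, 101), n_ref = 100L)
  det <- detect_monosynaptic(flat)
  expect_false(det$significant)               # zero flank SD -> undefined
  expect_false(det$defined)
})

test_that("planted connections are detected and null pairs are not", {
  pr <- sim_pair(p_trans = 0.05, seed = 7)
  cg <- compute_ccg(pr$pre, pr$post, pr$interval)
  det <- detect_monosynaptic(cg)
  expect_true(det$significant)
  expect_gt(det$peak_z, 3)

  null_fp <- vapply(1:20, function(s) {
    pr <- sim_pair(p_trans = 0, seed = 300 + s)
    detect_monosynaptic(compute_ccg(pr$pre, pr$post, pr$interval))$significant
  }, logical(1))
  expect_lte(mean(null_fp), 0.05)
})

test_that("transmission probability is ~1 for a perfect relay and ~0 for independence", {
  cfg <- sim_config(n_animals = 1, n_pyr = 1, n_int = 1,
                    pyr_rate_meanlog = log(1), pyr_rate_sdlog = 0,
                    int_rate_meanlog = log(1e-12), int_rate_sdlog = 0,
                    connections = data.frame(animal = 1, pre = 1, post = 1,
                                             p_FAM1 = 1, p_NOV = 0, p_FAML = 0,
                                             p_FAM2 = 0, p_REST = 0),
                    session_lengths_s = c(FAM1 = 1500), animal_rate_sd = 0,
                    seed = 47)
  sm <- simulate_dataset(cfg)
  tp <- transmission_probability(
    compute_ccg(sm$trains$a01_pyr01, sm$trains$a01_int01,
                session_interval(sm$sessions, "FAM1")))
  expect_equal(tp, 1.0, tolerance = 0.01)

  est <- vapply(1:10, function(s) {
    pr <- sim_pair(p_trans = 0, seed = 500 + s)
    transmission_probability(compute_ccg(pr$pre, pr$post, pr$interval))
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.004)
})

test_that("chance subtraction makes the transmission statistic rate-invariant", {
  set.seed(53)
  est_lo <- est_hi <- numeric(8)
  for (s in 1:8) {
    est_lo[s] <- transmission_probability(compute_ccg(
      poisson_train(1, 0, 1500, "p"), poisson_train(15, 0, 1500, "i"), c(0, 1500)))
    est_hi[s] <- transmission_probability(compute_ccg(
      poisson_train(4, 0, 1500, "p"), poisson_train(60, 0, 1500, "i"), c(0, 1500)))
  }
  expect_lt(abs(mean(est_lo)), 0.005)
  expect_lt(abs(mean(est_hi)), 0.005)         # 4x both rates: still mean-zero
})

test_that("quality filters enforce the count and dispersion thresholds", {
  low1 <- make_ccg(rep(9L, 101), n_ref = 1000L)     # total 909 < 1000
  low2 <- make_ccg(rep(7L, 101), n_ref = 1000L)     # total 707 < 1000
  qf <- apply_quality_filters(low1, low2)
  expect_false(qf$passes)
  expect_equal(qf$reasons, "min_counts")

  ok <- make_ccg(rep(10L, 101), n_ref = 1000L)      # total 1010, flat flanks
  qf2 <- apply_quality_filters(ok, NULL)
  expect_true(qf2$passes)

  # dispersed flanks: SD/mean ~ 1 in both sessions
  disp <- make_ccg(as.integer(rep(c(0L, 40L), length.out = 101)), n_ref = 1000L)
  qf3 <- apply_quality_filters(disp, disp)
  expect_false(qf3$passes)
  expect_equal(qf3$reasons, "dispersion")
})

test_that("the 1000-count boundary is exact", {
  exact <- make_ccg(as.integer(c(rep(10L, 100), 0L)), n_ref = 1000L)  # total 1000
  expect_true(apply_quality_filters(exact, NULL)$passes)
  under <- make_ccg(as.integer(c(rep(10L, 99), 9L, 0L)), n_ref = 1000L)  # 999
  expect_false(apply_quality_filters(under, NULL)$passes)
})

test_that("light-response PSTH classifies suppression, activation and silence correctly", {
  set.seed(61)
  pulses <- make_rest_pulses(c(0, 1080), 0.5, 3)
  # constant-rate cell: unmodulated, bins ~ rate * bin width
  cell <- poisson_train(20, 0, 1080, "c")
  ps <- light_response_psth(cell, pulses)
  expect_equal(ps$class, "unmodulated")
  expect_equal(mean(ps$prob), 20 * 0.02, tolerance = 0.05)

  cfg <- sim_config(n_animals = 1, n_pyr = 4, n_int = 4,
                    int_rate_meanlog = log(15), int_rate_sdlog = 0,
                    pyr_rate_meanlog = log(2), pyr_rate_sdlog = 0,
                    session_lengths_s = c(REST = 1080),
                    faml_light = list(fraction_suppressed_pyr = 0,
                                      fraction_suppressed_int = 1,
                                      fraction_disinhibited_pyr = 1,
                                      suppression_factor = 0.1,
                                      enhancement_factor = 2.5,
                                      epoch_s = 10, duty = 0.4),
                    animal_rate_sd = 0, seed = 67)
  sm <- simulate_dataset(cfg)
  pulses <- sm$sessions$light_intervals
  cells <- sm$truth$cells
  for (i in seq_len(nrow(cells))) {
    ps <- light_response_psth(sm$trains[[cells$cell_id[i]]], pulses)
    expected <- switch(cells$light_class[i], suppressed = "suppressed",
                       disinhibited = "activated", "unmodulated")
    expect_equal(ps$class, expected, label = cells$cell_id[i])
  }
  expect_error(light_response_psth(cell, data.frame(start_s = numeric(),
                                                    end_s = numeric())),
               "pulse")
})
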