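test_that("temporal averaging reproduces closed-form means and respects trace bounds", {
  times <- 0:200
  const <- matrix(0.7, nrow = length(times), ncol = 1)
  alt <- matrix(rep(c(0, 1), length.out = length(times)), ncol = 1)
  sine <- matrix(0.5 + 0.3 * sin(2 * pi * times / 20), ncol = 1)
  rec <- make_record(times, cbind(const, alt, sine))
  av <- temporal_average(rec, 0, 200)
  smc <- av[av$type == "smc", ]
  expect_equal(smc$mean_value[1], 0.7, tolerance = 1e-12)
  # alternating 0/1 over an even number of samples within a window
  av2 <- temporal_average(rec, 0, 199)
  expect_equal(av2$mean_value[av2$type == "smc"][2], 0.5, tolerance = 1e-12)
  # sinusoid over 10 full periods
  expect_equal(smc$mean_value[3], 0.5, tolerance = 0.01)
  # invariant: min <= mean <= max
  expect_true(all(smc$mean_value >= c(0.7, 0, 0.2) - 1e-12))
  expect_true(all(smc$mean_value <= c(0.7, 1, 0.8) + 1e-12))
  expect_error(temporal_average(rec, 100, 100), "t_i < t_f")
  expect_error(temporal_average(rec, 300, 400), "no recorded samples")
})

test_that("the kinase rate saturates in calcium with half-activation at K_a", {
  p <- phospho_params()
  expect_equal(kinase_rate(0, p), 0)
  expect_equal(kinase_rate(p$K_a, p), p$V_MK / 2, tolerance = 1e-12)
  expect_equal(kinase_rate(1e9, p), p$V_MK, tolerance = 1e-6)
  expect_error(kinase_rate(-1, p), "non-negative")
})

test_that("the phosphorylation cycle has the stated rate law, boundary behavior and steady states", {
  p <- phospho_params()
  expect_equal(phospho_rate(0, 0, p), 0)
  expect_gt(phospho_rate(0, 1, p), 0)
  expect_lt(phospho_rate(1, 1, p), 0)
  expect_error(phospho_rate(1.5, 1, p), "0, 1")
  # steady state: the root-finding oracle and long integration agree
  for (vk in c(0.5, 1.5, 3)) {
    w_star <- phospho_steady_state(vk, p)
    expect_equal(phospho_rate(w_star, vk, p), 0, tolerance = 1e-8)
    tr <- simulate_phospho(tibble::tibble(time = c(0, 500),
                                          value = rep(p$K_a * vk / (p$V_MK - vk), 2)),
                           p, W0 = 0.3, times = seq(0, 500, 1))
    expect_equal(tail(tr$W_star, 1), w_star, tolerance = 1e-3)
  }
})

test_that("the zero-order regime is an ultrasensitive switch crossing one half at balanced rates", {
  p <- phospho_params(K_1 = 0.01, K_2 = 0.01)
  ratios <- seq(0.5, 1.5, by = 0.05)
  w <- phospho_steady_state(ratios * p$v_p, p)
  expect_true(all(diff(w) > 0))
  expect_equal(phospho_steady_state(p$v_p, p), 0.5, tolerance = 1e-6)
  expect_lt(w[1], 0.05)
  expect_gt(w[length(w)], 0.95)
  # steeper than the non-zero-order cycle
  p1 <- phospho_params(K_1 = 1, K_2 = 1)
  w1 <- phospho_steady_state(ratios * p1$v_p, p1)
  expect_gt(max(diff(w)), 2 * max(diff(w1)))
})

test_that("W* stays within the unit interval and tracks slow calcium quasi-statically", {
  p <- phospho_params()
  times <- seq(0, 400, 0.5)
  ca <- 0.45 + 0.3 * sin(2 * pi * times / 100)       # slow drive
  tr <- simulate_phospho(ca, p, W0 = 0, times = times)
  expect_true(all(tr$W_star >= 0 & tr$W_star <= 1))
  qs <- phospho_steady_state(kinase_rate(ca[times > 100], p), p)
  expect_lt(mean(abs(tr$W_star[times > 100] - qs)), 0.1)
  # zero calcium decays to the kinase-free fixed point
  tr0 <- simulate_phospho(rep(0, 101), p, W0 = 0.8, times = 0:100)
  expect_lt(tail(tr0$W_star, 1), 0.01)
})

test_that("the mean phosphorylated fraction increases with calcium spike frequency", {
  p <- phospho_params()
  spike_train <- function(period, times) {
    phase <- times %% period
    0.2 + 0.6 * exp(-((phase - 2)^2) / 2)     # fixed spike shape, ~0.8 peak
  }
  times <- seq(0, 400, 0.25)
  wbar <- vapply(c(80, 40, 20, 10), function(per) {
    tr <- simulate_phospho(spike_train(per, times), p, W0 = 0, times = times)
    time_average_W(tr, 50, 400)
  }, numeric(1))
  expect_true(all(diff(wbar) > 0))
})

test_that("time averaging of W* handles constants and square waves exactly", {
  tr <- tibble::tibble(time = 0:100, W_star = rep(0.37, 101))
  expect_equal(time_average_W(tr), 0.37, tolerance = 1e-12)
  sq <- tibble::tibble(time = seq(0, 99.5, 0.5),
                       W_star = rep(c(1, 1, 0, 0), length.out = 200))
  expect_equal(time_average_W(sq), 0.5, tolerance = 0.02)
  expect_error(time_average_W(tr, 50, 50.2), "fewer than 2")
})

test_that("oscillation metrics recover known periods and flag flat traces", {
  times <- seq(0, 300, 1)
  sine20 <- 0.5 + 0.3 * sin(2 * pi * times / 20)
  flat <- rep(0.3, length(times))
  two <- 0.5 + 0.3 * sin(2 * pi * times / 20) + 0.05 * sin(2 * pi * times / 7)
  rec <- make_record(times, cbind(sine20, flat, two))
  m <- oscillation_metrics(rec, "smc", min_prominence = 0.1)
  expect_true(m$oscillatory[1])
  expect_equal(m$period[1], 20, tolerance = 0.5 / 20)
  expect_false(m$oscillatory[2])
  expect_equal(m$amplitude[2], 0)
  expect_equal(m$period[3], 20, tolerance = 1 / 20)   # dominant component wins
  expect_equal(m$amplitude[1], 0.55, tolerance = 0.1) # peak minus low baseline
})

test_that("wave-front speed is recovered from traveling pulses and standing waves are flagged", {
  times <- seq(0, 100, 0.5)
  n <- 30
  v_true <- 2                                  # cells per second
  pulse <- function(delay) 0.2 + 0.7 / (1 + exp(-(times - delay) / 0.8))
  mat <- vapply(seq_len(n), function(j) pulse(10 + (j - 1) / v_true),
                numeric(length(times)))
  rec <- make_record(times, mat)
  ws <- wave_front_speed(rec, path = seq_len(n), type = "smc",
                         spacing_mm = 0.05)
  expect_false(ws$flagged)
  expect_equal(ws$speed_cells_per_s, v_true, tolerance = 0.05)
  expect_equal(ws$speed_mm_per_s, v_true * 0.05, tolerance = 0.05)
  # additive noise at SNR ~ 10 still recovers the speed within 10 percent
  set.seed(1)
  noisy <- mat + matrix(rnorm(length(mat), sd = 0.07), nrow = nrow(mat))
  ws_n <- wave_front_speed(make_record(times, pmax(noisy, 0)),
                           path = seq_len(n), type = "smc", spacing_mm = 0.05)
  expect_equal(ws_n$speed_cells_per_s, v_true, tolerance = 0.1)
  # in-phase oscillation has no resolvable front
  standing <- vapply(seq_len(n), function(j) 0.5 + 0.4 * sin(times / 5),
                     numeric(length(times)))
  ws_s <- wave_front_speed(make_record(times, standing), path = seq_len(n),
                           type = "smc", spacing_mm = 0.05)
  expect_true(ws_s$flagged)
})
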