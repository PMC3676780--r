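test_that("right-hand side matches the governing equations", {
  p <- cartoon_params(tau_e = 0.1, tau_a = 10)
  # rest point
  expect_equal(cartoon_rhs(c(0, 0), 0, p), c(0, 0))
  # direct substitution
  expect_equal(cartoon_rhs(c(0, 0), 1, p), c(10, 0.1))
  # adapted state is stationary for any constant stimulus
  for (s0 in c(0.3, 1, 7)) {
    expect_equal(cartoon_rhs(c(0, s0), s0, p), c(0, 0))
  }
  expect_error(cartoon_rhs(c(NaN, 0), 1, p), "finite")
  expect_error(cartoon_rhs(c(0, 0), Inf, p), "finite")
})

test_that("parameter and protocol validation rejects bad inputs", {
  expect_error(cartoon_params(-0.1, 10), "> 0")
  expect_error(cartoon_params(0.1, 10, f = function(s) s + 1), "f\\(0\\)")
  expect_error(stimulus_protocol(c(0, 1), c(2, 3), c(1, 1)), "overlap")
  expect_error(stimulus_protocol(0, 1, -1), ">= 0")
  p <- cartoon_params(0.1, 10)
  expect_error(integrate_cartoon(p, stimulus_protocol(0, Inf, 1), dt = 2, t_end = 1),
               "dt")
  expect_error(analytic_step_response(cartoon_params(1, 1.0000000001), 1, 1),
               "confluent")
})

test_that("zero stimulus from rest stays identically at rest", {
  p <- cartoon_params(0.1, 10)
  tr <- integrate_cartoon(p, stimulus_protocol(5, 6, 0), dt = 0.01, t_end = 2)
  expect_true(all(tr$u1 == 0) && all(tr$u2 == 0))
})

test_that("exponential-update integrator matches the closed form to 1e-10", {
  for (prm in list(c(0.1, 10), c(0.01, 2), c(0.5, 5))) {
    p <- cartoon_params(prm[1], prm[2])
    tr <- integrate_cartoon(p, stimulus_protocol(0, Inf, 1.7),
                            dt = 0.01, t_end = 5)
    ana <- analytic_step_response(p, 1.7, tr$t)
    expect_lt(max(abs(tr$u1 - ana$u1)) / max(abs(ana$u1)), 1e-10)
    expect_lt(max(abs(tr$u2 - ana$u2)) / max(abs(ana$u2)), 1e-10)
  }
})

test_that("step-response peak agrees with the closed-form argmax", {
  p <- cartoon_params(0.1, 10)
  pk <- cartoon_step_peak(0.1, 10)
  tr <- integrate_cartoon(p, stimulus_protocol(0, Inf, 1), dt = 1e-3, t_end = 3)
  expect_equal(max(tr$u1), pk$u1, tolerance = 1e-5)
  expect_equal(tr$t[which.max(tr$u1)], pk$t, tolerance = 1e-2)
  # for these time constants the peak is ~0.95 near t ~ 0.47 s
  expect_equal(pk$u1, 0.954, tolerance = 1e-2)
  expect_equal(pk$t, 0.465, tolerance = 1e-2)
})

test_that("the system adapts perfectly to any constant stimulus", {
  p <- cartoon_params(0.05, 2)
  for (s0 in c(0.5, 1, 10)) {
    tr <- integrate_cartoon(p, stimulus_protocol(0, Inf, s0),
                            dt = 0.01, t_end = 20 * p$tau_a)
    # residual scales with the drive: u1(20 tau_a) ~ f(S0) e^-20
    expect_lt(abs(tr$u1[nrow(tr)]) / s0, 1e-8)
    expect_equal(tr$u2[nrow(tr)], s0, tolerance = 1e-4)
  }
  # also from a non-rest initial condition
  tr <- integrate_cartoon(p, stimulus_protocol(0, Inf, 1), dt = 0.01,
                          t_end = 20 * p$tau_a, state0 = c(0.7, -0.2))
  expect_lt(abs(tr$u1[nrow(tr)]), 1e-8)
})

test_that("response is linear in the stimulus for identity transduction", {
  p <- cartoon_params(0.1, 10)
  tr1 <- integrate_cartoon(p, stimulus_protocol(0, Inf, 1), dt = 0.01, t_end = 3)
  tr3 <- integrate_cartoon(p, stimulus_protocol(0, Inf, 3), dt = 0.01, t_end = 3)
  expect_equal(tr3$u1, 3 * tr1$u1, tolerance = 1e-12)
  # graded response: peak continuous and monotone in amplitude
  peaks <- sapply(seq(0.2, 2, by = 0.2), function(s) {
    max(integrate_cartoon(p, stimulus_protocol(0, Inf, s),
                          dt = 0.01, t_end = 3)$u1)
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("a pulse of duration tau_e peaks near 2/3 of its amplitude", {
  p <- cartoon_params(0.01, 10)
  pk <- pulse_response_peak(p, 1)
  expect_equal(pk, 1 - exp(-1), tolerance = 0.01)
  expect_identical(pulse_response_peak(p, 0), 0)
  # linear scaling of the pulse response
  p2 <- cartoon_params(0.001, 1)
  expect_equal(pulse_response_peak(p2, 2), 2 * pulse_response_peak(p2, 1),
               tolerance = 1e-10)
  expect_warning(pulse_response_peak(cartoon_params(0.5, 10), 1), "tau_a/tau_e")
})

test_that("well-separated equal steps give equal peaks after re-adaptation", {
  p <- cartoon_params(0.1, 10)
  gap <- 200  # 20 adaptation times between steps
  proto <- stimulus_protocol(c(0, gap), c(gap, Inf), c(1, 2))
  tr <- integrate_cartoon(p, proto, dt = 0.01, t_end = 2 * gap)
  pk1 <- max(tr$u1[tr$t < gap])
  pk2 <- max(tr$u1[tr$t >= gap])
  expect_equal(pk2, pk1, tolerance = 1e-6)
})

test_that("ramp segments integrate correctly (RK4 vs staircase limit)", {
  p <- cartoon_params(0.1, 2)
  ramp <- stimulus_protocol(0, 5, 0, slope = 0.4)
  tr <- integrate_cartoon(p, ramp, dt = 0.005, t_end = 5)
  # staircase approximation with very fine piecewise-constant segments
  nseg <- 4000
  edges <- seq(0, 5, length.out = nseg + 1)
  stair <- stimulus_protocol(edges[-(nseg + 1)], edges[-1],
                             0.4 * (edges[-(nseg + 1)] + edges[-1]) / 2)
  ts <- integrate_cartoon(p, stair, dt = 0.005, t_end = 5)
  expect_lt(max(abs(tr$u1 - ts$u1)), 1e-5)
})
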