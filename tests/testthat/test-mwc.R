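test_that("free-energy levels reproduce the ladder by direct substitution", {
  tp <- trimer_params(E_on = 0, E_off = 0, Kd_on = rep(1, 3), Kd_off = rep(1, 3))
  lev <- free_energy_levels(tp, L = 1)
  on1 <- lev$energy[lev$state == "on" & lev$n_bound == 1]
  expect_equal(on1, -log(3))
  on3 <- lev$energy[lev$state == "on" & lev$n_bound == 3]
  expect_equal(on3, 0)  # L^3/(1*1*1) = 1
  expect_error(free_energy_levels(tp, -1), ">= 0")
})

test_that("ligand-free levels are finite and bound levels carry zero weight at L = 0", {
  tp <- random_trimer_seeded <- { set.seed(11); random_trimer() }
  lev <- free_energy_levels(tp, L = 0)
  free <- lev$n_bound == 0
  expect_equal(lev$energy[free], c(tp$E_on, tp$E_off))
  expect_true(all(lev$weight[!free] == 0))
})

test_that("level weights reproduce the 3,3,1 degeneracies of a three-site polynomial", {
  set.seed(21)
  for (i in 1:10) {
    k <- 10^stats::runif(1, -2, 1)
    E0 <- stats::runif(1, -4, 4)
    L <- 10^stats::runif(1, -2, 1)
    tp <- trimer_params(E_on = E0, E_off = 0, Kd_on = rep(k, 3), Kd_off = rep(1, 3))
    lev <- free_energy_levels(tp, L)
    w_pkg <- lev$weight[lev$state == "on"][order(lev$n_bound[lev$state == "on"])]
    w_enum <- microstate_class_weights(E0, k, L)
    expect_equal(unname(w_pkg), unname(w_enum), tolerance = 1e-12)
  }
})

test_that("delta_f has the stated limits and crossing point", {
  tp <- trimer_params(E_on = -2, E_off = 1, Kd_on = rep(0.5, 3),
                      Kd_off = rep(0.02, 3))
  expect_equal(delta_f(tp, 0), -3)
  # identical on/off Kds: polynomial ratio is 1 for every L
  eq <- trimer_params(E_on = -2, E_off = 1, Kd_on = rep(0.1, 3),
                      Kd_off = rep(0.1, 3))
  expect_equal(delta_f(eq, c(0, 0.01, 1, 100)), rep(-3, 4))
  # zero crossing against a root-finding oracle on the defining equation
  tp6 <- trimer_params(E_on = -6, E_off = 0, Kd_on = rep(0.5, 3),
                       Kd_off = rep(0.02, 3))
  root <- stats::uniroot(function(L) (1 + L / 0.02)^3 / (1 + L / 0.5)^3 - exp(6),
                         c(1e-4, 10), tol = 1e-12)$root
  Lc <- stats::uniroot(function(L) delta_f(tp6, L), c(1e-4, 10), tol = 1e-12)$root
  expect_equal(Lc, root, tolerance = 1e-8)
  # stability at extreme concentrations
  expect_true(is.finite(delta_f(tp6, 1e12)))
})

test_that("trimer activity equals the Boltzmann partition sum over all levels", {
  set.seed(42)
  for (i in 1:30) {
    tp <- random_trimer()
    L <- 10^stats::runif(1, -3, 2)
    expect_equal(p_on_trimer(tp, L), p_on_partition_sum(tp, L),
                 tolerance = 1e-12)
  }
  # spot values
  expect_equal(p_on_trimer(trimer_params(0, 0, rep(1, 3), rep(1, 3)), 1), 0.5)
  tp0 <- trimer_params(-2, 0, rep(1, 3), rep(1, 3))
  expect_equal(p_on_trimer(tp0, 0), 1 / (1 + exp(-2)))
})

test_that("cluster activity composes trimer free energies linearly", {
  tp <- trimer_params(E_on = -6, E_off = 0, Kd_on = rep(0.5, 3),
                      Kd_off = rep(0.02, 3))
  L <- c(0, 0.05, 0.2, 1)
  expect_equal(p_on_cluster(1, tp, L), p_on_trimer(tp, L))
  # direct substitution at delta_f = 0.5 (engineered via E_on at L = 0)
  tp5 <- trimer_params(E_on = 0.5, E_off = 0, Kd_on = rep(1, 3), Kd_off = rep(1, 3))
  expect_equal(p_on_cluster(6, tp5, 0), 1 / (1 + exp(3)))
  # large n sharpens the response toward an indicator of sign(delta_f)
  expect_lt(p_on_cluster(500, tp5, 0), 1e-50)
  # monotone in n toward the limit
  pn <- sapply(1:8, function(n) p_on_cluster(n, tp5, 0))
  expect_true(all(diff(pn) < 0))
  expect_error(p_on_cluster(0, tp, 1), "integer")
})

test_that("mixed clusters reduce, swap and order as expected", {
  tar <- default_trimer_params("Tar")
  tsr <- default_trimer_params("Tsr")
  L <- 10^seq(-3, 1, length.out = 30)
  # degenerate composition reduces to the pure-type cluster
  pure <- cluster_spec(3, 0, tar = tar, tsr = tsr)
  expect_equal(p_on_mixed(pure, L, "Tar"), p_on_cluster(3, tar, L))
  # symmetric parameters: swapping (n_a, n_s) together with the ligand
  # target leaves the response invariant
  sym <- cluster_spec(2, 5, tar = tar, tsr = tar)
  sym2 <- cluster_spec(5, 2, tar = tar, tsr = tar)
  expect_equal(p_on_mixed(sym, L, "Tar"), p_on_mixed(sym2, L, "Tsr"))
  # response amplitude grows with the ligand-binding (Tar) count while the
  # non-target type contributes a constant offset
  amps <- sapply(c(1, 2, 6), function(na) {
    pr <- p_on_mixed(cluster_spec(na, 6, tar = tar, tsr = tsr), L, "Tar")
    max(pr) - min(pr)
  })
  expect_true(all(diff(amps) > 0))
  expect_error(p_on_mixed(pure, L, "Trg"), "arg")
  expect_error(cluster_spec(0, 0), "at least one")
})

test_that("dose-response curves are monotone, bounded and grid-faithful", {
  tp <- trimer_params(E_on = -6, E_off = 0, Kd_on = rep(0.5, 3),
                      Kd_off = rep(0.02, 3))
  L <- 10^seq(-4, 2, length.out = 60)
  dr <- dose_response(tp, L, n = 6)
  expect_true(all(dr$p_on > 0 & dr$p_on < 1))
  expect_true(all(diff(dr$p_on) <= 0))  # attractant convention: decreasing
  expect_equal(dr$p_on[1], p_on_cluster(6, tp, L[1]))
  expect_equal(dr$p_on[60], p_on_cluster(6, tp, L[60]))
  # far below Kd_off the curve is flat at the ligand-free activity
  Llow <- 10^seq(-7, -5, length.out = 20)
  drl <- dose_response(tp, Llow, n = 6)
  expect_equal(drl$p_on, rep(p_on_cluster(6, tp, 0), 20), tolerance = 1e-3)
  # reversed Kd ordering gives a non-decreasing (repellent-like) curve
  rp <- trimer_params(E_on = 2, E_off = 0, Kd_on = rep(0.02, 3),
                      Kd_off = rep(0.5, 3))
  expect_true(all(diff(dose_response(rp, L)$p_on) >= 0))
  expect_error(dose_response(tp, numeric(0)), "empty")
  expect_error(dose_response(tp, c(1, 0.5)), "increasing")
})
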