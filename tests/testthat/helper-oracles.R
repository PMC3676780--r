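# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths: partition sums are written out term by term and
# microstates are enumerated explicitly.

# Draw a random but well-behaved trimer parameter set.
random_trimer <- function() {
  trimer_params(
    E_on = stats::runif(1, -8, 2),
    E_off = stats::runif(1, -1, 1),
    Kd_on = 10^stats::runif(3, -2, 1),
    Kd_off = 10^stats::runif(3, -3, 0.5)
  )
}

# Brute-force Boltzmann activity from the eight free-energy levels,
# written directly from the level table (degeneracies 3, 3, 1 inside the
# binding terms).
p_on_partition_sum <- function(tp, L) {
  w <- function(E0, Kd) {
    c(exp(-E0),
      exp(-E0) * 3 * L / Kd[1],
      exp(-E0) * 3 * L^2 / (Kd[1] * Kd[2]),
      exp(-E0) * L^3 / (Kd[1] * Kd[2] * Kd[3]))
  }
  won <- w(tp$E_on, tp$Kd_on)
  woff <- w(tp$E_off, tp$Kd_off)
  sum(won) / (sum(won) + sum(woff))
}

# Enumerate the 2^3 site-occupancy microstates of one conformational state
# with identical intrinsic per-site dissociation constant k: the class
# weights must reproduce the 3, 3, 1 degeneracy ladder.
microstate_class_weights <- function(E0, k, L) {
  occ <- expand.grid(s1 = 0:1, s2 = 0:1, s3 = 0:1)
  wt <- exp(-E0) * (L / k)^(occ$s1 + occ$s2 + occ$s3)
  as.numeric(tapply(wt, occ$s1 + occ$s2 + occ$s3, sum))
}

# Exact step-response peak of the excitation-adaptation system from the
# closed form: argmax and value of u1(t) for a unit step.
cartoon_step_peak <- function(tau_e, tau_a, s0 = 1) {
  t_star <- log(tau_a / tau_e) / (1 / tau_e - 1 / tau_a)
  u1 <- s0 * tau_a / (tau_a - tau_e) *
    (exp(-t_star / tau_a) - exp(-t_star / tau_e))
  list(t = t_star, u1 = u1)
}
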