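# Internal helpers shared across modules.

# log(sum(exp(x))), stable against overflow; x may contain -Inf.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid("%s must be finite", what)
  invisible(x)
}

check_positive <- function(x, what) {
  check_finite(x, what)
  if (any(x <= 0)) stop_invalid("%s must be > 0", what)
  invisible(x)
}

# Exact update of the linear excitation-adaptation system over a step of
# length dt with the drive f(S) held constant:
#   du1/dt = (fS - u1 - u2)/tau_e,   du2/dt = (fS - u2)/tau_a.
# Vectorised over (u1, u2, fS).  Near-confluent time constants fall back to
# the t * exp(-t/tau) limit so the update stays well conditioned.
exp_update <- function(u1, u2, fS, dt, tau_e, tau_a) {
  ee <- exp(-dt / tau_e)
  ea <- exp(-dt / tau_a)
  if (abs(tau_a - tau_e) > 1e-9 * tau_a) {
    kern <- tau_a / (tau_a - tau_e) * (ea - ee)
  } else {
    kern <- dt / tau_e * ee
  }
  list(
    u1 = u1 * ee + (fS - u2) * kern,
    u2 = fS + (u2 - fS) * ea
  )
}
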