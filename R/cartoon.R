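#' Parameters of the two-variable excitation--adaptation model
#'
#' The model captures, in abstract form, the two essential features of
#' chemotactic signal transduction: a fast excitation variable `u1` that
#' responds to a change in the stimulus, and a slow adaptation variable `u2`
#' that restores `u1` to zero under any constant stimulus.  The dynamics are
#' \deqn{du_1/d\tau = (f(S(\tau)) - u_1 - u_2)/\tau_e, \qquad
#'       du_2/d\tau = (f(S(\tau)) - u_2)/\tau_a.}
#' With \eqn{\tau_e \ll \tau_a} the system is excitable with a graded (not
#' all-or-none) response, and it adapts perfectly: the steady state of
#' \eqn{u_1} is zero for every constant stimulus.
#'
#' @param tau_e excitation time constant (s, > 0).
#' @param tau_a adaptation time constant (s, > 0).
#' @param f transduction function mapping stimulus level to drive; must
#'   satisfy `f(0) == 0`.  Default identity.  A saturating form such as
#'   `function(S) S / (K + S)` may be supplied.
#' @return An object of class `cartoon_params`.
#' @examples
#' p <- cartoon_params(tau_e = 0.1, tau_a = 10)
#' cartoon_rhs(c(0, 0), s_level = 1, p)
#' @export
cartoon_params <- function(tau_e, tau_a, f = identity) {
  check_positive(tau_e, "tau_e")
  check_positive(tau_a, "tau_a")
  stopifnot(is.function(f))
  if (abs(f(0)) > 1e-12) stop_invalid("f(0) must be 0")
  structure(list(tau_e = tau_e, tau_a = tau_a, f = f),
            class = "cartoon_params")
}

#' @export
print.cartoon_params <- function(x, ...) {
  cat(sprintf("excitation-adaptation model: tau_e = %g s, tau_a = %g s\n",
              x$tau_e, x$tau_a))
  invisible(x)
}

#' Piecewise stimulus protocol
#'
#' A protocol is an ordered set of non-overlapping segments, each with a
#' start time, end time, starting level and (optionally) a linear ramp
#' slope.  The stimulus is 0 outside all segments.
#'
#' @param t_start,t_end numeric vectors of segment boundaries (s);
#'   `t_start` non-decreasing, segments non-overlapping.
#' @param level stimulus level at the start of each segment (>= 0).
#' @param slope optional ramp slope per segment (level units / s); 0 gives
#'   piecewise-constant segments.
#' @return Object of class `stimulus_protocol`.
#' @examples
#' step1 <- stimulus_protocol(0, Inf, 1)          # unit step at t = 0
#' pulse <- stimulus_protocol(0, 0.01, 1)         # pulse of duration 0.01 s
#' stimulus_level(pulse, c(0.005, 0.02))
#' @export
stimulus_protocol <- function(t_start, t_end, level, slope = 0) {
  n <- length(t_start)
  stopifnot(length(t_end) == n, length(level) == n)
  slope <- rep_len(slope, n)
  if (any(t_end <= t_start)) stop_invalid("segments need t_end > t_start")
  if (any(level < 0)) stop_invalid("stimulus levels must be >= 0")
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]
  level <- level[o]; slope <- slope[o]
  if (n > 1 && any(t_start[-1] < t_end[-n] - 1e-12))
    stop_invalid("stimulus segments must not overlap")
  structure(list(t_start = t_start, t_end = t_end,
                 level = level, slope = slope),
            class = "stimulus_protocol")
}

#' Evaluate a stimulus protocol
#'
#' @param protocol a [stimulus_protocol()].
#' @param t times (s), vectorised.
#' @return Stimulus level S(t) at each time.
#' @export
stimulus_level <- function(protocol, t) {
  s <- numeric(length(t))
  for (i in seq_along(protocol$t_start)) {
    in_seg <- t >= protocol$t_start[i] & t < protocol$t_end[i]
    s[in_seg] <- protocol$level[i] +
      protocol$slope[i] * (t[in_seg] - protocol$t_start[i])
  }
  s
}

#' Right-hand side of the excitation--adaptation system
#'
#' @param state numeric vector `c(u1, u2)`.
#' @param s_level current stimulus level S.
#' @param params a [cartoon_params()].
#' @return Numeric vector `c(du1, du2)` of time derivatives.
#' @export
cartoon_rhs <- function(state, s_level, params) {
  stopifnot(inherits(params, "cartoon_params"))
  check_finite(state, "state")
  check_finite(s_level, "stimulus level")
  fS <- params$f(s_level)
  c((fS - state[1] - state[2]) / params$tau_e,
    (fS - state[2]) / params$tau_a)
}

# One integration sub-step: exact exponential update for constant segments,
# classical RK4 for ramp segments (the system is linear, so fixed-step RK4
# at dt << tau_e is ample).  The sub-interval [t0, t0 + h] never straddles
# a segment boundary (the caller splits there), so the stimulus is
# evaluated from the segment containing the interval midpoint -- including
# at t0 + h, where a half-open lookup would otherwise read the next
# segment.
.cartoon_step <- function(u, t0, h, params, protocol) {
  i <- which(t0 + h / 2 >= protocol$t_start & t0 + h / 2 < protocol$t_end)
  if (length(i) == 0) {
    lev <- function(t) 0
    sl <- 0
  } else {
    i <- i[1]
    lev <- function(t) protocol$level[i] +
      protocol$slope[i] * (t - protocol$t_start[i])
    sl <- protocol$slope[i]
  }
  if (sl == 0) {
    up <- exp_update(u[1], u[2], params$f(lev(t0)), h,
                     params$tau_e, params$tau_a)
    c(up$u1, up$u2)
  } else {
    k1 <- cartoon_rhs(u, lev(t0), params)
    k2 <- cartoon_rhs(u + h / 2 * k1, lev(t0 + h / 2), params)
    k3 <- cartoon_rhs(u + h / 2 * k2, lev(t0 + h / 2), params)
    k4 <- cartoon_rhs(u + h * k3, lev(t0 + h), params)
    u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
}

#' Integrate the excitation--adaptation model
#'
#' Trajectories are sampled on a uniform time grid.  Within
#' piecewise-constant stimulus segments the integrator applies the exact
#' exponential update of the linear system, so the only error is round-off;
#' steps that straddle a segment boundary are split at the boundary.  Ramp
#' segments use fixed-step 4th-order Runge--Kutta.
#'
#' @param params a [cartoon_params()].
#' @param protocol a [stimulus_protocol()].
#' @param dt output time step (s, > 0).
#' @param t_end duration (s, > dt).
#' @param state0 initial state, default `c(0, 0)`.
#' @return A data.frame with columns `t`, `u1`, `u2`, `S`.
#' @examples
#' p <- cartoon_params(0.1, 10)
#' tr <- integrate_cartoon(p, stimulus_protocol(0, Inf, 1), dt = 0.01, t_end = 5)
#' max(tr$u1)  # transient peak, ~0.95 for these time constants
#' @export
integrate_cartoon <- function(params, protocol, dt, t_end, state0 = c(0, 0)) {
  stopifnot(inherits(params, "cartoon_params"),
            inherits(protocol, "stimulus_protocol"))
  check_positive(dt, "dt")
  check_positive(t_end, "t_end")
  if (dt >= t_end) stop_invalid("dt must be < t_end")
  check_finite(state0, "initial state")

  times <- seq(0, t_end, by = dt)
  brk <- sort(unique(c(protocol$t_start, protocol$t_end)))
  brk <- brk[is.finite(brk)]
  out <- matrix(NA_real_, length(times), 2)
  u <- state0
  out[1, ] <- u
  for (k in seq_len(length(times) - 1)) {
    t0 <- times[k]; t1 <- times[k + 1]
    cuts <- c(t0, brk[brk > t0 + 1e-12 & brk < t1 - 1e-12], t1)
    for (j in seq_len(length(cuts) - 1)) {
      u <- .cartoon_step(u, cuts[j], cuts[j + 1] - cuts[j], params, protocol)
    }
    out[k + 1, ] <- u
  }
  data.frame(t = times, u1 = out[, 1], u2 = out[, 2],
             S = stimulus_level(protocol, times))
}

#' Closed-form response to a step stimulus
#'
#' For a step of amplitude `s0` applied at t = 0 with the system initially
#' at rest, the solution is
#' \deqn{u_1(t) = f(S_0)\frac{\tau_a}{\tau_a-\tau_e}
#'       (e^{-t/\tau_a}-e^{-t/\tau_e}), \qquad
#'       u_2(t) = f(S_0)(1-e^{-t/\tau_a}).}
#' The prefactor \eqn{\tau_a/(\tau_a-\tau_e)} is the one consistent with the
#' governing equations (the initial slope of `u1` must equal
#' \eqn{f(S_0)/\tau_e}); a variant with denominator \eqn{\tau_a+\tau_e}
#' sometimes seen in print does not satisfy them.  In the
#' \eqn{\tau_e \ll \tau_a} regime of interest the two differ negligibly.
#'
#' @param params a [cartoon_params()]; `tau_a` must differ from `tau_e`
#'   (the confluent case is not supported).
#' @param s0 step amplitude.
#' @param t time(s) since the step (s, >= 0), vectorised.
#' @return A data.frame with columns `t`, `u1`, `u2`.
#' @export
analytic_step_response <- function(params, s0, t) {
  stopifnot(inherits(params, "cartoon_params"))
  if (any(t < 0)) stop_invalid("t must be >= 0")
  te <- params$tau_e; ta <- params$tau_a
  if (abs(ta - te) <= 1e-9 * ta)
    stop_invalid("tau_a = tau_e is a degenerate (confluent) case")
  fS <- params$f(s0)
  data.frame(
    t = t,
    u1 = fS * ta / (ta - te) * (exp(-t / ta) - exp(-t / te)),
    u2 = fS * (1 - exp(-t / ta))
  )
}

#' Peak excitation for a brief pulse
#'
#' For a linear transduction function and a stimulus pulse
#' \eqn{S(\tau) = S_1} on \eqn{(0, \tau_e)} and 0 after, the excitation
#' variable rises to approximately \eqn{(1 - e^{-1}) S_1 \approx 2S_1/3}
#' before returning to zero, provided \eqn{\tau_e \ll \tau_a}.
#'
#' @param params a [cartoon_params()] with (effectively) linear `f`.
#' @param s1 pulse amplitude.
#' @return Maximum of `u1` over time.
#' @export
pulse_response_peak <- function(params, s1) {
  stopifnot(inherits(params, "cartoon_params"))
  if (params$tau_a / params$tau_e < 100)
    warning("tau_a/tau_e < 100: the ~2/3 pulse-peak limit needs tau_e << tau_a")
  if (s1 == 0) return(0)
  proto <- stimulus_protocol(0, params$tau_e, s1)
  tr <- integrate_cartoon(params, proto, dt = params$tau_e / 200,
                          t_end = 10 * params$tau_e)
  max(tr$u1)
}
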