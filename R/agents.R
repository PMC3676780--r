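#' Parameters of the run-and-tumble agent model
#'
#' Each cell swims at constant speed `s0` and reorients ("turns") at a
#' state-dependent Poisson rate.  The internal state is the two-variable
#' excitation--adaptation system driven by the local signal,
#' \deqn{dy_1/dt = (G(S(x,t)) - y_1 - y_2)/t_e, \qquad
#'       dy_2/dt = (G(S(x,t)) - y_2)/t_a,}
#' and the turning rate is
#' \deqn{\lambda(y_1) = \lambda_0 \left(1 - \frac{y_1}{\gamma_0 + |y_1|}\right),}
#' which is bounded in (0, 2*lambda0): positive excitation (running up an
#' attractant gradient) lengthens runs.  The post-turn velocity is drawn
#' uniformly from the speed-`s0` sphere, independent of the incoming
#' direction.  In 2-D an optional angular drift `omega` biases headings
#' clockwise, as for cells swimming close to a surface.
#'
#' @param s0 swimming speed (um/s, > 0).
#' @param lambda0 baseline turning rate (1/s, > 0).
#' @param gamma0 turning-rate saturation constant (units of y1, > 0).
#' @param t_e excitation time (s); `t_e < t_a` required, `t_e << t_a`
#'   intended.
#' @param t_a adaptation time (s).
#' @param G signal detection function (default identity, `G(0) = 0`).
#' @param dim spatial dimension, 1 or 2.
#' @param omega angular drift rate (rad/s, default 0; 2-D only).  Positive
#'   `omega` turns headings clockwise.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(s0 = 20, lambda0 = 1, gamma0 = 1,
                         t_e = 0.1, t_a = 5, G = identity,
                         dim = 1, omega = 0) {
  check_positive(c(s0, lambda0, gamma0, t_e, t_a), "rates and times")
  if (t_e >= t_a) stop_invalid("t_e must be < t_a")
  if (!dim %in% c(1, 2)) stop_invalid("dim must be 1 or 2")
  if (omega != 0 && dim != 2) stop_invalid("omega is only meaningful in 2-D")
  stopifnot(is.function(G))
  structure(list(s0 = s0, lambda0 = lambda0, gamma0 = gamma0,
                 t_e = t_e, t_a = t_a, G = G,
                 dim = as.integer(dim), omega = omega),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "agent params (%d-D): s0 = %g um/s, lambda0 = %g /s, gamma0 = %g, t_e = %g s, t_a = %g s%s\n",
    x$dim, x$s0, x$lambda0, x$gamma0, x$t_e, x$t_a,
    if (x$omega != 0) sprintf(", omega = %g rad/s", x$omega) else ""))
  invisible(x)
}

#' Advance the internal excitation--adaptation variables
#'
#' Exact exponential update of the linear internal dynamics over one step,
#' treating the local signal as constant during the step.  Identical
#' arithmetic to the single-cell integrator, so trajectories of the two
#' agree to round-off on matching inputs.
#'
#' @param y1,y2 internal variables (vectorised over cells).
#' @param s_local local signal level(s).
#' @param dt time step (s, > 0).
#' @param params an [agent_params()].
#' @return A list with updated `y1`, `y2`.
#' @export
step_internal <- function(y1, y2, s_local, dt, params) {
  stopifnot(inherits(params, "agent_params"))
  check_positive(dt, "dt")
  up <- exp_update(y1, y2, params$G(s_local), dt, params$t_e, params$t_a)
  list(y1 = up$u1, y2 = up$u2)
}

#' State-dependent turning rate
#'
#' \eqn{\lambda(y_1) = \lambda_0 (1 - y_1/(\gamma_0 + |y_1|))}, bounded in
#' (0, 2 lambda0).
#'
#' @param y1 excitation variable (vectorised).
#' @param params an [agent_params()].
#' @return Turning rate(s) (1/s).
#' @export
turning_rate <- function(y1, params) {
  stopifnot(inherits(params, "agent_params"))
  params$lambda0 * (1 - y1 / (params$gamma0 + abs(y1)))
}

#' Draw post-turn velocities from the uniform kernel
#'
#' The turning kernel is uniform over the admissible velocity set (speed
#' `s0`), independent of the incoming velocity: in 1-D the new velocity is
#' +s0 or -s0 with probability 1/2 each (so a turn may re-select the same
#' direction); in 2-D the new heading angle is uniform on [0, 2*pi).
#'
#' @param n number of draws.
#' @param params an [agent_params()].
#' @return In 1-D a numeric vector of signed speeds; in 2-D a vector of
#'   heading angles (rad).
#' @export
draw_new_velocity <- function(n, params) {
  stopifnot(inherits(params, "agent_params"))
  if (params$dim == 1) {
    params$s0 * sample(c(-1, 1), n, replace = TRUE)
  } else {
    stats::runif(n, 0, 2 * pi)
  }
}

#' Simulate a run-and-tumble population
#'
#' Time-driven velocity-jump simulation: at each step of length `dt` every
#' cell updates its internal state from the local signal (exact exponential
#' update), turns with probability \eqn{1 - e^{-\lambda dt}} (reorienting
#' instantaneously via the uniform kernel), then advances
#' `x <- x + v * dt`.  In 2-D a heading drift `-omega * dt` is applied each
#' step.  The step must resolve excitation (`dt <= t_e / 5`), which also
#' keeps `lambda * dt` well below 1.  All random draws are vectorised
#' across cells from a single seeded stream, so results are independent of
#' any cell ordering and bit-reproducible given the seed.
#'
#' @param params an [agent_params()].
#' @param n_cells number of cells (>= 1).
#' @param t_end duration (s).
#' @param dt time step (s); must satisfy `dt <= t_e / 5`.
#' @param signal `NULL` for no signal, or a function `S(x, t)` returning
#'   the signal level at positions `x` (matrix n x dim) and time `t`.
#' @param seed integer seed for reproducibility (optional).
#' @param x0 initial positions, n x dim matrix; default all at the origin.
#' @param domain optional domain extent: length-2 vector per dimension
#'   (1-D: `c(lo, hi)`, 2-D: list of two such vectors or a 2 x 2 matrix
#'   with rows `c(lo, hi)`).
#' @param boundary `"none"`, `"periodic"` or `"reflecting"` (needs
#'   `domain`).
#' @param record_dt interval at which positions are sampled (default
#'   `max(dt, t_end / 200)`).
#' @return Object of class `population_trajectory`: list with `times`,
#'   `x` (array time x cell x dim), `turns` (data.frame `cell`, `t`),
#'   `y1`, `y2`, final `heading`, and the call parameters.
#' @examples
#' p <- agent_params(s0 = 20, lambda0 = 1, dim = 1)
#' tr <- simulate_population(p, n_cells = 50, t_end = 20, dt = 0.02, seed = 1)
#' mean(diff(tr$times))
#' @export
simulate_population <- function(params, n_cells, t_end, dt,
                                signal = NULL, seed = NULL,
                                x0 = NULL, domain = NULL,
                                boundary = c("none", "periodic", "reflecting"),
                                record_dt = NULL) {
  stopifnot(inherits(params, "agent_params"))
  boundary <- match.arg(boundary)
  if (n_cells < 1) stop_invalid("n_cells must be >= 1")
  check_positive(c(t_end, dt), "t_end and dt")
  if (dt > params$t_e / 5 + 1e-12)
    stop_invalid("dt = %g too large: need dt <= t_e/5 = %g to resolve excitation",
                 dt, params$t_e / 5)
  if (boundary != "none" && is.null(domain))
    stop_invalid("boundary %s needs a domain", boundary)
  if (!is.null(seed)) set.seed(seed)

  N <- params$dim
  dom <- NULL
  if (!is.null(domain)) {
    dom <- if (is.list(domain)) do.call(rbind, domain)
           else matrix(domain, ncol = 2, byrow = (N == 2 && length(domain) == 4))
    if (N == 1) dom <- matrix(dom, 1, 2)
  }
  x <- if (is.null(x0)) matrix(0, n_cells, N) else {
    x0 <- as.matrix(x0)
    stopifnot(nrow(x0) == n_cells, ncol(x0) == N)
    x0
  }
  # heading: signed speed in 1-D, angle in 2-D; start from the uniform kernel
  heading <- draw_new_velocity(n_cells, params)
  y1 <- numeric(n_cells); y2 <- numeric(n_cells)

  n_steps <- ceiling(t_end / dt)
  if (is.null(record_dt)) record_dt <- max(dt, t_end / 200)
  rec_every <- max(1L, round(record_dt / dt))
  rec_idx <- unique(c(seq(0L, n_steps, by = rec_every), n_steps))
  times <- rec_idx * dt
  xs <- array(NA_real_, c(length(rec_idx), n_cells, N))
  xs[1, , ] <- x
  rec_ptr <- 1L

  turn_cell <- vector("list", n_steps)
  turn_time <- vector("list", n_steps)

  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * dt
    s_loc <- if (is.null(signal)) 0 else signal(x, t_now)
    up <- exp_update(y1, y2, params$G(s_loc), dt, params$t_e, params$t_a)
    y1 <- up$u1; y2 <- up$u2
    lam <- turning_rate(y1, params)
    turned <- stats::runif(n_cells) < -expm1(-lam * dt)
    n_turn <- sum(turned)
    if (n_turn > 0) {
      heading[turned] <- draw_new_velocity(n_turn, params)
      turn_cell[[k]] <- which(turned)
      turn_time[[k]] <- rep.int(k * dt, n_turn)
    }
    if (N == 2 && params$omega != 0) heading <- heading - params$omega * dt
    v <- if (N == 1) cbind(heading)
         else params$s0 * cbind(cos(heading), sin(heading))
    x <- x + v * dt
    if (boundary == "periodic") {
      for (d in seq_len(N)) {
        w <- dom[d, 2] - dom[d, 1]
        x[, d] <- dom[d, 1] + (x[, d] - dom[d, 1]) %% w
      }
    } else if (boundary == "reflecting") {
      for (d in seq_len(N)) {
        lo <- dom[d, 1]; hi <- dom[d, 2]
        over <- x[, d] > hi; under <- x[, d] < lo
        if (any(over)) x[over, d] <- 2 * hi - x[over, d]
        if (any(under)) x[under, d] <- 2 * lo - x[under, d]
        if (any(over | under)) {
          if (N == 1) heading[over | under] <- -heading[over | under]
          else {
            # reflect the velocity component normal to the wall
            if (d == 1) heading[over | under] <- pi - heading[over | under]
            else heading[over | under] <- -heading[over | under]
          }
        }
      }
    }
    if (k == rec_idx[rec_ptr + 1L]) {
      rec_ptr <- rec_ptr + 1L
      xs[rec_ptr, , ] <- x
    }
  }

  turns <- data.frame(cell = unlist(turn_cell), t = unlist(turn_time))
  structure(list(times = times, x = xs, turns = turns,
                 y1 = y1, y2 = y2, heading = heading,
                 params = params, dt = dt, t_end = n_steps * dt,
                 n_cells = n_cells, seed = seed),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  cat(sprintf(
    "population trajectory: %d cells, %g s at dt = %g s, %d turn events\n",
    x$n_cells, x$t_end, x$dt, nrow(x$turns)))
  invisible(x)
}

#' Summary statistics of a population trajectory
#'
#' Pools run durations (intervals between successive turn events of the
#' same cell, measured from t = 0 for the first run; the final censored
#' interval of each cell is discarded) and estimates the macroscopic
#' diffusion coefficient from a linear fit of the mean-squared displacement
#' over a late window (default from `10 / lambda0` to the end), past the
#' ballistic-to-diffusive crossover at `~1/lambda0`.  For an unbiased
#' velocity-jump walk the expected diffusivity is
#' \eqn{D = s_0^2 / (N \lambda_0)}.
#'
#' @param traj a [simulate_population()] result.
#' @param msd_window length-2 vector of fit-window times (s); default
#'   `c(10 / lambda0, max(times))`.
#' @return A list with `mean_run`, `n_runs`, `runs` (pooled durations),
#'   `msd` (data.frame `t`, `msd`), `D_hat` and `D_theory`.
#' @export
run_statistics <- function(traj, msd_window = NULL) {
  stopifnot(inherits(traj, "population_trajectory"))
  if (nrow(traj$turns) < 100)
    stop_invalid("insufficient data: need >= 100 turn events, have %d",
                 nrow(traj$turns))
  runs <- unlist(lapply(split(traj$turns$t, traj$turns$cell),
                        function(tt) diff(c(0, tt))), use.names = FALSE)
  N <- traj$params$dim
  d2 <- 0
  for (d in seq_len(N)) {
    dx <- sweep(traj$x[, , d, drop = FALSE], 2, traj$x[1, , d])
    d2 <- d2 + dx[, , 1]^2
  }
  msd <- rowMeans(d2)
  msd_df <- data.frame(t = traj$times, msd = msd)
  lam <- traj$params$lambda0
  if (is.null(msd_window)) msd_window <- c(10 / lam, max(traj$times))
  w <- msd_df$t >= msd_window[1] & msd_df$t <= msd_window[2]
  if (sum(w) < 3) stop_invalid("MSD fit window contains < 3 samples")
  slope <- stats::coef(stats::lm(msd ~ t, data = msd_df[w, ]))[["t"]]
  list(
    mean_run = mean(runs),
    n_runs = length(runs),
    runs = runs,
    msd = msd_df,
    D_hat = slope / (2 * N),
    D_theory = traj$params$s0^2 / (N * lam)
  )
}
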