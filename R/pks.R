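#' Continuum transport coefficients from cell parameters
#'
#' In the shallow-gradient limit the velocity-jump process with linear
#' internal dynamics coarse-grains to the Patlak--Keller--Segel equation
#' \deqn{\partial n/\partial t = \nabla\cdot(D_n \nabla n - \chi n \nabla S)}
#' with microscopically derived coefficients
#' \deqn{D_n = \frac{s_0^2}{N \lambda_0}, \qquad
#'  \chi = \frac{b\, s_0^2\, t_a}{N \lambda_0 (1 + \lambda_0 t_a)(1 + \lambda_0 t_e)},}
#' where `b` is the magnitude of the turning-rate sensitivity
#' \eqn{|\partial\lambda/\partial y_1|} at the adapted state.  The sign
#' convention is fixed so that an attractant (turning rate decreasing in
#' excitation) gives positive `chi` and up-gradient drift.
#'
#' @param s0 cell speed (um/s).
#' @param lambda0 baseline turning rate (1/s).
#' @param b turning-rate sensitivity `|d lambda/d y1|` at rest (1/s per
#'   unit y1); see [b_from_turning_rate()].
#' @param t_a adaptation time (s).
#' @param t_e excitation time (s).
#' @param N spatial dimension (1, 2 or 3).
#' @return Object of class `pks_coefficients` with fields `D_n`, `chi`
#'   and the microscopic `provenance`.
#' @examples
#' co <- pks_coefficients(s0 = 20, lambda0 = 1, b = 4, t_a = 5, t_e = 0.1, N = 1)
#' co$D_n   # 400 um^2/s
#' @export
pks_coefficients <- function(s0, lambda0, b, t_a, t_e, N = 1) {
  check_positive(c(s0, lambda0, t_a, t_e), "cell parameters")
  check_finite(b, "b")
  if (!N %in% 1:3) stop_invalid("N must be 1, 2 or 3")
  structure(list(
    D_n = s0^2 / (N * lambda0),
    chi = b * s0^2 * t_a / (N * lambda0 * (1 + lambda0 * t_a) * (1 + lambda0 * t_e)),
    provenance = list(s0 = s0, lambda0 = lambda0, b = b,
                      t_a = t_a, t_e = t_e, N = N)
  ), class = "pks_coefficients")
}

#' @export
print.pks_coefficients <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("PKS coefficients (N = %d): D_n = %g um^2/s, chi = %g um^2/s\n",
              p$N, x$D_n, x$chi))
  cat(sprintf("  from s0 = %g, lambda0 = %g, b = %g, t_a = %g, t_e = %g\n",
              p$s0, p$lambda0, p$b, p$t_a, p$t_e))
  invisible(x)
}

#' Turning-rate sensitivity implied by the agent model
#'
#' For the saturating turning rate
#' \eqn{\lambda(y_1) = \lambda_0(1 - y_1/(\gamma_0 + |y_1|))} the
#' derivative at the adapted state `y1 = 0` is `-lambda0 / gamma0`; its
#' magnitude is the coefficient `b` entering the chemotactic sensitivity.
#' (The negative sign -- runs lengthen up-gradient -- is what makes the
#' drift point up the attractant gradient; `b` is reported as a positive
#' magnitude.)
#'
#' @param params an [agent_params()].
#' @return `b = lambda0 / gamma0` (1/s per unit y1).
#' @export
b_from_turning_rate <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  params$lambda0 / params$gamma0
}

#' Solve the 1-D Patlak--Keller--Segel equation
#'
#' Conservative finite-volume discretisation of
#' \eqn{\partial_t n = \partial_x(D_n \partial_x n - \chi n \partial_x S)}
#' with Scharfetter--Gummel (exponential-fitting) face fluxes: central
#' differencing in the low cell-Peclet limit, upwinding in the high, and a
#' discrete zero-flux stationary state exactly proportional to
#' `exp(chi * S / D_n)` at any resolution.  Explicit time stepping by
#' default with an automatic step satisfying both the diffusive and
#' advective stability limits; `method = "implicit"` applies
#' Crank--Nicolson to the full (linear) transport operator, which is
#' unconditionally stable and shares the exact discrete stationary state.
#' Under no-flux boundaries total mass is conserved to round-off.
#'
#' @param coeffs a [pks_coefficients()].
#' @param S static signal profile: numeric vector on the grid, or a
#'   function of x.
#' @param n0 initial density: numeric vector on the grid, or a function of
#'   x; must be non-negative.
#' @param dx grid spacing (um).
#' @param nx number of grid cells (used when `S`/`n0` are functions).
#' @param dt time step; `NULL` (default) chooses one automatically.
#' @param t_end final time (s).
#' @param bc `"noflux"` or `"periodic"`.
#' @param save_times times at which to store the profile (always includes
#'   0 and `t_end`).
#' @param method `"explicit"` or `"implicit"`.
#' @return Object of class `pks_solution`: list with `x`, `times`,
#'   `n` (matrix, one row per saved time), `S`, `coeffs`.
#' @examples
#' co <- pks_coefficients(20, 1, 4, 5, 0.1, N = 1)
#' sol <- solve_pks_1d(co, S = function(x) 1e-3 * x, n0 = function(x) dnorm(x, 500, 50),
#'                     dx = 10, nx = 101, t_end = 20)
#' @export
solve_pks_1d <- function(coeffs, S, n0, dx, nx = NULL, dt = NULL, t_end,
                         bc = c("noflux", "periodic"), save_times = NULL,
                         method = c("explicit", "implicit")) {
  stopifnot(inherits(coeffs, "pks_coefficients"))
  bc <- match.arg(bc)
  method <- match.arg(method)
  check_positive(c(dx, t_end), "dx and t_end")

  if (is.function(S) || is.function(n0)) {
    if (is.null(nx)) stop_invalid("nx is required when S or n0 is a function")
  } else {
    nx <- length(S)
  }
  x <- (seq_len(nx) - 1) * dx
  Sv <- if (is.function(S)) S(x) else as.numeric(S)
  nv <- if (is.function(n0)) n0(x) else as.numeric(n0)
  stopifnot(length(Sv) == nx, length(nv) == nx)
  if (any(nv < 0)) stop_invalid("initial density must be non-negative")
  D <- coeffs$D_n; chi <- coeffs$chi

  # face drift velocities u_{j+1/2} = chi * (S[j+1] - S[j]) / dx and
  # Scharfetter-Gummel (exponential-fitting) face weights.  The SG flux
  #   F = (D/dx) * [B(-P) n_j - B(P) n_(j+1)],  P = u dx / D,
  # with B(z) = z/(e^z - 1), limits to central differencing at small cell
  # Peclet number and to upwinding at large, and its zero-flux stationary
  # state is exactly n ~ exp(chi S / D_n) on any grid.
  bern <- function(z) ifelse(abs(z) < 1e-8, 1 - z / 2, z / expm1(z))
  if (bc == "periodic") {
    u_face <- chi * (Sv[c(2:nx, 1)] - Sv) / dx        # face j between j, j+1 (wraps)
  } else {
    u_face <- chi * diff(Sv) / dx                     # nx - 1 interior faces
  }
  P <- u_face * dx / D
  w_left <- D / dx * bern(-P)   # multiplies the left/owner node
  w_right <- D / dx * bern(P)   # multiplies the right node
  umax <- max(abs(u_face), 1e-12)
  if (is.null(dt)) {
    dt_adv <- 0.4 * dx / umax
    dt <- if (method == "explicit")
      min(0.4 * dx^2 / (2 * D * max(bern(-abs(P)))), dt_adv) else dt_adv
    dt <- t_end / ceiling(t_end / dt)
  }
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-8 * t_end)
    n_steps <- ceiling(t_end / dt)

  cn <- NULL
  if (method == "implicit") {
    # full SG transport operator M (dn/dt = M n), tridiagonal, zero column
    # sums; Crank-Nicolson on M keeps the exact stationary null vector.
    lf <- if (bc == "periodic") seq_len(nx) else seq_len(nx - 1)
    rf <- if (bc == "periodic") c(2:nx, 1) else 2:nx
    i <- c(lf, lf, rf, rf)
    j <- c(lf, rf, lf, rf)
    v <- c(-w_left, w_right, w_left, -w_right) / dx
    M <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(nx, nx))
    cn <- list(A = Matrix::lu(Matrix::Diagonal(nx) - dt / 2 * M),
               B = Matrix::Diagonal(nx) + dt / 2 * M)
  }

  if (is.null(save_times)) save_times <- t_end
  save_times <- sort(unique(c(0, pmin(save_times, n_steps * dt))))
  save_steps <- round(save_times / dt)
  out <- matrix(NA_real_, length(save_steps), nx)
  out[1, ] <- nv
  ptr <- 1L
  mass0 <- sum(nv)

  # flux difference (out minus in) per cell, from face fluxes f
  div_of <- function(f) {
    if (bc == "periodic") f - c(f[nx], f[-nx])
    else c(f, 0) - c(0, f)              # zero-flux boundary faces
  }
  pair <- function(n) {
    if (bc == "periodic") list(l = n, r = n[c(2:nx, 1)])
    else list(l = n[-nx], r = n[-1])
  }

  for (k in seq_len(n_steps)) {
    if (method == "explicit") {
      np <- pair(nv)
      nv <- nv - dt / dx * div_of(w_left * np$l - w_right * np$r)
    } else {
      nv <- as.numeric(Matrix::solve(cn$A, cn$B %*% nv))
    }
    if (any(!is.finite(nv)) || sum(nv) < 0)
      stop("PKS solver diverged (non-finite or negative mass); reduce dt",
           call. = FALSE)
    if (ptr < length(save_steps) && k == save_steps[ptr + 1L]) {
      ptr <- ptr + 1L
      out[ptr, ] <- nv
    }
  }
  if (bc == "noflux" && abs(sum(nv) - mass0) > 1e-8 * max(mass0, 1))
    warning("mass drift exceeds 1e-8 relative")

  structure(list(x = x, times = save_steps * dt, n = out, S = Sv,
                 coeffs = coeffs, dt = dt, bc = bc, method = method),
            class = "pks_solution")
}

#' @export
print.pks_solution <- function(x, ...) {
  cat(sprintf("PKS solution: %d cells of dx = %g um, t in [0, %g] s (%s, %s)\n",
              length(x$x), diff(x$x[1:2]), max(x$times), x$method, x$bc))
  invisible(x)
}

#' Compare the agent-based model with its continuum limit
#'
#' Runs the run-and-tumble simulator and the PKS solver under matched
#' parameters in a static 1-D signal, then reports the L1 and max-norm
#' discrepancies between the normalised agent histogram and the PDE
#' density at each requested time.  The PKS coefficients must have been
#' derived from the agent parameters ([pks_coefficients()] with
#' `b = ` [b_from_turning_rate()]); a mismatch is an error, not a warning.
#' The report includes the gradient-validity diagnostic
#' \eqn{s_0 |\nabla S|_{max} t_a} (signal change per adaptation time along
#' a run, in units of the detection function's input): the continuum limit
#' holds when this is well below 1.
#'
#' @param agent_params an [agent_params()] with `dim = 1`.
#' @param coeffs a [pks_coefficients()] derived from `agent_params`.
#' @param S signal profile as a function of x (um).
#' @param domain length-2 vector `c(lo, hi)` (um); reflecting for agents,
#'   no-flux for the PDE.
#' @param n_cells number of agents.
#' @param x0 initial agent positions (vector, recycled).  Default: evenly
#'   spaced across the domain (uniform density).  The PDE starts from the
#'   matching histogram density.
#' @param t_end final time (s).
#' @param times comparison times (default `t_end`).
#' @param bins number of histogram bins.
#' @param dt agent time step (default `t_e / 5`).
#' @param seed RNG seed.
#' @return Object of class `pks_comparison`: list with `times`, `L1`,
#'   `Linf`, `gradient_diagnostic`, `valid_regime`, per-time histograms
#'   (`agent_density`), PDE profiles (`pde_density`), `breaks`.
#' @export
compare_agents_to_pks <- function(agent_params, coeffs, S, domain,
                                  n_cells = 1e4, x0 = NULL,
                                  t_end = 100, times = NULL, bins = 40,
                                  dt = NULL, seed = 1) {
  stopifnot(inherits(agent_params, "agent_params"),
            inherits(coeffs, "pks_coefficients"),
            is.function(S))
  if (agent_params$dim != 1) stop_invalid("comparison is 1-D only")
  pr <- coeffs$provenance
  b_agents <- b_from_turning_rate(agent_params)
  mism <- c(s0 = abs(pr$s0 - agent_params$s0),
            lambda0 = abs(pr$lambda0 - agent_params$lambda0),
            t_a = abs(pr$t_a - agent_params$t_a),
            t_e = abs(pr$t_e - agent_params$t_e),
            b = abs(pr$b - b_agents),
            N = abs(pr$N - 1))
  if (any(mism > 1e-9))
    stop_invalid("agent/PKS parameter mismatch in: %s",
                 paste(names(mism)[mism > 1e-9], collapse = ", "))
  if (is.null(times)) times <- t_end
  if (is.null(dt)) dt <- agent_params$t_e / 5
  if (is.null(x0)) {
    h0 <- (domain[2] - domain[1]) / n_cells
    x0 <- seq(domain[1] + h0 / 2, domain[2] - h0 / 2, length.out = n_cells)
  }
  x0 <- rep_len(x0, n_cells)

  traj <- simulate_population(
    agent_params, n_cells = n_cells, t_end = t_end, dt = dt,
    signal = function(x, t) S(x[, 1]), seed = seed,
    x0 = matrix(x0, ncol = 1), domain = domain, boundary = "reflecting")

  breaks <- seq(domain[1], domain[2], length.out = bins + 1)
  h <- diff(breaks)[1]
  hist_density <- function(x) {
    cts <- graphics::hist(pmin(pmax(x, domain[1]), domain[2]),
                          breaks = breaks, plot = FALSE)$counts
    cts / (sum(cts) * h)
  }

  # PDE on a finer grid, initial condition = smoothed initial histogram
  nx <- 4 * bins + 1
  dx <- (domain[2] - domain[1]) / (nx - 1)
  xg <- domain[1] + (seq_len(nx) - 1) * dx
  n0g <- hist_density(x0)[pmin(bins, pmax(1, findInterval(xg, breaks,
                                                          rightmost.closed = TRUE)))]
  sol <- solve_pks_1d(coeffs, S = S(xg), n0 = n0g, dx = dx,
                      t_end = t_end, bc = "noflux",
                      save_times = times, method = "implicit")

  grad_max <- max(abs(diff(S(xg)) / dx))
  diag_val <- agent_params$s0 * grad_max * agent_params$t_a

  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  L1 <- Linf <- numeric(length(times))
  agent_den <- pde_den <- matrix(NA_real_, length(times), bins)
  for (i in seq_along(times)) {
    ti <- times[i]
    k <- which.min(abs(traj$times - ti))
    ad <- hist_density(traj$x[k, , 1])
    ks <- which.min(abs(sol$times - ti))
    pg <- sol$n[ks, ]
    pg <- pg / (sum(pg) * dx)
    pd <- stats::approx(xg, pg, xout = mids)$y
    pd <- pd / (sum(pd) * h)
    agent_den[i, ] <- ad
    pde_den[i, ] <- pd
    L1[i] <- sum(abs(ad - pd)) * h
    Linf[i] <- max(abs(ad - pd))
  }

  structure(list(times = times, L1 = L1, Linf = Linf,
                 gradient_diagnostic = diag_val,
                 valid_regime = diag_val < 1,
                 agent_density = agent_den, pde_density = pde_den,
                 mids = mids, breaks = breaks, pde = sol),
            class = "pks_comparison")
}

#' @export
print.pks_comparison <- function(x, ...) {
  cat("agent vs continuum comparison\n")
  for (i in seq_along(x$times))
    cat(sprintf("  t = %6g s: L1 = %.4f, Linf = %.3g\n",
                x$times[i], x$L1[i], x$Linf[i]))
  cat(sprintf("  gradient diagnostic s0*|dS/dx|max*t_a = %.3g (%s)\n",
              x$gradient_diagnostic,
              if (x$valid_regime) "shallow-gradient regime"
              else "steep gradient: continuum limit suspect"))
  invisible(x)
}
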