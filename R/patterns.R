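# Coupled agents + reaction-diffusion scenarios: attractant secretion in
# liquid medium, swarm-ring with nutrient, consumed-signal traveling band,
# and surface spirals.  Agents and fields share one dt (first-order
# splitting): interpolate S at cell positions -> internal update -> turn ->
# move -> deposit -> field step.

#' Run a coupled cell/field pattern-formation scenario
#'
#' Four canonical scenarios are provided, at desk scale:
#' \describe{
#'   \item{`"liquid"`}{cells in 2-D secrete an attractant and chemotax
#'     toward it; above the instability threshold a uniform lawn breaks
#'     into networks and aggregates (binned-density variance grows, then
#'     plateaus).  With `gamma = 0` the lawn stays statistically uniform.}
#'   \item{`"swarm_ring"`}{2-D, with a consumed nutrient layer and a
#'     secreted attractant; an inoculum at the centre spreads as a ring.}
#'   \item{`"adler"`}{1-D consumed-signal variant: the signal is the
#'     nutrient (`S(x,0) = 1` uniformly), cells consume it and ride the
#'     self-generated gradient as a band of asymptotically constant
#'     speed.}
#'   \item{`"spiral"`}{the liquid scenario plus a clockwise angular drift
#'     (`omega > 0`), as for cells swimming near a surface; aggregates
#'     wind into spiral streams.}
#' }
#'
#' @param scenario name above, or a full scenario list from
#'   [make_fixture()].
#' @param overrides named list of parameter overrides (see
#'   [pattern_defaults()] for names).
#' @param seed RNG seed.
#' @param snapshots number of density/field snapshots to keep.
#' @return Object of class `pattern_result`: list with `times`,
#'   `density` (list of node-count arrays), `S` (list of field arrays),
#'   `variance` (binned-density variance per snapshot), `mean_x` (mean
#'   cell position per snapshot), `clusters` (aggregate count/size
#'   summary per snapshot, aggregation scenarios only), `params`.
#' @export
run_pattern_scenario <- function(scenario, overrides = list(), seed = 1,
                                 snapshots = 20) {
  if (is.list(scenario) && !is.null(scenario$pattern)) {
    overrides <- utils::modifyList(scenario$pattern$overrides %||% list(),
                                   overrides)
    seed <- scenario$seed %||% seed
    scenario <- scenario$pattern$type
  }
  known <- c("liquid", "swarm_ring", "adler", "spiral")
  if (!is.character(scenario) || !scenario %in% known)
    stop_invalid("unknown scenario; valid: %s", paste(known, collapse = ", "))
  p <- utils::modifyList(pattern_defaults(scenario), overrides)
  set.seed(seed)

  two_d <- scenario != "adler"
  ap <- agent_params(s0 = p$s0, lambda0 = p$lambda0, gamma0 = p$gamma0,
                     t_e = p$t_e, t_a = p$t_a, dim = if (two_d) 2 else 1,
                     omega = if (scenario == "spiral") p$omega else 0)
  grid <- if (scenario == "adler") {
    field_grid(nx = p$nx, dx = p$dx, D_s = p$D_s, gamma = p$gamma,
               boundary = "noflux", S0 = 1, mode = "consumption")
  } else if (scenario == "swarm_ring") {
    field_grid(nx = p$nx, ny = p$nx, dx = p$dx, D_s = p$D_s, D_f = p$D_f,
               gamma = p$gamma, k = p$k, mu = p$mu,
               boundary = "periodic", S0 = 0, F0 = 1)
  } else {
    field_grid(nx = p$nx, ny = p$nx, dx = p$dx, D_s = p$D_s,
               gamma = p$gamma, mu = p$mu, boundary = "periodic", S0 = 0)
  }
  periodic <- grid$boundary == "periodic"
  extent <- if (periodic) grid$dims * p$dx else (grid$dims - 1) * p$dx
  N <- ap$dim

  n_cells <- p$n_cells
  x <- switch(scenario,
    adler = matrix(stats::runif(n_cells, 0, p$inoculum_width), ncol = 1),
    swarm_ring = {
      r <- p$inoculum_width * sqrt(stats::runif(n_cells))
      th <- stats::runif(n_cells, 0, 2 * pi)
      cbind(extent[1] / 2 + r * cos(th), extent[2] / 2 + r * sin(th))
    },
    # liquid / spiral: uniform lawn
    matrix(stats::runif(n_cells * 2, 0, extent[1]), ncol = 2)
  )
  heading <- draw_new_velocity(n_cells, ap)
  y1 <- numeric(n_cells); y2 <- numeric(n_cells)

  dt <- p$dt
  stopifnot(dt <= ap$t_e / 5 + 1e-12)
  n_steps <- ceiling(p$t_end / dt)
  ops <- make_diffusion_ops(grid, dt)
  snap_every <- max(1L, floor(n_steps / snapshots))

  times <- c(); dens <- list(); Ss <- list(); vars <- c(); mean_x <- c()
  clus <- list()
  take_snapshot <- function(k) {
    cts <- deposit(x, grid)
    times <<- c(times, k * dt)
    dens[[length(dens) + 1L]] <<- cts
    Ss[[length(Ss) + 1L]] <<- grid$S
    vars <<- c(vars, stats::var(as.numeric(cts)))
    mean_x <<- c(mean_x, mean(x[, 1]))
    if (scenario %in% c("liquid", "spiral", "swarm_ring"))
      clus[[length(clus) + 1L]] <<- summarize_clusters(cts)
  }
  take_snapshot(0)

  for (k in seq_len(n_steps)) {
    s_loc <- interpolate_field(grid, x, "S")
    up <- exp_update(y1, y2, ap$G(s_loc), dt, ap$t_e, ap$t_a)
    y1 <- up$u1; y2 <- up$u2
    lam <- turning_rate(y1, ap)
    turned <- stats::runif(n_cells) < -expm1(-lam * dt)
    if (any(turned)) heading[turned] <- draw_new_velocity(sum(turned), ap)
    if (N == 2 && ap$omega != 0) heading <- heading - ap$omega * dt
    v <- if (N == 1) cbind(heading)
         else ap$s0 * cbind(cos(heading), sin(heading))
    x <- x + v * dt
    if (periodic) {
      for (d in seq_len(N)) x[, d] <- x[, d] %% extent[d]
    } else {
      for (d in seq_len(N)) {
        over <- x[, d] > extent[d]; under <- x[, d] < 0
        if (any(over)) x[over, d] <- 2 * extent[d] - x[over, d]
        if (any(under)) x[under, d] <- -x[under, d]
        flip <- over | under
        if (any(flip)) {
          if (N == 1) heading[flip] <- -heading[flip]
          else if (d == 1) heading[flip] <- pi - heading[flip]
          else heading[flip] <- -heading[flip]
        }
      }
    }
    grid <- step_field(grid, sources = deposit(x, grid), dt = dt, ops = ops)
    if (k %% snap_every == 0L || k == n_steps) take_snapshot(k)
  }

  structure(list(scenario = scenario, times = times, density = dens, S = Ss,
                 variance = vars, mean_x = mean_x,
                 clusters = if (length(clus)) clus else NULL,
                 params = p, seed = seed, n_cells = n_cells,
                 clamp_count = grid$clamp_count),
            class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("pattern scenario '%s': %d cells, t = %g s\n",
              x$scenario, x$n_cells, max(x$times)))
  cat(sprintf("  density variance %.4g -> %.4g\n",
              x$variance[1], x$variance[length(x$variance)]))
  invisible(x)
}

#' Default parameters for the pattern scenarios
#'
#' Desk-scale defaults: domains of a few hundred micrometres and a few
#' hundred to ~1500 cells, chosen so each scenario exhibits its
#' characteristic behaviour (aggregation instability, ring spreading,
#' constant-speed band) within a few simulated minutes.  All values may be
#' overridden.
#'
#' @param scenario scenario name.
#' @return Named list of parameters.
#' @export
pattern_defaults <- function(scenario = c("liquid", "swarm_ring", "adler",
                                          "spiral")) {
  scenario <- match.arg(scenario)
  base <- list(
    s0 = 20, lambda0 = 1, gamma0 = 0.25, t_e = 0.1, t_a = 5,
    dt = 0.02, omega = 0.4
  )
  sc <- switch(scenario,
    liquid = list(nx = 32, dx = 20, n_cells = 1200, t_end = 200,
                  D_s = 100, gamma = 25, mu = 0.02),
    spiral = list(nx = 32, dx = 20, n_cells = 1200, t_end = 200,
                  D_s = 100, gamma = 25, mu = 0.02),
    swarm_ring = list(nx = 32, dx = 20, n_cells = 800, t_end = 150,
                      D_s = 100, D_f = 400, gamma = 25, k = 20, mu = 0.02,
                      inoculum_width = 60),
    adler = list(nx = 200, dx = 20, n_cells = 400, t_end = 600,
                 D_s = 200, gamma = 0.004, inoculum_width = 200)
  )
  c(base, sc)
}

# Aggregate (connected high-density component) count and sizes:
# nodes above `thresh` times the mean count, 4-connected, periodic wrap.
summarize_clusters <- function(counts, thresh = 2) {
  m <- as.matrix(counts)
  hot <- m > thresh * mean(m)
  if (!any(hot)) return(list(n_clusters = 0L, sizes = integer(0)))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(hot)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    sz <- 0L
    while (length(queue)) {
      id <- queue[[1]]; queue <- queue[-1]
      if (lab[id] != 0L || !hot[id]) next
      lab[id] <- cur
      sz <- sz + 1L
      i <- (id - 1L) %% nr + 1L
      j <- (id - 1L) %/% nr + 1L
      nb_i <- c(i %% nr + 1L, (i - 2L) %% nr + 1L, i, i)
      nb_j <- c(j, j, j %% nc + 1L, (j - 2L) %% nc + 1L)
      nb <- (nb_j - 1L) * nr + nb_i
      queue <- c(queue, nb[hot[nb] & lab[nb] == 0L])
    }
    sizes <- c(sizes, sz)
  }
  list(n_clusters = cur, sizes = sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
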