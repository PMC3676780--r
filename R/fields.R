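#' Discretised chemical field(s) on a rectangular lattice
#'
#' Holds one or two concentration layers on a regular grid: `S`, the
#' attractant (secreted by cells, or consumed in the consumed-signal
#' variant), and optionally `F`, a nutrient consumed by cells.  Dynamics
#' per layer are diffusion plus pointwise reaction:
#' \deqn{\partial S/\partial t = D_s \Delta S +
#'   \gamma \sum_i \delta(x - x_i) - \mu S, \qquad
#'   \partial F/\partial t = D_f \Delta F - k \sum_i \delta(x - x_i),}
#' with the delta sources spread onto the lattice by cloud-in-cell
#' weights.  The degradation term is first-order decay.  In the
#' consumed-signal (traveling-band) variant, `mode = "consumption"`, the
#' `gamma` term is a sink on `S` and the initial condition is uniform
#' `S = S0`.
#'
#' Grid nodes sit at `(i - 1) * dx`; under periodic boundaries the domain
#' length is `nx * dx`, under no-flux it is `(nx - 1) * dx`.
#'
#' @param nx,ny number of nodes per dimension; omit `ny` for 1-D.
#' @param dx lattice spacing (um, > 0).
#' @param D_s attractant diffusion coefficient (um^2/s).
#' @param D_f nutrient diffusion coefficient; `NULL` for no nutrient layer.
#' @param gamma per-cell secretion rate of S (concentration * um^N / s), or
#'   consumption rate in `"consumption"` mode.
#' @param k per-cell nutrient consumption rate.
#' @param mu attractant degradation rate (1/s).
#' @param boundary `"periodic"` or `"noflux"`.
#' @param S0,F0 initial uniform levels (or full arrays).
#' @param mode `"secretion"` (default) or `"consumption"`.
#' @return Object of class `field_grid`.
#' @export
field_grid <- function(nx, ny = NULL, dx, D_s, D_f = NULL,
                       gamma = 0, k = 0, mu = 0,
                       boundary = c("periodic", "noflux"),
                       S0 = 0, F0 = 0,
                       mode = c("secretion", "consumption")) {
  boundary <- match.arg(boundary)
  mode <- match.arg(mode)
  check_positive(dx, "dx")
  stopifnot(nx >= 3, is.null(ny) || ny >= 3)
  dims <- if (is.null(ny)) nx else c(nx, ny)
  mk <- function(v) {
    if (length(v) == 1) array(v, dims) else {
      stopifnot(all(dim(as.array(v)) == dims) || length(v) == prod(dims))
      array(v, dims)
    }
  }
  g <- list(nx = nx, ny = ny, dx = dx, dims = dims, ndim = length(dims),
            D_s = D_s, D_f = D_f, gamma = gamma, k = k, mu = mu,
            boundary = boundary, mode = mode,
            S = mk(S0),
            F = if (!is.null(D_f)) mk(F0) else NULL,
            clamp_count = 0L)
  class(g) <- "field_grid"
  g
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("field grid: %s nodes, dx = %g um, %s BC, mode = %s\n",
              paste(x$dims, collapse = " x "), x$dx, x$boundary, x$mode))
  cat(sprintf("  total S mass = %g%s\n", sum(x$S) * x$dx^x$ndim,
              if (!is.null(x$F)) sprintf(", total F mass = %g",
                                         sum(x$F) * x$dx^x$ndim) else ""))
  invisible(x)
}

# Cloud-in-cell index/weight pairs for positions along one axis.
# Returns node indices (i, i+1 wrapped/clamped) and weights (1-w, w).
.cic_axis <- function(pos, n, dx, periodic) {
  u <- pos / dx
  if (periodic) {
    u <- u %% n
    i0 <- floor(u)
    w <- u - i0
    list(i1 = as.integer(i0 %% n) + 1L,
         i2 = as.integer((i0 + 1) %% n) + 1L,
         w1 = 1 - w, w2 = w)
  } else {
    if (any(pos < -1e-9) || any(pos > (n - 1) * dx + 1e-9))
      stop_invalid("cell position outside the domain")
    u <- pmin(pmax(u, 0), n - 1)
    i0 <- pmin(floor(u), n - 2)
    w <- u - i0
    list(i1 = as.integer(i0) + 1L, i2 = as.integer(i0) + 2L,
         w1 = 1 - w, w2 = w)
  }
}

#' Deposit unit cell masses onto the grid
#'
#' Spreads each cell's unit mass to the surrounding nodes by linear
#' (1-D) or bilinear (2-D) cloud-in-cell weights.  The per-node weights
#' sum to the cell count exactly; the solver converts them to a
#' concentration source by dividing by the node volume `dx^N`.
#'
#' @param x cell positions: numeric vector (1-D) or n x 2 matrix (2-D).
#' @param grid a [field_grid()].
#' @return Array of node weights with `sum(result) == nrow(x)`.
#' @examples
#' g <- field_grid(nx = 8, dx = 10, D_s = 100)
#' sum(deposit(35, g))  # exactly 1
#' @export
deposit <- function(x, grid) {
  stopifnot(inherits(grid, "field_grid"))
  x <- if (grid$ndim == 1) matrix(x, ncol = 1) else as.matrix(x)
  stopifnot(ncol(x) == grid$ndim)
  per <- grid$boundary == "periodic"
  out <- array(0, grid$dims)
  ax <- .cic_axis(x[, 1], grid$nx, grid$dx, per)
  if (grid$ndim == 1) {
    inc <- function(i, w) {
      agg <- rowsum(w, i)
      out[as.integer(rownames(agg))] <<- out[as.integer(rownames(agg))] + agg[, 1]
    }
    inc(ax$i1, ax$w1); inc(ax$i2, ax$w2)
  } else {
    ay <- .cic_axis(x[, 2], grid$ny, grid$dx, per)
    inc <- function(i, j, w) {
      idx <- (j - 1L) * grid$nx + i
      agg <- rowsum(w, idx)
      out[as.integer(rownames(agg))] <<- out[as.integer(rownames(agg))] + agg[, 1]
    }
    inc(ax$i1, ay$i1, ax$w1 * ay$w1)
    inc(ax$i2, ay$i1, ax$w2 * ay$w1)
    inc(ax$i1, ay$i2, ax$w1 * ay$w2)
    inc(ax$i2, ay$i2, ax$w2 * ay$w2)
  }
  out
}

#' Sample a field at cell positions
#'
#' Interpolates a concentration layer at off-lattice positions with the
#' same cloud-in-cell weights as [deposit()], making the pair an exact
#' transpose (adjoint) of one another.
#'
#' @inheritParams deposit
#' @param layer `"S"` or `"F"`.
#' @return Numeric vector of sampled concentrations.
#' @export
interpolate_field <- function(grid, x, layer = c("S", "F")) {
  stopifnot(inherits(grid, "field_grid"))
  layer <- match.arg(layer)
  fld <- grid[[layer]]
  if (is.null(fld)) stop_invalid("grid has no %s layer", layer)
  x <- if (grid$ndim == 1) matrix(x, ncol = 1) else as.matrix(x)
  per <- grid$boundary == "periodic"
  ax <- .cic_axis(x[, 1], grid$nx, grid$dx, per)
  if (grid$ndim == 1) {
    fld[ax$i1] * ax$w1 + fld[ax$i2] * ax$w2
  } else {
    ay <- .cic_axis(x[, 2], grid$ny, grid$dx, per)
    fld[cbind(ax$i1, ay$i1)] * ax$w1 * ay$w1 +
      fld[cbind(ax$i2, ay$i1)] * ax$w2 * ay$w1 +
      fld[cbind(ax$i1, ay$i2)] * ax$w1 * ay$w2 +
      fld[cbind(ax$i2, ay$i2)] * ax$w2 * ay$w2
  }
}

# 1-D discrete Laplacian (dimensionless, spacing 1) as a sparse symmetric
# matrix; zero column sums under both BCs, so diffusion conserves mass.
.laplacian_1d <- function(n, periodic) {
  i <- c(seq_len(n), seq_len(n - 1), 2:n)
  j <- c(seq_len(n), 2:n, seq_len(n - 1))
  v <- c(rep(-2, n), rep(1, n - 1), rep(1, n - 1))
  if (periodic) {
    i <- c(i, 1, n); j <- c(j, n, 1); v <- c(v, 1, 1)
  } else {
    v[1] <- -1; v[n] <- -1  # reflecting ghost nodes
  }
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n, n), symmetric = FALSE)
}

#' Precompute Crank--Nicolson diffusion operators
#'
#' Factorises the implicit operator once so repeated [step_field()] calls
#' in a simulation loop amortise the cost.  In 1-D a full Crank--Nicolson
#' step is used; in 2-D the step is split by alternating direction
#' (Peaceman--Rachford), one implicit half-step per axis.  Both variants
#' conserve total mass to solver precision under periodic and no-flux
#' boundaries.
#'
#' @param grid a [field_grid()].
#' @param dt time step (s).
#' @return An opaque list of factorised operators, to pass to
#'   [step_field()] as `ops`.
#' @export
make_diffusion_ops <- function(grid, dt) {
  stopifnot(inherits(grid, "field_grid"))
  check_positive(dt, "dt")
  per <- grid$boundary == "periodic"
  one_layer <- function(D) {
    if (is.null(D)) return(NULL)
    if (grid$ndim == 1) {
      L <- .laplacian_1d(grid$nx, per)
      r <- D * dt / (2 * grid$dx^2)
      A <- Matrix::Diagonal(grid$nx) - r * L
      B <- Matrix::Diagonal(grid$nx) + r * L
      list(ndim = 1, A = Matrix::lu(A), B = B)
    } else {
      # Peaceman-Rachford: r for a half-step in each direction
      r <- D * dt / (2 * grid$dx^2)
      Lx <- .laplacian_1d(grid$nx, per)
      Ly <- .laplacian_1d(grid$ny, per)
      list(ndim = 2,
           Ax = Matrix::lu(Matrix::Diagonal(grid$nx) - r * Lx),
           Bx = Matrix::Diagonal(grid$nx) + r * Lx,
           Ay = Matrix::lu(Matrix::Diagonal(grid$ny) - r * Ly),
           By = Matrix::Diagonal(grid$ny) + r * Ly)
    }
  }
  list(dt = dt, S = one_layer(grid$D_s), F = one_layer(grid$D_f))
}

.diffuse <- function(field, op) {
  if (op$ndim == 1) {
    as.numeric(Matrix::solve(op$A, op$B %*% field))
  } else {
    # x-implicit half step (y explicit), then y-implicit half step
    star <- as.matrix(Matrix::solve(op$Ax, field %*% Matrix::t(op$By)))
    t(as.matrix(Matrix::solve(op$Ay, t(as.matrix(op$Bx %*% star)))))
  }
}

#' Advance the chemical fields one step
#'
#' One operator-split step: implicit (alternating-direction) diffusion,
#' then pointwise reaction.  In `"secretion"` mode the attractant gains
#' `gamma * sources / dx^N * dt` and decays at rate `mu`; in
#' `"consumption"` mode the `gamma` term is a sink.  The nutrient layer,
#' when present, loses `k * sources / dx^N * dt`.  Any negative
#' concentrations produced by a sink are clamped to zero; the clamped-node
#' count accumulates in `clamp_count` and a warning is emitted on the
#' first occurrence per grid.
#'
#' @param grid a [field_grid()].
#' @param sources node weights from [deposit()] (or `NULL` for none).
#' @param dt time step (s).
#' @param ops operators from [make_diffusion_ops()] (built on the fly if
#'   omitted; precompute for loops).
#' @return The updated `field_grid`.
#' @examples
#' g <- field_grid(nx = 32, dx = 10, D_s = 100, mu = 0.1, S0 = 1)
#' g <- step_field(g, sources = NULL, dt = 0.1)
#' @export
step_field <- function(grid, sources = NULL, dt, ops = NULL) {
  stopifnot(inherits(grid, "field_grid"))
  check_positive(dt, "dt")
  if (is.null(ops)) ops <- make_diffusion_ops(grid, dt)
  if (abs(ops$dt - dt) > 1e-12) stop_invalid("ops were built for dt = %g", ops$dt)
  vol <- grid$dx^grid$ndim
  src <- if (is.null(sources)) 0 else sources / vol

  S <- array(.diffuse(grid$S, ops$S), grid$dims)
  if (grid$mode == "secretion") {
    if (grid$mu > 0) {
      # exact integrating-factor update of dS/dt = gamma*src - mu*S
      ef <- exp(-grid$mu * dt)
      S <- S * ef + grid$gamma * src / grid$mu * (1 - ef)
    } else {
      S <- S + dt * grid$gamma * src
    }
  } else {
    S <- S - dt * grid$gamma * src
  }
  n_neg <- sum(S < 0)
  if (n_neg > 0) {
    if (grid$clamp_count == 0L)
      warning("negative concentrations clamped to 0 (sink exceeded local mass)")
    grid$clamp_count <- grid$clamp_count + n_neg
    S[S < 0] <- 0
  }
  if (any(!is.finite(S)))
    stop("field solver produced non-finite values; reduce dt", call. = FALSE)
  grid$S <- S

  if (!is.null(grid$F)) {
    F_ <- array(.diffuse(grid$F, ops$F), grid$dims)
    F_ <- F_ - dt * grid$k * src
    nn <- sum(F_ < 0)
    if (nn > 0) {
      grid$clamp_count <- grid$clamp_count + nn
      F_[F_ < 0] <- 0
    }
    grid$F <- F_
  }
  grid
}
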