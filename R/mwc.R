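#' Free-energy parameters of a trimer of receptor dimers
#'
#' The core signalling unit of the chemoreceptor array is a trimer of
#' receptor homodimers.  Under the two-state (Monod--Wyman--Changeux)
#' description, a trimer at a fixed methylation level is either active (on)
#' or inactive (off) and can bind 0--3 ligand molecules, giving eight
#' free-energy levels.  The ligand-free levels are `E_on` (which depends on
#' the methylation label) and `E_off` (taken independent of methylation:
#' only the offset between the two ladders matters).  Successive ligand
#' bindings lower the level of state x by `log(3 L / Kd1_x)`,
#' `log(3 L^2 / (Kd1_x Kd2_x))` and `log(L^3 / (Kd1_x Kd2_x Kd3_x))`, the
#' 3, 3, 1 factors being the degeneracies of a three-site binding
#' polynomial.  All energies are in units of kB*T; concentrations share the
#' units of the dissociation constants.
#'
#' For an attractant, binding deactivates the kinase, so the inactive state
#' binds more tightly: `Kd_off < Kd_on` componentwise.  That convention
#' makes dose-response curves decreasing in ligand concentration.
#'
#' @param E_on active-state ligand-free free energy (kB*T).
#' @param E_off inactive-state ligand-free free energy (kB*T), default 0.
#' @param Kd_on numeric length-3 vector of sequential dissociation constants
#'   of the active state (concentration units), all > 0.
#' @param Kd_off numeric length-3 vector for the inactive state, all > 0.
#' @param receptor_type label, e.g. `"Tar"` or `"Tsr"`.
#' @param methylation methylation-level label, e.g. `"QEQE"`; a fixed label
#'   selecting a parameter set (no methylation kinetics are modelled).
#' @return Object of class `trimer_params`.
#' @examples
#' tp <- trimer_params(E_on = -6, Kd_on = rep(0.5, 3), Kd_off = rep(0.02, 3))
#' p_on_trimer(tp, L = c(0, 0.1, 1))
#' @export
trimer_params <- function(E_on, E_off = 0, Kd_on, Kd_off,
                          receptor_type = "Tar", methylation = "QEQE") {
  check_finite(c(E_on, E_off), "free energies")
  stopifnot(length(Kd_on) == 3, length(Kd_off) == 3)
  check_positive(Kd_on, "Kd_on")
  check_positive(Kd_off, "Kd_off")
  structure(list(E_on = E_on, E_off = E_off,
                 Kd_on = as.numeric(Kd_on), Kd_off = as.numeric(Kd_off),
                 receptor_type = receptor_type, methylation = methylation),
            class = "trimer_params")
}

#' @export
print.trimer_params <- function(x, ...) {
  cat(sprintf("%s trimer (%s): E_on - E_off = %g kBT\n",
              x$receptor_type, x$methylation, x$E_on - x$E_off))
  cat(sprintf("  Kd_on  = %s\n", paste(signif(x$Kd_on, 4), collapse = ", ")))
  cat(sprintf("  Kd_off = %s\n", paste(signif(x$Kd_off, 4), collapse = ", ")))
  invisible(x)
}

#' Default trimer parameter sets
#'
#' Documented default parameters for Tar and Tsr trimers at the three
#' canonical methylation labels.  The exact values behind published
#' dose-response families are not available here, so these are order-of-
#' magnitude choices obeying the qualitative constraints: tighter binding to
#' the inactive state (attractant convention), ligand-free activity ordered
#' EEEE < QEQE < QQQQ, and sensitivity decreasing (effective K increasing)
#' with methylation.  All values can be overridden via [trimer_params()].
#'
#' @param receptor_type `"Tar"` or `"Tsr"`.
#' @param methylation `"EEEE"`, `"QEQE"` or `"QQQQ"`.
#' @return A [trimer_params()] object.
#' @export
default_trimer_params <- function(receptor_type = c("Tar", "Tsr"),
                                  methylation = c("QEQE", "EEEE", "QQQQ")) {
  receptor_type <- match.arg(receptor_type)
  methylation <- match.arg(methylation)
  base <- switch(receptor_type,
                 Tar = list(k_off = 0.02, k_on = 0.5),
                 Tsr = list(k_off = 0.01, k_on = 0.3))
  scale <- switch(methylation, EEEE = 0.3, QEQE = 1, QQQQ = 3)
  E_on <- switch(methylation, EEEE = 1, QEQE = -2, QQQQ = -6)
  trimer_params(E_on = E_on, E_off = 0,
                Kd_on = rep(base$k_on * scale, 3),
                Kd_off = rep(base$k_off * scale, 3),
                receptor_type = receptor_type, methylation = methylation)
}

#' Composition of a coupled receptor cluster
#'
#' A strongly coupled cluster of `n_a` Tar trimers and `n_s` Tsr trimers.
#' Under the approximation that only pure-type trimers exist, the cluster
#' free-energy difference is the sum of the per-trimer differences, so the
#' cluster switches as one unit.
#'
#' @param n_a number of Tar trimers (integer >= 0).
#' @param n_s number of Tsr trimers (integer >= 0); `n_a + n_s >= 1`.
#' @param tar,tsr [trimer_params()] for each type.
#' @return Object of class `cluster_spec`.
#' @export
cluster_spec <- function(n_a, n_s,
                         tar = default_trimer_params("Tar"),
                         tsr = default_trimer_params("Tsr")) {
  if (n_a != round(n_a) || n_s != round(n_s) || n_a < 0 || n_s < 0)
    stop_invalid("n_a and n_s must be non-negative integers")
  if (n_a + n_s < 1) stop_invalid("cluster needs at least one trimer")
  stopifnot(inherits(tar, "trimer_params"), inherits(tsr, "trimer_params"))
  structure(list(n_a = as.integer(n_a), n_s = as.integer(n_s),
                 tar = tar, tsr = tsr),
            class = "cluster_spec")
}

#' The eight free-energy levels of a trimer
#'
#' Tabulates the free-energy ladder of a pure-type trimer of dimers at
#' ligand concentration `L`.  At `L = 0` the ligand-bound levels are
#' unoccupied; they are reported with `energy = Inf` and Boltzmann
#' `weight = 0` rather than as finite numbers.
#'
#' @param trimer a [trimer_params()].
#' @param L ligand concentration (scalar, >= 0).
#' @return A data.frame with columns `state` ("on"/"off"), `n_bound`
#'   (0--3), `energy` (kB*T) and `weight` (unnormalised Boltzmann weight
#'   `exp(-energy)`).
#' @examples
#' free_energy_levels(trimer_params(0, 0, rep(1, 3), rep(1, 3)), L = 1)
#' @export
free_energy_levels <- function(trimer, L) {
  stopifnot(inherits(trimer, "trimer_params"), length(L) == 1)
  if (!is.finite(L) || L < 0) stop_invalid("L must be a finite value >= 0")
  lev <- function(E0, Kd) {
    # log binding-term for 1..3 ligands bound; -Inf weight at L = 0
    lt <- c(log(3) + log(L) - log(Kd[1]),
            log(3) + 2 * log(L) - log(Kd[1]) - log(Kd[2]),
            3 * log(L) - sum(log(Kd)))
    c(E0, E0 - lt)
  }
  e <- c(lev(trimer$E_on, trimer$Kd_on), lev(trimer$E_off, trimer$Kd_off))
  data.frame(
    state = rep(c("on", "off"), each = 4),
    n_bound = rep(0:3, 2),
    energy = e,
    weight = exp(-e)
  )
}

# log of the three-site binding polynomial
#   P(L) = 1 + 3 L/K1 + 3 L^2/(K1 K2) + L^3/(K1 K2 K3),
# computed in log space so very large L cannot overflow.
.log_binding_poly <- function(L, Kd) {
  lk <- log(Kd)
  vapply(L, function(l) {
    if (l == 0) return(0)
    ll <- log(l)
    logsumexp(c(0,
                log(3) + ll - lk[1],
                log(3) + 2 * ll - lk[1] - lk[2],
                3 * ll - sum(lk)))
  }, numeric(1))
}

#' Free-energy difference of a trimer
#'
#' \deqn{\Delta f(L) = E_{on} - E_{off} +
#'   \log\left[P_{off}(L) / P_{on}(L)\right]}
#' where \eqn{P_x(L) = 1 + 3L/K_{1,x} + 3L^2/(K_{1,x}K_{2,x}) +
#' L^3/(K_{1,x}K_{2,x}K_{3,x})} is the binding polynomial of state x.
#' Positive \eqn{\Delta f} favours the inactive state.
#'
#' @param trimer a [trimer_params()].
#' @param L ligand concentration(s) (>= 0), vectorised.
#' @return \eqn{\Delta f} in kB*T, same length as `L`.
#' @export
delta_f <- function(trimer, L) {
  stopifnot(inherits(trimer, "trimer_params"))
  if (any(!is.finite(L)) || any(L < 0)) stop_invalid("L must be finite and >= 0")
  trimer$E_on - trimer$E_off +
    .log_binding_poly(L, trimer$Kd_off) - .log_binding_poly(L, trimer$Kd_on)
}

#' Activity of a single trimer
#'
#' Equilibrium probability that the trimer is active,
#' \eqn{p_{on} = 1/(1 + e^{\Delta f})}; identical to the Boltzmann
#' partition-sum ratio over the eight free-energy levels.
#'
#' @inheritParams delta_f
#' @return Activity probability in (0, 1), vectorised over `L`.
#' @export
p_on_trimer <- function(trimer, L) {
  stats::plogis(-delta_f(trimer, L))
}

#' Activity of a cluster of n identical trimers
#'
#' The cluster free energy is linear in the number of trimers, so
#' \eqn{p_{on} = 1/(1 + e^{n\Delta f})}.  Coupling n trimers sharpens the
#' response: the fitted Hill coefficient grows with n.
#'
#' @param n number of coupled trimers (integer >= 1).
#' @inheritParams delta_f
#' @return Activity probability, vectorised over `L`.
#' @export
p_on_cluster <- function(n, trimer, L) {
  if (length(n) != 1 || n != round(n) || n < 1)
    stop_invalid("n must be a single integer >= 1")
  stats::plogis(-n * delta_f(trimer, L))
}

#' Activity of a mixed Tar/Tsr cluster
#'
#' \eqn{p_{on} = 1/(1 + e^{n_a \Delta f_a + n_s \Delta f_s})}.  Only
#' single-ligand protocols are supported: the ligand binds one receptor
#' type, and the other type contributes its ligand-free \eqn{\Delta f} as a
#' constant offset.
#'
#' @param spec a [cluster_spec()].
#' @param L ligand concentration(s) (>= 0), vectorised.
#' @param ligand_target `"Tar"` or `"Tsr"`: which receptor type binds the
#'   ligand.
#' @return Activity probability, vectorised over `L`.
#' @export
p_on_mixed <- function(spec, L, ligand_target = c("Tar", "Tsr")) {
  stopifnot(inherits(spec, "cluster_spec"))
  ligand_target <- match.arg(ligand_target)
  df_a <- if (ligand_target == "Tar") delta_f(spec$tar, L)
          else delta_f(spec$tar, 0)
  df_s <- if (ligand_target == "Tsr") delta_f(spec$tsr, L)
          else delta_f(spec$tsr, 0)
  stats::plogis(-(spec$n_a * df_a + spec$n_s * df_s))
}

#' Tabulate a dose-response curve
#'
#' Evaluates cluster (or single-trimer) activity over a grid of ligand
#' concentrations.
#'
#' @param spec a [trimer_params()] or a [cluster_spec()].
#' @param L increasing grid of ligand concentrations (>= 20 points
#'   recommended, spanning the transition).
#' @param n for a `trimer_params` spec, the number of coupled trimers
#'   (default 1).
#' @param ligand_target for a `cluster_spec`, which type binds the ligand.
#' @return A data.frame of class `dose_response` with columns `L`, `p_on`.
#' @examples
#' tp <- trimer_params(E_on = -6, Kd_on = rep(0.5, 3), Kd_off = rep(0.02, 3))
#' dr <- dose_response(tp, L = 10^seq(-3, 2, length.out = 50), n = 6)
#' @export
dose_response <- function(spec, L, n = 1, ligand_target = "Tar") {
  if (length(L) == 0) stop_invalid("empty ligand grid")
  if (is.unsorted(L, strictly = TRUE)) stop_invalid("L grid must be increasing")
  p <- if (inherits(spec, "cluster_spec")) {
    p_on_mixed(spec, L, ligand_target)
  } else if (inherits(spec, "trimer_params")) {
    p_on_cluster(n, spec, L)
  } else {
    stop_invalid("spec must be trimer_params or cluster_spec")
  }
  structure(data.frame(L = L, p_on = p),
            class = c("dose_response", "data.frame"))
}
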