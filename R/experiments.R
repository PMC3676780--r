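#' Canonical scenario fixtures
#'
#' Fully specified, self-contained scenarios with pinned seeds and
#' parameters, covering the canonical single-cell and population
#' computations: single and repeated step responses of the
#' excitation--adaptation model, dose-response families of receptor
#' clusters at varied expression level, methylation-state families,
#' pattern formation (liquid aggregation, swarm ring, consumed-signal
#' band, surface spiral), and the agent-vs-continuum comparison.
#'
#' Expression multipliers map to cluster size as
#' `n = max(1, round(base_n * multiplier))` with the base size stored in
#' the scenario (1 for the Tar-only family, 6 for the strongly coupled
#' Tsr family); the mapping is a modelling convenience, not a measured
#' stoichiometry.
#'
#' @param name one of the names returned by [list_fixtures()].
#' @return Object of class `scenario`: list with `name`, `module`,
#'   `params`, `seed`.
#' @examples
#' sc <- make_fixture("cartoon_step")
#' summ <- run_scenario(sc)
#' @export
make_fixture <- function(name) {
  fx <- .fixtures()
  if (!name %in% names(fx))
    stop_invalid("unknown scenario '%s'; valid names: %s",
                 name, paste(names(fx), collapse = ", "))
  structure(c(list(name = name), fx[[name]]), class = "scenario")
}

#' List the canonical scenario names
#' @return Character vector of fixture names.
#' @export
list_fixtures <- function() names(.fixtures())

.fixtures <- function() {
  list(
    cartoon_step = list(
      module = "cartoon", seed = 1,
      params = list(tau_e = 0.1, tau_a = 10, s0 = 1, dt = 0.005, t_end = 200)),
    cartoon_double_step = list(
      module = "cartoon", seed = 1,
      params = list(tau_e = 0.1, tau_a = 10, s0 = 1, gap = 200,
                    dt = 0.005, t_end = 400)),
    dose_response_tar_family = list(
      module = "mwc", seed = 1,
      params = list(receptor = "Tar", base_n = 1, multipliers = c(1, 2, 6),
                    L = 10^seq(-4, 2, length.out = 120))),
    dose_response_tsr_family = list(
      module = "mwc", seed = 1,
      params = list(receptor = "Tsr", base_n = 6, multipliers = c(0.3, 0.7, 5),
                    L = 10^seq(-5, 2, length.out = 400))),
    dose_response_mixed = list(
      module = "mwc_mixed", seed = 1,
      params = list(n_s = 6, tar_multipliers = c(0, 0.6, 1, 2, 6), base_n = 1,
                    L = 10^seq(-4, 2, length.out = 120))),
    dose_response_tsr_methylation = list(
      module = "mwc_methylation", seed = 1,
      params = list(n = 6, methylation = c("EEEE", "QEQE", "QQQQ"),
                    L = 10^seq(-5, 3, length.out = 300))),
    pattern_liquid = list(
      module = "pattern", seed = 7,
      pattern = list(type = "liquid", overrides = list())),
    pattern_swarm_ring = list(
      module = "pattern", seed = 7,
      pattern = list(type = "swarm_ring", overrides = list())),
    pattern_spiral = list(
      module = "pattern", seed = 7,
      pattern = list(type = "spiral", overrides = list())),
    pattern_adler = list(
      module = "pattern", seed = 7,
      pattern = list(type = "adler", overrides = list())),
    agents_vs_continuum = list(
      module = "pks", seed = 1,
      params = list(s0 = 20, lambda0 = 1, b = 4, t_a = 5, t_e = 0.1,
                    n_cells = 1e4, domain = c(0, 4000), peak = 2000,
                    s_max = 1, t_end = 200, times = c(50, 100, 200),
                    bins = 40))
  )
}

#' Execute a scenario and collect a machine-readable summary
#'
#' Runs the scenario's computation and returns (and optionally writes) a
#' summary of its key statistics: peak responses and adaptation checks for
#' step scenarios, Hill fits for dose-response families, variance/front
#' statistics for pattern scenarios, and L1 discrepancies for the
#' agent-vs-continuum comparison.  Identical seeds give identical
#' summaries.
#'
#' @param scenario a [make_fixture()] result (or a name passed through it).
#' @param out_dir optional directory: writes `summary.json` plus CSV
#'   outputs (trajectories or dose-response tables).
#' @return A named list (the summary), invisibly also written to disk when
#'   `out_dir` is given.
#' @export
run_scenario <- function(scenario, out_dir = NULL) {
  if (is.character(scenario)) scenario <- make_fixture(scenario)
  stopifnot(inherits(scenario, "scenario"))
  p <- scenario$params
  csvs <- list()

  summ <- switch(scenario$module,
    cartoon = {
      cp <- cartoon_params(p$tau_e, p$tau_a)
      proto <- if (scenario$name == "cartoon_double_step") {
        stimulus_protocol(c(0, p$gap), c(p$gap, Inf), c(p$s0, 2 * p$s0))
      } else {
        stimulus_protocol(0, Inf, p$s0)
      }
      tr <- integrate_cartoon(cp, proto, dt = p$dt, t_end = p$t_end)
      csvs$trajectory <- tr
      out <- list(peak_u1 = max(tr$u1),
                  t_peak = tr$t[which.max(tr$u1)],
                  u1_final = tr$u1[nrow(tr)],
                  adapted = abs(tr$u1[nrow(tr)]) < 1e-6)
      if (scenario$name == "cartoon_double_step") {
        first <- tr$t < p$gap
        out$peak_u1_step1 <- max(tr$u1[first])
        out$peak_u1_step2 <- max(tr$u1[!first])
      }
      out
    },
    mwc = {
      fits <- lapply(p$multipliers, function(m) {
        n <- max(1L, as.integer(round(p$base_n * m)))
        dr <- dose_response(default_trimer_params(p$receptor), p$L, n = n)
        csvs[[sprintf("dose_response_x%g", m)]] <<- dr
        f <- fit_hill(dr)
        list(multiplier = m, n_trimers = n, n_H = f$n_H, K_half = f$K_half,
             class = cooperativity_class(f))
      })
      list(receptor = p$receptor, fits = fits)
    },
    mwc_mixed = {
      amps <- lapply(p$tar_multipliers, function(m) {
        n_a <- as.integer(round(p$base_n * m))
        spec <- cluster_spec(max(n_a, 0), p$n_s)
        pr <- if (n_a == 0) p_on_mixed(cluster_spec(0, p$n_s), p$L, "Tar")
              else p_on_mixed(spec, p$L, "Tar")
        csvs[[sprintf("mixed_tar_x%g", m)]] <<-
          data.frame(L = p$L, p_on = pr)
        list(multiplier = m, n_a = n_a,
             amplitude = max(pr) - min(pr), p_on_basal = pr[1])
      })
      list(n_s = p$n_s, responses = amps)
    },
    mwc_methylation = {
      fits <- lapply(p$methylation, function(m) {
        dr <- dose_response(default_trimer_params("Tsr", m), p$L, n = p$n)
        csvs[[sprintf("tsr_%s", m)]] <<- dr
        f <- tryCatch(fit_hill(dr), error = function(e) NULL)
        list(methylation = m, p_on_basal = dr$p_on[1],
             n_H = if (is.null(f)) NA else f$n_H,
             K_half = if (is.null(f)) NA else f$K_half)
      })
      list(n_trimers = p$n, fits = fits)
    },
    pattern = {
      res <- run_pattern_scenario(scenario)
      last <- length(res$times)
      out <- list(scenario = res$scenario,
                  t_end = res$times[last],
                  variance_initial = res$variance[1],
                  variance_final = res$variance[last],
                  variance_ratio = res$variance[last] / res$variance[1])
      if (!is.null(res$clusters))
        out$n_clusters_final <- res$clusters[[last]]$n_clusters
      if (res$scenario == "adler") {
        w <- res$times >= max(res$times) / 2
        fit <- stats::lm(res$mean_x[w] ~ res$times[w])
        out$front_speed <- unname(stats::coef(fit)[2])
        out$front_r2 <- summary(fit)$r.squared
      }
      csvs$variance <- data.frame(t = res$times, variance = res$variance,
                                  mean_x = res$mean_x)
      out
    },
    pks = {
      ap <- agent_params(s0 = p$s0, lambda0 = p$lambda0,
                         gamma0 = p$lambda0 / p$b, t_e = p$t_e, t_a = p$t_a,
                         dim = 1)
      co <- pks_coefficients(p$s0, p$lambda0, b_from_turning_rate(ap),
                             p$t_a, p$t_e, N = 1)
      S <- local({
        pk <- p$peak; sm <- p$s_max; dom <- p$domain
        function(x) sm * pmax(0, 1 - abs(x - pk) / (pk - dom[1]))
      })
      cmp <- compare_agents_to_pks(ap, co, S, domain = p$domain,
                                   n_cells = p$n_cells, t_end = p$t_end,
                                   times = p$times, bins = p$bins,
                                   seed = scenario$seed)
      csvs$comparison <- data.frame(
        t = rep(cmp$times, each = length(cmp$mids)),
        x = rep(cmp$mids, length(cmp$times)),
        agent_density = as.numeric(t(cmp$agent_density)),
        pde_density = as.numeric(t(cmp$pde_density)))
      list(D_n = co$D_n, chi = co$chi,
           times = cmp$times, L1 = cmp$L1, Linf = cmp$Linf,
           gradient_diagnostic = cmp$gradient_diagnostic,
           valid_regime = cmp$valid_regime)
    },
    stop_invalid("scenario module '%s' has no runner", scenario$module)
  )

  summ <- c(list(scenario = scenario$name, seed = scenario$seed), summ)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(csvs))
      utils::write.csv(csvs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  summ
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("scenario '%s' (module %s, seed %d)\n",
              x$name, x$module, x$seed))
  invisible(x)
}

#' Read or write a scenario as YAML
#'
#' Scenario definitions are plain nested lists of scalars, so they
#' round-trip losslessly through YAML for editing and archiving.
#'
#' @param scenario a `scenario` object.
#' @param path file path.
#' @return `write_scenario_yaml` returns `path` invisibly;
#'   `read_scenario_yaml` returns a `scenario`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  structure(yaml::read_yaml(path), class = "scenario")
}
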