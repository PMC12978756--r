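# Idealized arch network and the per-condition analysis pipeline.
#
# The arch is an inlet feeding four Windkessel-terminated branches
# (O1 brachiocephalic, O2 left common carotid, O3 left subclavian,
# O4 descending aorta). Mean-flow fractions are fixed (the flow split is
# prescribed, not pressure-equalizing), so mass is conserved at the
# bifurcation by construction at every instant.

.default_branches <- function() {
  tibble::tibble(
    name = c("O1", "O2", "O3", "O4"),
    label = c("brachiocephalic", "left_carotid", "left_subclavian",
              "descending_aorta"),
    radius = c(0.006, 0.004, 0.004, 0.0105),
    flow_fraction = c(0.15, 0.075, 0.075, 0.70),
    length = 0.05
  )
}

#' Idealized aortic arch network
#'
#' An inlet plus four outlet branches, each carrying a fixed fraction of
#' the inlet flow and terminated by a three-element Windkessel. The default
#' radii (O1 0.006, O2 0.004, O3 0.004, O4 0.0105 m; inlet 0.0125 m), the
#' branch lengths (0.05 m) and the flow fractions (0.15 / 0.075 / 0.075 /
#' 0.70) are documented implementer assumptions at adult-aorta scale, not
#' literature-fixed values; all are configurable.
#'
#' @param inlet_radius Inlet (ascending aorta) radius (m).
#' @param branches A data frame with columns `name`, `radius`,
#'   `flow_fraction` (summing to 1), and optionally `label` and `length`.
#' @param mean_pressure Target mean outlet pressure (Pa) for the Windkessel
#'   estimates; default 13332 Pa (about 100 mmHg).
#' @param tau Diastolic decay constant (s) for the Windkessel estimates.
#' @param waveform A [waveform_params()] object; its mean fixes the mean
#'   inlet flow used in the per-branch resistance estimates.
#' @return An object of class `arch_network`: the branch tibble with a
#'   `windkessel` list-column, plus inlet metadata.
#' @examples
#' net <- make_default_network()
#' net$branches
#' @export
arch_network <- function(inlet_radius = 0.0125, branches = .default_branches(),
                         mean_pressure = 13332, tau = 1.0,
                         waveform = waveform_params()) {
  check_positive(inlet_radius, "inlet_radius")
  check_positive(mean_pressure, "mean_pressure")
  check_positive(tau, "tau")
  if (!is.data.frame(branches) ||
      !all(c("name", "radius", "flow_fraction") %in% names(branches))) {
    abort_invalid("`branches` needs columns name, radius, flow_fraction.")
  }
  check_positive(branches$radius, "branches$radius")
  if (any(branches$flow_fraction <= 0 | branches$flow_fraction >= 1)) {
    abort_invalid("flow fractions must lie in (0, 1).")
  }
  if (abs(sum(branches$flow_fraction) - 1) > 1e-12) {
    abort_invalid("flow fractions must sum to 1 (within 1e-12).")
  }
  branches <- tibble::as_tibble(branches)
  if (is.null(branches$length)) branches$length <- 0.05
  if (is.null(branches$label)) branches$label <- branches$name
  Q_in_mean <- mean_inlet_velocity(waveform) * pi * inlet_radius^2
  branches$windkessel <- purrr::map(branches$flow_fraction, function(f) {
    estimate_windkessel(mean_pressure, f * Q_in_mean, tau)
  })
  structure(list(inlet_radius = inlet_radius, branches = branches,
                 mean_pressure = mean_pressure, tau = tau),
            class = "arch_network")
}

#' @rdname arch_network
#' @export
make_default_network <- function(mean_pressure = 13332, tau = 1.0,
                                 waveform = waveform_params()) {
  arch_network(mean_pressure = mean_pressure, tau = tau, waveform = waveform)
}

#' @export
print.arch_network <- function(x, ...) {
  cat(sprintf("<arch_network: inlet R = %g m, mean pressure %g Pa, tau %g s>\n",
              x$inlet_radius, x$mean_pressure, x$tau))
  print(x$branches[c("name", "label", "radius", "flow_fraction", "length")])
  invisible(x)
}

#' Numerical configuration for the pipeline
#'
#' @param nr Radial nodes per branch (default 101).
#' @param steps_per_cycle Time steps per cardiac cycle (default 1000).
#' @param n_cycles Cycles to integrate (default 8; the last is reported).
#' @param picard_tol Picard relative tolerance.
#' @param max_iter Maximum Picard iterations per step.
#' @return A plain list, validated.
#' @export
pipeline_numerics <- function(nr = 101, steps_per_cycle = 1000, n_cycles = 8,
                              picard_tol = 1e-8, max_iter = 50L) {
  if (nr < 16) abort_invalid("`nr` must be >= 16.")
  if (steps_per_cycle < 16) abort_invalid("`steps_per_cycle` must be >= 16.")
  if (n_cycles < 1) abort_invalid("`n_cycles` must be >= 1.")
  list(nr = as.integer(nr), steps_per_cycle = as.integer(steps_per_cycle),
       n_cycles = as.integer(n_cycles), picard_tol = picard_tol,
       max_iter = as.integer(max_iter))
}

#' Run the arch analysis for one blood condition
#'
#' Drives every branch of the network with its share of the pulsatile inlet
#' flow (`Q_i(t) = flow_fraction_i * v_inlet(t) * pi * R_inlet^2`), solves
#' the radially resolved momentum equation per branch, feeds the branch
#' flow into its Windkessel outlet, and assembles min/avg/max summaries and
#' an illustrative severity classification from the final (periodic) cycle.
#' Branch wall pressure is reported as the Windkessel outlet pressure plus
#' the axial pressure-gradient contribution over the branch length.
#'
#' The pipeline contains no random numbers: identical inputs give
#' bitwise-identical outputs.
#'
#' @param condition A condition name (see [blood_conditions()]) or a
#'   [rheology_params()] object.
#' @param network An [arch_network()].
#' @param waveform A [waveform_params()].
#' @param numerics A [pipeline_numerics()] list.
#' @param wss_bands,pressure_bands Severity bands, defaulting to
#'   [severity_bands()].
#' @return An object of class `arch_report` with elements `condition`,
#'   `traces` (last-cycle tibble: `branch`, `t`, `ubar`, `Q`, `dpdx`,
#'   `wss`, `P_out`, `P_wall`), `summaries`, `severity`, `periodicity`
#'   (cycle-to-cycle relative L-infinity residuals: `traces` on the
#'   reported pressure/flow/WSS series, `profiles` on the full radial
#'   profiles), `mass_error`, and the inputs. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' \donttest{
#' rep <- run_condition("anemic", numerics = pipeline_numerics(
#'   nr = 41, steps_per_cycle = 200, n_cycles = 4))
#' rep$summaries
#' }
#' @export
run_condition <- function(condition, network = make_default_network(),
                          waveform = waveform_params(),
                          numerics = pipeline_numerics(),
                          wss_bands = severity_bands("wss"),
                          pressure_bands = severity_bands("pressure")) {
  rheology <- blood_condition(condition)
  if (!inherits(network, "arch_network")) {
    abort_invalid("`network` must be an arch_network.")
  }
  dt <- waveform$period / numerics$steps_per_cycle
  R_in <- network$inlet_radius
  br <- network$branches
  spc <- numerics$steps_per_cycle

  branch_out <- lapply(seq_len(nrow(br)), function(i) {
    name <- br$name[i]; radius <- br$radius[i]; frac <- br$flow_fraction[i]
    len <- br$length[i]; wk <- br$windkessel[[i]]
    {
      scale <- frac * (R_in / radius)^2
      wf_b <- waveform_params(
        period = waveform$period, systole_end = waveform$systole_end,
        amplitude = waveform$amplitude * scale,
        diastolic_level = waveform$diastolic_level * scale,
        phase_offset = waveform$phase_offset,
        angular_factor = waveform$angular_factor)
      fit <- tryCatch(
        solve_pulsatile_tube(radius, rheology, wf_b, nr = numerics$nr,
                             dt = dt, n_cycles = numerics$n_cycles,
                             picard_tol = numerics$picard_tol,
                             max_iter = numerics$max_iter),
        pulsarch_convergence_error = function(e) {
          rlang::abort(sprintf("branch %s, condition %s: %s",
                               name, rheology$name, conditionMessage(e)),
                       class = "pulsarch_convergence_error", parent = e)
        })
      area <- pi * radius^2
      flow <- tibble::tibble(t = fit$summary$t, Q = fit$summary$ubar * area)
      wk_trace <- windkessel_simulate(flow, wk, Pc0 = network$mean_pressure)
      # report the final cycle
      idx <- (nrow(flow) - spc + 1):nrow(flow)
      trace <- tibble::tibble(
        branch = name, t = fit$summary$t[idx],
        ubar = fit$summary$ubar[idx], Q = flow$Q[idx],
        dpdx = fit$summary$dpdx[idx], wss = fit$summary$wss[idx],
        P_out = wk_trace$P[idx],
        P_wall = wk_trace$P[idx] - fit$summary$dpdx[idx] * len)
      # cycle-to-cycle periodicity of the reported quantities (P, Q, WSS)
      cyc_per <- function(x) {
        if (numerics$n_cycles < 2) return(NA_real_)
        max(abs(x[idx] - x[idx - spc])) / max(abs(x[idx]))
      }
      list(trace = trace,
           trace_periodicity = max(cyc_per(fit$summary$wss),
                                   cyc_per(flow$Q), cyc_per(wk_trace$P)),
           profile_periodicity = fit$periodicity)
    }
  })

  traces <- dplyr::bind_rows(purrr::map(branch_out, "trace"))

  # mass conservation at the bifurcation: sum of branch flows vs inlet flow
  q_tot <- traces |>
    dplyr::summarise(Q = sum(.data$Q), .by = "t")
  q_in <- inlet_velocity(q_tot$t, waveform) * pi * R_in^2
  mass_error <- max(abs(q_tot$Q - q_in)) / max(abs(q_in))

  summaries <- dplyr::bind_rows(
    summarize_metric(traces$P_wall, "pressure_Pa"),
    summarize_metric(traces$ubar, "velocity_m_s"),
    summarize_metric(traces$wss, "wss_Pa"))

  severity <- dplyr::bind_rows(
    classify_severity(summaries[summaries$quantity == "wss_Pa", ], wss_bands),
    classify_severity(summaries[summaries$quantity == "pressure_Pa", ],
                      pressure_bands))

  structure(list(
    condition = rheology$name, rheology = rheology, network = network,
    waveform = waveform, numerics = numerics,
    traces = traces, summaries = summaries, severity = severity,
    bands = list(wss = wss_bands, pressure = pressure_bands),
    periodicity = list(
      traces = max(purrr::map_dbl(branch_out, "trace_periodicity")),
      profiles = max(purrr::map_dbl(branch_out, "profile_periodicity"))),
    mass_error = mass_error
  ), class = "arch_report")
}

#' @export
print.arch_report <- function(x, ...) {
  cat(sprintf("<arch_report: %s, %d branches, %d cycles (last reported)>\n",
              x$condition, nrow(x$network$branches), x$numerics$n_cycles))
  print(x$summaries)
  cat("severity (illustrative bands):\n")
  print(tibble::as_tibble(x$severity)[c("quantity", "metric", "value", "category")])
  cat(sprintf("periodicity: traces %.3g, profiles %.3g; mass error %.3g\n",
              x$periodicity$traces, x$periodicity$profiles, x$mass_error))
  invisible(x)
}

#' Run the arch analysis for all blood conditions
#'
#' Calls [run_condition()] for each requested condition and assembles a
#' cross-condition comparison table of min / avg / max for pressure,
#' velocity and wall shear stress, plus the cycle-peak pressure-gradient
#' magnitude per condition.
#'
#' @inheritParams run_condition
#' @param conditions Character vector of condition names (default all four).
#' @return An object of class `arch_run`: `reports` (named list of
#'   [run_condition()] outputs) and `comparison` (tibble with one row per
#'   condition and quantity).
#' @export
run_all <- function(network = make_default_network(),
                    waveform = waveform_params(),
                    numerics = pipeline_numerics(),
                    conditions = c("anemic", "diabetic", "healthy1", "healthy2")) {
  reports <- purrr::map(conditions, run_condition, network = network,
                        waveform = waveform, numerics = numerics)
  names(reports) <- conditions
  comparison <- purrr::map_dfr(reports, function(rep) {
    dplyr::mutate(rep$summaries, condition = rep$condition,
                  dpdx_peak = max(abs(rep$traces$dpdx)),
                  .before = 1)
  })
  structure(list(reports = reports, comparison = comparison),
            class = "arch_run")
}

#' @export
print.arch_run <- function(x, ...) {
  cat(sprintf("<arch_run: %d conditions>\n", length(x$reports)))
  print(x$comparison)
  invisible(x)
}
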