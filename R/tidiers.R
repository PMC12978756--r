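# broom-style tidiers for the fitted objects

#' Tidy a pulsatile tube fit
#'
#' @param x A `tube_fit` from [solve_pulsatile_tube()].
#' @param ... Unused.
#' @return The per-step summary tibble (`t`, `ubar`, `dpdx`, `wss`,
#'   `iters`) restricted to the reported final cycle.
#' @method tidy tube_fit
#' @export
tidy.tube_fit <- function(x, ...) {
  n <- nrow(x$summary)
  idx <- (n - x$steps_per_cycle + 1):n
  x$summary[idx, ]
}

#' @rdname tidy.tube_fit
#' @return For `glance`: a one-row tibble with cycle-averaged and peak wall
#'   shear stress, peak pressure-gradient magnitude, mean velocity,
#'   periodicity residual and mean Picard iteration count.
#' @method glance tube_fit
#' @export
glance.tube_fit <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    condition = x$rheology$name,
    wss_mean = mean(s$wss), wss_max = max(s$wss),
    dpdx_peak = max(abs(s$dpdx)), ubar_mean = mean(s$ubar),
    periodicity = x$periodicity, picard_iters = mean(s$iters))
}

#' Tidy an arch condition report
#'
#' @param x An `arch_report` from [run_condition()].
#' @param ... Unused.
#' @return For `tidy`: the min/avg/max summary tibble with the condition
#'   attached. For `glance`: a one-row overview (cycle-mean WSS and wall
#'   pressure, peak |dpdx|, periodicity, mass-conservation error).
#' @method tidy arch_report
#' @export
tidy.arch_report <- function(x, ...) {
  dplyr::mutate(x$summaries, condition = x$condition, .before = 1)
}

#' @rdname tidy.arch_report
#' @method glance arch_report
#' @export
glance.arch_report <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    wss_avg = x$summaries$avg[x$summaries$quantity == "wss_Pa"],
    wss_max = x$summaries$max[x$summaries$quantity == "wss_Pa"],
    pressure_avg = x$summaries$avg[x$summaries$quantity == "pressure_Pa"],
    dpdx_peak = max(abs(x$traces$dpdx)),
    trace_periodicity = x$periodicity$traces,
    profile_periodicity = x$periodicity$profiles,
    mass_error = x$mass_error)
}

#' @rdname tidy.arch_report
#' @method tidy arch_run
#' @export
tidy.arch_run <- function(x, ...) x$comparison

#' @rdname tidy.arch_report
#' @method glance arch_run
#' @export
glance.arch_run <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}
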