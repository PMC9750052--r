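#' Run the closed-loop 0D circulation model
#'
#' Integrates the closed-loop circuit (pulmonary-artery RLC block included)
#' over a whole number of heartbeats and records every state and algebraic
#' variable at every step. The default initial state is the shipped healthy
#' calibration ([default_initial_state()]), which sits on the limit cycle so
#' that beat-averaged metrics taken on the third heartbeat are
#' representative.
#'
#' @param params A [circulation_params()] object.
#' @param dt Time-step size (s); default `1e-3`.
#' @param beats Number of heartbeats to simulate; default 3.
#' @param method `"rk4"` (default) or `"euler"`.
#' @param y0 Named initial state vector (closed layout).
#' @return An object of class `pulmflow_run`: a list with `record` (tibble
#'   with columns `t`, every state variable and every algebraic variable,
#'   one row per step including the initial instant), `params`, `dt`,
#'   `method`, `beats`, `variant`.
#' @export
#' @examples
#' run <- run_closed0d(beats = 1)
#' dplyr::glimpse(tidy(run)[1:6])
run_closed0d <- function(params = circulation_params(), dt = 1e-3, beats = 3,
                         method = c("rk4", "euler"),
                         y0 = default_initial_state(params, "closed")) {
  method <- match.arg(method)
  topo <- circuit_topology("closed", params)
  stopifnot(setequal(names(y0), topo$state_names))
  y <- y0[topo$state_names]
  step <- .stepper(method)
  n_steps <- round(beats * params$T_cycle / dt)
  z <- algebraic_eval(0, y, topo)
  out <- matrix(NA_real_, nrow = n_steps + 1, ncol = 1 + length(y) + length(z))
  colnames(out) <- c("t", names(y), names(z))
  out[1, ] <- c(0, y, z)
  for (n in seq_len(n_steps)) {
    t_n <- (n - 1) * dt
    y <- step(t_n, y, dt, topo)
    z <- algebraic_eval(n * dt, y, topo)
    out[n + 1, ] <- c(n * dt, y, z)
  }
  structure(list(
    record = tibble::as_tibble(as.data.frame(out)),
    params = params, dt = dt, method = method, beats = beats,
    variant = "closed", topology = topo
  ), class = "pulmflow_run")
}

#' Monolithic interface reference from the closed-loop model
#'
#' Runs the closed-loop model and extracts the interface quadruple seen by
#' the pulmonary-artery block: `Q_IN` (flow entering the block), `P_IN`
#' (block inlet pressure `P_PA`), `Q_OUT` (flow leaving the block, `Q_PA`)
#' and `P_OUT` (microvasculature pressure `P_MV`). This deterministic series
#' is the reference against which the partitioned coupling algorithms are
#' compared, and the forcing record consumed by the one-way algorithm.
#'
#' @inheritParams run_closed0d
#' @param T_end Final time (s); overrides `beats` when given.
#' @return A tibble with columns `t`, `Q_IN`, `P_IN`, `Q_OUT`, `P_OUT`, and
#'   the full `pulmflow_run` as attribute `"run"`.
#' @export
monolithic_reference <- function(params = circulation_params(), dt = 1e-3,
                                 T_end = NULL, beats = 3,
                                 method = c("rk4", "euler"),
                                 y0 = default_initial_state(params, "closed")) {
  method <- match.arg(method)
  if (!is.null(T_end)) beats <- T_end / params$T_cycle
  run <- run_closed0d(params, dt = dt, beats = beats, method = method, y0 = y0)
  ref <- .interface_from_closed(run$record)
  attr(ref, "run") <- run
  ref
}

# internal: closed-record columns -> interface quadruple
.interface_from_closed <- function(record) {
  tibble::tibble(
    t = record$t,
    Q_IN = record$Q_IN,
    P_IN = record$P_PA,
    Q_OUT = record$Q_PA,
    P_OUT = record$P_MV
  )
}

#' @export
print.pulmflow_run <- function(x, ...) {
  cat("<pulmflow_run>", x$variant, "model,", x$method, "stepper\n")
  cat(sprintf("  dt = %g s, %g beat(s), %d recorded instants\n",
              x$dt, x$beats, nrow(x$record)))
  if (!is.null(x$stability) && isTRUE(x$stability$unstable)) {
    cat(sprintf("  UNSTABLE: first failure at t = %g s\n",
                x$stability$first_failure_time))
  }
  invisible(x)
}

#' Tidy a simulation run into its time-series record
#'
#' @param x A `pulmflow_run`.
#' @param ... Unused.
#' @return The per-step tibble record.
#' @method tidy pulmflow_run
#' @export
tidy.pulmflow_run <- function(x, ...) x$record

#' One-row summary of a simulation run
#'
#' Beat-averaged metrics on the metrics beat (the third heartbeat by
#' default, or the last complete beat for shorter runs) via
#' [cycle_metrics()], plus stepper settings and the stability flag.
#'
#' @param x A `pulmflow_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance pulmflow_run
#' @export
glance.pulmflow_run <- function(x, ...) {
  beat <- min(3, floor(x$beats + 1e-9))
  m <- if (beat >= 1) cycle_metrics(x, beat = beat) else
    tibble::tibble()
  dplyr::bind_cols(
    tibble::tibble(variant = x$variant, method = x$method, dt = x$dt,
                   beats = x$beats,
                   unstable = isTRUE(x$stability$unstable)),
    m
  )
}

#' Write a run record to CSV
#'
#' One row per step, header row with canonical variable names, `t` first.
#'
#' @param run A `pulmflow_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  utils::write.csv(run$record, path, row.names = FALSE)
  invisible(path)
}

#' Plot the main time series of a run
#'
#' Pressures (chamber and pulmonary-artery inlet) and the right-ventricular
#' volume against time, faceted by variable family.
#'
#' @param object A `pulmflow_run`.
#' @param vars Character vector of record columns to plot; defaults to the
#'   right-heart pressures/volume plus the interface pressure when present.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pulmflow_run
#' @export
autoplot.pulmflow_run <- function(object, vars = NULL, ...) {
  rec <- object$record
  if (is.null(vars)) {
    vars <- intersect(c("P_RV", "P_PA", "P_IN", "P_MV", "V_RV", "Q_IN"),
                      names(rec))
  }
  long <- tidyr::pivot_longer(rec[, c("t", vars)], -"t",
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
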