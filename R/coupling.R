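#' One splitting-explicit (SE) coupling step
#'
#' The distributed model and the open 0D circuit are solved sequentially
#' once per time step: the distributed model advances with the interface
#' data of the previous step `(Q_IN^n, P_OUT^n)` and produces
#' `(P_IN^{n+1}, Q_OUT^{n+1})`; the 0D circuit then advances with those as
#' forcings and provides `(Q_IN^{n+1}, P_OUT^{n+1})` for the next step.
#'
#' @param n Step index (state is at `t = n * dt`).
#' @param y Named 0D state vector at step `n`.
#' @param topology An open [circuit_topology()].
#' @param distributed A `distributed_model` (e.g. [pa_surrogate()]).
#' @param prev List with the previous exchange `Q_IN`, `P_OUT`.
#' @param dt Step size (s).
#' @param method 0D stepper, `"rk4"` or `"euler"`.
#' @return List with `y` (state at `n + 1`) and `exchange`
#'   (`Q_IN`, `P_IN`, `Q_OUT`, `P_OUT` at `n + 1`).
#' @export
se_step <- function(n, y, topology, distributed, prev, dt,
                    method = c("rk4", "euler")) {
  method <- match.arg(method)
  t_n <- n * dt
  resp <- distributed$advance(t_n, dt, prev$Q_IN, prev$P_OUT)
  forc <- list(P_IN = resp$P_IN, Q_OUT = resp$Q_OUT)
  y1 <- .stepper(method)(t_n, y, dt, topology, forc)
  out <- interface_outputs(t_n + dt, y1, topology, forc)
  list(y = y1,
       exchange = list(Q_IN = out$Q_IN, P_IN = resp$P_IN,
                       Q_OUT = resp$Q_OUT, P_OUT = out$P_OUT))
}

#' One splitting-implicit (SI) coupling step
#'
#' Fixed-point subiterations within the step: both subsystems restart from
#' their step-`n` checkpoints, the distributed model advancing with the
#' latest interface iterate `(Q_IN^{(k-1)}, P_OUT^{(k-1)})` and the 0D
#' circuit with the distributed model's response, until the relative change
#' of all four interface variables between successive iterates drops below
#' `epsilon`. The stopping norm is
#' `max_i |x_i^{(k)} - x_i^{(k-1)}| / max(|x_i^{(k)}|, floor)` with
#' `floor = 1e-8` in native units (scale-free, robust at near-zero flows).
#'
#' @inheritParams se_step
#' @param guess List with the starting iterate `Q_IN`, `P_OUT` (typically
#'   the previous step's exchange).
#' @param epsilon Relative stopping tolerance; default `1e-3`.
#' @param k_max Maximum subiterations; exceeded means a non-convergence
#'   error carrying the last residual.
#' @param relax Under-relaxation factor in `(0, 1]` applied to the interface
#'   update; 1 (default) is the plain fixed-point loop.
#' @return List with `y`, `exchange` and the subiteration count `k`.
#' @export
si_step <- function(n, y, topology, distributed, guess, dt,
                    epsilon = 1e-3, k_max = 100,
                    method = c("rk4", "euler"), relax = 1) {
  method <- match.arg(method)
  stopifnot(epsilon > 0, k_max >= 1)
  t_n <- n * dt
  step0d <- .stepper(method)
  token <- distributed$checkpoint()
  x <- c(Q_IN = guess$Q_IN, P_IN = NA_real_, Q_OUT = NA_real_,
         P_OUT = guess$P_OUT)
  y1 <- y
  for (k in seq_len(k_max)) {
    distributed$restore(token)
    resp <- distributed$advance(t_n, dt, x[["Q_IN"]], x[["P_OUT"]])
    forc <- list(P_IN = resp$P_IN, Q_OUT = resp$Q_OUT)
    y1 <- step0d(t_n, y, dt, topology, forc)
    out <- interface_outputs(t_n + dt, y1, topology, forc)
    x_new <- c(Q_IN = out$Q_IN, P_IN = resp$P_IN, Q_OUT = resp$Q_OUT,
               P_OUT = out$P_OUT)
    if (relax < 1 && all(is.finite(x))) {
      x_new <- relax * x_new + (1 - relax) * x
    }
    resid <- max(abs(x_new - x) / pmax(abs(x_new), 1e-8), na.rm = TRUE)
    x <- x_new
    if (is.finite(resid) && resid <= epsilon) {
      return(list(y = y1, exchange = as.list(x), k = k))
    }
  }
  stop(sprintf(
    "splitting-implicit subiterations did not converge: residual %.3g > %g after %d iterations",
    resid, epsilon, k_max), call. = FALSE)
}

#' Instability monitor for interface series
#'
#' Flags the first time step at which any monitored interface value is
#' non-finite or exceeds the physical caps (defaults: |pressure| > 500
#' mmHg, |flow| > 5000 ml/s).
#'
#' @param series Tibble or data frame of interface values over time; any
#'   column starting with `P` is treated as a pressure, any starting with
#'   `Q` as a flow; a `t` column (s) labels the failure time.
#' @param p_cap Pressure cap (mmHg).
#' @param q_cap Flow cap (ml/s).
#' @return List with `unstable` (flag) and `first_failure_time` (s, `NA` if
#'   stable).
#' @export
instability_monitor <- function(series, p_cap = 500, q_cap = 5000) {
  stopifnot(p_cap > 0, q_cap > 0)
  nm <- names(series)
  p_cols <- nm[startsWith(nm, "P")]
  q_cols <- nm[startsWith(nm, "Q")]
  # plain NA marks not-yet-available entries (e.g. the initial exchange) and
  # is tolerated; NaN and Inf are numerical failures
  bad_row <- rep(FALSE, nrow(series))
  for (cn in p_cols) {
    v <- series[[cn]]
    bad_row <- bad_row | is.nan(v) | is.infinite(v) |
      (!is.na(v) & abs(v) > p_cap)
  }
  for (cn in q_cols) {
    v <- series[[cn]]
    bad_row <- bad_row | is.nan(v) | is.infinite(v) |
      (!is.na(v) & abs(v) > q_cap)
  }
  if (any(bad_row)) {
    i <- which(bad_row)[1]
    tt <- if ("t" %in% nm) series$t[i] else i
    list(unstable = TRUE, first_failure_time = tt)
  } else {
    list(unstable = FALSE, first_failure_time = NA_real_)
  }
}

#' Run a partitioned 3D-0D coupled simulation
#'
#' Drives an open 0D circuit (setting 1 or 2) coupled to a distributed
#' model through the splitting-explicit, splitting-implicit or one-way
#' algorithm. The bridging-region check is run and logged up front; an
#' instability (non-finite state or interface value beyond the caps) halts
#' the run gracefully and the partial record is returned with the stability
#' flag set.
#'
#' @param distributed A `distributed_model`; see [pa_surrogate()] and
#'   [fem_tube_model()].
#' @param params A [circulation_params()] object.
#' @param setting Circuit setting, `2` (proximal compartment at the inlet,
#'   bridging-compatible) or `1` (valve coupled directly, unstable under
#'   explicit partitioning).
#' @param algorithm `"se"`, `"si"` or `"one_way"`.
#' @param dt Step size (s).
#' @param beats Number of heartbeats (period `params$T_cycle`).
#' @param epsilon,k_max,relax Splitting-implicit controls (see [si_step()]).
#' @param method 0D stepper, `"rk4"` or `"euler"`.
#' @param y0 Initial 0D state (open layout for `se`/`si`; closed layout for
#'   `one_way`, which first solves the closed loop offline).
#' @param p_cap,q_cap Instability caps (see [instability_monitor()]).
#' @return A `pulmflow_run` whose `record` holds the 0D trajectories and
#'   whose `interface` tibble holds `(t, Q_IN, P_IN, Q_OUT, P_OUT, k)`;
#'   `stability` carries the flag and first failure time, `mean_k` the mean
#'   subiteration count (1 for `se`).
#' @export
run_coupled <- function(distributed, params = circulation_params(),
                        setting = 2, algorithm = c("se", "si", "one_way"),
                        dt = 1e-3, beats = 3,
                        epsilon = 1e-3, k_max = 100, relax = 1,
                        method = c("rk4", "euler"),
                        y0 = NULL, p_cap = 500, q_cap = 5000) {
  algorithm <- match.arg(algorithm)
  method <- match.arg(method)
  if (algorithm == "one_way") {
    if (is.null(y0)) y0 <- default_initial_state(params, "closed")
    ref <- monolithic_reference(params, dt = dt, beats = beats,
                                method = method, y0 = y0)
    return(one_way_run(ref, distributed, dt,
                       T_end = beats * params$T_cycle,
                       p_cap = p_cap, q_cap = q_cap))
  }
  variant <- if (setting == 1) "open_setting1" else "open_setting2"
  topo <- circuit_topology(variant, params)
  bridging <- check_bridging(topo)
  if (is.null(y0)) y0 <- default_initial_state(params, variant)
  y <- y0[topo$state_names]
  n_steps <- round(beats * params$T_cycle / dt)

  # initial exchange: what the 0D provides at rest/start; setting 1 cannot
  # evaluate its valve without a P_IN, so start that from the downstream cap
  P_IN0 <- if (variant == "open_setting1") y[["P_MV"]] else NA_real_
  out0 <- interface_outputs(0, y, topo, list(P_IN = P_IN0, Q_OUT = NA_real_))
  exch <- list(Q_IN = out0$Q_IN, P_IN = P_IN0, Q_OUT = NA_real_,
               P_OUT = out0$P_OUT)

  rec <- matrix(NA_real_, nrow = n_steps + 1, ncol = 1 + length(y))
  colnames(rec) <- c("t", names(y))
  rec[1, ] <- c(0, y)
  iface <- matrix(NA_real_, nrow = n_steps + 1, ncol = 6)
  colnames(iface) <- c("t", "Q_IN", "P_IN", "Q_OUT", "P_OUT", "k")
  iface[1, ] <- c(0, exch$Q_IN, exch$P_IN, NA_real_, exch$P_OUT, NA_real_)

  unstable <- FALSE
  t_fail <- NA_real_
  last <- n_steps
  for (n in seq_len(n_steps) - 1L) {
    res <- tryCatch({
      if (algorithm == "se") {
        c(se_step(n, y, topo, distributed, exch, dt, method), k = 1L)
      } else {
        si_step(n, y, topo, distributed, exch, dt, epsilon, k_max,
                method, relax)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      unstable <- TRUE
      t_fail <- (n + 1) * dt
      last <- n
      break
    }
    y <- res$y
    exch <- res$exchange
    rec[n + 2, ] <- c((n + 1) * dt, y)
    iface[n + 2, ] <- c((n + 1) * dt, exch$Q_IN, exch$P_IN, exch$Q_OUT,
                        exch$P_OUT, res$k)
    mon <- instability_monitor(
      as.data.frame(t(c(t = (n + 1) * dt, unlist(exch)))), p_cap, q_cap)
    if (mon$unstable) {
      unstable <- TRUE
      t_fail <- (n + 1) * dt
      last <- n + 1
      break
    }
  }
  rec <- rec[seq_len(last + 1), , drop = FALSE]
  iface <- iface[seq_len(last + 1), , drop = FALSE]
  iface_tb <- tibble::as_tibble(as.data.frame(iface))
  structure(list(
    record = tibble::as_tibble(as.data.frame(rec)),
    interface = iface_tb,
    params = params, dt = dt, method = method, beats = beats,
    variant = variant, topology = topo, algorithm = algorithm,
    bridging = bridging,
    mean_k = mean(iface_tb$k, na.rm = TRUE),
    stability = list(unstable = unstable, first_failure_time = t_fail)
  ), class = "pulmflow_run")
}

#' One-way coupling run
#'
#' The closed-loop 0D model is solved offline and its interface signals
#' `Q_IN(t)` and `P_OUT(t)` drive the distributed model forward with no
#' feedback; the distributed model's responses `(P_IN, Q_OUT)` are recorded.
#'
#' @param closed_record Interface series from [monolithic_reference()] (or
#'   any tibble with columns `t`, `Q_IN`, `P_OUT` covering `T_end`).
#' @param distributed A `distributed_model`.
#' @param dt Step size (s), matching the record's sampling.
#' @param T_end Final time (s).
#' @param p_cap,q_cap Instability caps.
#' @return A `pulmflow_run` whose `interface` holds the forcings and the
#'   recorded responses; `record` carries the offline closed-loop
#'   trajectories when available.
#' @export
one_way_run <- function(closed_record, distributed, dt, T_end,
                        p_cap = 500, q_cap = 5000) {
  n_steps <- round(T_end / dt)
  if (nrow(closed_record) < n_steps + 1) {
    stop(sprintf("closed-loop record has %d rows, need %d to cover T_end",
                 nrow(closed_record), n_steps + 1), call. = FALSE)
  }
  iface <- matrix(NA_real_, nrow = n_steps + 1, ncol = 6)
  colnames(iface) <- c("t", "Q_IN", "P_IN", "Q_OUT", "P_OUT", "k")
  iface[1, ] <- c(0, closed_record$Q_IN[1], NA, NA, closed_record$P_OUT[1], NA)
  unstable <- FALSE
  t_fail <- NA_real_
  last <- n_steps
  for (n in seq_len(n_steps) - 1L) {
    resp <- tryCatch(
      distributed$advance(n * dt, dt,
                          closed_record$Q_IN[n + 1],
                          closed_record$P_OUT[n + 1]),
      error = function(e) e)
    bad <- inherits(resp, "error") ||
      !all(is.finite(c(resp$P_IN, resp$Q_OUT))) ||
      abs(resp$P_IN) > p_cap || abs(resp$Q_OUT) > q_cap
    if (bad) {
      unstable <- TRUE
      t_fail <- (n + 1) * dt
      last <- n
      break
    }
    iface[n + 2, ] <- c((n + 1) * dt, closed_record$Q_IN[n + 2], resp$P_IN,
                        resp$Q_OUT, closed_record$P_OUT[n + 2], NA_real_)
  }
  iface <- iface[seq_len(last + 1), , drop = FALSE]
  run <- attr(closed_record, "run")
  structure(list(
    record = if (!is.null(run)) run$record else NULL,
    interface = tibble::as_tibble(as.data.frame(iface)),
    params = if (!is.null(run)) run$params else NULL,
    dt = dt, method = if (!is.null(run)) run$method else NA_character_,
    beats = T_end / if (!is.null(run)) run$params$T_cycle else 0.8,
    variant = "one_way", algorithm = "one_way",
    mean_k = NA_real_,
    stability = list(unstable = unstable, first_failure_time = t_fail)
  ), class = "pulmflow_run")
}
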