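# trapezoidal quadrature on a (possibly non-uniform) grid
.trapz <- function(t, x) sum(diff(t) * (x[-1] + x[-length(x)]) / 2)

#' Per-beat hemodynamic metrics
#'
#' Time-averaged and extremal quantities over one heartbeat window
#' `[(beat-1) T_cycle, beat T_cycle]`: trapezoidal means of the
#' pulmonary-artery inlet pressure `P_IN`, inlet flow `Q_IN` and
#' right-ventricular pressure `P_RV`; end-diastolic (max) and end-systolic
#' (min) right-ventricular volume and their difference, the stroke volume;
#' and the pressure extrema. For a closed-loop run `P_IN` is the
#' pulmonary-artery inlet-node pressure `P_PA`; for a coupled run it is the
#' interface pressure reported by the distributed model.
#'
#' @param run A `pulmflow_run` (or a tibble with columns `t`, `V_RV`,
#'   `P_RV` and either `P_PA` or `P_IN`, and `Q_IN`).
#' @param beat Beat index (1-based); the conventional reporting beat is 3.
#' @param T_cycle Heartbeat period (s); taken from the run when available.
#' @return A one-row tibble with `beat`, `Q_IN_mean`, `P_IN_mean`,
#'   `P_RV_mean`, `EDV`, `ESV`, `SV`, `P_IN_min`, `P_IN_max`, `P_RV_max`,
#'   `V_RV_min`, `V_RV_max`.
#' @export
cycle_metrics <- function(run, beat = 3, T_cycle = NULL) {
  if (inherits(run, "pulmflow_run")) {
    if (is.null(T_cycle)) T_cycle <- run$params$T_cycle %||% 0.8
    rec <- run$record
    if (!is.null(run$interface) && "P_IN" %in% names(run$interface)) {
      rec <- dplyr::left_join(rec, run$interface[, c("t", "P_IN")], by = "t")
    }
  } else {
    rec <- run
    if (is.null(T_cycle)) T_cycle <- 0.8
  }
  if (!"P_IN" %in% names(rec) || all(is.na(rec$P_IN))) {
    if ("P_PA" %in% names(rec)) rec$P_IN <- rec$P_PA
  }
  t0 <- (beat - 1) * T_cycle
  t1 <- beat * T_cycle
  eps <- 1e-9
  w <- rec[rec$t >= t0 - eps & rec$t <= t1 + eps, , drop = FALSE]
  if (nrow(w) < 2 || max(w$t) < t1 - eps) {
    stop(sprintf("run does not span beat %d ([%g, %g] s)", beat, t0, t1),
         call. = FALSE)
  }
  mean_of <- function(col) {
    if (!col %in% names(w) || all(is.na(w[[col]]))) return(NA_real_)
    ok <- !is.na(w[[col]])
    .trapz(w$t[ok], w[[col]][ok]) / (max(w$t[ok]) - min(w$t[ok]))
  }
  edv <- if ("V_RV" %in% names(w)) max(w$V_RV) else NA_real_
  esv <- if ("V_RV" %in% names(w)) min(w$V_RV) else NA_real_
  tibble::tibble(
    beat = beat,
    Q_IN_mean = mean_of("Q_IN"),
    P_IN_mean = mean_of("P_IN"),
    P_RV_mean = mean_of("P_RV"),
    EDV = edv, ESV = esv, SV = edv - esv,
    P_IN_min = if (all(is.na(w$P_IN))) NA_real_ else min(w$P_IN, na.rm = TRUE),
    P_IN_max = if (all(is.na(w$P_IN))) NA_real_ else max(w$P_IN, na.rm = TRUE),
    P_RV_max = if ("P_RV" %in% names(w)) max(w$P_RV) else NA_real_,
    V_RV_min = esv, V_RV_max = edv
  )
}

#' Right-ventricular pressure-volume loop
#'
#' Extracts the ordered `(V_RV, P_RV)` samples of one heartbeat. The loop
#' area (stroke work, mmHg ml) is computed with the shoelace formula and
#' attached as attribute `"area"`.
#'
#' @inheritParams cycle_metrics
#' @return A tibble of class `pulmflow_pvloop` with columns `t`, `V_RV`,
#'   `P_RV`; attribute `area` holds the enclosed area.
#' @export
pv_loop <- function(run, beat = 3, T_cycle = NULL) {
  if (inherits(run, "pulmflow_run")) {
    if (is.null(T_cycle)) T_cycle <- run$params$T_cycle %||% 0.8
    rec <- run$record
  } else {
    rec <- run
    if (is.null(T_cycle)) T_cycle <- 0.8
  }
  if (!all(c("V_RV", "P_RV") %in% names(rec))) {
    stop("record lacks V_RV / P_RV series", call. = FALSE)
  }
  t0 <- (beat - 1) * T_cycle
  t1 <- beat * T_cycle
  eps <- 1e-9
  w <- rec[rec$t >= t0 - eps & rec$t <= t1 + eps, c("t", "V_RV", "P_RV")]
  if (nrow(w) < 2 || max(w$t) < t1 - eps) {
    stop(sprintf("run does not span beat %d", beat), call. = FALSE)
  }
  V <- w$V_RV
  P <- w$P_RV
  # close the polygon for the shoelace area
  Vc <- c(V, V[1])
  Pc <- c(P, P[1])
  area <- abs(sum(Vc[-length(Vc)] * Pc[-1] - Vc[-1] * Pc[-length(Pc)])) / 2
  out <- tibble::new_tibble(w, class = "pulmflow_pvloop")
  attr(out, "area") <- area
  out
}

#' @method autoplot pulmflow_pvloop
#' @export
autoplot.pulmflow_pvloop <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$V_RV, y = .data$P_RV)) +
    ggplot2::geom_path(color = "#d7301f") +
    ggplot2::labs(x = "right ventricular volume (ml)",
                  y = "right ventricular pressure (mmHg)") +
    ggplot2::theme_minimal()
}

#' Compare pressure-volume loops across scenarios
#'
#' @param ... Named `pulmflow_pvloop` objects (e.g. `healthy = ..., pah = ...`).
#' @return A ggplot object overlaying the loops.
#' @export
plot_pv_loops <- function(...) {
  loops <- list(...)
  stopifnot(length(loops) >= 1, !is.null(names(loops)))
  df <- dplyr::bind_rows(lapply(loops, tibble::as_tibble), .id = "case")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$V_RV, y = .data$P_RV,
                                   color = .data$case)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "right ventricular volume (ml)",
                  y = "right ventricular pressure (mmHg)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Richardson mesh-convergence extrapolation
#'
#' Given scalar indices `f_1, f_2, f_3` computed on three geometrically
#' refined meshes `h_1 < h_2 < h_3` with constant refinement ratio
#' `r = h_2/h_1 = h_3/h_2`, estimates the observed convergence order
#' \deqn{p = \log\big((f_3 - f_2)/(f_2 - f_1)\big) / \log r,}
#' the mesh-independent reference value
#' \deqn{f_{ref} = (h_2^p f_3 - h_3^p f_2)/(h_2^p - h_3^p),}
#' and the relative discrepancies `E_i = |f_i - f_ref| / |f_ref|`.
#'
#' Degenerate studies (equal consecutive `f`, non-positive log argument,
#' non-constant ratio) raise explicit errors rather than returning silent
#' nonsense.
#'
#' @param h Mesh sizes, ascending (fine to coarse), length 3. Alternatively
#'   a data frame with columns `h` and `f`.
#' @param f Scalar indices paired with `h`, length 3.
#' @param r Refinement ratio. By default it is taken from the mesh sizes,
#'   which must then have a constant ratio (within 1e-6 relative). Supplying
#'   `r` explicitly skips that check and uses the given nominal ratio in the
#'   order formula -- the practical situation when mesh sizes are quoted
#'   rounded (e.g. 0.4/0.7/1.1 for a nominal ratio of 1.6).
#' @return An object of class `richardson`: list with `p`, `f_ref`, `r`,
#'   `h`, `f`, `E` (relative discrepancies).
#' @export
#' @examples
#' # constructed second-order model: recovered exactly
#' h <- 0.4 * 1.6^(0:2)
#' richardson(h, 10 + 3 * h^2)
richardson <- function(h, f = NULL, r = NULL) {
  if (is.data.frame(h)) {
    f <- h$f
    h <- h$h
  }
  if (length(h) != 3 || length(f) != 3) {
    stop("a convergence study needs exactly three (h, f) pairs", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(!is.finite(f)) || any(h <= 0)) {
    stop("mesh sizes and indices must be finite, h positive", call. = FALSE)
  }
  if (is.unsorted(h, strictly = TRUE)) {
    stop("mesh sizes must be strictly increasing (fine to coarse)", call. = FALSE)
  }
  if (is.null(r)) {
    r1 <- h[2] / h[1]
    r2 <- h[3] / h[2]
    if (abs(r1 - r2) > 1e-6 * r1) {
      stop(sprintf(
        "refinement ratio is not constant: h2/h1 = %.8g, h3/h2 = %.8g (pass r explicitly for rounded mesh sizes)",
        r1, r2), call. = FALSE)
    }
    r <- r1
  }
  if (f[2] == f[1] || f[3] == f[2]) {
    stop("degenerate convergence study: consecutive indices are equal",
         call. = FALSE)
  }
  arg <- (f[3] - f[2]) / (f[2] - f[1])
  if (arg <= 0) {
    stop(sprintf("degenerate convergence study: non-positive ratio (f3-f2)/(f2-f1) = %.4g",
                 arg), call. = FALSE)
  }
  p <- log(arg) / log(r)
  f_ref <- (h[2]^p * f[3] - h[3]^p * f[2]) / (h[2]^p - h[3]^p)
  E <- abs(f - f_ref) / abs(f_ref)
  structure(list(p = p, f_ref = f_ref, r = r, h = h, f = f, E = E),
            class = "richardson")
}

#' @export
print.richardson <- function(x, ...) {
  cat("<richardson> order p =", format(x$p, digits = 4),
      " f_ref =", format(x$f_ref, digits = 6),
      " (ratio r =", format(x$r, digits = 4), ")\n")
  print(tidy.richardson(x))
  invisible(x)
}

#' @method tidy richardson
#' @export
tidy.richardson <- function(x, ...) {
  tibble::tibble(mesh = c("fine", "medium", "coarse"),
                 h = x$h, f = x$f, E = x$E)
}

#' @method glance richardson
#' @export
glance.richardson <- function(x, ...) {
  tibble::tibble(p = x$p, f_ref = x$f_ref, r = x$r)
}
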