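# Post-processing: temporal averaging on the unwrapped surface, oscillation
# and wave-front metrics, and the frequency-sensitive zero-order
# ultrasensitive phosphorylation cycle driven by cytosolic calcium.

#' Per-cell temporal average of a recorded species
#'
#' Arithmetic mean of the recorded samples in the window `[t_i, t_f]`
#' (inclusive endpoints, normalized by the sample count), per cell.  The
#' defaults average the final 200 s of a 500 s run, excluding the initial
#' transient.
#'
#' @param record A `sim_record`.
#' @param t_i,t_f Averaging window bounds (s).
#' @param species State field to average (default cytosolic calcium).
#' @return A tibble of class `averaged_field` with one row per cell:
#'   `cell_id`, `type`, `u`, `v`, `region`, `mean_value`.
#' @export
temporal_average <- function(record, t_i = 300, t_f = 500,
                             species = "ca_cyt") {
  if (t_i >= t_f) abort("require t_i < t_f")
  sel <- record$times >= t_i - 1e-9 & record$times <= t_f + 1e-9
  if (!any(sel)) abort("averaging window contains no recorded samples")
  mean_of <- function(block) colMeans(block[[species]][sel, , drop = FALSE])
  cells <- record$cells
  ec <- cells[cells$cell_type == "ec", ]
  smc <- cells[cells$cell_type == "smc", ]
  out <- dplyr::bind_rows(
    tibble(cell_id = ec$cell_id, type = "ec", u = ec$u, v = ec$v,
           region = ec$region, mean_value = mean_of(record$ec)),
    tibble(cell_id = smc$cell_id, type = "smc", u = smc$u, v = smc$v,
           region = smc$region, mean_value = mean_of(record$smc)))
  structure(out, class = c("averaged_field", class(out)),
            t_i = t_i, t_f = t_f, species = species)
}

# peak detection with a prominence criterion: local maxima whose height
# above the higher of the two flanking minima exceeds `prominence`.
find_spikes <- function(x, prominence = 0.05) {
  n <- length(x)
  if (n < 3) return(integer(0))
  up <- which(diff(sign(diff(x))) < 0) + 1L
  keep <- vapply(up, function(i) {
    left <- x[seq_len(i - 1L)]
    right <- x[(i + 1L):n]
    hl <- which(left >= x[i])
    hr <- which(right >= x[i])
    lmin <- if (length(hl)) min(x[max(hl):(i - 1L)]) else min(left)
    rmin <- if (length(hr)) min(x[(i + 1L):(i + min(hr))]) else min(right)
    x[i] - max(lmin, rmin) >= prominence
  }, logical(1))
  up[keep]
}

#' Oscillation metrics per cell
#'
#' Dominant oscillation period (median inter-peak interval, with an
#' autocorrelation fallback when fewer than three peaks are found),
#' spike amplitude (mean peak height above baseline) and baseline (10%
#' quantile) of a recorded species in a time window.  Cells without
#' prominent peaks are flagged non-oscillatory with zero amplitude.
#'
#' @param record A `sim_record`.
#' @param type `"smc"` or `"ec"`.
#' @param species State field (default `"ca_cyt"`).
#' @param window Time window `c(t_i, t_f)`; default the full record.
#' @param min_prominence Minimum peak prominence (uM) separating spikes
#'   from baseline jitter.
#' @param cells Optional type-local indices to restrict to.
#' @return Tibble of class `wave_metrics`: `index`, `region`, `oscillatory`,
#'   `period`, `amplitude`, `baseline`, `n_peaks`, `max_value`.
#' @export
oscillation_metrics <- function(record, type = c("smc", "ec"),
                                species = "ca_cyt", window = NULL,
                                min_prominence = 0.05, cells = NULL) {
  type <- match.arg(type)
  block <- record[[type]][[species]]
  tt <- record$times
  if (!is.null(window)) {
    sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
    block <- block[sel, , drop = FALSE]
    tt <- tt[sel]
  }
  idx <- cells %||% seq_len(ncol(block))
  meta <- record$cells[record$cells$cell_type == type, ]
  res <- lapply(idx, function(j) {
    x <- block[, j]
    pk <- find_spikes(x, prominence = min_prominence)
    base <- as.numeric(quantile(x, 0.1))
    if (length(pk) >= 3) {
      per <- median(diff(tt[pk]))
    } else if (length(pk) >= 1) {
      per <- .acf_period(x, tt)
    } else {
      per <- NA_real_
    }
    tibble(index = j, region = meta$region[j],
           oscillatory = length(pk) >= 2,
           period = per,
           amplitude = if (length(pk)) mean(x[pk]) - base else 0,
           baseline = base, n_peaks = length(pk), max_value = max(x))
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = c("wave_metrics", class(out)),
            type = type, species = species)
}

.acf_period <- function(x, tt) {
  if (length(x) < 8 || stats::sd(x) == 0) return(NA_real_)
  dt <- median(diff(tt))
  a <- acf(x, lag.max = min(length(x) - 1, floor(length(x) / 2)),
           plot = FALSE)$acf[-1]
  pk <- find_spikes(a, prominence = 0.05)
  if (!length(pk)) return(NA_real_)
  pk[1] * dt
}

#' Wave-front speed along a cell path
#'
#' Detects the first upward threshold crossing of each cell along an
#' ordered path and fits arrival time against cumulative distance; the
#' inverse slope is the front speed.  A path whose cells cross within one
#' recording interval of each other (effectively in phase) is flagged as
#' having no resolvable front.
#'
#' @param record A `sim_record`.
#' @param path Integer vector of type-local cell indices ordered along the
#'   propagation direction.
#' @param type `"smc"` or `"ec"`.
#' @param species State field.
#' @param threshold Crossing threshold; default midway between the global
#'   10% and 90% quantiles of the path traces.
#' @param spacing_mm Distance between consecutive path cells (mm); if
#'   `NULL`, taken from the unwrapped cell coordinates.
#' @return A one-row tibble: `speed_cells_per_s`, `speed_mm_per_s`,
#'   `flagged`, `n_crossed`.
#' @export
wave_front_speed <- function(record, path, type = c("smc", "ec"),
                             species = "ca_cyt", threshold = NULL,
                             spacing_mm = NULL) {
  type <- match.arg(type)
  block <- record[[type]][[species]][, path, drop = FALSE]
  tt <- record$times
  if (is.null(threshold)) {
    qs <- quantile(block, c(0.1, 0.9))
    threshold <- mean(qs)
  }
  arrive <- apply(block, 2, function(x) {
    i <- which(x[-1] >= threshold & x[-length(x)] < threshold)
    if (!length(i)) return(NA_real_)
    # linear interpolation of the crossing time
    i <- i[1]
    tt[i] + (threshold - x[i]) / (x[i + 1] - x[i]) * (tt[i + 1] - tt[i])
  })
  ok <- is.finite(arrive)
  meta <- record$cells[record$cells$cell_type == type, ]
  d <- if (is.null(spacing_mm)) {
    du <- c(0, cumsum(sqrt(diff(meta$u[path])^2 + diff(meta$v[path])^2)))
    du
  } else {
    (seq_along(path) - 1) * spacing_mm
  }
  if (sum(ok) < 3 || stats::sd(arrive[ok]) < median(diff(tt)) / 4) {
    return(tibble(speed_cells_per_s = NA_real_, speed_mm_per_s = NA_real_,
                  flagged = TRUE, n_crossed = sum(ok)))
  }
  fit <- stats::lm(arrive[ok] ~ d[ok])
  slope <- unname(stats::coef(fit)[2])  # s per mm
  cell_step <- mean(diff(d))
  tibble(speed_cells_per_s = 1 / (slope * cell_step),
         speed_mm_per_s = 1 / slope, flagged = FALSE, n_crossed = sum(ok))
}

# --- frequency-encoded phosphorylation -------------------------------------

#' Phosphorylation-cycle parameters
#'
#' Kinase/phosphatase cycle operating in the zero-order ultrasensitive
#' regime: reduced Michaelis constants `K_1`, `K_2` well below 1 make the
#' steady-state phosphorylated fraction a sharp sigmoidal switch in the
#' kinase/phosphatase rate ratio, crossing 1/2 at ratio 1.
#'
#' @param v_p Maximum phosphatase rate (1/s).
#' @param W_T Total target protein (normalized to 1).
#' @param K_1,K_2 Reduced Michaelis constants of the kinase and phosphatase
#'   steps (dimensionless; both 0.01 for the zero-order regime).
#' @param V_MK Maximum calcium-activated kinase rate (1/s).
#' @param K_a Calcium half-activation constant of the kinase (uM).
#' @return List of class `phospho_params`.
#' @export
phospho_params <- function(v_p = 2, W_T = 1, K_1 = 0.01, K_2 = 0.01,
                           V_MK = 4, K_a = 0.45) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) abort("phospho_params must all be positive")
  structure(p, class = "phospho_params")
}

#' Calcium-activated kinase rate
#'
#' Michaelis--Menten activation `v_k = V_MK * ca / (K_a + ca)`.
#'
#' @param ca Cytosolic calcium (uM), non-negative.
#' @param params [phospho_params()].
#' @return Kinase rate (1/s), bounded by `V_MK`.
#' @export
kinase_rate <- function(ca, params = phospho_params()) {
  if (any(ca < 0)) abort("`ca` must be non-negative")
  params$V_MK * ca / (params$K_a + ca)
}

#' Rate of change of the phosphorylated protein fraction
#'
#' `dW*/dt = v_p W_T [ (v_k/v_p)(1 - W*)/(K_1 + 1 - W*) - W*/(K_2 + W*) ]`.
#' The unit interval is invariant: the rate is non-negative at `W* = 0`
#' (strictly positive when `v_k > 0`) and negative at `W* = 1`.
#'
#' @param W_star Phosphorylated fraction in `[0, 1]`.
#' @param v_k Kinase rate (1/s), e.g. from [kinase_rate()].
#' @param params [phospho_params()].
#' @return dW*/dt (1/s).
#' @export
phospho_rate <- function(W_star, v_k, params = phospho_params()) {
  if (any(W_star < -1e-12) || any(W_star > 1 + 1e-12)) {
    abort("`W_star` must lie in [0, 1]")
  }
  p <- params
  p$v_p * p$W_T * ((v_k / p$v_p) * (1 - W_star) / (p$K_1 + 1 - W_star) -
                     W_star / (p$K_2 + W_star))
}

#' Steady-state phosphorylated fraction
#'
#' Root of [phospho_rate()] in `[0, 1]` for a constant kinase rate, found
#' by bisection.
#'
#' @param v_k Kinase rate (1/s).
#' @param params [phospho_params()].
#' @return Steady-state `W*`.
#' @export
phospho_steady_state <- function(v_k, params = phospho_params()) {
  vapply(v_k, function(v) {
    if (v <= 0) return(0)
    stats::uniroot(function(w) phospho_rate(w, v, params),
                   c(0, 1), tol = 1e-12)$root
  }, numeric(1))
}

#' Drive the phosphorylation cycle with a calcium trace
#'
#' Integrates the cycle with the kinase rate slaved to a (linearly
#' interpolated) cytosolic calcium trace.
#'
#' @param ca_trace Tibble/data frame with `time` (s) and `value` (uM), or a
#'   numeric vector sampled at `times`.
#' @param params [phospho_params()].
#' @param W0 Initial phosphorylated fraction.
#' @param times Sample times when `ca_trace` is a bare vector; also the
#'   output grid (defaults to the trace's own times).
#' @return Tibble with `time`, `ca`, `W_star`.
#' @export
simulate_phospho <- function(ca_trace, params = phospho_params(), W0 = 0,
                             times = NULL) {
  if (is.data.frame(ca_trace)) {
    times <- times %||% ca_trace$time
    ca_f <- approxfun(ca_trace$time, ca_trace$value, rule = 2)
  } else {
    if (is.null(times)) abort("`times` is required for a bare calcium vector")
    ca_f <- approxfun(times, ca_trace, rule = 2)
  }
  if (W0 < 0 || W0 > 1) abort("`W0` must lie in [0, 1]")
  f <- function(t, y, parms) {
    w <- min(max(y[1], 0), 1)
    list(phospho_rate(w, kinase_rate(ca_f(t), params), params))
  }
  sol <- deSolve::ode(c(W = W0), times, f, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  tibble(time = sol[, 1], ca = ca_f(sol[, 1]),
         W_star = pmin(pmax(sol[, 2], 0), 1))
}

#' Time-averaged phosphorylated fraction
#'
#' Trapezoidal mean of `W*(t)` over `[T_min, T_max]`.
#'
#' @param W_trace Tibble with `time` and `W_star` (as from
#'   [simulate_phospho()]).
#' @param T_min,T_max Window bounds (s); defaults to the whole trace.
#' @return Scalar mean fraction.
#' @export
time_average_W <- function(W_trace, T_min = NULL, T_max = NULL) {
  tt <- W_trace$time; w <- W_trace$W_star
  T_min <- T_min %||% min(tt); T_max <- T_max %||% max(tt)
  sel <- tt >= T_min - 1e-9 & tt <= T_max + 1e-9
  if (sum(sel) < 2) abort("averaging window contains fewer than 2 samples")
  pracma::trapz(tt[sel], w[sel]) / (max(tt[sel]) - min(tt[sel]))
}
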