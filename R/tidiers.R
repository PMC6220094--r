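# Broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy a simulation record into a long tibble
#'
#' @param x A `sim_record`.
#' @param species Character vector of state fields to include (default all
#'   recorded fields).
#' @param type Optional filter `"ec"` or `"smc"`.
#' @param cells Optional type-local indices to keep.
#' @param ... Unused.
#' @return Tibble with `time`, `type`, `index`, `species`, `value`.
#' @export
tidy.sim_record <- function(x, species = NULL, type = NULL, cells = NULL, ...) {
  types <- type %||% c("ec", "smc")
  out <- list()
  for (tp in types) {
    block <- x[[tp]]
    sp <- species %||% names(block)
    for (s in intersect(sp, names(block))) {
      m <- block[[s]]
      idx <- cells %||% seq_len(ncol(m))
      out[[paste(tp, s)]] <- tibble(
        time = rep(x$times, times = length(idx)),
        type = tp,
        index = rep(idx, each = length(x$times)),
        species = s,
        value = as.vector(m[, idx]))
    }
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a simulation record
#'
#' @param x A `sim_record`.
#' @param ... Unused.
#' @return Tibble with duration, snapshot count, cell counts and the
#'   range of recorded SMC calcium.
#' @export
glance.sim_record <- function(x, ...) {
  tibble(duration = max(x$times), n_snapshots = length(x$times),
         n_ec = x$n_ec, n_smc = x$n_smc,
         smc_ca_min = min(x$smc$ca_cyt), smc_ca_max = max(x$smc$ca_cyt),
         ec_ca_min = min(x$ec$ca_cyt), ec_ca_max = max(x$ec$ca_cyt))
}

#' @export
tidy.wave_metrics <- function(x, ...) as_tibble(unclass(x))

#' Summary of per-cell oscillation metrics
#'
#' @param x A `wave_metrics` tibble.
#' @param ... Unused.
#' @return One row per region: counts, fraction oscillatory, median period
#'   and amplitude.
#' @export
glance.wave_metrics <- function(x, ...) {
  as_tibble(unclass(x)) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n = dplyr::n(),
      frac_oscillatory = mean(.data$oscillatory),
      median_period = median(.data$period[.data$oscillatory], na.rm = TRUE),
      median_amplitude = median(.data$amplitude[.data$oscillatory], na.rm = TRUE),
      .groups = "drop")
}

#' @export
tidy.averaged_field <- function(x, ...) as_tibble(unclass(x))

#' Plot selected traces of a simulation record
#'
#' @param object A `sim_record`.
#' @param type `"smc"` or `"ec"`.
#' @param species State field.
#' @param cells Type-local indices to draw (default the first cell).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sim_record <- function(object, type = "smc", species = "ca_cyt",
                                cells = 1, ...) {
  df <- tidy(object, species = species, type = type, cells = cells)
  ggplot(df, aes(x = .data$time, y = .data$value,
                 group = .data$index, colour = factor(.data$index))) +
    geom_line() +
    labs(x = "time (s)", y = species, colour = "cell",
         title = sprintf("%s %s", toupper(type), species)) +
    theme_minimal()
}

#' Plot a time-averaged field on the unwrapped surface
#'
#' @param object An `averaged_field`.
#' @param type `"smc"` or `"ec"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.averaged_field <- function(object, type = "smc", ...) {
  df <- tidy(object) |> dplyr::filter(.data$type == !!type)
  ggplot(df, aes(x = .data$u, y = .data$v, colour = .data$mean_value)) +
    geom_point(size = 2) +
    scale_fill_viridis_c() +
    labs(x = "circumferential u (mm)", y = "axial v (mm)",
         colour = attr(object, "species")) +
    theme_minimal()
}

#' Plot the unwrapped cell map colored by region
#'
#' @param object An `unwrapped_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.unwrapped_map <- function(object, ...) {
  df <- as_tibble(unclass(object))
  ggplot(df, aes(x = .data$u, y = .data$v, colour = .data$region)) +
    geom_point(size = 1) +
    facet_wrap(~segment) +
    labs(x = "u (mm)", y = "v (mm)") +
    theme_minimal()
}

#' Plot per-cell oscillation metrics
#'
#' Period against amplitude for the oscillatory cells, colored by region;
#' non-oscillatory cells are dropped.
#'
#' @param object A `wave_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wave_metrics <- function(object, ...) {
  df <- tidy(object) |> dplyr::filter(.data$oscillatory)
  ggplot(df, aes(x = .data$period, y = .data$amplitude,
                 colour = .data$region)) +
    geom_point(alpha = 0.6) +
    labs(x = "period (s)", y = "amplitude (uM)") +
    theme_minimal()
}
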