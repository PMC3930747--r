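#' Broom-style tidiers and plots for analysis results
#'
#' `tidy()` returns a per-unit tibble (per residue, mode, bin or
#' position), `glance()` a one-row summary, and `autoplot()` a ggplot2
#' quick-look, for each of the package's result classes.
#'
#' @param x a result object.
#' @param ... unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy flexibility_report
#' @export
tidy.flexibility_report <- function(x, ...) {
  as_tibble(unclass(x)[c("residue", "sd_phi", "flexible", "glycine")])
}

#' @rdname tidiers
#' @method glance flexibility_report
#' @export
glance.flexibility_report <- function(x, ...) {
  tibble(
    n_residues = nrow(x),
    n_flexible = sum(x$flexible, na.rm = TRUE),
    threshold = attr(x, "threshold"),
    method = attr(x, "method"),
    state = attr(x, "state_label") %||% NA_character_
  )
}

#' @rdname tidiers
#' @param object a result object (ggplot2 `autoplot` convention).
#' @method autoplot flexibility_report
#' @export
autoplot.flexibility_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = residue, y = sd_phi, fill = glycine)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(
      yintercept = attr(object, "threshold"),
      linetype = "dashed"
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey25", `TRUE` = "black")) +
    ggplot2::labs(
      x = "residue", y = "phi dispersion (deg)",
      title = attr(object, "state_label") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy mode_set
#' @export
tidy.mode_set <- function(x, ...) {
  tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    fraction = x$values / sum(x$values),
    cum_fraction = cumsum(x$values) / sum(x$values)
  )
}

#' @rdname tidiers
#' @method glance mode_set
#' @export
glance.mode_set <- function(x, ...) {
  tibble(
    n_modes = length(x$values),
    total_variance = x$total_variance,
    top1_fraction = cumulative_variance(x, 1),
    top2_fraction = cumulative_variance(x, min(2, length(x$values))),
    degenerate = x$degenerate
  )
}

#' @rdname tidiers
#' @param n_modes number of leading modes shown.
#' @method autoplot mode_set
#' @export
autoplot.mode_set <- function(object, n_modes = 50, ...) {
  df <- head(tidy(object), n_modes)
  ggplot2::ggplot(df, ggplot2::aes(x = mode)) +
    ggplot2::geom_col(ggplot2::aes(y = fraction)) +
    ggplot2::geom_line(ggplot2::aes(y = cum_fraction)) +
    ggplot2::geom_point(ggplot2::aes(y = cum_fraction), size = 0.8) +
    ggplot2::labs(y = "variance fraction (bar) / cumulative (line)") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy projection_series
#' @export
tidy.projection_series <- function(x, ...) {
  df <- as_tibble(as.data.frame(x$values), .name_repair = "minimal")
  names(df) <- paste0("pc", x$modes)
  df$frame <- seq_len(nrow(df))
  df$time <- (df$frame - 1) * (x$dt %||% 1)
  dplyr::relocate(df, "frame", "time")
}

#' @rdname tidiers
#' @method tidy energy_landscape
#' @export
tidy.energy_landscape <- function(x, ...) {
  grid <- expand.grid(
    ix = seq_along(x$x_centers),
    iy = seq_along(x$y_centers)
  )
  xs <- x$x_centers[grid$ix]
  ys <- x$y_centers[grid$iy]
  gs <- as.vector(x$G)
  ns <- as.vector(x$counts)
  tibble(x = xs, y = ys, G = gs, count = ns)
}

#' @rdname tidiers
#' @method glance energy_landscape
#' @export
glance.energy_landscape <- function(x, ...) {
  tibble(
    n_bins_x = length(x$x_centers), n_bins_y = length(x$y_centers),
    n_occupied = sum(!is.na(x$G)), n_points = x$n,
    g_max = max(x$G, na.rm = TRUE), units = x$units,
    temperature = x$temperature
  )
}

#' @rdname tidiers
#' @method autoplot energy_landscape
#' @export
autoplot.energy_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = G)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      na.value = "white", direction = -1,
      name = paste0("G (", object$units, ")")
    ) +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy conservation_profile
#' @export
tidy.conservation_profile <- function(x, ...) {
  as_tibble(unclass(x)[c("position", "D", "n_nongap")])
}

#' @rdname tidiers
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = position, y = D)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(y = "conservation D (nats)") +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy sector_result
#' @export
tidy.sector_result <- function(x, ...) {
  x$weights
}

#' @rdname tidiers
#' @method glance sector_result
#' @export
glance.sector_result <- function(x, ...) {
  tibble(
    n_members = length(x$members),
    n_positions = nrow(x$weights),
    fraction = length(x$members) / nrow(x$weights),
    ic_index = x$ic_index, cdf_cutoff = x$cdf_cutoff,
    threshold = x$threshold, rule = x$rule
  )
}

#' @rdname tidiers
#' @method autoplot sector_result
#' @export
autoplot.sector_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = weight, fill = member)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(y = sprintf("IC%d weight", object$ic_index)) +
    ggplot2::theme_minimal()
}

#' @rdname tidiers
#' @method tidy sca_modes
#' @export
tidy.sca_modes <- function(x, ...) {
  tibble(
    mode = seq_along(x$values),
    eigenvalue = x$values,
    significant = seq_along(x$values) %in% x$retained
  )
}

#' @rdname tidiers
#' @method glance sca_modes
#' @export
glance.sca_modes <- function(x, ...) {
  tibble(
    n_retained = x$n_retained, null_max = x$null_max,
    n_null = length(x$null_values)
  )
}
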