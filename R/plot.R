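#' Plot an interaction-rate matrix
#'
#' Heat-map of the residue x site interaction rates, residues on the
#' vertical axis in tail order.
#'
#' @param object An `interaction_rate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_rate
#' @export
autoplot.interaction_rate <- function(object, ...) {
  tb <- object$table
  if (object$per_tail) {
    tb <- tb |> dplyr::summarise(rate = mean(.data$rate),
                                 .by = c("tail_residue", "site_id"))
  }
  tb |>
    dplyr::mutate(
      residue = factor(paste0("E", .data$tail_residue),
                       levels = rev(paste0("E", sort(unique(.data$tail_residue))))),
      site = paste("site", .data$site_id)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$site, y = .data$residue,
                                 fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA), name = "rate") +
    ggplot2::labs(
      title = sprintf("alphaCTT interaction rates (%s)", object$condition_tag),
      x = NULL, y = NULL,
      caption = sprintf("fraction of %d frames with >= 1 salt bridge",
                        object$n_frames)) +
    ggplot2::theme_minimal()
}

#' Plot an inaccessibility time series
#'
#' @param object An `accessibility_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot accessibility_series
#' @export
autoplot.accessibility_series <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$time_ns,
                               y = .data$inaccessible_fraction)) +
    ggplot2::geom_line(color = if (object$condition_tag == "GDP")
      "goldenrod3" else "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("Fraction of inaccessible tails (%s)",
                      object$condition_tag),
      x = "time (ns)", y = "inaccessible fraction") +
    ggplot2::theme_minimal()
}

#' Compare replicate series
#'
#' Per-replicate curves with the pooled mean over the common time support.
#'
#' @param object A `replicate_summary` from [aggregate_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot replicate_summary
#' @export
autoplot.replicate_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_replicate,
                  ggplot2::aes(x = .data$time_ns,
                               y = .data$inaccessible_fraction,
                               group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = object$pooled,
                       ggplot2::aes(group = NULL), linewidth = 1) +
    ggplot2::labs(title = sprintf("Inaccessibility, %d replicate(s) (%s)",
                                  max(object$per_replicate$replicate),
                                  object$condition_tag),
                  x = "time (ns)", y = "inaccessible fraction") +
    ggplot2::theme_minimal()
}

#' Tidiers for fitted result objects
#'
#' `tidy()` returns the underlying per-cell or per-frame tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x An `interaction_rate`, `accessibility_series` or
#'   `replicate_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy interaction_rate
#' @export
tidy.interaction_rate <- function(x, ...) {
  x$table |> dplyr::mutate(condition = x$condition_tag,
                           estimator = x$estimator)
}

#' @rdname tidiers
#' @method glance interaction_rate
#' @export
glance.interaction_rate <- function(x, ...) {
  top <- x$table |> dplyr::slice_max(.data$rate, n = 1L, with_ties = FALSE)
  tibble(condition = x$condition_tag, estimator = x$estimator,
         n_frames = x$n_frames, mean_rate = mean(x$table$rate),
         max_rate = top$rate, max_residue = top$tail_residue,
         max_site = top$site_id)
}

#' @rdname tidiers
#' @method tidy accessibility_series
#' @export
tidy.accessibility_series <- function(x, ...) {
  x$table |> dplyr::mutate(condition = x$condition_tag)
}

#' @rdname tidiers
#' @method glance accessibility_series
#' @export
glance.accessibility_series <- function(x, ...) {
  tibble(condition = x$condition_tag, n_frames = nrow(x$table),
         n_tails = x$n_tails,
         mean_fraction = mean(x$table$inaccessible_fraction),
         final_fraction = x$table$inaccessible_fraction[nrow(x$table)],
         smoothing_window = x$smoothing_window)
}

#' @rdname tidiers
#' @method tidy replicate_summary
#' @export
tidy.replicate_summary <- function(x, ...) x$per_replicate

#' @rdname tidiers
#' @method glance replicate_summary
#' @export
glance.replicate_summary <- function(x, ...) {
  tibble(condition = x$condition_tag,
         n_replicates = nrow(x$scalars),
         mean_fraction = mean(x$scalars$mean_fraction),
         pooled_frames = nrow(x$pooled))
}
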