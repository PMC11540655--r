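# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a procedure result
#'
#' One row per insertion event with relaxation statistics and the in-plane
#' displacement summary of the prostate at that event's snapshot.
#'
#' @param x A [run_procedure()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bs_procedure_result <- function(x, ...) {
  ev <- x$events
  if (nrow(ev) == 0) return(ev)
  stats <- dplyr::bind_rows(lapply(ev$event, function(e) {
    inplane_displacement_stats(x$snapshots[[e]], x$domain)[, 1:3]
  }))
  names(stats) <- paste0("inplane_", names(stats))
  dplyr::bind_cols(ev, stats)
}

#' Summarise a procedure result in one row
#'
#' @param x A [run_procedure()] result.
#' @param ... Unused.
#' @return One-row tibble: event counts, convergence, total iterations and
#'   final prostate displacement summaries.
#' @export
glance.bs_procedure_result <- function(x, ...) {
  stats <- inplane_displacement_stats(x$state, x$domain)
  umag <- sqrt(rowSums(x$state$u[x$domain$node_region == "prostate", ,
                                 drop = FALSE]^2))
  tibble::tibble(
    n_events = nrow(x$plan),
    n_snapshots = length(x$snapshots),
    all_converged = nrow(x$events) > 0 && all(x$events$converged),
    n_failed = length(x$failed_events),
    total_iterations = if (nrow(x$events) > 0) sum(x$events$iterations)
                       else 0L,
    anchor_stiffening = x$anchor_stiffening,
    mean_inplane_mm = stats$mean_mm,
    sd_inplane_mm = stats$sd_mm,
    max_inplane_mm = stats$max_mm,
    max_total_mm = max(umag))
}

#' Plot per-event displacement progression
#'
#' Mean and maximum in-plane prostate displacement after each insertion
#' event.
#'
#' @param object A [run_procedure()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bs_procedure_result <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td[, c("order_index", "event", "type", "inplane_mean_mm",
           "inplane_max_mm")],
    cols = c("inplane_mean_mm", "inplane_max_mm"),
    names_to = "statistic", values_to = "mm")
  long$statistic <- ifelse(long$statistic == "inplane_mean_mm", "mean",
                           "max")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$order_index, y = .data$mm,
                                     colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$type), size = 2) +
    ggplot2::labs(x = "insertion event", y = "in-plane displacement (mm)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a mid-slice of a voxel mask
#'
#' @param object A [voxel_mask()].
#' @param slice Slice index along z; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bs_voxel_mask <- function(object, slice = NULL, ...) {
  dm <- dim(object$data)
  if (is.null(slice)) slice <- ceiling(dm[3] / 2)
  df <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]))
  df$occupied <- as.vector(object$data[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$occupied)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("slice z=", slice)) +
    ggplot2::theme_minimal()
}

#' Plot a needle plan on the template face
#'
#' Entry positions on the insertion face, labelled by insertion order.
#'
#' @param object A [generate_needle_plan()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bs_needle_plan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$entry_x, y = .data$entry_y,
                                       colour = .data$type)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$order_index),
                       vjust = -1, size = 3, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}
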