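# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy pseudotime_fit
#' @export
tidy.pseudotime_fit <- function(x, ...) x$cells

#' @method glance pseudotime_fit
#' @export
glance.pseudotime_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_clusters = length(x$path),
    path = paste(x$path, collapse = " -> ")
  )
}

#' @method tidy delta_profiles
#' @export
tidy.delta_profiles <- function(x, ...) {
  out <- tibble::as_tibble(x$delta)
  out$gene <- rownames(x$delta)
  out <- tidyr::pivot_longer(out, -"gene", names_to = "bin", values_to = "delta")
  out$bin <- as.integer(sub("^bin", "", out$bin))
  dplyr::left_join(out, x$stats, by = "gene")
}

#' @method glance delta_profiles
#' @export
glance.delta_profiles <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$delta),
    n_bins = ncol(x$delta),
    conditions = paste(x$conditions, collapse = " vs "),
    n_significant = sum(x$stats$p <= 0.05, na.rm = TRUE)
  )
}

#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "m") <- NULL
  attr(out, "m0_estimate") <- NULL
  out
}

#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    m = attr(x, "m") %||% nrow(x),
    m0_estimate = attr(x, "m0_estimate") %||% NA_integer_,
    n_significant = sum(x$class == "significant"),
    n_trending = sum(x$class == "trending"),
    reference_mean = attr(x, "reference_mean") %||% NA_real_
  )
}

#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    stages = nrow(x$report),
    total_seconds = sum(x$report$seconds),
    n_cells = if (!is.null(x$counts)) ncol(x$counts) else NA_integer_,
    n_edges = if (!is.null(x$grn)) nrow(x$grn) else NA_integer_
  )
}

#' @method autoplot condition_density
#' @export
autoplot.condition_density <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t, y = .data$density,
                               colour = .data$condition)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "pseudotime", y = "cell density",
                  title = "Cell density along the trajectory") +
    ggplot2::theme_minimal()
}

#' @method autoplot delta_profiles
#' @export
autoplot.delta_profiles <- function(object, ...) {
  long <- tidy(object)
  ord <- order(apply(object$delta, 1, which.max))
  long$gene <- factor(long$gene, levels = rownames(object$delta)[ord])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$gene,
                                     fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = "pseudotime bin",
                  y = NULL,
                  fill = sprintf("delta\n(%s - %s)", object$conditions[2],
                                 object$conditions[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$relative_yfp,
                                   y = -log10(pmax(.data$p_adj, 1e-4)),
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.01), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = attr(object, "reference_mean"),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(significant = "#b2182b",
                                            trending = "#ef8a62",
                                            no_effect = "grey60")) +
    ggplot2::labs(x = "relative YFP (fraction of unablated control)",
                  y = expression(-log[10] ~ "adjusted p"),
                  title = "Crispant screen volcano") +
    ggplot2::theme_minimal()
}

#' @method autoplot pseudotime_fit
#' @export
autoplot.pseudotime_fit <- function(object, ...) {
  df <- object$cells
  df$cluster <- factor(df$cluster, levels = object$path)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, fill = .data$cluster)) +
    ggplot2::geom_histogram(bins = 50, position = "stack") +
    ggplot2::labs(x = "pseudotime", y = "cells",
                  title = "Cluster occupancy along pseudotime") +
    ggplot2::theme_minimal()
}
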