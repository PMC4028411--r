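#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stat map
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return The per-voxel tibble (`voxel`, `t`, `z`, `p`, coordinates and
#'   cluster labels when present).
#' @export
tidy.stat_map <- function(x, ...) x$table

#' One-row summary of a stat map
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @return Tibble with voxel count, df, cluster count and the minimum
#'   cluster FWE p (NA when no cluster survives).
#' @export
glance.stat_map <- function(x, ...) {
  has_cl <- !is.null(x$clusters) && nrow(x$clusters) > 0
  tibble::tibble(
    n_voxels = nrow(x$table),
    df = x$df,
    n_clusters = if (is.null(x$clusters)) NA_integer_ else nrow(x$clusters),
    max_extent = if (has_cl) max(x$clusters$extent) else 0L,
    min_p_fwe = if (has_cl && "p_fwe" %in% names(x$clusters))
      min(x$clusters$p_fwe) else NA_real_,
    p_voxel = x$p_voxel %||% NA_real_,
    min_extent = x$min_extent %||% NA_integer_,
    n_perm = x$n_perm %||% NA_integer_)
}

#' @export
tidy.power_analysis <- function(x, ...) tidy(x$group)

#' @export
glance.power_analysis <- function(x, ...) glance(x$group)

#' @export
tidy.coupling_analysis <- function(x, ...) tidy(x$group)

#' @export
glance.coupling_analysis <- function(x, ...) glance(x$group)

#' Plot a stat map as axial slice tiles
#'
#' Displays the per-voxel Z (or t) values slice by slice on the grid, with
#' surviving clusters outlined by their labels.
#'
#' @param object A `stat_map` with coordinates.
#' @param what Column to display (default `"z"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stat_map <- function(object, what = "z", ...) {
  tab <- object$table
  coords <- object$coords
  if (is.null(coords)) stop("stat map carries no coordinates", call. = FALSE)
  df <- tibble::tibble(x = coords[, 1], y = coords[, 2],
                       slice = factor(sprintf("z = %g mm", coords[, 3]),
                                      levels = sprintf("z = %g mm",
                                                       sort(unique(coords[, 3])))),
                       value = tab[[what]],
                       in_cluster = !is.na(tab$cluster %||%
                                             rep(NA_integer_, nrow(tab))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$in_cluster, ], fill = NA,
                       colour = "black", linewidth = 0.4) +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = what) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @export
autoplot.power_analysis <- function(object, ...) autoplot(object$group, ...)

#' @export
autoplot.coupling_analysis <- function(object, ...) autoplot(object$group, ...)

#' Plot condition-mean coupling per subject
#'
#' Paired baseline/cue coupling values at one voxel, one line per subject —
#' the consistency display behind "increase seen in k/n participants".
#'
#' @param analysis A `coupling_analysis`.
#' @param voxel Voxel index (default: the group peak voxel).
#' @return A ggplot object.
#' @export
plot_coupling_consistency <- function(analysis, voxel = NULL) {
  if (is.null(voxel)) {
    voxel <- analysis$group$table$voxel[which.max(analysis$group$table$t)]
  }
  cm <- analysis$condition_means
  cm <- cm[cm$voxel == voxel, ]
  df <- tidyr::pivot_longer(cm, c("mean_baseline", "mean_cue"),
                            names_to = "condition", values_to = "value")
  df$condition <- sub("mean_", "", df$condition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(y = paste(toupper(analysis$metric), "condition mean"),
                  x = NULL,
                  title = sprintf("voxel %d: increase in %d/%d subjects",
                                  voxel, sum(cm$difference > 0), nrow(cm)))
}
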