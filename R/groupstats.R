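# Second-level group statistics: per-subject seed selection, one-sample
# t maps across subjects, cluster-extent thresholding on the voxel grid,
# and sign-flip permutation control of the family-wise error rate of
# cluster extent. The permutation scheme replaces parametric random-field
# cluster correction: under the null the subject difference maps are
# symmetric about zero, so randomly flipping their signs generates the
# exact null distribution of the maximum cluster extent.

#' Select a subject's seed voxel near the group peak
#'
#' Returns the voxel with the largest subject contrast among voxels within
#' `radius` mm of the group peak coordinate, accounting for between-subject
#' variability in source location. Ties are broken by smaller distance to
#' the group peak, then by lower voxel index.
#'
#' @param contrast_map Tibble with `voxel`, `x`, `y`, `z` and `contrast`
#'   columns (e.g. a [power_contrast_map()] result).
#' @param group_peak_coord Length-3 numeric, group-level peak (mm).
#' @param radius Search radius in mm (default 20).
#' @return The selected voxel index.
#' @export
select_seed <- function(contrast_map, group_peak_coord, radius = 20) {
  xyz <- as.matrix(contrast_map[, c("x", "y", "z")])
  d <- sqrt(colSums((t(xyz) - group_peak_coord)^2))
  inside <- which(d <= radius + 1e-9)
  if (length(inside) == 0L) {
    stop("no voxel within the seed-search radius", call. = FALSE)
  }
  sub <- inside[order(-contrast_map$contrast[inside], d[inside],
                      contrast_map$voxel[inside])]
  as.integer(contrast_map$voxel[sub[1]])
}

#' One-sample t map over subjects
#'
#' Per voxel, `t = mean / (sd / sqrt(n))` with `df = n - 1` across subject
#' difference maps, with equivalent Z values obtained by matching upper-tail
#' probabilities of the t and standard normal distributions (clipped at
#' |Z| = 8). Voxels with zero variance across subjects are masked out (t =
#' NA) with a warning.
#'
#' @param subject_maps Numeric matrix, subjects x voxels, of per-subject
#'   difference values.
#' @param coords Optional voxel coordinate matrix (voxels x 3, mm).
#' @return A `stat_map` object: tibble `table` with per-voxel `t`, `z` and
#'   one-sided `p`, plus `df`.
#' @export
one_sample_t_map <- function(subject_maps, coords = NULL) {
  subject_maps <- as.matrix(subject_maps)
  n <- nrow(subject_maps)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  mu <- colMeans(subject_maps)
  sdv <- sqrt(colSums(sweep(subject_maps, 2, mu)^2) / (n - 1))
  tval <- rep(NA_real_, length(mu))
  ok <- sdv > 0
  if (any(!ok)) warning("zero-variance voxel(s) masked out of the t map")
  tval[ok] <- mu[ok] / (sdv[ok] / sqrt(n))
  df <- n - 1L
  logp <- stats::pt(tval, df, lower.tail = FALSE, log.p = TRUE)
  zval <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  zval <- pmin(8, pmax(-8, zval))
  tab <- tibble::tibble(voxel = seq_along(tval), t = tval, z = zval,
                        p = exp(logp))
  if (!is.null(coords)) {
    tab$x <- coords[, 1]; tab$y <- coords[, 2]; tab$z_mm <- coords[, 3]
  }
  structure(list(table = tab, df = df, coords = coords), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, df = %d", nrow(x$table), x$df))
  if (!is.null(x$clusters)) {
    cat(sprintf(", %d cluster(s)", nrow(x$clusters)))
  }
  cat("\n")
  if (!is.null(x$clusters) && nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# Precompute the 6-connectivity (faces only) neighbour list of a full grid
# from mm coordinates; voxels are neighbours iff exactly one coordinate
# differs by one grid step.
grid_neighbours <- function(coords, spacing = NULL) {
  coords <- as.matrix(coords)
  if (is.null(spacing)) {
    ux <- sort(unique(coords[, 1]))
    spacing <- if (length(ux) > 1) min(diff(ux)) else 10
  }
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- round(sweep(coords, 2, apply(coords, 2, min)) / spacing)
  lut <- stats::setNames(seq_len(nrow(ijk)), key(ijk))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lapply(seq_len(nrow(ijk)), function(v) {
    nb <- lut[key(sweep(offs, 2, ijk[v, ], `+`))]
    unname(nb[!is.na(nb)])
  })
}

# Connected components of a supra-threshold voxel set given the full-grid
# neighbour list; returns integer labels (0 = sub-threshold).
label_components <- function(supra, neighbours) {
  labels <- integer(length(neighbours))
  cur <- 0L
  in_set <- logical(length(neighbours))
  in_set[supra] <- TRUE
  for (v in supra) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    labels[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- neighbours[[u]]
      nb <- nb[in_set[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Cluster-extent thresholding of a stat map
#'
#' Voxels exceeding the one-sided `p_voxel` threshold are grouped into
#' connected components under 6-connectivity (faces only) on the grid;
#' components smaller than `min_extent` voxels are discarded.
#'
#' @param stat_map A [one_sample_t_map()] result (must carry coordinates).
#' @param coords Voxel coordinates (voxels x 3, mm); defaults to those
#'   stored in the map.
#' @param p_voxel One-sided voxel-level p threshold (default 0.001).
#' @param min_extent Minimum cluster extent in voxels (default 10).
#' @param spacing Grid spacing in mm (inferred if NULL).
#' @param neighbours Optional precomputed neighbour list (for repeated
#'   calls on the same grid).
#' @return The `stat_map` with a `cluster` column added to its table (NA =
#'   unclustered) and a `clusters` summary tibble (`cluster`, `extent`,
#'   `peak_voxel`, `peak_t`).
#' @export
cluster_threshold <- function(stat_map, coords = NULL, p_voxel = 0.001,
                              min_extent = 10L, spacing = NULL,
                              neighbours = NULL) {
  stopifnot(inherits(stat_map, "stat_map"))
  if (is.null(coords)) coords <- stat_map$coords
  if (is.null(coords)) stop("voxel coordinates required for clustering", call. = FALSE)
  if (is.null(neighbours)) neighbours <- grid_neighbours(coords, spacing)
  tcrit <- stats::qt(p_voxel, stat_map$df, lower.tail = FALSE)
  supra <- which(!is.na(stat_map$table$t) & stat_map$table$t > tcrit)
  labels <- label_components(supra, neighbours)
  keep <- which(tabulate(labels) >= min_extent)
  labels[!labels %in% keep] <- 0L
  relab <- match(labels, sort(unique(labels[labels > 0L])))
  stat_map$table$cluster <- ifelse(labels > 0L, relab, NA_integer_)
  cl <- sort(unique(stats::na.omit(stat_map$table$cluster)))
  stat_map$clusters <- dplyr::bind_rows(lapply(cl, function(k) {
    rows <- which(stat_map$table$cluster == k)
    pk <- rows[which.max(stat_map$table$t[rows])]
    tibble::tibble(cluster = k, extent = length(rows),
                   peak_voxel = stat_map$table$voxel[pk],
                   peak_t = stat_map$table$t[pk],
                   peak_z = stat_map$table$z[pk])
  }))
  stat_map$p_voxel <- p_voxel
  stat_map$min_extent <- as.integer(min_extent)
  stat_map
}

# t statistics for sign-flipped subject maps; flips is n_perm x n_subjects
# of +/-1. Sums of squares are flip-invariant, so only the mean changes.
flip_t <- function(subject_maps, flips) {
  n <- nrow(subject_maps)
  ss <- colSums(subject_maps^2)
  mu <- (flips %*% subject_maps) / n          # n_perm x voxels
  varv <- sweep(-n * mu^2, 2, ss, `+`) / (n - 1)
  varv[varv < 0] <- 0
  mu / sqrt(varv / n)
}

#' Cluster-level FWE by sign-flip permutation
#'
#' Builds the null distribution of the maximum supra-threshold cluster
#' extent by randomly flipping the sign of each subject's difference map
#' (valid under the one-sample null of symmetric differences), and assigns
#' each observed cluster `p_fwe = (1 + #{null max extent >= observed}) /
#' (n_perm + 1)`.
#'
#' @param subject_maps Subjects x voxels matrix of difference values.
#' @param coords Voxel coordinates (voxels x 3, mm).
#' @param p_voxel One-sided voxel threshold (default 0.001).
#' @param min_extent Minimum cluster extent (default 10).
#' @param n_perm Number of sign-flip permutations (default 1000; >= 1000
#'   recommended, < 100 draws a warning).
#' @param spacing Grid spacing in mm.
#' @return A `stat_map` with clusters and their `p_fwe`, plus the null
#'   maximum-extent distribution in `null_max_extent`.
#' @export
cluster_fwe_permutation <- function(subject_maps, coords, p_voxel = 0.001,
                                    min_extent = 10L, n_perm = 1000L,
                                    spacing = NULL) {
  subject_maps <- as.matrix(subject_maps)
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse FWE p-value")
  neighbours <- grid_neighbours(coords, spacing)
  sm <- one_sample_t_map(subject_maps, coords)
  sm <- cluster_threshold(sm, coords, p_voxel, min_extent,
                          spacing = spacing, neighbours = neighbours)
  n <- nrow(subject_maps)
  tcrit <- stats::qt(p_voxel, n - 1L, lower.tail = FALSE)
  flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  tnull <- flip_t(subject_maps, flips)
  null_max <- vapply(seq_len(n_perm), function(i) {
    supra <- which(!is.na(tnull[i, ]) & tnull[i, ] > tcrit)
    if (length(supra) == 0L) return(0L)
    labels <- label_components(supra, neighbours)
    sizes <- tabulate(labels)
    sizes <- sizes[sizes >= min_extent]
    if (length(sizes)) max(sizes) else 0L
  }, integer(1))
  if (!is.null(sm$clusters) && nrow(sm$clusters)) {
    sm$clusters$p_fwe <- vapply(sm$clusters$extent, function(e) {
      (1 + sum(null_max >= e)) / (n_perm + 1)
    }, numeric(1))
  }
  sm$null_max_extent <- null_max
  sm$n_perm <- as.integer(n_perm)
  sm
}
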