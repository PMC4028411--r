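# Trial-covariate normalization and linear residualization. Power and
# coupling measures can be biased by trial-to-trial changes in eye-movement
# artifacts and by signal-to-noise (oscillatory power) changes; regressing
# those covariates out across all 72 trial windows, pooled over conditions,
# leaves residual measures whose condition contrast cannot be explained by
# linear effects of the covariates. Condition itself is deliberately NOT a
# regressor: including it would absorb the effect of interest.

#' Normalize a trial covariate to mean 0, sd 1
#'
#' Uses the sample standard deviation (n - 1 denominator).
#'
#' @param values Numeric vector of per-trial covariate values (n >= 2,
#'   non-constant).
#' @return Normalized vector.
#' @examples
#' normalize_covariate(c(1, 2, 3))  # -1 0 1
#' @export
normalize_covariate <- function(values) {
  if (length(values) < 2L) stop("need at least 2 trials", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate covariate: constant across trials", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Residualize a per-trial measure against covariates
#'
#' Ordinary least squares of the response on the covariate columns plus an
#' intercept, fitted across all trial windows pooled over conditions;
#' returns the residuals. Covariates are normalized internally with
#' [normalize_covariate()]. Condition labels are untouched and carried to
#' the second-level contrast by the caller.
#'
#' @param response Numeric per-trial response vector.
#' @param covariates A data frame / tibble of per-trial covariate columns
#'   (e.g. eye-movement variance, seed power, source power).
#' @return Residual vector, same length as `response`.
#' @export
residualize <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  n <- length(response)
  if (nrow(covariates) != n) {
    stop("response and covariates must have the same number of trials",
         call. = FALSE)
  }
  if (n <= ncol(covariates) + 1L) {
    stop("need more trials than covariates + intercept", call. = FALSE)
  }
  X <- cbind(`(intercept)` = 1,
             as.matrix(as.data.frame(lapply(covariates, normalize_covariate))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  as.numeric(qr.resid(qrX, response))
}

#' Residualize every voxel of a coupling or power map
#'
#' Applies [residualize()] per voxel across the 2 x n_trials window rows of
#' a per-trial map. Shared covariates (eye variance, seed power) are common
#' to all voxels; the per-voxel source power covariate, if supplied, is
#' matched to each voxel independently.
#'
#' @param trial_map Tibble with columns `voxel`, `trial`, `condition`,
#'   `value` (or `power`).
#' @param shared Tibble of shared per-trial-window covariates, with `trial`
#'   and `condition` columns plus one column per covariate, ordered like the
#'   map rows within each voxel.
#' @param source_power Optional tibble `voxel`, `trial`, `condition`,
#'   `power` giving the per-voxel power covariate.
#' @return The map tibble with `value` replaced by residuals.
#' @details All voxels share the eye/seed covariates, so their projection is
#'   computed once and the per-voxel source-power column handled as a rank-1
#'   update (Frisch-Waugh); the result equals per-voxel OLS. A source-power
#'   column that is collinear with the shared covariates (e.g. at the seed
#'   voxel, where source power equals seed power) drops out automatically.
#' @export
residualize_map <- function(trial_map, shared, source_power = NULL) {
  value_col <- if ("value" %in% names(trial_map)) "value" else "power"
  ord <- order(trial_map$voxel, trial_map$trial, trial_map$condition)
  tm <- trial_map[ord, ]
  vox <- unique(tm$voxel)
  n <- nrow(tm) / length(vox)
  if (n != round(n)) stop("unbalanced trial map", call. = FALSE)
  R <- matrix(tm[[value_col]], n, length(vox))
  rows1 <- tm[seq_len(n), c("trial", "condition")]
  covkey <- paste(rows1$trial, rows1$condition)
  shared_m <- as.matrix(shared[match(covkey, paste(shared$trial, shared$condition)),
                               setdiff(names(shared), c("trial", "condition")),
                               drop = FALSE])
  if (anyNA(shared_m)) stop("covariate table does not cover all trials", call. = FALSE)
  if (n <= ncol(shared_m) + 1L + !is.null(source_power)) {
    stop("need more trials than covariates + intercept", call. = FALSE)
  }
  X <- cbind(`(intercept)` = 1, apply(shared_m, 2, normalize_covariate))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Q <- qr.Q(qrX)
  E <- R - Q %*% crossprod(Q, R)
  if (!is.null(source_power)) {
    spkey <- paste(source_power$voxel, source_power$trial,
                   source_power$condition)
    want <- paste(rep(vox, each = n), rep(rows1$trial, length(vox)),
                  rep(rows1$condition, length(vox)))
    S <- matrix(source_power$power[match(want, spkey)], n, length(vox))
    if (anyNA(S)) stop("source power table does not cover all voxels/trials",
                       call. = FALSE)
    S <- scale(S)
    S[is.na(S)] <- 0
    ES <- S - Q %*% crossprod(Q, S)
    den <- colSums(ES^2)
    beta <- ifelse(den > 1e-8 * (n - 1), colSums(ES * E) / den, 0)
    E <- E - sweep(ES, 2, beta, `*`)
  }
  res <- numeric(nrow(tm))
  res[ord] <- as.numeric(E)
  trial_map[[value_col]] <- res
  trial_map
}
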