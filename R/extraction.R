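#' Extract a region's average time series (AVT)
#'
#' Collapses a voxel x scan matrix into the single representative BOLD time
#' course of a region of interest. Two conventions are offered, because both
#' are in use for ROI summaries:
#' \describe{
#'   \item{`mean`}{element-wise average of the voxel series per scan (the
#'     default).}
#'   \item{`eigenvariate`}{temporal projection of the first singular
#'     direction of the matrix, rescaled to the root-mean-square of the
#'     input and sign-aligned so that its correlation with the voxel mean is
#'     non-negative.}
#' }
#'
#' @param voxel_matrix Numeric voxel x scan matrix (`>= 1` voxel,
#'   `>= 2` scans).
#' @param method `"mean"` or `"eigenvariate"`.
#' @return Numeric vector of length `n_scans`.
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' extract_avt(x, "mean")
#' @export
extract_avt <- function(voxel_matrix, method = c("mean", "eigenvariate")) {
  method <- match.arg(method)
  voxel_matrix <- as.matrix(voxel_matrix)
  if (nrow(voxel_matrix) < 1 || ncol(voxel_matrix) < 2) {
    stop("voxel_matrix needs >= 1 voxel and >= 2 scans", call. = FALSE)
  }
  if (anyNA(voxel_matrix)) stop("voxel_matrix contains missing values",
                                call. = FALSE)
  if (method == "mean") {
    return(colMeans(voxel_matrix))
  }
  if (stats::sd(as.vector(voxel_matrix)) == 0) {
    stop("eigenvariate undefined for an all-constant matrix", call. = FALSE)
  }
  sv <- svd(voxel_matrix, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  rms <- sqrt(mean(voxel_matrix^2))
  out <- v1 / sqrt(mean(v1^2)) * rms
  m <- colMeans(voxel_matrix)
  if (stats::sd(m) > 0 && stats::cor(out, m) < 0) out <- -out
  out
}

#' Select the scans of one condition from a block schedule
#'
#' Returns the columns of a series that the schedule labels with the given
#' condition, preserving run order then within-run scan order — the
#' concatenated condition epochs used for per-condition connectivity
#' estimation. AP, IP and REST selections partition the scans.
#'
#' @param series Numeric vector (scan-length) or ROI x scan matrix.
#' @param schedule Schedule data frame from [make_design()]; must have
#'   exactly one row per scan of `series`.
#' @param condition Condition label to select.
#' @return Object of the same kind as `series`, restricted to the selected
#'   scans.
#' @export
select_condition_epochs <- function(series, schedule, condition) {
  is_mat <- is.matrix(series)
  n_scans <- if (is_mat) ncol(series) else length(series)
  if (nrow(schedule) != n_scans) {
    stop(sprintf("schedule has %d rows but series has %d scans",
                 nrow(schedule), n_scans), call. = FALSE)
  }
  if (!condition %in% schedule$condition) {
    stop(sprintf("condition '%s' does not occur in the schedule", condition),
         call. = FALSE)
  }
  ord <- order(schedule$run, schedule$scan)
  keep <- ord[schedule$condition[ord] == condition]
  if (is_mat) series[, keep, drop = FALSE] else series[keep]
}

#' Remove a per-series linear trend
#'
#' Least-squares detrending along time; `order = 0` is the identity,
#' `order = 1` removes each series' best-fit line (intercept and slope).
#' Offered as the one temporal filter of this pipeline — scanner drift is
#' the dominant slow nuisance in block-design ROI series.
#'
#' @param series Numeric vector or ROI x scan matrix.
#' @param order 0 (none) or 1 (linear).
#' @return Detrended object of the same shape.
#' @export
detrend <- function(series, order = 1) {
  if (!order %in% c(0, 1)) stop("order must be 0 or 1", call. = FALSE)
  if (order == 0) return(series)
  detrend_vec <- function(y) {
    t <- seq_along(y)
    stats::lsfit(t, y)$residuals
  }
  if (is.matrix(series)) {
    out <- t(apply(series, 1, detrend_vec))
    dimnames(out) <- dimnames(series)
    out
  } else {
    unname(detrend_vec(series))
  }
}
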