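#' Lagged cross-correlation between two series
#'
#' Computes `rho(tau) = K(tau) / (sd_x * sd_y)` for every integer lag
#' `tau` in `-lag_max .. lag_max`, where the cross-covariance is
#' `K(tau) = (1/T) * sum_t (x(t + tau) - mean_x) * (y(t) - mean_y)` with the
#' sum truncated to the overlap of the shifted series (no padding), and the
#' means and standard deviations are taken over each full series with `1/T`
#' normalization. These are the classical time-series estimator conventions
#' (the same ones [stats::ccf()] implements), so a perfectly shifted copy of
#' a signal scores slightly below 1 at its true lag because the overlap is
#' shorter than the series.
#'
#' @param x,y numeric series of equal length `T >= 2`, neither constant.
#' @param lag_max non-negative integer, strictly less than `T`.
#' @return Named numeric vector of correlations, names = lags
#'   `-lag_max .. lag_max`.
#' @export
cross_correlation <- function(x, y, lag_max) {
  x <- as.numeric(x); y <- as.numeric(y)
  T <- length(x)
  if (length(y) != T) stop("series must have equal length", call. = FALSE)
  if (T < 2L) stop("series must have at least two samples", call. = FALSE)
  if (!is.numeric(lag_max) || length(lag_max) != 1L || lag_max < 0 ||
      lag_max != round(lag_max))
    stop("lag_max must be a non-negative integer", call. = FALSE)
  if (lag_max >= T) stop("lag_max must be smaller than the series length", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
  if (sx == 0 || sy == 0) stop("constant series have no defined correlation", call. = FALSE)
  taus <- seq.int(-lag_max, lag_max)
  rho <- vapply(taus, function(tau) {
    k <- if (tau >= 0) sum(xc[(1 + tau):T] * yc[seq_len(T - tau)]) / T
    else sum(xc[seq_len(T + tau)] * yc[(1 - tau):T]) / T
    k / (sx * sy)
  }, numeric(1))
  stats::setNames(rho, taus)
}

# lag preference order for best-lag tie-breaking: 0, -1, +1, -2, +2, ...
lag_preference <- function(lag_max) {
  if (lag_max == 0) return(0L)
  c(0L, as.vector(rbind(-seq_len(lag_max), seq_len(lag_max))))
}

#' Functional connectivity matrix from lagged cross-correlation
#'
#' For every cell pair the cross-correlation profile over lags
#' `-lag_max .. lag_max` is computed and the maximum absolute value is taken
#' as the connection strength (`rho_max`), accommodating short response
#' delays between cells. The lag attaining the maximum is recorded, ties
#' resolved deterministically by smallest `|tau|`, then negative before
#' positive. The default single-frame lag window (`lag_max = 1`) captures
#' next-frame delays at typical acquisition rates.
#'
#' Constant cells carry no correlation information; their rows and columns
#' are set to 0 (isolating them in any thresholded graph) with a warning.
#'
#' @param traces a `normalized_traces` or `binary_raster` (the `source` tag
#'   records which).
#' @param lag_max non-negative integer lag window half-width (default 1).
#' @return A `connectivity_matrix`: `rho_max` (symmetric, diagonal 1, values
#'   in `[0, 1]`), `best_lag` (integer matrix), `lag_set`, `source`,
#'   `cell_ids`.
#' @export
connectivity_matrix <- function(traces, lag_max = 1) {
  x <- trace_values(traces)
  storage.mode(x) <- "double"
  n <- nrow(x); T <- ncol(x)
  if (n < 2L) stop("connectivity requires at least two cells", call. = FALSE)
  if (!is.numeric(lag_max) || length(lag_max) != 1L || lag_max < 0 ||
      lag_max != round(lag_max))
    stop("lag_max must be a non-negative integer", call. = FALSE)
  if (lag_max >= T) stop("lag_max must be smaller than the recording length", call. = FALSE)
  source_tag <- if (inherits(traces, "binary_raster")) "binarized"
  else if (inherits(traces, "normalized_traces")) "normalized"
  else "raw"
  xc <- x - rowMeans(x)
  sdev <- sqrt(rowMeans(xc^2))
  flat <- sdev == 0
  if (any(flat)) {
    warning("constant cell(s) set to zero connectivity: ",
            paste(traces$cell_ids[flat], collapse = ", "), call. = FALSE)
    sdev[flat] <- 1 # numerators are zero for these cells
  }
  denom <- outer(sdev, sdev)
  rho_max <- matrix(-1, n, n)
  best <- matrix(0L, n, n)
  for (tau in lag_preference(lag_max)) {
    # K_ij(tau) = (1/T) sum_t xc_i(t+tau) * xc_j(t), truncated overlap
    K <- if (tau >= 0)
      xc[, (1 + tau):T, drop = FALSE] %*% t(xc[, seq_len(T - tau), drop = FALSE]) / T
    else
      xc[, seq_len(T + tau), drop = FALSE] %*% t(xc[, (1 - tau):T, drop = FALSE]) / T
    a <- abs(K / denom)
    upd <- a > rho_max # strict: earlier (preferred) lags win ties
    rho_max[upd] <- a[upd]
    best[upd] <- tau
  }
  rho_max <- (rho_max + t(rho_max)) / 2 # exact symmetry against rounding
  rho_max <- pmin(pmax(rho_max, 0), 1)
  rho_max[flat, ] <- 0
  rho_max[, flat] <- 0
  best[flat, ] <- 0L
  best[, flat] <- 0L
  diag(rho_max) <- 1
  diag(best) <- 0L
  dimnames(rho_max) <- dimnames(best) <- list(traces$cell_ids, traces$cell_ids)
  structure(list(rho_max = rho_max, best_lag = best,
                 lag_set = seq.int(-lag_max, lag_max), source = source_tag,
                 cell_ids = traces$cell_ids),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$rho_max[upper.tri(x$rho_max)]
  cat("<connectivity_matrix> ", nrow(x$rho_max), " cells, lags {",
      paste(x$lag_set, collapse = ", "), "}, source = ", x$source,
      ", median |rho_max| = ", signif(stats::median(off), 3), "\n", sep = "")
  invisible(x)
}
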