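#' Per-cell min-max normalization
#'
#' Rescales each cell's trace to `[0, 1]` via
#' `x'_t = (x_t - min(x)) / (max(x) - min(x))`, with the minimum and maximum
#' taken over that cell's full recording. This removes per-cell differences in
#' indicator expression level so cells are comparable; it is sensitive to
#' outlier frames, which set the bounds.
#'
#' A constant trace has no range; it maps to all zeros (keeping matrix shapes
#' intact downstream) and a warning names the cell.
#'
#' @param t a [trace_matrix()].
#' @return A `normalized_traces` object (`method = "minmax"`), values in
#'   `[0, 1]`; every non-constant row attains both 0 and 1.
#' @export
normalize_minmax <- function(t) {
  x <- trace_values(t)
  lo <- apply(x, 1L, min)
  hi <- apply(x, 1L, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning("constant trace(s) mapped to all zeros by min-max normalization: ",
            paste(t$cell_ids[flat], collapse = ", "), call. = FALSE)
    rng[flat] <- 1 # arbitrary; numerator is zero for these rows
  }
  out <- (x - lo) / rng
  new_trace_like(out, t, "normalized_traces", list(method = "minmax"))
}

#' Per-cell z-score normalization
#'
#' Centers each cell's trace to mean zero and scales to unit sample variance.
#' Unlike min-max the output is unbounded; it is offered as an alternative
#' preprocessing route and is not the pipeline default.
#'
#' @param t a [trace_matrix()].
#' @return A `normalized_traces` object (`method = "zscore"`).
#' @export
normalize_zscore <- function(t) {
  x <- trace_values(t)
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, stats::sd)
  if (any(sdev == 0))
    stop("zero-variance trace(s) cannot be z-scored: ",
         paste(t$cell_ids[sdev == 0], collapse = ", "), call. = FALSE)
  new_trace_like((x - mu) / sdev, t, "normalized_traces", list(method = "zscore"))
}

#' Binarize traces into active/inactive states
#'
#' A cell is active at frame `t` when its (normalized) signal strictly exceeds
#' `mean + k * sd`, both statistics taken over that cell's full recording and
#' the standard deviation being the sample (n-1) estimate. The default
#' `k = 2` flags excursions two standard deviations above baseline —
#' pronounced calcium transients — while suppressing small fluctuations.
#' Because the threshold co-varies with the trace's own mean and sd, the
#' raster is invariant to per-cell affine rescaling of the input.
#'
#' A custom rule replaces the threshold entirely: it receives one cell's
#' numeric trace and must return a logical (or 0/1) vector of the same length.
#'
#' @param n a `normalized_traces` (or any trace-shaped container).
#' @param k non-negative multiplier on the per-cell standard deviation.
#' @param custom_rule optional `function(x)` deciding activity per frame.
#' @return A `binary_raster` with a `threshold_spec` record of the rule used.
#' @export
binarize <- function(n, k = 2, custom_rule = NULL) {
  x <- trace_values(n)
  nt <- ncol(x)
  if (!is.null(custom_rule)) {
    stopifnot(is.function(custom_rule))
    out <- t(apply(x, 1L, function(row) {
      b <- custom_rule(row)
      if (length(b) != length(row))
        stop("custom_rule must return one value per time point", call. = FALSE)
      as.integer(as.logical(b))
    }))
    spec <- list(rule = "custom")
  } else {
    if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
      stop("k must be a non-negative scalar", call. = FALSE)
    mu <- rowMeans(x)
    sdev <- apply(x, 1L, stats::sd)
    if (any(sdev == 0))
      warning("constant trace(s) produce an all-zero raster row: ",
              paste(n$cell_ids[sdev == 0], collapse = ", "), call. = FALSE)
    thr <- mu + k * sdev
    out <- (x > thr) * 1L
    out[sdev == 0, ] <- 0L
    spec <- list(rule = "mean_plus_k_sd", k = k)
  }
  storage.mode(out) <- "integer"
  new_trace_like(out, n, "binary_raster", list(threshold_spec = spec))
}
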