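#' Principal component analysis of trace matrices
#'
#' Runs PCA on the normalized traces with cells as observations and time
#' points as variables — the literal orientation of passing a cells-by-time
#' matrix to [stats::prcomp()] — centering each variable but not rescaling
#' it. The fraction of variance captured by the leading components
#' summarizes how low-dimensional the population activity is: a few dominant
#' activity patterns concentrate variance in the first components, while
#' complex, heterogeneous activity spreads it out. `orientation = "time"`
#' transposes the analysis (time points as observations) for exploration.
#'
#' @param n a `normalized_traces` (or trace-shaped container) with at least
#'   two cells.
#' @param orientation `"cells"` (default) or `"time"`.
#' @return A `pca_result`: `explained_ratio` (fractions of variance,
#'   non-increasing, summing to 1 over the `min(n_obs - 1, n_var)` retained
#'   components), `top5_percent` (percentage of variance in the first
#'   `min(5, n_components)` components), `n_components`, and `sdev`.
#' @export
pca_traces <- function(n, orientation = c("cells", "time")) {
  orientation <- match.arg(orientation)
  x <- trace_values(n)
  if (orientation == "time") x <- t(x)
  if (nrow(x) < 2L)
    stop("PCA requires at least two observations (cells)", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ncomp <- min(nrow(x) - 1L, ncol(x))
  ev <- pc$sdev[seq_len(ncomp)]^2
  total <- sum(pc$sdev^2)
  ratio <- if (total > 0) ev / total else rep(0, ncomp)
  structure(list(explained_ratio = ratio,
                 top5_percent = 100 * sum(ratio[seq_len(min(5L, ncomp))]),
                 n_components = ncomp,
                 sdev = ev^0.5,
                 orientation = orientation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", x$n_components, " components; top-5 variance = ",
      signif(x$top5_percent, 4), "%\n", sep = "")
  invisible(x)
}

# internal: periodic window of length n
psd_window <- function(window, n) {
  switch(window,
         hann = 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)),
         rectangular = rep(1, n),
         stop("unknown window '", window, "'; use \"hann\" or \"rectangular\"",
              call. = FALSE))
}

#' Welch power spectral density per cell
#'
#' Estimates each cell's PSD by averaging modified periodograms over
#' overlapping windowed segments: the trace is cut into segments of
#' `segment_len` samples advancing by `segment_len * (1 - overlap_frac)`,
#' each segment is demeaned, multiplied by the taper, Fourier transformed,
#' and the one-sided power densities are averaged. Averaging trades
#' frequency resolution for variance reduction relative to the raw
#' periodogram. Power is scaled per unit frequency
#' (`1 / (fs * sum(w^2))`, interior bins doubled), so integrating the
#' spectrum over frequency approximates the signal variance.
#'
#' With a rectangular window, zero overlap and `segment_len = n_time`, the
#' estimate reduces to the plain periodogram.
#'
#' @param n a `normalized_traces` (or trace-shaped container).
#' @param frame_interval_s seconds per frame (default: the container's own);
#'   the sampling rate is its reciprocal.
#' @param segment_len samples per segment; default `min(256, n_time)`.
#' @param overlap_frac fractional overlap between consecutive segments in
#'   `[0, 1)`; default 0.5.
#' @param window `"hann"` (default) or `"rectangular"`.
#' @return A `psd_result`: `freqs_hz` (0 to Nyquist) and `power`
#'   (`n_cells x n_freqs`, nonnegative).
#' @export
welch_psd <- function(n, frame_interval_s = n$frame_interval_s,
                      segment_len = NULL, overlap_frac = 0.5,
                      window = "hann") {
  x <- trace_values(n)
  nt <- ncol(x)
  if (is.null(segment_len)) segment_len <- min(256L, nt)
  segment_len <- as.integer(segment_len)
  if (segment_len < 2L || segment_len > nt)
    stop("segment_len must be between 2 and n_time (", nt, ")", call. = FALSE)
  if (!is.numeric(overlap_frac) || overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)", call. = FALSE)
  fs <- 1 / frame_interval_s
  w <- psd_window(window, segment_len)
  step <- max(1L, as.integer(floor(segment_len * (1 - overlap_frac))))
  starts <- seq.int(1L, nt - segment_len + 1L, by = step)
  nfreq <- segment_len %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * fs / segment_len
  scale <- 1 / (fs * sum(w^2))
  # interior bins carry both halves of the two-sided spectrum
  fold <- rep(2, nfreq)
  fold[1L] <- 1
  if (segment_len %% 2L == 0L) fold[nfreq] <- 1
  power <- matrix(0, nrow(x), nfreq)
  for (s in starts) {
    seg <- x[, s:(s + segment_len - 1L), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * rep(w, each = nrow(seg))
    ft <- t(apply(seg, 1L, stats::fft))
    if (nrow(x) == 1L) ft <- matrix(ft, nrow = 1L)
    power <- power + Mod(ft[, seq_len(nfreq), drop = FALSE])^2 * scale
  }
  power <- power / length(starts)
  power <- power * rep(fold, each = nrow(power))
  dimnames(power) <- list(n$cell_ids, NULL)
  structure(list(freqs_hz = freqs, power = power,
                 segment_len = segment_len, overlap_frac = overlap_frac,
                 window = window, fs = fs),
            class = "psd_result")
}

#' @export
print.psd_result <- function(x, ...) {
  cat("<psd_result> ", nrow(x$power), " cells x ", length(x$freqs_hz),
      " frequencies (0-", signif(max(x$freqs_hz), 4), " Hz), ",
      x$window, " window, segment ", x$segment_len, "\n", sep = "")
  invisible(x)
}
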