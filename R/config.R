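#' Pipeline configuration
#'
#' Builds the flat key-value configuration consumed by [run_pipeline()].
#' Unset keys take the package defaults; the `"strict"` preset raises the
#' edge threshold to 0.6 (with a single-frame lag window), a conservative
#' setting that keeps only strong correlations.
#'
#' Keys (dots group keys by stage):
#' \describe{
#'   \item{normalization.method}{`"minmax"` (default) or `"zscore"`.}
#'   \item{binarize.k}{sd multiplier for the activity threshold (default 2).}
#'   \item{events.mode}{`"onsets"` (default) or `"frames"`.}
#'   \item{cluster.linkage / cluster.metric}{raster ordering; defaults
#'     `"ward"` / `"euclidean"`.}
#'   \item{connectivity.lag_max}{lag window half-width (default 1).}
#'   \item{connectivity.source}{`"binarized"` (default) or `"normalized"` —
#'     which signal feeds the cross-correlation.}
#'   \item{network.threshold}{edge threshold in `[0,1]` or `"none"`
#'     (default 0.3).}
#'   \item{network.count_low_degree}{count degree-<2 nodes as zero in the
#'     clustering average (default `FALSE`).}
#'   \item{community.large_threshold}{members needed beyond this count for a
#'     community to be "large" (default 5).}
#'   \item{subset.label}{label selecting the subset, or `NULL` to skip
#'     subset analysis.}
#'   \item{pca.orientation}{`"cells"` (default) or `"time"`.}
#'   \item{psd.segment_len / psd.overlap / psd.window}{Welch parameters;
#'     defaults `NULL` (= `min(256, n_time)`), 0.5, `"hann"`.}
#' }
#'
#' @param ... key = value overrides (keys as named above).
#' @param preset `"default"` or `"strict"`.
#' @return A named list of class `cinet_config`.
#' @export
cinet_config <- function(..., preset = c("default", "strict")) {
  preset <- match.arg(preset)
  cfg <- list(
    `normalization.method` = "minmax",
    `binarize.k` = 2,
    `events.mode` = "onsets",
    `cluster.linkage` = "ward",
    `cluster.metric` = "euclidean",
    `connectivity.lag_max` = 1,
    `connectivity.source` = "binarized",
    `network.threshold` = 0.3,
    `network.count_low_degree` = FALSE,
    `community.large_threshold` = 5,
    `subset.label` = NULL,
    `pca.orientation` = "cells",
    `psd.segment_len` = NULL,
    `psd.overlap` = 0.5,
    `psd.window` = "hann")
  if (preset == "strict") {
    cfg$`network.threshold` <- 0.6
    cfg$`connectivity.lag_max` <- 1
  }
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "cinet_config")
}

#' Read a YAML configuration file
#'
#' Keys mirror [cinet_config()]; nested YAML maps are flattened with dots
#' (`network: {threshold: 0.6}` becomes `network.threshold`). Explicit
#' `overrides` win over file values.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file.
#' @return A `cinet_config`.
#' @export
read_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  flat <- list()
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v) && !is.null(names(v))) {
      for (k2 in names(v)) flat[[paste(k, k2, sep = ".")]] <- v[[k2]]
    } else flat[[k]] <- v
  }
  flat[names(overrides)] <- overrides
  do.call(cinet_config, flat)
}

#' Write a configuration to YAML
#'
#' @param cfg a `cinet_config`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
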