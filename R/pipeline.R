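#' Run the full analysis pipeline
#'
#' Executes every stage in sequence on one recording: load and align inputs,
#' normalize, binarize, population activity (active-cell percentage, event
#' frequency, hierarchical raster ordering), lagged cross-correlation
#' connectivity, thresholded graph construction, topological metrics and
#' community detection, labeled-subset analysis (when a label is configured
#' and present), PCA and Welch PSD, and a summary report. The pipeline is
#' fully deterministic: two runs on identical inputs produce identical
#' numeric outputs, byte for byte.
#'
#' When `out_dir` is given every intermediate is written there as plain text
#' (CSV/GraphML/JSON) along with a manifest; a failing stage aborts with a
#' stage-tagged error after flushing the manifest with the failure recorded.
#'
#' @param traces a [trace_matrix()] or path to a traces CSV.
#' @param cells a [cell_table()], path to a coordinates CSV, or `NULL` (no
#'   coordinates; network plotting and subset analysis unavailable).
#' @param frame_interval_s seconds per frame; required when `traces` is a
#'   path, ignored otherwise.
#' @param config a [cinet_config()].
#' @param out_dir optional output directory for artifacts.
#' @return A `pipeline_report`: `summary` (top5pc_var_percent,
#'   clustering_coeff, global_efficiency, mean_degree, modularity,
#'   n_communities, large_communities, freq_events_per_min, and — when a
#'   subset label applies — ltu and freq_labeled), the echoed `config`,
#'   `artifacts` (paths, when `out_dir` given) and all stage `intermediates`.
#' @export
run_pipeline <- function(traces, cells = NULL, frame_interval_s = NULL,
                         config = cinet_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cinet_config"))
  artifacts <- list()
  manifest_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest_path <- file.path(out_dir, "manifest.json")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(manifest_path))
        jsonlite::write_json(
          list(complete = FALSE, failed_stage = name,
               artifacts = lapply(artifacts, basename)),
          manifest_path, auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(key, file, writer) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, file)
    writer(path)
    artifacts[[key]] <<- path
    invisible(path)
  }

  # -- load ------------------------------------------------------------
  tm <- stage("load", {
    if (is.character(traces)) {
      if (is.null(frame_interval_s))
        stop("frame_interval_s is required when reading traces from a file")
      read_traces(traces, frame_interval_s)
    } else if (inherits(traces, "trace_matrix")) traces
    else stop("traces must be a file path or a trace_matrix")
  })
  ct <- stage("load", {
    if (is.null(cells)) NULL
    else {
      tab <- if (is.character(cells)) read_cells(cells) else cells
      align_cells(tm, tab)
    }
  })

  # -- preprocess ------------------------------------------------------
  norm <- stage("normalize", switch(config$`normalization.method`,
                                    minmax = normalize_minmax(tm),
                                    zscore = normalize_zscore(tm),
                                    stop("unknown normalization.method '",
                                         config$`normalization.method`, "'")))
  emit("normalized", "normalized.csv", function(p) write_traces(norm, p))
  raster <- stage("binarize", binarize(norm, k = config$`binarize.k`))
  emit("raster", "raster.csv", function(p) write_traces(raster, p))

  # -- population activity ---------------------------------------------
  activity <- stage("population", active_percentage(raster))
  emit("activity", "activity.csv", function(p)
    utils::write.csv(data.frame(time_s = activity$time_s,
                                percent_active = activity$percent_active),
                     p, row.names = FALSE))
  freq <- stage("population",
                events_per_min(raster, mode = config$`events.mode`))
  cluster <- stage("population", if (nrow(tm$values) >= 2L)
    cluster_traces(norm, linkage = config$`cluster.linkage`,
                   metric = config$`cluster.metric`) else NULL)

  # -- connectivity ----------------------------------------------------
  conn_input <- switch(config$`connectivity.source`,
                       binarized = raster, normalized = norm,
                       stop("pipeline stage 'connectivity': unknown connectivity.source '",
                            config$`connectivity.source`, "'", call. = FALSE))
  conn <- stage("connectivity",
                connectivity_matrix(conn_input,
                                    lag_max = config$`connectivity.lag_max`))
  emit("connectivity", "connectivity.csv", function(p)
    utils::write.csv(as.data.frame(conn$rho_max), p, row.names = TRUE))

  # -- graph + metrics -------------------------------------------------
  graph <- stage("network",
                 build_graph(conn, theta = config$`network.threshold`,
                             cells = ct))
  degs <- stage("metrics", degree_stats(graph))
  cc <- stage("metrics",
              clustering_coefficient(graph,
                                     count_low_degree = config$`network.count_low_degree`))
  ge <- stage("metrics", global_efficiency(graph))
  comm <- stage("communities",
                detect_communities(graph,
                                   large_threshold = config$`community.large_threshold`))
  graph <- assign_communities(graph, comm)
  emit("graph", "graph.graphml", function(p) write_graph(graph, p, "graphml"))
  emit("edges", "edges.csv", function(p) write_graph(graph, p, "edge_csv"))
  emit("membership", "membership.csv", function(p)
    utils::write.csv(data.frame(Cell = names(comm$membership),
                                community = as.integer(comm$membership)),
                     p, row.names = FALSE))

  # -- subset ----------------------------------------------------------
  label <- config$`subset.label`
  subset_rep <- NULL
  if (!is.null(label)) {
    subset_rep <- stage("subset", {
      if (is.null(ct))
        stop("subset.label is set but no cell table with labels was provided")
      subset_summary(graph, raster, label)
    })
  }

  # -- spectra / dimensionality ---------------------------------------
  pca <- stage("pca", pca_traces(norm, orientation = config$`pca.orientation`))
  emit("scree", "scree.csv", function(p)
    utils::write.csv(data.frame(component = seq_along(pca$explained_ratio),
                                explained_percent = 100 * pca$explained_ratio),
                     p, row.names = FALSE))
  psd <- stage("psd",
               welch_psd(norm, segment_len = config$`psd.segment_len`,
                         overlap_frac = config$`psd.overlap`,
                         window = config$`psd.window`))
  emit("psd", "psd.csv", function(p) {
    df <- data.frame(freq_hz = psd$freqs_hz, t(psd$power), check.names = FALSE)
    names(df) <- c("freq_hz", rownames(psd$power))
    utils::write.csv(df, p, row.names = FALSE)
  })

  # -- report ----------------------------------------------------------
  summary <- list(
    n_cells = nrow(tm$values),
    n_time = ncol(tm$values),
    top5pc_var_percent = pca$top5_percent,
    clustering_coeff = cc,
    global_efficiency = ge,
    mean_degree = degs$mean_degree,
    modularity = comm$modularity,
    n_communities = comm$n_communities,
    large_communities = comm$large_community_count,
    freq_events_per_min = freq)
  if (!is.null(subset_rep)) {
    summary$ltu <- subset_rep$ltu
    summary$freq_labeled <- subset_rep$freq_labeled
  }
  report <- structure(
    list(summary = summary,
         config = config,
         artifacts = artifacts,
         intermediates = list(traces = tm, cells = ct, normalized = norm,
                              raster = raster, activity = activity,
                              cluster = cluster, connectivity = conn,
                              graph = graph, communities = comm,
                              degrees = degs, subset = subset_rep,
                              pca = pca, psd = psd)),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(summary, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts$report <- report_path
    cfg_path <- file.path(out_dir, "config.yaml")
    write_config(config, cfg_path)
    artifacts$config <- cfg_path
    report$artifacts <- artifacts
    # manifest records run-relative names so a run directory is relocatable
    # and byte-identical across reruns at different paths
    jsonlite::write_json(list(complete = TRUE,
                              artifacts = lapply(artifacts, basename)),
                         manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  %d cells x %d time points\n", s$n_cells, s$n_time))
  fields <- c(top5pc_var_percent = "Top-5 PC variance (%%)",
              clustering_coeff = "Clustering coefficient",
              global_efficiency = "Global efficiency",
              mean_degree = "Mean degree",
              modularity = "Modularity",
              large_communities = "Large communities (> threshold members)",
              freq_events_per_min = "Event frequency (events/min)",
              ltu = "Labeled-to-unlabeled proportion (LtU)",
              freq_labeled = "Labeled event frequency (events/min)")
  for (f in names(fields)) {
    if (!is.null(s[[f]]))
      cat(sprintf(paste0("  %-42s %s\n"), sprintf(fields[[f]]),
                  format(signif(s[[f]], 5))))
  }
  invisible(x)
}
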