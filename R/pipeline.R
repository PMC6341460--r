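#' Full-pipeline configuration
#'
#' Bundles the stage choices of the tumor-extraction pipeline:
#' noise filter, contrast enhancement, segmenter, cluster count, swarm
#' settings and extraction rule. The defaults are the recommended
#' combination — adaptive median filter, CLAHE, GCPSO with k = 3 (air
#' background / lung parenchyma / dense tissue and tumor), brightest-cluster
#' extraction.
#'
#' @param filter_kind `"adaptive_median"`, `"median"`, `"average"` or
#'   `"none"`.
#' @param window Odd filter window (>= 3).
#' @param smax Odd maximum window for the adaptive median (>= `window`).
#' @param enhance_kind `"clahe"`, `"global_he"` or `"none"`.
#' @param clahe_tiles Integer pair: CLAHE tile grid.
#' @param clahe_clip CLAHE clip limit, fraction of tile pixel count in
#'   (0, 1\].
#' @param segmenter `"gcpso"`, `"pso"`, `"iwpso"`, `"kmeans"` or
#'   `"kmedian"`.
#' @param k Number of intensity clusters (>= 2).
#' @param swarm A [swarm_config()] (swarm segmenters only).
#' @param extraction An [extraction_config()].
#' @param seed Integer seed consumed by every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_kind = c("adaptive_median", "median",
                                            "average", "none"),
                            window = 3L, smax = 7L,
                            enhance_kind = c("clahe", "global_he", "none"),
                            clahe_tiles = c(8L, 8L), clahe_clip = 0.01,
                            segmenter = c("gcpso", "pso", "iwpso", "kmeans",
                                          "kmedian"),
                            k = 3L, swarm = swarm_config(),
                            extraction = extraction_config(), seed = 1L) {
  filter_kind <- match.arg(filter_kind)
  enhance_kind <- match.arg(enhance_kind)
  segmenter <- match.arg(segmenter)
  if (filter_kind != "none") {
    window <- check_odd_window(window)
    smax <- check_odd_window(smax, "smax")
    if (smax < window) stop_param("smax must be >= window")
  }
  if (k < 2) stop_param("k must be >= 2")
  structure(list(filter_kind = filter_kind, window = window, smax = smax,
                 enhance_kind = enhance_kind, clahe_tiles = clahe_tiles,
                 clahe_clip = clahe_clip, segmenter = segmenter,
                 k = as.integer(k), swarm = swarm, extraction = extraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_param("in stage '", stage, "': ", conditionMessage(e)))
}

#' Run the full tumor-extraction pipeline on one image
#'
#' Applies, in order: noise filter, contrast enhancement, intensity
#' segmentation, tumor extraction. Filter quality (SSI/SMPI of the filtered
#' image against the input) is always reported; confusion rates are computed
#' iff a ground-truth mask is supplied. All stochastic stages consume
#' `config$seed`, so a fixed seed gives bitwise-identical reports.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param truth Optional binary reference mask (same shape).
#' @param config A [pipeline_config()].
#' @return A list of class `run_report` with elements `filtered`,
#'   `enhanced`, `model` (the `cluster_model`), `mask`, `filter_quality`
#'   (`ssi`, `smpi`), `confusion` (`confusion_report` or `NULL`), `config`.
#' @export
run_pipeline <- function(image, truth = NULL, config = pipeline_config()) {
  check_image(image)
  if (!is.null(truth)) {
    check_mask(truth, "truth")
    if (!all(dim(truth) == dim(image)))
      stop_param("truth mask must match the image shape")
  }
  filtered <- run_stage("filter", switch(config$filter_kind,
    none = image,
    median = median_filter(image, config$window),
    adaptive_median = adaptive_median_filter(image, config$window,
                                             config$smax),
    average = average_filter(image, config$window)))
  enhanced <- run_stage("enhance", switch(config$enhance_kind,
    none = filtered,
    global_he = global_hist_equalize(filtered),
    clahe = clahe(filtered, config$clahe_tiles, config$clahe_clip)))
  model <- run_stage("segment", {
    if (config$segmenter %in% c("kmeans", "kmedian")) {
      fn <- if (config$segmenter == "kmeans") kmeans_segment else
        kmedian_segment
      fn(enhanced, k = config$k, seed = config$seed)
    } else {
      sw <- config$swarm
      sw$seed <- config$seed
      swarm_segment(enhanced, variant = config$segmenter, k = config$k,
                    config = sw)
    }
  })
  mask <- run_stage("extract", extract_tumor(model, config$extraction))
  fq <- run_stage("filter_quality", {
    if (sd(as.vector(image)) > 0 && mean(image) > 0)
      list(ssi = ssi(image, filtered), smpi = smpi(image, filtered))
    else
      list(ssi = NA_real_, smpi = NA_real_)
  })
  confusion <- if (!is.null(truth))
    run_stage("evaluate", confusion_rates(mask, truth))
  structure(list(filtered = filtered, enhanced = enhanced, model = model,
                 mask = mask, filter_quality = fq, confusion = confusion,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$config$filter_kind, " -> ", x$config$enhance_kind,
      " -> ", x$config$segmenter, " (k = ", x$config$k, ")\n", sep = "")
  cat(sprintf("  SSI %.4f  SMPI %.4f  tumor pixels %d\n",
              x$filter_quality$ssi, x$filter_quality$smpi, sum(x$mask)))
  if (!is.null(x$confusion))
    cat(sprintf("  TPR %.4f  TNR %.4f  balanced accuracy %.4f\n",
                x$confusion$tpr, x$confusion$tnr, x$confusion$accuracy))
  invisible(x)
}

#' Tabulate per-image metrics from run reports
#'
#' One row per report, mirroring the usual evaluation-table layout: TPR,
#' TNR, FPR, FNR, balanced accuracy, pixel accuracy, SSI, SMPI, all in
#' percent (rates) to full precision; round on write.
#'
#' @param reports List of `run_report` objects.
#' @param ids Optional row identifiers (default `Image 1..n`).
#' @return A data frame.
#' @export
metrics_table <- function(reports, ids = NULL) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  if (is.null(ids)) ids <- paste("Image", seq_along(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    cf <- r$confusion
    data.frame(image = ids[i],
               tpr = if (is.null(cf)) NA_real_ else cf$tpr,
               tnr = if (is.null(cf)) NA_real_ else cf$tnr,
               fpr = if (is.null(cf)) NA_real_ else cf$fpr,
               fnr = if (is.null(cf)) NA_real_ else cf$fnr,
               accuracy = if (is.null(cf)) NA_real_ else cf$accuracy,
               pixel_accuracy = if (is.null(cf)) NA_real_ else
                 cf$pixel_accuracy,
               ssi = r$filter_quality$ssi,
               smpi = r$filter_quality$smpi)
  })
  do.call(rbind, rows)
}

#' Write a metrics table as CSV (rates rounded to 4 decimals)
#'
#' @param tab Data frame from [metrics_table()].
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = 4L)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run log
#'
#' Echoes the configuration and seed and records the segmenter's
#' per-iteration traces (objective for Lloyd-type methods, global-best
#' fitness and — for GCPSO — search radius and counters for swarm methods).
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @export
write_run_log <- function(report, path) {
  m <- report$model
  log <- list(
    config = unclass_deep(report$config),
    seed = report$config$seed,
    segmenter = m$method,
    centers = m$centers,
    n_iter = m$n_iter,
    converged = m$converged,
    objective = m$objective,
    objective_trace = m$objective_trace,
    fitness_trace = m$fitness_trace,
    rho_trace = m$rho_trace,
    filter_quality = report$filter_quality,
    confusion = if (!is.null(report$confusion))
      unclass(report$confusion))
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
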