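#' Tumor-extraction configuration
#'
#' @param rule `"brightest_cluster"` (tumors are hyperdense on CT) or
#'   `"cluster_index"` to pick an explicit cluster.
#' @param target_index Cluster index (1..k, in ascending-center order) when
#'   `rule = "cluster_index"`.
#' @param min_area Minimum connected-component area in pixels; smaller
#'   8-connected components are removed.
#' @param keep `"all_components"` or `"largest_component"`.
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(rule = c("brightest_cluster", "cluster_index"),
                              target_index = NULL, min_area = 30L,
                              keep = c("all_components", "largest_component")) {
  rule <- match.arg(rule)
  keep <- match.arg(keep)
  if (rule == "cluster_index" &&
      (is.null(target_index) || target_index < 1))
    stop_param("target_index required (>= 1) when rule = 'cluster_index'")
  if (min_area < 0) stop_param("min_area must be nonnegative")
  structure(list(rule = rule, target_index = target_index,
                 min_area = as.integer(min_area), keep = keep),
            class = "extraction_config")
}

#' Label 8-connected foreground components
#'
#' @param mask Matrix with values in \{0, 1\}.
#' @return Integer matrix: 0 for background, 1..n component ids.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  m <- mask
  storage.mode(m) <- "integer"
  label_components_cpp(m)
}

#' Extract a binary tumor mask from a cluster model
#'
#' Selects the tumor cluster (by default the one with the highest center
#' intensity), binarizes its label-map support, removes 8-connected
#' components smaller than `min_area` pixels, and optionally keeps only the
#' largest component. Deterministic.
#'
#' @param model A `cluster_model` from any segmenter.
#' @param config An [extraction_config()].
#' @return Binary matrix (0/1), image-shaped.
#' @export
extract_tumor <- function(model, config = extraction_config()) {
  if (!inherits(model, "cluster_model"))
    stop_param("model must be a cluster_model")
  target <- switch(config$rule,
    brightest_cluster = which.max(model$centers),
    cluster_index = {
      if (config$target_index > model$k)
        stop_param("target_index exceeds k = ", model$k)
      config$target_index
    })
  mask <- (model$labels == target) + 0
  if (!any(mask == 1)) {
    warning("selected cluster is empty; returning all-zero mask",
            call. = FALSE)
    return(mask)
  }
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0L])
  drop <- which(sizes < config$min_area)
  if (length(drop)) mask[comp %in% drop] <- 0
  if (config$keep == "largest_component" && any(mask == 1)) {
    keep_sizes <- sizes
    keep_sizes[drop] <- 0L
    mask[comp != which.max(keep_sizes)] <- 0
  }
  mask
}
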