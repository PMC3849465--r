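# End-to-end pipeline: configuration, the four-stage run, and artifacts.

#' Pipeline configuration
#'
#' Collects every tunable of the four stages plus I/O paths. Serializes to
#' a human-readable `key: value` (DCF) file; unknown keys are rejected on
#' read.
#'
#' @param n_levels pyramid depth.
#' @param c_levels,deltas,working_scale,angles saliency scale set.
#' @param target_n,compactness,seg_iterations segmentation parameters.
#' @param entropy_window,entropy_bins disorder-map parameters.
#' @param regulation,regulation_gamma attention regulation form.
#' @param knn_k,textons_per_region,vote_threshold recognition parameters.
#' @param df_threshold,df_features similarity-propagation parameters
#'   (`df_features` a subset of `I O C H`).
#' @param seed RNG seed for texton sampling.
#' @param image,mask,db_dir,out_dir file-system paths (optional).
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_levels = 9L, c_levels = 2:4, deltas = 3:4,
                            working_scale = 4L,
                            angles = c(0, 45, 90, 135),
                            target_n = 200L, compactness = 0.2,
                            seg_iterations = 10L,
                            entropy_window = 9L, entropy_bins = 32L,
                            regulation = "multiplicative",
                            regulation_gamma = 1,
                            knn_k = 5L, textons_per_region = 20L,
                            vote_threshold = 0.5,
                            df_threshold = 2.0,
                            df_features = c("I", "O", "C", "H"),
                            seed = 1L,
                            image = NULL, mask = NULL,
                            db_dir = NULL, out_dir = NULL) {
  cfg <- list(n_levels = as.integer(n_levels),
              c_levels = as.integer(c_levels),
              deltas = as.integer(deltas),
              working_scale = as.integer(working_scale),
              angles = as.numeric(angles),
              target_n = as.integer(target_n),
              compactness = as.numeric(compactness),
              seg_iterations = as.integer(seg_iterations),
              entropy_window = as.integer(entropy_window),
              entropy_bins = as.integer(entropy_bins),
              regulation = regulation,
              regulation_gamma = as.numeric(regulation_gamma),
              knn_k = as.integer(knn_k),
              textons_per_region = as.integer(textons_per_region),
              vote_threshold = as.numeric(vote_threshold),
              df_threshold = as.numeric(df_threshold),
              df_features = df_features,
              seed = as.integer(seed),
              image = image, mask = mask,
              db_dir = db_dir, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration file
#'
#' `key: value` lines (Debian-control format); vector values are
#' space-separated. Reading validates every key against
#' [pipeline_config()] and rejects unknown ones.
#'
#' @param config `pipeline_config`.
#' @param path file path.
#' @rdname pipeline_config_io
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  keep <- !vapply(config, is.null, logical(1))
  vals <- vapply(config[keep], function(v) paste(v, collapse = " "), "")
  writeLines(paste0(names(vals), ": ", vals), path)
  invisible(path)
}

#' @rdname pipeline_config_io
#' @export
read_pipeline_config <- function(path) {
  raw <- read.dcf(path)
  kv <- stats::setNames(as.character(raw[1, ]), colnames(raw))
  template <- pipeline_config()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  args <- list()
  char_keys <- c("regulation", "df_features", "image", "mask",
                 "db_dir", "out_dir")
  for (k in names(kv)) {
    parts <- strsplit(trimws(kv[[k]]), "\\s+")[[1]]
    args[[k]] <- if (k %in% char_keys) parts else as.numeric(parts)
  }
  do.call(pipeline_config, args)
}

saliency_params_from_config <- function(config) {
  saliency_params(c_levels = config$c_levels, deltas = config$deltas,
                  n_levels = config$n_levels,
                  working_scale = config$working_scale,
                  angles = config$angles)
}

#' Run the full RoI-extraction pipeline on one image
#'
#' Saliency, segmentation + disorder map, attention-ordered texton search,
#' and similarity propagation. When no region is recognised as a target the
#' result carries an all-zero mask and `no_target = TRUE`. With a fixed
#' config, database and seed the run is deterministic.
#'
#' @param config `pipeline_config`.
#' @param image `rgb_image`; if NULL, read from `config$image`.
#' @param db `texton_db`; if NULL, loaded from `config$db_dir`.
#' @param gt optional ground-truth 0/1 mask (or read from `config$mask`)
#'   for evaluation.
#' @return object of class `pipeline_result`: `mask`, `no_target`,
#'   `target_region_id`, `search`, `roi` (`roi_result` or NULL),
#'   `summaries` (attention-ordered), `saliency`, `regions`, `entropy`,
#'   `eval` (sens/spec or NULL).
#' @export
run_pipeline <- function(config = pipeline_config(), image = NULL,
                         db = NULL, gt = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(image)) {
    if (is.null(config$image)) stop("run_pipeline: no image given")
    image <- read_image(config$image)
  }
  if (is.null(db)) {
    if (is.null(config$db_dir)) stop("run_pipeline: no texton database given")
    db <- load_texton_db(config$db_dir)
  }
  if (is.null(gt) && !is.null(config$mask)) gt <- read_mask(config$mask)

  params <- saliency_params_from_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sal <- stage("saliency", saliency_map(image, params))
  intens <- to_intensity(image)
  ent <- stage("entropy",
               local_entropy_map(intens, config$entropy_window,
                                 config$entropy_bins))
  regions <- stage("segmentation",
                   segment_regions(image, config$target_n,
                                   config$compactness,
                                   config$seg_iterations))
  summ <- stage("summaries",
                summarize_regions(regions, sal,
                                  sal$conspicuity_full$I,
                                  sal$conspicuity_full$C,
                                  sal$conspicuity_full$O,
                                  ent, intens))
  ordered <- attention_scores(summ, bins = config$entropy_bins,
                              form = config$regulation,
                              gamma = config$regulation_gamma)
  ctx <- feature_context(sal, bins = config$entropy_bins)
  search <- stage("target search",
                  find_first_target(ordered, regions, image, db, ctx,
                                    m = config$textons_per_region,
                                    k = config$knn_k,
                                    vote_threshold = config$vote_threshold,
                                    seed = config$seed))
  if (is.na(search$target_region_id)) {
    roi <- NULL
    mask <- matrix(0L, image$height, image$width)
    no_target <- TRUE
  } else {
    roi <- stage("propagation",
                 propagate(search$target_region_id, ordered,
                           threshold = config$df_threshold,
                           features = config$df_features))
    mask <- compose_mask(regions, roi$accepted_region_ids)
    roi$mask <- mask
    no_target <- FALSE
  }
  ev <- if (!is.null(gt)) suppressMessages(sensitivity_specificity(mask, gt))
        else NULL
  res <- structure(list(mask = mask, no_target = no_target,
                        target_region_id = search$target_region_id,
                        search = search, roi = roi,
                        summaries = ordered, saliency = sal,
                        regions = regions, entropy = ent, eval = ev,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(res, config$out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  if (x$no_target) {
    cat("<pipeline_result: NO TARGET FOUND, mask all zero>\n")
  } else {
    cat(sprintf(
      "<pipeline_result: target region %d, %d region(s) accepted, mask area %d px>\n",
      x$target_region_id, length(x$roi$accepted_region_ids), sum(x$mask)))
  }
  if (!is.null(x$eval)) {
    cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
                x$eval["sensitivity"], x$eval["specificity"]))
  }
  invisible(x)
}

# Write PNG/CSV/JSON artifacts of a run; deterministic file contents.
write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(res$saliency$values, file.path(out_dir, "saliency.png"))
  png::writePNG(res$entropy$values / log2(res$entropy$bins),
                file.path(out_dir, "entropy.png"))
  write_mask(res$mask, file.path(out_dir, "roi_mask.png"))
  # label plane: lossless CSV plus an 8-bit preview
  utils::write.csv(as.data.frame(res$regions$labels),
                   file.path(out_dir, "region_labels.csv"),
                   row.names = FALSE)
  png::writePNG(res$regions$labels / res$regions$n_regions,
                file.path(out_dir, "regions.png"))
  utils::write.csv(res$summaries, file.path(out_dir, "region_summary.csv"),
                   row.names = FALSE)
  if (!is.null(res$roi)) {
    df_tab <- data.frame(region_id = as.integer(names(res$roi$df_values)),
                         df = unname(res$roi$df_values))
    df_tab$accepted <- df_tab$region_id %in% res$roi$accepted_region_ids
    utils::write.csv(df_tab, file.path(out_dir, "df_table.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("hvsroi")),
    no_target = res$no_target,
    target_region_id = if (res$no_target) NULL else res$target_region_id,
    n_regions = res$regions$n_regions,
    mask_area = sum(res$mask),
    config = res$config[!vapply(res$config, is.null, logical(1))],
    eval = if (!is.null(res$eval)) as.list(res$eval) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
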