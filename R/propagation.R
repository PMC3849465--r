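# Similarity propagation: once the first target region is found, every
# region whose (I, O, C, H) feature distance to the target falls under a
# threshold is accepted as an additional region of interest.

#' Feature distance between two region summaries
#'
#' Scaled Euclidean distance over the per-region mean features:
#' `df = sqrt( sum_f ((f_t - f_i) / scale_f)^2 )` for
#' `f in {I, O, C, H}` (a feature subset may be selected). Dimensions with
#' non-positive scale are dropped.
#'
#' @param s_t,s_i single-row data.frames (or named vectors) holding the
#'   features.
#' @param scales named positive scale per feature; defaults to 1 for each
#'   (unscaled variant).
#' @param features feature subset, default `c("I","O","C","H")`.
#' @return non-negative scalar.
#' @export
feature_distance <- function(s_t, s_i,
                             scales = c(I = 1, O = 1, C = 1, H = 1),
                             features = c("I", "O", "C", "H")) {
  get_feats <- function(s) {
    if (is.data.frame(s)) unlist(s[1, features, drop = TRUE])
    else s[features]
  }
  ft <- get_feats(s_t); fi <- get_feats(s_i)
  sc <- scales[features]
  use <- is.finite(sc) & sc > 0
  if (!any(use)) stop("feature_distance: no usable feature dimension")
  sqrt(sum(((ft[use] - fi[use]) / sc[use])^2))
}

# Per-feature scales for one image: standard deviation of each feature
# across all regions, so one threshold is comparable across magnifications.
feature_scales <- function(summaries, features = c("I", "O", "C", "H")) {
  vapply(features, function(f) stats::sd(summaries[[f]]), numeric(1))
}

#' Propagate the first target to similar regions
#'
#' Accepts the target plus every region whose feature distance to it is at
#' most `threshold`. Distances are recorded for all regions; the accepted
#' list starts with the target and continues in ascending distance (ties by
#' lower region id).
#'
#' @param target_id region id of the detected target.
#' @param summaries data.frame with columns `region_id` and the features.
#' @param threshold acceptance threshold in scaled distance units. The
#'   package-level default is `2 = sqrt(4)`: an average discrepancy of one
#'   per-image standard deviation in each of the four features.
#' @param scales per-feature scales; default: per-feature standard
#'   deviation across the image's regions (zero-spread dimensions dropped).
#' @param features feature subset used in the distance.
#' @return object of class `roi_result`: `accepted_region_ids`,
#'   `df_values` (named by region id), `threshold`, `mask` (NULL until
#'   [compose_mask()]).
#' @export
propagate <- function(target_id, summaries, threshold = 2,
                      scales = NULL, features = c("I", "O", "C", "H")) {
  stopifnot(is.data.frame(summaries))
  if (!target_id %in% summaries$region_id) {
    stop("propagate: target id ", target_id, " not among the summaries")
  }
  if (is.null(scales)) scales <- feature_scales(summaries, features)
  tgt <- summaries[summaries$region_id == target_id, , drop = FALSE]
  df <- vapply(seq_len(nrow(summaries)), function(i) {
    feature_distance(tgt, summaries[i, , drop = FALSE], scales, features)
  }, numeric(1))
  names(df) <- summaries$region_id
  ids <- summaries$region_id
  others <- ids[ids != target_id & df[as.character(ids)] <= threshold]
  ord <- order(df[as.character(others)], others)
  structure(list(
    accepted_region_ids = c(target_id, others[ord]),
    df_values = df,
    threshold = threshold,
    scales = scales,
    mask = NULL
  ), class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf("<roi_result: %d accepted region(s), threshold %.3g>\n",
              length(x$accepted_region_ids), x$threshold))
  invisible(x)
}

#' Compose the binary RoI mask from accepted regions
#'
#' @param regions `region_map`.
#' @param accepted_ids region ids; every id must exist in the map.
#' @return 0/1 integer matrix; a pixel is 1 iff its region id is accepted.
#' @export
compose_mask <- function(regions, accepted_ids) {
  stopifnot(inherits(regions, "region_map"))
  bad <- setdiff(accepted_ids, seq_len(regions$n_regions))
  if (length(bad) > 0L) {
    stop("compose_mask: unknown region id(s): ", paste(bad, collapse = ", "))
  }
  m <- regions$labels %in% accepted_ids
  matrix(as.integer(m), nrow(regions$labels), ncol(regions$labels))
}
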