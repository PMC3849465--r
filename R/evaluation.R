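# Pixel-level evaluation against ground-truth masks, mirroring the
# mean (variance) [%] presentation of sensitivity and specificity.

#' Pixel-level sensitivity and specificity
#'
#' `sens = 100 TP / (TP + FN)`, `spec = 100 TN / (TN + FP)` over pixels.
#' A metric whose denominator is empty (no positive, resp. no negative,
#' ground-truth pixels) is undefined and returned as `NA` with a message.
#'
#' @param pred,gt 0/1 matrices of equal dimensions.
#' @return named numeric `c(sensitivity=, specificity=)` in percent.
#' @export
sensitivity_specificity <- function(pred, gt) {
  stopifnot(is.matrix(pred), is.matrix(gt))
  if (!all(dim(pred) == dim(gt))) {
    stop("sensitivity_specificity: mask dimensions differ (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(gt), collapse = "x"), ")")
  }
  p <- pred != 0; g <- gt != 0
  tp <- sum(p & g); fn <- sum(!p & g)
  tn <- sum(!p & !g); fp <- sum(p & !g)
  sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
  if (is.na(sens)) message("sensitivity undefined: ground truth has no positives")
  if (is.na(spec)) message("specificity undefined: ground truth has no negatives")
  c(sensitivity = sens, specificity = spec)
}

#' Region-level (any-overlap) sensitivity and specificity
#'
#' Lenient variant: a ground-truth connected component counts as detected
#' if any predicted pixel overlaps it, and vice versa for false positives.
#' Provided for comparison; the pixel-level metric is the default reading.
#'
#' @inheritParams sensitivity_specificity
#' @return named numeric in percent (NA where undefined).
#' @export
region_sensitivity_specificity <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  comp_stats <- function(m, other) {
    lab <- connected_components(matrix(as.integer(m != 0), nrow(m), ncol(m)))
    ids <- unique(lab[m != 0])
    if (length(ids) == 0) return(c(hit = 0, tot = 0))
    hit <- sum(vapply(ids, function(i) any(other[lab == i] != 0), logical(1)))
    c(hit = hit, tot = length(ids))
  }
  g <- comp_stats(gt, pred)     # gt components detected
  p <- comp_stats(pred, gt)     # predicted components that are true
  sens <- if (g["tot"] == 0) NA_real_ else 100 * g["hit"] / g["tot"]
  spec <- if (p["tot"] == 0) NA_real_ else 100 * p["hit"] / p["tot"]
  c(sensitivity = unname(sens), specificity = unname(spec))
}

#' Aggregate mask evaluation over an image set
#'
#' Per-image pixel sensitivity/specificity plus the arithmetic mean and the
#' population variance of each (percent and percent^2). Images on which a
#' metric is undefined are excluded from that metric's aggregates.
#'
#' @param preds,gts parallel lists of 0/1 matrices. Names, if present,
#'   must pair up; unpaired names are an error.
#' @return list with `per_image` (data.frame), `mean_sensitivity`,
#'   `var_sensitivity`, `mean_specificity`, `var_specificity`.
#' @export
evaluate_batch <- function(preds, gts) {
  if (length(preds) != length(gts)) {
    stop("evaluate_batch: ", length(preds), " predictions vs ",
         length(gts), " ground truths")
  }
  if (!is.null(names(preds)) && !is.null(names(gts))) {
    unpaired <- c(setdiff(names(preds), names(gts)),
                  setdiff(names(gts), names(preds)))
    if (length(unpaired) > 0) {
      stop("evaluate_batch: unpaired mask files: ",
           paste(unique(unpaired), collapse = ", "))
    }
    gts <- gts[names(preds)]
  }
  per <- t(vapply(seq_along(preds), function(i) {
    suppressMessages(sensitivity_specificity(preds[[i]], gts[[i]]))
  }, numeric(2)))
  per_image <- data.frame(
    image = names(preds) %||% as.character(seq_along(preds)),
    sensitivity = per[, 1], specificity = per[, 2])
  pop_var <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    mean((x - mean(x))^2)
  }
  list(per_image = per_image,
       mean_sensitivity = mean(per[, 1], na.rm = TRUE),
       var_sensitivity = pop_var(per[, 1]),
       mean_specificity = mean(per[, 2], na.rm = TRUE),
       var_specificity = pop_var(per[, 2]))
}
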