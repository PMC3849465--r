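# Target recognition stage: a database of 32x32 texture exemplars (textons)
# reduced to (I, O, C, H) feature vectors, a classical kNN classifier, and
# the attention-ordered walk that stops at the first carcinoma-like region.

TEXTON_SIZE <- 32L

#' Extract texton patches from a labeled image
#'
#' Samples `n` patches of `size x size` pixels uniformly without replacement
#' from the top-left positions whose window lies entirely inside the mask
#' (`label = "roi"`) or entirely outside it (`label = "background"`).
#'
#' @param img `rgb_image`.
#' @param mask 0/1 matrix matching the image.
#' @param label `"roi"` or `"background"`.
#' @param n number of patches.
#' @param seed RNG seed (sampling is reproducible).
#' @param size patch side, default 32.
#' @param image_id identifier stored with each patch.
#' @return list of `texton` objects: `patch` (`size x size x 3` array),
#'   `row`, `col` (top-left corner), `label`, `image_id`.
#' @export
extract_textons <- function(img, mask, label = c("roi", "background"),
                            n, seed = 1L, size = TEXTON_SIZE,
                            image_id = "img") {
  label <- match.arg(label)
  stopifnot(inherits(img, "rgb_image"), is.matrix(mask))
  if (!all(dim(mask) == c(img$height, img$width))) {
    stop("extract_textons: mask dimensions do not match the image")
  }
  target <- if (label == "roi") mask else 1 - mask
  pos <- full_window_positions(target, size)
  if (nrow(pos) == 0L) {
    stop("extract_textons: no ", size, "x", size, " window fits entirely ",
         if (label == "roi") "inside" else "outside",
         " the mask; the region must span at least ", size, " px in both ",
         "directions")
  }
  if (n > nrow(pos)) {
    stop("extract_textons: requested ", n, " patches but only ", nrow(pos),
         " valid positions exist")
  }
  pick <- with_seed(seed, sample.int(nrow(pos), n))
  lapply(pick, function(i) {
    r <- pos[i, 1]; cc <- pos[i, 2]
    ri <- r:(r + size - 1L); ci <- cc:(cc + size - 1L)
    patch <- array(0, c(size, size, 3))
    patch[, , 1] <- img$r[ri, ci]
    patch[, , 2] <- img$g[ri, ci]
    patch[, , 3] <- img$b[ri, ci]
    structure(list(patch = patch, row = r, col = cc, label = label,
                   image_id = image_id), class = "texton")
  })
}

# Top-left corners (row, col) whose size x size window lies entirely in the
# support of `target` (a 0/1 matrix), found with an integral image.
full_window_positions <- function(target, size) {
  h <- nrow(target); w <- ncol(target)
  if (h < size || w < size) return(matrix(integer(0), 0, 2))
  S <- matrix(0, h + 1L, w + 1L)
  S[-1, -1] <- target
  S <- apply(S, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  ri1 <- (size + 1L):(h + 1L); ri0 <- 1:(h + 1L - size)
  ci1 <- (size + 1L):(w + 1L); ci0 <- 1:(w + 1L - size)
  cnt <- S[ri1, ci1, drop = FALSE] - S[ri0, ci1, drop = FALSE] -
         S[ri1, ci0, drop = FALSE] + S[ri0, ci0, drop = FALSE]
  which(cnt == size * size, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

#' Feature context for texton and region features
#'
#' Bundles the full-resolution conspicuity planes a texton's O and C
#' features are read from. Usually built from [saliency_map()] output.
#'
#' @param sal `saliency_map`, or NULL if `C_full`/`O_full` are given.
#' @param C_full,O_full full-resolution color / orientation conspicuity
#'   planes (override `sal`).
#' @param bins histogram bins for the patch-entropy feature.
#' @return list with `C`, `O`, `bins`.
#' @export
feature_context <- function(sal = NULL, C_full = NULL, O_full = NULL,
                            bins = 32L) {
  if (is.null(C_full)) C_full <- sal$conspicuity_full$C
  if (is.null(O_full)) O_full <- sal$conspicuity_full$O
  stopifnot(is.matrix(C_full), is.matrix(O_full))
  list(C = C_full, O = O_full, bins = as.integer(bins))
}

# Shannon entropy (bits) of the equal-width-bin histogram of values in [0,1].
histogram_entropy <- function(v, bins) {
  q <- pmin(bins, floor(pmax(0, pmin(1, v)) * bins) + 1L)
  p <- tabulate(q, nbins = bins) / length(v)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Feature vector (I, O, C, H) of a texton
#'
#' I is the mean patch intensity; O and C are the means of the orientation
#' and color conspicuity planes over the patch footprint; H is the Shannon
#' entropy (bits) of the binned intensity histogram of the patch itself.
#'
#' @param t `texton`.
#' @param context [feature_context()] for the source image.
#' @return named numeric vector `c(I=, O=, C=, H=)`.
#' @export
texton_features <- function(t, context) {
  stopifnot(inherits(t, "texton"))
  size <- dim(t$patch)[1]
  ri <- t$row:(t$row + size - 1L)
  ci <- t$col:(t$col + size - 1L)
  intens <- (t$patch[, , 1] + t$patch[, , 2] + t$patch[, , 3]) / 3
  c(I = mean(intens),
    O = mean(context$O[ri, ci]),
    C = mean(context$C[ri, ci]),
    H = histogram_entropy(intens, context$bins))
}

#' Build a texton database
#'
#' Fits a per-dimension z-normalization (mean, sd) on the feature vectors.
#' Dimensions with zero spread are dropped from the kNN metric with a
#' warning. Both classes must be represented.
#'
#' @param features numeric matrix, one row per exemplar, columns
#'   `I, O, C, H`.
#' @param labels character vector, `"roi"` / `"background"`, parallel to
#'   `features`.
#' @return object of class `texton_db`: `features`, `labels`, `center`,
#'   `scale`, `keep` (logical per dimension).
#' @export
build_database <- function(features, labels) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) colnames(features) <- c("I", "O", "C", "H")
  stopifnot(nrow(features) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("roi", "background"))) {
    stop("build_database: labels must be 'roi' or 'background'")
  }
  if (length(unique(labels)) < 2L) {
    stop("build_database: need at least one exemplar of each class ",
         "(kNN is undefined for a single-class database)")
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  keep <- scale > 0
  if (!all(keep)) {
    warning("build_database: constant feature dimension(s) dropped from ",
            "the metric: ", paste(colnames(features)[!keep], collapse = ", "))
  }
  structure(list(features = features, labels = labels,
                 center = center, scale = scale, keep = keep),
            class = "texton_db")
}

#' @export
print.texton_db <- function(x, ...) {
  cat(sprintf("<texton_db: %d exemplars (%d roi / %d background), dims %s>\n",
              length(x$labels), sum(x$labels == "roi"),
              sum(x$labels == "background"),
              paste(colnames(x$features)[x$keep], collapse = ",")))
  invisible(x)
}

#' Save / load a texton database
#'
#' Plain-text serialization: a CSV of feature vectors and labels plus a
#' JSON file with the fitted normalization, in one directory.
#'
#' @param db `texton_db`.
#' @param dir directory path (created if needed).
#' @rdname texton_db_io
#' @export
save_texton_db <- function(db, dir) {
  stopifnot(inherits(db, "texton_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(
    data.frame(db$features, label = db$labels, check.names = FALSE),
    file.path(dir, "textons.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(center = as.list(db$center), scale = as.list(db$scale),
         keep = as.list(db$keep)),
    file.path(dir, "normalization.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname texton_db_io
#' @export
load_texton_db <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "textons.csv"), check.names = FALSE)
  norm <- jsonlite::read_json(file.path(dir, "normalization.json"),
                              simplifyVector = TRUE)
  feats <- as.matrix(tab[, setdiff(names(tab), "label"), drop = FALSE])
  structure(list(features = feats, labels = as.character(tab$label),
                 center = unlist(norm$center), scale = unlist(norm$scale),
                 keep = unlist(norm$keep)),
            class = "texton_db")
}

# z-score rows using the database normalization, restricted to kept dims.
db_transform <- function(db, x) {
  x <- matrix(x, ncol = ncol(db$features),
              dimnames = list(NULL, colnames(db$features)))
  z <- sweep(sweep(x, 2, db$center), 2,
             ifelse(db$keep, db$scale, 1), "/")
  z[, db$keep, drop = FALSE]
}

#' Classify a feature vector with kNN
#'
#' Euclidean distance in the database's z-normalized feature space.
#' Distance ties are broken by database insertion order; vote ties are
#' resolved toward `"background"` (favoring specificity).
#'
#' @param v feature vector (I, O, C, H).
#' @param db `texton_db`.
#' @param k neighbor count, `1 <= k <=` database size.
#' @return list with `label` and `vote_fraction` (winning votes / k), plus
#'   `neighbors` (indices of the k nearest exemplars, in rank order).
#' @export
knn_classify <- function(v, db, k = 5L) {
  stopifnot(inherits(db, "texton_db"))
  n <- nrow(db$features)
  if (k < 1 || k > n) {
    stop("knn_classify: k must be in [1, ", n, "], got ", k)
  }
  z <- db_transform(db, db$features)
  q <- db_transform(db, matrix(v, 1))
  d <- sqrt(rowSums(sweep(z, 2, q)^2))
  ord <- order(d, seq_len(n))[seq_len(k)]   # stable: ties by insertion order
  votes_roi <- sum(db$labels[ord] == "roi")
  if (votes_roi * 2L > k) {
    list(label = "roi", vote_fraction = votes_roi / k, neighbors = ord)
  } else {
    list(label = "background", vote_fraction = (k - votes_roi) / k,
         neighbors = ord)
  }
}

# Candidate texton top-lefts for a region: windows inside the region's
# bounding box whose center pixel belongs to the region.
region_texton_positions <- function(regions, region_id, size = TEXTON_SIZE) {
  idx <- which(regions$labels == region_id, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("unknown region id ", region_id)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  if (r1 - r0 + 1L < size || c1 - c0 + 1L < size) {
    return(matrix(integer(0), 0, 2))
  }
  tl_r <- r0:(r1 - size + 1L)
  tl_c <- c0:(c1 - size + 1L)
  grid <- cbind(rep(tl_r, times = length(tl_c)),
                rep(tl_c, each = length(tl_r)))
  half <- size %/% 2L
  centered <- regions$labels[cbind(grid[, 1] + half, grid[, 2] + half)] ==
    region_id
  if (any(centered)) grid[centered, , drop = FALSE] else grid
}

#' Classify one region by its texton composition
#'
#' Samples up to `m` textons whose windows fit the region's bounding box
#' (preferring windows centered on the region's own pixels), classifies
#' each with kNN, and calls the region `"roi"` when the fraction of
#' roi-voted textons reaches `vote_threshold`. Regions whose bounding box
#' is thinner than a texton in either direction take the degenerate rule
#' `("background", 0)`.
#'
#' @param region_id region to classify.
#' @param regions `region_map`.
#' @param img `rgb_image`.
#' @param db `texton_db`.
#' @param context [feature_context()] of `img`.
#' @param m textons sampled per region.
#' @param k kNN neighbor count.
#' @param vote_threshold roi fraction needed to call the region roi.
#' @param seed RNG seed (each region decorrelated by its id).
#' @return list with `label` and `fraction` (of roi-classified textons).
#' @export
classify_region <- function(region_id, regions, img, db, context,
                            m = 20L, k = 5L, vote_threshold = 0.5,
                            seed = 1L) {
  pos <- region_texton_positions(regions, region_id)
  if (nrow(pos) == 0L) return(list(label = "background", fraction = 0))
  m_eff <- min(m, nrow(pos))
  pick <- with_seed(seed + region_id, sample.int(nrow(pos), m_eff))
  size <- TEXTON_SIZE
  hits <- vapply(pick, function(i) {
    r <- pos[i, 1]; cc <- pos[i, 2]
    ri <- r:(r + size - 1L); ci <- cc:(cc + size - 1L)
    intens <- (img$r[ri, ci] + img$g[ri, ci] + img$b[ri, ci]) / 3
    v <- c(I = mean(intens),
           O = mean(context$O[ri, ci]),
           C = mean(context$C[ri, ci]),
           H = histogram_entropy(intens, context$bins))
    knn_classify(v, db, k)$label == "roi"
  }, logical(1))
  frac <- mean(hits)
  list(label = if (frac >= vote_threshold) "roi" else "background",
       fraction = frac)
}

#' Walk regions in attention order until the first target
#'
#' Examines regions strictly in the order of the supplied summaries (the
#' search order fixed by [attention_scores()]) and stops at the first
#' region classified `"roi"`.
#'
#' @param summaries attention-ordered data.frame from [attention_scores()].
#' @param regions `region_map`.
#' @param img `rgb_image`.
#' @param db `texton_db`.
#' @param context [feature_context()].
#' @param m,k,vote_threshold,seed passed to [classify_region()].
#' @return object of class `search_result`: `target_region_id` (NA if no
#'   target), `regions_examined` (ids, in order), `fractions` (roi vote
#'   fraction per examined region).
#' @export
find_first_target <- function(summaries, regions, img, db, context,
                              m = 20L, k = 5L, vote_threshold = 0.5,
                              seed = 1L) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0,
            inherits(db, "texton_db"))
  examined <- integer(0)
  fractions <- numeric(0)
  target <- NA_integer_
  for (rid in summaries$region_id) {
    res <- classify_region(rid, regions, img, db, context,
                           m = m, k = k, vote_threshold = vote_threshold,
                           seed = seed)
    examined <- c(examined, rid)
    fractions <- c(fractions, res$fraction)
    if (res$label == "roi") { target <- rid; break }
  }
  structure(list(target_region_id = target,
                 regions_examined = examined,
                 fractions = stats::setNames(fractions, examined)),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  if (is.na(x$target_region_id)) {
    cat(sprintf("<search_result: no target after %d regions>\n",
                length(x$regions_examined)))
  } else {
    cat(sprintf("<search_result: target region %d (examined %d)>\n",
                x$target_region_id, length(x$regions_examined)))
  }
  invisible(x)
}
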