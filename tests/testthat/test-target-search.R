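# Texton extraction, features, database, kNN, region search.

const_image <- function(h, w, v) {
  rgb_image(matrix(v[1], h, w), matrix(v[2], h, w), matrix(v[3], h, w))
}

# context with flat conspicuity planes, for feature tests decoupled from the
# saliency stage
flat_context <- function(h, w, o = 0, cc = 0, bins = 32L) {
  feature_context(C_full = matrix(cc, h, w), O_full = matrix(o, h, w),
                  bins = bins)
}

test_that("extract_textons samples valid, reproducible windows", {
  img <- rand_image(64, 64, seed = 31)
  full <- matrix(1L, 64, 64)
  t1 <- extract_textons(img, full, "roi", n = 1, seed = 5)
  expect_length(t1, 1)
  expect_equal(dim(t1[[1]]$patch), c(32, 32, 3))
  expect_true(t1[[1]]$row >= 1 && t1[[1]]$row + 31 <= 64)
  expect_identical(t1[[1]]$patch[, , 2],
                   img$g[t1[[1]]$row + 0:31, t1[[1]]$col + 0:31])

  # same seed -> identical coordinates; different seed -> may differ
  t2 <- extract_textons(img, full, "roi", n = 5, seed = 9)
  t3 <- extract_textons(img, full, "roi", n = 5, seed = 9)
  expect_identical(lapply(t2, `[`, c("row", "col")),
                   lapply(t3, `[`, c("row", "col")))

  # 33x33 positive block: exactly 4 valid top-left corners
  img96 <- rand_image(96, 96, seed = 30)
  m <- matrix(0L, 96, 96); m[10:42, 20:52] <- 1L
  pos <- hvsroi:::full_window_positions(m, 32L)
  expect_equal(nrow(pos), 4)
  expect_setequal(pos[, 1], c(10, 11))
  expect_setequal(pos[, 2], c(20, 21))
  expect_error(extract_textons(img96, m, "roi", n = 5, seed = 1),
               "only 4 valid positions")
  # background textons must avoid the mask entirely
  bg <- extract_textons(img96, m, "background", n = 10, seed = 2)
  for (t in bg) {
    expect_equal(sum(m[t$row + 0:31, t$col + 0:31]), 0)
  }
  expect_error(extract_textons(img, matrix(1L, 64, 64), "background", n = 1),
               "no 32x32 window")
})

test_that("texton features match closed forms and are flip-invariant", {
  # constant gray patch in a constant image: O = C = H = 0, I = gray level
  gimg <- const_image(48, 48, c(0.55, 0.55, 0.55))
  sal <- suppressMessages(saliency_map(gimg))
  ctx <- feature_context(sal)
  t <- extract_textons(gimg, matrix(1L, 48, 48), "roi", 1, seed = 1)[[1]]
  f <- texton_features(t, ctx)
  expect_equal(unname(f), c(0.55, 0, 0, 0))

  # two-tone patch: H equals the binary entropy of the tone proportions
  n_hi <- 600
  v <- c(rep(0.2, 1024 - n_hi), rep(0.8, n_hi))
  patch <- array(matrix(v, 32, 32), c(32, 32, 3))
  tt <- structure(list(patch = patch, row = 1L, col = 1L, label = "roi",
                       image_id = "x"), class = "texton")
  p <- n_hi / 1024
  expect_equal(texton_features(tt, flat_context(32, 32))[["H"]],
               -p * log2(p) - (1 - p) * log2(1 - p))

  # horizontal patch flip leaves all four features unchanged
  set.seed(32)
  pv <- array(runif(32 * 32 * 3), c(32, 32, 3))
  t_a <- structure(list(patch = pv, row = 1L, col = 1L, label = "roi",
                        image_id = "x"), class = "texton")
  t_b <- structure(list(patch = pv[, 32:1, ], row = 1L, col = 1L,
                        label = "roi", image_id = "x"), class = "texton")
  ctxf <- flat_context(32, 32, o = 0.3, cc = 0.6)
  expect_equal(texton_features(t_a, ctxf), texton_features(t_b, ctxf),
               tolerance = 1e-6)
})

test_that("build_database fits normalization and guards its contract", {
  set.seed(33)
  f <- matrix(runif(16), 4, 4, dimnames = list(NULL, c("I", "O", "C", "H")))
  db <- build_database(f, c("roi", "roi", "background", "background"))
  expect_equal(db$center, colMeans(f))
  expect_equal(db$scale, apply(f, 2, sd))
  expect_true(all(db$keep))

  expect_error(build_database(f, rep("roi", 4)), "each class")
  expect_error(build_database(f, c("roi", "roi", "bg", "bg")), "labels")

  # constant dimension dropped from the metric with a warning,
  # neighbor sets equal to an oracle that ignores that dimension
  f2 <- f; f2[, "O"] <- 0.5
  expect_warning(db2 <- build_database(
    f2, c("roi", "roi", "background", "background")), "O")
  set.seed(34)
  for (i in 1:10) {
    probe <- runif(4)
    got <- knn_classify(probe, db2, k = 3)$neighbors
    expect_identical(got, oracle_knn_neighbors(f2, probe, 3))
  }
})

test_that("database round-trip preserves classification", {
  d <- withr::local_tempdir()
  set.seed(35)
  f <- matrix(runif(80), 20, 4, dimnames = list(NULL, c("I", "O", "C", "H")))
  labs <- rep(c("roi", "background"), 10)
  db <- build_database(f, labs)
  save_texton_db(db, file.path(d, "db"))
  db2 <- load_texton_db(file.path(d, "db"))
  expect_equal(db2$center, db$center)
  probes <- matrix(runif(40), 10, 4)
  for (i in 1:10) {
    a <- knn_classify(probes[i, ], db, 5)
    b <- knn_classify(probes[i, ], db2, 5)
    expect_identical(a$label, b$label)
    expect_equal(a$vote_fraction, b$vote_fraction)
    expect_identical(a$neighbors, b$neighbors)
  }
})

test_that("knn_classify matches the exhaustive oracle and its tie rules", {
  set.seed(36)
  f <- matrix(runif(120), 30, 4, dimnames = list(NULL, c("I", "O", "C", "H")))
  labs <- rep(c("roi", "background"), 15)
  db <- build_database(f, labs)

  # training vector probe, k = 1
  r1 <- knn_classify(f[7, ], db, k = 1)
  expect_equal(r1$label, labs[7])
  expect_equal(r1$vote_fraction, 1.0)
  expect_equal(r1$neighbors, 7L)

  # k = database size with balanced classes: vote tie -> background
  rt <- knn_classify(runif(4), db, k = 30)
  expect_equal(rt$label, "background")
  expect_equal(rt$vote_fraction, 0.5)

  # distance ties broken by insertion order
  fdup <- rbind(f[1, ], f[1, ], f[1, ] + 1)
  colnames(fdup) <- colnames(f)
  dbd <- build_database(fdup, c("roi", "background", "background"))
  expect_equal(knn_classify(fdup[1, ], dbd, k = 2)$neighbors, c(1L, 2L))

  expect_error(knn_classify(runif(4), db, k = 0), "k must be")
  expect_error(knn_classify(runif(4), db, k = 31), "k must be")

  # 30 seeded probes: identical neighbor sets to the brute-force oracle
  set.seed(37)
  for (i in 1:30) {
    probe <- runif(4)
    k <- sample(1:10, 1)
    expect_identical(knn_classify(probe, db, k)$neighbors,
                     oracle_knn_neighbors(f, probe, k))
  }
})

# A deterministic three-band world: each vertical band has its own texture;
# the database is built so that exactly one band's texture is "roi".
three_band_world <- function(roi_band = 3) {
  set.seed(38)
  h <- 96; w <- 96
  r <- matrix(0, h, w); g <- matrix(0, h, w); b <- matrix(0, h, w)
  bands <- list(1:32, 33:64, 65:96)
  levels <- list(c(0.9, 0.8, 0.85), c(0.5, 0.5, 0.7), c(0.25, 0.2, 0.45))
  for (k in 1:3) {
    cols <- bands[[k]]
    noise <- matrix(runif(h * length(cols), -0.05, 0.05), h, length(cols))
    r[, cols] <- levels[[k]][1] + noise
    g[, cols] <- levels[[k]][2] + noise
    b[, cols] <- levels[[k]][3] + noise
  }
  img <- rgb_image(pmin(pmax(r, 0), 1), pmin(pmax(g, 0), 1),
                   pmin(pmax(b, 0), 1))
  labels <- matrix(rep(rep(1:3, times = c(32, 32, 32)), each = h), h, w)
  rm <- structure(list(labels = labels, n_regions = 3L), class = "region_map")
  ctx <- flat_context(h, w)
  feats <- list(); labs <- character(0)
  for (k in 1:3) {
    mask <- matrix(0L, h, w); mask[, bands[[k]]] <- 1L
    tx <- extract_textons(img, mask, "roi", n = 8, seed = 40 + k)
    for (t in tx) {
      feats[[length(feats) + 1L]] <- texton_features(t, ctx)
      labs <- c(labs, if (k == roi_band) "roi" else "background")
    }
  }
  # flat context makes O and C constant: expect them dropped silently here
  db <- suppressWarnings(build_database(do.call(rbind, feats), labs))
  list(img = img, regions = rm, db = db, ctx = ctx)
}

test_that("classify_region and find_first_target honor the search contract", {
  wd <- three_band_world(roi_band = 3)

  # degenerate rule: a region thinner than one texton
  thin_labels <- matrix(2L, 96, 96); thin_labels[, 1:8] <- 1L
  thin <- structure(list(labels = thin_labels, n_regions = 2L),
                    class = "region_map")
  res_thin <- classify_region(1, thin, wd$img, wd$db, wd$ctx)
  expect_equal(res_thin, list(label = "background", fraction = 0))

  # the roi band classifies roi with a strong vote
  r3 <- classify_region(3, wd$regions, wd$img, wd$db, wd$ctx, m = 20, k = 5)
  expect_equal(r3$label, "roi")
  expect_gte(r3$fraction, 0.9)
  r1 <- classify_region(1, wd$regions, wd$img, wd$db, wd$ctx, m = 20, k = 5)
  expect_equal(r1$label, "background")

  # summaries ordered so the roi band ranks 3rd: examined length 3
  summ <- data.frame(region_id = c(1L, 2L, 3L))
  sr <- find_first_target(summ, wd$regions, wd$img, wd$db, wd$ctx)
  expect_equal(sr$regions_examined, c(1L, 2L, 3L))
  expect_equal(sr$target_region_id, 3L)

  # roi band ranked first: early stop after one region
  sr1 <- find_first_target(data.frame(region_id = c(3L, 1L, 2L)),
                           wd$regions, wd$img, wd$db, wd$ctx)
  expect_equal(length(sr1$regions_examined), 1)
  expect_equal(sr1$target_region_id, 3L)

  # reproducibility: identical results for identical seeds
  sr2 <- find_first_target(summ, wd$regions, wd$img, wd$db, wd$ctx)
  expect_identical(sr, sr2)

  # no-target case: roi exemplars far away, background exemplars matching
  # every band's texture, so nothing classifies roi
  db_far <- build_database(
    rbind(wd$db$features + 50, wd$db$features),
    c(rep("roi", nrow(wd$db$features)),
      rep("background", nrow(wd$db$features))))
  sr0 <- find_first_target(summ, wd$regions, wd$img, db_far, wd$ctx)
  expect_true(is.na(sr0$target_region_id))
  expect_equal(sr0$regions_examined, summ$region_id)
})

test_that("stricter vote thresholds never stop the search earlier", {
  wd <- three_band_world(roi_band = 2)
  summ <- data.frame(region_id = c(1L, 3L, 2L))
  counts <- vapply(c(0.2, 0.5, 0.9), function(vt) {
    length(find_first_target(summ, wd$regions, wd$img, wd$db, wd$ctx,
                             vote_threshold = vt)$regions_examined)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
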