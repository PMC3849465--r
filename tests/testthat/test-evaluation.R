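# Sensitivity/specificity, batch aggregation, configuration, pipeline, CLI.

test_that("sensitivity_specificity: direct counts and degenerate cases", {
  gt <- matrix(0L, 4, 4); gt[1, 1:4] <- 1L
  expect_equal(unname(sensitivity_specificity(gt, gt)), c(100, 100))
  expect_equal(unname(sensitivity_specificity(1L - gt, gt)), c(0, 0))
  pred <- gt; pred[1, 4] <- 0L   # 3 of 4 positives, no false alarms
  expect_equal(unname(sensitivity_specificity(pred, gt)), c(75, 100))
  expect_error(sensitivity_specificity(gt, matrix(0L, 3, 3)), "differ")
  # undefined metrics reported as NA
  expect_message(r <- sensitivity_specificity(gt, matrix(0L, 4, 4)),
                 "no positives")
  expect_true(is.na(r["sensitivity"]))
})

test_that("exhaustive 2x2 check against hand-enumerated confusion counts", {
  combos <- expand.grid(rep(list(0:1), 4))
  for (a in seq_len(16)) for (b in seq_len(16)) {
    pred <- matrix(as.integer(combos[a, ]), 2, 2)
    gt <- matrix(as.integer(combos[b, ]), 2, 2)
    tp <- fn <- tn <- fp <- 0
    for (i in 1:2) for (j in 1:2) {
      if (gt[i, j] == 1) {
        if (pred[i, j] == 1) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (pred[i, j] == 1) fp <- fp + 1 else tn <- tn + 1
      }
    }
    want_sens <- if (tp + fn == 0) NA_real_ else 100 * tp / (tp + fn)
    want_spec <- if (tn + fp == 0) NA_real_ else 100 * tn / (tn + fp)
    got <- suppressMessages(sensitivity_specificity(pred, gt))
    expect_equal(unname(got), c(want_sens, want_spec))
  }
})

test_that("evaluate_batch aggregates with population variance", {
  gt <- matrix(0L, 5, 2); gt[1:5, 1] <- 1L    # 5 positives, 5 negatives
  p80 <- gt; p80[5, 1] <- 0L                  # sens 80, spec 100
  p100 <- gt
  ev <- evaluate_batch(list(p80, p100), list(gt, gt))
  expect_equal(ev$mean_sensitivity, 90)
  expect_equal(ev$var_sensitivity, 100)       # two-point population variance
  expect_equal(ev$mean_specificity, 100)
  expect_equal(ev$var_specificity, 0)

  single <- evaluate_batch(list(p80), list(gt))
  expect_equal(single$var_sensitivity, 0)

  expect_error(evaluate_batch(stats::setNames(list(gt), "a"),
                              stats::setNames(list(gt), "b")), "unpaired")

  # 5 hand-set pairs vs a spreadsheet-style independent computation
  set.seed(71)
  preds <- list(); gts <- list(); sens <- c(); spec <- c()
  for (i in 1:5) {
    g <- matrix(rbinom(36, 1, 0.5), 6, 6)
    p <- matrix(rbinom(36, 1, 0.5), 6, 6)
    preds[[i]] <- p; gts[[i]] <- g
    sens <- c(sens, 100 * sum(p & g) / sum(g))
    spec <- c(spec, 100 * sum(!p & !g) / sum(!g))
  }
  ev5 <- evaluate_batch(preds, gts)
  expect_equal(ev5$mean_sensitivity, mean(sens))
  expect_equal(ev5$var_sensitivity, mean((sens - mean(sens))^2))
  expect_equal(ev5$per_image$specificity, spec)
})

test_that("region-level variant counts any-overlap detections", {
  gt <- matrix(0L, 10, 10)
  gt[2:4, 2:4] <- 1L; gt[7:9, 7:9] <- 1L   # two gt components
  pred <- matrix(0L, 10, 10); pred[3, 3] <- 1L
  r <- region_sensitivity_specificity(pred, gt)
  expect_equal(unname(r), c(50, 100))
})

test_that("pipeline config round-trips and rejects unknown keys", {
  d <- withr::local_tempdir()
  cfg <- pipeline_config(target_n = 24, df_threshold = 1.5, seed = 9,
                         df_features = c("I", "C", "H"))
  f <- file.path(d, "cfg.dcf")
  write_pipeline_config(cfg, f)
  back <- read_pipeline_config(f)
  for (k in c("target_n", "df_threshold", "seed", "df_features", "angles")) {
    expect_equal(back[[k]], cfg[[k]])
  }
  writeLines(c("target_n: 5", "bogus_key: 1"), file.path(d, "bad.dcf"))
  expect_error(read_pipeline_config(file.path(d, "bad.dcf")), "bogus_key")
})

test_that("run_pipeline flags the no-target case with an all-zero mask", {
  sp <- fixture_spec(preset = "mag10", seed = 72)
  sp$n_roi_blobs <- 0L
  fx <- generate_image(sp)
  res <- suppressMessages(
    run_pipeline(suite_config(), image = fx$image, db = suite_db()))
  expect_true(res$no_target)
  expect_equal(sum(res$mask), 0)
  expect_true(is.na(res$target_region_id))
  expect_equal(res$search$regions_examined, res$summaries$region_id)
})

test_that("run_pipeline recovers the lesion on an easy fixture", {
  fx <- generate_image(fixture_spec(image_size = c(128, 128), n_roi_blobs = 1,
                                    blob_scale = c(35, 45), seed = 73))
  cfg <- pipeline_config(target_n = 12, seed = 73)
  res <- suppressMessages(
    run_pipeline(cfg, image = fx$image, db = unit_db(), gt = fx$mask))
  expect_false(res$no_target)
  expect_gt(res$eval["sensitivity"], 50)
  expect_gt(res$eval["specificity"], 80)
  # the roi_result invariants
  expect_equal(res$roi$accepted_region_ids[1], res$target_region_id)
  expect_equal(unname(res$roi$df_values[as.character(res$target_region_id)]), 0)
  areas <- tabulate(res$regions$labels, res$regions$n_regions)
  expect_equal(sum(res$mask), sum(areas[res$roi$accepted_region_ids]))
})

test_that("artifacts are written and byte-identical across reruns", {
  d <- withr::local_tempdir()
  fx <- generate_image(fixture_spec(image_size = c(128, 128), n_roi_blobs = 1,
                                    blob_scale = c(35, 45), seed = 74))
  run_once <- function(out) {
    cfg <- pipeline_config(target_n = 12, seed = 74, out_dir = out)
    suppressMessages(run_pipeline(cfg, image = fx$image, db = unit_db()))
    sort(list.files(out))
  }
  f1 <- run_once(file.path(d, "a"))
  f2 <- run_once(file.path(d, "b"))
  expect_identical(f1, f2)
  expect_true(all(c("roi_mask.png", "region_summary.csv", "saliency.png",
                    "run_summary.json", "df_table.csv") %in% f1))
  for (f in f1) {
    if (f == "run_summary.json") next  # records out_dir, which differs here
    expect_identical(unname(tools::md5sum(file.path(d, "a", f))),
                     unname(tools::md5sum(file.path(d, "b", f))),
                     label = paste("artifact", f))
  }
})

test_that("the CLI front end runs its basic subcommands", {
  d <- withr::local_tempdir()
  out <- file.path(d, "fx")
  code <- suppressMessages(
    hvsroi_cli(c("make-fixtures", "--n", "1", "--seed", "3",
                 "--out-dir", out)))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "img_001.png")))
  expect_true(file.exists(file.path(out, "mask_001.png")))
  expect_equal(dim(read_mask(file.path(out, "mask_001.png"))), c(256L, 256L))
  expect_equal(suppressMessages(hvsroi_cli("no-such-command")), 1L)
  expect_equal(suppressMessages(hvsroi_cli(character(0))), 1L)
})
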