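test_that("run_config validates its inputs and names its metrics", {
  cfg <- run_config()
  expect_length(metric_names(cfg), 4 * 3 + 2 * 2 + 3)
  expect_true("pd_s3_linear" %in% metric_names(cfg))
  expect_true(all(c("resid_median_sigma", "ra", "sf", "rd") %in% metric_names(cfg)))
  small <- run_config(spans = 3, penalties = "linear",
                      residual_types = character(0), classic = FALSE)
  expect_identical(metric_names(small), "pd_s3_linear")
  expect_error(run_config(spans = integer(0), residual_types = character(0),
                          classic = FALSE), "no metric")
  expect_error(run_config(alpha = 1.5), "alpha")
  expect_error(run_config(spans = c(3, 4)), "odd")
})

test_that("score_nucleus accepts mask, contour, or both, consistently", {
  nuc <- make_contour(random_shape_spec("LSIL", seed = 21))
  cfg <- run_config(spans = 3, penalties = "linear")
  from_both <- score_nucleus(nuc$mask, nuc$contour, cfg)
  from_mask <- score_nucleus(mask = nuc$mask, config = cfg)
  from_ct <- score_nucleus(contour = nuc$contour, config = cfg)
  expect_named(from_both, metric_names(cfg), ignore.order = TRUE)
  expect_equal(from_mask, from_both, tolerance = 1e-12)
  expect_equal(from_ct[c("pd_s3_linear", "resid_mean_mu")],
               from_both[c("pd_s3_linear", "resid_mean_mu")], tolerance = 1e-12)
  expect_error(score_nucleus(config = cfg), "mask or a contour")
})

test_that("score_cohort returns one labelled row per item", {
  coh <- generate_cohort(3, master_seed = 2)
  cfg <- run_config(spans = c(3, 5), penalties = c("linear", "cubic"))
  sc <- score_cohort(coh, cfg)
  expect_equal(nrow(sc), 9L)
  expect_identical(names(sc), c("image_id", "class", metric_names(cfg)))
  expect_false(anyNA(sc))
})

test_that("score_batch handles masks, contours, images, and corrupt files", {
  dir <- file.path(tempdir(), "batch_test")
  unlink(dir, recursive = TRUE); dir.create(dir)
  coh <- generate_cohort(2, master_seed = 3, render = TRUE)
  for (it in coh$items[1:3]) {
    write_image(it$nucleus$mask, file.path(dir, paste0(it$id, ".png")))
  }
  write_contour(coh$items[[4]]$nucleus$contour, file.path(dir, "LSIL_extra.csv"))
  write_image(coh$items[[5]]$image, file.path(dir, "HSIL_img.png"))
  writeLines("not,a,contour", file.path(dir, "broken.csv"))
  man <- data.frame(
    image_id = c(coh$manifest$image_id[1:3], "LSIL_extra", "HSIL_img", "broken"),
    class = c(coh$manifest$class[1:3], "LSIL", "HSIL", "LSIL")
  )
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- run_config(spans = 3, penalties = "linear")
  out_csv <- file.path(dir, "scores.csv")
  res <- score_batch(dir, cfg, out = out_csv)
  expect_equal(nrow(res$scores), 5L)
  expect_equal(nrow(res$errors), 1L)
  expect_equal(res$errors$image_id, "broken")
  expect_true(file.exists(out_csv))
  # mask-input path is exact: scores equal direct scoring of the mask
  direct <- score_nucleus(mask = coh$items[[1]]$nucleus$mask, config = cfg)
  row1 <- res$scores[res$scores$image_id == coh$items[[1]]$id, ]
  expect_equal(unlist(row1[metric_names(cfg)]), direct, tolerance = 1e-10,
               ignore_attr = TRUE)
  # rerun is byte-identical
  res2 <- score_batch(dir, cfg)
  expect_identical(res$scores, res2$scores)
  expect_error(score_batch(file.path(dir, "missing")), "no readable inputs")
})

test_that("contour and image io round-trip", {
  ct <- make_contour(random_shape_spec("NILM", seed = 31))$contour
  f <- tempfile(fileext = ".csv")
  write_contour(ct, f)
  back <- read_contour(f)
  expect_equal(unname(back), unname(ct))
  m <- disk_mask(12)
  fm <- tempfile(fileext = ".png")
  write_image(m, fm)
  expect_identical(read_mask(fm), m)
  img <- render_image(m, seed = 1)$image
  fi <- tempfile(fileext = ".png")
  write_image(img, fi)
  expect_equal(read_image(fi), img, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(read_image("x.bmp"), "unsupported image format")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
  expect_error(read_contour(bad), "x,y columns")
})

test_that("full_pipeline produces scores and a significance report", {
  cfg <- run_config(spans = 3, penalties = "linear",
                    residual_types = "mean", classic = FALSE, seed = 7)
  res <- full_pipeline(cfg, n_per_class = 8, master_seed = 7)
  expect_equal(nrow(res$scores), 24L)
  expect_s3_class(res$report, "irr_significance")
  expect_setequal(names(res$report$metrics), metric_names(cfg))
  res2 <- full_pipeline(cfg, n_per_class = 8, master_seed = 7)
  expect_identical(res$scores, res2$scores)
  expect_equal(res$report$metrics$pd_s3_linear$p.value,
               res2$report$metrics$pd_s3_linear$p.value)
})
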