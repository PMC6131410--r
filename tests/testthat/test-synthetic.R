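test_that("lesion generation is a pure function of its seed", {
  lp <- lesion_params("tnbc", correlation_length_px = 1.3,
                      heterogeneity_amp = 20, seed = 9L)
  a <- generate_lesion(lp)
  b <- generate_lesion(lp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # a different seed changes the image
  lp2 <- lesion_params("tnbc", correlation_length_px = 1.3,
                       heterogeneity_amp = 20, seed = 10L)
  expect_false(identical(generate_lesion(lp2)$image, a$image))
})

test_that("gain raises in-ROI intensity; machine effects spare the mask", {
  lp <- lesion_params("fibroadenoma", seed = 3L)
  base <- generate_lesion(lp, machine_effect(gain = 1))
  hot <- generate_lesion(lp, machine_effect(gain = 1.5))
  expect_gt(mean(hot$image[hot$mask]), mean(base$image[base$mask]))
  expect_identical(base$mask, hot$mask)
  # first-order features respond to the machine effect
  f1 <- first_order_features(base$image[base$mask])
  f2 <- first_order_features(hot$image[hot$mask])
  expect_gt(f2[["mean"]], f1[["mean"]])
})

test_that("zero boundary irregularity gives the exact discretized ellipse", {
  lp <- lesion_params("fibroadenoma", ellipse_axes_px = c(30, 44),
                      boundary_irregularity = 0, seed = 5L)
  les <- generate_lesion(lp, image_size = c(96L, 96L))
  cr <- (96 + 1) / 2; cc <- (96 + 1) / 2
  want <- outer(1:96, 1:96, function(r, c) {
    ((r - cr) / 15)^2 + ((c - cc) / 22)^2 <= 1
  })
  expect_identical(les$mask, want)
})

test_that("out-of-bounds ellipses raise an invalid-geometry error", {
  lp <- lesion_params("tnbc", ellipse_axes_px = c(80, 80), seed = 1L)
  expect_error(generate_lesion(lp, image_size = c(64L, 64L)),
               "invalid geometry")
})

test_that("cohort labels follow the specified malignancy rate", {
  d <- withr::local_tempdir()
  # labels and metadata only: no images written
  tab <- generate_cohort(cohort_spec(1000L, malignancy_rate = 0.206,
                                     seed = 77L),
                         d, write_images = FALSE)
  n_mal <- sum(tab$class == "tnbc")
  ci <- qbinom(c(0.005, 0.995), 1000L, 0.206)
  expect_gte(n_mal, ci[1L])
  expect_lte(n_mal, ci[2L])
  # empirical machine mix close to the specification
  mix <- table(tab$machine)[c("iU22", "LOGIQE9", "HDI5000")] / 1000
  expect_lt(max(abs(mix - c(0.546, 0.361, 0.093))), 0.05)

  # full generation on a small cohort: table schema and files
  spec2 <- cohort_spec(12L, seed = 5L)
  tab2 <- generate_cohort(spec2, d)
  expect_equal(nrow(tab2), 12L)
  expect_named(tab2, c("lesion_id", "class", "machine", "birads",
                       "size_mm", "age", "image_path", "mask_path"))
  expect_true(all(file.exists(tab2$image_path)))
  expect_true(all(file.exists(tab2$mask_path)))
  expect_true(all(tab2$class %in% c("fibroadenoma", "tnbc")))
  expect_true(all(tab2$birads %in% c("3", "4a", "4b", "4c", "5")))
  # reproducible
  d2 <- withr::local_tempdir()
  tab3 <- generate_cohort(cohort_spec(12L, seed = 5L), d2)
  expect_identical(tab2$class, tab3$class)
  expect_identical(load_image(tab2$image_path[1L]),
                   load_image(tab3$image_path[1L]))
})

test_that("degenerate cohort specifications behave as stated", {
  d <- withr::local_tempdir()
  all_benign <- generate_cohort(cohort_spec(8L, malignancy_rate = 0,
                                            seed = 2L), d)
  expect_true(all(all_benign$class == "fibroadenoma"))

  d2 <- withr::local_tempdir()
  one_machine <- generate_cohort(
    cohort_spec(8L, machine_mix = c(iU22 = 1, LOGIQE9 = 0, HDI5000 = 0),
                seed = 3L), d2)
  expect_true(all(one_machine$machine == "iU22"))

  expect_error(cohort_spec(1L), "n_lesions")
  expect_error(cohort_spec(10L, machine_mix = c(a = 0.5, b = 0.6)),
               "sum to 1")
})
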