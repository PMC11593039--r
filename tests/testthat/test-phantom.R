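test_that("an undeformed vertebra renders its posterior height exactly", {
  ph <- generate_spine(phantom_spec(1, base_posterior_height_mm = 15,
                                    pixel_spacing_mm = c(1, 1)))
  expect_equal(ph$truth$Hp_mm, 15)
  expect_equal(ph$truth$hlr, 0)
  # posterior column pixel extent equals Hp within one pixel
  m <- ph$mask == 1
  oracle <- column_pixel_heights(m, c(0.15, 0.5, 0.85), 0.05)
  expect_lte(abs(oracle[3] - 15), 1)
  expect_equal(max(ph$mask), 1L)
})

test_that("wedge deformity realises the target height loss in the truth record", {
  ph <- wedge_phantom(target = 1 / 3, hp = 15)
  expect_equal(ph$truth$Ha_mm, 10)
  expect_equal(ph$truth$Hp_mm, 15)
  expect_equal(ph$truth$hlr, 1 / 3, tolerance = 1e-9)
  expect_true(ph$truth$fractured)
})

test_that("round-trip morphometry on generated phantoms recovers truth within a pixel", {
  plan <- data.frame(vertebra = 2L, class = "wedge", target_hlr = 0.3)
  ph <- generate_spine(phantom_spec(3, c(18, 20, 24), deformity_plan = plan))
  tab <- morphometry_table(ph$mask, c(1, 1))
  expect_equal(tab$Ha_mm, ph$truth$Ha_mm, tolerance = 1.01)
  expect_equal(tab$Hm_mm, ph$truth$Hm_mm, tolerance = 1.01)
  expect_equal(tab$Hp_mm, ph$truth$Hp_mm, tolerance = 1.01)
})

test_that("crush deformity is invisible to the height loss ratio", {
  for (t in c(0.2, 0.3, 0.45)) {
    plan <- data.frame(vertebra = 3L, class = "crush", target_hlr = t)
    ph <- generate_spine(phantom_spec(5, 20, deformity_plan = plan))
    # all three columns reduced by the same factor
    expect_equal(ph$truth$Ha_mm[3] / ph$truth$Hp_mm[3], 1, tolerance = 0.05)
    tab <- morphometry_table(ph$mask, c(1, 1))
    expect_lt(tab$hlr[3], 0.05)
    expect_true(ph$truth$fractured[3]) # still a true fracture: the blind spot
  }
})

test_that("phantom rasters and truth are bit-identical across runs and boxes tile the spine", {
  spec <- cohort_spec(5, 20, seed = 99)
  a <- generate_spine(spec)
  b <- generate_spine(cohort_spec(5, 20, seed = 99))
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth, b$truth)
  # bounding boxes non-overlapping along the spine (row) axis
  o <- order(a$truth$y0)
  expect_true(all(diff(a$truth[o, ]$y0) > 0))
  expect_true(all(head(a$truth$y1[o], -1) < tail(a$truth$y0[o], -1)))
})

test_that("oversized deformities are rejected with the offending vertebra named", {
  plan <- data.frame(vertebra = 2L, class = "crush", target_hlr = 0.9)
  expect_error(generate_spine(phantom_spec(3, 15, deformity_plan = plan)),
               "vertebra 2")
  expect_error(phantom_spec(2, deformity_plan = data.frame(
    vertebra = 5L, class = "wedge", target_hlr = 0.3)))
  expect_error(phantom_spec(2, deformity_plan = data.frame(
    vertebra = 1L, class = "wedge", target_hlr = 1.2)))
})

test_that("low-density texture lowers the trabecular interior and spares the rim", {
  ph <- generate_spine(phantom_spec(2, 20))
  img <- phantom_intensity(ph$mask)
  mask <- matrix(as.integer(ph$mask > 0), nrow(ph$mask), ncol(ph$mask))

  # identity range leaves the image untouched
  expect_equal(apply_low_density_texture(img, mask, c(0, 0)), img)

  out1 <- apply_low_density_texture(img, mask, c(100, 300), seed = 7)
  out2 <- apply_low_density_texture(img, mask, c(100, 300), seed = 7)
  expect_identical(out1, out2) # seeded reproducibility

  band <- make_contour_band(mask, 2)
  rim_inside <- mask == 1 & brute_dilate(band, 1) # cortical shell proxy
  interior <- mask == 1 & !rim_inside
  expect_lt(mean(out1[interior]), mean(img[interior]))
  expect_equal(out1[band == 1], img[band == 1]) # contour band unchanged
  expect_gte(mean(img[interior]) - mean(out1[interior]), 100)
  expect_lte(mean(img[interior]) - mean(out1[interior]), 300)

  # empty interior after erosion: warn and pass through
  tiny <- matrix(0L, 8, 8); tiny[4, 4] <- 1L
  expect_warning(out3 <- apply_low_density_texture(phantom_intensity(tiny), tiny, c(50, 60)),
                 "interior")
  expect_equal(out3, phantom_intensity(tiny))
})

test_that("mock detector hits its operating point on a 1000-vertebra cohort", {
  spec <- cohort_spec(500, 500, seed = 3)
  ph <- generate_spine(spec)
  det <- mock_detector(ph, sens_target = 0.83, spec_target = 0.96, seed = 5)
  tb <- cbind(vertebra = ph$truth$vertebra, px_box_to_norm(ph$truth, dim(ph$mask)))
  sc <- match_boxes(det, tb)
  conf <- sc$confidence[match(ph$truth$vertebra, sc$vertebra)]
  sens <- mean(conf[ph$truth$fractured] >= 0.5)
  spc <- mean(conf[!ph$truth$fractured] < 0.5)
  expect_lt(abs(sens - 0.83), 0.04) # binomial SE ~ 0.012 at n = 500
  expect_lt(abs(spc - 0.96), 0.04)

  # determinism
  det2 <- mock_detector(ph, 0.83, 0.96, seed = 5)
  expect_identical(det, det2)

  # degenerate calibration separates the classes completely
  det3 <- mock_detector(ph, 1.0, 1.0, seed = 2)
  sc3 <- match_boxes(det3, tb)
  conf3 <- sc3$confidence[match(ph$truth$vertebra, sc3$vertebra)]
  expect_true(all(conf3[ph$truth$fractured] > 0.5))
  expect_true(all(conf3[!ph$truth$fractured] < 0.5))
})

test_that("mask files round-trip through NIfTI and PNG with spacing", {
  ph <- generate_spine(phantom_spec(2, 18, pixel_spacing_mm = c(0.8, 0.6)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask_nifti(ph$mask, f, c(0.8, 0.6))
  back <- read_mask_nifti(f)
  expect_identical(back$mask, ph$mask)
  expect_equal(back$pixel_spacing_mm, c(0.8, 0.6), tolerance = 1e-6)

  p <- withr::local_tempfile(fileext = ".png")
  write_mask_png(ph$mask, p)
  expect_identical(read_mask_png(p), ph$mask)

  ct <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(ph, ct)
  back_truth <- read_truth_csv(ct, image_dim = dim(ph$mask))
  expect_equal(back_truth$hlr, ph$truth$hlr, tolerance = 1e-9)
  expect_equal(attr(back_truth, "image_dim"), dim(ph$mask))
})
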