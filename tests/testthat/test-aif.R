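test_that("LV detection finds the blood pool and erodes its border", {
  study <- clean_study()
  gt <- study$ground_truth
  mask <- detect_lv(study$myocardial[[1]])
  expect_true(all(gt$blood_mask[mask]))          # mask inside the true disk
  expect_gte(sum(mask) / sum(gt$blood_mask), 0.5)  # >= 50% of disk area
  # erosion contract: nothing within 1 px of the blood-pool boundary
  shrunk <- as.matrix(EBImage::erode(gt$blood_mask * 1,
                                     EBImage::makeBrush(3, "box"))) > 0.5
  expect_true(all(shrunk[mask]))
  # static series has no enhancing region
  ser <- study$myocardial[[1]]
  ser$frames[] <- 5
  expect_error(detect_lv(ser), "no LV candidate")
})

test_that("AIF extraction averages the mask and detects contamination", {
  study <- clean_study()
  gt <- study$ground_truth
  ser <- study$aif_series
  # single-pixel mask equals that pixel's series
  px <- which(gt$aif_blood_mask, arr.ind = TRUE)[1, ]
  m1 <- matrix(FALSE, dim(ser$frames)[1], dim(ser$frames)[2])
  m1[px[1], px[2]] <- TRUE
  cv <- extract_aif(ser, m1)
  sr <- which(ser$frame_roles == "SR")
  expect_equal(cv$values, ser$frames[px[1], px[2], sr])
  expect_equal(length(cv$values), length(sr))  # PD frames excluded
  # phantom blood mask recovers ground-truth blood CA within 2%
  conv <- si_to_concentration(ser, config = gt$config)
  ca <- mask_curve(conv$concentration, gt$aif_blood_mask)
  expect_lt(max(abs(ca - gt$aif_blood)) / max(gt$aif_blood), 0.02)
  # mask forced across myocardium raises the contamination flag
  bad <- gt$aif_blood_mask | qperf:::phantom_masks(
    qperf:::scale_spec(gt$spec, gt$spec$matrix / 2), 1)$myo
  cb <- extract_aif(ser, bad)
  expect_true(any(grepl("contamination", cb$flags)))
  expect_error(extract_aif(ser, matrix(FALSE, 48, 48)), "empty")
})

test_that("arrival detection matches constructed feet", {
  step <- c(rep(0, 9), rep(1, 10))
  expect_equal(detect_arrival(step, method = "triangle")$index, 10L)
  expect_equal(detect_arrival(step, method = "upslope_line")$index, 10L)
  t <- seq(0, 60, 1)
  g <- generate_aif(t, onset = 8)
  for (m in c("triangle", "upslope_line")) {
    a <- detect_arrival(g, t, method = m)
    expect_lte(abs(a$time - 8), 1)
  }
  # triangle is invariant to amplitude scaling
  expect_equal(detect_arrival(g, t)$index, detect_arrival(g * 37, t)$index)
  # flat curve: no bolus
  set.seed(5)
  expect_error(detect_arrival(rnorm(20, 0, 0.01)), "no bolus")
  expect_error(detect_arrival(g[1:3]), "5 samples")
})

test_that("plasma conversion applies the hematocrit once", {
  cv <- concentration_curve(0:9, c(0, 0, 0.1, 1, 2.9, 2, 1, 0.5, 0.3, 0.2),
                            role = "aif_blood")
  pl <- to_plasma(cv, quant_config(hematocrit = 0.42))
  expect_equal(max(pl$values), 2.9 / 0.58)
  expect_equal(max(pl$values), 5, tolerance = 1e-12)
  expect_equal(pl$role, "aif_plasma")
  expect_error(to_plasma(pl), "blood-role")  # applying twice is an error
  # Hct = 0 edge: division by (1 - 0) is the identity
  expect_equal(to_plasma(cv, quant_config(hematocrit = 1e-12))$values,
               cv$values, tolerance = 1e-9)
})

test_that("dual-bolus assembly scales and aligns the pre-bolus", {
  tpre <- seq(0, 60, 1)
  pre <- concentration_curve(tpre, generate_aif(tpre, peak = 0.4, onset = 6),
                             role = "aif_blood")
  tmain <- seq(0, 90, 1)
  # main-bolus LV signal arrives 30 s after the pre-bolus arrival
  main_lv <- concentration_curve(tmain,
                                 generate_aif(tmain, peak = 2, onset = 36),
                                 role = "aif_blood")
  db <- assemble_dual_bolus(pre, main_lv, dilution = 0.10)
  # amplitude scale is exactly 1/dilution (peaks compared on the same grid)
  expect_equal(max(db$values), max(pre$values) / 0.10, tolerance = 1e-9)
  arr <- detect_arrival(db)
  expect_lte(abs(arr$time - detect_arrival(main_lv)$time), 1)
  expect_error(assemble_dual_bolus(pre, main_lv, dilution = 0), "dilution")
  expect_error(assemble_dual_bolus(pre, main_lv, dilution = 1), "dilution")
})

test_that("dual-sequence and dual-bolus AIF routes agree on MBF", {
  study <- clean_study()
  gt <- study$ground_truth
  # dual-sequence route: converted low-res AIF series
  ds <- study_aif_plasma(study)
  # dual-bolus route: a 10x diluted pre-bolus rendered as ground truth,
  # rescaled and aligned to the same main-bolus arrival
  tpre <- gt$t_sr
  pre <- concentration_curve(tpre, gt$aif / 10, role = "aif_blood")
  main_lv <- concentration_curve(ds$times, ds$blood, role = "aif_blood")
  db <- assemble_dual_bolus(pre, main_lv, dilution = 0.10)
  dbp <- to_plasma(db, gt$config)
  tissue <- forward_tissue(ds$values, gt$params[[1]], gt$spec$tissue_model,
                           ds$times)
  cr1 <- crop_first_pass(ds$values, tissue, ds$times)
  cr2 <- crop_first_pass(dbp$values, tissue, dbp$times)
  f1 <- fit_fermi(cr1$aif, cr1$tissue, cr1$times)
  f2 <- fit_fermi(cr2$aif, cr2$tissue, cr2$times)
  expect_lt(abs(f1$F_p - f2$F_p) / f1$F_p, 0.05)
})
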