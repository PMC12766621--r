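test_that("translation registration recovers injected shifts", {
  # motion-free: all displacements exactly zero
  r0 <- register_translation(clean_study()$myocardial[[1]], reference = 1)
  expect_equal(r0$displacements, matrix(0, 60, 2))
  # integer shifts of +/-3 px recovered exactly
  m3 <- cbind(c(rep(0, 10), rep(3, 50)), c(rep(0, 10), rep(-3, 50)))
  s3 <- phantom_study(phantom_spec(motion = m3))
  r3 <- register_translation(s3$myocardial[[1]], reference = 1)
  expect_equal(round(r3$displacements), m3)
  expect_lt(max(abs(r3$displacements - m3)), 0.25)
  # 0.6 px subpixel shift recovered within 0.5 px
  ms <- cbind(c(rep(0, 30), rep(0.6, 30)), rep(0, 60))
  ss <- phantom_study(phantom_spec(motion = ms))
  rs <- register_translation(ss$myocardial[[1]], reference = 1)
  expect_lt(max(abs(rs$displacements - ms)), 0.5)
})

test_that("registration tolerates noise and flags constant frames", {
  m3 <- cbind(c(rep(0, 10), rep(3, 50)), c(rep(0, 10), rep(-3, 50)))
  sn <- phantom_study(phantom_spec(motion = m3, noise_sd = 0.05))
  rn <- register_translation(sn$myocardial[[1]], reference = 1)
  expect_lt(max(abs(rn$displacements - m3)), 0.5)
  ser <- clean_study()$myocardial[[1]]
  ser$frames[, , 4] <- 7
  rf <- register_translation(ser, reference = 1)
  expect_true(any(grepl("frame 4 constant", rf$flags)))
  expect_equal(rf$displacements[4, ], c(0, 0))
})

test_that("coil correction recovers a known quadratic bias", {
  bias <- c(1, 0.3, -0.2, -0.15, 0.1, 0.12)
  sb <- phantom_study(phantom_spec(coil_bias = bias))
  cc <- coil_correct(sb$myocardial[[1]], method = "surface_fit")
  # corrected PD is flat over the uniform-M0 heart region
  pd <- (cc$corrected$frames[, , 1] + cc$corrected$frames[, , 2]) / 2
  gt <- sb$ground_truth
  heart <- gt$myo_masks[[1]] | gt$blood_mask
  expect_lt(stats::sd(pd[heart]) / mean(pd[heart]), 0.02)
  # pixelwise correction flattens the PD frames by construction
  cp <- coil_correct(sb$myocardial[[1]], method = "pixelwise")
  pdp <- (cp$corrected$frames[, , 1] + cp$corrected$frames[, , 2]) / 2
  expect_lt(stats::sd(pdp[heart]) / mean(pdp[heart]), 0.005)
  # uniform PD: bias is identically ~1, frames unchanged
  su <- clean_study()$myocardial[[1]]
  cu <- coil_correct(su, method = "surface_fit")
  heart0 <- clean_study()$ground_truth$myo_masks[[1]]
  expect_lt(max(abs(cu$bias[heart0] - 1)), 0.02)
  # all-zero PD is an error
  sz <- su
  sz$frames[, , su$frame_roles == "PD"] <- 0
  expect_error(coil_correct(sz), "zero")
})

test_that("baseline correction nulls the pre-contrast level", {
  x <- c(10, 10.2, 9.8, 10, 14, 20, 30, 25, 18)
  b <- baseline_correct(x, 1:4)
  expect_equal(mean(b[1:4]), 0)
  expect_equal(baseline_correct(b, 1:4), b)  # already-nulled: identity
  # averaging 4 noisy pre-contrast frames cuts estimator variance ~4x
  set.seed(31)
  est1 <- replicate(2000, rnorm(1))
  est4 <- replicate(2000, mean(rnorm(4)))
  expect_equal(var(est1) / var(est4), 4, tolerance = 0.35)
  ser <- clean_study()$myocardial[[1]]
  pre <- pre_contrast_frames(ser)
  expect_true(all(ser$frame_roles[pre] == "SR"))
  cor <- baseline_correct(ser, pre)
  expect_lt(max(abs(apply(cor$frames[, , pre, drop = FALSE], c(1, 2), mean))),
            1e-9)
  expect_error(baseline_correct(x, integer(0)), "empty")
})

test_that("spatial filtering is limited to myocardial series", {
  ser <- clean_study()$myocardial[[1]]
  expect_identical(spatial_filter(ser, "none"), ser)
  aif <- clean_study()$aif_series
  expect_error(spatial_filter(aif, "gaussian"), "AIF")
  # normalized gaussian kernel preserves mass of a delta image
  ser2 <- ser
  ser2$frames[] <- 0
  ser2$frames[48, 48, ] <- 1
  g <- spatial_filter(ser2, "gaussian", width = 1.5)
  expect_equal(sum(g$frames[, , 1]), 1, tolerance = 1e-6)
  # median filter removes a single-pixel outlier
  ser3 <- clean_study()$myocardial[[1]]
  ser3$frames[40, 40, 30] <- 50 * max(ser3$frames[, , 30])
  md <- spatial_filter(ser3, "median", width = 1)
  expect_lt(md$frames[40, 40, 30], 0.1 * ser3$frames[40, 40, 30])
})

test_that("preprocessing preserves frame ordering and timing", {
  ser <- clean_study()$myocardial[[1]]
  r <- register_translation(ser)$corrected
  c1 <- coil_correct(r, method = "pixelwise")$corrected
  f <- spatial_filter(c1, "gaussian", 1)
  expect_identical(f$trigger_times, ser$trigger_times)
  expect_identical(f$frame_roles, ser$frame_roles)
})

test_that("register + coil + convert restores the clean render", {
  bias <- c(1, 0.2, -0.15, -0.1, 0.08, 0.1)
  mo <- cbind(c(rep(0, 10), rep(1, 50)), c(rep(0, 10), rep(-1, 50)))
  sp <- phantom_study(phantom_spec(coil_bias = bias, motion = mo))
  clean <- clean_study()
  gt <- clean$ground_truth
  # the coil pattern is static in space while the anatomy moves, so the
  # exact pipeline order is coil-correct (from the motion-free PD frames),
  # then register, then convert
  cc <- coil_correct(sp$myocardial[[1]], method = "pixelwise", smooth = 0)
  reg <- register_translation(cc$corrected, reference = 1)
  conv_c <- si_to_concentration(reg$corrected, config = gt$config)
  conv_0 <- si_to_concentration(clean$myocardial[[1]], config = gt$config)
  m <- gt$myo_masks[[1]]
  for (i in 1:2)
    m <- as.matrix(EBImage::erode(m * 1, EBImage::makeBrush(3, "box"))) > 0.5
  pk <- which.max(gt$tissue[[1]])
  err <- abs(conv_c$concentration[, , pk] - conv_0$concentration[, , pk])
  expect_lt(max(err[m]) / max(conv_0$concentration[, , pk][m]), 0.01)
})
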