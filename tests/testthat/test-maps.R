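small_map_study <- function(fp = 1, region_kinetics = list(), seed = 1) {
  spec <- phantom_spec(matrix = 40, n_slices = 1, n_frames = 55,
                       base_kinetics = kinetic_params(F_p = fp, v_p = 0.08,
                                                      v_e = 0.2, PS = 0.5),
                       region_kinetics = region_kinetics, seed = seed)
  phantom_study(spec)
}

quantify_study <- function(study, model = "fermi", ...) {
  gt <- study$ground_truth
  conv <- si_to_concentration(study$myocardial[[1]], config = gt$config)
  aif <- study_aif_plasma(study)
  quantify_pixelwise(conv$concentration, conv$times, aif$values,
                     gt$myo_masks[[1]], model = model, config = gt$config,
                     arrival_delays = NULL, ...)
}

test_that("pixel-wise quantification is uniform on a uniform phantom", {
  map <- quantify_study(small_map_study())
  m <- map$mask
  expect_true(all(is.na(map$mbf[!m])))           # undefined outside the mask
  v <- map$F_p[m]
  expect_lt(stats::sd(v, na.rm = TRUE) / mean(v, na.rm = TRUE), 0.02)
  expect_equal(sum(map$qc_flags[m] == 1), 0)
  expect_error(quantify_pixelwise(array(0, c(4, 4, 10)), 1:10, rep(1, 10),
                                  matrix(FALSE, 4, 4)), "empty")
})

test_that("a half-flow subendocardial sector maps at half flow", {
  study <- small_map_study(
    fp = 2,
    region_kinetics = list(list(
      angles = c(0, 90),
      params = kinetic_params(F_p = 1, v_p = 0.08, v_e = 0.2, PS = 0.5))))
  map <- quantify_study(study)
  gt <- study$ground_truth
  hypo <- gt$region_masks[[1]] == 1 & gt$myo_masks[[1]]
  remote <- gt$region_masks[[1]] == 0 & gt$myo_masks[[1]]
  ratio <- mean(map$F_p[hypo], na.rm = TRUE) / mean(map$F_p[remote], na.rm = TRUE)
  expect_gte(ratio, 0.45)
  expect_lte(ratio, 0.55)
})

test_that("MPR maps divide stress by rest with a rest floor", {
  map <- quantify_study(small_map_study())
  same <- compute_mpr(map, map)
  expect_true(all(abs(same$mpr[same$mask] - 1) < 1e-9, na.rm = TRUE))
  stress <- map
  stress$mbf <- map$mbf * 3
  mpr <- compute_mpr(stress, map)
  expect_equal(stats::median(mpr$mpr[mpr$mask], na.rm = TRUE), 3,
               tolerance = 1e-9)
  # rest below the floor: undefined, flagged
  low <- map
  low$mbf[map$mask][1:5] <- 0.01
  ml <- compute_mpr(stress, low)
  expect_true(all(is.na(ml$mpr[map$mask][1:5])))
  other <- map
  other$mask <- !map$mask
  expect_error(compute_mpr(stress, other), "mask")
})

test_that("AHA 16-segment labels partition base/mid/apex as 6+6+4", {
  study <- clean_study()
  gt <- study$ground_truth
  ctr <- gt$spec$center
  rv <- c(ctr[1], 5)
  labels <- integer()
  for (s in 1:3) {
    lev <- c("base", "mid", "apex")[s]
    seg <- aha16_segment(gt$myo_masks[[s]], ctr, rv, lev)
    m <- gt$myo_masks[[s]]
    expect_true(all(!is.na(seg$labels[m])))      # no gaps
    expect_true(all(is.na(seg$labels[!m])))      # no spill-over
    labels <- c(labels, unique(na.omit(as.vector(seg$labels))))
  }
  expect_setequal(labels, 1:16)
  # rotating the RV insertion by 60 degrees rotates base labels one sector
  seg1 <- aha16_segment(gt$myo_masks[[1]], ctr, rv, "base")
  ang <- atan2(rv[2] - ctr[2], rv[1] - ctr[1]) + pi / 3
  rv2 <- ctr + 20 * c(cos(ang), sin(ang))
  seg2 <- aha16_segment(gt$myo_masks[[1]], ctr, rv2, "base")
  m <- gt$myo_masks[[1]]
  shifted <- ((seg1$labels[m] - 1 - 1) %% 6) + 1
  expect_gt(mean(seg2$labels[m] == shifted), 0.95)
  expect_error(aha16_segment(m, ctr, NULL, "base"), "RV insertion")
})

test_that("ischemic burden reports percent of myocardium", {
  study <- clean_study()
  gt <- study$ground_truth
  m <- gt$myo_masks[[1]]
  seg <- aha16_segment(m, gt$spec$center, c(gt$spec$center[1], 5), "base")
  mbf <- matrix(NA_real_, nrow(m), ncol(m))
  mbf[m] <- 2.5
  map <- structure(list(mbf = mbf, mask = m,
                        qc_flags = matrix(0, nrow(m), ncol(m)),
                        model = "fermi"), class = "parameter_map")
  b0 <- ischemic_burden(map, seg, threshold = 1.5)
  expect_equal(b0$percent_abnormal, 0)
  # two segments abnormal: 2/16 = 12.5% by equal segment weight
  mbf2 <- mbf
  mbf2[seg$labels %in% c(1, 2) & m] <- 0.8
  map2 <- map; map2$mbf <- mbf2
  b2 <- ischemic_burden(map2, seg, threshold = 1.5)
  expect_equal(b2$percent_by_segments, 12.5)
  expect_setequal(b2$affected_segments, c(1, 2))
  expect_gt(b2$percent_abnormal, 12)  # printed rule of thumb: >12%
  # everything abnormal
  map3 <- map; map3$mbf[m] <- 0.5
  expect_equal(ischemic_burden(map3, seg, threshold = 1.5)$percent_abnormal,
               100)
  # invariant to joint scaling of map and threshold
  map4 <- map2; map4$mbf <- map2$mbf * 7
  b4 <- ischemic_burden(map4, seg, threshold = 1.5 * 7)
  expect_equal(b4$percent_abnormal, b2$percent_abnormal)
})

test_that("achievable resolution reproduces the protocol worked example", {
  expect_equal(achievable_resolution(100, 2.5, 0.8, 2, 300), 3.0)
  expect_equal(achievable_resolution(120, 2, 1.0, 1, 360), 6.0)
  expect_equal(achievable_resolution(100, 2.5, 1, 1, 300),
               300 / floor(100 / 2.5))
  # homogeneous in FOV
  expect_equal(achievable_resolution(100, 2.5, 0.8, 2, 600),
               2 * achievable_resolution(100, 2.5, 0.8, 2, 300))
  expect_error(achievable_resolution(1, 2.5), "window")
  expect_error(achievable_resolution(100, 2.5, 1.4), "partial_fraction")
})

test_that("protocol validation checks every recommended acquisition bound", {
  myo <- seq_params(10, TR = 2.5, TE = 1.2, TS = 140, TD = 5,
                    lines_to_center = 55, acquisition_window = 100)
  rep <- validate_protocol(seq_myo = myo, seq_aif = default_seq_aif(),
                           pixel_spacing = 2.5, slice_thickness = 8,
                           n_slices = 2, n_pd_frames = 2)
  get <- function(rule) rep$status[grepl(rule, rep$rule)]
  expect_equal(get("myocardial TS"), "violation")   # 140 > 130
  expect_equal(get("AIF TS"), "pass")               # 22.5 < 30
  expect_equal(get("coverage"), "violation")        # 2 < 3 slices
  expect_equal(get("in-plane"), "pass")
  expect_equal(get("thickness"), "pass")
  rep2 <- validate_protocol(seq_myo = NULL, seq_aif = NULL)
  expect_true(all(rep2$status %in% c("unverifiable")))
})
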