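test_that("reference kinetic model is calibrated and exact per frame", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  # zero amplitudes give a zero TAC
  expect_equal(reference_tac_model(sch, amplitudes = c(0, 0))$values,
               rep(0, 37))
  expect_error(reference_tac_model(sch, rates = c(-0.1, 0.004)), "rates")
  # default late-window SUV inside the reference-region plausibility band
  s <- suv_window(ref, scan_meta(185, 74))$value
  expect_gte(s, 0.35); expect_lte(s, 0.72)
  # perfusion peak before 5 min
  cf <- attr(ref, "cont_fun")
  tt <- seq(0, 20, by = 0.02)
  expect_lt(tt[which.max(cf(tt))], 5)
  # frame averages match dense quadrature of the continuous model
  q <- vapply(1:37, function(i)
    integrate(cf, sch$starts[i], sch$ends[i],
              rel.tol = 1e-9)$value / sch$durations[i], numeric(1))
  expect_lt(max(abs(q - ref$values) / pmax(abs(q), 1e-12)), 0.01)
  # full-scan running integral agrees with quadrature of the model
  iq <- integrate(cf, 0, 120, rel.tol = 1e-10,
                  subdivisions = 2000L)$value
  expect_lt(abs(cumulative_integral(ref, 120) - iq) / iq, 0.01)
})

test_that("phantom construction is deterministic with calibrated truth", {
  p1 <- make_phantom("oCN")
  p2 <- make_phantom("oCN")
  expect_identical(p1$labels$data, p2$labels$data)
  expect_identical(p1$truth, p2$truth)
  # small entorhinal-like region of ~650 voxels
  id_ent <- p1$labels$labels$id[p1$labels$labels$name == "entorhinal"]
  expect_lt(abs(sum(p1$labels$data == id_ent) - 650) / 650, 0.15)
  # shell strictly outside the brain
  expect_false(any(p1$labels$data == p1$shell_id & p1$brain_mask))
  # target R1 truths inside the published bracket
  tgt <- subset(p1$truth, role == "target")
  expect_true(all(tgt$R1 >= 0.66 & tgt$R1 <= 1.39))
  # AD profile reaches the high-binding ceiling
  pa <- make_phantom("AD")
  expect_gt(max(pa$truth$dvr_true), 2.5)
  expect_lte(max(pa$truth$dvr_true), 2.9)
})

test_that("cohort profiles land inside the calibration bands", {
  sch <- mk6240_frame_schedule()
  meta <- scan_meta(185, 74)
  for (profile in c("oCN", "AD")) {
    ph <- make_phantom(profile)
    tacs <- phantom_tacs(ph, sch)
    suvs <- vapply(tacs, function(tc) suv_window(tc, meta)$value,
                   numeric(1))
    sv <- suvs / suvs[["cergm"]]
    tgt <- sv[ph$truth$region[ph$truth$role == "target"]]
    if (profile == "oCN") {
      expect_true(all(tgt >= 0.6 & tgt <= 1.2))
    } else {
      expect_gt(max(tgt), 2.5)       # up to ~2.8 in high-binding cortex
      expect_lte(max(tgt), 3.0)
    }
    expect_gt(sv[["extracerebral"]], 1.2)  # shell above every target mean
    expect_gte(suvs[["cergm"]], 0.35); expect_lte(suvs[["cergm"]], 0.72)
  }
})

test_that("noise-free unblurred simulation paints the exact truth", {
  ph <- make_phantom("oCN")
  sch <- mk6240_frame_schedule()
  img <- simulate_dynamic(ph, sch, psf_fwhm = 0, noise_cv = 0, seed = 1)
  specs <- phantom_region_specs(ph)
  tacs <- sample_regions(img, ph$labels, specs, sch)
  truth <- attr(img, "tacs")
  for (r in c("cergm", "entorhinal", "insula", "extracerebral")) {
    expect_equal(tacs[[r]]$values, truth[[r]]$values, tolerance = 1e-12)
  }
})

test_that("seeds separate noise realizations from shared truth", {
  ph <- make_phantom("oCN")
  sch <- mk6240_frame_schedule()
  i1 <- simulate_dynamic(ph, sch, 0, 0.05, seed = 1)
  i2 <- simulate_dynamic(ph, sch, 0, 0.05, seed = 2)
  expect_false(identical(as.numeric(i1), as.numeric(i2)))
  t1 <- attr(i1, "tacs"); t2 <- attr(i2, "tacs")
  expect_equal(t1$entorhinal$values, t2$entorhinal$values)
  i1b <- simulate_dynamic(ph, sch, 0, 0.05, seed = 1)
  expect_identical(as.numeric(i1), as.numeric(i1b))
})

test_that("matched-kernel PVC removes most of the simulated spill", {
  ph <- make_phantom("oCN")
  sch <- mk6240_frame_schedule()
  img <- simulate_dynamic(ph, sch, psf_fwhm = 5, noise_cv = 0, seed = 1,
                          heterogeneity = 0)
  truth <- attr(img, "tacs")
  specs <- phantom_region_specs(ph)
  masks <- resolve_region_masks(ph$labels, specs)
  w <- frames_in_window(sch, 90, 110)
  win_mean <- function(im, reg) {
    tc <- sample_regions(im, ph$labels, specs[reg], sch,
                         masks[reg])[[reg]]
    mean(tc$values[w])
  }
  tru <- mean(truth$cergm$values[w])
  bias_blur <- abs(win_mean(img, "cergm") / tru - 1)
  expect_gt(bias_blur, 0.001)  # blur biases the reference toward neighbors
  corr <- iterative_yang(img, ph$labels, pvc_config(5, 10))
  bias_pvc <- abs(win_mean(corr, "cergm") / tru - 1)
  expect_lt(bias_pvc, 0.05)
  expect_lt(bias_pvc, bias_blur)
})

test_that("test-retest pairs share truth and collapse at zero CV", {
  ph <- make_phantom("oCN")
  quiet <- retest_perturbation(0, 0, 0, 0, 0)
  pair <- make_trt_pair(ph, quiet, seed = 3)
  expect_equal(as.numeric(pair$test), as.numeric(pair$retest))
  specs <- phantom_region_specs(ph)
  sch <- mk6240_frame_schedule()
  t1 <- sample_regions(pair$test, ph$labels, specs, sch)
  t2 <- sample_regions(pair$retest, ph$labels, specs, sch)
  meta <- pair$meta_test
  for (r in c("cergm", "entorhinal", "extracerebral")) {
    expect_equal(trt_percent(suv_window(t1[[r]], meta)$value,
                             suv_window(t2[[r]], meta)$value), 0)
  }
  # same seed reproduces the pair; sessions carry matching metadata
  pair2 <- make_trt_pair(ph, quiet, seed = 3)
  expect_equal(as.numeric(pair$test), as.numeric(pair2$test))
  expect_equal(pair$meta_test$session, "test")
  expect_equal(pair$meta_retest$session, "retest")
})

test_that("phantom writes its label map and truth sidecars", {
  ph <- make_phantom("oCN")
  d <- tempfile()
  write_phantom(ph, d)
  expect_true(file.exists(file.path(d, "labels.nii.gz")))
  expect_true(file.exists(file.path(d, "labels.labels.json")))
  expect_true(file.exists(file.path(d, "truth.json")))
  back <- read_label_volume(file.path(d, "labels.nii.gz"))
  expect_identical(back$data, ph$labels$data)
})
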