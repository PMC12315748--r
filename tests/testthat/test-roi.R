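test_that("erosion is exact against the brute-force voxel-distance oracle", {
  shape <- c(16, 16, 16); vox <- c(2, 2, 2)
  m <- ball_phantom(shape, vox, 10)
  er <- erode_mask(m, 4, vox)
  bg <- which(!m)
  d_oracle <- brute_min_dist(which(m), bg, shape, vox)
  # boundary surface lies half a voxel beyond the outermost centers
  keep_oracle <- which(m)[d_oracle >= 4 + mean(vox) / 2]
  expect_identical(sort(which(er)), sort(keep_oracle))
  # survivors honour the nominal distance a fortiori
  expect_true(all(d_oracle[which(m) %in% which(er)] >= 4))
  # distance 0 is the identity
  expect_identical(erode_mask(m, 0, vox), m)
  # erosion to extinction is an error naming the region
  expect_error(erode_mask(m, 50, vox, name = "cergm"), "cergm")
})

test_that("sequential erosion nests inside single-step erosion", {
  # exact in continuous morphology; on a voxel lattice the two differ by
  # at most one voxel diagonal of quantization
  vox <- c(2, 2, 2)
  diag_mm <- sqrt(sum(vox^2))
  m <- ball_phantom(c(20, 20, 20), vox, 14)
  e_ab <- erode_mask(erode_mask(m, 3, vox), 3, vox)
  e_relaxed <- erode_mask(m, 6 - diag_mm, vox)
  expect_true(all(e_relaxed[e_ab]))
  expect_lt(sum(e_ab), sum(erode_mask(m, 3, vox)))  # strictly deeper
})

test_that("extracerebral shell sits strictly outside within its thickness", {
  shape <- c(20, 20, 20); vox <- c(2, 2, 2)
  m <- ball_phantom(shape, vox, 10)
  sh <- build_extracerebral_shell(m, 5, vox)
  expect_false(any(sh & m))
  d_oracle <- brute_min_dist(which(sh), which(m), shape, vox)
  expect_true(all(d_oracle > 0 & d_oracle <= 5))
  # every outside voxel within 5 mm is captured (exactness both ways)
  out_idx <- which(!m)
  d_all <- brute_min_dist(out_idx, which(m), shape, vox)
  expect_identical(sort(which(sh)), sort(out_idx[d_all <= 5]))
  expect_error(build_extracerebral_shell(m, 0, vox), "thickness")
  expect_error(build_extracerebral_shell(array(FALSE, shape), 5, vox),
               "empty")
})

test_that("morphology is mm-aware under voxel-size refinement", {
  # same physical ball sampled at 2 mm and 1 mm: eroded physical volumes
  # agree within 10%
  m2 <- ball_phantom(c(24, 24, 24), c(2, 2, 2), 14)
  m1 <- ball_phantom(c(48, 48, 48), c(1, 1, 1), 14)
  v2 <- sum(erode_mask(m2, 4, c(2, 2, 2))) * 8
  v1 <- sum(erode_mask(m1, 4, c(1, 1, 1))) * 1
  expect_lt(abs(v2 - v1) / v1, 0.10)
  s2 <- sum(build_extracerebral_shell(m2, 5, c(2, 2, 2))) * 8
  s1 <- sum(build_extracerebral_shell(m1, 5, c(1, 1, 1))) * 1
  expect_lt(abs(s2 - s1) / s1, 0.10)
})

test_that("composites union constituents and partition cleanly", {
  ph <- make_phantom("oCN")
  mt <- composite_region(ph$labels, meta_temporal_constituents(),
                         name = "meta_temporal")
  expect_length(mt$ids, 6L)
  vox_count <- vapply(meta_temporal_constituents(), function(nm)
    sum(ph$labels$data == ph$labels$labels$id[ph$labels$labels$name == nm]),
    numeric(1))
  expect_equal(sum(ph$labels$data %in% mt$ids), sum(vox_count))
  expect_error(composite_region(ph$labels, c("entorhinal", "nonesuch")),
               "nonesuch")
  # inferior/superior split partitions the parent region
  cer <- ph$labels$data == ph$labels$labels$id[ph$labels$labels$name ==
                                                 "cergm"]
  dim(cer) <- dim(ph$labels$data)
  sup <- cer
  sup[, , 1:32] <- FALSE                       # a superior half-mask
  inf <- mask_difference(cer, sup)
  expect_false(any(inf & sup))
  expect_equal(sum(inf) + sum(sup), sum(cer))
})

test_that("region sampling is exact on piecewise-constant volumes", {
  ph <- make_phantom("oCN")
  sch <- frame_schedule(c(0, 1), c(1, 2))
  truth1 <- 1.5; truth2 <- 2.5
  id_ent <- ph$labels$labels$id[ph$labels$labels$name == "entorhinal"]
  img <- array(0, c(dim(ph$labels$data), 2))
  img[, , , 1][ph$labels$data == id_ent] <- truth1
  img[, , , 2][ph$labels$data == id_ent] <- truth2
  spec <- region_spec("entorhinal", id_ent, role = "target")
  tc <- sample_regions(img, ph$labels, spec, sch)$entorhinal
  expect_equal(tc$values, c(truth1, truth2))
})

test_that("bilateral pooling equals the voxel-count-weighted hemisphere mean", {
  lab <- array(0L, c(10, 10, 4))
  lab[2:4, 2:5, 1:2] <- 1L   # left: 24 voxels
  lab[7:9, 2:7, 1:2] <- 2L   # right: 36 voxels
  lv <- label_volume(lab, c(2, 2, 2),
                     data.frame(id = 1:2, name = c("roi_lh", "roi_rh"),
                                hemisphere = c("L", "R"), role = "target"))
  set.seed(9)
  img <- array(rnorm(prod(dim(lab)), 5), c(dim(lab), 1))
  sch1 <- frame_schedule(0, 1)
  pooled <- sample_regions(img, lv, region_spec("roi", 1:2), sch1)$roi
  lh <- sample_regions(img, lv, region_spec("lh", 1L), sch1)$lh
  rh <- sample_regions(img, lv, region_spec("rh", 2L), sch1)$rh
  n_l <- sum(lab == 1L); n_r <- sum(lab == 2L)
  expect_equal(pooled$values,
               (n_l * lh$values + n_r * rh$values) / (n_l + n_r))
  # single-voxel region returns that voxel's trajectory
  one <- array(FALSE, dim(lab)); one[5, 5, 3] <- TRUE
  lab2 <- lab; lab2[5, 5, 3] <- 3L
  lv2 <- label_volume(lab2, c(2, 2, 2))
  tr <- sample_regions(img, lv2, region_spec("pt", 3L), sch1)$pt
  expect_equal(tr$values, img[5, 5, 3, 1])
})

test_that("label volumes round-trip through NIfTI with their dictionary", {
  ph <- make_phantom("oCN")
  f <- tempfile(fileext = ".nii.gz")
  write_label_volume(ph$labels, f)
  back <- read_label_volume(f)
  expect_identical(back$data, ph$labels$data)
  expect_equal(back$voxdim, ph$labels$voxdim)
  expect_equal(back$labels$name, ph$labels$labels$name)
  expect_error(label_volume(array(0L, c(4, 4, 4)),
                            labels = data.frame(id = 9, name = "gone")),
               "empty")
})
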