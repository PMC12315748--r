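test_that("SUV normalizes concentration by dose per body weight", {
  expect_equal(suv(1.5, scan_meta(185, 74))$value, 0.6)
  expect_equal(suv(0, scan_meta(185, 74))$value, 0)
  expect_equal(suv(2.5, scan_meta(100, 100))$value, 2.5)
  expect_error(scan_meta(0, 74), "injected_dose")
  expect_error(scan_meta(185, -1), "body_weight")
})

test_that("windowed SUV averages the contained frames unweighted", {
  sch <- mk6240_frame_schedule()
  meta1 <- scan_meta(100, 100)      # dose/weight = 1 kBq/g
  vals <- rep(0.5, 37)
  vals[frames_in_window(sch, 90, 110)] <- c(1, 2, 3, 4)
  expect_equal(suv_window(tac(sch, vals), meta1)$value, 2.5)
  expect_equal(suv_window(tac(sch, rep(2, 37)), meta1)$value, 2)
  expect_error(suv_window(tac(sch, vals), meta1, t0 = 66, t1 = 79))
})

test_that("windowed SUV of a model TAC matches continuous quadrature", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  tgt <- srtm_forward(ref, srtm_params(0.8, 0.032, 1.7))  # AD-like uptake
  cf <- attr(tgt, "cont_fun")
  truth <- integrate(cf, 90, 110, rel.tol = 1e-8)$value / 20
  got <- suv_window(tgt, scan_meta(100, 100))$value
  expect_lt(abs(got - truth) / truth, 0.01)
})

test_that("SUVR is a guarded ratio of like-for-like SUVs", {
  m <- scan_meta(185, 74)
  a <- suv(1.5, m, window = c(90, 110))
  expect_equal(suvr(a, a), 1)
  b <- suv(1.25, m, window = c(90, 110))
  expect_equal(suvr(a, b), 1.2)
  expect_error(suvr(a, suv(1, m, window = c(80, 100))), "identical windows")
  expect_error(suvr(a, suv(1, m, window = c(90, 110), pvc_applied = TRUE)),
               "mix PVC")
  expect_error(suvr(a, suv(0, m, window = c(90, 110))), "positive")
})

test_that("SRTM forward simulation has the right limits", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  # R1 = 1, BP = 0 collapses the convolution term: output equals reference
  out <- srtm_forward(ref, srtm_params(1, 0.07, 0))
  expect_identical(out$values, ref$values)
  # zero reference propagates to zero target
  zero <- tac(sch, rep(0, 37))
  expect_equal(srtm_forward(zero, srtm_params(0.8, 0.05, 0.5))$values,
               rep(0, 37))
  expect_error(srtm_params(0.8, -0.1, 0.5), "k2")
  expect_error(srtm_params(0.8, 0.05, -1.2), "BP")
})

test_that("SRTM forward agrees with an independent ODE solution", {
  skip_if_not_installed("deSolve")
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  p <- srtm_params(0.8, 0.05, 0.5)
  cf <- attr(ref, "cont_fun")
  dcr <- function(t, h = 1e-5) (cf(t + h) - cf(t - h)) / (2 * h)
  rhs <- function(t, y, parms)
    list(p$R1 * dcr(t) + (p$k2 - p$R1 * p$k2a) * cf(t) -
           p$k2a * (y[1] - p$R1 * cf(t)))
  times <- sort(unique(c(seq(0, 120, by = 0.01), sch$starts, sch$ends)))
  sol <- deSolve::ode(y = c(ct = 0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  ctf <- approxfun(sol[, 1], sol[, 2])
  frame_avg <- vapply(1:37, function(i)
    integrate(ctf, sch$starts[i], sch$ends[i],
              rel.tol = 1e-7)$value / sch$durations[i], numeric(1))
  fwd <- srtm_forward(ref, p)
  expect_lt(max(abs(fwd$values - frame_avg) / pmax(abs(frame_avg), 1e-9)),
            0.005)
})

test_that("SRTM basis-function fit recovers generating parameters", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  tgt <- srtm_forward(ref, srtm_params(0.8, 0.05, 0.5))
  fit <- srtm_fit(tgt, ref)
  expect_lt(abs(fit$R1 - 0.8) / 0.8, 0.01)
  expect_lt(abs(fit$BP - 0.5) / 0.5, 0.02)
  expect_equal(unname(coef(fit)["R1"]), fit$R1)
  # target identical to reference: R1 = 1, BP = 0, washout unidentifiable
  idf <- srtm_fit(ref, ref)
  expect_equal(idf$R1, 1, tolerance = 1e-6)
  expect_equal(idf$BP, 0, tolerance = 1e-6)
  expect_true(idf$diagnostics$k2_unidentifiable)
  expect_error(srtm_fit(tac(sch, rep(0, 37)), ref), "all zero")
})

test_that("SRTM fit is robust to frame noise (median R1 within 3%)", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  truth <- srtm_params(0.9, 0.036, 0.3)
  clean <- srtm_forward(ref, truth)
  set.seed(7)
  r1 <- replicate(100, {
    noisy <- tac(sch, clean$values * (1 + rnorm(37, 0, 0.05)))
    srtm_fit(noisy, ref)$R1
  })
  expect_lt(abs(median(r1) - 0.9) / 0.9, 0.03)
})

test_that("MRTM2 reproduces DVR = 1 + BP on model data", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)   # generating reference efflux 0.04/min
  ident <- mrtm2_fit(ref, ref, t_star = 30, k2_prime = 0.04)
  expect_lt(abs(ident$dvr - 1), 0.005)
  tgt <- srtm_forward(ref, srtm_params(0.9, 0.9 * 0.04, 0.8))
  fit <- mrtm2_fit(tgt, ref, t_star = 30, k2_prime = 0.04)
  expect_lt(abs(fit$dvr - 1.8) / 1.8, 0.02)
  expect_gte(fit$n_frames_used, 3L)
  expect_error(mrtm2_fit(tgt, ref, t_star = 118), ">= 3 frames")
})

test_that("DVR rank order follows true binding across regions", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  bp <- c(0.04, -0.15, 0.6, 1.16, 1.51, 1.77, 0.32)
  r1 <- c(0.69, 0.91, 0.85, 0.90, 0.83, 1.06, 1.39)
  dvr <- mapply(function(R1, BP) {
    tgt <- srtm_forward(ref, srtm_params(R1, R1 * 0.04, BP))
    mrtm2_fit(tgt, ref)$dvr
  }, r1, bp)
  expect_equal(order(dvr), order(1 + bp))
})

test_that("noise-free SUVR and DVR are strongly rank-correlated", {
  sch <- mk6240_frame_schedule()
  ref <- reference_tac_model(sch)
  meta <- scan_meta(185, 74)
  ref_suv <- suv_window(ref, meta)
  tt <- subset(make_phantom("oCN")$truth, role == "target")
  vals <- t(mapply(function(R1, k2, BP) {
    tgt <- srtm_forward(ref, srtm_params(R1, k2, BP))
    c(suvr = suvr(suv_window(tgt, meta), ref_suv),
      dvr = mrtm2_fit(tgt, ref)$dvr)
  }, tt$R1, tt$k2, tt$BP))
  rho <- rank_association(vals[, "suvr"], vals[, "dvr"])$rho
  expect_gte(rho, 0.84)
})
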