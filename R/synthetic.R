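#' Synthetic reference-region time-activity curve
#'
#' Continuous reference kinetic used by the phantom generator: a
#' one-tissue-compartment response (efflux `k2_ref`) to a plasma-like input
#' built from a fast rise and a bi-exponential washout,
#' `Cp(t) = sum_i a_i e^(-lambda_i t) - (sum_i a_i) e^(-rise_rate t)`.
#' Everything is a sum of exponentials, so frame averages are computed from
#' the closed-form antiderivative (exact under reconstructed-frame
#' semantics) and the continuous model is attached as attribute `cont_fun`
#' for quadrature oracles and dense forward simulation.
#'
#' The defaults are calibrated so that, at a typical injected dose per body
#' weight (185 MBq / 74 kg), the reference-region SUV over 90-110 min lands
#' mid-range in 0.35-0.72 g/mL, with an early perfusion peak before 5 min.
#'
#' @param schedule a [frame_schedule].
#' @param amplitudes plasma washout amplitudes (kBq/mL), all >= 0.
#' @param rates plasma washout rates (1/min), all > 0, same length.
#' @param rise_rate plasma appearance rate (1/min, > 0).
#' @param k1_ref reference influx scale (mL/min/mL).
#' @param k2_ref reference efflux rate (1/min); this is the generating
#'   reference efflux that a matched MRTM2 `k2_prime` should equal.
#' @param region_id label for the TAC.
#' @return A [tac] with attributes `cont_fun` and `k2_ref`.
#' @export
reference_tac_model <- function(schedule, amplitudes = c(15, 0.2),
                                rates = c(1.0, 0.004), rise_rate = 4,
                                k1_ref = 0.36, k2_ref = 0.04,
                                region_id = "cergm") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (any(rates <= 0) || rise_rate <= 0 || k2_ref <= 0)
    stop("rates must be > 0 (1/min)")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  if (length(amplitudes) != length(rates))
    stop("amplitudes and rates must have equal length")
  # C_R = k1_ref * sum_i a_i h(lambda_i) - k1_ref * A h(rise_rate),
  # h(l) = (e^(-l t) - e^(-k2_ref t)) / (k2_ref - l): collect into a single
  # exponential mixture sum_j c_j e^(-mu_j t)
  mus <- c(rates, rise_rate, k2_ref)
  a_all <- c(amplitudes, -sum(amplitudes))
  cs <- numeric(length(mus))
  for (i in seq_along(a_all)) {
    den <- k2_ref - mus[i]
    if (abs(den) < 1e-9) den <- 1e-9   # guard coincident rates
    cs[i] <- cs[i] + a_all[i] / den
    cs[length(mus)] <- cs[length(mus)] - a_all[i] / den
  }
  cs <- cs * k1_ref
  cont <- function(t) {
    out <- 0
    for (j in seq_along(mus)) out <- out + cs[j] * exp(-mus[j] * t)
    out
  }
  vals <- .expmix_frame_avg(cs, mus, schedule)
  out <- tac(schedule, vals, region_id)
  attr(out, "cont_fun") <- cont
  attr(out, "k2_ref") <- k2_ref
  out
}

# exact frame averages of sum_j c_j exp(-mu_j t)
.expmix_frame_avg <- function(cs, mus, schedule) {
  s <- schedule$starts; e <- schedule$ends; dur <- schedule$durations
  vals <- numeric(length(s))
  for (j in seq_along(mus)) {
    if (abs(mus[j]) < 1e-12) vals <- vals + cs[j]
    else vals <- vals + cs[j] * (exp(-mus[j] * s) - exp(-mus[j] * e)) /
        (mus[j] * dur)
  }
  vals
}

#' Synthetic extracerebral (meningeal) time-activity curve
#'
#' Slow saturating accumulation `A (1 - e^(-rate t))`, calibrated so the
#' 90-110 min shell-to-reference ratio equals `suvr_level` (extracerebral
#' uptake sits above all cerebral reference regions in cognitively normal
#' subjects).
#'
#' @param schedule a [frame_schedule].
#' @param ref a reference [tac] used for calibration.
#' @param suvr_level target late-window shell/reference ratio. Default 1.38.
#' @param rate accumulation rate (1/min). Default 0.03.
#' @param window calibration window (minutes). Default `c(90, 110)`.
#' @return A [tac] with attribute `cont_fun`.
#' @export
shell_tac_model <- function(schedule, ref, suvr_level = 1.38, rate = 0.03,
                            window = c(90, 110)) {
  stopifnot(inherits(schedule, "frame_schedule"), inherits(ref, "tac"))
  if (rate <= 0) stop("rate must be > 0 (1/min)")
  idx <- frames_in_window(schedule, window[1], window[2])
  shape <- .expmix_frame_avg(c(1, -1), c(0, rate), schedule)
  amp <- suvr_level * mean(ref$values[idx]) / mean(shape[idx])
  out <- tac(schedule, amp * shape, "extracerebral")
  attr(out, "cont_fun") <- function(t) amp * (1 - exp(-rate * t))
  out
}

# per-profile ground-truth kinetic parameters; BP = DVR - 1 with DVR and R1
# chosen inside the published older-CN / AD plausibility ranges
.phantom_truth_table <- function(profile) {
  regions <- c("cergm", "pons", "wm", "cerebrum_rest",
               "entorhinal", "amygdala", "hippocampus", "parahippocampal",
               "fusiform", "inf_temporal", "mid_temporal", "precuneus",
               "insula")
  roles <- c("reference", "reference", "reference", "other",
             rep("target", 9))
  tt <- switch(profile,
    oCN = data.frame(
      region = regions, role = roles,
      R1 = c(1.00, 0.80, 0.55, 0.90,
             0.69, 0.91, 0.91, 0.85, 0.90, 0.83, 0.84, 1.06, 1.39),
      BP = c(0.00, -0.35, -0.20, -0.05,
             0.04, -0.15, -0.10, 0.00, 0.03, 0.05, 0.02, -0.09, -0.14)),
    yCN = data.frame(
      region = regions, role = roles,
      R1 = c(1.00, 0.80, 0.55, 0.90,
             0.68, 0.72, 0.79, 0.82, 0.95, 0.85, 0.86, 1.05, 1.22),
      BP = c(0.00, -0.35, -0.20, -0.05,
             -0.05, -0.31, -0.25, -0.05, -0.01, 0.06, -0.02, -0.13, -0.19)),
    AD = data.frame(
      region = regions, role = roles,
      R1 = c(1.00, 0.80, 0.55, 0.85,
             0.66, 0.76, 0.77, 0.75, 0.84, 0.70, 0.72, 0.83, 0.93),
      BP = c(0.00, -0.35, 0.10, 0.15,
             0.72, 0.29, 0.07, 0.60, 1.16, 1.51, 1.40, 1.77, 0.32)),
    stop("unknown profile"))
  tt$k2 <- tt$R1 * 0.04   # SRTM consistency: k2 = R1 * k2_ref
  tt$dvr_true <- 1 + tt$BP
  tt
}

# digital ball: voxel centers within radius r (mm) of center (mm)
.ball_mask <- function(shape, voxdim, center, radius) {
  cx <- (seq_len(shape[1]) - 0.5) * voxdim[1]
  cy <- (seq_len(shape[2]) - 0.5) * voxdim[2]
  cz <- (seq_len(shape[3]) - 0.5) * voxdim[3]
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' Build a spherical-blob dynamic-PET phantom
#'
#' Deterministic geometry on a 64^3 grid of 2 mm isotropic voxels (by
#' default): a spherical brain envelope holding a cerebellar grey reference
#' blob, pons, a white-matter core, and nine target blobs including a small
#' entorhinal-like region of ~650 voxels; unassigned brain voxels form a
#' `cerebrum_rest` filler region, and a 5 mm extracerebral shell surrounds
#' the brain. Per-region ground-truth kinetics (R1, k2, BP and the implied
#' DVR) follow the cohort profile.
#'
#' @param profile `"oCN"`, `"yCN"` or `"AD"`.
#' @param shape grid dimensions. Default `c(64, 64, 64)`.
#' @param voxdim voxel size in mm. Default 2 mm isotropic.
#' @param shell_thickness extracerebral shell thickness in mm. Default 5.
#' @param seed retained for interface symmetry; the geometry and truth are
#'   fully deterministic.
#' @return An object of class `pet_phantom`: `labels` (a [label_volume]
#'   whose dictionary carries roles), `truth` (per-region parameter table),
#'   `brain_mask`, `profile`.
#' @export
make_phantom <- function(profile = c("oCN", "yCN", "AD"),
                         shape = c(64, 64, 64), voxdim = c(2, 2, 2),
                         shell_thickness = 5, seed = 1L) {
  profile <- match.arg(profile)
  ctr <- shape * voxdim / 2
  geom <- list(
    cergm          = list(pos = c(0, 0, -30), r = 13),
    pons           = list(pos = c(0, -22, -25), r = 7),
    wm             = list(pos = c(0, 0, 0), r = 11),
    entorhinal     = list(pos = c(26, 0, -10), r = 10.75),
    amygdala       = list(pos = c(-26, 0, -10), r = 8),
    hippocampus    = list(pos = c(0, 26, -10), r = 8),
    parahippocampal= list(pos = c(0, -26, 5), r = 8),
    fusiform       = list(pos = c(18, 18, 12), r = 9),
    inf_temporal   = list(pos = c(-18, 18, 12), r = 9),
    mid_temporal   = list(pos = c(18, -18, 12), r = 9),
    precuneus      = list(pos = c(-18, -18, 12), r = 9),
    insula         = list(pos = c(0, 0, 26), r = 9))
  brain <- .ball_mask(shape, voxdim, ctr, 46)
  lab <- array(0L, shape)
  truth <- .phantom_truth_table(profile)
  id_of <- stats::setNames(seq_len(nrow(truth)), truth$region)
  for (nm in names(geom)) {
    m <- .ball_mask(shape, voxdim, ctr + geom[[nm]]$pos, geom[[nm]]$r)
    if (any(lab[m] != 0L)) stop(sprintf("phantom blob '%s' overlaps", nm))
    lab[m] <- id_of[[nm]]
  }
  lab[brain & lab == 0L] <- id_of[["cerebrum_rest"]]
  shell <- build_extracerebral_shell(brain, shell_thickness, voxdim)
  shell_id <- nrow(truth) + 1L
  lab[shell] <- shell_id
  dict <- data.frame(id = c(unname(id_of), shell_id),
                     name = c(truth$region, "extracerebral"),
                     hemisphere = NA_character_,
                     role = c(truth$role, "extracerebral"))
  structure(list(labels = label_volume(lab, voxdim, dict),
                 truth = truth, brain_mask = brain, profile = profile,
                 shell_id = shell_id),
            class = "pet_phantom")
}

#' @export
print.pet_phantom <- function(x, ...) {
  cat(sprintf("<pet_phantom: %s profile, %d regions + shell, %s voxels>\n",
              x$profile, nrow(x$truth), paste(dim(x$labels$data),
                                              collapse = "x")))
  invisible(x)
}

#' Write phantom outputs
#'
#' Emits the label map as NIfTI (+ JSON dictionary sidecar) and the truth
#' table as JSON.
#'
#' @param phantom a `pet_phantom`.
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_volume(phantom$labels, file.path(dir, "labels.nii.gz"))
  jsonlite::write_json(phantom$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Test-retest perturbation model
#'
#' Within-subject variability applied independently to each session:
#' a global multiplicative scale jitter (dose/weight measurement analogue,
#' common to all regions, cancelling in SUVR) and per-region multiplicative
#' jitter `~ Normal(1, CV)` by region class. The reference class carries no
#' independent jitter by default, so the expected SUVR test-retest
#' percentage difference is `112.8 x target_cv`. The extracerebral shell
#' receives its own, larger CV.
#'
#' @param target_cv within-subject CV for target-class regions. Default
#'   0.05.
#' @param reference_cv within-subject CV for reference-class regions.
#'   Default 0.
#' @param shell_cv within-subject CV for the extracerebral shell. Default
#'   0.12.
#' @param scale_cv CV of the global scale jitter. Default 0.07.
#' @param noise_cv acquisition noise CV at 300-s frames (voxel level).
#'   Default 0.03.
#' @return An object of class `retest_perturbation`.
#' @export
retest_perturbation <- function(target_cv = 0.05, reference_cv = 0,
                                shell_cv = 0.12, scale_cv = 0.07,
                                noise_cv = 0.03) {
  cvs <- c(target_cv, reference_cv, shell_cv, scale_cv, noise_cv)
  if (any(cvs < 0)) stop("CVs must be >= 0")
  structure(list(target_cv = target_cv, reference_cv = reference_cv,
                 shell_cv = shell_cv, scale_cv = scale_cv,
                 noise_cv = noise_cv), class = "retest_perturbation")
}

#' Between-subject variation of a phantom's truth
#'
#' Draws one subject's kinetic truth around the cohort profile:
#' multiplicative jitter on R1 and on 1+BP, a reference-amplitude factor
#' (global uptake level) and a shell-amplitude factor with the large
#' between-subject spread characteristic of extracerebral signal.
#'
#' @param phantom a `pet_phantom`.
#' @param seed integer seed.
#' @param r1_cv,dvr_cv,ref_amp_cv between-subject CVs. Defaults 0.10, 0.10,
#'   0.20.
#' @param shell_amp_cv lognormal CV of the shell amplitude. Default 0.4.
#' @return A list: `truth` (jittered table), `ref_amp`, `shell_amp`.
#' @export
subject_truth <- function(phantom, seed, r1_cv = 0.10, dvr_cv = 0.10,
                          ref_amp_cv = 0.20, shell_amp_cv = 0.4) {
  set.seed(seed)
  tt <- phantom$truth
  n <- nrow(tt)
  jig <- function(cv, m = n) if (cv > 0) pmax(stats::rnorm(m, 1, cv), 0.2)
    else rep(1, m)
  r1f <- jig(r1_cv); dvrf <- jig(dvr_cv)
  keep <- tt$region == "cergm"   # the reference defines R1 = 1, BP = 0
  r1f[keep] <- 1; dvrf[keep] <- 1
  tt$R1 <- tt$R1 * r1f
  tt$BP <- (1 + tt$BP) * dvrf - 1
  tt$k2 <- tt$R1 * 0.04
  tt$dvr_true <- 1 + tt$BP
  list(truth = tt,
       ref_amp = jig(ref_amp_cv, 1),
       shell_amp = exp(stats::rnorm(1, 0, sqrt(log(1 + shell_amp_cv^2)))))
}

#' Phantom spatial basis and ground-truth regional TACs
#'
#' `phantom_basis` returns the voxels-by-regions matrix of (optionally
#' PSF-blurred) spatial weights — indicator columns per region, with a
#' seeded smooth heterogeneity field on the extracerebral shell
#' (mean 1 over the shell). `phantom_tacs` returns the unscaled regional
#' ground-truth TACs (reference kinetic, SRTM forward curves, shell
#' accumulation curve). [simulate_dynamic()] combines them; precomputing
#' lets a test-retest pair share anatomy and kinetics across sessions.
#'
#' @param phantom a `pet_phantom`.
#' @param psf_fwhm PSF FWHM in mm (0 = no blur).
#' @param heterogeneity shell field relative amplitude.
#' @param field_seed seed for the shell field.
#' @return `phantom_basis`: numeric matrix (voxels x regions+shell).
#' @export
phantom_basis <- function(phantom, psf_fwhm = 5, heterogeneity = 0.3,
                          field_seed = 1L) {
  lab <- phantom$labels$data
  voxdim <- phantom$labels$voxdim
  shp <- dim(lab)
  nvox <- prod(shp)
  ids <- c(seq_len(nrow(phantom$truth)), phantom$shell_id)
  B <- matrix(0, nvox, length(ids))
  for (j in seq_along(ids)) B[, j] <- as.numeric(lab == ids[j])
  if (heterogeneity > 0) {
    set.seed(field_seed)
    fld <- gaussian_smooth(array(stats::rnorm(nvox), shp), 8, voxdim)
    sh <- which(B[, length(ids)] > 0)
    f <- fld[sh]
    f <- 1 + heterogeneity * (f - mean(f)) / stats::sd(f)
    f <- pmax(f, 0.1)
    B[sh, length(ids)] <- f / mean(f)
  }
  if (psf_fwhm > 0) {
    for (j in seq_along(ids))
      B[, j] <- as.numeric(gaussian_smooth(array(B[, j], shp), psf_fwhm,
                                           voxdim))
  }
  B
}

#' @rdname phantom_basis
#' @param schedule a [frame_schedule].
#' @param truth truth table (default the phantom's).
#' @param ref_amp,shell_amp subject-level amplitude multipliers.
#' @export
phantom_tacs <- function(phantom, schedule = mk6240_frame_schedule(),
                         truth = phantom$truth, ref_amp = 1,
                         shell_amp = 1) {
  ref <- reference_tac_model(schedule, k1_ref = 0.36 * ref_amp)
  tacs <- vector("list", nrow(truth) + 1L)
  names(tacs) <- c(truth$region, "extracerebral")
  for (i in seq_len(nrow(truth))) {
    tacs[[i]] <- if (truth$region[i] == "cergm") ref else
      srtm_forward(ref, srtm_params(truth$R1[i], truth$k2[i], truth$BP[i]),
                   truth$region[i])
  }
  tacs[["extracerebral"]] <- shell_tac_model(schedule, ref,
                                             suvr_level = 1.38 * shell_amp)
  tacs
}

#' Simulate a dynamic PET volume from a phantom
#'
#' Paints per-region TACs (reference kinetic for the cerebellar blob, SRTM
#' forward curves for every other brain region, the saturating shell curve
#' for the extracerebral shell) into the label volume, applies an optional
#' Gaussian PSF per frame (the source of partial-volume effects), and adds
#' zero-mean Gaussian voxel noise with per-frame SD proportional to
#' `value / sqrt(duration)` scaled so that a 300-s frame has CV `noise_cv`.
#' The shell carries a seeded smooth spatial heterogeneity field
#' (mean 1 across the shell).
#'
#' @param phantom a `pet_phantom`.
#' @param schedule a [frame_schedule]. Default the 37-frame two-segment
#'   schedule.
#' @param psf_fwhm PSF FWHM in mm (0 disables blurring). Default 5.
#' @param noise_cv acquisition noise CV at 300-s frames (0 disables noise).
#' @param seed integer seed.
#' @param truth truth table to use (default the phantom's; pass a
#'   [subject_truth()] table for subject-level variation).
#' @param ref_amp multiplier on the reference input amplitude.
#' @param shell_amp multiplier on the shell amplitude.
#' @param region_scale optional named multipliers applied to regional TACs
#'   (session jitter); names are region names, missing names default to 1.
#' @param heterogeneity relative amplitude of the shell spatial field.
#'   Default 0.3.
#' @param field_seed seed for the shell heterogeneity field; defaults to
#'   `seed`. A test-retest pair passes one common value so the field is
#'   part of the subject's anatomy, not of the session noise.
#' @param basis optional precomputed spatial basis from
#'   [phantom_basis()]; a test-retest pair shares one basis across its two
#'   sessions (identical anatomy and PSF).
#' @param base_tacs optional precomputed unscaled regional TACs (list as
#'   returned in attribute `tacs`); session jitter is applied on top.
#' @return 4D array (x, y, z, frame) with attributes `tacs` (list of
#'   painted ground-truth [tac]s, after scaling) and `schedule`.
#' @export
simulate_dynamic <- function(phantom, schedule = mk6240_frame_schedule(),
                             psf_fwhm = 5, noise_cv = 0.03, seed = 1L,
                             truth = phantom$truth, ref_amp = 1,
                             shell_amp = 1, region_scale = NULL,
                             heterogeneity = 0.3, field_seed = seed,
                             basis = NULL, base_tacs = NULL) {
  stopifnot(inherits(phantom, "pet_phantom"))
  shp <- dim(phantom$labels$data)
  tacs <- if (is.null(base_tacs))
    phantom_tacs(phantom, schedule, truth, ref_amp, shell_amp)
  else base_tacs
  if (!is.null(region_scale)) {
    for (nm in names(region_scale)) {
      if (!nm %in% names(tacs)) next
      tacs[[nm]]$values <- tacs[[nm]]$values * region_scale[[nm]]
    }
  }
  B <- if (is.null(basis))
    phantom_basis(phantom, psf_fwhm, heterogeneity, field_seed)
  else basis
  Tm <- do.call(rbind, lapply(tacs, function(tc) tc$values))
  img <- B %*% Tm
  if (noise_cv > 0) {
    set.seed(seed)
    sd_f <- noise_cv * sqrt(300 / (schedule$durations * 60))
    noise <- matrix(stats::rnorm(length(img)), nrow(img))
    img <- img + noise * abs(img) * rep(sd_f, each = nrow(img))
  }
  out <- array(img, c(shp, length(schedule$starts)))
  attr(out, "tacs") <- tacs
  attr(out, "schedule") <- schedule
  out
}

#' Simulate a test-retest scan pair
#'
#' Both sessions share one ground truth and one label volume (identical
#' regions are applied to test and retest). Each session independently
#' receives a global scale jitter and per-region multiplicative jitter at
#' its class CV (see [retest_perturbation()]), plus independent acquisition
#' noise. With all CVs and noise at zero the sessions are identical and
#' every test-retest difference is exactly zero.
#'
#' @param phantom a `pet_phantom`.
#' @param perturbation a [retest_perturbation].
#' @param seed integer seed (drives jitters and both sessions' noise).
#' @param schedule a [frame_schedule].
#' @param psf_fwhm PSF FWHM in mm.
#' @param subject optional [subject_truth()] result; default draws none
#'   (cohort-mean truth).
#' @param heterogeneity shell spatial-field amplitude (0 disables; the
#'   field is shared by both sessions).
#' @param subject_id,group metadata for the returned [scan_meta] pair.
#' @return A list: `test`, `retest` (4D arrays), `meta_test`, `meta_retest`,
#'   `truth`, `phantom`.
#' @export
make_trt_pair <- function(phantom, perturbation = retest_perturbation(),
                          seed = 1L, schedule = mk6240_frame_schedule(),
                          psf_fwhm = 5, subject = NULL,
                          heterogeneity = 0.3, subject_id = "s1",
                          group = phantom$profile) {
  stopifnot(inherits(perturbation, "retest_perturbation"))
  truth <- if (is.null(subject)) phantom$truth else subject$truth
  ref_amp <- if (is.null(subject)) 1 else subject$ref_amp
  shell_amp <- if (is.null(subject)) 1 else subject$shell_amp
  set.seed(seed)
  session_scale <- function() {
    cls_cv <- c(reference = perturbation$reference_cv,
                target = perturbation$target_cv,
                other = perturbation$target_cv)
    g <- if (perturbation$scale_cv > 0)
      stats::rnorm(1, 1, perturbation$scale_cv) else 1
    j <- vapply(seq_len(nrow(truth)), function(i) {
      cv <- cls_cv[[truth$role[i]]]
      if (cv > 0) stats::rnorm(1, 1, cv) else 1
    }, numeric(1))
    sj <- if (perturbation$shell_cv > 0)
      stats::rnorm(1, 1, perturbation$shell_cv) else 1
    stats::setNames(c(g * j, g * sj), c(truth$region, "extracerebral"))
  }
  sc_test <- session_scale()
  sc_retest <- session_scale()
  seeds <- sample.int(2^30, 2)
  basis <- phantom_basis(phantom, psf_fwhm, heterogeneity,
                         field_seed = seed)
  base_tacs <- phantom_tacs(phantom, schedule, truth, ref_amp, shell_amp)
  test <- simulate_dynamic(phantom, schedule, psf_fwhm,
                           perturbation$noise_cv, seeds[1], truth,
                           ref_amp, shell_amp, sc_test, field_seed = seed,
                           basis = basis, base_tacs = base_tacs)
  retest <- simulate_dynamic(phantom, schedule, psf_fwhm,
                             perturbation$noise_cv, seeds[2], truth,
                             ref_amp, shell_amp, sc_retest,
                             field_seed = seed, basis = basis,
                             base_tacs = base_tacs)
  list(test = test, retest = retest,
       meta_test = scan_meta(185, 74, subject_id, "test", group),
       meta_retest = scan_meta(185, 74, subject_id, "retest", group),
       truth = truth, phantom = phantom)
}
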