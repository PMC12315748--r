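#' Pipeline configuration
#'
#' Config for the end-to-end synthetic test-retest experiment: simulate a
#' cohort of paired scans, optionally apply partial-volume correction,
#' sample regions, compute outcome measures and summarize their
#' test-retest reliability. Identical config + seed reproduces the
#' tables byte-identically.
#'
#' @param profile cohort profile (`"oCN"`, `"yCN"`, `"AD"`).
#' @param n_subjects number of test-retest subjects. Default 7.
#' @param seed master seed (all randomness derives from it).
#' @param reference reference region name for ratio outcomes. Default
#'   `"cergm"`.
#' @param window SUV window in minutes. Default `c(90, 110)`.
#' @param t_star,k2_prime MRTM2 settings. Defaults 30 min and 0.04 /min.
#' @param pvc logical: also compute outcomes on PVC data.
#' @param pvc_cfg a [pvc_config].
#' @param psf_fwhm simulated scanner PSF FWHM in mm. Default 5.
#' @param perturbation a [retest_perturbation].
#' @param outcomes subset of `c("SUV", "SUVR", "DVR", "R1")`.
#' @param heterogeneity shell spatial-field amplitude passed to
#'   [make_trt_pair()]. Default 0.3; 0 disables the field.
#' @param between named list of between-subject CVs passed to
#'   [subject_truth()] (`r1_cv`, `dvr_cv`, `ref_amp_cv`, `shell_amp_cv`);
#'   empty list uses that function's defaults, zeros give an identical
#'   cohort.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = "oCN", n_subjects = 7, seed = 1L,
                            reference = "cergm", window = c(90, 110),
                            t_star = 30, k2_prime = 0.04,
                            pvc = FALSE, pvc_cfg = pvc_config(),
                            psf_fwhm = 5,
                            perturbation = retest_perturbation(),
                            outcomes = c("SUV", "SUVR", "DVR", "R1"),
                            heterogeneity = 0.3, between = list(),
                            out_dir = NULL) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (!(window[1] < window[2])) stop("invalid SUV window")
  structure(list(profile = profile, n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), reference = reference,
                 window = as.numeric(window), t_star = t_star,
                 k2_prime = k2_prime, pvc = pvc, pvc_cfg = pvc_cfg,
                 psf_fwhm = psf_fwhm, perturbation = perturbation,
                 outcomes = outcomes, heterogeneity = heterogeneity,
                 between = between, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Accepts a flat mapping of [pipeline_config()] arguments; nested
#' `perturbation` and `pvc_cfg` mappings are converted to their
#' constructors. Unknown keys are an error (typo protection).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(cfg$perturbation))
    cfg$perturbation <- do.call(retest_perturbation, cfg$perturbation)
  if (!is.null(cfg$pvc_cfg))
    cfg$pvc_cfg <- do.call(pvc_config, cfg$pvc_cfg)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, cfg)
}

#' Standard region specifications for a phantom
#'
#' All named phantom regions plus the morphological variants used as
#' candidate reference regions: cerebellar grey with a 3 mm erosion of the
#' outer mask voxels and white matter with a 4 mm erosion, and the
#' meta-temporal composite.
#'
#' @param phantom a `pet_phantom`.
#' @return Named list of [region_spec] objects.
#' @export
phantom_region_specs <- function(phantom) {
  dict <- phantom$labels$labels
  specs <- lapply(seq_len(nrow(dict)), function(i)
    region_spec(dict$name[i], dict$id[i], role = dict$role[i]))
  names(specs) <- dict$name
  specs$cergm_3mm <- region_spec("cergm_3mm", specs$cergm$ids,
                                 op = "erode", distance = 3,
                                 role = "reference")
  specs$wm_4mm <- region_spec("wm_4mm", specs$wm$ids, op = "erode",
                              distance = 4, role = "reference")
  mt <- composite_region(phantom$labels, meta_temporal_constituents(),
                         name = "meta_temporal")
  specs$meta_temporal <- mt
  specs
}

# simulate the cohort and sample every scan into regional TACs.
# Returns list(records, specs, schedule, phantom); records have one entry
# per subject x session x pvc-status with the sampled TACs and metadata.
.cohort_scan_data <- function(cfg) {
  phantom <- make_phantom(cfg$profile)
  specs <- phantom_region_specs(phantom)
  masks <- resolve_region_masks(phantom$labels, specs)
  schedule <- mk6240_frame_schedule()
  set.seed(cfg$seed)
  subj_seeds <- sample.int(2^30, cfg$n_subjects)
  pair_seeds <- sample.int(2^30, cfg$n_subjects)
  records <- list()
  for (i in seq_len(cfg$n_subjects)) {
    subj <- do.call(subject_truth,
                    c(list(phantom, subj_seeds[i]), cfg$between))
    pair <- make_trt_pair(phantom, cfg$perturbation, pair_seeds[i],
                          schedule, cfg$psf_fwhm, subj,
                          heterogeneity = cfg$heterogeneity,
                          subject_id = sprintf("sub%02d", i))
    for (ses in c("test", "retest")) {
      img <- pair[[ses]]
      meta <- pair[[paste0("meta_", ses)]]
      tacs <- sample_regions(img, phantom$labels, specs, schedule, masks)
      records[[length(records) + 1L]] <-
        list(subject = meta$subject_id, session = ses, pvc = FALSE,
             meta = meta, tacs = tacs)
      if (cfg$pvc) {
        imgc <- iterative_yang(img, phantom$labels, cfg$pvc_cfg)
        tacsc <- sample_regions(imgc, phantom$labels, specs, schedule,
                                masks)
        records[[length(records) + 1L]] <-
          list(subject = meta$subject_id, session = ses, pvc = TRUE,
               meta = meta, tacs = tacsc)
      }
      rm(img)
    }
    rm(pair); gc(FALSE)
  }
  list(records = records, specs = specs, schedule = schedule,
       phantom = phantom)
}

# outcome long table from sampled scan records
.compute_outcomes <- function(records, specs, cfg) {
  roles <- vapply(specs, function(s) s$role, character(1))
  errors <- list()
  rows <- list()
  for (rec in records) {
    ref_tac <- rec$tacs[[cfg$reference]]
    suvs <- lapply(rec$tacs, suv_window, meta = rec$meta,
                   t0 = cfg$window[1], t1 = cfg$window[2],
                   pvc_applied = rec$pvc)
    ref_suv <- suvs[[cfg$reference]]
    for (nm in names(rec$tacs)) {
      add <- function(outcome, value) {
        rows[[length(rows) + 1L]] <<- data.frame(
          subject = rec$subject, session = rec$session,
          group = rec$meta$group, region = nm, outcome = outcome,
          pvc = rec$pvc, value = value)
      }
      if ("SUV" %in% cfg$outcomes) add("SUV", suvs[[nm]]$value)
      if ("SUVR" %in% cfg$outcomes && nm != cfg$reference)
        add("SUVR", suvr(suvs[[nm]], ref_suv))
      if (roles[[nm]] == "target") {
        if ("DVR" %in% cfg$outcomes) {
          v <- tryCatch(
            mrtm2_fit(rec$tacs[[nm]], ref_tac, cfg$t_star,
                      cfg$k2_prime)$dvr,
            error = function(e) {
              errors[[length(errors) + 1L]] <<- list(
                subject = rec$subject, session = rec$session, region = nm,
                outcome = "DVR", message = conditionMessage(e))
              NA_real_
            })
          add("DVR", v)
        }
        if ("R1" %in% cfg$outcomes) {
          v <- tryCatch(srtm_fit(rec$tacs[[nm]], ref_tac)$R1,
            error = function(e) {
              errors[[length(errors) + 1L]] <<- list(
                subject = rec$subject, session = rec$session, region = nm,
                outcome = "R1", message = conditionMessage(e))
              NA_real_
            })
          add("R1", v)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fit_errors") <- errors
  out
}

#' Test-retest report from a long outcome table
#'
#' For every region x outcome x PVC status: group mean and SD of the test
#' values, mean and SD of the absolute percentage test-retest difference,
#' two-way ICC (with 95% CI and reliability band), Bland-Altman bias and
#' limits of agreement, and the exact Wilcoxon signed-rank p-value. No
#' multiple-comparison adjustment is applied. Subjects in `icc_exclude`
#' groups (default the AD group, whose disease-driven spread would inflate
#' the between-subject variance) are omitted from the ICC only.
#'
#' @param outcomes data.frame with columns `subject`, `session`, `group`,
#'   `region`, `outcome`, `pvc`, `value`.
#' @param icc_type ICC form, `"agreement"` (default) or `"consistency"`.
#' @param icc_exclude groups excluded from the ICC. Default `"AD"`.
#' @return data.frame, one row per region x outcome x PVC status.
#' @export
trt_report <- function(outcomes, icc_type = "agreement",
                       icc_exclude = "AD") {
  keys <- unique(outcomes[, c("region", "outcome", "pvc")])
  keys <- keys[order(keys$outcome, keys$region, keys$pvc), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- outcomes[outcomes$region == keys$region[i] &
                  outcomes$outcome == keys$outcome[i] &
                  outcomes$pvc == keys$pvc[i], ]
    wide <- merge(d[d$session == "test", c("subject", "group", "value")],
                  d[d$session == "retest", c("subject", "value")],
                  by = "subject", suffixes = c("_test", "_retest"))
    wide <- wide[order(wide$subject), ]
    wide <- wide[is.finite(wide$value_test) & is.finite(wide$value_retest), ]
    n <- nrow(wide)
    base <- data.frame(region = keys$region[i], outcome = keys$outcome[i],
                       pvc = keys$pvc[i], n_pairs = n)
    if (n < 2L)
      return(cbind(base, mean_test = NA, sd_test = NA, trt_mean = NA,
                   trt_sd = NA, icc = NA, icc_lo = NA, icc_hi = NA,
                   icc_band = NA, ba_bias = NA, ba_loa_lo = NA,
                   ba_loa_hi = NA, wilcoxon_p = NA))
    trt <- trt_percent(wide$value_test, wide$value_retest)
    iw <- wide[!(wide$group %in% icc_exclude), ]
    icc <- if (nrow(iw) >= 3L)
      icc_two_way(iw$value_test, iw$value_retest, type = icc_type)
    else list(icc = NA_real_, ci = c(NA_real_, NA_real_),
              band = NA_character_)
    ba <- bland_altman(wide$value_test, wide$value_retest)
    wp <- paired_wilcoxon(wide$value_test, wide$value_retest)
    cbind(base,
          mean_test = mean(wide$value_test),
          sd_test = stats::sd(wide$value_test),
          trt_mean = mean(trt), trt_sd = stats::sd(trt),
          icc = icc$icc, icc_lo = icc$ci[1], icc_hi = icc$ci[2],
          icc_band = icc$band, ba_bias = ba$bias,
          ba_loa_lo = ba$loa[1], ba_loa_hi = ba$loa[2],
          wilcoxon_p = wp$p_value)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end synthetic test-retest pipeline
#'
#' Simulates (or, with PVC enabled, also corrects) a seeded cohort of
#' paired dynamic scans, samples all phantom regions, computes the
#' configured outcome measures (late-window SUV, SUVR against the
#' configured reference, MRTM2 DVR and SRTM R1 for target regions) and
#' summarizes test-retest reliability per region. Failed kinetic fits
#' yield NA-valued rows and are collected in `fit_errors` rather than
#' aborting the cohort. PVC and non-PVC outcomes are kept separate
#' throughout and never mixed inside a ratio.
#'
#' @param cfg a [pipeline_config].
#' @return An object of class `pipeline_result`: `outcomes` (long table),
#'   `report` (the [trt_report()] table), `truth` (phantom truth),
#'   `fit_errors`, `config`. When `cfg$out_dir` is set, writes
#'   `outcomes.tsv`, `trt_report.tsv` and `config.json` there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dat <- .cohort_scan_data(cfg)
  outcomes <- .compute_outcomes(dat$records, dat$specs, cfg)
  report <- trt_report(outcomes)
  res <- structure(list(outcomes = outcomes, report = report,
                        truth = dat$phantom$truth,
                        fit_errors = attr(outcomes, "fit_errors"),
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(outcomes, file.path(cfg$out_dir, "outcomes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(report, file.path(cfg$out_dir, "trt_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    cfg_log <- cfg
    cfg_log$perturbation <- unclass(cfg$perturbation)
    cfg_log$pvc_cfg <- unclass(cfg$pvc_cfg)
    cfg_log <- c(unclass(cfg_log),
                 list(package_version =
                        as.character(utils::packageVersion("dynpet"))))
    jsonlite::write_json(cfg_log, file.path(cfg$out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Test-retest pipeline result: %d subjects (%s), outcomes %s%s\n",
              x$config$n_subjects, x$config$profile,
              paste(x$config$outcomes, collapse = "/"),
              if (x$config$pvc) " (with and without PVC)" else ""))
  cat(sprintf("  %d outcome rows, %d regions; %d failed fits\n",
              nrow(x$outcomes), length(unique(x$outcomes$region)),
              length(x$fit_errors)))
  show <- x$report[x$report$outcome %in% c("SUVR", "SUV") & !x$report$pvc,
                   c("region", "outcome", "mean_test", "trt_mean", "icc",
                     "icc_band")]
  print(utils::head(show, 12), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare reference-region choices
#'
#' One cohort pass computing the late-window SUVR of every region under
#' each candidate reference region, with the corresponding mean absolute
#' test-retest percentage difference, plus the rank order of the target
#' regions' mean SUVR under each reference (ratios by a positive reference
#' preserve target rank order, so the orders should agree across
#' references).
#'
#' @param cfg a [pipeline_config].
#' @param references character vector of reference region names; default
#'   the phantom's reference-role regions plus their eroded variants.
#' @return A list: `suvr` (long table: reference, region, mean SUVR, T-RT%),
#'   `rank_order` (named list: target regions in decreasing mean-SUVR order
#'   per reference).
#' @export
compare_reference_regions <- function(cfg,
                                      references = c("cergm", "cergm_3mm",
                                                     "pons", "wm",
                                                     "wm_4mm")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  cfg$outcomes <- "SUV"
  dat <- .cohort_scan_data(cfg)
  suv_tab <- .compute_outcomes(dat$records, dat$specs, cfg)
  missing <- setdiff(references, unique(suv_tab$region))
  if (length(missing))
    stop(sprintf("reference region(s) not present: %s",
                 paste(missing, collapse = ", ")))
  roles <- vapply(dat$specs, function(s) s$role, character(1))
  targets <- names(roles)[roles == "target"]
  rows <- list(); rank_order <- list()
  for (ref in references) {
    refv <- suv_tab[suv_tab$region == ref, ]
    names(refv)[names(refv) == "value"] <- "ref_value"
    m <- merge(suv_tab, refv[, c("subject", "session", "pvc", "ref_value")],
               by = c("subject", "session", "pvc"))
    m$suvr <- m$value / m$ref_value
    for (reg in setdiff(unique(m$region), ref)) {
      d <- m[m$region == reg, ]
      wide <- merge(d[d$session == "test", c("subject", "suvr")],
                    d[d$session == "retest", c("subject", "suvr")],
                    by = "subject", suffixes = c("_t", "_r"))
      rows[[length(rows) + 1L]] <- data.frame(
        reference = ref, region = reg,
        mean_suvr = mean(d$suvr[d$session == "test"]),
        trt_mean = mean(trt_percent(wide$suvr_t, wide$suvr_r)))
    }
    tab <- do.call(rbind, rows)
    mt <- tab[tab$reference == ref & tab$region %in% targets, ]
    rank_order[[ref]] <- mt$region[order(-mt$mean_suvr)]
  }
  list(suvr = do.call(rbind, rows), rank_order = rank_order)
}
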