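#' Standardized uptake value
#'
#' Converts an activity concentration to a standardized uptake value by
#' normalizing to injected dose per unit body weight:
#' `SUV = C / (dose / weight)` with the dose in kBq and the weight in grams,
#' so a concentration in kBq/mL yields g/mL.
#'
#' @param concentration activity concentration in kBq/mL.
#' @param meta a [scan_meta] (dose in MBq, weight in kg).
#' @param window optional `[t0, t1]` window (minutes) the concentration was
#'   averaged over; recorded on the result.
#' @param pvc_applied logical flag recorded on the result; ratios refuse to
#'   mix corrected and uncorrected values.
#' @return An object of class `suv_value` with fields `value` (g/mL),
#'   `window` and `pvc_applied`.
#' @export
suv <- function(concentration, meta, window = c(NA_real_, NA_real_),
                pvc_applied = FALSE) {
  stopifnot(inherits(meta, "scan_meta"))
  dose_per_g <- (meta$injected_dose * 1e3) / (meta$body_weight * 1e3) # kBq/g
  structure(list(value = concentration / dose_per_g,
                 window = as.numeric(window),
                 pvc_applied = isTRUE(pvc_applied)),
            class = "suv_value")
}

#' @export
print.suv_value <- function(x, ...) {
  cat(sprintf("<suv: %.4g g/mL, window [%g, %g] min%s>\n", x$value,
              x$window[1], x$window[2], if (x$pvc_applied) ", PVC" else ""))
  invisible(x)
}

#' Late-window SUV from a time-activity curve
#'
#' Averages the frames fully contained in `[t0, t1]` (unweighted, matching
#' the convention of averaging equal-duration late reconstructed frames) and
#' converts to SUV. The default 90-110 min window selects four 5-min frames
#' of the two-segment schedule.
#'
#' @inheritParams suv
#' @param tc a [tac].
#' @param t0,t1 window bounds in minutes.
#' @return A `suv_value`.
#' @export
suv_window <- function(tc, meta, t0 = 90, t1 = 110, pvc_applied = FALSE) {
  stopifnot(inherits(tc, "tac"))
  idx <- frames_in_window(tc$schedule, t0, t1)
  suv(mean(tc$values[idx]), meta, window = c(t0, t1),
      pvc_applied = pvc_applied)
}

#' SUV ratio
#'
#' Ratio of a target-region SUV to a reference-region SUV. Both values must
#' have been computed on the same time window and with the same
#' partial-volume-correction status.
#'
#' @param target,reference `suv_value` objects.
#' @return Unitless ratio (plain numeric).
#' @export
suvr <- function(target, reference) {
  stopifnot(inherits(target, "suv_value"), inherits(reference, "suv_value"))
  if (!isTRUE(all.equal(target$window, reference$window)) &&
      !(all(is.na(target$window)) && all(is.na(reference$window))))
    stop("SUVR requires target and reference SUV on identical windows")
  if (target$pvc_applied != reference$pvc_applied)
    stop("SUVR must not mix PVC and non-PVC SUV values")
  if (!is.finite(reference$value) || reference$value <= 0)
    stop("reference SUV must be positive")
  target$value / reference$value
}

#' SRTM parameter set
#'
#' Parameters of the simplified reference tissue model: relative delivery
#' `R1 = K1_target / K1_reference`, target efflux `k2` (1/min), binding
#' potential `BP`, and the derived apparent efflux `k2a = k2 / (1 + BP)`.
#'
#' @param R1 relative delivery (unitless, > 0).
#' @param k2 target efflux rate (1/min, > 0).
#' @param BP binding potential (> -1).
#' @return An object of class `srtm_params`.
#' @export
srtm_params <- function(R1, k2, BP) {
  if (!is.numeric(k2) || k2 <= 0) stop("k2 must be > 0 (1/min)")
  if (!is.numeric(BP) || BP <= -1) stop("BP must exceed -1")
  if (!is.numeric(R1) || R1 <= 0) stop("R1 must be > 0")
  structure(list(R1 = R1, k2 = k2, BP = BP, k2a = k2 / (1 + BP)),
            class = "srtm_params")
}

# Dense time grid for convolution: uniform spacing unioned with all frame
# boundaries so each grid segment lies wholly inside one frame or one gap.
.dense_grid <- function(schedule, dt = 0.05) {
  tmax <- schedule$ends[length(schedule$ends)]
  g <- sort(unique(c(seq(0, tmax, by = dt), tmax,
                     schedule$starts, schedule$ends)))
  g[g >= 0 & g <= tmax + 1e-12]
}

# Continuous reference concentration sampled on the dense grid. TACs built
# by the synthetic generator carry their continuous model as attribute
# "cont_fun"; measured TACs are linearly interpolated through frame
# midpoints with zero concentration at the first frame start.
.dense_ref <- function(ref, grid) {
  f <- attr(ref, "cont_fun")
  if (is.function(f)) return(f(grid))
  sch <- ref$schedule
  stats::approx(x = c(sch$starts[1], sch$mids), y = c(0, ref$values),
                xout = grid, rule = 2)$y
}

# Trapezoid frame-average operator: sparse-in-spirit weight matrix A
# (n_frames x n_grid) with A %*% y(grid) = per-frame time-averages.
.frame_avg_matrix <- function(schedule, grid) {
  nf <- length(schedule$starts)
  A <- matrix(0, nf, length(grid))
  for (f in seq_len(nf)) {
    inside <- which(grid >= schedule$starts[f] - 1e-12 &
                    grid <= schedule$ends[f] + 1e-12)
    h <- diff(grid[inside])
    w <- c(h / 2, 0) + c(0, h / 2)
    A[f, inside] <- w / schedule$durations[f]
  }
  A
}

# Exponential convolution y(t) = int_0^t C(u) exp(-k (t - u)) du for C
# piecewise linear on 'grid', evaluated at every grid point, exactly per
# segment. Vectorized over a vector of rate constants k: returns an
# n_grid x length(k) matrix.
.exp_conv <- function(cr, grid, k) {
  n <- length(grid); K <- length(k)
  Y <- matrix(0, n, K)
  y <- numeric(K)
  for (i in seq_len(n - 1L)) {
    d <- grid[i + 1L] - grid[i]
    E <- exp(-k * d)
    s <- (cr[i + 1L] - cr[i]) / d
    q <- (1 - E) / k
    y <- y * E + cr[i] * q + s * (d - q) / k
    Y[i + 1L, ] <- y
  }
  Y
}

#' Forward-simulate a target TAC under the simplified reference tissue model
#'
#' Computes `C_T(t) = R1 C_R(t) + (k2 - R1 k2a) [C_R (x) exp(-k2a t)](t)` on
#' a dense uniform grid (0.05 min, unioned with frame boundaries) and
#' returns per-frame time-averages on the reference schedule, matching
#' reconstructed-frame semantics. The delivery term `R1 C_R` uses the
#' reference frame values directly, so `R1 = 1, BP = 0` reproduces the
#' reference TAC exactly.
#'
#' @param ref reference-region [tac]; if it carries a continuous model in
#'   attribute `cont_fun` that model is used on the dense grid, otherwise
#'   the frame values are interpolated.
#' @param params an [srtm_params].
#' @param region_id label for the simulated TAC.
#' @return A [tac] on the same schedule.
#' @export
srtm_forward <- function(ref, params, region_id = NA_character_) {
  stopifnot(inherits(ref, "tac"), inherits(params, "srtm_params"))
  sch <- ref$schedule
  coef <- params$k2 - params$R1 * params$k2a
  vals <- params$R1 * ref$values
  if (abs(coef) > 0) {
    grid <- .dense_grid(sch)
    cr <- .dense_ref(ref, grid)
    conv <- .exp_conv(cr, grid, params$k2a)[, 1]
    A <- .frame_avg_matrix(sch, grid)
    vals <- vals + coef * as.numeric(A %*% conv)
  }
  out <- tac(sch, vals, region_id)
  f <- attr(ref, "cont_fun")
  if (is.function(f) && abs(coef) > 0) {
    # carry a continuous model for the target too (used by quadrature
    # oracles); closure over the dense convolution via interpolation
    cfun <- stats::approxfun(grid, params$R1 * cr + coef * conv, rule = 2)
    attr(out, "cont_fun") <- cfun
  }
  out
}

#' Fit the simplified reference tissue model by basis functions
#'
#' For each apparent efflux `k2a` on a fixed logarithmic grid, the model is
#' linear in `(R1, k2)`; the weighted linear subproblem is solved in closed
#' form and the grid point minimizing the weighted residual sum of squares
#' is refined by golden-section search. Weights default to frame durations
#' (longer frames carry more counts).
#'
#' @param target,ref [tac] objects on one shared schedule.
#' @param k2a_grid basis grid of apparent efflux values (1/min); default 256
#'   log-spaced points on `[0.001, 1]`.
#' @param weights per-frame fit weights; default frame durations.
#' @return An object of class `srtm_fit`: estimates `R1`, `k2`, `BP`,
#'   `k2a`, plus `wrss`, fitted values, and a `diagnostics` list with
#'   `boundary` (best grid point at the edge of the basis grid) and
#'   `k2_unidentifiable` (washout term indistinguishable from zero, as when
#'   target equals reference).
#' @export
srtm_fit <- function(target, ref,
                     k2a_grid = exp(seq(log(0.001), log(1), length.out = 256)),
                     weights = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  sch <- target$schedule
  if (!isTRUE(all.equal(sch$starts, ref$schedule$starts)) ||
      !isTRUE(all.equal(sch$ends, ref$schedule$ends)))
    stop("target and reference TACs must share one schedule")
  if (all(ref$values == 0)) stop("reference TAC is identically zero")
  if (all(target$values == 0)) stop("degenerate fit: target TAC is all zero")
  w <- if (is.null(weights)) sch$durations else as.numeric(weights)
  y <- target$values
  x1 <- ref$values

  grid <- .dense_grid(sch)
  cr <- .dense_ref(ref, grid)
  A <- .frame_avg_matrix(sch, grid)
  B <- A %*% .exp_conv(cr, grid, k2a_grid)   # n_frames x K basis matrix

  a11 <- sum(w * x1 * x1)
  b1 <- sum(w * x1 * y)
  syy <- sum(w * y * y)
  a12 <- as.numeric(crossprod(B, w * x1))
  a22 <- as.numeric(crossprod(B^2, w))
  b2 <- as.numeric(crossprod(B, w * y))
  det <- a11 * a22 - a12^2
  det[det <= 0] <- NA_real_
  th1 <- (a22 * b1 - a12 * b2) / det
  th2 <- (a11 * b2 - a12 * b1) / det
  wrss <- syy - th1 * b1 - th2 * b2
  j <- which.min(wrss)

  obj <- function(k2a) {
    bb <- as.numeric(A %*% .exp_conv(cr, grid, k2a))
    m12 <- sum(w * bb * x1); m22 <- sum(w * bb * bb)
    v2 <- sum(w * bb * y)
    dd <- a11 * m22 - m12^2
    if (dd <= 0) return(list(wrss = Inf, th = c(NA, NA)))
    t1 <- (m22 * b1 - m12 * v2) / dd
    t2 <- (a11 * v2 - m12 * b1) / dd
    list(wrss = syy - t1 * b1 - t2 * v2, th = c(t1, t2))
  }

  boundary <- j == 1L || j == length(k2a_grid)
  lo <- k2a_grid[max(j - 1L, 1L)]
  hi <- k2a_grid[min(j + 1L, length(k2a_grid))]
  # golden-section refinement on log(k2a)
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- obj(exp(c1))$wrss; f2 <- obj(exp(c2))$wrss
  for (it in seq_len(40)) {
    if (f1 < f2) { b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- obj(exp(c1))$wrss
    } else { a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- obj(exp(c2))$wrss }
    if (b - a < 1e-6) break
  }
  k2a_hat <- exp((a + b) / 2)
  sol <- obj(k2a_hat)
  if (!is.finite(sol$wrss) || sol$wrss > wrss[j]) { # fall back to grid point
    k2a_hat <- k2a_grid[j]
    sol <- list(wrss = wrss[j], th = c(th1[j], th2[j]))
  }
  R1 <- sol$th[1]
  k2 <- sol$th[2] + R1 * k2a_hat
  BP <- k2 / k2a_hat - 1
  scale2 <- sqrt(sum(w * y^2) / sum(w))
  unident <- abs(sol$th[2]) * sqrt(sum(w * (A %*% .exp_conv(cr, grid, k2a_hat))^2) / sum(w)) < 1e-5 * scale2
  fitted <- R1 * x1 + sol$th[2] * as.numeric(A %*% .exp_conv(cr, grid, k2a_hat))
  structure(list(R1 = R1, k2 = k2, BP = BP, k2a = k2a_hat,
                 wrss = sol$wrss, fitted = fitted, weights = w,
                 diagnostics = list(boundary = boundary,
                                    k2_unidentifiable = unident)),
            class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("SRTM basis-function fit\n  R1 = %.4f   k2 = %.4f /min   BP = %.4f   (k2a = %.4f /min)\n",
              x$R1, x$k2, x$BP, x$k2a))
  if (x$diagnostics$k2_unidentifiable)
    cat("  note: washout term ~ 0; k2 and BP unidentifiable\n")
  if (x$diagnostics$boundary)
    cat("  warning: best k2a at basis-grid boundary\n")
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) {
  c(R1 = object$R1, k2 = object$k2, BP = object$BP)
}

#' Fit the multilinear reference tissue model 2 (MRTM2)
#'
#' Regresses the target TAC on the combined reference regressor
#' `int_0^t C_R + C_R(t)/k2'` and the running target integral
#' `int_0^t C_T`, over frames whose midpoints fall at or after `t_star`.
#' The distribution volume ratio is the negative ratio of the two
#' coefficients, `DVR = -gamma1 / gamma2`. Running integrals bridge the
#' acquisition break as described in [cumulative_integral()]; the fit is
#' weighted by frame durations.
#'
#' @param target,ref [tac] objects on one shared schedule.
#' @param t_star start of the linear regime (minutes); frames with midpoint
#'   `>= t_star` enter the regression. Default 30.
#' @param k2_prime fixed reference-region efflux rate (1/min). Default 0.04.
#' @param weights per-frame weights for the included frames; default frame
#'   durations.
#' @return An object of class `mrtm2_fit` with `dvr`, `gamma1`, `gamma2`,
#'   `t_star`, `k2_prime`, `n_frames_used`, `residual_rms`.
#' @export
mrtm2_fit <- function(target, ref, t_star = 30, k2_prime = 0.04,
                      weights = NULL) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  sch <- target$schedule
  if (!isTRUE(all.equal(sch$starts, ref$schedule$starts)) ||
      !isTRUE(all.equal(sch$ends, ref$schedule$ends)))
    stop("target and reference TACs must share one schedule")
  if (k2_prime <= 0) stop("k2_prime must be > 0 (1/min)")
  use <- which(sch$mids >= t_star)
  if (length(use) < 3L)
    stop(sprintf("MRTM2 needs >= 3 frames with midpoint >= t* = %g min", t_star))
  mids <- sch$mids[use]
  x1 <- cumulative_integral(ref, mids) + ref$values[use] / k2_prime
  x2 <- cumulative_integral(target, mids)
  y <- target$values[use]
  w <- if (is.null(weights)) sch$durations[use] else as.numeric(weights)
  X <- cbind(x1, x2)
  XtWX <- crossprod(X, w * X)
  if (!is.finite(rcond <- rcond(XtWX)) || rcond < 1e-14)
    stop("MRTM2 design matrix is singular")
  g <- solve(XtWX, crossprod(X, w * y))
  gamma1 <- g[1]; gamma2 <- g[2]
  if (abs(gamma2) < .Machine$double.eps)
    stop("MRTM2 washout coefficient is zero; DVR undefined")
  res <- y - X %*% g
  structure(list(dvr = -gamma1 / gamma2, gamma1 = gamma1, gamma2 = gamma2,
                 t_star = t_star, k2_prime = k2_prime,
                 n_frames_used = length(use),
                 residual_rms = sqrt(mean(res^2))),
            class = "mrtm2_fit")
}

#' @export
print.mrtm2_fit <- function(x, ...) {
  cat(sprintf("MRTM2 fit (t* = %g min, k2' = %g /min, %d frames)\n  DVR = %.4f   (gamma1 = %.4g, gamma2 = %.4g, residual RMS = %.3g)\n",
              x$t_star, x$k2_prime, x$n_frames_used, x$dvr,
              x$gamma1, x$gamma2, x$residual_rms))
  invisible(x)
}

#' @export
coef.mrtm2_fit <- function(object, ...) {
  c(dvr = object$dvr, gamma1 = object$gamma1, gamma2 = object$gamma2)
}
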