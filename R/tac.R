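#' Time-activity curves
#'
#' A time-activity curve (TAC) stores the regional activity concentration
#' (kBq/mL) for each frame of a [frame_schedule]. Frame values carry
#' reconstructed-frame semantics: each value is the time-average of the
#' underlying continuous concentration over the frame, not an instantaneous
#' sample. Forward simulation in this package honours that convention.
#'
#' @param schedule a [frame_schedule].
#' @param values numeric vector of per-frame activity concentrations
#'   (kBq/mL); must be finite and match the frame count. Negative values are
#'   permitted (noise excursions in measured data).
#' @param region_id optional region label.
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, values, region_id = NA_character_) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != length(schedule$starts))
    stop("'values' length must equal the frame count")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(schedule = schedule, values = values,
                 region_id = as.character(region_id)),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac%s: %d frames, range [%.4g, %.4g] kBq/mL>\n",
              if (is.na(x$region_id)) "" else paste0(" ", x$region_id),
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Per-scan metadata
#'
#' @param injected_dose injected dose in MBq (must be positive).
#' @param body_weight body weight in kg (must be positive).
#' @param subject_id subject identifier.
#' @param session `"test"` or `"retest"`.
#' @param group cohort label: `"yCN"`, `"oCN"` or `"AD"`.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(injected_dose, body_weight, subject_id = NA_character_,
                      session = c("test", "retest"),
                      group = c("oCN", "yCN", "AD")) {
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("injected_dose must be > 0 (MBq)")
  if (!is.numeric(body_weight) || body_weight <= 0)
    stop("body_weight must be > 0 (kg)")
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 subject_id = as.character(subject_id),
                 session = match.arg(session), group = match.arg(group)),
            class = "scan_meta")
}

# Piecewise representation used by cumulative_integral: within frames the
# integrand is the (constant) frame value; across gaps it is the linear
# interpolant between the midpoints of the two adjacent frames, restricted
# to the gap. Returns breakpoints, cumulative integral at breakpoints, and
# per-segment descriptors.
.tac_pieces <- function(tc) {
  sch <- tc$schedule
  v <- tc$values
  n <- length(v)
  # segments: alternating frame / gap
  seg_t0 <- seg_t1 <- seg_a <- seg_b <- numeric(0)
  for (i in seq_len(n)) {
    seg_t0 <- c(seg_t0, sch$starts[i]); seg_t1 <- c(seg_t1, sch$ends[i])
    seg_a <- c(seg_a, v[i]); seg_b <- c(seg_b, 0)  # constant
    if (i < n && sch$starts[i + 1] - sch$ends[i] > 1e-9) {
      # linear bridge: value(t) = a + b * (t - t0)
      slope <- (v[i + 1] - v[i]) / (sch$mids[i + 1] - sch$mids[i])
      a0 <- v[i] + slope * (sch$ends[i] - sch$mids[i])
      seg_t0 <- c(seg_t0, sch$ends[i]); seg_t1 <- c(seg_t1, sch$starts[i + 1])
      seg_a <- c(seg_a, a0); seg_b <- c(seg_b, slope)
    }
  }
  len <- seg_t1 - seg_t0
  seg_int <- seg_a * len + seg_b * len^2 / 2
  list(t0 = seg_t0, t1 = seg_t1, a = seg_a, b = seg_b,
       cum = c(0, cumsum(seg_int)))
}

#' Running integral of a time-activity curve
#'
#' Integrates a TAC from time 0 (activity is taken as zero before the first
#' frame start) up to each requested time. Within a frame the integrand is
#' the stored frame value; across acquisition gaps (e.g. a mid-scan break)
#' the integrand bridges linearly between the midpoints of the two adjacent
#' frames. The result is additive over disjoint intervals and, for
#' nonnegative TACs, nondecreasing in `t`.
#'
#' @param tc a [tac].
#' @param t numeric vector of upper integration limits (minutes); every
#'   element must lie in `[0, last frame end]`.
#' @return Numeric vector of integrals (kBq*min/mL), one per element of `t`.
#' @export
cumulative_integral <- function(tc, t) {
  stopifnot(inherits(tc, "tac"))
  t <- as.numeric(t)
  tmax <- tail_end <- tc$schedule$ends[length(tc$schedule$ends)]
  if (any(t < -1e-9 | t > tmax + 1e-9))
    stop(sprintf("integration limit outside scan span [0, %g] min", tail_end))
  p <- .tac_pieces(tc)
  out <- numeric(length(t))
  for (j in seq_along(t)) {
    tt <- min(max(t[j], 0), tmax)
    if (tt <= p$t0[1]) { out[j] <- 0; next }
    i <- findInterval(tt, p$t0, rightmost.closed = FALSE)
    # findInterval on segment starts; tt may fall in a gap *before* a
    # segment if schedule starts past 0 -- integrand is zero there
    dt <- min(tt, p$t1[i]) - p$t0[i]
    dt <- max(dt, 0)
    out[j] <- p$cum[i] + p$a[i] * dt + p$b[i] * dt^2 / 2
  }
  out
}

#' Write or read TACs as TSV
#'
#' Columns: `frame_start`, `frame_end`, `region`, `value`.
#'
#' @param tacs a list of [tac] objects sharing one schedule.
#' @param path file path.
#' @export
write_tac_tsv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  tab <- do.call(rbind, lapply(tacs, function(tc) {
    data.frame(frame_start = tc$schedule$starts, frame_end = tc$schedule$ends,
               region = tc$region_id, value = tc$values)
  }))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tac_tsv
#' @export
read_tac_tsv <- function(path) {
  tab <- utils::read.delim(path)
  lapply(split(tab, tab$region), function(d) {
    d <- d[order(d$frame_start), ]
    tac(frame_schedule(d$frame_start, d$frame_end), d$value, d$region[1])
  })
}
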