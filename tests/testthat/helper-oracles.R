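# independent oracles and small fixtures built in code

# exhaustive signed-rank two-sided p by enumerating all sign assignments
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  v_all <- vapply(0:(2^n - 1), function(msk)
    sum(r[bitwAnd(bitwShiftL(1L, 0:(n - 1L)), msk) > 0]), numeric(1))
  mean(abs(v_all - center) >= abs(v_obs - center) - 1e-9)
}

# brute-force nearest-neighbour voxel distance (mm) from each 'from' voxel
# to the nearest 'to' voxel, by exhaustive search
brute_min_dist <- function(from_idx, to_idx, shape, voxdim) {
  cf <- sweep(arrayInd(from_idx, shape), 2, voxdim, `*`)
  ct <- sweep(arrayInd(to_idx, shape), 2, voxdim, `*`)
  vapply(seq_len(nrow(cf)), function(i)
    sqrt(min(colSums((t(ct) - cf[i, ])^2))), numeric(1))
}

# digital ball mask helper (voxel centers within radius of the grid center)
ball_phantom <- function(shape = c(24, 24, 24), voxdim = c(2, 2, 2),
                         radius = 10, offset = c(0, 0, 0)) {
  ctr <- shape * voxdim / 2 + offset
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 0.5) * voxdim[a] -
                                   ctr[a])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) <= radius^2
}

# dense Riemann quadrature of the piecewise integrand that defines
# cumulative_integral (frame-constant inside frames, midpoint-linear
# across gaps, zero elsewhere)
quadrature_tac_integral <- function(tc, t, dt = 1e-4) {
  sch <- tc$schedule
  f <- function(tt) {
    v <- numeric(length(tt))
    for (i in seq_along(sch$starts)) {
      inside <- tt >= sch$starts[i] & tt < sch$ends[i]
      v[inside] <- tc$values[i]
      if (i < length(sch$starts) &&
          sch$starts[i + 1] - sch$ends[i] > 1e-9) {
        ing <- tt >= sch$ends[i] & tt < sch$starts[i + 1]
        slope <- (tc$values[i + 1] - tc$values[i]) /
          (sch$mids[i + 1] - sch$mids[i])
        v[ing] <- tc$values[i] + slope * (tt[ing] - sch$mids[i])
      }
    }
    v[tt >= sch$ends[length(sch$ends)]] <- tc$values[length(tc$values)]
    v
  }
  grid <- seq(0, t, by = dt)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  sum(f(mids)) * dt
}

# a small two-region label volume with a hot sphere in background
two_compartment_phantom <- function(shape = c(40, 40, 40),
                                    voxdim = c(2, 2, 2), radius = 14,
                                    hot = 4, cold = 1) {
  sph <- ball_phantom(shape, voxdim, radius)
  lab <- array(0L, shape)
  lab[sph] <- 1L
  truth <- array(cold, shape)
  truth[sph] <- hot
  list(labels = label_volume(lab, voxdim), truth = truth, sphere = sph)
}
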