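# Independent brute-force oracles, deliberately written as plain loops that
# follow the textbook definitions, separate from the package's vectorized
# production code.

# k-sample Anderson-Darling A2akN (midrank/tie-adjusted), literal summation.
ad_oracle <- function(samples) {
  x <- unlist(samples)
  N <- length(x)
  k <- length(samples)
  zstar <- sort(unique(x))
  A2 <- 0
  for (i in seq_len(k)) {
    xi <- samples[[i]]
    ni <- length(xi)
    inner <- 0
    for (j in seq_along(zstar)) {
      lj <- sum(x == zstar[j])
      Bj <- sum(x < zstar[j]) + lj / 2
      fij <- sum(xi == zstar[j])
      Mij <- sum(xi < zstar[j]) + fij / 2
      denom <- Bj * (N - Bj) - N * lj / 4
      if (denom > 0)
        inner <- inner + (lj / N) * (N * Mij - ni * Bj)^2 / denom
    }
    A2 <- A2 + inner / ni
  }
  A2 * (N - 1) / N
}

# GLRLM run counts for one direction by explicitly walking every line.
glrlm_oracle <- function(disc, direction) {
  dm <- dim(disc)
  runs <- list()
  visited <- array(FALSE, dm)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    # start of a line: the previous voxel along -direction is out of range
    prev <- c(x, y, z) - direction
    in_range <- all(prev >= 1) && all(prev <= dm)
    if (in_range) next
    pos <- c(x, y, z)
    cur_lev <- NA
    cur_len <- 0
    while (all(pos >= 1) && all(pos <= dm)) {
      v <- disc[pos[1], pos[2], pos[3]]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lev))
          runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- if (is.na(v)) NA else v
        cur_len <- if (is.na(v)) 0 else 1
      }
      pos <- pos + direction
    }
    if (!is.na(cur_lev)) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (!length(runs)) return(matrix(0, 0, 2))
  do.call(rbind, runs)   # rows: (level, run length)
}

glrlm_features_oracle <- function(disc, n_levels, directions) {
  n_vox <- sum(!is.na(disc))
  max_len <- 0
  mats <- list()
  for (r in seq_len(nrow(directions))) {
    runs <- glrlm_oracle(disc, directions[r, ])
    max_len <- max(max_len, if (nrow(runs)) max(runs[, 2]) else 1)
    mats[[r]] <- runs
  }
  avg <- matrix(0, n_levels, max_len)
  for (runs in mats)
    for (q in seq_len(nrow(runs)))
      avg[runs[q, 1], runs[q, 2]] <- avg[runs[q, 1], runs[q, 2]] + 1
  avg <- avg / length(mats)
  nr <- sum(avg)
  i <- row(avg); j <- col(avg)
  c(sre = sum(avg / j^2) / nr, lre = sum(avg * j^2) / nr,
    gln = sum(rowSums(avg)^2) / nr, rln = sum(colSums(avg)^2) / nr,
    rp = nr / n_vox, lglre = sum(avg / i^2) / nr,
    hglre = sum(avg * i^2) / nr)
}

# NGTDM s_i / p_i by explicit neighborhood loops, then the feature formulas.
ngtdm_oracle <- function(disc, dist_vox, eps = 1e-6) {
  dm <- dim(disc)
  lev_used <- c(); abar_used <- c()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- disc[x, y, z]
    if (is.na(v)) next
    nb <- c()
    for (dx in -dist_vox[1]:dist_vox[1])
      for (dy in -dist_vox[2]:dist_vox[2])
        for (dz in -dist_vox[3]:dist_vox[3]) {
          if (dx == 0 && dy == 0 && dz == 0) next
          p <- c(x + dx, y + dy, z + dz)
          if (any(p < 1) || any(p > dm)) next
          w <- disc[p[1], p[2], p[3]]
          if (!is.na(w)) nb <- c(nb, w)
        }
    if (length(nb) == 0) next
    lev_used <- c(lev_used, v)
    abar_used <- c(abar_used, mean(nb))
  }
  n_eff <- length(lev_used)
  lv <- sort(unique(lev_used))
  s <- sapply(lv, function(l) sum(abs(l - abar_used)[lev_used == l]))
  p <- sapply(lv, function(l) mean(lev_used == l))
  ng <- length(lv)
  coars <- 1 / (sum(p * s) + eps)
  if (ng > 1) {
    con <- 0; ipd <- 0; cmplx <- 0; strn <- 0
    for (a in seq_len(ng)) for (b in seq_len(ng)) {
      con <- con + p[a] * p[b] * (lv[a] - lv[b])^2
      ipd <- ipd + abs(lv[a] * p[a] - lv[b] * p[b])
      cmplx <- cmplx + abs(lv[a] - lv[b]) *
        (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
      strn <- strn + (p[a] + p[b]) * (lv[a] - lv[b])^2
    }
    contrast <- con / (ng * (ng - 1)) * sum(s) / n_eff
    busy <- if (ipd > 0) sum(p * s) / ipd else 0
    cmplx <- cmplx / n_eff
    strn <- if (sum(s) > 0) strn / (eps + sum(s)) else 0
  } else {
    contrast <- 0; busy <- 0; cmplx <- 0; strn <- 0
  }
  c(coarseness = coars, contrast = contrast, busyness = busy,
    complexity = cmplx, strength = strn)
}

# GLSZM zones by breadth-first flood fill over 26-connected equal levels.
glszm_oracle <- function(disc) {
  dm <- dim(disc)
  seen <- array(FALSE, dm)
  zones <- list()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- disc[x, y, z]
    if (is.na(v) || seen[x, y, z]) next
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        p <- cur + c(dx, dy, dz)
        if (any(p < 1) || any(p > dm)) next
        w <- disc[p[1], p[2], p[3]]
        if (!is.na(w) && w == v && !seen[p[1], p[2], p[3]]) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue[[length(queue) + 1]] <- p
        }
      }
    }
    zones[[length(zones) + 1]] <- c(v, size)
  }
  do.call(rbind, zones)   # rows: (level, size)
}

# Harrell's C by exhaustive unordered-pair enumeration.
cstat_oracle <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1) next
      short <- if (event[i] == 1) i else j
      long <- if (event[i] == 1) j else i
    } else {
      short <- if (time[i] < time[j]) i else j
      long <- if (time[i] < time[j]) j else i
      if (event[short] != 1) next
    }
    den <- den + 1
    if (risk[short] > risk[long]) num <- num + 1
    else if (risk[short] == risk[long]) num <- num + 0.5
  }
  num / den
}

# Hand-coded Cox partial log-likelihood (no ties assumed) for grid search.
cox_loglik_oracle <- function(beta, x, time, event) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    at_risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Small test image: textured ellipsoid-ish blob.
make_test_image <- function(shape = c(8, 8, 6), spacing = c(1, 1, 2),
                            seed = 1, roi = "box") {
  set.seed(seed)
  arr <- array(rnorm(prod(shape), mean = 100, sd = 10), shape)
  m <- array(FALSE, shape)
  m[2:(shape[1] - 1), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- TRUE
  voxel_image(arr, spacing, m)
}

random_discretized <- function(shape, n_levels, p_mask = 0.8, seed = 1) {
  set.seed(seed)
  d <- array(sample.int(n_levels, prod(shape), replace = TRUE), shape)
  keep <- array(runif(prod(shape)) < p_mask, shape)
  if (!any(keep)) keep[1] <- TRUE
  d[!keep] <- NA_integer_
  d
}
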