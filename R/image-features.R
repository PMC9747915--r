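# Radiomic feature extraction: resampling to a common grid, physical-unit
# neighborhood offsets, intensity discretization, and seven feature
# families (intensity, histogram, volumetric, morphology, GLRLM, NGTDM,
# GLSZM). Conventions that the literature leaves open are fixed here and
# documented: equal-width min-max discretization (default 32 bins),
# population moments, 13 averaged GLRLM directions, 26-connected GLSZM
# zones, skewness/kurtosis of a constant ROI defined as 0.

#' Extraction parameters
#'
#' @param offset_mm physical distance (mm) between a center voxel and its
#'   texture neighbors; the study design uses 3 or 5 mm so that extraction
#'   happens at the same physical scale regardless of voxel spacing.
#' @param n_bins number of equal-width discretization bins (>= 2).
#' @param families subset of
#'   `c("intensity","histogram","volumetric","morphology","glrlm","ngtdm","glszm")`.
#' @return object of class `extraction_params`.
#' @export
extraction_params <- function(offset_mm = 3, n_bins = 32,
                              families = c("intensity", "histogram",
                                           "volumetric", "morphology",
                                           "glrlm", "ngtdm", "glszm")) {
  stopifnot(offset_mm > 0, n_bins >= 2)
  families <- match.arg(families, several.ok = TRUE,
                        choices = c("intensity", "histogram", "volumetric",
                                    "morphology", "glrlm", "ngtdm", "glszm"))
  structure(list(offset_mm = offset_mm, n_bins = as.integer(n_bins),
                 families = families),
            class = "extraction_params")
}

#' Per-axis minimum voxel spacing over a dataset
#'
#' The common resampling target: the minimum of each spacing axis across
#' all images (axes treated independently).
#'
#' @param images non-empty list of [voxel_image()].
#' @return numeric length-3 vector (mm).
#' @export
compute_min_spacing <- function(images) {
  if (length(images) == 0) stop("empty image list")
  sp <- vapply(images, function(im) im$spacing, numeric(3))
  apply(sp, 1, min)
}

#' Convert a physical offset to per-axis voxel distances
#'
#' Nearest-integer `offset_mm / spacing` per axis, clamped to a minimum of
#' 1 voxel so coarse axes still have neighbors.
#'
#' @param offset_mm physical offset (> 0).
#' @param spacing voxel spacing triple (mm).
#' @return integer length-3 vector of voxel distances.
#' @export
offset_to_voxels <- function(offset_mm, spacing) {
  stopifnot(offset_mm > 0, all(spacing > 0))
  pmax(1L, as.integer(round(offset_mm / spacing)))
}

#' Resample an image to a target spacing
#'
#' Intensities are trilinearly interpolated, the mask is nearest-neighbor
#' interpolated (kept strictly binary). The new grid keeps the origin at
#' the first voxel center and covers the original physical extent to within
#' one voxel per axis.
#'
#' @param image a [voxel_image()].
#' @param target_spacing positive spacing triple (mm).
#' @return a resampled [voxel_image()].
#' @export
resample_image <- function(image, target_spacing) {
  stopifnot(inherits(image, "voxel_image"), length(target_spacing) == 3L,
            all(target_spacing > 0))
  dm <- dim(image$intensities)
  extent <- (dm - 1) * image$spacing
  if (any(target_spacing > extent & dm > 1))
    stop("target spacing coarser than the image extent on at least one axis")
  n_new <- pmax(1L, as.integer(floor(extent / target_spacing)) + 1L)

  # continuous source index (0-based) of each new voxel centre, per axis
  ax_pos <- lapply(1:3, function(a) {
    (seq_len(n_new[a]) - 1) * target_spacing[a] / image$spacing[a]
  })
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  i0 <- lapply(1:3, function(a) {
    p <- clamp(ax_pos[[a]], 0, dm[a] - 1)
    lo <- pmin(floor(p), dm[a] - 2)
    lo <- pmax(lo, 0)
    list(lo = as.integer(lo), t = p - lo)
  })
  if (any(dm == 1)) {  # degenerate axes: repeat the single slice
    for (a in which(dm == 1)) i0[[a]] <- list(lo = rep(0L, n_new[a]),
                                              t = rep(0, n_new[a]))
  }

  g <- expand.grid(x = seq_len(n_new[1]), y = seq_len(n_new[2]),
                   z = seq_len(n_new[3]))
  lox <- i0[[1]]$lo[g$x]; tx <- i0[[1]]$t[g$x]
  loy <- i0[[2]]$lo[g$y]; ty <- i0[[2]]$t[g$y]
  loz <- i0[[3]]$lo[g$z]; tz <- i0[[3]]$t[g$z]

  at <- function(ix, iy, iz) {
    image$intensities[cbind(ix + 1L, iy + 1L, iz + 1L)]
  }
  hix <- pmin(lox + 1L, dm[1] - 1L)
  hiy <- pmin(loy + 1L, dm[2] - 1L)
  hiz <- pmin(loz + 1L, dm[3] - 1L)
  vals <-
    at(lox, loy, loz) * (1 - tx) * (1 - ty) * (1 - tz) +
    at(hix, loy, loz) * tx       * (1 - ty) * (1 - tz) +
    at(lox, hiy, loz) * (1 - tx) * ty       * (1 - tz) +
    at(hix, hiy, loz) * tx       * ty       * (1 - tz) +
    at(lox, loy, hiz) * (1 - tx) * (1 - ty) * tz +
    at(hix, loy, hiz) * tx       * (1 - ty) * tz +
    at(lox, hiy, hiz) * (1 - tx) * ty       * tz +
    at(hix, hiy, hiz) * tx       * ty       * tz
  new_int <- array(vals, n_new)

  nn <- function(lo, t) lo + as.integer(t >= 0.5)
  mvals <- image$mask[cbind(pmin(nn(lox, tx), dm[1] - 1L) + 1L,
                            pmin(nn(loy, ty), dm[2] - 1L) + 1L,
                            pmin(nn(loz, tz), dm[3] - 1L) + 1L)]
  new_mask <- array(mvals, n_new)
  if (!any(new_mask))
    stop("mask lost during resampling (ROI smaller than target spacing)")
  voxel_image(new_int, target_spacing, new_mask)
}

#' Discretize ROI intensities into equal-width gray levels
#'
#' Bins span the ROI's `[min, max]`; a constant ROI maps wholly to level 1.
#' Voxels outside the mask are NA.
#'
#' @param image a [voxel_image()].
#' @param n_bins number of levels.
#' @return integer 3D array of levels `1..n_bins` (NA outside the ROI).
#' @export
discretize <- function(image, n_bins = 32) {
  stopifnot(inherits(image, "voxel_image"), n_bins >= 2)
  x <- image$intensities
  m <- image$mask
  v <- x[m]
  lo <- min(v); hi <- max(v)
  lev <- array(NA_integer_, dim(x))
  if (hi == lo) {
    lev[m] <- 1L
  } else {
    lev[m] <- pmin(as.integer(floor((x[m] - lo) / (hi - lo) * n_bins)) + 1L,
                   as.integer(n_bins))
  }
  lev
}

named_features <- function(values, family) {
  stats::setNames(values, paste0(family, "_", names(values)))
}

#' First-order intensity statistics over the ROI
#'
#' Population-variance convention; skewness and (excess) kurtosis of a
#' constant ROI are defined as 0.
#'
#' @param image a [voxel_image()].
#' @return named numeric vector (family prefix `int_`).
#' @export
intensity_features <- function(image) {
  v <- image$intensities[image$mask]
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 > 0) {
    skew <- mean((v - mu)^3) / m2^1.5
    kurt <- mean((v - mu)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  named_features(c(mean = mu, variance = m2, sd = sqrt(m2),
                   skewness = skew, kurtosis = kurt,
                   min = min(v), max = max(v), range = max(v) - min(v),
                   energy = sum(v^2), rms = sqrt(mean(v^2))), "int")
}

#' Histogram features of the discretized ROI
#'
#' Entropy in bits over bin probabilities (empty bins contribute 0),
#' uniformity (energy of the histogram), mean/variance of the level
#' distribution and level percentiles.
#'
#' @param discretized integer level array from [discretize()].
#' @param n_bins the bin count used for discretization.
#' @return named numeric vector (family prefix `hist_`).
#' @export
histogram_features <- function(discretized, n_bins) {
  lev <- discretized[!is.na(discretized)]
  p <- tabulate(lev, nbins = n_bins) / length(lev)
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  mu <- sum(seq_len(n_bins) * p)
  va <- sum((seq_len(n_bins) - mu)^2 * p)
  qs <- stats::quantile(lev, c(.10, .25, .50, .75, .90), names = FALSE)
  named_features(c(entropy = entropy, uniformity = sum(p^2),
                   mean = mu, variance = va,
                   p10 = qs[1], p25 = qs[2], p50 = qs[3],
                   p75 = qs[4], p90 = qs[5]), "hist")
}

#' Volumetric (intensity-volume) features
#'
#' Two monotone families linking intensity and the fraction of ROI volume:
#' the intensity below which a given volume fraction lies (a quantile), and
#' the volume fraction at or above intensity thresholds placed at fixed
#' fractions of the ROI intensity range. The latter is non-increasing in
#' the threshold by construction.
#'
#' @param image a [voxel_image()].
#' @param fractions volume/range fractions to evaluate.
#' @return named numeric vector (family prefix `vol_`).
#' @export
volumetric_features <- function(image, fractions = c(.10, .25, .50, .75, .90)) {
  v <- image$intensities[image$mask]
  iv <- stats::quantile(v, fractions, names = FALSE)
  rng <- range(v)
  thr <- rng[1] + fractions * (rng[2] - rng[1])
  vf <- vapply(thr, function(t) mean(v >= t), 0)
  tag <- function(prefix) paste0(prefix, round(100 * fractions))
  named_features(stats::setNames(c(iv, vf),
                                 c(tag("intensity_at_f"), tag("fraction_ge_r"))),
                 "vol")
}

#' Morphologic features of the ROI
#'
#' Volume as voxel count times voxel volume; surface area by exposed-face
#' counting (each mask voxel face not shared with another mask voxel
#' contributes its physical face area); sphericity
#' `pi^(1/3) (6V)^(2/3) / A`; maximum 3D diameter as the largest
#' center-to-center distance between surface voxels; physical centroid.
#'
#' @param image a [voxel_image()] (only `mask` and `spacing` are used).
#' @return named numeric vector (family prefix `morph_`).
#' @export
morphology_features <- function(image) {
  m <- image$mask
  sp <- image$spacing
  n <- sum(m)
  vol <- n * prod(sp)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  exposed <- array(0L, dim(m))
  area <- 0
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[ax] <- s
      nb <- shift_array(m, d, fill = FALSE)
      exp_face <- m & !nb
      area <- area + sum(exp_face) * face_area[ax]
      exposed <- exposed + exp_face
    }
  }
  sphericity <- (pi^(1 / 3) * (6 * vol)^(2 / 3)) / area
  idx <- which(m, arr.ind = TRUE)
  cent <- colMeans((idx - 1) * rep(sp, each = nrow(idx)))
  surf <- which(exposed > 0 & m, arr.ind = TRUE)
  if (nrow(surf) > 1) {
    pts <- (surf - 1) * rep(sp, each = nrow(surf))
    maxdiam <- sqrt(max(as.numeric(stats::dist(pts))^2))
  } else maxdiam <- 0
  named_features(c(volume_mm3 = vol, surface_mm2 = area,
                   sphericity = sphericity, max_diameter_mm = maxdiam,
                   centroid_x = cent[1], centroid_y = cent[2],
                   centroid_z = cent[3]), "morph")
}

# Run-length matrix for one direction: rows = gray level, cols = run length.
# Voxels outside the ROI (NA) break runs.
glrlm_matrix <- function(discretized, direction, n_levels) {
  idx <- which(!is.na(discretized), arr.ind = TRUE)
  lev <- discretized[idx]
  d <- as.integer(direction)
  # order voxels by line, then by position along the line
  t_par <- as.numeric(idx %*% d) / sum(d * d)
  line_key <- idx - outer(t_par, d)
  key <- paste(round(line_key[, 1], 6), round(line_key[, 2], 6),
               round(line_key[, 3], 6))
  o <- order(key, t_par)
  keyo <- key[o]; to <- t_par[o]; levo <- lev[o]
  same_line <- c(FALSE, keyo[-1] == keyo[-length(keyo)])
  consecutive <- c(FALSE, abs(to[-1] - to[-length(to)] - 1) < 1e-9)
  same_lev <- c(FALSE, levo[-1] == levo[-length(levo)])
  new_run <- !(same_line & consecutive & same_lev)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_lev <- levo[new_run]
  max_len <- max(run_len)
  mat <- matrix(0, n_levels, max_len)
  for (r in seq_along(run_len))
    mat[run_lev[r], run_len[r]] <- mat[run_lev[r], run_len[r]] + 1
  mat
}

glrlm_from_matrix <- function(mat, n_vox) {
  i <- matrix(seq_len(nrow(mat)), nrow(mat), ncol(mat))
  j <- matrix(seq_len(ncol(mat)), nrow(mat), ncol(mat), byrow = TRUE)
  nr <- sum(mat)
  c(sre = sum(mat / j^2) / nr,
    lre = sum(mat * j^2) / nr,
    gln = sum(rowSums(mat)^2) / nr,
    rln = sum(colSums(mat)^2) / nr,
    rp = nr / n_vox,
    lglre = sum(mat / i^2) / nr,
    hglre = sum(mat * i^2) / nr)
}

#' Gray-level run length (GLRLM) features
#'
#' Runs of identical discretized gray level along each of the 13 unique 3D
#' directions; the run matrices are padded to a common size and averaged,
#' and features are computed from the averaged matrix. The conservation
#' identity `sum(count * run length) = ROI voxel count` holds per direction
#' and after averaging.
#'
#' @param discretized integer level array from [discretize()].
#' @param n_levels number of gray levels used in discretization.
#' @param directions integer matrix of direction vectors (rows); default
#'   the 13 unique 3D directions.
#' @return named numeric vector (family prefix `glrlm_`): SRE, LRE, GLN,
#'   RLN, RP, low/high gray-level run emphasis.
#' @export
glrlm_features <- function(discretized, n_levels,
                           directions = directions13()) {
  n_vox <- sum(!is.na(discretized))
  mats <- lapply(seq_len(nrow(directions)), function(r)
    glrlm_matrix(discretized, directions[r, ], n_levels))
  max_len <- max(vapply(mats, ncol, 0L))
  avg <- matrix(0, n_levels, max_len)
  for (m in mats) avg[, seq_len(ncol(m))] <- avg[, seq_len(ncol(m))] + m
  avg <- avg / length(mats)
  named_features(glrlm_from_matrix(avg, n_vox), "glrlm")
}

#' Neighboring gray tone difference (NGTDM) features
#'
#' For each ROI voxel with at least one valid neighbor inside the
#' rectangular neighborhood (per-axis voxel distance `dist_vox`, usually
#' from [offset_to_voxels()]), the absolute difference between its level
#' and the mean neighbor level is accumulated per level (`s_i`).
#' Coarseness, contrast, busyness, complexity and strength follow the
#' Amadasun-King definitions; a constant ROI has all `s_i = 0` and
#' contrast 0.
#'
#' @param discretized integer level array from [discretize()].
#' @param dist_vox per-axis integer neighborhood distance.
#' @param eps numerical guard for coarseness/strength denominators.
#' @return named numeric vector (family prefix `ngtdm_`).
#' @export
ngtdm_features <- function(discretized, dist_vox = c(1L, 1L, 1L),
                           eps = 1e-6) {
  valid <- !is.na(discretized)
  lev0 <- ifelse(valid, discretized, 0L)
  nb_sum <- array(0, dim(discretized))
  nb_cnt <- array(0, dim(discretized))
  offs <- expand.grid(dx = -dist_vox[1]:dist_vox[1],
                      dy = -dist_vox[2]:dist_vox[2],
                      dz = -dist_vox[3]:dist_vox[3])
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    d <- as.integer(offs[r, ])
    nb_sum <- nb_sum + shift_array(lev0, d, fill = 0)
    nb_cnt <- nb_cnt + shift_array(array(as.numeric(valid),
                                         dim(discretized)), d, fill = 0)
  }
  use <- valid & nb_cnt > 0
  a_bar <- nb_sum[use] / nb_cnt[use]
  lev <- discretized[use]
  n_eff <- length(lev)
  levels_present <- sort(unique(lev))
  s <- vapply(levels_present, function(l) sum(abs(l - a_bar)[lev == l]), 0)
  p <- vapply(levels_present, function(l) mean(lev == l), 0)
  ng <- length(levels_present)
  coarseness <- 1 / (sum(p * s) + eps)
  if (ng > 1) {
    ii <- levels_present
    pg <- outer(p, p)
    dd2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- (sum(pg * dd2) / (ng * (ng - 1))) * (sum(s) / n_eff)
    ipd <- abs(outer(ii * p, ii * p, "-"))
    denom_b <- sum(ipd)
    busyness <- if (denom_b > 0) sum(p * s) / denom_b else 0
    ps <- p * s
    complexity <- sum(abs(outer(ii, ii, "-")) *
                        (outer(ps, ps, "+") / outer(p, p, "+"))) / n_eff
    strength_num <- sum(outer(p, p, "+") * dd2)
    strength <- if (sum(s) > 0) strength_num / (eps + sum(s)) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  named_features(c(coarseness = coarseness, contrast = contrast,
                   busyness = busyness, complexity = complexity,
                   strength = strength), "ngtdm")
}

# 26-connected zones of identical gray level; returns a data.frame with one
# row per zone (level, size).
glszm_zones <- function(discretized) {
  idx <- which(!is.na(discretized))
  nvox <- length(idx)
  pos <- which(!is.na(discretized), arr.ind = TRUE)
  lev <- discretized[idx]
  vox_id <- array(NA_integer_, dim(discretized))
  vox_id[idx] <- seq_len(nvox)
  dirs <- directions13()
  edges <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    sh_id <- shift_array(vox_id, d, fill = NA)
    sh_lev <- shift_array(discretized, d, fill = NA)
    ok <- !is.na(vox_id) & !is.na(sh_id) & discretized == sh_lev
    if (any(ok)) edges <- c(edges, rbind(vox_id[ok], sh_id[ok]))
  }
  g <- igraph::make_graph(edges = edges, n = nvox, directed = FALSE)
  comp <- igraph::components(g)
  data.frame(level = lev[match(seq_len(comp$no), comp$membership)],
             size = as.integer(comp$csize))
}

#' Gray-level size zone (GLSZM) features
#'
#' Zones are maximal 26-connected groups of ROI voxels sharing a
#' discretized gray level. The conservation identity
#' `sum(zone size x zone count) = ROI voxel count` always holds.
#'
#' @param discretized integer level array from [discretize()].
#' @return named numeric vector (family prefix `glszm_`): small/large zone
#'   emphasis, gray-level nonuniformity, zone-size nonuniformity, zone
#'   percentage.
#' @export
glszm_features <- function(discretized) {
  z <- glszm_zones(discretized)
  nz <- nrow(z)
  nvox <- sum(z$size)
  named_features(c(
    sze = sum(1 / z$size^2) / nz,
    lze = sum(z$size^2) / nz,
    gln = sum(tapply(rep(1, nz), z$level, sum)^2) / nz,
    zsn = sum(tapply(rep(1, nz), z$size, sum)^2) / nz,
    zp = nz / nvox), "glszm")
}

#' Extract a full radiomic feature vector from one image
#'
#' Orchestrates discretization and the requested families; the NGTDM
#' neighborhood distance is derived from the physical offset via
#' [offset_to_voxels()], so extraction happens at the same physical scale
#' regardless of voxel spacing. ROIs below 10 voxels trigger a warning and
#' texture families (glrlm/ngtdm/glszm, plus histogram of levels) are
#' skipped.
#'
#' @param image a [voxel_image()].
#' @param params an [extraction_params()].
#' @return named numeric vector; `attr(, "family")` tags each feature.
#' @export
extract_features <- function(image, params = extraction_params()) {
  stopifnot(inherits(image, "voxel_image"),
            inherits(params, "extraction_params"))
  fams <- params$families
  n_roi <- sum(image$mask)
  if (n_roi < 10 && any(fams %in% c("glrlm", "ngtdm", "glszm"))) {
    warning("ROI below 10 voxels; texture families skipped")
    fams <- setdiff(fams, c("glrlm", "ngtdm", "glszm"))
  }
  need_disc <- any(fams %in% c("histogram", "glrlm", "ngtdm", "glszm"))
  disc <- if (need_disc) discretize(image, params$n_bins) else NULL
  out <- numeric(0)
  if ("intensity" %in% fams) out <- c(out, intensity_features(image))
  if ("histogram" %in% fams) out <- c(out, histogram_features(disc, params$n_bins))
  if ("volumetric" %in% fams) out <- c(out, volumetric_features(image))
  if ("morphology" %in% fams) out <- c(out, morphology_features(image))
  if ("glrlm" %in% fams) out <- c(out, glrlm_features(disc, params$n_bins))
  if ("ngtdm" %in% fams) {
    dv <- offset_to_voxels(params$offset_mm, image$spacing)
    out <- c(out, ngtdm_features(disc, dv))
  }
  if ("glszm" %in% fams) out <- c(out, glszm_features(disc))
  attr(out, "family") <- sub("_.*$", "", names(out))
  out
}

#' Extract features for a cohort of images
#'
#' @param images list of [voxel_image()].
#' @param params an [extraction_params()].
#' @param ids patient IDs (row names); defaults to `img001`, ...
#' @return numeric matrix (patients x features) with a `family` attribute.
#' @export
extract_cohort_features <- function(images, params = extraction_params(),
                                    ids = NULL) {
  stopifnot(length(images) >= 1)
  rows <- lapply(images, extract_features, params = params)
  nm <- names(rows[[1]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
    stop("inconsistent feature sets across images")
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- nm
  rownames(m) <- ids %||% sprintf("img%03d", seq_along(images))
  attr(m, "family") <- attr(rows[[1]], "family")
  m
}
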