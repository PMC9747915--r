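# Synthetic cohort generator: feature tables under the ComBat generative
# model, textured 3D images with acquisition-style batch effects, and
# exponential survival outcomes. Every downstream stage of the pipeline is
# testable against cohorts produced here.

#' Describe batch variables and their planted location/scale effects
#'
#' A batch design holds one or more categorical batch variables (scanner,
#' kernel, contrast, dichotomized spacing, ...), the per-patient assignment
#' probabilities of their levels, and the planted feature-level effects:
#' `gamma` (additive location shift, in feature-standardized units) and
#' `delta` (multiplicative scale factor, > 0), each a `n_features x n_levels`
#' matrix per variable.
#'
#' @param n_features number of features the effects apply to.
#' @param variables list of variable descriptors. Each descriptor is a list
#'   with elements `name`, `levels` (character), optional `probs` (assignment
#'   probabilities, default uniform), optional `gamma` and `delta` (scalar,
#'   per-level vector, or `n_features x n_levels` matrix; defaults 0 and 1),
#'   and optional `affected` (integer feature indices carrying the effect;
#'   default all features).
#' @return object of class `batch_design`.
#' @examples
#' bd <- batch_design(10, list(
#'   list(name = "kernel", levels = c("soft", "sharp"), gamma = c(0, 1),
#'        delta = c(1, 2))))
#' @export
batch_design <- function(n_features, variables) {
  stopifnot(n_features >= 1, is.list(variables), length(variables) >= 1)
  vars <- lapply(variables, function(v) {
    stopifnot(!is.null(v$name), !is.null(v$levels), length(v$levels) >= 2)
    L <- length(v$levels)
    probs <- v$probs %||% rep(1 / L, L)
    if (length(probs) != L || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
      stop("assignment probabilities for '", v$name, "' must be length ",
           L, " and sum to 1")
    expand <- function(x, default) {
      if (is.null(x)) x <- default
      if (is.matrix(x)) {
        stopifnot(nrow(x) == n_features, ncol(x) == L)
        return(x)
      }
      if (length(x) == 1L) x <- rep(x, L)
      stopifnot(length(x) == L)
      matrix(rep(x, each = n_features), n_features, L)
    }
    gamma <- expand(v$gamma, 0)
    delta <- expand(v$delta, 1)
    if (!is.null(v$affected)) {
      keep <- logical(n_features)
      keep[v$affected] <- TRUE
      gamma[!keep, ] <- 0
      delta[!keep, ] <- 1
    }
    if (any(delta <= 0)) stop("delta must be strictly positive")
    list(name = v$name, levels = as.character(v$levels), probs = probs,
         gamma = gamma, delta = delta)
  })
  names(vars) <- vapply(vars, `[[`, "", "name")
  structure(list(n_features = n_features, variables = vars),
            class = "batch_design")
}

#' Describe a latent phenotype with separable feature signal
#'
#' @param n_classes number of latent classes (default 2, the setting in
#'   which exactly two stable radiomic phenotypes are expected).
#' @param class_proportions class probabilities (default uniform).
#' @param effect_size mean shift per affected feature between consecutive
#'   classes, in standard-deviation units.
#' @param affected_fraction fraction of features carrying the phenotype
#'   signal (the first `ceiling(affected_fraction * n_features)` features).
#' @return object of class `phenotype_design`.
#' @export
phenotype_design <- function(n_classes = 2, class_proportions = NULL,
                             effect_size = 1.5, affected_fraction = 0.3) {
  stopifnot(n_classes >= 1, affected_fraction >= 0, affected_fraction <= 1)
  props <- class_proportions %||% rep(1 / n_classes, n_classes)
  if (length(props) != n_classes || abs(sum(props) - 1) > 1e-8)
    stop("class proportions must have length n_classes and sum to 1")
  structure(list(n_classes = n_classes, class_proportions = props,
                 effect_size = effect_size,
                 affected_fraction = affected_fraction),
            class = "phenotype_design")
}

#' Describe an exponential survival-generating process
#'
#' Event times are exponential with per-patient rate
#' `baseline_rate * exp(linear predictor)`; censoring is an independent
#' exponential clock, so proportional hazards holds by construction and the
#' expected event fraction has the closed form `rate / (rate + censoring)`.
#'
#' @param baseline_rate events per time unit for the reference patient (> 0).
#' @param phenotype_loghr log hazard ratio per unit increase of the (0-based)
#'   phenotype class index.
#' @param covariate_loghr named numeric vector of log hazard ratios for
#'   cohort covariate columns (may be empty).
#' @param censoring_rate rate of the independent censoring process (>= 0;
#'   0 means no censoring).
#' @return object of class `survival_design`.
#' @export
survival_design <- function(baseline_rate = 0.1, phenotype_loghr = 1,
                            covariate_loghr = c(covar1 = 0.5),
                            censoring_rate = 0.05) {
  stopifnot(baseline_rate > 0, censoring_rate >= 0)
  structure(list(baseline_rate = baseline_rate,
                 phenotype_loghr = phenotype_loghr,
                 covariate_loghr = covariate_loghr,
                 censoring_rate = censoring_rate),
            class = "survival_design")
}

assign_levels <- function(n, probs, levels) {
  factor(sample(levels, n, replace = TRUE, prob = probs), levels = levels)
}

#' Simulate a patient-by-feature table under the ComBat generative model
#'
#' Entry for patient i, feature g:
#' `mu_g + x_i' beta_g + phenotype shift + sum_v gamma_v[g, level] +
#'  prod_v delta_v[g, level] * eps`, with standard Gaussian noise `eps`.
#' Location effects of multiple batch variables add; scale effects multiply.
#'
#' @param n_patients,n_features cohort dimensions.
#' @param batch a [batch_design()] (its `n_features` must match).
#' @param phenotype a [phenotype_design()].
#' @param covariate_effects optional `n_features x q` matrix of slopes for q
#'   protected covariates (covariates drawn standard normal); a vector is
#'   one covariate. `NULL` gives a single zero-effect covariate `covar1`.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param confounding_or odds ratio linking phenotype class 2 to level 2 of
#'   the *first* batch variable (both must be 2-level); 1 = independent
#'   assignment (default).
#' @return list with `features` (numeric matrix, patients x features, row
#'   names = patient IDs) and `cohort` (data.frame: patient_id, one column
#'   per batch variable, covariates, `phenotype`, `time` = NA, `event` = NA).
#' @export
simulate_feature_table <- function(n_patients, n_features, batch, phenotype,
                                   covariate_effects = NULL, seed = 1,
                                   confounding_or = 1) {
  stopifnot(inherits(batch, "batch_design"),
            inherits(phenotype, "phenotype_design"),
            batch$n_features == n_features, n_patients >= 4)
  if (is.null(covariate_effects))
    covariate_effects <- matrix(0, n_features, 1)
  if (!is.matrix(covariate_effects))
    covariate_effects <- matrix(covariate_effects, n_features, 1)
  stopifnot(nrow(covariate_effects) == n_features)
  q <- ncol(covariate_effects)

  with_seed(seed, {
    classes <- factor(
      sample(seq_len(phenotype$n_classes), n_patients, replace = TRUE,
             prob = phenotype$class_proportions),
      levels = seq_len(phenotype$n_classes))

    levels_by_var <- lapply(batch$variables, function(v)
      assign_levels(n_patients, v$probs, v$levels))

    if (confounding_or != 1) {
      v1 <- batch$variables[[1]]
      if (length(v1$levels) != 2 || phenotype$n_classes != 2)
        stop("confounding_or requires a 2-level first batch variable and 2 classes")
      # tilt the level-2 probability for class-2 patients so that the
      # phenotype/batch odds ratio equals confounding_or
      p1 <- v1$probs[2]
      odds2 <- confounding_or * p1 / (1 - p1)
      p2 <- odds2 / (1 + odds2)
      lv <- character(n_patients)
      is2 <- classes == "2"
      lv[!is2] <- sample(v1$levels, sum(!is2), TRUE, prob = v1$probs)
      lv[is2] <- sample(v1$levels, sum(is2), TRUE, prob = c(1 - p2, p2))
      levels_by_var[[1]] <- factor(lv, levels = v1$levels)
    }

    for (nm in names(levels_by_var)) {
      tab <- table(levels_by_var[[nm]])
      if (any(tab < 2))
        stop("batch variable '", nm, "' has a level with < 2 patients; ",
             "ComBat variance estimation is undefined (increase n_patients)")
    }

    covars <- matrix(stats::rnorm(n_patients * q), n_patients, q)
    colnames(covars) <- paste0("covar", seq_len(q))

    n_aff <- ceiling(phenotype$affected_fraction * n_features)
    shift <- matrix(0, n_patients, n_features)
    if (n_aff > 0)
      shift[, seq_len(n_aff)] <- phenotype$effect_size *
        (as.integer(classes) - 1)

    gam <- matrix(0, n_patients, n_features)
    del <- matrix(1, n_patients, n_features)
    for (v in batch$variables) {
      idx <- as.integer(levels_by_var[[v$name]])
      gam <- gam + t(v$gamma[, idx, drop = FALSE])
      del <- del * t(v$delta[, idx, drop = FALSE])
    }

    eps <- matrix(stats::rnorm(n_patients * n_features), n_patients, n_features)
    y <- covars %*% t(covariate_effects) + shift + gam + del * eps

    ids <- sprintf("P%04d", seq_len(n_patients))
    rownames(y) <- ids
    colnames(y) <- sprintf("feat%03d", seq_len(n_features))

    cohort <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (nm in names(levels_by_var)) cohort[[nm]] <- levels_by_var[[nm]]
    cohort <- cbind(cohort, as.data.frame(covars))
    cohort$phenotype <- classes
    cohort$time <- NA_real_
    cohort$event <- NA_integer_
    list(features = y, cohort = cohort)
  })
}

#' Simulate survival outcomes for a cohort
#'
#' @param cohort data.frame with `phenotype` and the covariate columns named
#'   in `design$covariate_loghr`.
#' @param design a [survival_design()].
#' @param seed integer seed.
#' @return `cohort` with `time` (> 0) and `event` (0/1) filled in. If no
#'   events occur a warning is raised and `attr(, "all_censored")` is TRUE.
#' @export
simulate_survival <- function(cohort, design, seed = 1) {
  stopifnot(inherits(design, "survival_design"),
            "phenotype" %in% names(cohort))
  lp <- design$phenotype_loghr * (as.integer(cohort$phenotype) - 1)
  for (nm in names(design$covariate_loghr)) {
    if (!nm %in% names(cohort))
      stop("covariate '", nm, "' not present in cohort")
    lp <- lp + design$covariate_loghr[[nm]] * cohort[[nm]]
  }
  with_seed(seed, {
    n <- nrow(cohort)
    t_event <- stats::rexp(n, rate = design$baseline_rate * exp(lp))
    t_cens <- if (design$censoring_rate > 0)
      stats::rexp(n, rate = design$censoring_rate) else rep(Inf, n)
    cohort$time <- pmin(t_event, t_cens)
    cohort$event <- as.integer(t_event <= t_cens)
  })
  if (all(cohort$event == 0)) {
    warning("all simulated outcomes are censored")
    attr(cohort, "all_censored") <- TRUE
  }
  cohort
}

#' Simulate a cohort of textured 3D images with acquisition batch effects
#'
#' Each patient gets an ellipsoidal ROI rendered in physical (mm)
#' coordinates at that patient's voxel spacing, filled with spatially
#' correlated noise whose correlation length (mm) depends on the latent
#' phenotype class; a per-batch reconstruction-kernel blur (extra Gaussian
#' smoothing) and a per-batch additive contrast-enhancement offset complete
#' the acquisition model. Coarser texture (longer correlation length) is the
#' planted class signal: it is visible to neighborhood texture families
#' (e.g. NGTDM coarseness) and invisible to the ROI mean.
#'
#' @param n_patients cohort size.
#' @param base_shape voxel grid (x, y, z), default `c(24, 24, 16)`.
#' @param spacing_by_batch named list: level name -> spacing triple (mm).
#' @param kernel_sigma_by_batch named list: level name -> extra smoothing
#'   sigma in mm (0 = sharp kernel).
#' @param contrast_shift_by_batch named list: level name -> additive
#'   intensity offset.
#' @param phenotype a [phenotype_design()]; only `n_classes` and
#'   `class_proportions` are used for images.
#' @param correlation_length_by_class per-class texture correlation length
#'   in mm (calibrated defaults `c(0.8, 2.4)`; pinned by a fixture test).
#' @param seed integer seed.
#' @param roi_fraction ellipsoid semi-axes as a fraction of the half-extent
#'   of the grid on each axis.
#' @return list with `images` (list of [voxel_image()]) and `cohort`
#'   (patient_id, spacing_group/kernel/contrast levels, numeric
#'   pixel_spacing and slice_thickness, covariate, phenotype, time/event NA).
#' @export
simulate_images <- function(n_patients,
                            base_shape = c(24, 24, 16),
                            spacing_by_batch = list(fine = c(0.7, 0.7, 1.5),
                                                    coarse = c(1.0, 1.0, 3.0)),
                            kernel_sigma_by_batch = list(sharp = 0, soft = 1.0),
                            contrast_shift_by_batch = list(nce = 0, ce = 100),
                            phenotype = phenotype_design(),
                            correlation_length_by_class = c(0.8, 2.4),
                            seed = 1,
                            roi_fraction = 0.72) {
  stopifnot(n_patients >= 1, length(base_shape) == 3L,
            inherits(phenotype, "phenotype_design"),
            length(correlation_length_by_class) >= phenotype$n_classes)
  for (sp in spacing_by_batch)
    if (any(sp <= 0)) stop("spacings must be strictly positive")

  with_seed(seed, {
    classes <- factor(
      sample(seq_len(phenotype$n_classes), n_patients, replace = TRUE,
             prob = phenotype$class_proportions),
      levels = seq_len(phenotype$n_classes))
    sp_lv <- assign_levels(n_patients, NULL, names(spacing_by_batch))
    kn_lv <- assign_levels(n_patients, NULL, names(kernel_sigma_by_batch))
    ct_lv <- assign_levels(n_patients, NULL, names(contrast_shift_by_batch))
    covar <- stats::rnorm(n_patients)
    img_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)

    images <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      images[[i]] <- render_patient_image(
        shape = base_shape,
        spacing = spacing_by_batch[[as.character(sp_lv[i])]],
        corr_len = correlation_length_by_class[as.integer(classes[i])],
        kernel_sigma = kernel_sigma_by_batch[[as.character(kn_lv[i])]],
        contrast_shift = contrast_shift_by_batch[[as.character(ct_lv[i])]],
        roi_fraction = roi_fraction,
        seed = img_seeds[i])
    }

    ids <- sprintf("P%04d", seq_len(n_patients))
    cohort <- data.frame(
      patient_id = ids,
      spacing_group = sp_lv, kernel = kn_lv, contrast = ct_lv,
      pixel_spacing = vapply(images, function(im) im$spacing[1], 0),
      slice_thickness = vapply(images, function(im) im$spacing[3], 0),
      covar1 = covar, phenotype = classes,
      time = NA_real_, event = NA_integer_,
      stringsAsFactors = FALSE)
    list(images = images, cohort = cohort)
  })
}

# Render one synthetic tumor image. Texture is white noise smoothed to the
# requested correlation length (in mm, converted to per-axis voxel sigmas)
# and rescaled to unit variance so classes differ in texture scale, not
# intensity spread; the ROI is an ellipsoid around the grid centre.
render_patient_image <- function(shape, spacing, corr_len, kernel_sigma,
                                 contrast_shift, roi_fraction, seed) {
  semi_mm <- roi_fraction * (shape - 1) / 2 * spacing
  if (any(semi_mm / spacing < 2))
    stop("degenerate ellipsoid: a semi-axis spans < 2 voxels at this spacing")
  with_seed(seed, {
    noise <- array(stats::rnorm(prod(shape)), shape)
    tex <- gaussian_smooth3(noise, corr_len / spacing)
    tex <- tex / stats::sd(as.numeric(tex)) * 10   # texture SD 10 units
    cx <- (shape - 1) / 2
    gx <- (seq_len(shape[1]) - 1 - cx[1]) * spacing[1]
    gy <- (seq_len(shape[2]) - 1 - cx[2]) * spacing[2]
    gz <- (seq_len(shape[3]) - 1 - cx[3]) * spacing[3]
    r2 <- outer(outer((gx / semi_mm[1])^2, (gy / semi_mm[2])^2, "+"),
                (gz / semi_mm[3])^2, "+")
    mask <- r2 <= 1
    if (sum(mask) < 50) stop("ROI smaller than 50 voxels; enlarge the grid")
    img <- 100 + tex + ifelse(mask, 40, 0)   # tumor plateau over background
    if (kernel_sigma > 0) img <- gaussian_smooth3(img, kernel_sigma / spacing)
    img <- img + contrast_shift
    voxel_image(img, spacing, mask)
  })
}

#' Write a simulated imaging cohort to disk
#'
#' Writes one NIfTI image/mask pair per patient plus a `manifest.csv`
#' linking patient IDs to files, and the cohort table as `cohort.csv`.
#'
#' @param sim result of [simulate_images()].
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default TRUE).
#' @return path of the manifest file, invisibly.
#' @export
write_image_cohort <- function(sim, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  ids <- sim$cohort$patient_id
  img_files <- file.path(dir, paste0(ids, "_image", ext))
  msk_files <- file.path(dir, paste0(ids, "_mask", ext))
  for (i in seq_along(ids))
    write_voxel_image(sim$images[[i]], img_files[i], msk_files[i])
  manifest <- data.frame(patient_id = ids,
                         image = basename(img_files),
                         mask = basename(msk_files),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
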