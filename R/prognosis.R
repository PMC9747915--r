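# Prognostic evaluation by batch group: dichotomized batch groupings, Cox
# models combining phenotype with clinical covariates, Harrell's C (apparent
# and cross-validated), NMI between phenotype labelings, and chi-square
# covariate associations.

#' Divide a cohort into two groups by a batch variable
#'
#' Numeric variables use a strict `< threshold` vs `>= threshold` split
#' (values exactly at the threshold go to the `>=` group, the convention of
#' dichotomized imaging parameters such as pixel spacing `< 0.78 mm`).
#' Categorical variables split a given level set against the rest.
#'
#' @param cohort data.frame with one row per patient.
#' @param variable column name.
#' @param threshold numeric threshold (numeric variables).
#' @param levels character level set defining the first group (categorical
#'   variables); defaults to the first level of a 2-level factor.
#' @return list of class `batch_grouping`: `variable`, `threshold` or
#'   `levels`, `groups` (factor of group names per patient).
#' @export
group_by_batch <- function(cohort, variable, threshold = NULL,
                           levels = NULL) {
  if (!variable %in% names(cohort)) stop("variable '", variable,
                                         "' not in cohort")
  v <- cohort[[variable]]
  if (!is.null(threshold)) {
    stopifnot(is.numeric(v))
    g <- factor(ifelse(v < threshold, paste0("<", threshold),
                       paste0(">=", threshold)),
                levels = c(paste0("<", threshold), paste0(">=", threshold)))
  } else {
    v <- as.factor(v)
    lv <- levels %||% base::levels(v)[1]
    g <- factor(ifelse(v %in% lv, paste(lv, collapse = "|"), "other"),
                levels = c(paste(lv, collapse = "|"), "other"))
    if (is.null(levels) && nlevels(v) == 2) {
      g <- v  # natural 2-level split keeps its own names
    }
  }
  if (any(table(g) == 0)) stop("empty group for variable '", variable, "'")
  structure(list(variable = variable, threshold = threshold,
                 levels = levels, groups = g),
            class = "batch_grouping")
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood maximization with Efron tie handling (delegated to
#' `survival::coxph` with a tightened convergence tolerance). Returns the
#' per-patient linear predictor as the risk score. Non-convergence or
#' monotone-likelihood warnings are captured into a flag rather than
#' crashing.
#'
#' @param x data.frame or matrix of model covariates (phenotype indicator
#'   plus clinical covariates); no constant columns.
#' @param time,event survival outcome.
#' @return list of class `cox_fit`: `coefficients`, `risk` (linear
#'   predictor), `flag` (NULL or the captured warning message), `fit`.
#' @export
fit_cox <- function(x, time, event) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(time), length(time) == length(event))
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  const <- vapply(x, function(col) length(unique(col)) < 2, TRUE)
  if (any(const))
    stop("constant column(s): ", paste(names(x)[const], collapse = ", "))
  dat <- cbind(x, .time = time, .event = event)
  flag <- NULL
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                    data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  structure(list(coefficients = stats::coef(fit),
                 risk = unname(fit$linear.predictors),
                 flag = flag, fit = fit),
            class = "cox_fit")
}

#' Harrell's concordance statistic
#'
#' A pair is usable when the shorter observed time is an event (ties in
#' time with exactly one event treat the event as the shorter); concordant
#' when that patient has the higher risk score; risk-score ties count 0.5.
#'
#' @param risk numeric risk scores (higher = worse).
#' @param time,event survival outcome.
#' @return scalar C in `[0, 1]`.
#' @export
c_statistic <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  ev <- matrix(event == 1, n, n)
  shorter <- outer(time, time, "<")
  equal <- outer(time, time, "==")
  usable <- (shorter & ev) | (equal & ev & !t(ev))
  n_usable <- sum(usable)
  if (n_usable == 0) stop("no comparable pairs")
  dr <- outer(risk, risk, "-")
  (sum(usable & dr > 0) + 0.5 * sum(usable & dr == 0)) / n_usable
}

#' Cross-validated concordance
#'
#' Five-fold cross-validation repeated over `n_iterations` reshuffles: per
#' fold, a Cox model is fitted on the training folds and C computed on the
#' held-out fold. Iterations whose folds leave a training set with fewer
#' than 2 events (or an unusable test fold) are reshuffled and logged.
#'
#' @param x model covariates (data.frame/matrix).
#' @param time,event survival outcome.
#' @param n_folds folds per iteration (default 5).
#' @param n_iterations reshuffled iterations (default 200).
#' @param seed integer seed.
#' @return list: `mean` (mean held-out C), `ci` (2.5/97.5 percentiles over
#'   fold-level values), `values`, `n_reshuffles`.
#' @export
cv_c_statistic <- function(x, time, event, n_folds = 5, n_iterations = 200,
                           seed = 1) {
  x <- as.data.frame(x)
  n <- nrow(x)
  xm <- stats::model.matrix(~ ., data = x)[, -1, drop = FALSE]
  vals <- numeric(0)
  n_reshuffles <- 0L
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      for (try in 1:100) {
        folds <- sample(rep(seq_len(n_folds), length.out = n))
        ok <- all(vapply(seq_len(n_folds), function(f)
          sum(event[folds != f]) >= 2, TRUE))
        if (ok) break
        n_reshuffles <- n_reshuffles + 1L
      }
      fold_c <- rep(NA_real_, n_folds)
      for (f in seq_len(n_folds)) {
        tr <- folds != f
        fit <- tryCatch(fit_cox(x[tr, , drop = FALSE], time[tr], event[tr]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        beta <- stats::coef(fit$fit)
        risk_te <- as.numeric(xm[!tr, names(beta), drop = FALSE] %*% beta)
        fold_c[f] <- tryCatch(
          c_statistic(risk_te, time[!tr], event[!tr]),
          error = function(e) NA_real_)
      }
      vals <- c(vals, fold_c[!is.na(fold_c)])
    }
  })
  list(mean = mean(vals), ci = stats::quantile(vals, c(.025, .975),
                                               names = FALSE),
       values = vals, n_reshuffles = n_reshuffles)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information divided by the arithmetic mean of the two label
#' entropies (natural logs cancel). Symmetric, invariant to label
#' permutation; a single-cluster labeling on either side gives 0 by
#' convention.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  a <- as.factor(labels_a); b <- as.factor(labels_b)
  if (nlevels(droplevels(a)) < 2 || nlevels(droplevels(b)) < 2) return(0)
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  min(max(mi / ((ha + hb) / 2), 0), 1)
}

#' Chi-square association between phenotype and a categorical covariate
#'
#' Pearson chi-square without continuity correction; cells with expected
#' count below 5 are flagged, not corrected.
#'
#' @param labels phenotype labels.
#' @param covariate categorical covariate.
#' @return list: `statistic`, `p.value`, `table`, `low_expected` (TRUE when
#'   any expected count < 5).
#' @export
covariate_association <- function(labels, covariate) {
  tab <- table(as.factor(labels), as.factor(covariate))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table (a zero margin)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p.value = ct$p.value,
       table = tab, low_expected = any(ct$expected < 5))
}

#' Per-batch-group prognostic report across scenarios
#'
#' For every batch grouping and every scenario, fits a Cox model on the
#' patients of each group combining that group's phenotype indicator with
#' the clinical covariates, and reports the apparent c-score (the primary
#' metric; models are fitted on all patients of the group). Also tabulates
#' NMI between each scenario's phenotypes and a reference scenario, per
#' group.
#'
#' @param phenotypes named list: scenario id -> named list: grouping name
#'   -> named list: group name -> integer labels named by patient ID.
#' @param cohort cohort data.frame with `patient_id`, `time`, `event` and
#'   covariate columns.
#' @param groupings named list of [group_by_batch()] results.
#' @param covariate_cols character vector of clinical covariate columns.
#' @param reference scenario id used for the NMI comparison (default "3").
#' @return list of class `prognostic_report`: `cscores` (long data.frame:
#'   variable, group, n, scenario, c), `nmi` (data.frame vs reference),
#'   `flags`.
#' @export
build_report <- function(phenotypes, cohort, groupings, covariate_cols,
                         reference = "3") {
  stopifnot(length(phenotypes) >= 1, all(c("time", "event") %in%
                                           names(cohort)))
  scen_ids <- names(phenotypes)
  rows <- list(); nrows <- list(); flags <- list()
  for (gname in names(groupings)) {
    grouping <- groupings[[gname]]
    for (gl in levels(grouping$groups)) {
      sel <- grouping$groups == gl
      ids <- cohort$patient_id[sel]
      for (sc in scen_ids) {
        lab <- phenotypes[[sc]][[gname]][[gl]]
        if (is.null(lab)) next
        lab <- lab[ids]
        cs <- tryCatch({
          xm <- data.frame(phenotype = as.integer(lab == max(lab)),
                           cohort[sel, covariate_cols, drop = FALSE])
          fit <- fit_cox(xm, cohort$time[sel], cohort$event[sel])
          if (!is.null(fit$flag))
            flags[[length(flags) + 1L]] <- sprintf("%s/%s/%s: %s", sc,
                                                   gname, gl, fit$flag)
          c_statistic(fit$risk, cohort$time[sel], cohort$event[sel])
        }, error = function(e) {
          flags[[length(flags) + 1L]] <<- sprintf("%s/%s/%s: %s", sc, gname,
                                                  gl, conditionMessage(e))
          NA_real_
        })
        rows[[length(rows) + 1L]] <- data.frame(
          variable = gname, group = gl, n = sum(sel), scenario = sc,
          c = cs, stringsAsFactors = FALSE)
        if (sc != reference && reference %in% scen_ids) {
          ref_lab <- phenotypes[[reference]][[gname]][[gl]]
          if (!is.null(ref_lab))
            nrows[[length(nrows) + 1L]] <- data.frame(
              variable = gname, group = gl, scenario = sc,
              nmi_vs_reference = nmi(lab, ref_lab[ids]),
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(cscores = do.call(rbind, rows),
                 nmi = if (length(nrows)) do.call(rbind, nrows) else NULL,
                 reference = reference,
                 flags = unlist(flags)),
            class = "prognostic_report")
}

#' @export
print.prognostic_report <- function(x, ...) {
  cat("prognostic report (apparent c-scores by batch group)\n")
  wide <- stats::reshape(x$cscores, idvar = c("variable", "group", "n"),
                         timevar = "scenario", direction = "wide")
  names(wide) <- sub("^c\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}
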