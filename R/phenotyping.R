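# Radiomic phenotype discovery: Ward/Euclidean hierarchical clustering,
# consensus-based selection of the cluster number, the cluster index (CI),
# SigClust significance against a single-Gaussian null, and per-split
# dendrogram significance.

#' Ward hierarchical clustering of patients
#'
#' Euclidean distance with Ward's minimum-variance criterion
#' (`hclust(method = "ward.D2")`). Features are z-scored per column first
#' (Ward/Euclidean is scale-sensitive); pass `scale = FALSE` for
#' pre-standardized input.
#'
#' @param features numeric matrix, patients x features (n >= 3).
#' @param k number of clusters, `2 <= k <= n - 1`.
#' @param scale z-score columns before clustering.
#' @return list of class `ward_clustering`: `labels` (integer vector named
#'   by patient), `hclust` (the merge record), `k`.
#' @export
ward_cluster <- function(features, k, scale = TRUE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3) stop("clustering needs at least 3 patients")
  stopifnot(k >= 2, k <= n - 1)
  if (scale) x <- zscore(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(features)
  structure(list(labels = labels, hclust = hc, k = k),
            class = "ward_clustering")
}

#' Cluster index (CI)
#'
#' Sum of within-cluster sums of squares about each cluster mean divided by
#' the total sum of squares about the overall mean. CI is in `[0, 1]`
#' (smaller = tighter clustering) and is invariant to rigid rotation and
#' translation of the feature space.
#'
#' @param features numeric matrix, patients x features.
#' @param labels cluster assignment, >= 2 non-empty clusters.
#' @return scalar CI.
#' @export
cluster_index <- function(features, labels) {
  x <- as.matrix(features)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need >= 2 non-empty clusters")
  if (any(table(labels) == 0)) stop("empty cluster in labels")
  grand <- colMeans(x)
  tss <- sum(sweep(x, 2, grand, "-")^2)
  if (tss == 0) return(0)
  wss <- 0
  for (l in levels(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    wss <- wss + sum(sweep(xi, 2, colMeans(xi), "-")^2)
  }
  wss / tss
}

# CI of the best 2-means split (several random restarts); NA on degenerate
# (zero-variance) input.
best_two_means_ci <- function(x, n_restarts = 10) {
  tss <- sum(sweep(x, 2, colMeans(x), "-")^2)
  if (tss <= .Machine$double.eps) return(NA_real_)
  km <- tryCatch(
    stats::kmeans(x, centers = 2, nstart = n_restarts, iter.max = 50),
    error = function(e)
      stats::kmeans(x, centers = 2, nstart = n_restarts, iter.max = 100,
                    algorithm = "Lloyd"))
  km$tot.withinss / km$totss
}

#' SigClust: significance of a 2-cluster split
#'
#' Tests the observed cluster index of the best 2-means split (best of
#' `n_restarts` random starts) against a null of `n_sim` datasets drawn
#' from a single Gaussian fit to the data: mean at the sample mean and
#' diagonal covariance given by the eigenvalues of the sample covariance
#' (the principal-axis null; CI is rotation invariant so only the spectrum
#' matters). `p = (1 + #\{null CI <= observed\}) / (n_sim + 1)`.
#'
#' The null draws are conditioned on the fitted spectrum: each simulated
#' dataset is constructed so that its own sample covariance equals
#' `diag(lambda_hat)` exactly (whitening a Gaussian draw and rescaling).
#' Plain plug-in sampling re-spreads the sample eigenvalues a second time,
#' which makes the test severely conservative at moderate n/p; with exact
#' second-moment matching the Monte Carlo test is calibrated (for Gaussian
#' data the residual randomness given the sample covariance is a uniform
#' rotation, which CI is invariant to).
#'
#' @param features numeric matrix, patients x features (n >= 10).
#' @param n_sim number of null simulations (warning below 100).
#' @param seed integer seed.
#' @param n_restarts 2-means restarts for observed and null CIs.
#' @return list of class `sigclust_result`: `ci_observed`, `ci_null`
#'   (length `n_sim`), `p.value`, `n_sim`.
#' @export
sigclust <- function(features, n_sim = 1000, seed = 1, n_restarts = 10) {
  x <- as.matrix(features)
  n <- nrow(x); p <- ncol(x)
  if (n < 10) stop("sigclust needs n >= 10 patients")
  if (n_sim < 100) warning("n_sim < 100 gives a coarse p-value resolution")
  ci_obs <- with_seed(seed, best_two_means_ci(x, n_restarts))
  if (is.na(ci_obs)) {
    return(structure(list(ci_observed = NA_real_, ci_null = numeric(0),
                          p.value = 1, n_sim = n_sim),
                     class = "sigclust_result"))
  }
  r <- min(n - 1L, p)   # CI only sees the rank-r principal subspace
  ev <- eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev[seq_len(r)], 0)
  sds <- sqrt(ev)
  ci_null <- with_seed(seed, vapply(seq_len(n_sim), function(s) {
    z <- matrix(stats::rnorm(n * r), n, r)
    z <- sweep(z, 2, colMeans(z))
    Rch <- chol(crossprod(z) / (n - 1))
    xs <- t(backsolve(Rch, t(z), transpose = TRUE)) *
      rep(sds, each = n)
    ci <- best_two_means_ci(xs, n_restarts)
    if (is.na(ci)) 1 else ci
  }, 0))
  pval <- (1 + sum(ci_null <= ci_obs)) / (n_sim + 1)
  structure(list(ci_observed = ci_obs, ci_null = ci_null,
                 p.value = pval, n_sim = n_sim),
            class = "sigclust_result")
}

#' Significance of successive dendrogram splits
#'
#' Walks the Ward tree from the top: split j is the transition from j to
#' j + 1 clusters; [sigclust()] is applied to the patients of the cluster
#' being divided. Splits on subsets of fewer than `min_size` patients are
#' skipped with a warning. The first row (the top split over all patients)
#' is the headline dendrogram p-value.
#'
#' @param features numeric matrix used to build the tree (same row order).
#' @param hc an `hclust` object (e.g. from [ward_cluster()]).
#' @param n_splits how many successive splits to test.
#' @param n_sim,seed,n_restarts forwarded to [sigclust()].
#' @param min_size minimum subset size for a testable split.
#' @param scale z-score columns before testing (matching [ward_cluster()]).
#' @return data.frame with columns `split`, `size`, `p` (NA if skipped).
#' @export
split_significance <- function(features, hc, n_splits = 1, n_sim = 1000,
                               seed = 1, n_restarts = 10, min_size = 10,
                               scale = TRUE) {
  x <- as.matrix(features)
  if (scale) x <- zscore(x)
  n <- nrow(x)
  n_splits <- min(n_splits, n - 1)
  seeds <- derive_seeds(seed, n_splits)
  out <- data.frame(split = seq_len(n_splits), size = NA_integer_,
                    p = NA_real_)
  for (j in seq_len(n_splits)) {
    lab_lo <- stats::cutree(hc, k = j)
    lab_hi <- stats::cutree(hc, k = j + 1)
    split_cluster <- which(tapply(lab_hi, lab_lo,
                                  function(v) length(unique(v))) > 1)[1]
    members <- which(lab_lo == split_cluster)
    out$size[j] <- length(members)
    if (length(members) < min_size) {
      warning("split ", j, " involves ", length(members),
              " patients (< ", min_size, "); skipped")
      next
    }
    out$p[j] <- sigclust(x[members, , drop = FALSE], n_sim = n_sim,
                         seed = seeds[j], n_restarts = n_restarts)$p.value
  }
  out
}

#' Consensus clustering over candidate cluster numbers
#'
#' Repeatedly subsamples patients, clusters each subsample with
#' [ward_cluster()] at each candidate k, and records for every patient pair
#' the proportion of co-clusterings out of co-appearances (the consensus
#' matrix). Cluster stability per k is the area under the CDF of consensus
#' entries, computed exactly as `1 - mean(entries)`.
#'
#' The cluster number is chosen in two stages. (1) Consensus stage: with
#' `A(k)` the CDF area and `delta(2) = A(2)`,
#' `delta(k) = (A(k) - A(k-1)) / A(k-1)`, the candidate is the largest k
#' with `delta(k) > threshold`. (2) Significance gate (default on): walking
#' down the dendrogram of the full data, successive splits must be
#' SigClust-significant at `alpha`; the chosen k is capped at one more than
#' the longest initial run of significant splits (never below 2).
#'
#' @param features numeric matrix, patients x features.
#' @param k_range candidate cluster numbers (default 2:6).
#' @param n_subsamples number of subsampling rounds (>= 50 recommended).
#' @param subsample_fraction fraction of patients per round, in (0.5, 1).
#' @param seed integer seed (fixed seed gives identical results).
#' @param scale z-score features before clustering.
#' @param threshold relative CDF-area increase required to keep raising k.
#' @param sigclust_gate apply the split-significance gate.
#' @param n_sim SigClust null simulations for the gate.
#' @param alpha significance level of the gate.
#' @param refine polish the final full-data Ward labels with one k-means
#'   pass initialized at the Ward cluster means (hierarchical-initialized
#'   k-means); corrects greedy boundary misassignments of the dendrogram
#'   cut without changing the clustering criterion.
#' @return list of class `consensus_result`: `k_range`, `consensus` (list
#'   of matrices), `areas`, `deltas`, `k_consensus` (stage-1 candidate),
#'   `chosen_k`, `labels` (full-data Ward labels at `chosen_k`), `split_p`
#'   (gate p-values, if the gate ran), `hclust`.
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_subsamples = 100,
                              subsample_fraction = 0.8, seed = 1,
                              scale = TRUE, threshold = 0.05,
                              sigclust_gate = TRUE, n_sim = 200,
                              alpha = 0.05, refine = TRUE) {
  x <- as.matrix(features)
  n <- nrow(x)
  stopifnot(n >= 3, subsample_fraction > 0.5, subsample_fraction < 1,
            all(k_range >= 2), all(k_range <= n - 1))
  if (n_subsamples < 50)
    warning("fewer than 50 subsamples gives unstable consensus estimates")
  if (scale) x <- zscore(x)
  m <- floor(subsample_fraction * n)

  k_range <- sort(unique(as.integer(k_range)))
  co_appear <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)

  with_seed(seed, {
    for (b in seq_len(n_subsamples)) {
      sub <- sort(sample.int(n, m))
      co_appear[sub, sub] <- co_appear[sub, sub] + 1
      hc <- stats::hclust(stats::dist(x[sub, , drop = FALSE]),
                          method = "ward.D2")
      for (ki in seq_along(k_range)) {
        lab <- stats::cutree(hc, k = k_range[ki])
        same <- outer(lab, lab, "==")
        co_cluster[[ki]][sub, sub] <- co_cluster[[ki]][sub, sub] + same
      }
    }
  })

  never <- co_appear == 0
  diag(never) <- FALSE
  if (any(never[upper.tri(never)]))
    warning(sum(never[upper.tri(never)]),
            " patient pair(s) never co-sampled; excluded from the CDF")

  consensus <- lapply(co_cluster, function(cc) {
    cm <- cc / ifelse(co_appear == 0, NA, co_appear)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(features), rownames(features))
    cm
  })
  entries <- lapply(consensus, function(cm) {
    v <- cm[upper.tri(cm)]
    v[!is.na(v)]
  })
  areas <- vapply(entries, function(v) 1 - mean(v), 0)
  deltas <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(deltas) <- names(areas)

  passing <- k_range[deltas > threshold]
  k_consensus <- as.integer(if (length(passing)) max(passing) else min(k_range))

  hc_full <- stats::hclust(stats::dist(x), method = "ward.D2")
  split_p <- NULL
  chosen_k <- k_consensus
  if (sigclust_gate && k_consensus >= 2) {
    split_p <- split_significance(x, hc_full, n_splits = k_consensus - 1,
                                  n_sim = n_sim, seed = seed,
                                  scale = FALSE)
    sig <- !is.na(split_p$p) & split_p$p < alpha
    run <- 0
    for (s in sig) {
      if (!s) break
      run <- run + 1
    }
    chosen_k <- max(2L, min(k_consensus, 1L + as.integer(run)))
  }
  labels <- stats::cutree(hc_full, k = chosen_k)
  if (refine) {
    centers <- t(vapply(seq_len(chosen_k), function(cl)
      colMeans(x[labels == cl, , drop = FALSE]), numeric(ncol(x))))
    km <- tryCatch(stats::kmeans(x, centers = centers, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km) && length(unique(km$cluster)) == chosen_k)
      labels <- km$cluster
  }
  names(labels) <- rownames(features)

  structure(list(k_range = k_range, consensus = consensus, areas = areas,
                 deltas = deltas, k_consensus = k_consensus,
                 chosen_k = chosen_k, labels = labels, split_p = split_p,
                 hclust = hc_full, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus clustering over k =",
      paste(x$k_range, collapse = ", "), "\n")
  cat("  CDF areas:", paste(sprintf("%s: %.3f", names(x$areas), x$areas),
                            collapse = ", "), "\n")
  cat("  chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Heatmap with dendrogram for a phenotype clustering
#'
#' Writes a standard heatmap (patients ordered by the Ward tree) annotated
#' with the top-split p-value to a PNG file.
#'
#' @param features numeric matrix, patients x features.
#' @param result a `consensus_result` (or `ward_clustering`).
#' @param path output PNG path.
#' @param top_p optional top-split p-value for the title.
#' @return `path`, invisibly.
#' @export
plot_phenotype_heatmap <- function(features, result, path, top_p = NULL) {
  x <- zscore(features)
  hc <- result$hclust
  if (is.null(top_p) && !is.null(result$split_p)) top_p <- result$split_p$p[1]
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  stats::heatmap(t(x), Colv = stats::as.dendrogram(hc), Rowv = NA,
                 scale = "none",
                 main = if (!is.null(top_p))
                   sprintf("radiomic phenotypes (top split p = %.3g)", top_p)
                 else "radiomic phenotypes")
  invisible(path)
}
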