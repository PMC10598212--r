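#' Spearman correlation matrix between imaging and clinical features
#'
#' Pairwise Spearman correlations (imaging features as rows, clinical /
#' biological features as columns) with two-sided p values adjusted by
#' Benjamini-Hochberg across the whole matrix. Missing values are handled
#' pairwise-complete, with the per-cell sample size recorded. Constant
#' columns yield missing correlations.
#'
#' @param imaging numeric matrix/data.frame, patients x imaging features.
#' @param clinical numeric matrix/data.frame, patients x clinical features,
#'   same row (patient) order.
#' @return list with matrices `r`, `p`, `p_adj`, `n`.
#' @export
correlation_matrix <- function(imaging, clinical) {
  imaging <- as.matrix(imaging); clinical <- as.matrix(clinical)
  stopifnot(nrow(imaging) == nrow(clinical), nrow(imaging) >= 5)
  ni <- ncol(imaging); nc <- ncol(clinical)
  r <- p <- n <- matrix(NA_real_, ni, nc,
                        dimnames = list(colnames(imaging), colnames(clinical)))
  for (a in seq_len(ni)) for (b in seq_len(nc)) {
    ok <- stats::complete.cases(imaging[, a], clinical[, b])
    n[a, b] <- sum(ok)
    x <- imaging[ok, a]; y <- clinical[ok, b]
    if (sum(ok) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      r[a, b] <- unname(ct$estimate)
      p[a, b] <- ct$p.value
    }
  }
  p_adj <- matrix(benjamini_hochberg(as.vector(p)), ni, nc,
                  dimnames = dimnames(p))
  list(r = r, p = p, p_adj = p_adj, n = n)
}

# mean over clusters of the best per-clinical-feature association,
# association = median (or max) |r| over cluster members
cluster_metric <- function(rmat, assignment, stat = c("median", "max")) {
  stat <- match.arg(stat)
  fun <- if (stat == "median") stats::median else max
  mean(vapply(split(seq_len(nrow(rmat)), assignment), function(members) {
    per_clin <- apply(abs(rmat[members, , drop = FALSE]), 2, fun, na.rm = TRUE)
    max(per_clin, na.rm = TRUE)
  }, numeric(1)))
}

#' Cluster imaging features by their clinical correlation profiles
#'
#' Imaging features are clustered hierarchically (average linkage on
#' Euclidean distances between the rows of the imaging-by-clinical Spearman
#' matrix). For every candidate k the cluster-to-clinical association
#' metric is the median absolute correlation over cluster members, taken
#' per clinical feature, maximized over clinical features and averaged over
#' clusters (a max-over-members variant is also computed). The chosen k is
#' the smallest k whose metric is within `plateau_tol` of the maximum over
#' the candidate range (the plateau rule).
#'
#' @param rmat correlation matrix (imaging rows x clinical columns), e.g.
#'   `correlation_matrix(...)$r`.
#' @param k_range candidate cluster numbers (default 2:12).
#' @param linkage hierarchical linkage method (default "average").
#' @param plateau_tol relative tolerance defining the plateau (default 0.02).
#' @return list of class `cluster_report`: `k`, `assignment` (named),
#'   `metric_curve` (data.frame k / metric_median / metric_max), `hclust`.
#' @export
choose_k_and_cluster <- function(rmat, k_range = 2:12, linkage = "average",
                                 plateau_tol = 0.02) {
  rmat <- as.matrix(rmat)
  if (max(k_range) > nrow(rmat))
    stop("k_range exceeds the number of imaging features (", nrow(rmat), ")")
  prof <- rmat
  prof[is.na(prof)] <- 0
  hc <- stats::hclust(stats::dist(prof), method = linkage)
  cuts <- stats::cutree(hc, k = k_range)
  if (length(k_range) == 1L) cuts <- matrix(cuts, ncol = 1)
  med <- vapply(seq_along(k_range), function(i)
    cluster_metric(rmat, cuts[, i], "median"), numeric(1))
  mx <- vapply(seq_along(k_range), function(i)
    cluster_metric(rmat, cuts[, i], "max"), numeric(1))
  plateau <- med >= (1 - plateau_tol) * max(med)
  k <- k_range[which(plateau)[1]]
  assignment <- stats::setNames(cuts[, match(k, k_range)], rownames(rmat))
  structure(list(k = k, assignment = assignment,
                 metric_curve = data.frame(k = k_range, metric_median = med,
                                           metric_max = mx),
                 hclust = hc),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("<cluster_report> k=", x$k, " over ", length(x$assignment),
      " imaging features\n", sep = "")
  print(table(x$assignment))
  invisible(x)
}

#' Per-cluster composition and best clinical associations
#'
#' Summarizes a clustering of imaging features: the fractional composition
#' of each cluster by feature class (volume / semantic / shape /
#' first-order / IVH / texture / rim / peripheral), the clinical feature
#' with the strongest median absolute member correlation (and that
#' r_median), and optionally the member most correlated with response.
#'
#' @param rmat imaging-by-clinical Spearman matrix.
#' @param assignment cluster assignment (from [choose_k_and_cluster]).
#' @param response_cor optional named vector of imaging-feature
#'   correlations with the response endpoint.
#' @return data.frame, one row per cluster.
#' @export
cluster_composition <- function(rmat, assignment, response_cor = NULL) {
  cls <- function(f) {
    if (grepl("^rim_ratio\\.", f)) "rim"
    else if (grepl("^peripheral_ratio\\.", f)) "peripheral"
    else if (grepl("^shape\\.", f)) "shape"
    else if (grepl("^fo\\.", f)) "first_order"
    else if (grepl("^ivh\\.", f)) "ivh"
    else if (grepl("^glcm\\.", f)) "texture"
    else if (grepl("^(vol|nles)", f)) "volume"
    else "semantic"
  }
  rows <- lapply(sort(unique(assignment)), function(cc) {
    members <- names(assignment)[assignment == cc]
    classes <- vapply(members, cls, character(1))
    comp <- table(factor(classes, levels = c("volume", "semantic", "shape",
                                             "first_order", "ivh", "texture",
                                             "rim", "peripheral"))) / length(members)
    med <- apply(abs(rmat[members, , drop = FALSE]), 2, stats::median, na.rm = TRUE)
    best <- which.max(med)
    top_resp <- NA_character_
    if (!is.null(response_cor)) {
      rc <- abs(response_cor[members])
      if (any(!is.na(rc))) top_resp <- members[which.max(rc)]
    }
    data.frame(cluster = cc, n_features = length(members),
               best_clinical = colnames(rmat)[best],
               r_median = unname(med[best]),
               top_response_feature = top_resp,
               t(as.numeric(comp)) |> `colnames<-`(paste0("frac_", names(comp))))
  })
  do.call(rbind, rows)
}

#' Non-negative matrix factorization (multiplicative updates)
#'
#' Rank-k factorization X ~ W H of a non-negative matrix minimizing the
#' Frobenius reconstruction error by multiplicative updates from a seeded
#' non-negative random initialisation.
#'
#' @param X non-negative numeric matrix.
#' @param k factorization rank.
#' @param max_iter maximum update sweeps (default 2000).
#' @param tol relative change in residual for convergence (default 1e-6).
#' @param seed RNG seed for the random initialisation.
#' @return list with `W`, `H`, `residual` (final Frobenius norm), and
#'   `converged`.
#' @export
nmf_factorize <- function(X, k, max_iter = 2000L, tol = 1e-6, seed = 1L) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)
  eps <- 1e-12
  res_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    res <- sqrt(sum((X - W %*% H)^2))
    if (is.finite(res_old) && abs(res_old - res) <= tol * max(res_old, eps)) {
      converged <- TRUE
      break
    }
    res_old <- res
  }
  if (!converged)
    warning("NMF did not converge; final residual ", signif(res, 6))
  list(W = W, H = H, residual = res, converged = converged)
}

#' Cross-check a feature clustering with NMF
#'
#' Correlation profiles are shifted to non-negative values via
#' x -> (x + 1)/2 (Spearman coefficients lie in \[-1, 1\]), factorized at
#' the chosen rank, and each feature assigned to its largest factor
#' loading. Agreement with the hierarchical assignment is reported as the
#' adjusted Rand index.
#'
#' @param rmat imaging-by-clinical Spearman matrix.
#' @param k number of factors (the chosen cluster count).
#' @param assignment hierarchical cluster assignment to compare against.
#' @param seed RNG seed for the NMF initialisation.
#' @return list with `membership`, `ari`, `residual`.
#' @export
nmf_crosscheck <- function(rmat, k, assignment, seed = 1L) {
  prof <- as.matrix(rmat)
  prof[is.na(prof)] <- 0
  X <- (prof + 1) / 2
  fit <- nmf_factorize(X, k, seed = seed)
  membership <- stats::setNames(apply(fit$W, 1, which.max), rownames(prof))
  list(membership = membership,
       ari = mclust::adjustedRandIndex(membership, assignment[names(membership)]),
       residual = fit$residual)
}
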