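#' Ensemble pipeline specification
#'
#' Configuration of the ensemble regressor: three base algorithms (elastic
#' net, RBF-kernel support vector regression, random forest), each preceded
#' by collinearity reduction, z-score standardization and univariable
#' F-statistic feature selection. Hyperparameters (including the selection
#' size k) are tuned by randomized search under k-fold cross-validation,
#' repeated over several seeds; the final prediction is the average over all
#' seed-by-algorithm members.
#'
#' @param algorithms subset of `c("elastic_net", "svr_rbf", "random_forest")`.
#' @param collinearity_threshold absolute Pearson correlation above which
#'   two features are considered duplicates (default 0.95).
#' @param cv_folds folds for hyperparameter scoring (default 5).
#' @param n_seeds number of repeated cross-validation seeds (default 5).
#' @param search_iterations randomized-search draws per algorithm per seed
#'   (default 60).
#' @param k_options candidate values for the univariable selection size;
#'   `Inf` means keep all surviving features.
#' @param hyper_ranges named list of per-algorithm hyperparameter ranges;
#'   see [default_hyper_ranges].
#' @return object of class `pipeline_spec`.
#' @export
pipeline_spec <- function(algorithms = c("elastic_net", "svr_rbf", "random_forest"),
                          collinearity_threshold = 0.95,
                          cv_folds = 5L, n_seeds = 5L,
                          search_iterations = 60L,
                          k_options = c(5, 10, 20, 40, Inf),
                          hyper_ranges = default_hyper_ranges()) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot(collinearity_threshold > 0, collinearity_threshold <= 1,
            cv_folds >= 2, n_seeds >= 1, search_iterations >= 1)
  structure(list(algorithms = algorithms,
                 collinearity_threshold = collinearity_threshold,
                 cv_folds = as.integer(cv_folds),
                 n_seeds = as.integer(n_seeds),
                 search_iterations = as.integer(search_iterations),
                 k_options = k_options,
                 hyper_ranges = hyper_ranges),
            class = "pipeline_spec")
}

#' Default randomized-search ranges
#'
#' Elastic net: penalty strength log-uniform on \[1e-3, 1e2\], mixing
#' uniform on \[0.05, 1\]. SVR-RBF: cost log-uniform \[1e-2, 1e3\], gamma
#' log-uniform \[1e-4, 1e1\], epsilon uniform \[0.01, 1\]. Random forest:
#' 100-500 trees, max depth 2-10 or unlimited, minimum node size 1-10.
#'
#' @return named list of ranges.
#' @export
default_hyper_ranges <- function() {
  list(elastic_net = list(log10_lambda = c(-3, 2), alpha = c(0.05, 1)),
       svr_rbf = list(log10_cost = c(-2, 3), log10_gamma = c(-4, 1),
                      epsilon = c(0.01, 1)),
       random_forest = list(num_trees = c(100L, 500L), max_depth = c(2L, 10L),
                            min_node = c(1L, 10L)))
}

#' Collinearity reduction
#'
#' Builds a graph with an edge between every feature pair whose absolute
#' Pearson correlation exceeds the threshold; within each connected
#' component only the feature with the largest absolute correlation with
#' the response survives (ties broken by column order). Constant columns
#' are dropped and logged.
#'
#' @param X numeric matrix, no missing values.
#' @param y response vector.
#' @param threshold correlation threshold (default 0.95).
#' @return character vector of kept column names, in original column order.
#' @export
reduce_collinearity <- function(X, y, threshold = 0.95) {
  stopifnot(nrow(X) >= 2, !anyNA(X))
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    message("dropping ", sum(const), " constant feature(s)")
  keep_cols <- colnames(X)[!const]
  Xk <- X[, keep_cols, drop = FALSE]
  p <- ncol(Xk)
  if (p == 0) return(character(0))
  cm <- abs(stats::cor(Xk))
  ry <- abs(stats::cor(Xk, y))[, 1]
  adj <- cm > threshold
  diag(adj) <- FALSE
  comp <- integer(p)
  cur <- 0L
  for (i in seq_len(p)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  survivors <- vapply(seq_len(cur), function(cc) {
    members <- which(comp == cc)
    members[which.max(ry[members])]          # first max: column-order tie-break
  }, integer(1))
  keep_cols[sort(survivors)]
}

#' Univariable F-statistic feature selection
#'
#' Ranks features by the F statistic of the univariable regression of the
#' response on each feature (equal to the square of the t statistic) and
#' keeps the top k, with deterministic column-order tie-breaking. `k`
#' larger than the feature count keeps everything.
#'
#' @param X numeric matrix.
#' @param y response.
#' @param k number of features to keep.
#' @return character vector of selected column names (decreasing F order).
#' @export
select_univariable <- function(X, y, k) {
  stopifnot(k >= 1)
  f <- univariable_f(X, y)
  ord <- order(-f, seq_along(f))
  colnames(X)[ord[seq_len(min(k, ncol(X)))]]
}

univariable_f <- function(X, y) {
  n <- nrow(X)
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[is.na(r)] <- 0
  r2 <- pmin(r^2, 1 - 1e-12)
  r2 * (n - 2) / (1 - r2)
}

# fit preprocessing state on training rows only
fit_prep <- function(X, y, threshold) {
  means <- colMeans(X, na.rm = TRUE)
  means[is.na(means)] <- 0
  Xi <- impute_matrix(X, means)
  kept <- reduce_collinearity_quiet(Xi, y, threshold)
  Xk <- Xi[, kept, drop = FALSE]
  ctr <- colMeans(Xk)
  scl <- apply(Xk, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(Xk, ctr, scl)
  f <- univariable_f(Xs, y)
  ord <- order(-f, seq_along(f))
  list(impute_means = means, kept = kept, center = ctr, scale = scl,
       f_order = kept[ord])
}

reduce_collinearity_quiet <- function(X, y, threshold)
  suppressMessages(reduce_collinearity(X, y, threshold))

impute_matrix <- function(X, means) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- means[[colnames(X)[j]]]
  }
  X
}

# standardized, selected design matrix for a fitted prep and selection size k
apply_prep <- function(prep, X, k) {
  full <- matrix(NA_real_, nrow(X), length(prep$impute_means),
                 dimnames = list(rownames(X), names(prep$impute_means)))
  common <- intersect(colnames(X), colnames(full))
  full[, common] <- as.matrix(X[, common, drop = FALSE])
  full <- impute_matrix(full, prep$impute_means)
  sel <- prep$f_order[seq_len(min(k, length(prep$f_order)))]
  scale(full[, sel, drop = FALSE],
        prep$center[sel], prep$scale[sel])
}

draw_config <- function(algorithm, ranges, k_options, p_available) {
  k <- sample(k_options, 1L)
  rg <- ranges[[algorithm]]
  hp <- switch(algorithm,
    elastic_net = list(lambda = 10^stats::runif(1, rg$log10_lambda[1], rg$log10_lambda[2]),
                       alpha = stats::runif(1, rg$alpha[1], rg$alpha[2])),
    svr_rbf = list(cost = 10^stats::runif(1, rg$log10_cost[1], rg$log10_cost[2]),
                   gamma = 10^stats::runif(1, rg$log10_gamma[1], rg$log10_gamma[2]),
                   epsilon = stats::runif(1, rg$epsilon[1], rg$epsilon[2])),
    random_forest = list(num_trees = sample(rg$num_trees[1]:rg$num_trees[2], 1L),
                         max_depth = sample(c(rg$max_depth[1]:rg$max_depth[2], 0L), 1L),
                         min_node = sample(rg$min_node[1]:rg$min_node[2], 1L),
                         rf_seed = sample.int(.Machine$integer.max - 1L, 1L)))
  list(k = k, hp = hp)
}

fit_algorithm <- function(algorithm, Xs, y, hp) {
  switch(algorithm,
    elastic_net = glmnet::glmnet(Xs, y, alpha = hp$alpha, lambda = hp$lambda,
                                 standardize = FALSE),
    svr_rbf = e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                         cost = hp$cost, gamma = hp$gamma, epsilon = hp$epsilon,
                         scale = FALSE),
    random_forest = ranger::ranger(
      x = as.data.frame(Xs), y = y, num.trees = hp$num_trees,
      max.depth = hp$max_depth, min.node.size = hp$min_node,
      seed = hp$rf_seed, num.threads = 1L, importance = "impurity"))
}

predict_algorithm <- function(algorithm, model, Xs) {
  switch(algorithm,
    elastic_net = as.vector(stats::predict(model, Xs)),
    svr_rbf = as.vector(stats::predict(model, Xs)),
    random_forest = stats::predict(model, data = as.data.frame(Xs),
                                   num.threads = 1L)$predictions)
}

#' Fit the ensemble regressor
#'
#' For each of `n_seeds` cross-validation seeds, a randomized search over
#' hyperparameters (including the univariable selection size) is scored by
#' k-fold cross-validated mean squared error for each base algorithm; the
#' best configuration per algorithm is refit on the whole training set. All
#' preprocessing (imputation means, collinearity pruning, standardization,
#' F-ranking) is fitted inside the training data of each fold, so held-out
#' rows never influence fitted state. The frozen model predicts as the
#' unweighted mean over all seed-by-algorithm members.
#'
#' @param X training feature matrix (or data.frame) with named columns;
#'   missing values are imputed with training-column means.
#' @param y numeric response (finite).
#' @param spec a [pipeline_spec].
#' @param base_seed first cross-validation seed; the seeds used are
#'   `base_seed + 0:(n_seeds-1)` (default 0, giving seeds 0..4).
#' @return object of class `ensemble_model`.
#' @export
fit_ensemble <- function(X, y, spec = pipeline_spec(), base_seed = 0L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(y))) stop("response must be finite")
  n <- nrow(X)
  if (n < 2 * spec$cv_folds)
    stop("need at least ", 2 * spec$cv_folds, " samples for ",
         spec$cv_folds, "-fold tuning")
  full_prep <- fit_prep(X, y, spec$collinearity_threshold)
  members <- list()
  for (si in seq_len(spec$n_seeds)) {
    seed_val <- as.integer(base_seed) + si - 1L
    set.seed(seed_val)
    fold_id <- sample(rep(seq_len(spec$cv_folds), length.out = n))
    configs <- lapply(spec$algorithms, function(alg)
      lapply(seq_len(spec$search_iterations), function(i)
        draw_config(alg, spec$hyper_ranges, spec$k_options, ncol(X))))
    names(configs) <- spec$algorithms
    fold_preps <- lapply(seq_len(spec$cv_folds), function(f) {
      tr <- fold_id != f
      if (stats::sd(y[tr]) == 0) {
        warning("fold ", f, " has constant response; skipped")
        return(NULL)
      }
      fit_prep(X[tr, , drop = FALSE], y[tr], spec$collinearity_threshold)
    })
    for (alg in spec$algorithms) {
      fold_mse <- vapply(configs[[alg]], function(cfg) {
        vapply(seq_len(spec$cv_folds), function(f) {
          prep <- fold_preps[[f]]
          if (is.null(prep)) return(NA_real_)
          tr <- fold_id != f
          Xtr <- apply_prep(prep, X[tr, , drop = FALSE], cfg$k)
          Xva <- apply_prep(prep, X[!tr, , drop = FALSE], cfg$k)
          fitv <- fit_algorithm(alg, Xtr, y[tr], cfg$hp)
          pv <- predict_algorithm(alg, fitv, Xva)
          mean((pv - y[!tr])^2)
        }, numeric(1))
      }, numeric(spec$cv_folds))
      if (spec$cv_folds == 1L) fold_mse <- matrix(fold_mse, nrow = 1)
      cv_mse <- colMeans(fold_mse, na.rm = TRUE)
      cv_mse[!is.finite(cv_mse)] <- Inf
      # one-standard-error parsimony rule: among configurations within one
      # standard error of the best cross-validated MSE, prefer the smallest
      # univariable selection size (then draw order)
      bi <- which.min(cv_mse)
      se1 <- stats::sd(fold_mse[, bi], na.rm = TRUE) /
        sqrt(sum(!is.na(fold_mse[, bi])))
      if (!is.finite(se1)) se1 <- 0
      cand <- which(cv_mse <= cv_mse[bi] + se1)
      ks <- vapply(configs[[alg]][cand], function(cfg) cfg$k, numeric(1))
      best_idx <- cand[order(ks, seq_along(cand))[1]]
      best <- configs[[alg]][[best_idx]]
      cv_mse <- cv_mse[best_idx]
      sel <- full_prep$f_order[seq_len(min(best$k, length(full_prep$f_order)))]
      Xs <- apply_prep(full_prep, X, best$k)
      model <- fit_algorithm(alg, Xs, y, best$hp)
      members[[length(members) + 1L]] <- list(
        seed = seed_val, algorithm = alg, k = best$k, hp = best$hp,
        cv_mse = min(cv_mse), selected = sel, model = model)
    }
  }
  structure(list(members = members, prep = full_prep, spec = spec,
                 feature_names = colnames(X), n_train = n,
                 base_seed = as.integer(base_seed), frozen = TRUE),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " members (",
      x$spec$n_seeds, " seeds x ", length(x$spec$algorithms),
      " algorithms), trained on n=", x$n_train, ", p=",
      length(x$feature_names), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted ensemble
#'
#' Columns of `newdata` are mapped to the training schema by name; columns
#' absent from `newdata` (and any missing values) are imputed with the
#' stored training-set means. The prediction is the unweighted mean over
#' all members, equivalently the mean over seeds of the per-seed mean over
#' the three algorithm pipelines.
#'
#' @param object an `ensemble_model`.
#' @param newdata matrix or data.frame with named columns.
#' @param per_member return the member-by-row prediction matrix instead of
#'   the averaged scores.
#' @param ... unused.
#' @return numeric vector of predicted response scores (or a matrix when
#'   `per_member = TRUE`).
#' @export
predict.ensemble_model <- function(object, newdata, per_member = FALSE, ...) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  if (!length(intersect(colnames(newdata), object$feature_names)))
    stop("no columns of newdata match the training schema; expected: ",
         paste(utils::head(object$feature_names, 5), collapse = ", "), ", ...")
  preds <- vapply(object$members, function(mb) {
    Xs <- apply_prep(object$prep, newdata, mb$k)
    predict_algorithm(mb$algorithm, mb$model, Xs)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) preds <- matrix(preds, nrow = 1L)
  if (per_member) return(preds)
  rowMeans(preds)
}
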