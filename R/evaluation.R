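#' Rank-based AUC of scores against a binary class
#'
#' Area under the ROC curve computed through the Mann-Whitney U statistic
#' with mid-rank handling of ties: AUC = U / (n1 * n0), the probability that
#' a random positive outranks a random negative.
#'
#' @param scores numeric scores (larger = more positive-like).
#' @param classes logical/0-1 vector.
#' @return AUC in \[0, 1\]; 0.5 when scores are constant or a class is empty.
#' @export
auc_rank <- function(scores, classes) {
  classes <- as.logical(classes)
  n1 <- sum(classes); n0 <- sum(!classes)
  if (n1 == 0 || n0 == 0 || stats::sd(scores) == 0) return(0.5)
  r <- rank(scores)
  (sum(r[classes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous score and a binary group
#' indicator, with a two-tailed p value from the t transform on n - 2
#' degrees of freedom.
#'
#' @param scores numeric vector.
#' @param groups logical/0-1 group indicator; both groups must be non-empty.
#' @return list with `r` and `p`.
#' @export
point_biserial <- function(scores, groups) {
  g <- as.numeric(as.logical(groups))
  if (length(unique(g)) < 2) stop("both groups must be non-empty")
  n <- length(scores)
  r <- stats::cor(scores, g)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' the input order is preserved in the output.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return adjusted p values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Mann-Whitney U comparison of two groups
#'
#' U is computed with mid-rank ties. For small samples (both groups of size
#' at most `exact_max` and no ties) the exact permutation distribution is
#' used; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param values numeric vector.
#' @param groups two-level factor/logical splitting `values`.
#' @param exact_max exact-branch size limit per group (default 8).
#' @return list with `U` (first group), `p`, and `exact` flag.
#' @export
group_compare <- function(values, groups, exact_max = 8) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("groups must have exactly two levels")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(x) == length(y) && all(sort(x) == sort(y))) {
    # identical samples: no evidence of a shift
    U <- length(x) * length(y) / 2
    return(list(U = U, p = 1, exact = FALSE))
  }
  use_exact <- max(length(x), length(y)) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = use_exact)
}

#' Validation metrics for predicted response scores
#'
#' Calibration and discrimination of predicted versus observed volumetric
#' response: mean squared error; Pearson and Spearman correlations with
#' two-sided p values; AUC of the scores against the binary responder
#' classes of the four volumetric criteria (scores are negated for AUC so
#' that larger = more responder-like, since more negative predicted
#' response means more shrinkage); and, when RECIST labels are supplied,
#' the responder-vs-rest AUC and point-biserial tests for responder-vs-rest
#' and progression-vs-rest splits plus the ordinal Spearman correlation.
#'
#' @param scores predicted response scores.
#' @param responses observed log volume ratios.
#' @param labels optional RECIST-style labels; values in
#'   `c("CR", "PR", "SD", "PD")`.
#' @return list of class `validation_report`.
#' @export
validation_metrics <- function(scores, responses, labels = NULL) {
  stopifnot(length(scores) == length(responses))
  n <- length(scores)
  mse <- mean((scores - responses)^2)
  cor_block <- function(method) {
    if (n < 3 || stats::sd(scores) == 0 || stats::sd(responses) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(scores, responses, method = method))
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  pe <- cor_block("pearson")
  sp <- cor_block("spearman")
  criteria <- c("recist30", "who50", "sphere65", "ellipsoid30")
  aucs <- vapply(criteria, function(cr)
    auc_rank(-scores, classify_volumetric_response(responses, cr)), numeric(1))
  out <- list(n = n, mse = mse,
              pearson_r = pe$r, pearson_p = pe$p,
              spearman_r = sp$r, spearman_p = sp$p,
              auc = aucs)
  if (!is.null(labels)) {
    responder <- labels %in% c("CR", "PR")
    progression <- labels == "PD"
    out$auc_recist_label <- auc_rank(-scores, responder)
    if (length(unique(responder)) == 2)
      out$pb_responder <- point_biserial(-scores, responder)
    if (length(unique(progression)) == 2)
      out$pb_progression <- point_biserial(scores, progression)
    ordinal <- ifelse(responder, 0, ifelse(progression, 2, 1))
    if (stats::sd(ordinal) > 0 && stats::sd(scores) > 0)
      out$spearman_ordinal <- unname(suppressWarnings(
        stats::cor.test(scores, ordinal, method = "spearman"))$estimate)
  }
  structure(out, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> n=", x$n, "  MSE=", signif(x$mse, 4),
      "  Spearman r=", signif(x$spearman_r, 3),
      " (p=", signif(x$spearman_p, 3), ")\n", sep = "")
  cat("  AUC:", paste(names(x$auc), signif(x$auc, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Feature selection frequency and importance report
#'
#' Counts, for every feature, the number of ensemble members (seeds times
#' algorithms, 15 for the default configuration) in which it survived the
#' collinearity-reduction and univariable-selection steps. Importances are
#' available for the elastic net (absolute coefficients) and random forest
#' (impurity importance) members only; each member's importances are
#' normalized to sum 1 over its selected features and then averaged across
#' the seeds and the two algorithms (non-selected features contribute 0).
#' The report keeps features selected in at least `min_seeds` distinct
#' seeds (default 3 of 5), for robustness.
#'
#' @param model an `ensemble_model`.
#' @param min_seeds minimum distinct seeds a feature must be selected in to
#'   be reported (default 3).
#' @return data.frame with `feature`, `selection_count`, `n_seeds_selected`,
#'   `importance`, sorted by decreasing selection count then importance.
#' @export
importance_report <- function(model, min_seeds = 3L) {
  stopifnot(inherits(model, "ensemble_model"))
  feats <- model$feature_names
  sel_count <- stats::setNames(integer(length(feats)), feats)
  seed_sel <- list()
  imp_sum <- stats::setNames(numeric(length(feats)), feats)
  n_imp_members <- 0L
  for (mb in model$members) {
    sel_count[mb$selected] <- sel_count[mb$selected] + 1L
    key <- as.character(mb$seed)
    seed_sel[[key]] <- union(seed_sel[[key]], mb$selected)
    imp <- NULL
    if (mb$algorithm == "elastic_net") {
      co <- as.vector(stats::coef(mb$model))[-1]
      imp <- stats::setNames(abs(co), mb$selected)
    } else if (mb$algorithm == "random_forest") {
      imp <- mb$model$variable.importance
      imp <- pmax(imp, 0)
    }
    if (!is.null(imp)) {
      n_imp_members <- n_imp_members + 1L
      if (sum(imp) > 0) imp <- imp / sum(imp)
      imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
    }
  }
  n_seeds_selected <- vapply(feats, function(f)
    sum(vapply(seed_sel, function(s) f %in% s, logical(1))), integer(1))
  avg_imp <- if (n_imp_members > 0) imp_sum / n_imp_members else imp_sum
  rep <- data.frame(feature = feats,
                    selection_count = unname(sel_count),
                    n_seeds_selected = unname(n_seeds_selected),
                    importance = unname(avg_imp))
  rep <- rep[rep$n_seeds_selected >= min_seeds, , drop = FALSE]
  rep[order(-rep$selection_count, -rep$importance), , drop = FALSE]
}
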