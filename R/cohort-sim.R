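#' Specification of a simulated patient cohort
#'
#' A cohort of independent standard-normal features with an optional
#' planted linear signal, collinear duplicate columns at a target
#' correlation, and a missingness pattern. The response is interpreted on
#' the log-volume-ratio scale and clipped to \[-9.2, 1\] (from the
#' complete-response floor at one end to modest progression at the other),
#' and RECIST-like labels are derived from the volumetric thresholds.
#'
#' @param n_patients cohort size.
#' @param n_features number of base features (named `x1..xp`).
#' @param beta named numeric vector of planted coefficients over a subset
#'   of the features (default none: a null cohort).
#' @param noise_sd residual standard deviation (>= 0).
#' @param collinear list of `list(feature =, copy_of =, r =)` entries
#'   appending duplicate columns at population correlation `r` (|r| < 1).
#' @param missing named numeric vector: fraction of rows set missing per
#'   feature.
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_features, beta = numeric(0),
                        noise_sd = 0.1, collinear = list(),
                        missing = numeric(0), seed = 1L) {
  stopifnot(n_patients >= 2, n_features >= 1, noise_sd >= 0)
  feature_names <- paste0("x", seq_len(n_features))
  if (length(beta) && !all(names(beta) %in% feature_names))
    stop("beta names must be a subset of the generated features")
  for (cp in collinear) {
    stopifnot(!is.null(cp$feature), cp$copy_of %in% feature_names)
    if (abs(cp$r) >= 1) stop("duplicate correlation |r| must be < 1")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 beta = beta, noise_sd = noise_sd, collinear = collinear,
                 missing = missing, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort with planted feature-response structure
#'
#' @param spec a [cohort_spec].
#' @return list with `features` (data.frame), `response` (numeric, log
#'   volume ratio scale), `labels` (RECIST-like CR/PR/SD/PD), `beta`
#'   (full named coefficient vector) and `support` (names of informative
#'   features).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  p <- spec$n_features
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- stats::setNames(numeric(p), colnames(X))
  beta[names(spec$beta)] <- spec$beta
  y <- as.vector(X %*% beta) + stats::rnorm(n, 0, spec$noise_sd)
  y <- pmin(pmax(y, -9.2), 1)
  for (cp in spec$collinear) {
    src <- X[, cp$copy_of]
    X <- cbind(X, cp$r * src + sqrt(1 - cp$r^2) * stats::rnorm(n))
    colnames(X)[ncol(X)] <- cp$feature
  }
  for (f in names(spec$missing)) {
    k <- round(spec$missing[[f]] * n)
    if (k > 0) X[sample.int(n, k), f] <- NA
  }
  reduction <- 1 - exp(y)
  labels <- ifelse(reduction >= 0.99, "CR",
            ifelse(reduction >= 0.30, "PR",
            ifelse(exp(y) >= 1.2, "PD", "SD")))
  list(features = as.data.frame(X), response = y, labels = labels,
       beta = beta, support = names(spec$beta))
}
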