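# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities from first principles (per-pixel loops, exhaustive
# pair enumeration) rather than calling the package's vectorized paths.

# 2-D physical-margin morphology, per the set definition: a pixel is in the
# erosion iff every pixel whose centre lies within the physical radius
# around it belongs to the mask (outside the grid counts as background);
# it is in the dilation iff at least one mask pixel lies within the radius.
oracle_morph_slice <- function(sl, margin_mm, mode, sp) {
  d <- dim(sl)
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ok <- if (mode == "erode") TRUE else FALSE
    for (di in -ceiling(margin_mm / sp[1]):ceiling(margin_mm / sp[1])) {
      for (dj in -ceiling(margin_mm / sp[2]):ceiling(margin_mm / sp[2])) {
        if ((di * sp[1])^2 + (dj * sp[2])^2 > margin_mm^2 + 1e-9) next
        ii <- i + di; jj <- j + dj
        inside <- ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && sl[ii, jj]
        if (mode == "erode" && !inside) { ok <- FALSE; break }
        if (mode == "dilate" && inside) { ok <- TRUE; break }
      }
      if (mode == "erode" && !ok) break
      if (mode == "dilate" && ok) break
    }
    out[i, j] <- ok
  }
  out
}

# Exhaustive-pair GLCM oracle: enumerates every ordered pixel pair per
# in-plane direction over all slices, accumulates counts, normalizes per
# direction and averages over non-empty directions.
oracle_glcm <- function(mask, image, n_levels, max_hu = 1000, floor_hu = -100) {
  d <- dim(mask)
  vox <- image$voxels
  lev <- array(NA_integer_, d)
  for (lin in which(mask)) {
    v <- vox[lin]
    if (v < floor_hu) next
    v <- min(max(v, floor_hu), max_hu)
    lev[lin] <- min(n_levels, 1L + floor((v - floor_hu) / (max_hu - floor_hu) * n_levels))
  }
  dirs <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  mats <- lapply(dirs, function(o) matrix(0, n_levels, n_levels))
  for (k in seq_len(d[3])) for (di in seq_along(dirs)) {
    o <- dirs[[di]]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      a <- lev[i, j, k]
      if (is.na(a)) next
      for (sgn in c(1L, -1L)) {           # symmetric: both ordered pairs
        ii <- i + sgn * o[1]; jj <- j + sgn * o[2]
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2]) next
        b <- lev[ii, jj, k]
        if (is.na(b)) next
        mats[[di]][a, b] <- mats[[di]][a, b] + 1
      }
    }
  }
  sums <- vapply(mats, sum, numeric(1))
  if (all(sums == 0)) return(NULL)
  keep <- which(sums > 0)
  Reduce(`+`, lapply(keep, function(k) mats[[k]] / sums[k])) / length(keep)
}

# Haralick statistics recomputed with plain elementwise loops.
oracle_haralick_stats <- function(P) {
  N <- nrow(P)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:N) * px); muy <- sum((1:N) * py)
  sx <- sqrt(sum(((1:N) - mux)^2 * px)); sy <- sqrt(sum(((1:N) - muy)^2 * py))
  psum <- numeric(2 * N); pdiff <- numeric(N)
  asm <- contrast <- idm <- ent <- ssq <- autoc <- shade <- prom <- diss <- corr_n <- 0
  HXY1 <- HXY2 <- 0
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
    asm <- asm + p^2
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    ent <- ent - p * lg(p)
    ssq <- ssq + (i - mux)^2 * p
    autoc <- autoc + i * j * p
    shade <- shade + (i + j - mux - muy)^3 * p
    prom <- prom + (i + j - mux - muy)^4 * p
    diss <- diss + abs(i - j) * p
    corr_n <- corr_n + i * j * p
    HXY1 <- HXY1 - p * lg(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  sum_avg <- sum(seq_along(psum) * psum)
  sum_var <- sum((seq_along(psum) - sum_avg)^2 * psum)
  sum_ent <- -sum(vapply(psum, function(q) q * lg(q), numeric(1)))
  mean_d <- sum((seq_along(pdiff) - 1) * pdiff)
  diff_var <- sum((seq_along(pdiff) - 1 - mean_d)^2 * pdiff)
  diff_ent <- -sum(vapply(pdiff, function(q) q * lg(q), numeric(1)))
  HX <- -sum(vapply(px, function(q) q * lg(q), numeric(1)))
  HY <- -sum(vapply(py, function(q) q * lg(q), numeric(1)))
  corr <- if (sx > 0 && sy > 0) (corr_n - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(HX, HY) > 0) (ent - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - ent))))
  c(asm, contrast, corr, ssq, idm, sum_avg, sum_var, sum_ent, ent,
    diff_var, diff_ent, imc1, imc2, autoc, shade, prom, diss, max(P))
}

# AUC by exhaustive positive/negative pair counting.
oracle_auc_pairs <- function(scores, classes) {
  pos <- scores[as.logical(classes)]
  neg <- scores[!as.logical(classes)]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# random in-plane blob phantom used by texture tests
random_blob_image <- function(dims, seed, hu_range = c(-50, 400),
                              density = 0.6, spacing = c(1, 1, 5)) {
  set.seed(seed)
  mask <- array(stats::runif(prod(dims)) < density, dims)
  if (!any(mask)) mask[1] <- TRUE
  vox <- array(stats::runif(prod(dims), hu_range[1], hu_range[2]), dims)
  list(mask = mask, image = image_volume(vox, spacing))
}
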