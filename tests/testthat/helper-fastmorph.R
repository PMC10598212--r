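# Per-pixel disc-membership morphology oracle, vectorized over the offsets
# of one pixel (still a direct transcription of the set definition; used for
# the larger acceptance-scale masks where the doubly-looped oracle is slow).
oracle_morph_slice_fast <- function(sl, margin_mm, mode, sp) {
  d <- dim(sl)
  a <- ceiling(margin_mm / sp[1]); b <- ceiling(margin_mm / sp[2])
  g <- as.matrix(expand.grid(di = -a:a, dj = -b:b))
  g <- g[(g[, 1] * sp[1])^2 + (g[, 2] * sp[2])^2 <= margin_mm^2 + 1e-9, ,
         drop = FALSE]
  out <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ii <- i + g[, 1]; jj <- j + g[, 2]
    inb <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    vals <- logical(nrow(g))                     # outside grid = background
    vals[inb] <- sl[cbind(ii[inb], jj[inb])]
    out[i, j] <- if (mode == "erode") all(vals) else any(vals)
  }
  out
}
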