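# simulated cohort with 3 planted imaging-feature blocks, each a noisy copy
# of one clinical driver
planted_block_data <- function(n = 100, per_block = 8, noise = 0.55, seed = 1L) {
  set.seed(seed)
  drivers <- matrix(rnorm(n * 3), n, 3,
                    dimnames = list(NULL, c("ca125", "tp53_maf", "age")))
  clinical <- cbind(drivers, figo_ordinal = rnorm(n), tmad = rnorm(n))
  imaging <- NULL
  truth <- integer(0)
  for (b in 1:3) for (f in seq_len(per_block)) {
    imaging <- cbind(imaging, drivers[, b] + noise * rnorm(n))
    truth <- c(truth, b)
  }
  colnames(imaging) <- paste0("img", seq_len(ncol(imaging)))
  list(imaging = imaging, clinical = clinical, truth = truth)
}
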