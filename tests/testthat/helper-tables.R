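# small labelled feature tables with two Gaussian-blob features, used by the
# classifier and evaluation tests
blob_tab <- function(n, d, p_noise = 0, seed = 1,
                     split = "construction-train") {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  x <- cbind(f1 = rnorm(n) + d * y, f2 = rnorm(n) + d * y)
  if (p_noise > 0) {
    nz <- matrix(rnorm(n * p_noise), n,
                 dimnames = list(NULL, paste0("nz", seq_len(p_noise))))
    x <- cbind(x, nz)
  }
  data.frame(id = seq_len(n), centre = "A", trg = ifelse(y == 1, 1, 4),
             label = ifelse(y == 1, "responder", "nonresponder"),
             split = split, provenance = "manual", x, check.names = FALSE)
}
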