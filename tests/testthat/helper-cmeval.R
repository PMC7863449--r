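# Shared test helpers: independent oracles kept deliberately naive.

# Brute-force enumeration of all confusion matrices of size n via
# expand.grid — independent of enumerateCMs().
enumOracle <- function(n) {
  g <- expand.grid(tp = 0:n, fn = 0:n, fp = 0:n)
  g <- g[g$tp + g$fn + g$fp <= n, ]
  g$tn <- n - g$tp - g$fn - g$fp
  as.matrix(g)
}

# Reconstruct the reference/predicted label vectors a confusion matrix
# tabulates (order is immaterial for correlation).
labelsFromCM <- function(tp, fn, fp, tn) {
  list(ref  = rep(c(1, 1, 0, 0), c(tp, fn, fp, tn)),
       pred = rep(c(1, 0, 1, 0), c(tp, fn, fp, tn)))
}

# Random valid count matrices of total n (uniform over compositions,
# implemented independently of sampleCMs).
randomCMs <- function(k, n) {
  n <- as.integer(n)
  t(vapply(seq_len(k), function(i) {
    cuts <- sort(sample.int(n + 3L, 3L))
    c(tp = cuts[1] - 1L, fn = cuts[2] - cuts[1] - 1L,
      fp = cuts[3] - cuts[2] - 1L, tn = n + 3L - cuts[3])
  }, integer(4)))
}

# Rows with all four marginals positive (phi and beta strictly inside
# (0, 1)): the domain of every prevalence/bias identity.
nonDegenerate <- function(m) {
  m[m[, "tp"] + m[, "fn"] > 0 & m[, "tn"] + m[, "fp"] > 0 &
    m[, "tp"] + m[, "fp"] > 0 & m[, "tn"] + m[, "fn"] > 0, , drop = FALSE]
}
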