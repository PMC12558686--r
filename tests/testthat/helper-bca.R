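# Independently coded brute-force BCa oracle for the sample mean: the same
# documented resampling convention (one sample.int(n, n, TRUE) per replicate
# after set.seed), then its own bias-correction, jackknife acceleration and
# normal-scale-interpolated percentile endpoints.
brute_force_bca <- function(x, B, seed, conf = 0.95) {
  n <- length(x)
  t0 <- mean(x)
  set.seed(seed)
  t <- numeric(B)
  for (b in seq_len(B)) t[b] <- mean(x[sample.int(n, n, replace = TRUE)])
  z0 <- qnorm((sum(t < t0) + 0.5 * sum(t == t0)) / B)
  jk <- vapply(seq_len(n), function(i) mean(x[-i]), numeric(1))
  dd <- mean(jk) - jk
  a <- sum(dd^3) / (6 * sum(dd^2)^1.5)
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  adj <- pnorm(z0 + (z0 + qnorm(alpha)) / (1 - a * (z0 + qnorm(alpha))))
  ts <- sort(t)
  ends <- vapply(adj, function(al) {
    r <- (B + 1) * al
    if (r <= 1) return(ts[1])
    if (r >= B) return(ts[B])
    lo <- floor(r)
    g <- (qnorm(al) - qnorm(lo / (B + 1))) /
      (qnorm((lo + 1) / (B + 1)) - qnorm(lo / (B + 1)))
    (1 - g) * ts[lo] + g * ts[lo + 1]
  }, numeric(1))
  list(ci = ends, z0 = z0, a = a, t = t)
}
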