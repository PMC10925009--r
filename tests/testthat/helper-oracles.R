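# Independent oracles and fixture generators used across the suite.

# All codewords of the length-m, residue-0, modulus-2m code, by exhaustive
# enumeration of every m-bit word (independent of the systematic encoder).
enumerate_codewords <- function(m) {
  U <- 2L * m
  out <- list()
  for (v in 0:(2^m - 1L)) {
    bits <- int_to_bits(v, m)
    if (sum(seq_len(m) * bits) %% U == 0L) out[[length(out) + 1L]] <- bits
  }
  out
}

# Naive SSIM: direct sliding-window evaluation with an explicit double loop
# over window positions, weighted means computed from first principles.
naive_ssim <- function(a, b, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                       L = 1) {
  x <- seq_len(window) - (window + 1) / 2
  k1d <- exp(-x^2 / (2 * sigma^2))
  w <- outer(k1d, k1d)
  w <- w / sum(w)
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  h <- (window - 1L) / 2L
  vals <- c()
  for (i in (h + 1L):(nrow(a) - h)) {
    for (j in (h + 1L):(ncol(a) - h)) {
      wa <- a[(i - h):(i + h), (j - h):(j + h)]
      wb <- b[(i - h):(i + h), (j - h):(j + h)]
      mu_a <- sum(w * wa); mu_b <- sum(w * wb)
      va <- sum(w * wa^2) - mu_a^2
      vb <- sum(w * wb^2) - mu_b^2
      cab <- sum(w * wa * wb) - mu_a * mu_b
      vals <- c(vals, ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
                  ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

random_bits <- function(n) sample(0:1, n, replace = TRUE)

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# apply one complement transversion (T<->A or C<->G) at a deterministic
# position of a sequence; such substitutions keep every pair valid
complement_transversion <- function(seq, pos = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[pos] <- chartr("ACGT", "TGCA", chars[pos])
  paste(chars, collapse = "")
}
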