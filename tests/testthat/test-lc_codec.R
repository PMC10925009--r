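test_that("code geometry follows the systematic construction", {
  p <- lc_params(12)
  expect_equal(p$m, 18L)
  expect_equal(p$U, 36L)
  expect_equal(p$m - p$l, 6L)  # six check bits
  expect_equal(p$parity_positions, c(1L, 2L, 4L, 8L, 16L, 18L))

  p1 <- lc_params(1)
  expect_equal(p1$m, 4L)
  expect_equal(p1$U, 8L)
  expect_equal(p1$parity_positions, c(1L, 2L, 4L))

  expect_equal(lc_params(26)$m, 32L)

  for (l in 1:20) {
    p <- lc_params(l)
    # minimality: no smaller codeword length admits l message bits
    smaller <- (l + 1):(p$m - 1)
    expect_false(any(smaller - ceiling(log2(smaller)) - 1 == l))
    expect_true(p$m %in% p$parity_positions)          # last position: parity
    expect_false((p$m - 1L) %in% p$parity_positions)  # second-to-last: message
    expect_length(p$parity_positions, p$m - p$l)
  }

  expect_error(lc_params(0), "integer >= 1")
})

test_that("weighted position sums match hand-computed frames", {
  p <- lc_params(12)
  frame <- integer(18)
  frame[p$message_positions] <- as_bits("101000011110")
  expect_equal(lc_weighted_sum(frame), 63)

  expect_equal(lc_weighted_sum(integer(18)), 0)

  expect_equal(lc_weighted_sum("101001010001111000"), 72)
  expect_equal(72 %% p$U, 0)
})

test_that("encoder reproduces known codewords and always emits code members", {
  p <- lc_params(12)
  expect_equal(bits_to_string(lc_encode("101000011110", p)),
               "101001010001111000")
  expect_equal(bits_to_string(lc_encode(integer(12), p)),
               paste(rep("0", 18), collapse = ""))

  p1 <- lc_params(1)
  expect_equal(bits_to_string(lc_encode("1", p1)), "1011")

  expect_error(lc_encode("101", p), "expected l = 12")

  set.seed(71)
  for (l in 1:14) {
    pl <- lc_params(l)
    for (rep in 1:25) {
      cw <- lc_encode(random_bits(l), pl)
      expect_equal(lc_weighted_sum(cw) %% pl$U, 0)
    }
  }
})

test_that("greedy parity decomposition covers every residue", {
  # every s in [0, 2m) must decompose over {m} plus the powers of two <= m
  for (l in c(1:10, 12, 20, 26, 40, 57)) {
    p <- lc_params(l)
    if (p$m > 64) next
    weights <- rev(p$parity_positions)
    for (s in 0:(p$U - 1L)) {
      r <- s
      for (w in weights) if (w <= r) r <- r - w
      expect_equal(r, 0)
    }
  }
})

test_that("round trips are exact for exhaustive and random message sets", {
  for (l in c(1:8, 12)) {
    p <- lc_params(l)
    vals <- if (l <= 8) 0:(2^l - 1) else {
      set.seed(l)
      sample(0:(2^l - 1), 256)
    }
    for (v in vals) {
      msg <- int_to_bits(v, l)
      out <- lc_decode(lc_encode(msg, p), p)
      expect_identical(out$message, msg)
      expect_equal(out$report$status, "intact")
    }
  }
})

test_that("a single substitution, deletion, or insertion is always corrected", {
  p <- lc_params(12)
  set.seed(13)
  for (v in sample(0:4095, 60)) {
    msg <- int_to_bits(v, 12)
    cw <- lc_encode(msg, p)
    for (k in 1:18) {
      y <- cw; y[k] <- 1L - y[k]
      r <- lc_decode(y, p)
      expect_identical(r$message, msg)
      expect_equal(r$report$status,
                   if (all(y == cw)) "intact" else "substitution_corrected")
      expect_equal(r$report$position, k)
    }
    for (k in 1:18) {
      r <- lc_decode(cw[-k], p)
      expect_identical(r$message, msg)
      expect_equal(r$report$status, "deletion_corrected")
    }
    for (k in 0:18) for (b in 0:1) {
      r <- lc_decode(append(cw, b, after = k), p)
      expect_identical(r$message, msg)
      expect_true(r$report$status %in% c("insertion_corrected", "intact"))
    }
  }
})

test_that("worked-example error cases decode as expected", {
  p <- lc_params(12)
  cw <- lc_encode("101000011110", p)

  y <- cw; y[5] <- 1L
  r <- lc_decode(y, p)
  expect_equal(r$report$syndrome, 5)           # 72 + 5 = 77 = 5 mod 36
  expect_equal(r$report$status, "substitution_corrected")
  expect_equal(r$report$position, 5)
  expect_equal(bits_to_string(r$message), "101000011110")

  r <- lc_decode(cw[-12], p)
  expect_equal(r$report$status, "deletion_corrected")
  expect_equal(bits_to_string(r$message), "101000011110")

  # verify uniqueness with an independent exhaustive-reinsertion oracle
  y <- cw[-12]
  uniq <- unique(Filter(
    function(w) lc_weighted_sum(w) %% p$U == 0L,
    unlist(lapply(1:18, function(pos) lapply(0:1, function(b)
      append(y, b, after = pos - 1L))), recursive = FALSE)))
  expect_length(uniq, 1L)
  expect_identical(uniq[[1]], cw)
})

test_that("out-of-scope lengths and unresolvable inputs are flagged, never guessed", {
  p <- lc_params(12)
  cw <- lc_encode("101000011110", p)

  r <- lc_decode(cw[-(1:2)], p)   # two deletions
  expect_equal(r$report$status, "uncorrectable")
  expect_null(r$message)

  r <- lc_decode(c(cw, 0L, 1L), p)  # two insertions
  expect_equal(r$report$status, "uncorrectable")

  # length-m word at Hamming distance >= 2 from every codeword whose syndrome
  # points at an inconsistent bit value must not be "corrected"
  y <- integer(18); y[2] <- 1L; y[3] <- 1L  # syndrome 5, but y[5] == 0
  stopifnot(lc_weighted_sum(y) %% 36 == 5)
  r <- lc_decode(y, p)
  expect_equal(r$report$status, "uncorrectable")
})

test_that("deletion balls of distinct codewords are disjoint (m = 8 oracle)", {
  cws <- enumerate_codewords(8L)
  expect_gt(length(cws), 1L)
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(cws)) {
    dels <- unique(vapply(1:8, function(k) bits_to_string(cws[[i]][-k]),
                          character(1)))
    for (d in dels) {
      owner <- seen[[d]]
      expect_true(is.null(owner) || owner == i)
      seen[[d]] <- i
    }
  }
})
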