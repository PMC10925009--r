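test_that("config geometry rounds to whole LC blocks", {
  cfg <- codec_config()
  expect_equal(cfg$block_nt, 12L)
  expect_equal(cfg$n_blocks, 17L)
  expect_equal(cfg$effective_oligo_nt, 204L)
  expect_equal(cfg$message_bits_per_oligo, 204L)

  tiny <- codec_config(oligo_length_nt = 12)
  expect_equal(tiny$n_blocks, 1L)

  # l = 4 gives m = 8, which cannot align blocks to base pairs
  expect_error(codec_config(lc_message_bits = 4), "divisible by 3")
  expect_error(codec_config(oligo_length_nt = 8), "too short")
})

test_that("oligo counts follow the capacity ceiling exactly", {
  cfg <- codec_config(oligo_length_nt = 12, index_bits = 4)
  pool <- build_oligos(random_bits(64), cfg)
  expect_equal(nrow(pool$oligos), 8L)          # ceiling(64 / (12 - 4))
  expect_equal(pool$oligos$index, 0:7)
  expect_equal(unique(nchar(pool$oligos$sequence)), 12L)

  set.seed(31)
  for (rep in 1:10) {
    n <- sample(1:4000, 1)
    cfg <- codec_config(index_bits = 16)
    pool <- build_oligos(random_bits(n), cfg)
    cap <- cfg$message_bits_per_oligo - 16L
    expect_equal(nrow(pool$oligos), ceiling(n / cap))
  }

  # a payload of exactly one oligo's capacity fits in one oligo
  cfg <- codec_config(oligo_length_nt = 12, index_bits = 4)
  pool <- build_oligos(random_bits(8), cfg)
  expect_equal(nrow(pool$oligos), 1L)

  expect_error(build_oligos(integer(0), cfg), "empty payload")
  expect_error(build_oligos(random_bits(10), codec_config(oligo_length_nt = 12,
                                                          index_bits = 18)),
               "capacity")
})

test_that("payloads round trip losslessly and order-free across configs", {
  set.seed(17)
  configs <- list(
    codec_config(oligo_length_nt = 12, index_bits = 4),
    codec_config(oligo_length_nt = 60),
    codec_config(),
    codec_config(oligo_length_nt = 40, lc_message_bits = 7)
  )
  lengths <- c(1, 7, 100, 1000, 5000)
  for (cfg in configs) {
    for (n in lengths) {
      if (cfg$message_bits_per_oligo - 13L < 1L && n > 50) next
      payload <- random_bits(n)
      pool <- tryCatch(build_oligos(payload, cfg), error = function(e) NULL)
      if (is.null(pool)) next  # tiny configs cannot address huge payloads
      shuffled <- sample(pool$oligos$sequence)
      out <- reassemble(shuffled, pool$sidecar)
      expect_identical(out$payload, as.integer(payload))
      expect_true(out$checksum_ok)
    }
  }
})

test_that("every emitted oligo satisfies the storage constraints", {
  set.seed(23)
  pool <- build_oligos(random_bits(2000), codec_config())
  for (s in pool$oligos$sequence) {
    a <- audit_sequence(s)
    expect_equal(a$gc_percent, 50)
    expect_lte(a$max_homopolymer, 2)
    expect_equal(nrow(a$motif_hits), 0)
  }
})

test_that("a missing oligo raises a partial-recovery condition naming its index", {
  set.seed(41)
  cfg <- codec_config(oligo_length_nt = 36, index_bits = 4)
  pool <- build_oligos(random_bits(200), cfg)
  expect_gt(nrow(pool$oligos), 3L)
  dropped <- pool$oligos$sequence[-3]   # remove index 2
  cond <- tryCatch(reassemble(dropped, pool$sidecar),
                   oligocodec_partial_recovery = function(c) c)
  expect_s3_class(cond, "oligocodec_partial_recovery")
  expect_equal(cond$missing, 2L)
})

test_that("a wrong-but-decodable oligo is caught by the payload checksum", {
  set.seed(43)
  cfg <- codec_config(oligo_length_nt = 36, index_bits = 4)
  a <- build_oligos(random_bits(200), cfg)
  b <- build_oligos(random_bits(200), cfg)
  forged <- a$oligos$sequence
  forged[2] <- b$oligos$sequence[2]  # same index, different payload
  expect_error(reassemble(forged, a$sidecar),
               class = "oligocodec_integrity_error")
})

test_that("one complement transversion per oligo is corrected transparently", {
  set.seed(47)
  payload <- random_bits(1500)
  pool <- build_oligos(payload, codec_config())
  mutated <- vapply(pool$oligos$sequence, function(s)
    complement_transversion(s, sample(nchar(s), 1)), character(1))
  out <- reassemble(unname(mutated), pool$sidecar)
  expect_identical(out$payload, as.integer(payload))
  expect_true(out$checksum_ok)
  expect_true(all(grepl("corrected", out$report$status) |
                    out$report$status == "intact"))
  expect_true(any(grepl("substitution_corrected|erasure_corrected",
                        out$report$status)))
})

test_that("FASTA and sidecar files round trip", {
  set.seed(53)
  pool <- build_oligos(random_bits(500), codec_config(oligo_length_nt = 60))
  fa <- tempfile(fileext = ".fa")
  sc <- tempfile(fileext = ".sidecar")
  write_pool_fasta(pool, fa)
  write_sidecar(pool$sidecar, sc)

  seqs <- read_fasta_sequences(fa)
  expect_equal(unname(seqs), pool$oligos$sequence)
  expect_equal(names(seqs), sprintf("seq_%d", pool$oligos$index))
  # single-line sequence dialect
  expect_equal(sum(grepl("^>", readLines(fa))), nrow(pool$oligos))

  side <- read_sidecar(sc)
  expect_equal(side$payload_length_bits, pool$sidecar$payload_length_bits)
  expect_equal(side$checksum, unname(pool$sidecar$checksum))
  out <- reassemble(unname(seqs), side)
  expect_true(out$checksum_ok)
})
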