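#' Codec configuration for oligo pool assembly
#'
#' Fixes the geometry shared by encoder and decoder: the oligo length, the
#' Levenshtein block size, and the index width. Each oligo carries a whole
#' number of LC blocks; a block of m code bits occupies 2m/3 bases, so the
#' requested oligo length is rounded down to the largest multiple of the
#' block footprint (e.g. the default 208 nt with m = 18 yields 17 blocks and
#' an effective length of 204 nt). The codeword length m must be divisible
#' by 3 so that block boundaries align with base pairs, which is what lets
#' the decoder localise and repair indels block by block.
#'
#' @param oligo_length_nt Target oligo length in bases (default 208).
#' @param lc_message_bits Message bits per LC block (default 12, giving
#'   m = 18 code bits per block).
#' @param index_bits Width of the per-oligo sequence index in bits, or NULL
#'   to size it automatically from the payload at encode time.
#' @param compressor Name of the compression stage ("gzip" or "passthrough").
#' @return An object of class `codec_config` with the derived fields
#'   `lc` (the [lc_params()]), `n_blocks`, `block_nt`, `effective_oligo_nt`
#'   and `message_bits_per_oligo`.
#' @examples
#' cfg <- codec_config()
#' cfg$effective_oligo_nt   # 204
#' cfg$n_blocks             # 17
#' @export
codec_config <- function(oligo_length_nt = 208L, lc_message_bits = 12L,
                         index_bits = NULL, compressor = "gzip") {
  params <- lc_params(lc_message_bits)
  if (params$m %% 3L != 0L)
    stop(sprintf(paste0("codeword length m = %d is not divisible by 3; choose a ",
                        "message length whose codeword aligns to base pairs ",
                        "(e.g. l = 2, 7, 12, 15)"), params$m))
  block_nt <- 2L * params$m %/% 3L
  n_blocks <- as.integer(oligo_length_nt) %/% block_nt
  if (n_blocks < 1L)
    stop("oligo length too short for even one LC block (need >= ", block_nt, " nt)")
  if (!is.null(index_bits)) {
    index_bits <- as.integer(index_bits)
    stopifnot(index_bits >= 1L)
  }
  structure(
    list(
      oligo_length_nt = as.integer(oligo_length_nt),
      lc_message_bits = params$l,
      lc = params,
      block_nt = block_nt,
      n_blocks = n_blocks,
      effective_oligo_nt = n_blocks * block_nt,
      message_bits_per_oligo = n_blocks * params$l,
      index_bits = index_bits,
      compressor = compressor
    ),
    class = "codec_config"
  )
}

#' @export
print.codec_config <- function(x, ...) {
  cat(sprintf("oligo codec: %d nt/oligo (%d LC blocks of l=%d/m=%d), %d message bits/oligo\n",
              x$effective_oligo_nt, x$n_blocks, x$lc$l, x$lc$m,
              x$message_bits_per_oligo))
  invisible(x)
}

# MD5 over the packed payload bitstream plus its exact bit length; used to
# decide whether a reassembled payload is the encoded one.
payload_checksum <- function(bits) {
  bits <- as_bits(bits)
  pad <- (8L - length(bits) %% 8L) %% 8L
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(tmp, "wb")
  writeBin(length(bits), con, size = 8L)
  writeBin(bits_to_raw(c(bits, integer(pad))), con)
  close(con)
  unname(tools::md5sum(tmp))
}

resolve_index_bits <- function(payload_bits, config) {
  if (!is.null(config$index_bits)) return(config$index_bits)
  mb <- config$message_bits_per_oligo
  ib <- 1L
  repeat {
    cap <- mb - ib
    if (cap < 1L) stop("index width leaves no payload capacity per oligo")
    n <- ceiling(payload_bits / cap)
    need <- max(1L, as.integer(ceiling(log2(max(n, 2)))))
    if (need <= ib) return(ib)
    ib <- need
  }
}

#' Segment a payload bitstream into an indexed, LC-protected oligo pool
#'
#' Each oligo carries `[index bits | payload slice | zero padding]` split into
#' l-bit messages, every message encoded to an m-bit Levenshtein codeword,
#' and the concatenated code bits transcoded to DNA under the constrained
#' codebook. The index occupies the leading message bits and is therefore
#' protected by the same code as the payload. The sidecar records everything
#' the decoder needs: payload bit length, index width, geometry, compressor
#' name, and an MD5 checksum of the payload bitstream.
#'
#' @param payload Bit vector or 0/1 string (non-empty).
#' @param config A [codec_config()].
#' @return An object of class `oligo_pool`: list with `oligos` (data.frame of
#'   `index` and `sequence`) and `sidecar` (named list).
#' @examples
#' cfg <- codec_config(oligo_length_nt = 12, index_bits = 4)
#' pool <- build_oligos(rep(c(1L, 0L), 32), cfg)   # 64 payload bits
#' nrow(pool$oligos)   # 8 oligos of 8 payload bits each
#' @export
build_oligos <- function(payload, config) {
  stopifnot(inherits(config, "codec_config"))
  payload <- as_bits(payload)
  if (length(payload) == 0L) stop("empty payload")

  ib <- resolve_index_bits(length(payload), config)
  cap <- config$message_bits_per_oligo - ib
  if (cap < 1L)
    stop("index_bits (", ib, ") leaves no payload capacity in ",
         config$message_bits_per_oligo, " message bits per oligo")
  n_oligos <- as.integer(ceiling(length(payload) / cap))
  if (n_oligos > 2^ib)
    stop("index width ", ib, " bits cannot address ", n_oligos, " oligos")

  params <- config$lc
  sequences <- character(n_oligos)
  for (i in seq_len(n_oligos)) {
    lo <- (i - 1L) * cap + 1L
    hi <- min(i * cap, length(payload))
    slice <- payload[lo:hi]
    msg <- c(int_to_bits(i - 1L, ib), slice,
             integer(cap - length(slice)))          # zero padding
    blocks <- matrix(msg, nrow = params$l)
    code <- as.vector(apply(blocks, 2L, lc_encode, params = params))
    sequences[i] <- bits_to_dna(code)
  }

  sidecar <- list(
    payload_length_bits = length(payload),
    index_bits = ib,
    oligo_length_nt = config$effective_oligo_nt,
    lc_message_bits = params$l,
    n_blocks = config$n_blocks,
    n_oligos = n_oligos,
    compressor = config$compressor,
    checksum = payload_checksum(payload)
  )
  structure(list(oligos = data.frame(index = seq_len(n_oligos) - 1L,
                                     sequence = sequences),
                 sidecar = sidecar),
            class = "oligo_pool")
}

#' @export
print.oligo_pool <- function(x, ...) {
  cat(sprintf("oligo pool: %d oligos x %d nt (%d payload bits)\n",
              nrow(x$oligos), x$sidecar$oligo_length_nt,
              x$sidecar$payload_length_bits))
  invisible(x)
}

config_from_sidecar <- function(sidecar) {
  codec_config(oligo_length_nt = sidecar$oligo_length_nt,
               lc_message_bits = sidecar$lc_message_bits,
               index_bits = sidecar$index_bits,
               compressor = sidecar$compressor)
}

# ---- per-block decoding with erasure resolution and indel repair ----------

.valid_pairs <- c("TC", "TG", "AC", "AG", "CT", "CA", "GT", "GA")

# valid pairs at Hamming distance 1 from each possible dinucleotide
.pair_neighbours <- local({
  bases <- c("A", "C", "G", "T")
  all16 <- as.vector(outer(bases, bases, paste0))
  nb <- lapply(all16, function(p) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    cand <- c(paste0(setdiff(bases, a), b), paste0(a, setdiff(bases, b)))
    intersect(cand, .valid_pairs)
  })
  names(nb) <- all16
  nb
})

# Decode one block-sized DNA chunk. strict = require an exact codeword
# (no erasures, zero syndrome); otherwise allow one substitution correction
# or the resolution of up to two invalid pairs (erasures) by enumerating
# replacement pairs and demanding a unique zero-syndrome assignment.
# Returns list(message, status) or NULL on failure.
decode_block_chunk <- function(chunk, params, strict = FALSE) {
  db <- dna_to_bits(chunk)
  if (length(db$erasures) == 0L) {
    res <- lc_decode(db$bits, params)
    st <- res$report$status
    if (st == "intact")
      return(list(message = res$message, status = "ok"))
    if (!strict && st == "substitution_corrected")
      return(list(message = res$message, status = "substitution_corrected"))
    return(NULL)
  }
  if (strict || length(db$erasures) > 2L) return(NULL)

  n <- nchar(chunk)
  pairs <- substring(chunk, seq(1L, n, by = 2L), seq(2L, n, by = 2L))
  try_sets <- function(cand_sets) {
    if (any(vapply(cand_sets, length, integer(1)) == 0L)) return(character(0))
    grid <- expand.grid(cand_sets, stringsAsFactors = FALSE)
    found <- character(0)
    for (g in seq_len(nrow(grid))) {
      bits <- db$bits
      for (j in seq_along(db$erasures)) {
        e <- db$erasures[j]
        bits[(3L * e - 2L):(3L * e)] <- .bits_by_pair[[grid[g, j]]]
      }
      if (lc_weighted_sum(bits) %% params$U == 0L)
        found <- union(found, bits_to_string(bits[params$message_positions]))
    }
    found
  }
  # single-substitution model first: the true pair differs in one base
  found <- try_sets(lapply(db$erasures, function(e) .pair_neighbours[[pairs[e]]]))
  if (length(found) == 0L)
    found <- try_sets(rep(list(.valid_pairs), length(db$erasures)))
  if (length(found) != 1L) return(NULL)
  list(message = as_bits(found), status = "erasure_corrected")
}

# Repair a chunk that is one base short or long: enumerate single-base
# reinsertions (or deletions), keep candidates that decode as exact
# codewords, and accept only a unique resulting message.
decode_block_indel <- function(chunk, params, block_nt) {
  n <- nchar(chunk)
  cands <- character(0)
  if (n == block_nt - 1L) {
    for (p in seq_len(block_nt)) {
      for (base in c("A", "C", "G", "T")) {
        cands <- c(cands, paste0(substr(chunk, 1L, p - 1L), base,
                                 substr(chunk, p, n)))
      }
    }
  } else if (n == block_nt + 1L) {
    cands <- vapply(seq_len(n), function(p)
      paste0(substr(chunk, 1L, p - 1L), substr(chunk, p + 1L, n)), character(1))
  } else {
    return(NULL)
  }
  msgs <- character(0)
  for (cc in unique(cands)) {
    r <- decode_block_chunk(cc, params, strict = TRUE)
    if (!is.null(r)) msgs <- union(msgs, bits_to_string(r$message))
  }
  if (length(msgs) != 1L) return(NULL)
  list(message = as_bits(msgs), status = "indel_repaired")
}

#' Decode one sequencing read into its message bits
#'
#' Walks the read block by block. A block-sized chunk is decoded directly
#' (zero syndrome, a single corrected substitution, or a uniquely resolved
#' invalid-pair erasure). When the running length bookkeeping indicates a
#' missing or extra base, the decoder first tries an exact-codeword match at
#' the nominal size, then a single-base reinsertion/deletion repair of the
#' off-by-one chunk, and finally a lenient nominal-size decode; a block that
#' survives none of these invalidates the read. A read is valid when every
#' block decodes and no bases are left over.
#'
#' @param seq A nucleotide string (one read).
#' @param config A [codec_config()] (or one rebuilt from a sidecar).
#' @return A list: `valid` (logical); when valid, `index` (decoded oligo
#'   index), `payload_bits` (the oligo's message bits after the index),
#'   `message_bits` and `block_status` (per-block correction statuses).
#' @export
decode_read <- function(seq, config) {
  params <- config$lc
  block_nt <- config$block_nt
  n_blocks <- config$n_blocks
  L <- nchar(seq)
  if (abs(L - config$effective_oligo_nt) > n_blocks)
    return(list(valid = FALSE))

  msgs <- vector("list", n_blocks)
  statuses <- character(n_blocks)
  cur <- 1L
  for (b in seq_len(n_blocks)) {
    delta <- (L - cur + 1L) - (n_blocks - b + 1L) * block_nt
    res <- NULL
    attempt <- function(take, fun, ...) {
      if (!is.null(res)) return(res)
      if (take < 1L || cur + take - 1L > L) return(NULL)
      fun(substr(seq, cur, cur + take - 1L), params, ...)
    }
    if (delta == 0L) {
      res <- attempt(block_nt, decode_block_chunk)
      used <- block_nt
      if (is.null(res)) {
        res <- attempt(block_nt - 1L, decode_block_indel, block_nt = block_nt)
        used <- block_nt - 1L
      }
      if (is.null(res)) {
        res <- attempt(block_nt + 1L, decode_block_indel, block_nt = block_nt)
        used <- block_nt + 1L
      }
    } else {
      off <- if (delta < 0L) -1L else 1L
      res <- attempt(block_nt, decode_block_chunk, strict = TRUE)
      used <- block_nt
      if (is.null(res)) {
        res <- attempt(block_nt + off, decode_block_indel, block_nt = block_nt)
        used <- block_nt + off
      }
      if (is.null(res)) {
        res <- attempt(block_nt, decode_block_chunk)
        used <- block_nt
      }
    }
    if (is.null(res)) return(list(valid = FALSE, failed_block = b))
    msgs[[b]] <- res$message
    statuses[b] <- res$status
    cur <- cur + used
  }
  if (cur != L + 1L) return(list(valid = FALSE, failed_block = NA_integer_))

  message_bits <- unlist(msgs)
  ib <- config$index_bits
  if (is.null(ib)) stop("config lacks index_bits; rebuild it from the sidecar")
  list(valid = TRUE,
       index = bits_to_int(message_bits[seq_len(ib)]),
       payload_bits = message_bits[-seq_len(ib)],
       message_bits = message_bits,
       block_status = statuses)
}

#' Reassemble a payload from a pool of (possibly corrupted, unordered) reads
#'
#' Decodes every read, groups valid reads by their recovered index, selects
#' the majority payload per index, and concatenates slices in index order,
#' truncating to the recorded payload length. Raises a
#' `oligocodec_partial_recovery` condition (carrying the missing indices)
#' when some index has no valid read, and a `oligocodec_integrity_error`
#' when the reassembled payload fails the sidecar checksum.
#'
#' @param sequences Character vector of reads (order-free; indices are
#'   recovered from sequence content), or an `oligo_pool`.
#' @param sidecar Sidecar metadata list (from [build_oligos()] or
#'   [read_sidecar()]). Unused when `sequences` is an `oligo_pool`.
#' @return A list with `payload` (bit vector), `checksum_ok` (TRUE), and
#'   `report` (data.frame with per-index read counts, valid-read counts,
#'   agreeing-candidate counts, and a representative correction status).
#' @examples
#' cfg <- codec_config(oligo_length_nt = 12, index_bits = 4)
#' pool <- build_oligos(rep(1L, 20), cfg)
#' out <- reassemble(sample(pool$oligos$sequence), pool$sidecar)
#' all(out$payload == rep(1L, 20))
#' @export
reassemble <- function(sequences, sidecar = NULL) {
  if (inherits(sequences, "oligo_pool")) {
    sidecar <- sequences$sidecar
    sequences <- sequences$oligos$sequence
  }
  if (is.null(sidecar)) stop("sidecar metadata is required")
  config <- config_from_sidecar(sidecar)
  n_oligos <- sidecar$n_oligos

  decoded <- lapply(sequences, decode_read, config = config)
  valid <- decoded[vapply(decoded, `[[`, logical(1), "valid")]
  valid <- Filter(function(d) d$index < n_oligos, valid)

  by_index <- split(valid, vapply(valid, `[[`, numeric(1), "index"))
  slices <- vector("list", n_oligos)
  report <- data.frame(index = seq_len(n_oligos) - 1L,
                       n_reads = 0L, n_valid = 0L, n_agree = 0L,
                       status = NA_character_)
  for (key in names(by_index)) {
    idx <- as.integer(key)
    grp <- by_index[[key]]
    pats <- vapply(grp, function(d) bits_to_string(d$payload_bits), character(1))
    tab <- sort(table(pats), decreasing = TRUE)
    winner <- names(tab)[1L]
    slices[[idx + 1L]] <- as_bits(winner)
    pick <- grp[[match(winner, pats)]]
    report$n_valid[idx + 1L] <- length(grp)
    report$n_agree[idx + 1L] <- as.integer(tab[1L])
    st <- unique(pick$block_status)
    report$status[idx + 1L] <-
      if (identical(st, "ok")) "intact" else paste(setdiff(st, "ok"), collapse = "+")
  }
  report$n_reads <- length(sequences)  # reads are unindexed until decoded

  missing <- which(vapply(slices, is.null, logical(1))) - 1L
  if (length(missing) > 0L) {
    stop(errorCondition(
      paste("no valid read recovered for oligo indices:",
            paste(missing, collapse = ", ")),
      missing = missing, report = report,
      class = c("oligocodec_partial_recovery", "error")))
  }

  payload <- unlist(slices)[seq_len(sidecar$payload_length_bits)]
  if (!identical(unname(payload_checksum(payload)), unname(sidecar$checksum))) {
    stop(errorCondition(
      "reassembled payload fails the sidecar checksum",
      report = report,
      class = c("oligocodec_integrity_error", "error")))
  }
  list(payload = payload, checksum_ok = TRUE, report = report)
}

# ---- FASTA and sidecar I/O -------------------------------------------------

#' Read and write oligo pools and sidecar metadata
#'
#' Pools are written as single-line-sequence FASTA with headers
#' `seq_<index>` (the index is also recoverable from sequence content);
#' reads from the channel simulator use headers `read_<n>`. The sidecar is
#' a plain `key=value` text file.
#'
#' @param pool An `oligo_pool` from [build_oligos()].
#' @param path Output (or input) file path.
#' @return `read_fasta_sequences()` returns a named character vector;
#'   `read_sidecar()` returns the metadata list.
#' @name pool_io
NULL

#' @rdname pool_io
#' @export
write_pool_fasta <- function(pool, path) {
  stopifnot(inherits(pool, "oligo_pool"))
  x <- Biostrings::DNAStringSet(stats::setNames(
    pool$oligos$sequence, sprintf("seq_%d", pool$oligos$index)))
  Biostrings::writeXStringSet(x, path, width = 100000L)
  invisible(path)
}

#' @rdname pool_io
#' @param sequences Named character vector of sequences to write.
#' @export
write_reads_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("read_%d", seq_along(sequences))
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 100000L)
  invisible(path)
}

#' @rdname pool_io
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname pool_io
#' @param sidecar Sidecar metadata list.
#' @export
write_sidecar <- function(sidecar, path) {
  lines <- vapply(names(sidecar), function(k)
    paste0(k, "=", as.character(sidecar[[k]])), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pool_io
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  out <- stats::setNames(lapply(kv, function(x) paste(x[-1L], collapse = "=")),
                         vapply(kv, `[[`, character(1), 1L))
  numeric_keys <- c("payload_length_bits", "index_bits", "oligo_length_nt",
                    "lc_message_bits", "n_blocks", "n_oligos", "original_bytes")
  for (k in intersect(numeric_keys, names(out))) out[[k]] <- as.integer(out[[k]])
  out
}
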