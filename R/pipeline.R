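#' Encode a file into a DNA oligo pool
#'
#' Runs the full encoding pipeline: read the file, compress it, segment the
#' bitstream into indexed, Levenshtein-protected blocks, transcode to DNA,
#' and write a FASTA pool plus a sidecar metadata file. Every emitted oligo
#' is audited against the storage constraints (GC 50%, homopolymer <= 2, no
#' GAATTC/GGC); a violation would indicate an internal defect and aborts.
#'
#' @param path Input file (any byte stream).
#' @param fasta_out Output FASTA path.
#' @param sidecar_out Output sidecar path (default: `fasta_out` +
#'   `".sidecar"`).
#' @param config A [codec_config()].
#' @param verbose Print oligo count and density to stderr?
#' @return The `oligo_pool`, invisibly; its sidecar gains `original_bytes`.
#' @examples
#' f <- tempfile(); writeBin(as.raw(1:64), f)
#' pool <- encode_file(f, tempfile(fileext = ".fa"),
#'                     config = codec_config(oligo_length_nt = 48))
#' @export
encode_file <- function(path, fasta_out, sidecar_out = paste0(fasta_out, ".sidecar"),
                        config = codec_config(), verbose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  data <- readBin(path, "raw", n = file.size(path))
  if (length(data) == 0L) stop("empty input file")
  spec <- compressor_spec(config$compressor)
  payload <- compress_bytes(data, spec)

  pool <- build_oligos(payload, config)
  pool$sidecar$original_bytes <- length(data)

  bad <- which(vapply(pool$oligos$sequence, function(s) {
    a <- audit_sequence(s)
    a$gc_percent != 50 || a$max_homopolymer > 2 || nrow(a$motif_hits) > 0
  }, logical(1)))
  if (length(bad) > 0L)  # structurally impossible; guards against regressions
    stop("internal error: constraint violation in oligo(s) ",
         paste(bad, collapse = ", "))

  write_pool_fasta(pool, fasta_out)
  write_sidecar(pool$sidecar, sidecar_out)
  if (verbose) {
    message(sprintf("encoded %d bytes -> %d oligos x %d nt (%.2f bits/nt)",
                    length(data), nrow(pool$oligos),
                    pool$sidecar$oligo_length_nt,
                    net_information_density(length(data), nrow(pool$oligos),
                                            pool$sidecar$oligo_length_nt)))
  }
  invisible(pool)
}

#' Decode sequencing reads back into the original file
#'
#' Reads may be unordered, duplicated (multiple reads per oligo), and
#' corrupted by substitutions and single indels. Each read is decoded
#' independently ([decode_read()]); per oligo index the majority payload
#' among valid reads is selected, the payload is reassembled and verified
#' against the sidecar checksum, then decompressed and written out. No file
#' is written when the checksum fails or indices are missing; the
#' corresponding condition (`oligocodec_integrity_error` /
#' `oligocodec_partial_recovery`) propagates to the caller.
#'
#' @param reads_fasta FASTA of reads (or a character vector of sequences).
#' @param sidecar Sidecar path or metadata list.
#' @param out Output file path, or NULL to return the bytes only.
#' @param verbose Print a per-oligo summary to stderr?
#' @return A list with `bytes` (raw vector), `report` (per-oligo
#'   data.frame), and `checksum_ok`.
#' @export
decode_pool <- function(reads_fasta, sidecar, out = NULL, verbose = FALSE) {
  sequences <- if (is.character(reads_fasta) && length(reads_fasta) == 1L &&
                   file.exists(reads_fasta)) {
    read_fasta_sequences(reads_fasta)
  } else {
    reads_fasta
  }
  if (is.character(sidecar)) sidecar <- read_sidecar(sidecar)

  res <- reassemble(unname(sequences), sidecar)
  spec <- compressor_spec(sidecar$compressor)
  bytes <- decompress_bytes(res$payload, spec)
  if (!is.null(sidecar$original_bytes) &&
      length(bytes) != sidecar$original_bytes) {
    stop(errorCondition("decompressed size differs from the recorded original",
                        class = c("oligocodec_integrity_error", "error")))
  }
  if (verbose) {
    ok <- sum(res$report$status == "intact", na.rm = TRUE)
    message(sprintf("recovered %d/%d oligos intact, %d via correction",
                    ok, nrow(res$report), nrow(res$report) - ok))
  }
  if (!is.null(out)) writeBin(bytes, out)
  list(bytes = bytes, report = res$report, checksum_ok = res$checksum_ok)
}

#' Compare an original and a decoded image
#'
#' Computes SSIM between two raster images (read via [read_image()] when
#' paths are given).
#'
#' @param original,decoded Image paths or numeric arrays.
#' @param ... Passed on to [ssim()].
#' @return The SSIM value.
#' @export
evaluate_images <- function(original, decoded, ...) {
  if (is.character(original)) original <- read_image(original)
  if (is.character(decoded)) decoded <- read_image(decoded)
  ssim(original, decoded, ...)
}
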