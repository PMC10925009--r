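#' Compression front-end
#'
#' The pipeline treats compression as a pluggable stage so that any bit
#' source — including externally produced compressed payloads — can feed the
#' transcoder. Two built-in specs are provided: `"passthrough"` (identity)
#' and `"gzip"` (DEFLATE via [memCompress()]), both lossless.
#'
#' The gzip container is framed with a 28-byte header — magic `OCGZ`, the
#' original byte length, and an MD5 digest of the deflated body — which is
#' verified before inflating, so truncated or corrupted streams raise a
#' decode error instead of returning garbage.
#'
#' @param name `"gzip"` or `"passthrough"`.
#' @return `compressor_spec()` returns an object of class `compressor_spec`
#'   with fields `name` and `lossless`.
#' @examples
#' sp <- compressor_spec("gzip")
#' bits <- compress_bytes(as.raw(rep(0, 100)), sp)
#' identical(decompress_bytes(bits, sp), as.raw(rep(0, 100)))
#' @export
compressor_spec <- function(name = c("gzip", "passthrough")) {
  name <- match.arg(name)
  structure(list(name = name, lossless = TRUE), class = "compressor_spec")
}

.gz_magic <- charToRaw("OCGZ")

raw_md5 <- function(r) {
  tmp <- tempfile(fileext = ".bin")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(r, tmp)
  h <- unname(tools::md5sum(tmp))
  as.raw(strtoi(substring(h, seq(1L, 31L, 2L), seq(2L, 32L, 2L)), 16L))
}

uint64_raw <- function(n) {
  out <- raw(8)
  for (i in 8:1) {
    out[i] <- as.raw(n %% 256)
    n <- n %/% 256
  }
  out
}

raw_uint64 <- function(r) sum(as.integer(r) * 256^(7:0))

#' @rdname compressor_spec
#' @param data A non-empty raw vector.
#' @param spec A [compressor_spec()].
#' @return `compress_bytes()` returns an integer 0/1 bit vector.
#' @export
compress_bytes <- function(data, spec) {
  stopifnot(is.raw(data), inherits(spec, "compressor_spec"))
  if (length(data) == 0L) stop("empty input")
  out <- switch(spec$name,
    passthrough = data,
    gzip = {
      body <- memCompress(data, type = "gzip")
      c(.gz_magic, uint64_raw(length(data)), raw_md5(body), body)
    }
  )
  bits_from_raw(out)
}

#' @rdname compressor_spec
#' @param bits Bit vector produced by a matching `compress_bytes()` call.
#' @return `decompress_bytes()` returns the original raw vector.
#' @export
decompress_bytes <- function(bits, spec) {
  stopifnot(inherits(spec, "compressor_spec"))
  r <- bits_to_raw(bits)
  switch(spec$name,
    passthrough = r,
    gzip = {
      if (length(r) < 29L || !identical(r[1:4], .gz_magic))
        stop("corrupted compressed stream: bad or missing header")
      n_orig <- raw_uint64(r[5:12])
      digest <- r[13:28]
      body <- r[-(1:28)]
      if (!identical(raw_md5(body), digest))
        stop("corrupted compressed stream: body digest mismatch")
      out <- memDecompress(body, type = "gzip")
      if (length(out) != n_orig)
        stop("corrupted compressed stream: length mismatch after inflation")
      out
    }
  )
}
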