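#' Bit vector utilities
#'
#' Bit strings are represented throughout the package as plain integer vectors
#' of 0s and 1s, 1-based as required by the weighted-sum arithmetic of the
#' Levenshtein code. These helpers convert between that representation,
#' ASCII "0"/"1" strings (used for debugging and in examples), raw byte
#' vectors (MSB-first within each byte), and unsigned integers (big-endian).
#'
#' @param x For `as_bits()`, a character scalar of 0/1 digits or a numeric
#'   vector of 0s and 1s.
#' @return `as_bits()` and `bits_from_raw()` return an integer vector of 0/1;
#'   `bits_to_string()` a character scalar; `bits_to_raw()` a raw vector;
#'   `int_to_bits()` an integer 0/1 vector of length `width`;
#'   `bits_to_int()` a non-negative number.
#' @examples
#' as_bits("1011")
#' bits_to_string(int_to_bits(9, 6))   # "001001"
#' bits_from_raw(as.raw(c(0xA5)))
#' @name bits
NULL

#' @rdname bits
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!nzchar(x)) return(integer(0))
    v <- strtoi(strsplit(x, "", fixed = TRUE)[[1]])
    if (anyNA(v) || any(v > 1L)) stop("bit string may contain only '0' and '1'")
    return(as.integer(v))
  }
  v <- as.integer(x)
  if (anyNA(v) || any(v < 0L | v > 1L)) stop("bits must be 0 or 1")
  v
}

#' @rdname bits
#' @param bits An integer vector of 0/1.
#' @export
bits_to_string <- function(bits) paste(as_bits(bits), collapse = "")

#' @rdname bits
#' @param r A raw vector.
#' @export
bits_from_raw <- function(r) {
  if (length(r) == 0L) return(integer(0))
  m <- matrix(as.integer(rawToBits(r)), nrow = 8L)  # LSB-first per byte
  as.vector(m[8:1, ])                               # emit MSB-first
}

#' @rdname bits
#' @export
bits_to_raw <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) %% 8L != 0L)
    stop("bit length must be a multiple of 8 to pack into bytes")
  if (length(bits) == 0L) return(raw(0))
  m <- matrix(bits, nrow = 8L)
  packBits(as.integer(m[8:1, ]), type = "raw")
}

#' @rdname bits
#' @param n A non-negative integer scalar.
#' @param width Number of bits in the big-endian representation.
#' @export
int_to_bits <- function(n, width) {
  stopifnot(length(n) == 1L, n >= 0, width >= 1L, width <= 52L)
  out <- integer(width)
  for (i in width:1) {
    out[i] <- n %% 2
    n <- n %/% 2
  }
  if (n != 0) stop("integer does not fit in ", width, " bits")
  as.integer(out)
}

#' @rdname bits
#' @export
bits_to_int <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) > 52L) stop("too many bits for exact integer conversion")
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}
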