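#' Constrained 3-bit to 2-base codebook
#'
#' Each 3-bit group is transcoded to one of eight dinucleotides:
#' 000->TC, 001->TG, 010->AC, 011->AG, 100->CT, 101->CA, 110->GT, 111->GA.
#' Every pair couples one weak base (A/T) with one strong base (G/C), so any
#' concatenation has exactly 50% GC in every pair-aligned window, never forms
#' a homopolymer longer than two bases, and can contain neither GAATTC (the
#' EcoRI restriction site) nor GGC (an Illumina error-prone motif). The eight
#' unused dinucleotides are invalid; encountering one during decoding marks an
#' erasure.
#'
#' @format A named character vector of length 8 (names are the bit triplets).
#' @export
pair_codebook <- c(
  "000" = "TC", "001" = "TG", "010" = "AC", "011" = "AG",
  "100" = "CT", "101" = "CA", "110" = "GT", "111" = "GA"
)

# decimal value of triplet -> pair, and pair -> triplet bits
.pair_by_value <- unname(pair_codebook)
.bits_by_pair <- local({
  env <- new.env(parent = emptyenv())
  for (k in names(pair_codebook)) assign(pair_codebook[[k]], as_bits(k), envir = env)
  env
})

#' Transcode bits to DNA under the constrained codebook
#'
#' @param bits Bit vector or 0/1 string whose length is a multiple of 3
#'   (padding to a multiple of 3 is the packetizer's responsibility).
#' @return A nucleotide string of length `2/3 * length(bits)`.
#' @examples
#' bits_to_dna("101001010001111000")  # "CATGACTGGATC"
#' @export
bits_to_dna <- function(bits) {
  bits <- as_bits(bits)
  if (length(bits) %% 3L != 0L)
    stop("bit length must be a multiple of 3 (got ", length(bits), ")")
  if (length(bits) == 0L) return("")
  g <- matrix(bits, nrow = 3L)
  vals <- 4L * g[1L, ] + 2L * g[2L, ] + g[3L, ] + 1L
  paste(.pair_by_value[vals], collapse = "")
}

#' Transcode DNA back to bits, flagging invalid pairs as erasures
#'
#' Inverse of [bits_to_dna()]. Dinucleotides outside the codebook decode to
#' placeholder bits 000 and are recorded as erasures so the error-correcting
#' layer can attempt recovery; an odd-length input signals a probable indel
#' and is an error at this layer.
#'
#' @param dna A nucleotide string of even length over A/C/G/T.
#' @return A list with `bits` (integer 0/1 vector, 3 bits per pair) and
#'   `erasures` (integer vector of 1-based indices of invalid pairs).
#' @examples
#' dna_to_bits("CATGACTGGATC")$bits
#' dna_to_bits("GC")$erasures  # 1
#' @export
dna_to_bits <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna)
  if (n %% 2L != 0L)
    stop("DNA length is odd: probable insertion/deletion, handle upstream")
  if (n == 0L) return(list(bits = integer(0), erasures = integer(0)))
  pairs <- substring(dna, seq(1L, n, by = 2L), seq(2L, n, by = 2L))
  bits <- integer(3L * length(pairs))
  erasures <- integer(0)
  for (i in seq_along(pairs)) {
    b <- .bits_by_pair[[pairs[i]]]
    if (is.null(b)) {
      erasures <- c(erasures, i)      # placeholder 000 already in place
    } else {
      bits[(3L * i - 2L):(3L * i)] <- b
    }
  }
  list(bits = bits, erasures = erasures)
}

#' Audit a DNA sequence against the storage constraints
#'
#' Reports exact GC percentage, the longest homopolymer run, every
#' (overlapping) occurrence of the undesired motifs GAATTC and GGC, and —
#' for even-length sequences — which dinucleotide pairs fall outside the
#' codebook. Scanning is on the given strand only by default; set
#' `both_strands = TRUE` to also scan the reverse complement for motifs.
#'
#' @param dna A non-empty nucleotide string over A/C/G/T.
#' @param both_strands Also scan the reverse complement for motifs?
#' @return An object of class `constraint_report`: list with `gc_percent`,
#'   `max_homopolymer`, `motif_hits` (data.frame of motif and 1-based
#'   position), and `invalid_pairs` (1-based pair indices; empty for
#'   odd-length input).
#' @examples
#' audit_sequence("CATGACTGGATC")
#' audit_sequence("GGCGAATTC")$motif_hits
#' @export
audit_sequence <- function(dna, both_strands = FALSE) {
  stopifnot(is.character(dna), length(dna) == 1L)
  n <- nchar(dna)
  if (n == 0L) stop("empty sequence")
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("sequence contains non-ACGT symbols")

  gc <- 100 * sum(chars %in% c("G", "C")) / n
  runs <- rle(chars)
  motifs <- c("GAATTC", "GGC")

  find_hits <- function(s) {
    hits <- lapply(motifs, function(mo) {
      p <- gregexpr(paste0("(?=", mo, ")"), s, perl = TRUE)[[1]]
      p <- p[p > 0L]
      if (length(p) == 0L) return(NULL)
      data.frame(motif = mo, position = as.integer(p))
    })
    do.call(rbind, hits)
  }
  hits <- find_hits(dna)
  if (both_strands) {
    rc <- paste(rev(chartr("ACGT", "TGCA", chars)), collapse = "")
    rc_hits <- find_hits(rc)
    if (!is.null(rc_hits)) {
      rc_hits$position <- -rc_hits$position  # negative = reverse strand
      hits <- rbind(hits, rc_hits)
    }
  }
  if (is.null(hits)) hits <- data.frame(motif = character(0), position = integer(0))

  invalid <- integer(0)
  if (n %% 2L == 0L) invalid <- dna_to_bits(dna)$erasures

  structure(
    list(gc_percent = gc,
         max_homopolymer = max(runs$lengths),
         motif_hits = hits,
         invalid_pairs = invalid),
    class = "constraint_report"
  )
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("GC %.2f%% | max homopolymer %d nt | motif hits %d | invalid pairs %d\n",
              x$gc_percent, x$max_homopolymer, nrow(x$motif_hits),
              length(x$invalid_pairs)))
  invisible(x)
}
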