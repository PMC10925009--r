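#' Levenshtein (Varshamov-Tenengolts) code geometry
#'
#' A binary Levenshtein code L(m, r, U) is the set of length-m words whose
#' weighted position sum satisfies sum(k * x_k) = r (mod U). With r = 0 and
#' U = 2m the code corrects a single substitution, deletion, or insertion per
#' codeword. This package uses the systematic construction in which check
#' (parity) bits occupy the power-of-two positions plus the last position m;
#' all other positions carry message bits. Consequently the last position is
#' always a parity bit and the second-to-last a message bit.
#'
#' Given a message length `l`, the codeword length is the smallest m'
#' satisfying l = m' - ceiling(log2(m')) - 1; the parity positions are then
#' \{2^i : 2^i <= m\} together with \{m\}, exactly m - l of them.
#'
#' @param l Message length in bits (integer >= 1).
#' @return An object of class `lc_params`: a list with elements `l`, `m`
#'   (codeword length), `U` (modulus, `2 * m`), `r` (target residue, 0),
#'   `parity_positions` (sorted 1-based positions of the check bits) and
#'   `message_positions` (the remaining `l` positions).
#' @examples
#' p <- lc_params(12)
#' p$m               # 18
#' p$U               # 36
#' p$parity_positions  # 1 2 4 8 16 18
#' @seealso [lc_encode()], [lc_decode()]
#' @export
lc_params <- function(l) {
  if (!is.numeric(l) || length(l) != 1L || is.na(l) || l < 1 || l %% 1 != 0)
    stop("message length `l` must be a single integer >= 1")
  l <- as.integer(l)
  m <- l + 1L
  repeat {
    if (m - as.integer(ceiling(log2(m))) - 1L == l) break
    m <- m + 1L
  }
  parity <- sort(unique(c(2L^(0:floor(log2(m))), m)))
  structure(
    list(
      l = l,
      m = m,
      U = 2L * m,
      r = 0L,
      parity_positions = parity,
      message_positions = setdiff(seq_len(m), parity)
    ),
    class = "lc_params"
  )
}

#' @export
print.lc_params <- function(x, ...) {
  cat(sprintf("Levenshtein code L(%d, %d, %d): %d message bits, %d check bits\n",
              x$m, x$r, x$U, x$l, x$m - x$l))
  cat("parity positions:", paste(x$parity_positions, collapse = " "), "\n")
  invisible(x)
}

#' Weighted position sum of a codeword frame
#'
#' Computes sum(k * x_k) over a bit frame, unreduced. A valid codeword has
#' weighted sum congruent to 0 modulo `U = 2m`; the residue (the syndrome)
#' localises a single error.
#'
#' @param frame Bit vector (or 0/1 string) of any length; typically length m.
#' @return The integer weighted sum (not reduced modulo U).
#' @examples
#' lc_weighted_sum("101001010001111000")  # 72; 72 %% 36 == 0
#' @export
lc_weighted_sum <- function(frame) {
  frame <- as_bits(frame)
  sum(seq_along(frame) * frame)
}

#' Encode a message block with the systematic Levenshtein code
#'
#' Places the `l` message bits into the non-parity positions of the m-bit
#' frame in ascending order, then chooses check bits so that the weighted sum
#' of the full codeword is 0 modulo U. The parity contribution
#' s = (U - message_sum mod U) mod U is decomposed greedily,
#' largest-weight-first, over the parity position weights \{m, 2^t, ..., 2, 1\};
#' this decomposition is total on [0, 2m) (see the package vignette).
#'
#' @param message Bit vector or 0/1 string of length `params$l`.
#' @param params An [lc_params()] object.
#' @return Integer bit vector of length `params$m` (the codeword).
#' @examples
#' p <- lc_params(12)
#' bits_to_string(lc_encode("101000011110", p))
#' # "101001010001111000"
#' @export
lc_encode <- function(message, params) {
  message <- as_bits(message)
  if (length(message) != params$l)
    stop(sprintf("message has %d bits; expected l = %d", length(message), params$l))
  cw <- integer(params$m)
  cw[params$message_positions] <- message
  s <- (params$U - sum(params$message_positions * message) %% params$U) %% params$U
  for (w in rev(params$parity_positions)) {
    if (w <= s) {
      cw[w] <- 1L
      s <- s - w
    }
  }
  if (s != 0L)  # provably unreachable: greedy decomposition is total on [0, 2m)
    stop("internal error: greedy parity decomposition failed")
  cw
}

new_correction_report <- function(status, position = NA_integer_, syndrome = NA_integer_) {
  structure(list(status = status, position = position, syndrome = syndrome),
            class = "lc_correction_report")
}

#' @export
print.lc_correction_report <- function(x, ...) {
  cat(sprintf("LC decode: %s (position %s, syndrome %s)\n",
              x$status, x$position, x$syndrome))
  invisible(x)
}

# Syndromes of all words obtained by inserting one bit into `y` (length m-1),
# and of all words obtained by deleting one bit from `y` (length m+1).
# Both are O(m) via suffix sums.
insertion_candidates <- function(y, params) {
  m <- params$m
  U <- params$U
  s0 <- lc_weighted_sum(y)
  suffix <- c(rev(cumsum(rev(y))), 0L)  # suffix[p] = sum(y[p:(m-1)]), suffix[m] = 0
  hits <- list()
  for (p in seq_len(m)) {
    for (b in 0:1) {
      if ((s0 + suffix[p] + b * p) %% U == 0L)
        hits[[length(hits) + 1L]] <- c(p = p, b = b)
    }
  }
  hits
}

deletion_candidates <- function(y, params) {
  U <- params$U
  n <- length(y)            # m + 1
  s0 <- lc_weighted_sum(y)
  suffix <- c(rev(cumsum(rev(y)))[-1L], 0L)  # suffix[p] = sum(y[(p+1):n])
  which(vapply(seq_len(n), function(p) {
    (s0 - p * y[p] - suffix[p]) %% U == 0L
  }, logical(1)))
}

#' Decode a received block, correcting one substitution, deletion, or insertion
#'
#' Accepts a received word of length m (possible substitution), m - 1 (single
#' deletion) or m + 1 (single insertion) and attempts to recover the original
#' codeword and message.
#'
#' At length m a zero syndrome means the word is intact. A non-zero syndrome d
#' identifies a unique flipped position: d <= m with a received 1 at position d
#' indicates a 0-to-1 flip there; d >= m with a received 0 at position 2m - d
#' indicates a 1-to-0 flip (at d = m the received bit at position m decides the
#' direction). Indels are decoded by enumerating every single-bit reinsertion
#' (or deletion) and demanding a unique candidate with zero syndrome; the
#' single-indel correction property of the code guarantees uniqueness for
#' genuinely single errors, and any tie is reported as `ambiguous` rather than
#' guessed.
#'
#' @param received Bit vector or 0/1 string of length m - 1, m, or m + 1.
#' @param params An [lc_params()] object.
#' @return A list with `message` (integer bit vector, or NULL when
#'   unrecoverable) and `report`, a correction report with fields `status`
#'   (one of "intact", "substitution_corrected", "deletion_corrected",
#'   "insertion_corrected", "uncorrectable", "ambiguous"), `position`
#'   (1-based, only for corrected states) and `syndrome`.
#' @examples
#' p <- lc_params(12)
#' cw <- lc_encode("101000011110", p)
#' lc_decode(cw, p)$report$status            # "intact"
#' lc_decode(cw[-12], p)$report$status       # "deletion_corrected"
#' @export
lc_decode <- function(received, params) {
  y <- as_bits(received)
  m <- params$m
  U <- params$U
  n <- length(y)

  extract <- function(cw) cw[params$message_positions]

  if (n == m) {
    d <- lc_weighted_sum(y) %% U
    if (d == 0L) {
      return(list(message = extract(y),
                  report = new_correction_report("intact", syndrome = 0L)))
    }
    if (d <= m && y[d] == 1L) {
      cw <- y
      cw[d] <- 0L
      if (lc_weighted_sum(cw) %% U == 0L)
        return(list(message = extract(cw),
                    report = new_correction_report("substitution_corrected",
                                                   position = d, syndrome = d)))
    }
    if (d >= m && y[2L * m - d] == 0L) {
      cw <- y
      cw[2L * m - d] <- 1L
      if (lc_weighted_sum(cw) %% U == 0L)
        return(list(message = extract(cw),
                    report = new_correction_report("substitution_corrected",
                                                   position = 2L * m - d,
                                                   syndrome = d)))
    }
    return(list(message = NULL,
                report = new_correction_report("uncorrectable", syndrome = d)))
  }

  if (n == m - 1L) {
    hits <- insertion_candidates(y, params)
    words <- unique(lapply(hits, function(h) append(y, h[["b"]], after = h[["p"]] - 1L)))
    if (length(words) == 1L) {
      return(list(message = extract(words[[1L]]),
                  report = new_correction_report("deletion_corrected",
                                                 position = hits[[1L]][["p"]],
                                                 syndrome = lc_weighted_sum(y) %% U)))
    }
    status <- if (length(words) == 0L) "uncorrectable" else "ambiguous"
    return(list(message = NULL,
                report = new_correction_report(status,
                                               syndrome = lc_weighted_sum(y) %% U)))
  }

  if (n == m + 1L) {
    pos <- deletion_candidates(y, params)
    words <- unique(lapply(pos, function(p) y[-p]))
    if (length(words) == 1L) {
      return(list(message = extract(words[[1L]]),
                  report = new_correction_report("insertion_corrected",
                                                 position = pos[1L],
                                                 syndrome = lc_weighted_sum(y) %% U)))
    }
    status <- if (length(words) == 0L) "uncorrectable" else "ambiguous"
    return(list(message = NULL,
                report = new_correction_report(status,
                                               syndrome = lc_weighted_sum(y) %% U)))
  }

  list(message = NULL,
       report = new_correction_report("uncorrectable",
                                      syndrome = lc_weighted_sum(y) %% U))
}
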