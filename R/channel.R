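#' Storage/sequencing channel configuration
#'
#' Models the error process of DNA synthesis, storage, and sequencing as
#' i.i.d. per-base errors at rate `p`, with the error type drawn from a
#' substitution/deletion/insertion mix — by default (0.5, 0.25, 0.25),
#' i.e. substitutions make up half of all errors, matching their higher
#' prevalence on common platforms. Substituted bases are drawn uniformly
#' from the three alternatives; insertions add a uniform base after the
#' errant position. `reads_per_oligo` independent noisy copies of each
#' oligo are emitted. `fixed_count = TRUE` switches to exactly
#' `round(p * n)` errors per read at uniformly sampled distinct positions,
#' for variance-matched experiments.
#'
#' @param per_base_error_rate Error probability per base, in [0, 1].
#' @param mix Length-3 numeric: substitution, deletion, insertion fractions
#'   (must sum to 1).
#' @param reads_per_oligo Number of independent reads per oligo (>= 1).
#' @param seed Integer RNG seed, or NULL to use the current RNG state.
#' @param fixed_count Use an exact per-read error count instead of i.i.d.
#'   draws?
#' @return An object of class `channel_config`.
#' @export
channel_config <- function(per_base_error_rate, mix = c(0.5, 0.25, 0.25),
                           reads_per_oligo = 1L, seed = NULL,
                           fixed_count = FALSE) {
  stopifnot(per_base_error_rate >= 0, per_base_error_rate <= 1,
            length(mix) == 3L, all(mix >= 0),
            abs(sum(mix) - 1) < 1e-9,
            reads_per_oligo >= 1L)
  structure(list(p = per_base_error_rate, mix = mix,
                 reads_per_oligo = as.integer(reads_per_oligo),
                 seed = seed, fixed_count = isTRUE(fixed_count)),
            class = "channel_config")
}

.bases <- c("A", "C", "G", "T")

corrupt_one <- function(seq, config) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (config$fixed_count) {
    k <- round(config$p * n)
    err <- sample.int(n, min(k, n))
  } else {
    err <- which(stats::runif(n) < config$p)
  }
  if (length(err) == 0L) return(seq)
  types <- sample(c("sub", "del", "ins"), length(err),
                  replace = TRUE, prob = config$mix)
  out <- as.list(chars)
  for (j in seq_along(err)) {
    i <- err[j]
    out[[i]] <- switch(types[j],
      sub = sample(setdiff(.bases, chars[i]), 1L),
      del = character(0),
      ins = c(chars[i], sample(.bases, 1L))   # insert after the position
    )
  }
  paste(unlist(out), collapse = "")
}

#' Pass an oligo pool through the simulated error channel
#'
#' Emits `reads_per_oligo` noisy reads per oligo, with the oligo identity
#' hidden (reads carry no index; the decoder must recover it from content).
#' Fully reproducible given `config$seed`.
#'
#' @param pool An `oligo_pool` from [build_oligos()], or a character vector
#'   of sequences.
#' @param config A [channel_config()].
#' @return A character vector of reads named `read_<n>`, in shuffled order.
#' @examples
#' cfg <- codec_config(oligo_length_nt = 12, index_bits = 4)
#' pool <- build_oligos(rep(1L, 16), cfg)
#' reads <- corrupt_pool(pool, channel_config(0.02, seed = 1, reads_per_oligo = 3))
#' @export
corrupt_pool <- function(pool, config) {
  stopifnot(inherits(config, "channel_config"))
  sequences <- if (inherits(pool, "oligo_pool")) pool$oligos$sequence else pool
  if (!is.null(config$seed)) set.seed(config$seed)
  reads <- character(0)
  for (s in sequences) {
    for (r in seq_len(config$reads_per_oligo)) {
      reads <- c(reads, corrupt_one(s, config))
    }
  }
  reads <- sample(reads)   # hide pool order, as a sequencer would
  stats::setNames(reads, sprintf("read_%d", seq_along(reads)))
}
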