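#' Net information density of a stored file
#'
#' Bits of original file per synthesized nucleotide:
#' `8 * original_size_bytes / (oligo_count * oligo_length_nt)`. Densities
#' above 2 bits/nt are only reachable through compression, since two bits is
#' the hard limit for uncompressed quaternary encoding. File sizes quoted in
#' KB use the binary convention, 1 KB = 1024 bytes.
#'
#' @param original_size_bytes Size of the stored file in bytes (use
#'   `kb * 1024` for sizes quoted in KB).
#' @param oligo_count Number of oligos in the pool.
#' @param oligo_length_nt Length of each oligo in bases.
#' @return Density in bits per nucleotide.
#' @examples
#' net_information_density(95.2 * 1024, 1293, 208)  # ~2.90
#' net_information_density(95.2 * 1024, 2927, 216)  # ~1.23
#' @export
net_information_density <- function(original_size_bytes, oligo_count,
                                    oligo_length_nt) {
  stopifnot(original_size_bytes > 0, oligo_count > 0, oligo_length_nt > 0)
  8 * original_size_bytes / (oligo_count * oligo_length_nt)
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-mode separable 2D filtering (crops the half-window margin)
filter2_valid <- function(M, k) {
  h <- (length(k) - 1L) %/% 2L
  down <- function(X) {
    F <- apply(X, 2L, function(v) stats::filter(v, k, sides = 2L))
    F[(h + 1L):(nrow(X) - h), , drop = FALSE]
  }
  t(down(t(down(M))))
}

to_gray <- function(img, luma = FALSE) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    ch <- min(dim(img)[3L], 3L)  # ignore alpha
    if (luma && ch == 3L)
      return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
    return(apply(img[, , seq_len(ch), drop = FALSE], c(1L, 2L), mean))
  }
  stop("expected a matrix or H x W x C array")
}

#' Structural similarity index (SSIM) between two images
#'
#' Standard single-scale SSIM: local means, variances and covariance are
#' taken under a Gaussian window (size 11, sigma 1.5) and combined as
#' `[(2*mu_a*mu_b + C1) * (2*cov_ab + C2)] /
#'  [(mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)]`
#' with C1 = (K1*L)^2, C2 = (K2*L)^2, K1 = 0.01, K2 = 0.03, and L the
#' dynamic range. The result lies in [-1, 1]; 1 means the images are
#' identical. Colour images are averaged over channels by default
#' (`luma = TRUE` uses Rec.601 luma instead).
#'
#' @param a,b Numeric matrices or H x W x C arrays of equal dimensions.
#' @param dynamic_range Value range L; defaults to 1 when the data lie in
#'   [0, 1], else 255.
#' @param window,sigma Gaussian window size (odd) and standard deviation.
#' @param K1,K2 Stability constants.
#' @param luma Convert colour images via Rec.601 luma instead of the
#'   channel mean?
#' @return The mean SSIM over the valid window positions.
#' @examples
#' img <- matrix(runif(32 * 32), 32)
#' ssim(img, img)   # 1
#' @export
ssim <- function(a, b, dynamic_range = NULL, window = 11L, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, luma = FALSE) {
  a <- to_gray(a, luma)
  b <- to_gray(b, luma)
  if (!identical(dim(a), dim(b))) stop("image dimensions differ")
  if (any(dim(a) < window))
    stop("images must be at least ", window, " pixels in each dimension")
  if (is.null(dynamic_range))
    dynamic_range <- if (max(a, b) <= 1 && min(a, b) >= 0) 1 else 255
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  k <- gaussian_kernel(window, sigma)

  mu_a <- filter2_valid(a, k)
  mu_b <- filter2_valid(b, k)
  var_a <- filter2_valid(a * a, k) - mu_a^2
  var_b <- filter2_valid(b * b, k) - mu_b^2
  cov_ab <- filter2_valid(a * b, k) - mu_a * mu_b

  s <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  mean(s)
}

#' Summarise a pool: constraints, size, and optional density
#'
#' Audits every oligo and aggregates GC content, the longest homopolymer,
#' and pool-wide motif counts; with an original file size it also reports
#' the net information density.
#'
#' @param pool An `oligo_pool` or character vector of sequences.
#' @param original_size_bytes Optional original file size for the density.
#' @return An object of class `pool_metrics`: oligo count, oligo length(s),
#'   total bases, GC range, maximum homopolymer, motif count, and density
#'   (NA without a file size).
#' @examples
#' pool_summary(c("CATGACTGGATC", "ACGTACGTACGT"))
#' @export
pool_summary <- function(pool, original_size_bytes = NULL) {
  sequences <- if (inherits(pool, "oligo_pool")) pool$oligos$sequence else pool
  if (length(sequences) == 0L) stop("empty pool")
  audits <- lapply(sequences, audit_sequence)
  lens <- nchar(sequences)
  gc <- vapply(audits, `[[`, numeric(1), "gc_percent")
  structure(list(
    oligo_count = length(sequences),
    oligo_length_nt = if (length(unique(lens)) == 1L) lens[1L] else NA_integer_,
    total_nt = sum(lens),
    gc_percent_min = min(gc),
    gc_percent_max = max(gc),
    max_homopolymer = max(vapply(audits, `[[`, numeric(1), "max_homopolymer")),
    motif_count = sum(vapply(audits, function(a) nrow(a$motif_hits), integer(1))),
    net_information_density = if (is.null(original_size_bytes)) NA_real_ else
      net_information_density(original_size_bytes, 1, sum(lens))
  ), class = "pool_metrics")
}

#' @export
print.pool_metrics <- function(x, ...) {
  cat(sprintf("%d oligos, %d nt total | GC %.1f-%.1f%% | max homopolymer %d | motif hits %d\n",
              x$oligo_count, x$total_nt, x$gc_percent_min, x$gc_percent_max,
              x$max_homopolymer, x$motif_count))
  if (!is.na(x$net_information_density))
    cat(sprintf("net information density: %.2f bits/nt\n",
                x$net_information_density))
  invisible(x)
}

#' Read a raster image as a numeric array in [0, 1]
#'
#' @param path Path to a PNG file.
#' @return A matrix (grayscale) or H x W x C array.
#' @export
read_image <- function(path) png::readPNG(path)
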