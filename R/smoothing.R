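#' Sample an isotropic 2D Gaussian kernel on the genomic grid
#'
#' The kernel is sampled at grid offsets and truncated at 3 standard
#' deviations, so the half-width in grid points is `ceiling(3*sigma/spacing)`.
#' The analysis scale is defined as 6 sigma (the full kernel support), e.g. a
#' 2 Mb scale uses sigma = 1/3 Mb. Weights are normalized to sum to one,
#' which leaves peak ranking unchanged and makes convolution of a constant
#' matrix exact.
#'
#' @param sigma_bp Gaussian standard deviation in base pairs.
#' @param spacing Grid spacing in base pairs.
#' @return A `kernel_spec`: `sigma_bp`, `spacing`, half-width `h` in grid
#'   points, the normalized 1D profile `weights1d` (length `2h+1`) and the
#'   full 2D `weights` matrix (their outer product).
#' @export
sample_kernel <- function(sigma_bp, spacing) {
  if (sigma_bp <= 0 || spacing <= 0) stop("sigma_bp and spacing must be > 0")
  if (sigma_bp < spacing)
    warning("sigma (", sigma_bp, " bp) below grid spacing (", spacing,
            " bp): kernel degenerates toward a delta")
  h <- as.integer(ceiling(3 * sigma_bp / spacing))
  off <- (-h:h) * spacing
  g1 <- exp(-off^2 / (2 * sigma_bp^2))
  w1 <- g1 / sum(g1)
  out <- list(sigma_bp = sigma_bp, spacing = spacing, h = h,
              weights1d = w1, weights = outer(w1, w1))
  class(out) <- "kernel_spec"
  out
}

#' Mirror-pad a matrix at its boundaries
#'
#' Pads by reflecting the data about each edge without duplicating the edge
#' sample (row `(a, b, c)` padded by 2 becomes `(c, b, a, b, c, b, a)`).
#' Padding isolates chromosome arms: the convolution never mixes signal
#' across a centromere or chromosome boundary. When the requested depth
#' exceeds the available data the reflection continues periodically (period
#' `2n - 2`) with a warning.
#'
#' @param S Numeric matrix.
#' @param h Padding depth in grid points on every side.
#' @return A `(nrow(S) + 2h) x (ncol(S) + 2h)` matrix whose central block
#'   equals `S` exactly.
#' @export
mirror_pad <- function(S, h) {
  if (h < 1L) stop("h must be >= 1")
  if (h >= nrow(S) || h >= ncol(S))
    warning("padding depth ", h, " meets or exceeds matrix extent; ",
            "reflection wraps periodically")
  S[reflect_index(nrow(S), h), reflect_index(ncol(S), h), drop = FALSE]
}

# Indices implementing reflection about the boundaries (edge not repeated),
# extended periodically when the depth exceeds the data.
reflect_index <- function(n, h) {
  if (n == 1L) return(rep(1L, 1L + 2L * h))
  i <- seq.int(1L - h, n + h)
  m <- (i - 1L) %% (2L * n - 2L)
  m <- ifelse(m >= n, 2L * n - 2L - m, m)
  m + 1L
}

#' Convolve a score matrix into a Convolved Co-occurrence Matrix (CCM)
#'
#' Convolves the co-occurrence score matrix with the sampled 2D Gaussian
#' kernel after mirror padding, and crops back to the original shape. The
#' Gaussian is separable, so the 2D convolution is computed as two exact 1D
#' passes.
#'
#' @param S A [score_matrix()] object (or a plain numeric matrix).
#' @param kernel A [sample_kernel()] spec.
#' @return For a `score_matrix` input, a `ccm` object carrying the smoothed
#'   `values` plus mode/arm/coordinate metadata, `sigma_bp` and
#'   `scale_bp = 6 * sigma_bp`; for a plain matrix, the smoothed matrix.
#' @export
convolve_ccm <- function(S, kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  vals <- if (inherits(S, "score_matrix")) S$S else S
  if (any(!is.finite(vals))) stop("score matrix must be finite")
  h <- kernel$h
  padded <- mirror_pad(vals, h)
  k1 <- kernel$weights1d
  tmp <- stats::filter(padded, k1, method = "convolution", sides = 2)
  tmp <- t(stats::filter(t(tmp), k1, method = "convolution", sides = 2))
  out <- tmp[h + seq_len(nrow(vals)), h + seq_len(ncol(vals)), drop = FALSE]
  if (any(!is.finite(out))) stop("internal error: convolution produced NA")
  if (!inherits(S, "score_matrix")) return(out)
  res <- list(arm_a = S$arm_a, arm_b = S$arm_b, mode = S$mode,
              sigma_bp = kernel$sigma_bp, scale_bp = 6 * kernel$sigma_bp,
              values = out, pos_a = S$pos_a, pos_b = S$pos_b,
              chrom_a = S$chrom_a, chrom_b = S$chrom_b)
  class(res) <- "ccm"
  res
}
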