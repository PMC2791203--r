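#' Summed pairwise minimum of two non-negative sample vectors
#'
#' The continuous analogue of a Boolean AND: for each sample the smaller of
#' the two channel values is taken, and the minima are summed across samples.
#' High values require both loci to be aberrated in the same samples.
#'
#' @param u,v Non-negative numeric vectors of equal length (one entry per
#'   sample).
#' @return The scalar sum of per-sample minima.
#' @export
min_sum <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  if (any(u < 0) || any(v < 0)) stop("channel values must be non-negative")
  sum(pmin(u, v))
}

#' Population covariance of two sample vectors
#'
#' Covariance across samples with the 1/T (population) normalization, i.e.
#' the expectation form `E[(u - E u)(v - E v)]`. The sample (1/(T-1))
#' convention is available via `denominator`; peak ranking is invariant to
#' this constant factor, absolute scores are not.
#'
#' @param u,v Numeric vectors of equal length T >= 2.
#' @param denominator `"population"` (default, 1/T) or `"sample"` (1/(T-1)).
#' @return Scalar covariance.
#' @export
pair_covariance <- function(u, v, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  if (length(u) != length(v)) stop("u and v must have equal length")
  t_n <- length(u)
  if (t_n < 2L) stop("covariance requires at least 2 samples")
  s <- sum((u - mean(u)) * (v - mean(v)))
  if (denominator == "population") s / t_n else s / (t_n - 1L)
}

#' Co-occurrence score of a single locus pair
#'
#' The product of the summed minimum ([min_sum()]) and the across-sample
#' covariance ([pair_covariance()]). The minimum alone lets constitutively
#' aberrated loci dominate; weighting by covariance suppresses them and
#' rewards concerted change.
#'
#' @inheritParams pair_covariance
#' @return Scalar score.
#' @export
cooccurrence_score <- function(u, v, denominator = c("population", "sample")) {
  min_sum(u, v) * pair_covariance(u, v, denominator)
}

#' Pairwise co-occurrence score matrix for an arm pair
#'
#' Computes, for every pair of grid points (j on arm a, k on arm b), the
#' min-sum matrix `M`, the covariance matrix `C` and the score matrix
#' `S = M * C` (elementwise). Negative scores (anti-covarying pairs) are
#' retained; peak extraction takes maxima so they never rank.
#'
#' @param pair A [select_mode_columns()] `mode_pair`.
#' @param denominator Covariance normalization, see [pair_covariance()].
#' @return A `score_matrix` object with components `M`, `C`, `S` (each
#'   P_a x P_b), the mode, arm labels and grid coordinates.
#' @export
score_matrix <- function(pair, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pair, "mode_pair"))
  U <- pair$U
  V <- pair$V
  t_n <- nrow(U)
  if (t_n < 2L) stop("at least 2 samples are required")
  pa <- ncol(U)
  pb <- ncol(V)
  if (pa == 0L || pb == 0L) stop("empty arm in mode pair")
  M <- matrix(0, pa, pb)
  for (t in seq_len(t_n)) {
    M <- M + pmin(matrix(U[t, ], pa, pb),
                  matrix(V[t, ], pa, pb, byrow = TRUE))
  }
  Uc <- sweep(U, 2L, colMeans(U))
  Vc <- sweep(V, 2L, colMeans(V))
  den <- if (denominator == "population") t_n else t_n - 1L
  C <- crossprod(Uc, Vc) / den
  out <- list(arm_a = pair$arm_a, arm_b = pair$arm_b, mode = pair$mode,
              M = M, C = C, S = M * C,
              pos_a = pair$pos_a, pos_b = pair$pos_b,
              chrom_a = pair$chrom_a, chrom_b = pair$chrom_b)
  class(out) <- "score_matrix"
  out
}
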