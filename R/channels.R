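#' Separate a grid matrix into gain and loss channels
#'
#' Gains and losses are scored separately so that positive and negative log2
#' ratios cannot cancel when summed downstream. The gain channel retains
#' positive values, the loss channel the absolute value of negative values;
#' all other entries are zero. The original matrix is reconstructed exactly
#' as `gain - loss`, and the channels have disjoint support.
#'
#' @param A A [interpolate_dataset()] `grid_matrix`.
#' @return A list with `gain` and `loss`, each a `channel_matrix` (same
#'   layout as the input, non-negative values, plus a `channel` label).
#' @export
separate_signals <- function(A) {
  stopifnot(inherits(A, "grid_matrix"))
  if (any(!is.finite(A$values))) stop("grid matrix must be finite")
  mk <- function(vals, channel) {
    out <- list(channel = channel, sample_ids = A$sample_ids, grid = A$grid,
                values = vals, mask = A$mask)
    class(out) <- "channel_matrix"
    out
  }
  list(gain = mk(pmax(A$values, 0), "gain"),
       loss = mk(pmax(-A$values, 0), "loss"))
}

MODES <- c("gain-gain", "loss-loss", "gain-loss", "loss-gain")

#' Select the channel submatrices for one co-occurrence mode
#'
#' Gains and losses on two distinct arms give four co-occurrence modes:
#' gain-gain, loss-loss, gain-loss and loss-gain. The first half of the mode
#' name selects the channel for arm `arm_a` (matrix `U`), the second half
#' the channel for `arm_b` (matrix `V`).
#'
#' @param gain,loss The channel matrices from [separate_signals()].
#' @param mode One of `"gain-gain"`, `"loss-loss"`, `"gain-loss"`,
#'   `"loss-gain"`.
#' @param arm_a,arm_b Arm labels (e.g. `"1p"`, `"17q"`); must differ.
#' @return A `mode_pair`: `U` (samples x arm-a grid points), `V` (samples x
#'   arm-b grid points) and the per-axis grid coordinates.
#' @export
select_mode_columns <- function(gain, loss, mode, arm_a, arm_b) {
  mode <- match.arg(mode, MODES)
  if (identical(arm_a, arm_b)) stop("arm_a and arm_b must be distinct arms")
  grid <- gain$grid
  for (a in c(arm_a, arm_b))
    if (is.null(grid$arm_index[[a]])) stop("unknown arm: ", a)
  parts <- strsplit(mode, "-", fixed = TRUE)[[1]]
  ch <- list(gain = gain, loss = loss)
  ia <- grid$arm_index[[arm_a]]
  ib <- grid$arm_index[[arm_b]]
  out <- list(mode = mode, arm_a = arm_a, arm_b = arm_b,
              U = ch[[parts[1]]]$values[, ia, drop = FALSE],
              V = ch[[parts[2]]]$values[, ib, drop = FALSE],
              pos_a = grid$pos[ia], pos_b = grid$pos[ib],
              chrom_a = grid$chrom[ia[1]], chrom_b = grid$chrom[ib[1]])
  class(out) <- "mode_pair"
  out
}
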