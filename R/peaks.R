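#' Extract peaks from a convolved co-occurrence matrix
#'
#' Greedy peak picking: the global maximum of the CCM is taken as a peak, a
#' square neighborhood of half-width `exclusion_radius_bp` around it is
#' zeroed out, and the procedure repeats until `max_peaks` peaks are found or
#' no positive score remains. The default exclusion radius of 2 sigma matches
#' the reporting window used for gene annotation, guaranteeing distinct loci.
#' Ties are broken deterministically by (row, column) ascending.
#'
#' @param ccm A [convolve_ccm()] `ccm` object.
#' @param max_peaks Maximum number of peaks to emit.
#' @param exclusion_radius_bp Half-width (bp) of the square zeroed around
#'   each accepted peak; defaults to `2 * sigma`.
#' @return A data.frame with one row per peak: `chrom_a`, `arm_a`, `pos_a`,
#'   `chrom_b`, `arm_b`, `pos_b`, `score`, `mode`, `scale_bp`.
#' @export
extract_peaks <- function(ccm, max_peaks = 50L,
                          exclusion_radius_bp = 2 * ccm$sigma_bp) {
  stopifnot(inherits(ccm, "ccm"))
  if (exclusion_radius_bp < 0) stop("exclusion_radius_bp must be >= 0")
  vals <- ccm$values
  rows <- integer(0)
  cols <- integer(0)
  scores <- numeric(0)
  while (length(rows) < max_peaks) {
    top <- max(vals)
    if (top <= 0) break
    idx <- which(vals == top)
    ri <- (idx - 1L) %% nrow(vals) + 1L
    ci <- (idx - 1L) %/% nrow(vals) + 1L
    o <- order(ri, ci)[1L]
    r <- ri[o]; cc <- ci[o]
    rows <- c(rows, r)
    cols <- c(cols, cc)
    scores <- c(scores, top)
    kill_r <- abs(ccm$pos_a - ccm$pos_a[r]) <= exclusion_radius_bp
    kill_c <- abs(ccm$pos_b - ccm$pos_b[cc]) <= exclusion_radius_bp
    vals[kill_r, kill_c] <- 0
  }
  data.frame(chrom_a = rep(ccm$chrom_a, length(rows)), arm_a = rep(ccm$arm_a, length(rows)),
             pos_a = ccm$pos_a[rows],
             chrom_b = rep(ccm$chrom_b, length(rows)), arm_b = rep(ccm$arm_b, length(rows)),
             pos_b = ccm$pos_b[cols],
             score = scores,
             mode = rep(ccm$mode, length(rows)),
             scale_bp = rep(ccm$scale_bp, length(rows)),
             stringsAsFactors = FALSE)
}

#' Pool per-arm-pair peaks into a global ranked top-N list
#'
#' Peaks from all arm pairs of one (mode, scale) analysis are pooled, pairs
#' whose loci lie on the same chromosome are optionally removed (the p/q
#' pairs are computed but disregarded, as same-chromosome co-occurrence is
#' confounded by physical linkage), and the list is sorted by score and
#' truncated to `n_top`. Score ties are broken by genomic coordinates
#' ascending, then arm labels, for reproducibility.
#'
#' @param peaks A data.frame of peaks as returned by [extract_peaks()]
#'   (rows from several arm pairs may be concatenated).
#' @param n_top Number of peaks to retain.
#' @param exclude_same_chromosome Drop peaks with both loci on one
#'   chromosome (default TRUE).
#' @return The input data.frame filtered, sorted by decreasing score, with a
#'   `rank` column running 1..n.
#' @export
rank_global <- function(peaks, n_top = 50L, exclude_same_chromosome = TRUE) {
  if (n_top <= 0) stop("n_top must be positive")
  if (exclude_same_chromosome && nrow(peaks) > 0)
    peaks <- peaks[peaks$chrom_a != peaks$chrom_b, , drop = FALSE]
  if (nrow(peaks) > 0) {
    o <- order(-peaks$score, peaks$pos_a, peaks$pos_b,
               peaks$arm_a, peaks$arm_b)
    peaks <- peaks[o, , drop = FALSE]
    peaks <- utils::head(peaks, n_top)
    peaks$rank <- seq_len(nrow(peaks))
  } else {
    peaks$rank <- integer(0)
  }
  rownames(peaks) <- NULL
  peaks
}

#' Write a ranked peak list as BEDPE
#'
#' Each locus is written as the interval `peak position +/- sigma` (clamped
#' at zero), with the peak score and a name of the form
#' `<mode>/<scale>/<rank>`. Coordinates follow BEDPE's 0-based half-open
#' convention.
#'
#' @param peaks A ranked peak data.frame from [rank_global()].
#' @param path Output file.
#' @param sigma_bp Half-width of the reported interval (bp).
#' @return The path, invisibly.
#' @export
write_peaks_bedpe <- function(peaks, path, sigma_bp) {
  df <- data.frame(
    chrom1 = peaks$chrom_a,
    start1 = pmax(0, peaks$pos_a - sigma_bp),
    end1 = peaks$pos_a + sigma_bp,
    chrom2 = peaks$chrom_b,
    start2 = pmax(0, peaks$pos_b - sigma_bp),
    end2 = peaks$pos_b + sigma_bp,
    name = paste(peaks$mode, peaks$scale_bp, peaks$rank, sep = "/"),
    score = peaks$score)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a ranked peak list as TSV with full metadata
#'
#' @param peaks A ranked peak data.frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_peaks_tsv <- function(peaks, path) {
  data.table::fwrite(peaks, path, sep = "\t")
  invisible(path)
}

#' Read a peak TSV written by [write_peaks_tsv()]
#' @param path Input file.
#' @return A peak data.frame.
#' @export
read_peaks_tsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  for (col in c("chrom_a", "chrom_b", "arm_a", "arm_b", "mode"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df
}
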