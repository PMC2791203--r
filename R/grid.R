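#' Chromosome-arm definitions
#'
#' Constructs a validated table of chromosome arms, the unit of all pairwise
#' co-occurrence analyses. Coordinates are 0-based, half-open.
#'
#' @param chrom Character vector of chromosome names.
#' @param arm Character vector of arm labels, `"p"` or `"q"`.
#' @param start,end Integer vectors of arm boundaries in base pairs
#'   (0-based, half-open).
#'
#' @return A `data.frame` of class `arm_definition` with columns `chrom`,
#'   `arm`, `start`, `end` and `label` (`<chrom><arm>`).
#' @export
arm_definition <- function(chrom, arm, start, end) {
  chrom <- as.character(chrom)
  arm <- as.character(arm)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  stopifnot(length(arm) == n, length(start) == n, length(end) == n)
  if (n == 0L) stop("empty arm list")
  if (!all(arm %in% c("p", "q"))) stop("arm labels must be 'p' or 'q'")
  if (any(start >= end)) stop("arm start must be < end")
  label <- paste0(chrom, arm)
  if (anyDuplicated(label)) stop("duplicate (chromosome, arm) definitions")
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) > 1L) {
      o <- i[order(start[i])]
      if (any(start[o][-1] < end[o][-length(o)]))
        stop("overlapping arms on chromosome ", ch)
    }
  }
  out <- data.frame(chrom = chrom, arm = arm, start = start, end = end,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("arm_definition", "data.frame")
  out
}

#' Read chromosome-arm definitions from a BED file
#'
#' The BED name column must encode the arm as `<chrom>_<p|q>`. BED's native
#' 0-based half-open convention is preserved.
#'
#' @param path Path to a BED file.
#' @return An [arm_definition()] table.
#' @export
read_arms_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  nm <- strsplit(as.character(df$name), "_", fixed = TRUE)
  if (any(lengths(nm) != 2L))
    stop("arm BED name column must be of the form <chrom>_<p|q>")
  arm_definition(chrom = vapply(nm, `[`, "", 1L),
                 arm = vapply(nm, `[`, "", 2L),
                 start = df$start - 1L,   # back to BED 0-based starts
                 end = df$end)
}

#' Build an equally spaced genomic grid
#'
#' Lays a grid of spacing `spacing` over each chromosome arm, anchored at the
#' arm start. Each arm contributes `floor((end - start) / spacing) + 1` grid
#' points; grids never cross arm boundaries, so every downstream arm-pair
#' computation is exactly decomposable.
#'
#' @param arms An [arm_definition()] table.
#' @param spacing Grid spacing in base pairs (default 20000).
#'
#' @return An object of class `genomic_grid`: a list with `spacing`, the
#'   per-point vectors `chrom`, `arm`, `label`, `pos`, the `arms` table and
#'   `arm_index`, a named list mapping each arm label to its contiguous
#'   slice of grid indices.
#' @export
build_grid <- function(arms, spacing = 20000) {
  if (!inherits(arms, "arm_definition"))
    arms <- arm_definition(arms$chrom, arms$arm, arms$start, arms$end)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number")
  too_small <- arms$end - arms$start < spacing
  if (any(too_small))
    stop("spacing ", spacing, " exceeds the length of arm(s): ",
         paste(arms$label[too_small], collapse = ", "))
  per_arm <- lapply(seq_len(nrow(arms)), function(i) {
    n <- floor((arms$end[i] - arms$start[i]) / spacing) + 1
    arms$start[i] + (seq_len(n) - 1) * spacing
  })
  counts <- lengths(per_arm)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  arm_index <- stats::setNames(
    lapply(seq_along(counts), function(i) seq.int(starts[i], ends[i])),
    arms$label)
  out <- list(
    spacing = spacing,
    chrom = rep(arms$chrom, counts),
    arm = rep(arms$arm, counts),
    label = rep(arms$label, counts),
    pos = unlist(per_arm, use.names = FALSE),
    arms = arms,
    arm_index = arm_index)
  class(out) <- "genomic_grid"
  out
}

#' @export
print.genomic_grid <- function(x, ...) {
  cat("genomic_grid:", length(x$pos), "points,", nrow(x$arms),
      "arms, spacing", x$spacing, "bp\n")
  invisible(x)
}

#' Probe-level copy-number track for one sample
#'
#' @param chrom Character vector of probe chromosomes.
#' @param pos Numeric vector of probe midpositions (bp).
#' @param value Numeric vector of log2 ratios.
#' @param sample_id Sample label.
#' @return A `probe_track` data.frame with columns `chrom`, `pos`, `value`.
#' @export
probe_track <- function(chrom, pos, value, sample_id = "sample") {
  if (anyNA(value) || any(!is.finite(value)))
    stop("probe values must be finite (sample ", sample_id, ")")
  o <- order(chrom, pos)
  out <- data.frame(chrom = as.character(chrom)[o], pos = as.numeric(pos)[o],
                    value = as.numeric(value)[o], stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("probe_track", "data.frame")
  out
}

#' Interpolate one probe track onto the genomic grid
#'
#' Each grid value is a kernel-weighted regression of the probe values within
#' one grid spacing of the grid point, using a triangular kernel of maximal
#' amplitude 1 and width twice the spacing: a probe at distance `d < spacing`
#' from grid point `g` receives weight `1 - d/spacing`; a probe at exactly
#' one spacing away receives weight 0. Only probes on the grid point's own
#' arm contribute, so no information leaks across centromeres. Grid points
#' with no supporting probe (or total weight zero) are masked and set to 0.
#'
#' @param probes A [probe_track()].
#' @param grid A [build_grid()] object.
#' @return A list with numeric `values` and logical `mask` (TRUE where no
#'   probe supported the grid point), both of length `length(grid$pos)`.
#' @export
interpolate_profile <- function(probes, grid) {
  if (anyNA(probes$value)) stop("NaN/NA probe values are not allowed")
  P <- length(grid$pos)
  num <- numeric(P)
  den <- numeric(P)
  dg <- grid$spacing
  arms <- grid$arms
  used <- rep(FALSE, nrow(probes))
  for (i in seq_len(nrow(arms))) {
    sel <- probes$chrom == arms$chrom[i] &
      probes$pos >= arms$start[i] & probes$pos < arms$end[i]
    if (!any(sel)) next
    used <- used | sel
    gi <- grid$arm_index[[arms$label[i]]]
    n <- length(gi)
    r <- (probes$pos[sel] - arms$start[i]) / dg   # position in grid units
    j1 <- floor(r)
    w1 <- 1 - (r - j1)          # weight on the grid point at/below the probe
    w2 <- 1 - w1                # weight on the grid point above
    v <- probes$value[sel]
    ii <- c(j1, j1 + 1) + 1L
    ww <- c(w1, w2)
    vv <- c(v, v)
    ok <- ii >= 1L & ii <= n & ww > 0
    if (any(ok)) {
      aw <- rowsum(ww[ok], ii[ok])
      an <- rowsum(ww[ok] * vv[ok], ii[ok])
      at <- as.integer(rownames(aw))
      den[gi[at]] <- den[gi[at]] + as.vector(aw)
      num[gi[at]] <- num[gi[at]] + as.vector(an)
    }
  }
  if (!all(used))
    warning(sum(!used), " probe(s) outside all arms were dropped")
  mask <- den == 0
  values <- numeric(P)
  values[!mask] <- num[!mask] / den[!mask]
  list(values = values, mask = mask)
}

#' Interpolate a set of probe tracks into a grid matrix
#'
#' @param tracks List of [probe_track()] objects.
#' @param grid A [build_grid()] object.
#' @return An object of class `grid_matrix`: `sample_ids`, `grid`, a
#'   samples x grid-points `values` matrix and the matching logical `mask`
#'   matrix (TRUE where no probe supported the grid point).
#' @export
interpolate_dataset <- function(tracks, grid) {
  ids <- vapply(tracks, function(t) as.character(attr(t, "sample_id")), "")
  if (anyDuplicated(ids)) stop("duplicate sample_ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  P <- length(grid$pos)
  values <- matrix(0, length(tracks), P, dimnames = list(ids, NULL))
  mask <- matrix(FALSE, length(tracks), P, dimnames = list(ids, NULL))
  for (i in seq_along(tracks)) {
    r <- interpolate_profile(tracks[[i]], grid)
    values[i, ] <- r$values
    mask[i, ] <- r$mask
  }
  out <- list(sample_ids = ids, grid = grid, values = values, mask = mask)
  class(out) <- "grid_matrix"
  out
}

#' @export
print.grid_matrix <- function(x, ...) {
  cat("grid_matrix:", length(x$sample_ids), "samples x",
      length(x$grid$pos), "grid points\n")
  invisible(x)
}
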