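#' Read a probe-level copy-number table
#'
#' Tab-separated file with header `chrom  pos  <sample1> <sample2> ...` and
#' log2 ratios in the sample columns. Rows are sorted by (chrom, pos);
#' 1-based probe positions are accepted via `one_based = TRUE`, which shifts
#' them onto the package's 0-based convention.
#'
#' @param path TSV file path.
#' @param one_based Set TRUE if probe positions are 1-based.
#' @return A list of [probe_track()] objects, one per sample column.
#' @export
read_probe_table <- function(path, one_based = FALSE) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (ncol(df) < 3L) stop("probe table needs chrom, pos and >= 1 sample column")
  names(df)[1:2] <- c("chrom", "pos")
  for (j in 2:ncol(df)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))
    if (length(bad))
      stop("non-numeric or missing value in column '", names(df)[j],
           "', line ", bad[1] + 1L)
    df[[j]] <- as.numeric(df[[j]])
  }
  if (anyDuplicated(df[c("chrom", "pos")])) {
    d <- which(duplicated(df[c("chrom", "pos")]))[1]
    stop("duplicate (chrom, pos) at line ", d + 1L, ": ",
         df$chrom[d], ":", df$pos[d])
  }
  if (one_based) df$pos <- df$pos - 1
  ids <- names(df)[-(1:2)]
  lapply(ids, function(s) probe_track(df$chrom, df$pos, df[[s]], sample_id = s))
}

#' Write a probe table to TSV
#'
#' @param probes data.frame with `chrom`, `pos` and one column per sample
#'   (the `probes` element of [simulate_dataset()]).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  data.table::fwrite(probes, path, sep = "\t")
  invisible(path)
}
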