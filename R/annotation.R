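#' Read a gene annotation BED file
#'
#' The BED name column carries the gene identifier. Gene midpositions (the
#' coordinate used to assign genes to peak windows) are computed as the
#' integer midpoint of the 0-based half-open interval.
#'
#' @param path BED file with gene intervals and identifiers.
#' @return A data.frame with `gene_id`, `chrom`, `start`, `end`, `mid`.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  start0 <- df$start - 1L
  data.frame(gene_id = as.character(df$name),
             chrom = as.character(df$seqnames),
             start = start0, end = df$end,
             mid = (start0 + df$end) %/% 2,
             stringsAsFactors = FALSE)
}

#' Genes whose midposition falls in a window around a locus
#'
#' Selects genes on the locus's chromosome whose midposition lies within
#' `sigma_bp` of the locus coordinate (a 2-sigma window centered on the
#' peak), boundary inclusive at exactly +/- sigma.
#'
#' @param chrom Locus chromosome.
#' @param pos Locus coordinate (bp).
#' @param sigma_bp Window half-width (bp).
#' @param genes Gene table from [read_genes_bed()].
#' @return Character vector of gene ids (genomic order).
#' @export
genes_in_window <- function(chrom, pos, sigma_bp, genes) {
  if (sigma_bp <= 0) stop("sigma_bp must be > 0")
  sel <- genes$chrom == chrom & abs(genes$mid - pos) <= sigma_bp
  genes$gene_id[sel][order(genes$mid[sel])]
}

#' Gene sets for each peak in a ranked list
#'
#' @param peaks Ranked peak data.frame from [rank_global()].
#' @param genes Gene table from [read_genes_bed()].
#' @param sigma_bp Window half-width (bp); the analysis scale / 6.
#' @return A list with one element per peak, each holding `genes_a` and
#'   `genes_b` character vectors.
#' @export
peak_gene_sets <- function(peaks, genes, sigma_bp) {
  lapply(seq_len(nrow(peaks)), function(i) {
    list(genes_a = genes_in_window(peaks$chrom_a[i], peaks$pos_a[i], sigma_bp, genes),
         genes_b = genes_in_window(peaks$chrom_b[i], peaks$pos_b[i], sigma_bp, genes))
  })
}

#' Fisher-exact enrichment of a gene category in a selected gene set
#'
#' Builds the 2x2 contingency table of category membership versus selection
#' over a gene universe and applies a two-sided Fisher's exact test. Category
#' genes absent from the universe are dropped first.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param category Character vector of category gene ids (e.g. oncogenes).
#' @param universe Character vector of all gene ids under consideration.
#' @param category_label Label stored on the result.
#' @return An `enrichment_result` list: 2x2 `table`, `p_value`, `odds_ratio`,
#'   `category`.
#' @export
fisher_enrichment <- function(selected, category, universe,
                              category_label = "category") {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe")
  selected <- unique(selected)
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  category <- intersect(unique(category), universe)
  a <- length(intersect(selected, category))
  b <- length(setdiff(selected, category))
  cc <- length(setdiff(category, selected))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("selected", "not_selected"),
                                c("in_category", "not_in_category")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  out <- list(table = tab, p_value = unname(ft$p.value),
              odds_ratio = unname(ft$estimate), category = category_label)
  class(out) <- "enrichment_result"
  out
}

#' Read a gene-gene interaction table
#'
#' Tab-separated file with columns `gene_a`, `gene_b`, `confidence` (in
#' [0, 1]). Interactions are undirected; pairs are stored with gene ids in
#' lexicographic order and duplicates keep the maximum confidence.
#'
#' @param path TSV file path.
#' @return A data.frame with `gene_a`, `gene_b`, `confidence`.
#' @export
read_interactions <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  names(df)[1:3] <- c("gene_a", "gene_b", "confidence")
  if (any(df$confidence < 0 | df$confidence > 1))
    stop("interaction confidence must lie in [0, 1]")
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  dt <- data.table::data.table(gene_a = a, gene_b = b,
                               confidence = df$confidence)
  out <- dt[, list(confidence = max(confidence)), by = c("gene_a", "gene_b")]
  as.data.frame(out)
}

#' Read a gene-category list (one gene id per line)
#' @param path Plain-text file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' High-confidence cross-locus interacting gene pairs
#'
#' Returns all interacting pairs with one gene in `genes_a` and the other in
#' `genes_b` whose confidence strictly exceeds `threshold`. Pairs internal to
#' one locus are excluded: only between-locus functional relationships count.
#'
#' @param genes_a,genes_b Character vectors of gene ids at the two loci.
#' @param interactions Interaction table from [read_interactions()].
#' @param threshold Confidence threshold (default 0.9, exclusive).
#' @return A data.frame `gene_a`, `gene_b`, `confidence` where `gene_a` is
#'   the locus-a member of each qualifying pair.
#' @export
interaction_pairs <- function(genes_a, genes_b, interactions,
                              threshold = 0.9) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  x <- interactions[interactions$confidence > threshold, , drop = FALSE]
  ab <- x$gene_a %in% genes_a & x$gene_b %in% genes_b
  ba <- x$gene_a %in% genes_b & x$gene_b %in% genes_a
  keep <- ab | ba
  x <- x[keep, , drop = FALSE]
  flip <- ba[keep] & !ab[keep]
  out <- data.frame(gene_a = ifelse(flip, x$gene_b, x$gene_a),
                    gene_b = ifelse(flip, x$gene_a, x$gene_b),
                    confidence = x$confidence, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Interaction ratio over a set of peak gene sets
#'
#' The fraction of genes on the co-occurring loci that take part in at least
#' one qualifying cross-locus interaction: the union, over peaks, of genes in
#' qualifying pairs, divided by the union of all genes on the loci. Set
#' semantics throughout, so a gene shared between peaks is counted once.
#'
#' @param gene_sets List from [peak_gene_sets()].
#' @param interactions Interaction table.
#' @param threshold Confidence threshold (exclusive).
#' @return A list: `ratio`, `interacting_genes`, `all_genes`.
#' @export
interaction_ratio <- function(gene_sets, interactions, threshold = 0.9) {
  if (length(gene_sets) == 0L) stop("at least one peak is required")
  interacting <- character(0)
  all_genes <- character(0)
  for (gs in gene_sets) {
    all_genes <- union(all_genes, union(gs$genes_a, gs$genes_b))
    ip <- interaction_pairs(gs$genes_a, gs$genes_b, interactions, threshold)
    interacting <- union(interacting, union(ip$gene_a, ip$gene_b))
  }
  if (length(all_genes) == 0L) stop("no genes found on any locus")
  list(ratio = length(interacting) / length(all_genes),
       interacting_genes = interacting, all_genes = all_genes)
}

#' Random-locus control for interaction enrichment
#'
#' Draws `n_random` random pairs of genomic loci (arms sampled with
#' probability proportional to their grid length, positions uniform on the
#' arm grid, chromosomes of a pair forced distinct when
#' `distinct_chromosomes`), computes the pooled interaction ratio of the
#' random set with windows size-matched to the observed ones, and tests
#' observed versus random interacting-gene counts with a two-sided Fisher's
#' exact test.
#'
#' @param peaks Ranked peak data.frame (the observed co-occurring loci).
#' @param arms [arm_definition()] table to draw random loci from.
#' @param genes Gene table from [read_genes_bed()].
#' @param interactions Interaction table.
#' @param sigma_bp Window half-width (bp), matched between observed and
#'   random loci.
#' @param threshold Interaction confidence threshold (exclusive).
#' @param n_random Number of random locus pairs (default 100).
#' @param seed Integer seed; the control is fully reproducible.
#' @param spacing Grid spacing used to discretize random positions.
#' @param distinct_chromosomes Force the two loci of a random pair onto
#'   different chromosomes (default TRUE, matching the same-chromosome
#'   exclusion of the observed list).
#' @return A list: `ratio_observed`, `ratio_random`, `fisher` (an
#'   `enrichment_result`), and the random locus table.
#' @export
random_loci_control <- function(peaks, arms, genes, interactions, sigma_bp,
                                threshold = 0.9, n_random = 100L, seed = 1L,
                                spacing = 20000, distinct_chromosomes = TRUE) {
  if (n_random < 1L) stop("n_random must be >= 1")
  if (any(arms$end - arms$start < 2 * sigma_bp))
    stop("some arms are shorter than the annotation window")
  obs_sets <- peak_gene_sets(peaks, genes, sigma_bp)
  obs <- interaction_ratio(obs_sets, interactions, threshold)

  n_points <- floor((arms$end - arms$start) / spacing) + 1
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draw_locus <- function(n) {
    ai <- sample.int(nrow(arms), n, replace = TRUE, prob = n_points)
    off <- floor(stats::runif(n) * n_points[ai]) * spacing
    data.frame(chrom = arms$chrom[ai], arm = arms$label[ai],
               pos = arms$start[ai] + off, stringsAsFactors = FALSE)
  }
  la <- draw_locus(n_random)
  lb <- draw_locus(n_random)
  if (distinct_chromosomes) {
    for (i in seq_len(n_random)) {
      while (lb$chrom[i] == la$chrom[i]) lb[i, ] <- draw_locus(1L)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  rand_sets <- lapply(seq_len(n_random), function(i) {
    list(genes_a = genes_in_window(la$chrom[i], la$pos[i], sigma_bp, genes),
         genes_b = genes_in_window(lb$chrom[i], lb$pos[i], sigma_bp, genes))
  })
  rand_all <- unique(unlist(lapply(rand_sets, function(g) c(g$genes_a, g$genes_b))))
  rnd <- if (length(rand_all) == 0L) {
    list(ratio = 0, interacting_genes = character(0), all_genes = character(0))
  } else {
    interaction_ratio(rand_sets, interactions, threshold)
  }

  tab <- matrix(c(length(obs$interacting_genes),
                  length(rnd$interacting_genes),
                  length(obs$all_genes) - length(obs$interacting_genes),
                  length(rnd$all_genes) - length(rnd$interacting_genes)),
                2, 2, dimnames = list(c("observed", "random"),
                                      c("interacting", "non_interacting")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  fisher <- list(table = tab, p_value = unname(ft$p.value),
                 odds_ratio = unname(ft$estimate),
                 category = "interaction_ratio_vs_random")
  class(fisher) <- "enrichment_result"
  list(ratio_observed = obs$ratio, ratio_random = rnd$ratio,
       fisher = fisher,
       random_loci = cbind(stats::setNames(la, c("chrom_a", "arm_a", "pos_a")),
                           stats::setNames(lb, c("chrom_b", "arm_b", "pos_b"))))
}
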