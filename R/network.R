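#' Pairwise genomic distance matrix between loci
#'
#' Same-arm distances are absolute base-pair differences; loci on different
#' arms are assigned a large constant (default 1e8 bp, exceeding any
#' chromosome-arm length) so that clusters can never span an arm boundary.
#'
#' @param loci data.frame with columns `chrom`, `arm`, `pos`.
#' @param off_arm_distance Constant distance for cross-arm pairs.
#' @return A `locus_distance_matrix` list: `loci` and the square symmetric
#'   matrix `D`.
#' @export
locus_distance_matrix <- function(loci, off_arm_distance = 1e8) {
  if (nrow(loci) == 0L) stop("loci must be non-empty")
  arm_id <- paste0(loci$chrom, loci$arm)
  same_arm <- outer(arm_id, arm_id, "==")
  D <- matrix(off_arm_distance, nrow(loci), nrow(loci))
  D[same_arm] <- abs(outer(loci$pos, loci$pos, "-"))[same_arm]
  diag(D) <- 0
  out <- list(loci = loci, D = D, off_arm_distance = off_arm_distance)
  class(out) <- "locus_distance_matrix"
  out
}

#' Cluster loci by single-linkage at a distance cutoff
#'
#' Single-linkage hierarchical clustering of the locus distance matrix, with
#' the dendrogram cut at `cutoff_bp`: loci are merged while the linkage
#' distance is strictly below the cutoff (single linkage chains, so loci
#' 0, 8 Mb and 16 Mb form one cluster at a 10 Mb cutoff). Cross-arm loci can
#' never merge because the off-arm constant exceeds any sensible cutoff.
#' Cluster labels are renumbered by the genomic position of each cluster's
#' leftmost locus, so the assignment is independent of input order.
#'
#' @param dm A [locus_distance_matrix()].
#' @param cutoff_bp Dendrogram cut height in bp (default 1e7).
#' @return Integer vector assigning each locus to a cluster.
#' @export
cluster_loci <- function(dm, cutoff_bp = 1e7) {
  stopifnot(inherits(dm, "locus_distance_matrix"))
  if (cutoff_bp >= dm$off_arm_distance)
    stop("cutoff must be below the off-arm distance constant")
  n <- nrow(dm$D)
  if (n == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(dm$D), method = "single")
    # cutree merges at height <= h; distances are integer bp, so backing off
    # by half a base pair makes the cut strict at the cutoff itself
    cl <- stats::cutree(hc, h = cutoff_bp - 0.5)
  }
  key <- order(dm$loci$chrom, dm$loci$arm, dm$loci$pos)
  relabel <- integer(max(cl))
  nxt <- 0L
  for (i in key) {
    if (relabel[cl[i]] == 0L) {
      nxt <- nxt + 1L
      relabel[cl[i]] <- nxt
    }
  }
  unname(relabel[cl])
}

#' Build a co-occurrence graph from clustered loci
#'
#' Clusters become nodes; an edge joins two clusters whenever at least one
#' co-occurrence links a locus of one to a locus of the other, weighted by
#' the number of such co-occurrences (`support`). Co-occurrences internal to
#' a single cluster are dropped from the graph and reported in the
#' `dropped_within_cluster` graph attribute.
#'
#' @param assignment Integer cluster assignment from [cluster_loci()].
#' @param loci The locus table that was clustered (`chrom`, `arm`, `pos`).
#' @param cooccurrences data.frame with integer columns `idx_a`, `idx_b`
#'   indexing rows of `loci`, and optionally `rank`.
#' @param sigma_bp Half-width added to each cluster's spanned interval in
#'   the node annotation.
#' @return An `igraph` graph. Node attributes: `name`, `chrom`, `arm`,
#'   `interval`, `n_loci`, `best_rank`; edge attribute `support`.
#' @export
build_graph <- function(assignment, loci, cooccurrences, sigma_bp = 0) {
  if (length(assignment) != nrow(loci))
    stop("assignment length must match loci")
  ia <- cooccurrences$idx_a
  ib <- cooccurrences$idx_b
  if (any(is.na(ia)) || any(is.na(ib)) ||
      any(ia < 1L | ia > nrow(loci)) || any(ib < 1L | ib > nrow(loci)))
    stop("co-occurrence refers to an unassigned locus")
  ranks <- if (!is.null(cooccurrences$rank)) cooccurrences$rank
           else rep(NA_integer_, length(ia))

  k <- sort(unique(assignment))
  node_attr <- do.call(rbind, lapply(k, function(cl) {
    m <- assignment == cl
    data.frame(
      name = paste0("N", cl),
      chrom = loci$chrom[m][1],
      arm = loci$arm[m][1],
      interval = sprintf("%s:%d-%d", paste0(loci$chrom[m][1], loci$arm[m][1]),
                         as.integer(max(0, min(loci$pos[m]) - sigma_bp)),
                         as.integer(max(loci$pos[m]) + sigma_bp)),
      n_loci = sum(m), stringsAsFactors = FALSE)
  }))

  ca <- assignment[ia]
  cb <- assignment[ib]
  within <- ca == cb
  eu <- pmin(ca[!within], cb[!within])
  ev <- pmax(ca[!within], cb[!within])
  if (length(eu)) {
    tab <- table(paste(eu, ev, sep = "|"))
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    edges <- data.frame(
      from = paste0("N", vapply(parts, `[`, "", 1L)),
      to = paste0("N", vapply(parts, `[`, "", 2L)),
      support = as.integer(tab), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        support = integer(0))
  }

  best_rank <- vapply(k, function(cl) {
    r <- ranks[(ca == cl | cb == cl) & !is.na(ranks)]
    if (length(r)) min(r) else NA_integer_
  }, 1L)
  node_attr$best_rank <- best_rank

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = node_attr)
  g <- igraph::set_graph_attr(g, "dropped_within_cluster", sum(within))
  g
}

#' Prune a co-occurrence graph to its core network
#'
#' Removes edges supported by fewer than `min_fraction` of the
#' `total_cooccurrences` that built the graph (default 5% of the top 500,
#' i.e. edges of support below 25 are removed and support 25 is retained),
#' then removes nodes left without any edge.
#'
#' @param graph An `igraph` graph from [build_graph()].
#' @param total_cooccurrences The number of co-occurrences that fed the
#'   graph (default 500).
#' @param min_fraction Minimum supported fraction (default 0.05).
#' @return The pruned `igraph` graph.
#' @export
prune_core <- function(graph, total_cooccurrences = 500L,
                       min_fraction = 0.05) {
  if (min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must be in (0, 1)")
  threshold <- min_fraction * total_cooccurrences
  drop <- igraph::E(graph)[igraph::E(graph)$support < threshold]
  g <- igraph::delete_edges(graph, drop)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Write a co-occurrence graph to GraphML or SIF
#'
#' GraphML preserves all node and edge attributes; SIF carries topology only
#' (`node1 cooccurs node2` lines), for interoperability with network viewers.
#'
#' @param graph An `igraph` graph.
#' @param path Output file.
#' @param format `"graphml"` or `"sif"`.
#' @return The path, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    lines <- if (nrow(el)) paste(el[, 1], "cooccurs", el[, 2]) else character(0)
    isolated <- setdiff(igraph::V(graph)$name, as.vector(el))
    writeLines(c(lines, isolated), path)
  }
  invisible(path)
}
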