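#' Number of convolved co-occurrence matrices in a full analysis
#'
#' One CCM is computed per distinct (unordered) arm pair, per scale, per
#' gain/loss mode; self-pairs are never scored. For the 39 usable human
#' autosome arms at 3 scales and 4 modes this is
#' `choose(39, 2) * 3 * 4 = 8892`.
#'
#' @param n_arms Number of chromosome arms.
#' @param n_scales Number of analysis scales.
#' @param n_modes Number of gain/loss modes (default 4).
#' @return Integer task count.
#' @export
count_ccm_tasks <- function(n_arms, n_scales = 3L, n_modes = 4L) {
  if (n_arms < 2L) stop("at least 2 arms are required")
  choose(n_arms, 2) * n_scales * n_modes
}

#' Assemble a pipeline run configuration
#'
#' Scales are the full kernel support (6 sigma); sigma is derived as
#' `scale / 6`. Defaults mirror a genome-wide multi-scale analysis: 20 kb
#' grid, scales 2/10/20 Mb, all four modes, top 50 peaks per (mode, scale)
#' list and top 500 for network construction.
#'
#' @param probes,arms Paths to the probe TSV and arm BED inputs.
#' @param genes,interactions,categories Optional paths to the gene BED, the
#'   interaction TSV and a named list/vector of category list files.
#' @param spacing Grid spacing in bp.
#' @param scales Analysis scales in bp (6 sigma each).
#' @param modes Subset of the four modes to run.
#' @param top_n Peaks per ranked list.
#' @param network_top_n Co-occurrences fed into network construction.
#' @param interaction_threshold Confidence threshold (exclusive).
#' @param core_fraction Core-network pruning fraction.
#' @param cluster_cutoff_bp Single-linkage cut height.
#' @param off_arm_distance Cross-arm distance constant.
#' @param n_random Random locus pairs for the interaction control.
#' @param exclude_same_chromosome Drop same-chromosome peaks at ranking.
#' @param seed Integer seed for all randomized stages.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(probes, arms, genes = NULL, interactions = NULL,
                       categories = NULL, spacing = 20000,
                       scales = c(2e6, 10e6, 20e6),
                       modes = c("gain-gain", "loss-loss", "gain-loss",
                                 "loss-gain"),
                       top_n = 50L, network_top_n = 500L,
                       interaction_threshold = 0.9, core_fraction = 0.05,
                       cluster_cutoff_bp = 1e7, off_arm_distance = 1e8,
                       n_random = 100L, exclude_same_chromosome = TRUE,
                       seed = 1L, out_dir = ".") {
  if (any(scales <= 0)) stop("scales must be positive")
  modes <- match.arg(modes, MODES, several.ok = TRUE)
  cfg <- list(probes = probes, arms = arms, genes = genes,
              interactions = interactions, categories = categories,
              spacing = spacing, scales = scales, sigmas = scales / 6,
              modes = modes, top_n = as.integer(top_n),
              network_top_n = as.integer(network_top_n),
              interaction_threshold = interaction_threshold,
              core_fraction = core_fraction,
              cluster_cutoff_bp = cluster_cutoff_bp,
              off_arm_distance = off_arm_distance,
              n_random = as.integer(n_random),
              exclude_same_chromosome = exclude_same_chromosome,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Score all arm pairs of one (mode, scale) analysis
#'
#' Iterates the distinct arm pairs, computes the raw score matrix and its
#' convolution, and extracts per-pair peaks. Only one arm-pair score matrix
#' is resident at a time, so memory is bounded by the largest arm pair.
#'
#' @param gain,loss Channel matrices from [separate_signals()].
#' @param mode One of the four modes.
#' @param sigma_bp Kernel standard deviation (scale / 6).
#' @param max_peaks_per_pair Peaks extracted per arm pair.
#' @param verbose Log one line per arm pair.
#' @return A data.frame of pooled (unranked) peaks.
#' @export
scan_arm_pairs <- function(gain, loss, mode, sigma_bp,
                           max_peaks_per_pair = 50L, verbose = FALSE) {
  grid <- gain$grid
  labels <- grid$arms$label
  kern <- sample_kernel(sigma_bp, grid$spacing)
  out <- list()
  for (i in seq_len(length(labels) - 1L)) {
    for (j in seq.int(i + 1L, length(labels))) {
      pair <- select_mode_columns(gain, loss, mode, labels[i], labels[j])
      sm <- score_matrix(pair)
      ccm <- convolve_ccm(sm, kern)
      pk <- extract_peaks(ccm, max_peaks = max_peaks_per_pair)
      out[[length(out) + 1L]] <- pk
      if (verbose)
        message(sprintf("[%s sigma=%g] %s x %s: %d peak(s)", mode, sigma_bp,
                        labels[i], labels[j], nrow(pk)))
    }
  }
  do.call(rbind, out)
}

#' Run the full co-occurrence pipeline
#'
#' Reads all inputs, interpolates the probe tracks onto the genomic grid,
#' splits gains and losses, scores and convolves every distinct arm pair for
#' every requested (mode, scale), writes ranked peak lists (TSV and BEDPE),
#' and — when annotation inputs are supplied — enrichment reports and
#' co-occurrence networks (GraphML and SIF) built from the top
#' `network_top_n` co-occurrences. Deterministic given (config, seed).
#'
#' @param config A [run_config()].
#' @param verbose Log progress per arm pair.
#' @return Invisibly, a list with `peak_lists` (named `<mode>_<scale>`),
#'   `enrichment`, `networks` and the output file manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  arms <- if (is.character(config$arms)) read_arms_bed(config$arms) else config$arms
  tracks <- if (is.character(config$probes)) read_probe_table(config$probes)
            else config$probes
  grid <- build_grid(arms, config$spacing)
  A <- interpolate_dataset(tracks, grid)
  ch <- separate_signals(A)

  n_tasks <- count_ccm_tasks(nrow(arms), length(config$scales),
                             length(config$modes))
  if (verbose) message(n_tasks, " CCM task(s): ", choose(nrow(arms), 2),
                       " arm pair(s) x ", length(config$scales),
                       " scale(s) x ", length(config$modes), " mode(s)")

  genes <- if (!is.null(config$genes)) read_genes_bed(config$genes) else NULL
  inter <- if (!is.null(config$interactions))
    read_interactions(config$interactions) else NULL

  peak_lists <- list()
  enrichment <- list()
  networks <- list()
  files <- character(0)
  for (scale in config$scales) {
    sigma <- scale / 6
    for (mode in config$modes) {
      key <- sprintf("%s_%g", mode, scale)
      pooled <- scan_arm_pairs(ch$gain, ch$loss, mode, sigma,
                               max_peaks_per_pair = max(config$top_n,
                                                        config$network_top_n),
                               verbose = verbose)
      ranked <- rank_global(pooled, n_top = config$network_top_n,
                            exclude_same_chromosome = config$exclude_same_chromosome)
      top <- utils::head(ranked, config$top_n)
      peak_lists[[key]] <- top
      f_tsv <- file.path(config$out_dir, paste0("peaks_", key, ".tsv"))
      f_bedpe <- file.path(config$out_dir, paste0("peaks_", key, ".bedpe"))
      write_peaks_tsv(top, f_tsv)
      write_peaks_bedpe(top, f_bedpe, sigma)
      files <- c(files, f_tsv, f_bedpe)

      if (!is.null(genes)) {
        gs <- peak_gene_sets(top, genes, sigma)
        selected <- unique(unlist(lapply(gs, function(g) c(g$genes_a, g$genes_b))))
        universe <- unique(genes$gene_id)
        enr <- list()
        if (!is.null(config$categories)) {
          for (cat_name in names(config$categories)) {
            category <- read_gene_list(config$categories[[cat_name]])
            enr[[cat_name]] <- fisher_enrichment(selected, category, universe,
                                                 category_label = cat_name)
          }
        }
        if (!is.null(inter) && nrow(top) > 0) {
          enr[["interactions"]] <- random_loci_control(
            top, arms, genes, inter, sigma_bp = sigma,
            threshold = config$interaction_threshold,
            n_random = config$n_random, seed = config$seed,
            spacing = config$spacing)
        }
        enrichment[[key]] <- enr
        f_enr <- file.path(config$out_dir, paste0("enrichment_", key, ".tsv"))
        write_enrichment_tsv(enr, f_enr)
        files <- c(files, f_enr)
      }

      if (nrow(ranked) > 0) {
        net <- peaks_to_network(ranked, sigma_bp = sigma,
                                cutoff_bp = config$cluster_cutoff_bp,
                                off_arm_distance = config$off_arm_distance)
        core <- prune_core(net, total_cooccurrences = nrow(ranked),
                           min_fraction = config$core_fraction)
        networks[[key]] <- list(full = net, core = core)
        f_gml <- file.path(config$out_dir, paste0("network_", key, ".graphml"))
        f_sif <- file.path(config$out_dir, paste0("network_", key, ".sif"))
        f_core <- file.path(config$out_dir, paste0("core_", key, ".graphml"))
        write_network(net, f_gml, "graphml")
        write_network(net, f_sif, "sif")
        write_network(core, f_core, "graphml")
        files <- c(files, f_gml, f_sif, f_core)
      }
    }
  }
  manifest <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(
    list(spacing = config$spacing, scales = config$scales,
         modes = config$modes, n_ccm_tasks = n_tasks, seed = config$seed,
         files = basename(files)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(peak_lists = peak_lists, enrichment = enrichment,
                 networks = networks, files = c(files, manifest),
                 n_ccm_tasks = n_tasks))
}

#' Cluster a ranked peak list into a co-occurrence network
#'
#' Convenience wrapper chaining [locus_distance_matrix()], [cluster_loci()]
#' and [build_graph()] on the loci of a ranked peak list.
#'
#' @param ranked Ranked peak data.frame from [rank_global()].
#' @param sigma_bp Node-interval half-width annotation.
#' @param cutoff_bp Single-linkage cut height.
#' @param off_arm_distance Cross-arm distance constant.
#' @return An `igraph` co-occurrence graph.
#' @export
peaks_to_network <- function(ranked, sigma_bp = 0, cutoff_bp = 1e7,
                             off_arm_distance = 1e8) {
  n <- nrow(ranked)
  loci <- data.frame(
    chrom = c(ranked$chrom_a, ranked$chrom_b),
    arm = c(ranked$arm_a, ranked$arm_b),
    pos = c(ranked$pos_a, ranked$pos_b), stringsAsFactors = FALSE)
  dm <- locus_distance_matrix(loci, off_arm_distance)
  assignment <- cluster_loci(dm, cutoff_bp)
  cooc <- data.frame(idx_a = seq_len(n), idx_b = n + seq_len(n),
                     rank = ranked$rank)
  build_graph(assignment, loci, cooc, sigma_bp = sigma_bp)
}

# Flat TSV report of enrichment results for one (mode, scale) analysis.
write_enrichment_tsv <- function(enr, path) {
  rows <- lapply(names(enr), function(nm) {
    e <- enr[[nm]]
    if (inherits(e, "enrichment_result")) {
      data.frame(test = nm, p_value = e$p_value, odds_ratio = e$odds_ratio,
                 a = e$table[1, 1], b = e$table[1, 2],
                 c = e$table[2, 1], d = e$table[2, 2],
                 ratio_observed = NA_real_, ratio_random = NA_real_)
    } else {
      data.frame(test = nm, p_value = e$fisher$p_value,
                 odds_ratio = e$fisher$odds_ratio,
                 a = e$fisher$table[1, 1], b = e$fisher$table[1, 2],
                 c = e$fisher$table[2, 1], d = e$fisher$table[2, 2],
                 ratio_observed = e$ratio_observed,
                 ratio_random = e$ratio_random)
    }
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
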