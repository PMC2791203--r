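#' Generate the four archetypal locus-pair signals
#'
#' Produces sample vectors for the four qualitative relationships a pair of
#' copy-number measurements can show across a tumor panel: a random
#' (noise-only) pair, a constitutive-member pair (one locus continuously
#' aberrated, the other two-level), a co-occurring pair (concerted two-level
#' change in the same carriers) and a mutually exclusive pair (anti-concerted
#' two-level change). At zero noise the co-occurring pair has population
#' covariance `amplitude^2 * f * (1 - f)` for carrier fraction `f`.
#'
#' @param n_samples Number of samples (default 50).
#' @param amplitude Aberration amplitude in log2 units (default 2).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (default 0.1).
#' @param carrier_fraction Fraction of samples carrying the two-level signal
#'   (default 0.5; the carrier count is `round(f * n)`).
#' @param seed Integer seed.
#' @return A named list (`random`, `constitutive`, `cooccurring`,
#'   `mutually_exclusive`), each element a list with vectors `u` and `v`.
#' @export
generate_archetype_pairs <- function(n_samples = 50L, amplitude = 2,
                                     noise_sd = 0.1, carrier_fraction = 0.5,
                                     seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  n <- n_samples
  carriers <- sample.int(n, round(carrier_fraction * n))
  z <- as.numeric(seq_len(n) %in% carriers)
  noise <- function() stats::rnorm(n, 0, noise_sd)
  list(
    random = list(u = noise(), v = noise()),
    constitutive = list(u = amplitude + noise(), v = amplitude * z + noise()),
    cooccurring = list(u = amplitude * z + noise(), v = amplitude * z + noise()),
    mutually_exclusive = list(u = amplitude * z + noise(),
                              v = amplitude * (1 - z) + noise()))
}

#' Specify a planted copy-number lesion
#'
#' @param arm Arm label (must exist in the arm table used for simulation).
#' @param start,end Lesion interval in bp (0-based half-open, within the
#'   arm).
#' @param sign `"gain"` or `"loss"`.
#' @param amplitude Absolute log2 amplitude (> 0).
#' @param carrier_fraction Fraction of samples carrying the lesion.
#' @param group_id Lesions sharing a `group_id` are planted in the same
#'   carrier samples (co-occurring lesions); `NA` gives the lesion its own
#'   carrier draw.
#' @return A one-row data.frame; rows may be `rbind`-ed into a lesion table.
#' @export
lesion_spec <- function(arm, start, end, sign = c("loss", "gain"),
                        amplitude = 1, carrier_fraction = 0.5,
                        group_id = NA_character_) {
  sign <- match.arg(sign)
  if (amplitude <= 0) stop("amplitude must be > 0")
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  if (start >= end) stop("lesion start must be < end")
  data.frame(arm = arm, start = start, end = end, sign = sign,
             amplitude = amplitude, carrier_fraction = carrier_fraction,
             group_id = group_id, stringsAsFactors = FALSE)
}

#' Simulate a probe-level copy-number dataset with planted lesions
#'
#' Probes are placed along each arm at `probe_spacing` intervals with
#' uniform integer positional jitter below half the spacing, so probes and
#' grid points are misaligned by construction and the triangular-kernel
#' interpolation is exercised nontrivially. Sample baselines are 0; carriers
#' of a lesion get +/- `amplitude` over the lesion interval; i.i.d. Gaussian
#' noise is added everywhere. Lesions sharing a `group_id` are planted in
#' identical carrier sets. An optional `purity` in (0, 1] scales all lesion
#' amplitudes (tumor-cell-fraction dilution; defaults to 1, appropriate for
#' clonal cell lines).
#'
#' @param arms An [arm_definition()] table.
#' @param lesions A lesion table built from [lesion_spec()] rows (may have
#'   zero rows).
#' @param n_samples Number of samples.
#' @param probe_spacing Probe spacing in bp (default 10000).
#' @param noise_sd Gaussian noise standard deviation in log2 units
#'   (default 0.2).
#' @param seed Integer seed; output is reproducible from (config, seed).
#' @param purity Amplitude scaling in (0, 1].
#' @param carriers_by_group Optional named list mapping a `group_id` to an
#'   explicit vector of carrier sample indices, overriding the random
#'   carrier draw for that group.
#' @return A list with `probes` (data.frame `chrom`, `pos`, one column per
#'   sample) and `truth` (sample ids, per-lesion carrier lists, lesion
#'   table, noise sd, probe spacing, seed).
#' @export
simulate_dataset <- function(arms, lesions, n_samples, probe_spacing = 10000,
                             noise_sd = 0.2, seed = 1L, purity = 1,
                             carriers_by_group = NULL) {
  if (probe_spacing <= 0) stop("probe_spacing must be > 0")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (!inherits(arms, "arm_definition"))
    arms <- arm_definition(arms$chrom, arms$arm, arms$start, arms$end)
  if (nrow(lesions) > 0) {
    bad <- !(lesions$arm %in% arms$label)
    if (any(bad)) stop("lesion arm(s) not in arm table: ",
                       paste(unique(lesions$arm[bad]), collapse = ", "))
    ai <- match(lesions$arm, arms$label)
    if (any(lesions$start < arms$start[ai] | lesions$end > arms$end[ai]))
      stop("lesion interval outside its arm")
  }
  set.seed(seed)

  # carriers: one draw per group, one per ungrouped lesion
  n_lesions <- nrow(lesions)
  carriers <- vector("list", n_lesions)
  if (n_lesions > 0) {
    gid <- lesions$group_id
    gid[is.na(gid)] <- paste0(".solo", seq_len(n_lesions))[is.na(gid)]
    for (g in unique(gid)) {
      rows <- which(gid == g)
      f <- lesions$carrier_fraction[rows[1]]
      if (any(lesions$carrier_fraction[rows] != f))
        stop("lesions in group ", g, " disagree on carrier_fraction")
      cs <- if (!is.null(carriers_by_group[[g]])) {
        sort(as.integer(carriers_by_group[[g]]))
      } else {
        sort(sample.int(n_samples, round(f * n_samples)))
      }
      if (any(cs < 1L | cs > n_samples)) stop("carrier index out of range")
      for (r in rows) carriers[[r]] <- cs
    }
    # contradictory overlaps: same arm, overlapping interval, opposite sign,
    # shared carriers
    if (n_lesions > 1) {
      for (i in seq_len(n_lesions - 1)) for (j in seq.int(i + 1, n_lesions)) {
        if (lesions$arm[i] == lesions$arm[j] &&
            lesions$start[i] < lesions$end[j] &&
            lesions$start[j] < lesions$end[i] &&
            lesions$sign[i] != lesions$sign[j] &&
            length(intersect(carriers[[i]], carriers[[j]])) > 0)
          stop("overlapping contradictory lesions ", i, " and ", j,
               " share carrier samples")
      }
    }
  }

  # probe layout: regular spacing + integer jitter strictly below spacing/2
  jmax <- max(0L, as.integer(floor(probe_spacing / 2)) - 1L)
  per_arm <- lapply(seq_len(nrow(arms)), function(i) {
    base <- seq(arms$start[i], arms$end[i] - 1, by = probe_spacing)
    jit <- if (jmax > 0) sample.int(2L * jmax + 1L, length(base),
                                    replace = TRUE) - jmax - 1L else 0L
    pos <- pmin(pmax(base + jit, arms$start[i]), arms$end[i] - 1)
    data.frame(chrom = arms$chrom[i], arm = arms$label[i], pos = pos,
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, per_arm)
  np <- nrow(probes)

  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  values <- matrix(stats::rnorm(np * n_samples, 0, noise_sd), np, n_samples,
                   dimnames = list(NULL, sample_ids))
  for (l in seq_len(n_lesions)) {
    hit <- probes$arm == lesions$arm[l] &
      probes$pos >= lesions$start[l] & probes$pos < lesions$end[l]
    delta <- purity * lesions$amplitude[l] *
      if (lesions$sign[l] == "loss") -1 else 1
    values[hit, carriers[[l]]] <- values[hit, carriers[[l]]] + delta
  }

  probe_table <- cbind(probes[c("chrom", "pos")], as.data.frame(values))
  truth <- list(sample_ids = sample_ids, lesions = lesions,
                carriers = carriers, noise_sd = noise_sd,
                probe_spacing = probe_spacing, seed = seed, purity = purity)
  list(probes = probe_table, truth = truth)
}

#' Two-lineage co-deletion scenario
#'
#' Emulates lineage-specific programmed co-deletions (the positive control
#' provided by V(D)J recombination at T-cell receptor and immunoglobulin
#' loci): the sample panel splits into two lineages; lineage A carries
#' co-occurring deletions at two loci on two arms, lineage B at three loci on
#' three arms. Within-lineage locus pairs co-occur perfectly; cross-lineage
#' pairs are mutually exclusive. The default genome is four 12 Mb arms.
#'
#' @param n_samples Panel size (default 60; split evenly).
#' @param amplitude Deletion amplitude in log2 units (default 1).
#' @param noise_sd Noise standard deviation (default 0.2, i.e.
#'   amplitude/noise = 5).
#' @param lesion_size Deletion length in bp (default 2e6).
#' @param probe_spacing Probe spacing in bp (default 10000).
#' @param seed Integer seed.
#' @return As [simulate_dataset()], plus `arms`, `lineages` (sample index
#'   lists) and `planted_pairs` (data.frame of the within-lineage locus
#'   pairs with midpoints and lineage labels).
#' @export
lineage_scenario <- function(n_samples = 60L, amplitude = 1, noise_sd = 0.2,
                             lesion_size = 2e6, probe_spacing = 10000,
                             seed = 1L) {
  arms <- arm_definition(chrom = c("1", "2", "3", "4"),
                         arm = rep("p", 4),
                         start = rep(0, 4), end = rep(12e6, 4))
  half <- lesion_size / 2
  mk <- function(arm, mid, group)
    lesion_spec(arm, mid - half, mid + half, sign = "loss",
                amplitude = amplitude, carrier_fraction = 0.5,
                group_id = group)
  lesions <- rbind(
    mk("1p", 4e6, "lineageA"),   # A1
    mk("2p", 7e6, "lineageA"),   # A2
    mk("1p", 10e6, "lineageB"),  # B1
    mk("3p", 5e6, "lineageB"),   # B2
    mk("4p", 6e6, "lineageB"))   # B3
  set.seed(seed)
  a_carriers <- sort(sample.int(n_samples, round(n_samples / 2)))
  b_carriers <- setdiff(seq_len(n_samples), a_carriers)
  sim <- simulate_dataset(arms, lesions, n_samples,
                          probe_spacing = probe_spacing,
                          noise_sd = noise_sd, seed = seed,
                          carriers_by_group = list(lineageA = a_carriers,
                                                   lineageB = b_carriers))
  mids <- c(4e6, 7e6, 10e6, 5e6, 6e6)
  arms_of <- c("1p", "2p", "1p", "3p", "4p")
  pair_idx <- list(c(1L, 2L), c(3L, 4L), c(3L, 5L), c(4L, 5L))
  planted_pairs <- do.call(rbind, lapply(seq_along(pair_idx), function(i) {
    p <- pair_idx[[i]]
    data.frame(arm_a = arms_of[p[1]], mid_a = mids[p[1]],
               arm_b = arms_of[p[2]], mid_b = mids[p[2]],
               lineage = if (i == 1) "A" else "B", stringsAsFactors = FALSE)
  }))
  c(sim, list(arms = arms,
              lineages = list(A = a_carriers, B = b_carriers),
              planted_pairs = planted_pairs))
}
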