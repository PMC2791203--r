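# Shared fixture builders; everything is generated in code.

two_arm_genome <- function(len = 1e7) {
  arm_definition(chrom = c("1", "2"), arm = c("p", "p"),
                 start = c(0, 0), end = c(len, len))
}

# A mode_pair built directly from channel submatrices, bypassing the grid,
# for scoring unit tests.
raw_mode_pair <- function(U, V, mode = "gain-gain") {
  out <- list(mode = mode, arm_a = "1p", arm_b = "2p", U = U, V = V,
              pos_a = (seq_len(ncol(U)) - 1) * 20000,
              pos_b = (seq_len(ncol(V)) - 1) * 20000,
              chrom_a = "1", chrom_b = "2")
  class(out) <- "mode_pair"
  out
}

# Naive triple-loop reference for M, C and S (population covariance).
naive_score_matrix <- function(U, V) {
  pa <- ncol(U); pb <- ncol(V); t_n <- nrow(U)
  M <- matrix(0, pa, pb); C <- matrix(0, pa, pb)
  for (j in seq_len(pa)) for (k in seq_len(pb)) {
    m <- 0
    for (t in seq_len(t_n)) m <- m + min(U[t, j], V[t, k])
    M[j, k] <- m
    C[j, k] <- sum((U[, j] - mean(U[, j])) * (V[, k] - mean(V[, k]))) / t_n
  }
  list(M = M, C = C, S = M * C)
}

# Brute-force 2D convolution with mirror padding (double summation).
naive_convolve <- function(S, kernel) {
  h <- kernel$h
  P <- mirror_pad(S, h)
  out <- matrix(0, nrow(S), ncol(S))
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    acc <- 0
    for (dx in -h:h) for (dy in -h:h)
      acc <- acc + kernel$weights[dx + h + 1, dy + h + 1] *
        P[i + h + dx, j + h + dy]
    out[i, j] <- acc
  }
  out
}

# Two-sided Fisher p by full hypergeometric enumeration via choose(); the
# standard relative tolerance is used when comparing point probabilities.
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  k <- a + c          # column 1 total
  n <- a + b + c + d
  if (n == 0) return(1)
  lo <- max(0, k - (n - m))
  hi <- min(k, m)
  supp <- lo:hi
  pr <- vapply(supp, function(x)
    choose(m, x) * choose(n - m, k - x) / choose(n, k), 0)
  sum(pr[pr <= pr[supp == a] * (1 + 1e-7)])
}

# Probe tracks from a simulated probe table.
sim_tracks <- function(probes) {
  lapply(names(probes)[-(1:2)], function(s)
    probe_track(probes$chrom, probes$pos, probes[[s]], sample_id = s))
}

# Full pipeline on a simulation, in memory: ranked loss-loss peaks.
rank_losses <- function(sim, spacing = 20000, scale = 2e6, n_top = 10L) {
  grid <- build_grid(sim$arms, spacing)
  A <- interpolate_dataset(sim_tracks(sim$probes), grid)
  ch <- separate_signals(A)
  pk <- scan_arm_pairs(ch$gain, ch$loss, "loss-loss", scale / 6)
  rank_global(pk, n_top)
}

# Does ranked peak i match a planted pair (either orientation) within tol bp?
matches_planted <- function(peak, planted, tol) {
  fwd <- planted$arm_a == peak$arm_a & planted$arm_b == peak$arm_b &
    abs(planted$mid_a - peak$pos_a) <= tol & abs(planted$mid_b - peak$pos_b) <= tol
  rev <- planted$arm_a == peak$arm_b & planted$arm_b == peak$arm_a &
    abs(planted$mid_a - peak$pos_b) <= tol & abs(planted$mid_b - peak$pos_a) <= tol
  any(fwd | rev)
}
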