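toy_genes <- function(n = 100, chrom = "1", start0 = 0, step = 100000,
                      width = 20000, prefix = "G") {
  s <- start0 + (seq_len(n) - 1) * step
  data.frame(gene_id = paste0(prefix, seq_len(n)), chrom = chrom,
             start = s, end = s + width, mid = (2 * s + width) %/% 2,
             stringsAsFactors = FALSE)
}

test_that("window gene selection matches a linear-scan oracle", {
  genes <- toy_genes()
  sigma <- 1e6 / 3
  expect_true("G11" %in% genes_in_window("1", genes$mid[11], sigma, genes))
  # midposition 0.4 Mb away with sigma = 1/3 Mb: excluded
  expect_false("G11" %in%
    genes_in_window("1", genes$mid[11] + 4e5, sigma, genes))

  set.seed(41)
  rnd <- data.frame(gene_id = paste0("R", 1:100),
                    chrom = sample(c("1", "2"), 100, replace = TRUE),
                    start = 0, end = 0,
                    mid = sample(0:1e7, 100), stringsAsFactors = FALSE)
  for (pos in c(1e6, 5e6, 9e6)) {
    got <- genes_in_window("1", pos, sigma, rnd)
    want <- rnd$gene_id[rnd$chrom == "1" & abs(rnd$mid - pos) <= sigma]
    expect_setequal(got, want)
  }
  # monotone in sigma
  small <- genes_in_window("1", 5e6, 2e5, rnd)
  big <- genes_in_window("1", 5e6, 1e6, rnd)
  expect_true(all(small %in% big))
  # boundary inclusive at exactly +/- sigma
  g1 <- data.frame(gene_id = "X", chrom = "1", start = 0, end = 0, mid = 5e5)
  expect_equal(genes_in_window("1", 0, 5e5, g1), "X")
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  u <- paste0("g", 1:4)
  r1 <- fisher_enrichment(u[1:2], u[c(1, 3)], u)   # table [[1,1],[1,1]]
  expect_equal(r1$p_value, 1.0)
  expect_equal(unname(r1$table), matrix(c(1, 1, 1, 1), 2))

  r2 <- fisher_enrichment(u[1:2], u[1:2], u)       # table [[2,0],[0,2]]
  expect_equal(r2$p_value, 1 / 3, tolerance = 1e-12)

  r3 <- fisher_enrichment(u[1:2], u, u)            # category = universe
  expect_equal(r3$p_value, 1.0)

  # category genes outside the universe are dropped before testing
  r4 <- fisher_enrichment(u[1:2], c(u[1:2], "zz1", "zz2"), u)
  expect_equal(r4$table, r2$table)
  expect_error(fisher_enrichment(character(0), u, character(0)), "universe")
})

test_that("Fisher enrichment matches enumeration on all small tables", {
  for (n in 1:12) {
    combos <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    combos <- combos[combos$a + combos$b + combos$c <= n, ]
    for (r in sample(nrow(combos), min(60, nrow(combos)))) {
      a <- combos$a[r]; b <- combos$b[r]; cc <- combos$c[r]
      d <- n - a - b - cc
      p_ref <- enumerate_fisher_p(a, b, cc, d)
      p_got <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      expect_equal(p_got, p_ref, tolerance = 1e-9,
                   label = sprintf("table (%d,%d,%d,%d)", a, b, cc, d))
    }
  }
})

toy_interactions <- function() {
  data.frame(gene_a = c("a1", "a1", "a2", "b1"),
             gene_b = c("b1", "a2", "b2", "b2"),
             confidence = c(0.95, 0.99, 0.5, 0.92), stringsAsFactors = FALSE)
}

test_that("cross-locus interaction pairs honour threshold and locus split", {
  A <- c("a1", "a2"); B <- c("b1", "b2")
  ip <- interaction_pairs(A, B, toy_interactions(), 0.9)
  # (a1,b1) 0.95 in; (a1,a2) within-locus out; (a2,b2) 0.5 below; (b1,b2)
  # within-locus out
  expect_equal(nrow(ip), 1L)
  expect_equal(ip$gene_a, "a1")
  expect_equal(ip$gene_b, "b1")

  set.seed(42)
  ga <- paste0("x", 1:15); gb <- paste0("y", 1:15)
  tbl <- expand.grid(gene_a = c(ga, gb), gene_b = c(ga, gb),
                     stringsAsFactors = FALSE)
  tbl <- tbl[tbl$gene_a < tbl$gene_b, ]
  tbl$confidence <- runif(nrow(tbl))
  got <- interaction_pairs(ga, gb, tbl, 0.8)
  want <- 0L
  for (i in seq_len(nrow(tbl))) {
    x <- tbl$gene_a[i]; y <- tbl$gene_b[i]
    if (tbl$confidence[i] > 0.8 &&
        ((x %in% ga && y %in% gb) || (x %in% gb && y %in% ga)))
      want <- want + 1L
  }
  expect_equal(nrow(got), want)
  expect_true(all(got$gene_a %in% ga) && all(got$gene_b %in% gb))
})

test_that("interaction ratio uses set semantics over peaks", {
  gs <- list(list(genes_a = paste0("a", 1:10), genes_b = paste0("b", 1:10)))
  none <- interaction_ratio(gs, toy_interactions()[0, ], 0.9)
  expect_equal(none$ratio, 0)

  # 4 interacting among 20 genes -> 0.2
  tbl <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    confidence = c(0.95, 0.93))
  r <- interaction_ratio(gs, tbl, 0.9)
  expect_equal(r$ratio, 4 / 20)
  expect_setequal(r$interacting_genes, c("a1", "a2", "b1", "b2"))

  # a gene shared between two peaks is counted once in both sets
  gs2 <- c(gs, list(list(genes_a = paste0("a", 1:10),
                         genes_b = paste0("c", 1:10))))
  r2 <- interaction_ratio(gs2, tbl, 0.9)
  expect_equal(r2$ratio, 4 / 30)
  expect_equal(r2$ratio,
               interaction_ratio(rev(gs2), tbl, 0.9)$ratio)
  expect_equal(interaction_ratio(c(gs2, gs2[2]), tbl, 0.9)$ratio, r2$ratio)
  expect_error(interaction_ratio(list(list(genes_a = character(0),
                                           genes_b = character(0))),
                                 tbl, 0.9), "no genes")
})

test_that("random-locus control is seeded and matches its expectation", {
  arms <- arm_definition(as.character(1:10), rep("p", 10),
                         rep(0, 10), rep(5e7, 10))
  sigma <- 2.5e5
  genes <- do.call(rbind, lapply(1:10, function(i)
    toy_genes(n = 1000, chrom = as.character(i), start0 = 0, step = 50000,
              prefix = paste0("c", i, "g"))))
  peaks <- data.frame(chrom_a = "1", arm_a = "p", pos_a = 1e6,
                      chrom_b = "2", arm_b = "p", pos_b = 2e6,
                      score = 1, mode = "loss-loss", scale_bp = 6 * sigma,
                      rank = 1L)

  mk_inter <- function(seed, d = 0.15) {
    set.seed(seed)
    ids <- genes$gene_id
    n_pairs <- 30000L
    a <- ids[sample.int(length(ids), n_pairs, replace = TRUE)]
    b <- ids[sample.int(length(ids), n_pairs, replace = TRUE)]
    keep <- a != b
    data.frame(gene_a = a[keep], gene_b = b[keep],
               confidence = ifelse(runif(sum(keep)) < d, 0.95, 0.1),
               stringsAsFactors = FALSE)
  }

  inter <- mk_inter(1)
  r1 <- random_loci_control(peaks, arms, genes, inter, sigma, n_random = 20,
                            seed = 7, spacing = 50000)
  r2 <- random_loci_control(peaks, arms, genes, inter, sigma, n_random = 20,
                            seed = 7, spacing = 50000)
  expect_identical(r1$random_loci, r2$random_loci)
  expect_identical(r1$fisher$p_value, r2$fisher$p_value)

  # empty interaction table: both ratios zero, p = 1
  r0 <- random_loci_control(peaks, arms, genes, inter[0, ], sigma,
                            n_random = 10, seed = 3, spacing = 50000)
  expect_equal(r0$ratio_observed, 0)
  expect_equal(r0$ratio_random, 0)
  expect_equal(r0$fisher$p_value, 1.0)

  # realized random ratio tracks the per-gene analytic expectation
  obs <- exp_p <- var_sum <- n_genes <- numeric(20)
  for (s in 1:20) {
    inter_s <- mk_inter(100 + s)
    high <- inter_s[inter_s$confidence > 0.9, ]
    rc <- random_loci_control(peaks, arms, genes, high, sigma,
                              n_random = 20, seed = 200 + s,
                              spacing = 50000)
    sets <- lapply(seq_len(nrow(rc$random_loci)), function(i)
      list(a = genes_in_window(rc$random_loci$chrom_a[i],
                               rc$random_loci$pos_a[i], sigma, genes),
           b = genes_in_window(rc$random_loci$chrom_b[i],
                               rc$random_loci$pos_b[i], sigma, genes)))
    all_g <- unique(unlist(sets))
    key <- paste(pmin(high$gene_a, high$gene_b),
                 pmax(high$gene_a, high$gene_b))
    # per-gene expectation from realized cross-locus partner counts and the
    # realized high-confidence pair density
    partners <- lapply(stats::setNames(all_g, all_g), function(g) character(0))
    for (st in sets) {
      for (g in st$a) partners[[g]] <- union(partners[[g]], st$b)
      for (g in st$b) partners[[g]] <- union(partners[[g]], st$a)
    }
    d_hat <- length(unique(key)) / choose(length(unique(genes$gene_id)), 2)
    p_g <- vapply(partners, function(pp)
      1 - (1 - d_hat)^length(setdiff(pp, "")), 0)
    obs[s] <- rc$ratio_random
    exp_p[s] <- mean(p_g)
    var_sum[s] <- sum(p_g * (1 - p_g))
    n_genes[s] <- length(all_g)
  }
  se <- sqrt(sum(var_sum / n_genes^2)) / 20
  expect_lt(abs(mean(obs) - mean(exp_p)), 3 * se + 1e-12)
})
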