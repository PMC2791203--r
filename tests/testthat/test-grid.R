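test_that("grid construction follows the per-arm point count", {
  g1 <- build_grid(arm_definition("1", "p", 0, 100000), 20000)
  expect_equal(g1$pos, seq(0, 100000, by = 20000))

  g2 <- build_grid(arm_definition(c("1", "1"), c("p", "q"),
                                  c(0, 1.2e6), c(1e6, 2.2e6)), 20000)
  expect_length(g2$pos, 102L)
  expect_equal(lengths(g2$arm_index), c(`1p` = 51L, `1q` = 51L))

  # a 39-arm genome: total count equals the per-arm oracle, summed
  set.seed(11)
  lens <- round(stats::runif(39, 15e6, 250e6))
  starts <- c(rep(0, 20), rep(3e8, 19))
  arms <- arm_definition(chrom = as.character(c(1:20, 1:19)),
                         arm = c(rep("p", 20), rep("q", 19)),
                         start = starts, end = starts + lens)
  g <- build_grid(arms, 20000)
  expect_equal(length(g$pos), sum(floor(lens / 20000) + 1))
})

test_that("grid construction rejects degenerate input", {
  expect_error(arm_definition(character(0), character(0), numeric(0), numeric(0)),
               "empty")
  expect_error(build_grid(arm_definition("1", "p", 0, 5000), 20000), "1p")
  expect_error(arm_definition(c("1", "1"), c("p", "q"), c(0, 5e5), c(1e6, 2e6)),
               "overlap")
  expect_error(arm_definition(c("1", "1"), c("p", "p"), c(0, 2e6), c(1e6, 3e6)),
               "duplicate")
})

test_that("triangular-kernel interpolation matches hand evaluation", {
  g <- build_grid(arm_definition("1", "p", 0, 100000), 20000)

  # probes at +5 kb (1.0) and +10 kb (2.0) from the 40 kb grid point:
  # weights 0.75 and 0.5, value (0.75 + 1.0) / 1.25 = 1.4
  pt <- probe_track(c("1", "1"), c(45000, 50000), c(1.0, 2.0))
  r <- interpolate_profile(pt, g)
  expect_equal(r$values[3], 1.4)

  # single probe exactly on a grid point, isolated: weight 1, value copied
  pt2 <- probe_track("1", 60000, 0.7)
  r2 <- interpolate_profile(pt2, g)
  expect_equal(r2$values[4], 0.7)
  expect_false(r2$mask[4])

  # dense constant profile: every unmasked grid value equals the constant
  pos <- seq(500, 99500, by = 3000)
  r3 <- interpolate_profile(probe_track(rep("1", length(pos)), pos,
                                        rep(0.3, length(pos))), g)
  expect_equal(r3$values[!r3$mask], rep(0.3, sum(!r3$mask)))
  expect_false(any(r3$mask))
})

test_that("interpolation boundary and error contracts hold", {
  g <- build_grid(arm_definition("1", "p", 0, 100000), 20000)
  # probe at exactly one spacing from its only in-range grid points gets
  # weight 0 on the far point; a probe exactly on 20 kb supports only 20 kb
  r <- interpolate_profile(probe_track("1", 20000, 1.5), g)
  expect_equal(r$values[2], 1.5)
  expect_true(all(r$mask[-2]))
  expect_equal(r$values[c(1, 3)], c(0, 0))

  expect_warning(interpolate_profile(probe_track(c("1", "9"), c(1e3, 1e3),
                                                 c(1, 1)), g),
                 "outside")
  expect_error(probe_track("1", 1000, NaN), "finite")
})

test_that("interpolation is order-invariant and convex", {
  set.seed(5)
  g <- build_grid(two_arm_genome(1e6), 20000)
  pos <- sort(sample(0:999999, 300))
  chrom <- sample(c("1", "2"), 300, replace = TRUE)
  val <- rnorm(300)
  a <- interpolate_profile(probe_track(chrom, pos, val), g)
  shuf <- sample(300)
  b <- interpolate_profile(probe_track(chrom[shuf], pos[shuf], val[shuf]), g)
  expect_identical(a, b)
  expect_true(all(a$values[!a$mask] >= min(val) - 1e-12))
  expect_true(all(a$values[!a$mask] <= max(val) + 1e-12))
  expect_true(all(a$values[a$mask] == 0))
})

test_that("dataset interpolation is row-wise and rejects duplicate ids", {
  set.seed(6)
  g <- build_grid(two_arm_genome(1e6), 20000)
  tracks <- lapply(1:10, function(i) {
    pos <- sort(sample(0:999999, 120))
    probe_track(sample(c("1", "2"), 120, replace = TRUE), pos, rnorm(120),
                sample_id = paste0("t", i))
  })
  gm <- interpolate_dataset(tracks, g)
  for (i in c(1, 4, 10)) {
    r <- interpolate_profile(tracks[[i]], g)
    expect_equal(unname(gm$values[i, ]), r$values)
    expect_equal(unname(gm$mask[i, ]), r$mask)
  }
  same <- interpolate_dataset(list(tracks[[1]],
                                   `attr<-`(tracks[[1]], "sample_id", "b"),
                                   `attr<-`(tracks[[1]], "sample_id", "c")), g)
  expect_equal(same$values[1, ], same$values[2, ], ignore_attr = TRUE)
  expect_equal(same$values[2, ], same$values[3, ], ignore_attr = TRUE)
  expect_error(interpolate_dataset(list(tracks[[1]], tracks[[1]]), g),
               "duplicate")
})
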