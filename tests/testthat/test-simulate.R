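test_that("the synthetic genome is deterministic with plausible tracks", {
  g1 <- sim_genome(seed = 5)
  g2 <- sim_genome(seed = 5)
  expect_identical(g1, g2)
  expect_true(all(g1$gc >= 0.3 & g1$gc <= 0.6))
  expect_true(all(g1$map > 0 & g1$map <= 1))
  expect_gt(nrow(g1), 2800)  # hg19 autosomes at 1 Mb
})

test_that("profiles attach integer copies and a consistent ploidy", {
  g <- tiny_genome(seed = 1)
  p <- sim_profile(g, tibble::tibble(chrom = "chr1", start = 0, end = 30e6, copies = 4))
  expect_equal(unique(p$copies[p$chrom == "chr1" & p$start < 30e6]), 4L)
  expect_equal(unique(p$copies[p$chrom == "chr2"]), 2L)
  expect_equal(attr(p, "ploidy"), mean(p$copies[p$valid]))

  hp <- default_tumor_profile(sim_genome(seed = 2))
  expect_gt(attr(hp, "ploidy"), 2)
  expect_lt(attr(hp, "ploidy"), 2.2)
  expect_gt(mean(hp$copies != 2), 0.3)  # heavy SCNA burden
})

test_that("simulated counts follow the admixture forward model", {
  g <- tiny_genome(seed = 2)
  neutral <- sim_profile(g)

  # fixed seed is bit-identical
  a <- simulate_counts(neutral, tf = 0.2, total_reads = 2e5, seed = 9)
  b <- simulate_counts(neutral, tf = 0.2, total_reads = 2e5, seed = 9)
  expect_identical(a$count, b$count)

  # tf = 0 without GC bias: expectation flat up to mappability, no GC trend
  flat <- simulate_counts(neutral, tf = 0, total_reads = 5e5, gc_bias = FALSE, seed = 3)
  rel <- flat$count / flat$map
  expect_lt(abs(cor(rel, flat$gc, method = "spearman")), 0.05)
  halves <- split(rel, seq_along(rel) %% 2)
  expect_lt(abs(mean(halves[[1]]) / mean(halves[[2]]) - 1), 0.05)

  # tf = 1 with a c = 4 region at phi-normalization: region mean 2x neutral
  p4 <- sim_profile(g, tibble::tibble(chrom = "chr1", start = 0, end = 20e6, copies = 4))
  tr <- simulate_counts(p4, tf = 1, total_reads = 1e6, gc_bias = FALSE, seed = 4)
  in4 <- tr$chrom == "chr1" & tr$start < 20e6 & tr$map > 0.9
  neut <- tr$chrom != "chr1" & tr$map > 0.9
  ratio <- (mean(tr$count[in4]) / mean(tr$map[in4])) /
    (mean(tr$count[neut]) / mean(tr$map[neut]))
  expect_equal(ratio, 2, tolerance = 0.03)

  expect_error(simulate_counts(neutral, tf = 1.5), "\\[0, 1\\]")
})

test_that("downsampling is binomial thinning", {
  g <- tiny_genome(seed = 3)
  tr <- simulate_counts(sim_profile(g), tf = 0, total_reads = 5e5, seed = 2)
  expect_identical(downsample(tr, 1, seed = 1)$count, tr$count)
  expect_true(all(downsample(tr, 0, seed = 1)$count == 0))

  half <- downsample(tr, 0.5, seed = 8)
  expect_true(all(half$count <= tr$count))
  tot <- sum(tr$count)
  expect_lt(abs(sum(half$count) - tot / 2), 3 * sqrt(tot * 0.25))
  expect_error(downsample(tr, 1.5), "\\[0, 1\\]")
})

test_that("serial mixtures hit the requested proportions and coverage", {
  g <- tiny_genome(seed = 4)
  tumor <- simulate_counts(
    sim_profile(g, tibble::tibble(chrom = "chr1", start = 0, end = 60e6, copies = 3)),
    tf = 0.78, total_reads = 2e6, seed = 11)
  normal <- simulate_counts(sim_profile(g), tf = 0, total_reads = 2e6, seed = 12)

  mix <- serial_mixture(tumor, normal, tumor_prop = 0.4, total_reads = 4e5, seed = 13)
  expect_lt(abs(sum(mix$count) - 4e5), 3 * sqrt(4e5))

  # tumor_prop = 0 is statistically a thinned normal (flat genome)
  mix0 <- serial_mixture(tumor, normal, tumor_prop = 0, total_reads = 4e5, seed = 14)
  r <- mean(mix0$count[mix0$chrom == "chr1"]) / mean(mix0$count[mix0$chrom != "chr1"])
  expect_lt(abs(r - 1), 0.05)

  # mixture linearity: chr1 enrichment scales with tumor proportion
  mix1 <- serial_mixture(tumor, normal, tumor_prop = 1, total_reads = 4e5, seed = 15)
  r1 <- mean(mix1$count[mix1$chrom == "chr1"]) / mean(mix1$count[mix1$chrom != "chr1"])
  rexp <- (2 + 0.78) / 2  # 3 copies at purity 0.78 over diploid
  expect_equal(r1, rexp, tolerance = 0.05)

  g2 <- build_bin_grid(c(chr1 = 2e6)); g2$count <- c(1L, 1L)
  expect_error(serial_mixture(tumor, g2, 0.5), "grids")
})

test_that("exact-TF mixtures use the printed read formulas", {
  g <- tiny_genome(seed = 6)
  ct <- simulate_counts(sim_profile(g), tf = 0, total_reads = 1e6, seed = 21)
  hd <- simulate_counts(sim_profile(g), tf = 0, total_reads = 2e6, seed = 22)

  res <- exact_tf_mixture(ct, hd, target_tf = 0.10, wes_purity = 0.5,
                          total_reads = 1.5e6, seed = 23)
  expect_equal(res$spec$ct_reads, 3e5)
  expect_equal(res$spec$hd_reads, 1.2e6)
  expect_equal(res$spec$expected_tf, 0.10)

  pure <- exact_tf_mixture(ct, hd, target_tf = 0, wes_purity = 0.5,
                           total_reads = 1.5e6, seed = 24)
  expect_equal(pure$spec$ct_reads, 0)

  expect_error(exact_tf_mixture(ct, hd, 0.6, 0.5), "exceed")
  expect_error(exact_tf_mixture(ct, hd, 0.5, 0.5, total_reads = 5e6), "insufficient")

  # ten-step ladder gives ten mixtures per source pair
  specs <- lapply(seq(0.01, 0.10, by = 0.01), function(tf) {
    exact_tf_mixture(ct, hd, tf, wes_purity = 0.5, seed = round(100 * tf))$spec
  })
  expect_length(specs, 10)
  expect_equal(vapply(specs, function(s) s$expected_tf, numeric(1)),
               seq(0.01, 0.10, by = 0.01))
})

test_that("spike-ins rescale event bins by the admixture ratio", {
  g <- tiny_genome(seed = 7)
  neutral <- simulate_counts(sim_profile(g), tf = 0, total_reads = 2e6, seed = 31)

  none <- spike_in(neutral, tibble::tibble(chrom = character(), start = numeric(),
                                           end = numeric(), kind = character()),
                   tf = 0.2, seed = 1)
  expect_identical(none$count, neutral$count)

  ev <- tibble::tibble(chrom = "chr2", start = 0, end = 60e6, kind = "gain")
  sp <- spike_in(neutral, ev, tf = 0.2, seed = 32)
  idx <- sp$chrom == "chr2"
  obs <- log2(mean(sp$count[idx]) / mean(neutral$count[idx]))
  expect_equal(obs, log2((2 * 0.8 + 3 * 0.2) / 2), tolerance = 0.02)
  expect_equal(unique(sp$true_copies[idx]), 3L)
  expect_equal(unique(sp$true_copies[!idx]), 2L)

  loss <- spike_in(neutral, tibble::tibble(chrom = "chr3", start = 0, end = 60e6,
                                           kind = "loss"), tf = 0.2, seed = 33)
  idx3 <- loss$chrom == "chr3"
  expect_equal(log2(mean(loss$count[idx3]) / mean(neutral$count[idx3])),
               log2(0.9), tolerance = 0.02)

  overlap <- tibble::tibble(chrom = c("chr2", "chr2"), start = c(0, 30e6),
                            end = c(40e6, 50e6), kind = c("gain", "loss"))
  expect_error(spike_in(neutral, overlap, tf = 0.1), "overlap")
})
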