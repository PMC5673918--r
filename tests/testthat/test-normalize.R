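test_that("LOESS correction removes injected GC and mappability bias", {
  genome <- tiny_genome(seed = 3)
  profile <- sim_profile(genome)

  # no bias injected: corrected stays proportional to raw, no GC correlation
  flat <- simulate_counts(profile, tf = 0, total_reads = 4e5, gc_bias = FALSE, seed = 1)
  cf <- loess_correct(flat)
  ok <- cf$valid
  expect_lt(abs(cor(cf$corrected[ok], cf$gc[ok], method = "spearman")), 0.05)

  # quadratic GC bias: decorrelated after correction
  biased <- simulate_counts(profile, tf = 0, total_reads = 4e5, gc_bias = TRUE, seed = 2)
  okr <- biased$valid & is_autosome(biased$chrom)
  raw_rho <- cor(biased$count[okr], biased$gc[okr], method = "spearman")
  cb <- loess_correct(biased)
  okc <- cb$valid
  rho <- cor(cb$corrected[okc], cb$gc[okc], method = "spearman")
  expect_gt(abs(raw_rho), 0.2)  # the injected bias is real
  expect_lt(abs(rho), 0.05)

  # mappability-degraded bins (counts halved) restored within 10%
  degraded <- flat
  low <- withr::with_seed(9, sample(which(degraded$valid), 40))
  degraded$map[low] <- 0.5
  degraded$count[low] <- rbinom(40, degraded$count[low], 0.5)
  cd <- loess_correct(degraded, min_mappability = 0.3)
  base <- mean(cd$corrected[cd$valid & !(seq_len(nrow(cd)) %in% low)])
  expect_lt(abs(mean(cd$corrected[low]) / base - 1), 0.1)

  expect_error(loess_correct(flat[1:50, ]), "at least")
})

test_that("sex inference applies both printed criteria", {
  mk <- function(y_prop, x_med) {
    n_a <- 200; n_x <- 50; n_y <- 10
    total <- 1e5
    y_counts <- rep(y_prop * total / n_y, n_y)
    a_counts <- rep((total - sum(y_counts)) / (n_a + n_x), n_a + n_x)
    tibble::tibble(
      chrom = c(rep("chr1", n_a), rep("chrX", n_x), rep("chrY", n_y)),
      start = 0, end = 1e6, bin = 1:(n_a + n_x + n_y), valid = TRUE,
      count = c(a_counts, y_counts),
      corrected = c(rep(1, n_a), rep(2^x_med, n_x), rep(0.5, n_y))
    )
  }
  expect_equal(as.character(infer_sex(mk(0.002, -0.6))), "male")
  expect_equal(as.character(infer_sex(mk(0.0005, -0.6))), "female")
  expect_equal(as.character(infer_sex(mk(0.002, -0.3))), "female")
  expect_warning(sx <- infer_sex(tibble::tibble(chrom = "chr1", count = 1)), "chrX/chrY")
  expect_equal(as.character(sx), "female")
})

test_that("male chrX rescaling divides by the chrX median", {
  tr <- tibble::tibble(chrom = c("chr1", "chrX", "chrX", "chrX"),
                       valid = TRUE, corrected = c(1, 2, 4, 6))
  out <- rescale_male_chrX(tr)
  expect_equal(out$corrected, c(1, 0.5, 1, 1.5))

  allsame <- tibble::tibble(chrom = rep("chrX", 5), valid = TRUE, corrected = rep(3, 5))
  expect_equal(rescale_male_chrX(allsame)$corrected, rep(1, 5))

  rnd <- tibble::tibble(chrom = rep("chrX", 101), valid = TRUE,
                        corrected = withr::with_seed(5, runif(101, 0.5, 2)))
  expect_equal(median(rescale_male_chrX(rnd)$corrected), 1)

  none <- tibble::tibble(chrom = "chr1", valid = TRUE, corrected = 1)
  expect_error(rescale_male_chrX(none), "chrX")
})

test_that("reference panel is the per-bin median and flags bad bins", {
  g <- build_bin_grid(c(chr1 = 3e6))
  mk <- function(vals) { t <- g; t$corrected <- vals; t }
  one <- build_reference(list(mk(c(1, 2, 3))))
  expect_equal(one$h, c(1, 2, 3))

  three <- build_reference(list(mk(c(1, 1, 1)), mk(c(2, 2, 2)), mk(c(9, 9, 9))))
  expect_equal(three$h, c(2, 2, 2))
  expect_equal(attr(three, "n_samples"), 3)

  bad <- build_reference(list(mk(c(1, 0, NA))))
  expect_equal(bad$valid, c(TRUE, FALSE, FALSE))

  expect_error(build_reference(list()), "empty")
  g2 <- build_bin_grid(c(chr1 = 2e6))
  t2 <- g2; t2$corrected <- c(1, 1)
  expect_error(build_reference(list(mk(c(1, 1, 1)), t2)), "grid")
})

test_that("panel median is a consistent estimator of the common bin mean", {
  genome <- tiny_genome(seed = 8)
  profile <- sim_profile(genome)
  tracks <- lapply(1:27, function(i) {
    loess_correct(simulate_counts(profile, tf = 0, total_reads = 4e5,
                                  gc_bias = FALSE, seed = 100 + i))
  })
  ref <- build_reference(tracks)
  # corrected tracks are mean-1; h should sit within 3 SE of 1 per bin
  reads_per_bin <- 4e5 / nrow(genome)
  se_median <- 1.2533 / sqrt(27 * reads_per_bin)
  frac_in <- mean(abs(ref$h[ref$valid] - 1) < 3 * se_median)
  expect_gt(frac_in, 0.98)
})

test_that("log2 ratios invert exactly and compose with the reference", {
  genome <- tiny_genome(seed = 4)
  tr <- loess_correct(simulate_counts(sim_profile(genome), tf = 0,
                                      total_reads = 4e5, seed = 3))
  self_ref <- build_reference(list(tr))
  lr <- log2_ratio(tr, self_ref)
  expect_true(all(abs(lr$l[lr$valid]) < 1e-12))

  double <- self_ref
  double$h <- double$h / 2
  lr2 <- log2_ratio(tr, double)
  expect_true(all(abs(lr2$l[lr2$valid] - 1) < 1e-12))

  # inversion: 2^l * h recovers corrected bit-for-bit
  other <- build_reference(lapply(1:3, function(i) {
    loess_correct(simulate_counts(sim_profile(genome), tf = 0,
                                  total_reads = 4e5, seed = 50 + i))
  }))
  lr3 <- log2_ratio(tr, other)
  ok <- lr3$valid
  expect_equal(2^lr3$l[ok] * other$h[ok], tr$corrected[ok])
})

test_that("full normalization of a tumor-free sample is centered with no GC trend", {
  genome <- tiny_genome(seed = 12)
  profile <- sim_profile(genome)
  ref <- build_reference(lapply(1:10, function(i) {
    loess_correct(simulate_counts(profile, tf = 0, total_reads = 4e5, seed = 200 + i))
  }))
  lr <- normalize_track(simulate_counts(profile, tf = 0, total_reads = 4e5, seed = 300), ref)
  ok <- lr$valid
  expect_lt(abs(median(lr$l[ok])), 0.05)
  expect_lt(abs(cor(lr$l[ok], lr$gc[ok], method = "spearman")), 0.05)
})
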