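single_geno <- function(dos, pos) {
  geno_matrix(matrix(dos, nrow = 1), variant_table("1", pos), "ind1")
}

test_that("homozygous runs are called under the stated window rules", {
  # 60 fully homozygous SNPs spanning ~400 kb, even spacing
  pos <- seq(1e6, 1e6 + 400e3, length.out = 60)
  g <- single_geno(rep(0L, 60), pos)
  seg <- call_roh(g)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 60L)
  expect_equal(seg$start, as.integer(pos[1]))
  expect_equal(seg$end, as.integer(pos[60]))
  expect_equal(seg$length, seg$end - seg$start + 1)

  # only 40 SNPs: below min_snps, no call
  g40 <- single_geno(rep(0L, 40), seq(1e6, 1.4e6, length.out = 40))
  expect_equal(nrow(call_roh(g40)), 0L)

  # one heterozygote in the middle is tolerated (window_het = 1) and
  # stays inside the segment
  dos <- rep(0L, 60); dos[30] <- 1L
  seg2 <- call_roh(single_geno(dos, pos))
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$n_snps, 60L)
  expect_equal(seg2$n_het, 1L)

  # a gap larger than max_gap splits the run and both halves fail min_snps
  pos3 <- c(seq(1e6, 1e6 + 29 * 5e3, by = 5e3),
            seq(3e6, 3e6 + 29 * 5e3, by = 5e3))
  expect_equal(nrow(call_roh(single_geno(rep(0L, 60), pos3))), 0L)
})

test_that("ROH caller matches the naive window reimplementation", {
  set.seed(77)
  for (rep in 1:60) {
    L <- sample(30:200, 1)
    p_het <- sample(c(0.02, 0.05, 0.2), 1)
    dos <- ifelse(runif(L) < p_het, 1L, ifelse(runif(L) < 0.5, 0L, 2L))
    dos[runif(L) < 0.03] <- NA
    pos <- sort(sample.int(L * 8000L, L))
    w <- sample(c(5L, 10L, 25L), 1)
    params <- list(window_snps = w, window_het = sample(0:1, 1),
                   window_missing = 2L, hit_threshold = 0.05,
                   min_snps = sample(c(5L, 15L), 1), min_length_bp = 5e4,
                   max_gap_bp = sample(c(5e4, 1e6), 1), density_bp = 5e4)
    got <- do.call(call_roh, c(list(single_geno(dos, pos)), params))
    want <- naive_roh(dos, pos, params$window_snps, params$window_het,
                      params$window_missing, params$hit_threshold,
                      params$min_snps, params$min_length_bp,
                      params$max_gap_bp, params$density_bp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("emitted segments satisfy their own invariants and het monotonicity", {
  sim <- simulate_populations(sim_config(n_diploid = 25, n_sites = 1500,
                                         chrom_length = 1.5e7, n_pops = 1,
                                         sweep_pop = "none",
                                         total_generations = 150, seed = 31))
  g <- sim$genotypes[[1]]
  seg <- call_roh(g)
  expect_gt(nrow(seg), 0)
  expect_true(all(seg$n_snps >= 50))
  expect_true(all(seg$length >= 3e5))
  expect_true(all(seg$length / seg$n_snps <= 5e4))
  expect_true(all(seg$start <= seg$end))
  # flipping homozygous calls to heterozygous never lengthens a segment
  d2 <- g$dosages
  set.seed(8)
  flip <- sample(length(d2), length(d2) %/% 20)
  d2[flip] <- 1L
  seg2 <- call_roh(geno_matrix(d2, g$variants, g$individual_ids))
  expect_lte(sum(seg2$length), sum(seg$length))
})

test_that("length classes use half-open (lower, upper] boundaries", {
  seg <- tibble::tibble(length = c(5e6, 1e6, 3e6, 2e6, 20e6),
                        individual_id = "i", chrom = "1")
  sp <- classify_spectrum(seg)
  expect_equal(as.character(sp$class),
               c("0-2 Mb", "2-4 Mb", "4-8 Mb", "8-16 Mb", ">16 Mb"))
  expect_equal(sp$n, c(2L, 1L, 1L, 0L, 1L))  # exactly-2 Mb run is "0-2 Mb"
  expect_equal(sum(sp$n), nrow(seg))
  expect_equal(sp$mean_length_bp[1], mean(c(1e6, 2e6)))
  expect_true(is.na(sp$mean_length_bp[4]))
})

test_that("F_ROH is summed ROH length over autosome length", {
  seg <- tibble::tibble(individual_id = c("a", "a", "b"),
                        length = c(2e8, 0.497e8, 1e7))
  f <- froh(seg, l_auto = 2.497e9, individual_ids = c("a", "b", "c"))
  expect_equal(f$froh, c(0.1, 1e7 / 2.497e9, 0))
  expect_error(froh(seg, l_auto = 1e8), "exceeds")
  expect_equal(froh(tibble::tibble(individual_id = character(),
                                   length = numeric()),
                    l_auto = 1e6, individual_ids = "x")$froh, 0)
})

test_that("island track flags the uppermost coverage percentile", {
  v <- variant_table("1", seq(1e5, 2e6, by = 1e4))
  # 9/10 individuals share a ROH over a 1 Mb core; background ROH in 2
  segs <- dplyr::bind_rows(
    tibble::tibble(individual_id = paste0("i", 1:9), chrom = "1",
                   start = 5e5, end = 1.5e6),
    tibble::tibble(individual_id = paste0("i", 1:2), chrom = "1",
                   start = 1.9e6, end = 2.0e6)
  )
  segs$length <- segs$end - segs$start + 1
  isl <- island_track(segs, v, n_individuals = 10, top_fraction = 0.05)
  covered <- v$pos >= 5e5 & v$pos <= 1.5e6
  expect_equal(unique(isl$percent[covered]), 90)
  expect_true(all(isl$pos[isl$significant] >= 5e5 &
                  isl$pos[isl$significant] <= 1.5e6))
  # simple count check: 7/10 individuals -> 70%
  segs2 <- tibble::tibble(individual_id = paste0("i", 1:7), chrom = "1",
                          start = 1e5, end = 1e5, length = 1)
  isl2 <- island_track(segs2, variant_table("1", 1e5), 10)
  expect_equal(isl2$percent, 70)
  # uniform coverage: ties at the threshold are flagged
  isl3 <- island_track(segs2, variant_table("1", c(1e5, 1e5 + 1)), 10)
  expect_true(all(isl3$significant ==
                    (isl3$percent >= attr(isl3, "threshold"))))
})

test_that("mean F_ROH rises as simulated populations become more inbred", {
  mean_froh <- function(N, seed) {
    sim <- simulate_populations(sim_config(
      n_diploid = N, n_sites = 1500, chrom_length = 1.5e7, n_pops = 1,
      sweep_pop = "none", total_generations = 150, seed = seed))
    g <- sim$genotypes[[1]]
    seg <- call_roh(g)
    mean(froh(seg, variants = g$variants,
              individual_ids = g$individual_ids)$froh)
  }
  grid <- c(15, 40, 100)
  f <- vapply(seq_along(grid), function(i) mean_froh(grid[i], 700 + i), 0)
  expect_lt(cor(grid, f, method = "spearman"), 0)
})
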