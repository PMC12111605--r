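test_that("EHH group refinement reproduces hand-enumerated values", {
  # 4 carriers of the focal allele; at the next marker they split (0,0,1,1)
  A <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1), c(1, 1, 1))
  h <- hap_matrix(A, variant_table("1", c(1000, 2000, 3000)))
  d <- ehh_at(h, 1, 1, stop_threshold = 0, max_extension = Inf)
  right <- d$points[d$points$side == "right", ]
  expect_equal(right$value, c((2 * 1 + 2 * 1) / (4 * 3), 1 / 3))
  # value at the focal SNP is 1 whenever there are >= 2 carriers
  expect_equal(d$points$value[d$points$side == "focal"], 1)

  # once every carrier is distinct, EHH = 0 and the scan stops
  A2 <- rbind(c(1, 0, 0, 0), c(1, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 1, 1))
  h2 <- hap_matrix(A2, variant_table("1", c(10, 20, 30, 40)))
  d2 <- ehh_at(h2, 1, 1, stop_threshold = 0, max_extension = Inf)
  r2 <- d2$points[d2$points$side == "right", ]
  expect_equal(r2$value, c(1 / 3, 0))  # scan stopped before column 4

  # fewer carriers than min_carriers: not computable, no exception
  h3 <- hap_matrix(rbind(c(1, 0), c(0, 0), c(0, 1), c(0, 0)),
                   variant_table("1", c(10, 20)))
  expect_null(ehh_at(h3, 1, 1, min_carriers = 2))
})

test_that("EHHS includes the focal site's own alleles in the haplotype", {
  A <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1))
  h <- hap_matrix(A, variant_table("1", c(1000, 2000, 3000)))
  d <- ehhs_at(h, 2, stop_threshold = 0, max_extension = Inf)
  # focal alleles (0,0,1,1): groups (2,2) -> EHHS = 1/3 at the focal itself
  expect_equal(d$anchor, 1 / 3)
  expect_equal(d$points$value, rep(1 / 3, 3))

  # monomorphic segment: EHHS = 1 throughout
  hm <- hap_matrix(matrix(0L, 4, 5), variant_table("1", 1:5 * 100))
  dm <- ehhs_at(hm, 3, stop_threshold = 0, max_extension = Inf)
  expect_true(all(dm$points$value == 1))

  # include_focal = FALSE starts from a single group
  d0 <- ehhs_at(h, 2, stop_threshold = 0, max_extension = Inf,
                include_focal = FALSE)
  expect_equal(d0$anchor, 1)
})

test_that("trapezoidal integration matches hand arithmetic", {
  mk <- function(pos, val, truncated = FALSE) {
    structure(list(points = tibble::tibble(
      side = c("focal", rep("right", length(pos) - 1)), pos = pos,
      value = val),
      focal_pos = pos[1], anchor = val[1], stop_threshold = 0,
      truncated = c(left = FALSE, right = truncated),
      hit_end = c(left = FALSE, right = FALSE)), class = "ehh_decay")
  }
  # (0, 1.0), (1000, 0.5), (2000, 0.0) -> 750 + 250
  expect_equal(integrate_decay(mk(c(0, 1000, 2000), c(1, 0.5, 0)),
                               gap_cap_bp = Inf), 1000)
  # flat EHH = 1 over 10 kb
  expect_equal(integrate_decay(mk(c(0, 10000), c(1, 1)), gap_cap_bp = Inf),
               10000)
  # single-point decay (focal at a chromosome end): 0
  expect_equal(integrate_decay(mk(0, 1)), 0)
  # truncation interpolates linearly down to the threshold crossing
  d <- mk(c(0, 1000, 2000), c(1, 0.5, 0), truncated = TRUE)
  d$stop_threshold <- 0.05
  # crossing at 1900 bp: 750 + (0.5 + 0.05)/2 * 900
  expect_equal(integrate_decay(d, gap_cap_bp = Inf), 750 + 247.5)
  # gap cap limits each interval's width
  expect_equal(integrate_decay(mk(c(0, 50000), c(1, 1)), gap_cap_bp = 2e4),
               2e4)
})

test_that("raw scan statistics match the direct-enumeration oracle", {
  for (seed in 1:12) {
    n_hap <- sample(seq(6, 20, by = 2), 1)
    m <- sample(10:50, 1)
    h <- random_panel(n_hap, m, seed)
    sc <- scan_ihs(h, max_extension = Inf, gap_cap_bp = Inf, bin_width = 1,
                   min_bin_count = 1)
    expect_equal(sc$raw, oracle_unihs(h), tolerance = 1e-12)
    ok <- is.finite(sc$raw)
    if (any(ok)) {
      expect_equal(sc$score[ok], oracle_standardize(sc$raw)[ok],
                   tolerance = 1e-12)
    }
    h2 <- random_panel(n_hap, m, seed + 1000)
    h2$variants <- h$variants
    x <- scan_xpehh(h, h2, max_extension = Inf, gap_cap_bp = Inf)
    expect_equal(x$raw, oracle_unxp(h, h2), tolerance = 1e-12)
    r <- scan_rsb(h, h2, max_extension = Inf, gap_cap_bp = Inf)
    expect_equal(r$raw, oracle_unrsb(h, h2), tolerance = 1e-12)
  }
})

test_that("decay-object path and fused scan path agree", {
  h <- random_panel(16, 40, 99)
  sc <- scan_ihs(h, max_extension = Inf, gap_cap_bp = Inf, bin_width = 1,
                 min_bin_count = 1)
  for (j in c(3, 17, 33)) {
    da <- ehh_at(h, j, 0, stop_threshold = 0.05, max_extension = Inf)
    dd <- ehh_at(h, j, 1, stop_threshold = 0.05, max_extension = Inf)
    if (is.null(da) || is.null(dd)) {
      expect_true(is.na(sc$raw[j]))
    } else {
      ia <- integrate_decay(da, gap_cap_bp = Inf)
      id <- integrate_decay(dd, gap_cap_bp = Inf)
      expect_equal(sc$raw[j], log(ia / id), tolerance = 1e-12)
    }
  }
  t1 <- integrated_ehhs(h, max_extension = Inf, gap_cap_bp = Inf)
  for (j in c(5, 21)) {
    ds <- ehhs_at(h, j, stop_threshold = 0.05, max_extension = Inf)
    expect_equal(t1$ies[j], integrate_decay(ds, gap_cap_bp = Inf),
                 tolerance = 1e-12)
  }
})

test_that("swapping ancestral/derived labels flips uniHS; population swap negates XP-EHH", {
  h <- random_panel(14, 30, 42)
  hf <- hap_matrix(1L - h$alleles, h$variants)
  a <- scan_ihs(h, bin_width = 1, min_bin_count = 1)
  b <- scan_ihs(hf, bin_width = 1, min_bin_count = 1)
  expect_equal(a$raw, -b$raw)
  h2 <- random_panel(14, 30, 43)
  h2$variants <- h$variants
  x12 <- scan_xpehh(h, h2)
  x21 <- scan_xpehh(h2, h)
  expect_identical(x12$raw, -x21$raw)
  # identical populations: zero everywhere scores exist (and the
  # degenerate zero-variance track warns)
  expect_warning(xs <- scan_xpehh(h, h), "zero-variance")
  expect_true(all(xs$raw[!is.na(xs$raw)] == 0))
  expect_warning(rs <- scan_rsb(h, h), "zero-variance")
  expect_true(all(rs$raw[!is.na(rs$raw)] == 0))
})

test_that("Rsb is invariant under a population-wide rescaling of iES", {
  h1 <- random_panel(12, 30, 7)
  h2 <- random_panel(12, 30, 8)
  h2$variants <- h1$variants
  t1 <- integrated_ehhs(h1)
  t2 <- integrated_ehhs(h2)
  r0 <- scan_rsb(h1, h2, ies1 = t1, ies2 = t2)
  t2s <- t2
  t2s$ies <- t2s$ies * 3.7
  r1 <- scan_rsb(h1, h2, ies1 = t1, ies2 = t2s)
  expect_equal(r0$raw, r1$raw, tolerance = 1e-12)
  # XP-EHH, by contrast, shifts by the log factor
  x0 <- scan_xpehh(h1, h2, ies1 = t1, ies2 = t2)
  x1 <- scan_xpehh(h1, h2, ies1 = t1, ies2 = t2s)
  expect_equal(x1$raw - x0$raw, rep(-log(3.7), length(x0$raw)),
               tolerance = 1e-12)
})

test_that("standardize centres and scales within strata", {
  expect_equal(standardize(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_warning(z <- standardize(c(2, 2, 2)), "zero-variance")
  expect_equal(z, c(0, 0, 0))
  x <- c(rnorm(20, 5, 2), rnorm(30, -1, 0.5))
  s <- standardize(x, rep(1:2, c(20, 30)))
  for (g in split(s, rep(1:2, c(20, 30)))) {
    expect_equal(mean(g), 0, tolerance = 1e-12)
    expect_equal(sqrt(mean(g^2)), 1, tolerance = 1e-12)
  }
  # small strata merge with their neighbour before standardizing
  s2 <- standardize(c(1, 2, 3, 10), strata = c(1, 1, 1, 2), min_count = 2)
  expect_equal(s2, oracle_standardize(c(1, 2, 3, 10)), tolerance = 1e-12)
})

test_that("p-value transform matches the Gaussian two-sided tail", {
  expect_equal(pvalue_transform(0), 0)
  expect_equal(pvalue_transform(1.959964), -log10(0.05), tolerance = 1e-4)
  x <- seq(-4, 4, by = 0.37)
  expect_equal(pvalue_transform(x), pvalue_transform(-x))
  expect_equal(pvalue_transform(2.5), -log10(2 * pnorm(-2.5)),
               tolerance = 1e-12)
  # extreme scores clamp instead of overflowing
  expect_equal(pvalue_transform(60, cap = 320), 320)
})

test_that("EHH curves stay in [0,1], start at 1 and never increase outward", {
  sim <- simulate_populations(sim_config(n_diploid = 40, n_sites = 300,
                                         chrom_length = 3e6, n_pops = 1,
                                         sweep_pop = "none",
                                         total_generations = 60, seed = 5))
  h <- sim$pops[[1]]
  for (j in seq(10, 290, by = 35)) {
    for (al in 0:1) {
      d <- ehh_at(h, j, al, stop_threshold = 0, max_extension = Inf)
      if (is.null(d)) next
      for (sd in c("left", "right")) {
        v <- d$points$value[d$points$side == sd]
        if (sd == "left") v <- rev(v)
        vv <- c(1, v)
        expect_true(all(vv >= 0 & vv <= 1))
        expect_true(all(diff(vv) <= 1e-12))
      }
    }
    ds <- ehhs_at(h, j, stop_threshold = 0, max_extension = Inf)
    v <- ds$points$value
    expect_true(all(v >= 0 & v <= 1))
    i0 <- which(ds$points$side == "focal")
    expect_true(all(diff(v[i0:length(v)]) <= 1e-12))
    expect_true(all(diff(rev(v[1:i0])) <= 1e-12))
  }
})

test_that("iHS scores have mean 0 and sd 1 within every frequency bin", {
  h <- random_panel(60, 400, 314)
  sc <- scan_ihs(h)
  bins <- pmin(findInterval(sc$daf, seq(0, 1, by = 0.025),
                            rightmost.closed = TRUE), 40)
  # reconstruct the merged strata the scan used
  merged <- sweepscan:::merge_small_strata(bins, is.finite(sc$raw), 10)
  for (g in unique(merged)) {
    z <- sc$score[merged == g & is.finite(sc$score)]
    if (length(z) < 2) next
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  }
})
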