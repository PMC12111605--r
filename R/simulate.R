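#' Configuration for the two-population sweep simulator
#'
#' Forward diploid Wright-Fisher model on a single chromosome with
#' standing variation (no new mutation), Poisson recombination, optional
#' additive viability selection at one sweep site, and an optional
#' population split. Defaults describe the desk-scale scenario the
#' package is validated on: two populations of 100 diploids, 2000 SNPs on
#' a 20 Mb chromosome at 1e-8 Morgan/bp (100 Mb per Morgan), founder
#' frequencies uniform on (0.05, 0.95), a 50-generation shared burn-in
#' before the split, and a sweep starting from frequency 0.05.
#'
#' @param n_diploid diploid individuals per population.
#' @param n_sites number of SNPs.
#' @param chrom_length chromosome length, bp.
#' @param recomb_rate recombination rate, Morgan per bp.
#' @param founder_freq_range range of founder derived-allele frequencies.
#' @param n_pops 1 or 2 populations.
#' @param split_generation generation at which the ancestral population is
#'   duplicated (ignored when `n_pops = 1`).
#' @param total_generations generations simulated in total.
#' @param s additive selection coefficient (fitness 1, 1+s, 1+2s).
#' @param sweep_pos requested sweep position, bp (nearest SNP is used);
#'   chromosome midpoint by default.
#' @param sweep_start_freq initial derived frequency at the sweep site.
#' @param sweep_pop which population(s) selection acts in after the split:
#'   `"1"`, `"2"`, `"both"` or `"none"`.
#' @param sweep_inject when the derived sweep allele enters: `"founding"`
#'   places it at `sweep_start_freq` among the founders (a sweep from
#'   standing variation), `"sel_start"` zeroes the site at founding and
#'   injects `round(2N * sweep_start_freq)` copies (at least one, a de
#'   novo hard sweep) into the selected population(s) in the generation
#'   selection switches on.
#' @param sel_start generation at which selection switches on (default:
#'   after the split, or generation 1 for a single population).
#' @param stop_at_freq stop simulating once the sweep frequency in the
#'   (first) selected population reaches this value.
#' @param condition rerun policy: `"none"`, `"not_lost"` (sweep allele
#'   still segregating or fixed at the end), `"fixed"`, or
#'   `"reach_target"` (`stop_at_freq` was reached). Reruns draw fresh
#'   randomness from the same seeded stream; attempts are logged.
#' @param max_attempts maximum conditioning reruns.
#' @param seed integer seed governing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_diploid = 100, n_sites = 2000, chrom_length = 2e7,
                       recomb_rate = 1e-8,
                       founder_freq_range = c(0.05, 0.95), n_pops = 2,
                       split_generation = 50, total_generations = 100,
                       s = 0, sweep_pos = NULL, sweep_start_freq = 0.05,
                       sweep_pop = "both", sweep_inject = c("founding",
                                                            "sel_start"),
                       sel_start = NULL, stop_at_freq = NULL,
                       condition = c("none", "not_lost", "fixed",
                                     "reach_target"),
                       max_attempts = 100, seed = 1) {
  condition <- match.arg(condition)
  sweep_inject <- match.arg(sweep_inject)
  sweep_pop <- as.character(sweep_pop)
  stopifnot(n_diploid >= 2, n_sites >= 2, chrom_length > n_sites,
            recomb_rate >= 0, n_pops %in% c(1, 2), s >= -1,
            sweep_pop %in% c("1", "2", "both", "none"))
  if (is.null(sweep_pos)) sweep_pos <- chrom_length / 2
  stopifnot(sweep_pos >= 1, sweep_pos <= chrom_length)
  if (is.null(sel_start)) {
    sel_start <- if (n_pops == 2) split_generation + 1 else 1
  }
  structure(list(
    n_diploid = n_diploid, n_sites = n_sites, chrom_length = chrom_length,
    recomb_rate = recomb_rate, founder_freq_range = founder_freq_range,
    n_pops = n_pops, split_generation = split_generation,
    total_generations = total_generations, s = s, sweep_pos = sweep_pos,
    sweep_start_freq = sweep_start_freq, sweep_pop = sweep_pop,
    sweep_inject = sweep_inject, sel_start = sel_start,
    stop_at_freq = stop_at_freq,
    condition = condition, max_attempts = max_attempts, seed = seed
  ), class = "sim_config")
}

#' Run the Wright-Fisher sweep simulator
#'
#' Simulates phased haplotypes under the scenario in a [sim_config()]:
#' founders are drawn site-wise from the standing-variation spectrum, the
#' ancestral population drifts (with recombination) to the split, the two
#' daughter populations then evolve independently, and an additive sweep
#' may act on one site in chosen population(s). Deterministic under the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return A `sweep_sim` list: `pops` (list of [hap_matrix()], one per
#'   population), `genotypes` (list of [geno_matrix()]), and `truth` with
#'   the sweep site/position, per-generation frequency trajectories,
#'   final frequencies, fixation/loss flags, attempts used and the seed.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  for (attempt in seq_len(config$max_attempts)) {
    res <- sim_once(config)
    if (sim_satisfies(res, config)) {
      res$truth$attempts <- attempt
      pops <- lapply(res$haps, function(a) hap_matrix(a, res$variants))
      return(structure(list(pops = pops,
                            genotypes = lapply(pops, hap_to_geno),
                            truth = res$truth),
                       class = "sweep_sim"))
    }
  }
  stop("simulate_populations: conditioning not met within max_attempts")
}

sim_satisfies <- function(res, config) {
  tr <- res$truth
  pop_sel <- switch(config$sweep_pop, "1" = 1L, "2" = min(2L, config$n_pops),
                    "both" = 1L, "none" = 1L)
  f <- tr$final_freq[pop_sel]
  switch(config$condition,
         none = TRUE,
         not_lost = f > 0,
         fixed = f == 1,
         reach_target = !is.null(config$stop_at_freq) &&
           tr$reached_target)
}

sim_once <- function(cfg) {
  m <- cfg$n_sites
  N <- cfg$n_diploid
  pos <- sort(sample.int(cfg$chrom_length, m))
  fq <- stats::runif(m, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  haps <- matrix(stats::rbinom(2 * N * m, 1L, rep(fq, each = 2 * N)),
                 nrow = 2 * N)
  sweep_idx <- which.min(abs(pos - cfg$sweep_pos))
  col <- integer(2 * N)
  if (cfg$sweep_inject == "founding") {
    k0 <- round(2 * N * cfg$sweep_start_freq)
    col[sample.int(2 * N, k0)] <- 1L
  }
  haps[, sweep_idx] <- col
  sel_in <- function(pop) cfg$sweep_pop == "both" || cfg$sweep_pop == as.character(pop)

  traj <- list()
  pops <- list(haps)
  reached <- FALSE
  pop_sel <- switch(cfg$sweep_pop, "1" = 1L, "2" = 2L, 1L)
  gen_stop <- cfg$total_generations
  for (gen in seq_len(cfg$total_generations)) {
    if (cfg$n_pops == 2 && gen == cfg$split_generation + 1 && length(pops) == 1) {
      pops <- list(pops[[1]], pops[[1]])
    }
    if (cfg$sweep_inject == "sel_start" && gen == cfg$sel_start &&
        cfg$sweep_pop != "none") {
      k0 <- max(1L, round(2 * N * cfg$sweep_start_freq))
      for (ip in seq_along(pops)) {
        if (length(pops) == 1 || sel_in(ip)) {
          cc <- integer(2 * N)
          cc[sample.int(2 * N, k0)] <- 1L
          pops[[ip]][, sweep_idx] <- cc
        }
      }
    }
    for (ip in seq_along(pops)) {
      s_now <- if (gen >= cfg$sel_start &&
                   (length(pops) == 1 || sel_in(ip)) &&
                   cfg$sweep_pop != "none") cfg$s else 0
      pops[[ip]] <- wf_generation(pops[[ip]], pos, cfg$chrom_length,
                                  cfg$recomb_rate, sweep_idx, s_now)
    }
    for (ip in seq_along(pops)) {
      traj[[length(traj) + 1L]] <- c(gen, ip, mean(pops[[ip]][, sweep_idx]))
    }
    fsel <- mean(pops[[min(pop_sel, length(pops))]][, sweep_idx])
    if (!is.null(cfg$stop_at_freq) && fsel >= cfg$stop_at_freq) {
      reached <- TRUE
      gen_stop <- gen
      break
    }
    # a lost sweep allele can never satisfy a conditioning rule: stop the
    # attempt now rather than simulate the remaining generations
    if (cfg$condition != "none" && fsel == 0 &&
        (cfg$sweep_inject == "founding" || gen >= cfg$sel_start)) {
      gen_stop <- gen
      break
    }
  }
  if (cfg$n_pops == 2 && length(pops) == 1) pops <- list(pops[[1]], pops[[1]])
  trm <- do.call(rbind, traj)
  variants <- variant_table(chrom = "1", pos = pos)
  final_freq <- vapply(pops, function(a) mean(a[, sweep_idx]), 0)
  list(
    haps = pops, variants = variants,
    truth = list(
      sweep_index = sweep_idx, sweep_pos = pos[sweep_idx],
      s = cfg$s, sweep_pop = cfg$sweep_pop,
      trajectory = tibble::tibble(generation = trm[, 1], pop = trm[, 2],
                                  freq = trm[, 3]),
      final_freq = final_freq,
      fixed = final_freq == 1, lost = final_freq == 0,
      generations_run = gen_stop, reached_target = reached,
      seed = cfg$seed
    )
  )
}

# one diploid Wright-Fisher generation with additive viability selection
# at sweep_idx and Poisson crossovers (compiled hot loop)
wf_generation <- function(haps, pos, chrom_length, recomb_rate, sweep_idx, s) {
  wf_generation_cpp(haps, pos, chrom_length, chrom_length * recomb_rate,
                    sweep_idx - 1L, s)
}

#' @export
print.sweep_sim <- function(x, ...) {
  cat(sprintf(
    "<sweep_sim> %d population(s) of %d individuals, %d sites; sweep at %s bp (s = %g), final freq %s\n",
    length(x$pops), length(x$pops[[1]]$individual_ids),
    n_sites(x$pops[[1]]), format(x$truth$sweep_pos, big.mark = ","),
    x$truth$s, paste(sprintf("%.3f", x$truth$final_freq), collapse = " / ")))
  invisible(x)
}

#' Small neutral haplotype panel for tests and examples
#'
#' Draws `2n` haplotypes from a pool of `n_founders` founder haplotypes
#' whose site frequencies are uniform; a small founder pool induces
#' strong linkage (2 founders give complete LD), a pool of size `2n`
#' leaves only the finite-sample background. When the pool is at least
#' as large as the sample, founders are used at most once each.
#'
#' @param n diploid individuals.
#' @param m SNP count.
#' @param seed integer seed.
#' @param n_founders founder haplotype pool size.
#' @param spacing_bp distance between adjacent SNPs, bp.
#' @return A [hap_matrix()].
#' @export
neutral_fixture <- function(n, m, seed = 1, n_founders = 2 * n,
                            spacing_bp = 5000) {
  set.seed(seed)
  fq <- stats::runif(m, 0.05, 0.95)
  founders <- matrix(stats::rbinom(n_founders * m, 1L,
                                   rep(fq, each = n_founders)),
                     nrow = n_founders)
  rows <- founders[sample.int(n_founders, 2 * n,
                              replace = n_founders < 2 * n), , drop = FALSE]
  hap_matrix(rows, variant_table(chrom = "1", pos = spacing_bp * seq_len(m)))
}
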