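# Independent direct-enumeration oracles. These share no code with the
# package internals: haplotype grouping is done by pasting allele strings,
# integration is recomputed from the written definition.

# homozygosity of the partition of `rows` by identity of A[, cols] (plus
# an optional per-row prefix key)
oracle_group_hom <- function(A, rows, cols, prefix = NULL) {
  n <- length(rows)
  if (n < 2) return(NA_real_)
  key <- apply(A[rows, cols, drop = FALSE], 1, paste, collapse = ",")
  if (!is.null(prefix)) key <- paste(prefix, key)
  tab <- table(key)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

# decay curve on one side, recomputing every window from scratch
oracle_side <- function(A, pos, focal, rows, side, stop, prefix = NULL) {
  m <- ncol(A)
  out_pos <- numeric(0); out_val <- numeric(0)
  t <- focal + side
  truncated <- FALSE
  while (t >= 1 && t <= m) {
    cols <- min(focal, t):max(focal, t)
    v <- oracle_group_hom(A, rows, cols, prefix)
    out_pos <- c(out_pos, pos[t]); out_val <- c(out_val, v)
    if (v < stop) { truncated <- TRUE; break }
    if (v == 0) break
    t <- t + side
  }
  list(pos = out_pos, val = out_val, truncated = truncated)
}

# trapezoid area with interpolation down to the stop threshold
oracle_area_side <- function(anchor_pos, anchor_val, sd, stop) {
  px <- c(anchor_pos, sd$pos); v <- c(anchor_val, sd$val)
  k <- length(v)
  if (k < 2) return(0)
  a <- 0
  for (i in 2:k) {
    w <- abs(px[i] - px[i - 1])
    if (i == k && sd$truncated) {
      f <- (v[i - 1] - stop) / (v[i - 1] - v[i])
      a <- a + (v[i - 1] + stop) / 2 * w * f
    } else {
      a <- a + (v[i - 1] + v[i]) / 2 * w
    }
  }
  a
}

# per-site iHH for one core allele; NA when carriers < 2 or area 0
oracle_ihh <- function(A, pos, focal, allele, stop = 0.05) {
  rows <- which(A[, focal] == allele)
  if (length(rows) < 2) return(NA_real_)
  left <- oracle_side(A, pos, focal, rows, -1L, stop)
  right <- oracle_side(A, pos, focal, rows, +1L, stop)
  oracle_area_side(pos[focal], 1, left, stop) +
    oracle_area_side(pos[focal], 1, right, stop)
}

# raw uniHS track (no binning)
oracle_unihs <- function(h, stop = 0.05) {
  A <- h$alleles; pos <- as.numeric(h$variants$pos)
  vapply(seq_len(ncol(A)), function(j) {
    ia <- oracle_ihh(A, pos, j, 0L, stop)
    id <- oracle_ihh(A, pos, j, 1L, stop)
    if (is.na(ia) || is.na(id) || ia <= 0 || id <= 0) return(NA_real_)
    log(ia) - log(id)
  }, 0)
}

# per-site iES (EHHS over all haplotypes, focal site included)
oracle_ies <- function(h, stop = 0.05) {
  A <- h$alleles; pos <- as.numeric(h$variants$pos)
  rows <- seq_len(nrow(A))
  vapply(seq_len(ncol(A)), function(j) {
    prefix <- A[rows, j]
    anchor <- oracle_group_hom(A, rows, j)
    left <- oracle_side(A, pos, j, rows, -1L, stop, prefix)
    right <- oracle_side(A, pos, j, rows, +1L, stop, prefix)
    oracle_area_side(pos[j], anchor, left, stop) +
      oracle_area_side(pos[j], anchor, right, stop)
  }, 0)
}

oracle_unxp <- function(h1, h2, stop = 0.05) {
  i1 <- oracle_ies(h1, stop); i2 <- oracle_ies(h2, stop)
  ifelse(i1 > 0 & i2 > 0, log(i1) - log(i2), NA_real_)
}

oracle_unrsb <- function(h1, h2, stop = 0.05) {
  i1 <- oracle_ies(h1, stop); i2 <- oracle_ies(h2, stop)
  ok <- i1 > 0 & i2 > 0
  l1 <- log(i1); l2 <- log(i2)
  out <- (l1 - median(l1[ok])) - (l2 - median(l2[ok]))
  out[!ok] <- NA_real_
  out
}

# population-form standardization over one global stratum
oracle_standardize <- function(x) {
  ok <- is.finite(x)
  mu <- mean(x[ok]); sdev <- sqrt(mean((x[ok] - mu)^2))
  (x - mu) / sdev
}

# naive reimplementation of the sliding-window ROH rules
naive_roh <- function(dos, pos, w, max_het, max_miss, thr, min_snps,
                      min_len, max_gap, dens) {
  L <- length(dos)
  if (L < w) return(data.frame(start = numeric(0), end = numeric(0),
                               n_snps = integer(0)))
  nwin <- L - w + 1
  hom <- vapply(seq_len(nwin), function(a) {
    win <- dos[a:(a + w - 1)]
    sum(win == 1, na.rm = TRUE) <= max_het && sum(is.na(win)) <= max_miss
  }, TRUE)
  insnp <- vapply(seq_len(L), function(j) {
    ws <- max(1, j - w + 1):min(j, nwin)
    if (ws[1] > ws[length(ws)]) return(FALSE)
    mean(hom[ws]) >= thr
  }, TRUE)
  runs <- list(); cur <- integer(0)
  for (j in seq_len(L)) {
    if (insnp[j]) {
      if (length(cur) && pos[j] - pos[cur[length(cur)]] > max_gap) {
        runs <- c(runs, list(cur)); cur <- integer(0)
      }
      cur <- c(cur, j)
    } else if (length(cur)) {
      runs <- c(runs, list(cur)); cur <- integer(0)
    }
  }
  if (length(cur)) runs <- c(runs, list(cur))
  keep <- Filter(function(idx) {
    len <- pos[idx[length(idx)]] - pos[idx[1]] + 1
    length(idx) >= min_snps && len >= min_len && len / length(idx) <= dens
  }, runs)
  data.frame(
    start = vapply(keep, function(i) pos[i[1]], 0),
    end = vapply(keep, function(i) pos[i[length(i)]], 0),
    n_snps = vapply(keep, length, 0L)
  )
}

# exact HWE p by full enumeration with plain factorials
hwe_enum <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  n1 <- 2 * nAA + nAa
  nm <- min(n1, 2 * n - n1)
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nm - h) / 2
    bb <- n - aa - h
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  }, 0)
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(nAa, hets)] * (1 + 1e-12)])
}

# textbook step-up FDR
bh_oracle <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= q * i / m) k <- i
  flags <- rep(FALSE, m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# Hudson-style Fst from two dosage matrices (used for drift checks)
fst_hudson <- function(d1, d2) {
  p1 <- colMeans(d1) / 2; p2 <- colMeans(d2) / 2
  n1 <- nrow(d1) * 2; n2 <- nrow(d2) * 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  mean(num[ok]) / mean(den[ok])
}
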