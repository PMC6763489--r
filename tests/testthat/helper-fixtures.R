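# fixtures are built in code: small worlds, toy tracks, and brute-force
# oracles used across test files

small_world_cfg <- function(n_genes = 24, gene_gap = 50, ...) {
  world_config(
    chrom_sizes = c(chrA = 80000, chrB = 80000),
    n_genes = n_genes,
    n_origins_early = 4, n_origins_late = 4,
    min_origin_gap = 9000,
    gene_length_meanlog = log(900), gene_length_sdlog = 0.25,
    gene_gap = gene_gap,
    ...
  )
}

toy_track <- function(chrom_sizes = c(chrI = 100), plus = NULL, minus = NULL) {
  signal_track(chrom_sizes, plus, minus)
}

random_track <- function(chrom_sizes, density = 0.01) {
  plus <- lapply(chrom_sizes, function(L) {
    v <- numeric(L)
    idx <- sample.int(L, max(1, round(L * density)))
    v[idx] <- round(runif(length(idx), 0.5, 20), 3)
    v
  })
  minus <- lapply(chrom_sizes, function(L) {
    v <- numeric(L)
    idx <- sample.int(L, max(1, round(L * density)))
    v[idx] <- round(runif(length(idx), 0.5, 20), 3)
    v
  })
  signal_track(chrom_sizes, plus, minus)
}

# independent enumeration oracle for the two-sided Mann-Whitney p:
# every C(nx+ny, nx) relabelling of the pooled values
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  s_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  sums <- apply(combos, 2, function(i) sum(r[i]))
  eps <- 1e-9
  p_le <- mean(sums <= s_obs + eps)
  p_ge <- mean(sums >= s_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force BH q-values from the definition q_i = min_{j>=i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force strand-aware region sum, position by position
brute_region_sum <- function(track, chrom, start, end, strand) {
  arr <- if (strand == "+") track$plus[[chrom]] else track$minus[[chrom]]
  tot <- 0
  for (p in seq.int(start, end - 1)) tot <- tot + arr[p + 1]
  tot
}

# brute-force all-pairs timing classification
brute_classify <- function(genes, origins, window = 4000) {
  anchors <- tss(genes)
  vapply(seq_len(nrow(genes)), function(i) {
    de <- Inf; dl <- Inf
    for (j in seq_len(nrow(origins))) {
      if (origins$chrom[j] != genes$chrom[i]) next
      d <- abs(origins$position[j] - anchors[i])
      if (origins$timing[j] == "early") de <- min(de, d) else dl <- min(dl, d)
    }
    if (de <= window && dl <= window) "ambiguous"
    else if (de <= window) "early"
    else if (dl <= window) "late"
    else "unclassified"
  }, character(1))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
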