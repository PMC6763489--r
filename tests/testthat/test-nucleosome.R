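cosine_profile <- function(baseline = 1, amplitude = 0.5, period = 165,
                           phase = 50, flank = c(-200, 1400)) {
  offs <- flank[1]:flank[2]
  structure(data.frame(offset = offs,
                       density = baseline + amplitude * cos(2 * pi * (offs - phase) / period)),
            class = c("nucleosome_profile", "data.frame"),
            smooth_width = 0, n_genes = 1L, n_skipped = 0L)
}

test_that("TSS profile reproduces a shared local pattern exactly", {
  cs <- c(cA = 5000)
  pattern <- numeric(1601)
  pattern[c(261, 421, 581)] <- 5   # dyads at offsets +60, +220, +380
  arr <- numeric(5000)
  arr[1000 - 200 + seq_along(pattern)] <- pattern   # + strand gene, TSS 1000
  arr[3000 + 200 + 2 - seq_along(pattern)] <- pattern  # - strand gene, TSS 3000
  tr <- signal_track(cs, plus = list(cA = arr))
  g <- gene_set(c("p", "m"), "cA", c(1000, 2200), c(2000, 3001), c("+", "-"))
  pr <- tss_profile(tr, g)
  expect_equal(pr$density, pattern)   # both genes contribute identically
  pr1 <- tss_profile(tr, g[1, ])
  expect_equal(pr$density, pr1$density)
})

test_that("TSS profile equals brute-force extraction and scales linearly", {
  w <- simulate_world(small_world_cfg(), seed = 51)
  tr <- simulate_dyad_track(w, "nascent", depth = 4, seed = 52)
  pr <- tss_profile(tr, w$genes)
  offs <- -200:1400
  acc <- numeric(length(offs)); n <- 0
  for (i in seq_len(nrow(w$genes))) {
    tssp <- tss(w$genes)[i]
    dirn <- if (w$genes$strand[i] == "+") 1 else -1
    pos <- tssp + dirn * offs
    if (min(pos) < 0 || max(pos) >= w$config$chrom_sizes[[w$genes$chrom[i]]]) next
    acc <- acc + tr$plus[[w$genes$chrom[i]]][pos + 1]
    n <- n + 1
  }
  expect_equal(pr$density, acc / n)
  expect_equal(attr(pr, "n_genes"), n)
  pr3 <- tss_profile(scale_track(tr, 3), w$genes)
  expect_equal(pr3$density, 3 * pr$density)
})

test_that("peak calling recovers closed-form cosine maxima", {
  pr <- cosine_profile(period = 165, phase = 50)
  pc <- call_peaks(pr, expected_peaks = 7)
  expect_true(all(abs(pc$peaks$offset - (50 + 165 * (0:6))) <= 1))
  expect_error(call_peaks(cosine_profile(amplitude = 0)), class = "noPeaks")
})

test_that("peak positions are invariant under positive affine transforms", {
  pr <- cosine_profile(period = 160, phase = 60)
  p0 <- call_peaks(pr)$peaks$offset
  pr2 <- pr; pr2$density <- 3.2 * pr2$density + 7
  expect_equal(call_peaks(pr2)$peaks$offset, p0)
})

test_that("maturation metrics follow their defining arithmetic", {
  mk_calls <- function(offsets, heights, troughs) {
    structure(list(peaks = data.frame(index = seq_along(offsets), offset = offsets,
                                      height = heights,
                                      trough_left_offset = offsets - 80,
                                      trough_left = troughs,
                                      trough_right_offset = offsets + 80,
                                      trough_right = troughs),
                   ndr_offset = -30, smooth_width = 31),
              class = "peak_calls")
  }
  calls <- mk_calls(c(50, 215, 380, 545, 710, 875, 1040), rep(4, 7), rep(2, 7))
  m <- maturation_metrics(calls)
  expect_equal(m$peak_trough_ratio, 2.0)
  expect_equal(m$linker_length, 165 - 147)
  expect_equal(unname(m$linkers), rep(18, 3))
  expect_error(maturation_metrics(mk_calls(c(50, 215, 380), rep(4, 3), rep(2, 3))),
               "at least 4")
})

test_that("cosine peak/trough ratio matches the closed form and falls with background", {
  # unsmoothed, so the closed form (b + a) / (b - a) holds exactly
  ratios <- vapply(c(1, 2, 4), function(b) {
    pc <- call_peaks(cosine_profile(baseline = b, amplitude = 0.5), smooth_width = 1)
    maturation_metrics(pc)$peak_trough_ratio
  }, numeric(1))
  # integer offset grid truncates the troughs by < 0.1%
  expect_equal(ratios, (c(1, 2, 4) + 0.5) / (c(1, 2, 4) - 0.5), tolerance = 1e-3)
  expect_true(all(diff(ratios) < 0))
  pc <- call_peaks(cosine_profile(baseline = 2, amplitude = 0.5), smooth_width = 1)
  pr2 <- cosine_profile(baseline = 2, amplitude = 0.5); pr2$density <- pr2$density * 5
  expect_equal(maturation_metrics(call_peaks(pr2, smooth_width = 1))$peak_trough_ratio,
               maturation_metrics(pc)$peak_trough_ratio, tolerance = 1e-9)
})

test_that("linker estimates are unbiased within 1 bp on noise-free planted arrays", {
  w <- simulate_world(small_world_cfg(n_genes = 12, gene_gap = 400), seed = 61)
  for (r in c(155, 160, 165, 170, 180)) {
    tr <- simulate_dyad_track(w, state_params = list(repeat_length = r, jitter = 0,
                                                     occupancy = 1),
                              depth = 10, seed = 62)
    m <- maturation_metrics(call_peaks(tss_profile(tr, w$genes)))
    expect_lt(abs(m$linker_length - (r - 147)), 1 + 1e-9)
  }
})

test_that("state comparison aggregates mean and SD across timepoints", {
  metrics <- data.frame(genotype = c("WT", "WT", "WT", "WT"),
                        state = c("nascent", "nascent", "mature", "mature"),
                        timepoint = c(1, 2, 1, 2),
                        peak_trough_ratio = c(2, 3, 4, 4),
                        linker_length = c(20, 16, 13, 13))
  cmp <- compare_states(metrics)
  nas <- cmp[cmp$state == "nascent", ]
  expect_equal(nas$ratio_mean, 2.5)
  expect_equal(nas$ratio_sd, sd(c(2, 3)))
  expect_equal(cmp[cmp$state == "mature", ]$ratio_sd, 0)
  single <- compare_states(metrics[1, ])
  expect_true(is.na(single$ratio_sd))
})
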