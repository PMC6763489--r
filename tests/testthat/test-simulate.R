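test_that("generators are pure functions of (config, seed)", {
  cfg <- small_world_cfg()
  w1 <- simulate_world(cfg, seed = 7)
  w2 <- simulate_world(cfg, seed = 7)
  expect_identical(w1, w2)
  l1 <- simulate_netseq_library(w1, list(genotype = "WT", timepoint = "G1", replicate = 1), seed = 3)
  l2 <- simulate_netseq_library(w2, list(genotype = "WT", timepoint = "G1", replicate = 1), seed = 3)
  expect_identical(l1$track, l2$track)
  expect_identical(l1$spike_reads, l2$spike_reads)
  d1 <- simulate_dyad_track(w1, "mature", depth = 5, seed = 9)
  d2 <- simulate_dyad_track(w2, "mature", depth = 5, seed = 9)
  expect_identical(d1, d2)
  expect_false(identical(simulate_world(cfg, seed = 8)$genes, w1$genes))
})

test_that("an empty world is valid", {
  w <- simulate_world(small_world_cfg(n_genes = 0), seed = 1)
  expect_equal(nrow(w$genes), 0)
  expect_equal(nrow(w$truth), 0)
  expect_s3_class(w$genes, "gene_set")
})

test_that("planted timing classes are recovered exactly and dosage is monotone", {
  w <- simulate_world(small_world_cfg(n_genes = 30), seed = 5)
  cl <- classify_genes(w$genes, w$origins, window = w$config$origin_window)
  planted <- ifelse(w$truth$timing_class == "far", "unclassified", w$truth$timing_class)
  expect_equal(cl$class, planted)
  d <- as.matrix(w$truth[, c("d_G1", "d_S30", "d_S60", "d_S90")])
  expect_true(all(d %in% c(1, 2)))
  expect_true(all(diff(t(d)) >= 0))
  expect_true(all(d[, "d_S90"] == 2))
})

test_that("simulated totals match the analytic expectation (law of large numbers)", {
  cfg <- small_world_cfg(n_genes = 8, antisense_fraction = 0, depth_sdlog = 0)
  w <- simulate_world(cfg, seed = 2)
  mu <- sum(expected_counts(w, "WT", "G1"))
  tot <- vapply(1:100, function(s) {
    simulate_netseq_library(w, list(genotype = "WT", timepoint = "G1", replicate = 1),
                            seed = s)$target_reads
  }, numeric(1))
  # mean of 100 Poisson(mu) draws: SE = sqrt(mu/100)
  expect_lt(abs(mean(tot) - mu), 4 * sqrt(mu / 100))
})

test_that("dosage doubling doubles the expected counts by construction", {
  w <- simulate_world(small_world_cfg(), seed = 3)
  expect_equal(expected_counts(w, "WT", "S90"), 2 * expected_counts(w, "WT", "G1"))
  f <- w$config$genotypes$asf1$fold_early_s30
  e <- w$truth$timing_class == "early"
  r <- expected_counts(w, "asf1", "S30") / expected_counts(w, "WT", "S30")
  expect_equal(r[e], rep(f, sum(e)))
  expect_equal(r[!e], rep(1, sum(!e)))
})

test_that("alpha = 0 gives uniform read positions along the gene", {
  # single long gene, no antisense: KS test cannot reject uniformity
  g <- gene_set("g1", "chrI", 1000, 11000, "+")
  truth <- data.frame(id = "g1", lambda = 1, alpha = 0, timing_class = "far",
                      d_G1 = 1, d_S30 = 1, d_S60 = 1, d_S90 = 2)
  w <- structure(list(genes = g, origins = origin_set(character(), numeric(), character()),
                      truth = truth,
                      config = world_config(chrom_sizes = c(chrI = 20000),
                                            antisense_fraction = 0, depth_sdlog = 0)),
                 class = "synthetic_world")
  lib <- simulate_netseq_library(w, list(genotype = "WT", timepoint = "G1", replicate = 1),
                                 depth = 1, seed = 4)
  counts <- track_slice(lib$track, "chrI", 1000, 11000, "+")
  expect_gt(sum(counts), 9000)
  set.seed(1)
  pos <- rep(seq_along(counts), counts) - 1 + runif(sum(counts))
  ks <- suppressWarnings(stats::ks.test(pos / 10000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("genes not longer than the 5' segment collapse to a uniform shape", {
  g <- gene_set("g1", "chrI", 100, 400, "+")  # length 300 = first_bp
  truth <- data.frame(id = "g1", lambda = 10, alpha = 0.9, timing_class = "far",
                      d_G1 = 1, d_S30 = 1, d_S60 = 1, d_S90 = 2)
  w <- structure(list(genes = g, origins = origin_set(character(), numeric(), character()),
                      truth = truth,
                      config = world_config(chrom_sizes = c(chrI = 1000),
                                            antisense_fraction = 0, depth_sdlog = 0)),
                 class = "synthetic_world")
  lib <- simulate_netseq_library(w, list(genotype = "WT", timepoint = "G1", replicate = 1), seed = 6)
  v <- track_slice(lib$track, "chrI", 100, 400, "+")
  # thirds of the gene should carry comparable mass under uniformity
  thirds <- c(sum(v[1:100]), sum(v[101:200]), sum(v[201:300]))
  expect_gt(stats::chisq.test(thirds)$p.value, 0.001)
})

test_that("dyad generator plants exact positions when jitter is off", {
  cfg <- small_world_cfg(n_genes = 2)
  w <- simulate_world(cfg, seed = 10)
  tr <- simulate_dyad_track(w, "mature", depth = 10, seed = 1,
                            state_params = list(repeat_length = 160, jitter = 0, occupancy = 1))
  nz <- sort(unlist(lapply(names(tr$plus), function(ch) which(tr$plus[[ch]] > 0) - 1)))
  expected <- sort(unlist(lapply(seq_len(2), function(i) {
    tssp <- tss(w$genes)[i]
    dirn <- if (w$genes$strand[i] == "+") 1 else -1
    tssp + dirn * (60 + (0:7) * 160)
  })))
  expect_true(all(nz %in% expected))
  expect_error(simulate_dyad_track(w, "mature", seed = 1,
                                   state_params = list(repeat_length = 140, jitter = 0, occupancy = 1)),
               "147")
})

test_that("planted nascent chromatin yields longer linkers than mature", {
  w <- simulate_world(world_config(n_genes = 150), seed = 12)
  lk <- vapply(c("mature", "nascent"), function(st) {
    tr <- simulate_dyad_track(w, st, depth = 20, seed = 13)
    maturation_metrics(call_peaks(tss_profile(tr, w$genes)))$linker_length
  }, numeric(1))
  expect_lt(lk["mature"], lk["nascent"])
})
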