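test_that("timing classification follows the 4 kb screening rule", {
  o <- origin_set(c("cA", "cA"), c(10000, 30000), c("early", "late"))
  g <- gene_set(c("near_early", "far", "near_late"), "cA",
                c(12000, 16000, 26800), c(13000, 17000, 27800), "+")
  # TSS: 12000 (2 kb from early), 16000 (5 kb+ from both), 26800 (3.2 kb from late)
  cl <- classify_genes(g, o, window = 4000)
  expect_equal(cl$class[cl$id == "near_early"], "early")
  expect_equal(cl$class[cl$id == "far"], "unclassified")
  expect_equal(cl$class[cl$id == "near_late"], "late")
  gb <- gene_set("amb", "cA", 29000, 29900, "-")   # TSS 29899: 0.1 kb late...
  o2 <- origin_set(c("cA", "cA"), c(29000, 30000), c("early", "late"))
  expect_equal(classify_genes(gb, o2)$class, "ambiguous")
  expect_equal(classify_genes(g, origin_set(character(), numeric(), character()))$class,
               rep("unclassified", 3))
})

test_that("classification matches the brute-force all-pairs scan on random worlds", {
  for (s in 1:25) {
    set.seed(s)
    n <- 30
    g <- gene_set(sprintf("g%d", 1:n),
                  sample(c("cA", "cB"), n, TRUE),
                  st <- sample.int(9e4, n), st + sample(500:2000, n, TRUE),
                  sample(c("+", "-"), n, TRUE))
    no <- 8
    o <- origin_set(sample(c("cA", "cB"), no, TRUE), sample.int(1e5, no),
                    sample(c("early", "late"), no, TRUE))
    expect_equal(classify_genes(g, o)$class, brute_classify(g, o))
  }
})

test_that("classification is invariant under strand flip preserving the TSS", {
  o <- origin_set("cA", 10000, "early")
  plus <- gene_set("g", "cA", 12000, 13000, "+")         # TSS 12000
  minus <- gene_set("g", "cA", 11500, 12001, "-")        # TSS 12000
  expect_equal(classify_genes(plus, o)$class, classify_genes(minus, o)$class)
  expect_equal(classify_genes(plus, o)$distance, classify_genes(minus, o)$distance)
})

test_that("time-course medians and contrasts match a hand computation", {
  genes <- sprintf("g%d", 1:5)
  counts <- rbind(
    data.frame(region_id = genes, genotype = "WT", timepoint = "G1",
               replicate = 1, count = c(10, 20, 30, 40, 50)),
    data.frame(region_id = genes, genotype = "WT", timepoint = "S90",
               replicate = 1, count = c(20, 40, 60, 80, 100)),
    data.frame(region_id = genes, genotype = "mut", timepoint = "G1",
               replicate = 1, count = c(30, 60, 90, 120, 150)),
    data.frame(region_id = genes, genotype = "mut", timepoint = "S90",
               replicate = 1, count = c(20, 40, 60, 80, 100)))
  classes <- data.frame(id = genes, class = rep("early", 5))
  tc <- timecourse_summary(counts, classes, reference_genotype = "WT")
  s <- tc$summary
  expect_equal(s$median[s$class == "all" & s$genotype == "WT" & s$timepoint == "G1"], 30)
  expect_equal(s$q1[s$class == "all" & s$genotype == "WT" & s$timepoint == "G1"], 20)
  cc <- tc$contrasts
  expect_equal(cc$fold_ratio[cc$class == "all" & cc$contrast == "G1_vs_WT"], 3)
  expect_equal(cc$fold_ratio[cc$class == "all" & cc$contrast == "S90_vs_WT"], 1)
  expect_equal(cc$fold_ratio[cc$class == "all" & cc$genotype == "WT" &
                             cc$contrast == "S90_vs_G1"], 2)
  # early class mirrors "all" here (all genes are early)
  expect_equal(cc$fold_ratio[cc$class == "early" & cc$contrast == "G1_vs_WT"], 3)
})

test_that("identical mutant and reference counts give unit fold ratios", {
  genes <- sprintf("g%d", 1:6)
  base <- expand.grid(region_id = genes, timepoint = c("G1", "S30", "S60", "S90"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  base$count <- rep(c(5, 10, 15, 20, 25, 30), 8)
  counts <- rbind(cbind(base, genotype = "WT"), cbind(base, genotype = "mut"))
  classes <- data.frame(id = genes, class = rep("late", 6))
  cc <- timecourse_summary(counts, classes)$contrasts
  expect_true(all(cc$fold_ratio[grepl("_vs_WT", cc$contrast)] == 1))
})

test_that("replicates are averaged per gene before medians", {
  counts <- rbind(
    data.frame(region_id = "g1", genotype = "WT", timepoint = "G1",
               replicate = 1:2, count = c(10, 30)),
    data.frame(region_id = "g1", genotype = "WT", timepoint = "S90",
               replicate = 1:2, count = c(40, 40)))
  classes <- data.frame(id = "g1", class = "early")
  b <- buffering_step(counts, classes)
  expect_equal(b$ratio[b$class == "all"], 2)   # mean(10,30)=20 -> 40/20
})

test_that("buffering step is the S90/G1 ratio of medians", {
  genes <- sprintf("g%d", 1:5)
  g1 <- data.frame(region_id = genes, genotype = "WT", timepoint = "G1",
                   replicate = 1, count = c(2, 4, 6, 8, 10))
  classes <- data.frame(id = genes, class = rep("far", 5))
  s90 <- g1; s90$timepoint <- "S90"; s90$count <- 2 * g1$count
  b2 <- buffering_step(rbind(g1, s90), classes)
  expect_equal(b2$ratio, rep(2, nrow(b2)))
  s90b <- g1; s90b$timepoint <- "S90"
  b1 <- buffering_step(rbind(g1, s90b), classes)
  expect_equal(b1$ratio, rep(1, nrow(b1)))
  g0 <- g1; g0$count <- 0
  expect_error(buffering_step(rbind(g0, s90), classes), "zero G1 median")
})
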