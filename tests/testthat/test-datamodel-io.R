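test_that("BED6 gene annotation parses 0-based half-open with strand-aware TSS", {
  f <- write_lines_tmp(c("chrI\t100\t200\tg1\t0\t+",
                         "chrI\t300\t450\tg2\t0\t-\tCUT"), ".bed")
  g <- read_gene_annotation(f, "BED6")
  expect_equal(g$start, c(100, 300))
  expect_equal(g$end, c(200, 450))
  expect_equal(tss(g), c(100, 449))
  expect_equal(tts(g), c(199, 300))
  expect_equal(g$biotype, c("coding", "CUT"))
})

test_that("GFF3 1-based closed coordinates convert to internal convention", {
  f <- write_lines_tmp(c("##gff-version 3",
                         "chrI\ttest\tgene\t101\t200\t.\t+\t.\tID=g1",
                         "chrI\ttest\tgene\t301\t450\t.\t-\t.\tID=g2;biotype=SUT"),
                       ".gff3")
  g <- read_gene_annotation(f, "GFF3")
  expect_equal(g$start, c(100, 300))
  expect_equal(g$end, c(200, 450))
  expect_equal(g$biotype, c("coding", "SUT"))
})

test_that("malformed annotation lines fail with the offending line reported", {
  f <- write_lines_tmp(c("chrI\t100\t200\tg1\t0\t+", "chrI\t1\t2\tg2\t0\t*"))
  expect_error(read_gene_annotation(f, "BED6"), "line 2.*strand")
  f2 <- write_lines_tmp("chrI\tx\t200\tg1\t0\t+")
  expect_error(read_gene_annotation(f2, "BED6"), "line 1")
  f3 <- write_lines_tmp(c("chrI\t1\t2\tg1\t0\t+", "chrI\t5\t9\tg1\t0\t+"))
  expect_error(read_gene_annotation(f3, "BED6"), "duplicate")
})

test_that("gene sets round-trip through BED write/read field by field", {
  g <- gene_set(c("a", "b", "c"), c("chrII", "chrI", "chrI"),
                c(500, 10, 3000), c(900, 700, 3620),
                c("-", "+", "-"), c("coding", "CUT", "SUT"))
  f <- tempfile(fileext = ".bed")
  write_gene_annotation(g, f)
  g2 <- read_gene_annotation(f, "BED6")
  g2 <- g2[match(g$id, g2$id), ]
  rownames(g2) <- NULL
  expect_equal(as.data.frame(g2), as.data.frame(g))
})

test_that("bedGraph intervals expand to dense arrays with zeros elsewhere", {
  f <- write_lines_tmp("chrI\t0\t10\t2.0", ".bedgraph")
  fm <- write_lines_tmp(character(0), ".bedgraph")
  tr <- read_signal_track(f, fm, c(chrI = 20))
  expect_equal(tr$plus$chrI, c(rep(2, 10), rep(0, 10)))
  expect_equal(tr$minus$chrI, rep(0, 20))
})

test_that("bedGraph bounds and sign are validated with line numbers", {
  fm <- write_lines_tmp(character(0))
  f1 <- write_lines_tmp("chrI\t15\t25\t1.0")
  expect_error(read_signal_track(f1, fm, c(chrI = 20)), "line 1.*bounds")
  f2 <- write_lines_tmp(c("chrI\t0\t5\t1.0", "chrI\t5\t8\t-2.0"))
  expect_error(read_signal_track(f2, fm, c(chrI = 20)), "line 2.*negative")
  f3 <- write_lines_tmp("chrX\t0\t5\t1.0")
  expect_error(read_signal_track(f3, fm, c(chrI = 20)), "unknown chromosome")
})

test_that("run-length merged bedGraph output omits zero runs", {
  tr <- toy_track(c(chrI = 4), plus = list(chrI = c(0, 3, 3, 1)))
  out <- tempfile()
  write_signal_track(tr, out)
  expect_equal(readLines(out), c("chrI\t1\t3\t3", "chrI\t3\t4\t1"))
  tr0 <- toy_track(c(chrI = 4))
  write_signal_track(tr0, out)
  expect_equal(readLines(out), character(0))
})

test_that("signal tracks round-trip write -> read exactly over many random tracks", {
  for (s in 1:100) {
    set.seed(s)
    cs <- c(cA = sample(50:400, 1), cB = sample(50:400, 1))
    tr <- random_track(cs, density = 0.1)
    fp <- tempfile(); fm <- tempfile()
    write_signal_track(tr, fp, fm)
    tr2 <- read_signal_track(fp, fm, cs)
    expect_equal(tr2$plus, tr$plus)
    expect_equal(tr2$minus, tr$minus)
  }
})

test_that("origin annotations parse, validate timing labels, and sort", {
  f <- write_lines_tmp(c("chrII\t15000\t15001\tARS_b\tlate",
                         "chrI\t9000\t9001\tARS_a\tearly",
                         "chrI\t2000\t2001\tARS_c\tearly",
                         "chrII\t100\t101\tARS_d\tlate",
                         "chrI\t15000\t15001\tARS_e\tearly"))
  o <- read_origin_annotation(f)
  expect_equal(o$name, c("ARS_c", "ARS_a", "ARS_e", "ARS_d", "ARS_b"))
  expect_equal(o$position, c(2000, 9000, 15000, 100, 15000))
  bad <- write_lines_tmp("chrI\t1\t2\tARS1\tmid")
  expect_error(read_origin_annotation(bad), "timing label 'mid'")
})

test_that("origin and gene-set round trips are lossless on random fixtures", {
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- sample(1:12, 1)
    o <- origin_set(sample(c("c1", "c2"), n, replace = TRUE),
                    sample.int(5e4, n),
                    sample(c("early", "late"), n, replace = TRUE))
    f <- tempfile()
    write_origin_annotation(o, f)
    expect_equal(read_origin_annotation(f), o)
    ng <- sample(1:8, 1)
    st <- sort(sample.int(1e4, ng)) * 10
    g <- gene_set(sprintf("g%d", 1:ng), "c1", st, st + sample(100:500, ng, TRUE),
                  sample(c("+", "-"), ng, TRUE),
                  sample(c("coding", "CUT", "SUT"), ng, TRUE))
    fg <- tempfile()
    write_gene_annotation(g, fg)
    g2 <- read_gene_annotation(fg, "BED6")
    g2 <- g2[match(g$id, g2$id), ]; rownames(g2) <- NULL
    expect_equal(as.data.frame(g2), as.data.frame(g))
  }
})
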