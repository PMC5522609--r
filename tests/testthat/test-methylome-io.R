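test_that("CX-report and coverage dialects parse to the same sites", {
  cx <- tempfile(fileext = ".cx")
  writeLines(c("chr1\t102\t+\t8\t2\tCG\tCGT",
               "chr1\t57\t-\t0\t5\tCHH\tCAT",
               "chr2\t7\t+\t3\t3\tCHG\tCTG"), cx)
  s <- read_cytosine_table(cx, "cx_report", dose = 0, replicate = 1)
  expect_equal(nrow(s$records), 3)
  # sorted by chrom then pos
  expect_equal(s$records$pos, c(57L, 102L, 7L))
  r <- s$records[s$records$pos == 102, ]
  expect_equal(r$context, "CG")
  expect_equal(r$n_meth, 8L)
  expect_equal(r$n_unmeth, 2L)

  cov <- tempfile(fileext = ".cov")
  writeLines("chr1\t102\t102\t80.0\t8\t2", cov)
  sc <- read_cytosine_table(cov, "cov")
  expect_equal(sc$records$strand, "*")
  expect_equal(sc$records$context, "UNKNOWN")
  expect_equal(methylation_ratio(sc$records), 0.8)
})

test_that("malformed and degenerate cytosine tables are handled", {
  bad <- tempfile()
  writeLines(c("chr1\t102\t+\t8\t2\tCG\tCGT", "chr1\tnotanumber\t+\t1"), bad)
  expect_error(read_cytosine_table(bad, "cx_report"), "line 2")

  neg <- tempfile()
  writeLines("chr1\t10\t10\t50\t-1\t1", neg)
  expect_error(read_cytosine_table(neg, "cov"), "negative")

  empty <- tempfile(); file.create(empty)
  expect_warning(s <- read_cytosine_table(empty, "cx_report"), "empty")
  expect_equal(nrow(s$records), 0)
})

test_that("sample round-trips through the CX-report format exactly", {
  ex <- small_experiment(11, planted = FALSE)
  s <- ex$sim$samples[[1]]
  f <- tempfile()
  write_cytosine_table(s, f)
  back <- read_cytosine_table(f, "cx_report", sample_id = s$sample_id,
                              dose = s$dose, replicate = s$replicate)
  expect_equal(back$records, s$records)
})

test_that("context classification matches the definition and infers strand", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTACTGAC"), fa)
  # pos2 + : C,G -> CG; pos6 + : C,T,G -> CHG; pos3 - (G): CpG symmetry
  s <- sample_set(rec_frame("chr1", c(2, 6, 3), c("+", "+", "-"),
                            "UNKNOWN", 1L, 1L), "t")
  out <- classify_contexts(s, fa)
  expect_equal(out$records$context[match(c(2, 6, 3), out$records$pos)],
               c("CG", "CHG", "CG"))

  # coverage-dialect strand inference: pos 2 holds C -> +, pos 3 holds G -> -
  s2 <- sample_set(rec_frame("chr1", c(2, 3), "*", "UNKNOWN", 1L, 1L), "t2")
  out2 <- classify_contexts(s2, fa)
  expect_equal(out2$records$strand, c("+", "-"))

  # non-C/G position errors; truncated context near the end is dropped
  s3 <- sample_set(rec_frame("chr1", 4, "+", "UNKNOWN", 1L, 1L), "t3")
  expect_error(classify_contexts(s3, fa), "mismatch")
  # pos 8 is G: minus-strand context reads T,C upstream -> complement A,G -> CHG
  s4 <- sample_set(rec_frame("chr1", 8, "-", "UNKNOWN", 1L, 1L), "t4")
  expect_silent(out4 <- classify_contexts(s4, fa))
  expect_equal(out4$records$context, "CHG")
  s5 <- sample_set(rec_frame("chr1", c(2, 10), c("+", "+"), "UNKNOWN",
                             c(1L, 1L), c(1L, 1L)), "t5")
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTACTGCC"), fa2)  # pos 10 = C at contig end
  expect_warning(out5 <- classify_contexts(s5, fa2), "dropped")
  expect_equal(out5$records$pos, 2L)
})

test_that("context classification agrees with a naive scan on random sequence", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">rnd", seq), fa)
  chars <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # independent oracle: explicit per-position scan on both strands
  oracle <- do.call(rbind, lapply(seq_len(400), function(p) {
    out <- NULL
    if (chars[p] == "C" && p + 1 <= 400) {
      ctx <- if (chars[p + 1] == "G") "CG"
        else if (p + 2 <= 400) { if (chars[p + 2] == "G") "CHG" else "CHH" }
        else NA
      if (!is.na(ctx)) out <- rbind(out, data.frame(pos = p, strand = "+",
                                                    context = ctx))
    }
    if (chars[p] == "G" && p - 1 >= 1) {
      b1 <- comp[[chars[p - 1]]]
      ctx <- if (b1 == "G") "CG"
        else if (p - 2 >= 1) { if (comp[[chars[p - 2]]] == "G") "CHG" else "CHH" }
        else NA
      if (!is.na(ctx)) out <- rbind(out, data.frame(pos = p, strand = "-",
                                                    context = ctx))
    }
    out
  }))
  s <- sample_set(rec_frame("rnd", oracle$pos, oracle$strand, "UNKNOWN",
                            1L, 1L), "rnd")
  got <- classify_contexts(s, fa)$records
  key <- paste(got$pos, got$strand)
  expect_equal(got$context,
               oracle$context[match(key, paste(oracle$pos, oracle$strand))])
})

test_that("conversion-rate estimation is a pooled ratio and is unbiased", {
  s <- toy_sample("a", m = c(3, 2), cov = 500L, chrom = "chloro")
  rep <- estimate_conversion(s, "chloro")
  expect_equal(rep$non_conversion_rate, 5 / 1000)
  expect_equal(rep$efficiency, 0.995)

  s0 <- toy_sample("b", m = c(0, 0), cov = 10L, chrom = "chloro")
  expect_equal(estimate_conversion(s0, "chloro")$non_conversion_rate, 0)
  expect_error(estimate_conversion(s0, "nuclear"), "control")

  # binomial sampling: 2000 sites at 50x, true non-conversion 0.005
  set.seed(99)
  truth <- 0.005
  ests <- replicate(100, {
    m <- rbinom(2000, 50, truth)
    s <- sample_set(rec_frame("chloro", seq_len(2000), "+", "CHH",
                              m, 50L - m), "sim")
    estimate_conversion(s, "chloro")$non_conversion_rate
  })
  se_one <- sqrt(truth * (1 - truth) / (2000 * 50))
  expect_true(all(abs(ests - truth) < 3 * se_one + 1e-12) ||
                mean(abs(ests - truth) < 3 * se_one) > 0.95)
  # Monte-Carlo unbiasedness of the mean over 100 simulations
  expect_lt(abs(mean(ests) - truth), 3 * se_one / sqrt(100))
})

test_that("DMR tables round-trip through BED6+ and GFF features convert", {
  ex <- call_reconciled(1)
  dmrs <- rbind(ex$rec$unique_5, ex$rec$unique_10, ex$rec$shared)
  f <- tempfile(fileext = ".bed")
  write_dmrs_bed(dmrs, f)
  back <- read_dmrs_bed(f)
  rownames(dmrs) <- NULL
  expect_equal(back, dmrs)
  # first BED fields follow the 0-based half-open convention
  first <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(as.integer(first[2:3]), c(dmrs$start[1], dmrs$end[1]))

  bad <- dmrs[1, ]; bad$end <- bad$start
  expect_error(write_dmrs_bed(bad, tempfile()), "interval")

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t100\t200\t.\t+\t.\tID=g1",
               "chr1\ttest\ttransposable_element\t500\t700\t.\t-\t.\tID=te1",
               "chr1\ttest\texon\t100\t150\t.\t+\t.\tID=e1"), gff)
  feats <- read_features_gff(gff)
  expect_equal(nrow(feats), 2)  # exon dropped
  g1 <- feats[feats$id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(99, 200))  # 1-based inclusive -> 0-based half-open
  expect_equal(feats$feature_type[feats$id == "te1"],
               "transposable_element")
})
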