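test_that("cytosine reports parse the Bismark CX dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               "Chr1\t1001\t+\t8\t2\tCG\tCGT",
               "Chr1\t1005\t-\t0\t7\tCHH"), f)
  rep <- read_cytosine_report(f)
  expect_equal(rep$chrom, c("Chr1", "Chr1"))
  expect_equal(rep$pos, c(1001L, 1005L))
  expect_equal(rep$context, c("CG", "CHH"))
  expect_equal(rep$count_meth, c(8L, 0L))
  expect_equal(rep$count_unmeth, c(2L, 7L))
})

test_that("cytosine report validation names the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr1\t1001\t+\t8\t2\tCG",
               "Chr1\t1002\t+\t8\t2\tXXX"), f)
  expect_error(read_cytosine_report(f), "line 2.*unknown context 'XXX'")
  writeLines("Chr1\t1001\t+\t8", f)
  expect_error(read_cytosine_report(f), "line 1.*6 tab-separated")
  writeLines("Chr1\t1001\t+\t-3\t2\tCG", f)
  expect_error(read_cytosine_report(f), "negative")
  writeLines(c("Chr1\t1001\t+\t8\t2\tCG",
               "Chr1\t1001\t+\t3\t2\tCG"), f)
  expect_error(read_cytosine_report(f), "duplicate")
  writeLines(character(), f)
  expect_equal(nrow(read_cytosine_report(f)), 0L)
})

test_that("cytosine reports round-trip and apply chromosome renames", {
  sites <- make_sites(c(10L, 20L), c("CG", "CHH"), c(3L, 0L), c(1L, 5L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(sites, f)
  expect_equal(read_cytosine_report(f), sites)
  sites2 <- read_cytosine_report(f, rename_chroms = c(Chr1 = "1"))
  expect_equal(unique(sites2$chrom), "1")
})

test_that("GFF3 features keep 1-based inclusive coordinates and kinds", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
               "Chr1\tsrc\ttransposable_element\t3001\t3400\t.\t-\t.\tID=t1",
               "Chr1\tsrc\ttransposable_element_gene\t5001\t5400\t.\t+\t.\tID=t2",
               "Chr1\tsrc\tpseudogene\t7001\t7200\t.\t+\t.\tID=x1"), f)
  ft <- read_features(f)
  expect_equal(ft$start, c(1001L, 3001L, 5001L, 7001L))
  expect_equal(ft$end[1], 2000L)  # spans bases 1001..2000 inclusive
  expect_equal(ft$kind, c("gene", "TE", "TE", "other"))
  expect_equal(ft$feature_id, c("g1", "t1", "t2", "x1"))
})

test_that("BED features are converted from 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t1000\t2000\tAT1TE45510\t0\t+",
               "Chr1\t4000\t6000\tAT1G01010\t0\t-"), f)
  ft <- read_features(f)
  expect_equal(ft$start, c(1001L, 4001L))
  expect_equal(ft$end, c(2000L, 6000L))
  expect_equal(ft$kind, c("TE", "gene"))
})

test_that("annotation GFF3 output round-trips", {
  feats <- make_features(c(101L, 501L), c(400L, 900L), c("gene", "TE"),
                         strand = c("+", "-"), id = c("g1", "te1"))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(feats, f)
  expect_equal(read_features(f), feats)
})

test_that("DMR files round-trip, sort and encode scores", {
  dmrs <- make_dmrs(start = c(1001L, 51L), end = c(1150L, 200L),
                    chrom = c("Chr2", "Chr1"),
                    p_min = c(1e-5, 0), delta_total = c(-0.32, 0.4),
                    direction = c("hypo", "hyper"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmrs(dmrs, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#chrom")
  fields <- strsplit(lines[-1], "\t")
  # sorted: Chr1 first, and BED start is 0-based
  expect_equal(vapply(fields, `[[`, "", 1), c("Chr1", "Chr2"))
  expect_equal(fields[[2]][2], "1000")
  expect_equal(fields[[2]][3], "1150")
  expect_equal(as.numeric(fields[[2]][5]), 5)      # -log10(1e-5)
  expect_equal(as.numeric(fields[[1]][5]), 300)    # capped at p = 0
  back <- read_dmrs(f)
  ord <- order(dmrs$chrom, dmrs$start)
  expect_equal(back[, c("chrom", "start", "end", "direction",
                        "n_windows", "delta_total", "p_min")],
               dmrs[ord, c("chrom", "start", "end", "direction",
                           "n_windows", "delta_total", "p_min")],
               ignore_attr = TRUE)
})

test_that("an empty DMR set round-trips to an empty set", {
  f <- withr::local_tempfile(fileext = ".bed")
  write_dmrs(make_dmrs(integer(0), integer(0))[0, ], f)
  expect_equal(nrow(read_dmrs(f)), 0L)
})
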