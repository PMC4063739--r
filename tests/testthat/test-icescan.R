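simpleFeatures <- function() {
  # anchor at 10 kb, core block at 60 kb (90% identity, 15 kb), integrase at
  # 18 kb, tRNA-Gly just past the integrase: all windows satisfied
  data.frame(
    genome_id = "g1", contig_id = "c1",
    kind = c("tciR_hit", "core_block", "integrase", "tRNA_gly"),
    start = c(10000, 60000, 18000, 19600),
    end = c(10900, 75000, 19200, 19680),
    strand = c("+", "+", "-", "+"),
    evalue = c(1e-40, NA, NA, NA),
    pct_identity = c(98, 90, NA, NA))
}

test_that("E-value filter is strict and passes non-hit rows through", {
  ft <- simpleFeatures()
  ft$evalue[1] <- 1e-10
  out <- filterHits(ft)
  expect_false(any(out$kind == "tciR_hit"))   # 1e-10 not below 1e-15
  expect_equal(nrow(out), 3)                  # other kinds untouched
  ft$evalue[1] <- 0
  expect_equal(nrow(filterHits(ft)), 4)       # evalue 0 retained
  empty <- validateFeatureTable(
    data.frame(genome_id = character(0), contig_id = character(0),
               kind = character(0), start = numeric(0), end = numeric(0)))
  expect_equal(nrow(filterHits(empty)), 0)
  ft$evalue[1] <- NA
  expect_error(filterHits(ft), "evalue")
})

test_that("feature-table validation enforces the coordinate contract", {
  bad <- simpleFeatures(); bad$start[2] <- bad$end[2] + 1
  expect_error(validateFeatureTable(bad), "start")
  bad2 <- simpleFeatures(); bad2$pct_identity[2] <- 101
  expect_error(validateFeatureTable(bad2), "pct_identity")
  bad3 <- simpleFeatures(); bad3$kind[1] <- "mystery"
  expect_error(validateFeatureTable(bad3), "kind")
})

test_that("the windowed screen calls the textbook constellation", {
  calls <- callIce(filterHits(simpleFeatures()))
  expect_equal(nrow(calls), 1)
  expect_true(calls$core_ok && calls$integrase_ok && calls$trna_scored)
  expect_equal(calls$anchor_start, 10000)
  expect_equal(calls$start, 10000)
  expect_equal(calls$end, 75000)
  # nearest-edge distances
  expect_equal(calls$dist_core, 60000 - 10900)
  expect_equal(calls$dist_integrase, 18000 - 10900)
  expect_equal(nrow(callIce(simpleFeatures()[0, ])), 0)
})

test_that("each screening criterion gates the call", {
  base <- simpleFeatures()
  # integrase at 30 kb: outside the 5-20 kb window
  f1 <- base; f1$start[3] <- 40900; f1$end[3] <- 42100
  expect_equal(nrow(callIce(f1)), 0)
  # core block identity exactly at the bound: 75 is not > 75
  f2 <- base; f2$pct_identity[2] <- 75
  expect_equal(nrow(callIce(f2)), 0)
  # core outside the 1-100 kb window
  f3 <- base; f3$start[2] <- 160900; f3$end[2] <- 175900
  expect_equal(nrow(callIce(f3)), 0)
  # summed core coverage below the completeness minimum
  f4 <- base; f4$end[2] <- f4$start[2] + 5000
  expect_equal(nrow(callIce(f4)), 0)
  # tRNA far away: call still emitted, just not scored
  f5 <- base; f5$start[4] <- 99000; f5$end[4] <- 99080
  calls <- callIce(f5)
  expect_equal(nrow(calls), 1)
  expect_false(calls$trna_scored)
  # features on another contig never combine
  f6 <- base; f6$contig_id[2] <- "c2"
  expect_equal(nrow(callIce(f6)), 0)
})

test_that("calls are independent of input row order", {
  ft <- genFeatureTable(501, n_plants = 3)$data
  c1 <- iceScan(ft)
  c2 <- iceScan(ft[rev(seq_len(nrow(ft))), ])
  c3 <- iceScan(ft[withSeed(3, sample.int(nrow(ft))), ])
  rownames(c1) <- rownames(c2) <- rownames(c3) <- NULL
  expect_equal(c1, c2)
  expect_equal(c1, c3)
})

test_that("overlapping calls merge; disjoint calls are untouched", {
  base <- simpleFeatures()
  # second anchor ~3 kb upstream of the first, sharing integrase and core
  two <- rbind(base, data.frame(
    genome_id = "g1", contig_id = "c1", kind = "tciR_hit",
    start = 6500, end = 7400, strand = "+", evalue = 1e-30,
    pct_identity = 97))
  calls <- callIce(filterHits(two))
  expect_equal(nrow(calls), 2)
  merged <- mergeOverlappingCalls(calls)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_anchors, 2)
  expect_equal(merged$start, 6500)
  expect_equal(merged$end, 75000)
  # identical duplicated call collapses
  dup <- mergeOverlappingCalls(rbind(calls[1, ], calls[1, ]))
  expect_equal(nrow(dup), 1)
  # disjoint constellations survive merging
  ft <- genFeatureTable(502, n_plants = 2)$data
  cc <- callIce(filterHits(ft))
  expect_equal(nrow(mergeOverlappingCalls(cc)), nrow(cc))
})

test_that("tightening any threshold never increases the call count", {
  ft <- genFeatureTable(503, n_plants = 4)$data
  n0 <- nrow(iceScan(ft))
  expect_lte(nrow(iceScan(ft, evalue_max = 1e-50)), n0)
  expect_lte(nrow(iceScan(ft, identity_min = 92)), n0)
  expect_lte(nrow(iceScan(ft, int_window = c(5e3, 1e4))), n0)
  expect_lte(nrow(iceScan(ft, core_window = c(1e3, 4e4))), n0)
  expect_lte(nrow(iceScan(ft, core_min_len = 3e4)), n0)
})

test_that("feature tables and calls round-trip through TSV and BED", {
  ft <- genFeatureTable(504, n_plants = 1)$data
  tsv <- tempfile(fileext = ".tsv")
  writeFeatureTable(ft, tsv)
  back <- readFeatureTable(tsv)
  expect_equal(back[order(back$start), c("kind", "start", "end")],
               ft[order(ft$start), c("kind", "start", "end")],
               ignore_attr = TRUE)
  calls <- iceScan(ft)
  out_tsv <- tempfile(fileext = ".tsv")
  writeCallsTsv(calls, out_tsv)
  expect_equal(utils::read.delim(out_tsv)$start, calls$start)
  bed <- tempfile(fileext = ".bed")
  exportCallsBed(calls, bed)
  gr <- rtracklayer::import(bed)
  # BED is 0-based half-open; rtracklayer restores 1-based inclusive
  expect_equal(GenomicRanges::start(gr), calls$start)
  expect_equal(GenomicRanges::end(gr), calls$end)
  raw <- utils::read.table(bed, sep = "\t")
  expect_equal(raw$V2, calls$start - 1)   # 0-based start on disk
  expect_equal(raw$V3, calls$end)
})

test_that("BLAST tabular and GFF3 readers map onto the feature contract", {
  blast <- tempfile(fileext = ".tsv")
  writeLines(paste(c("tciR", "contigA", "97.5", "900", "10", "2",
                     "1", "900", "5000", "4101", "1e-40", "1200"),
                   collapse = "\t"), blast)
  hits <- readBlastHits(blast, genome_id = "gX")
  expect_equal(hits$start, 4101)
  expect_equal(hits$end, 5000)
  expect_equal(hits$strand, "-")
  expect_equal(hits$evalue, 1e-40)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("contigA", "test", "gene", "8000", "9200", ".", "+", ".",
                     "ID=int1;product=site-specific integrase", sep = "\t"),
               paste("contigA", "test", "tRNA", "9500", "9575", ".", "-", ".",
                     "ID=t1;product=tRNA-Gly", sep = "\t"),
               paste("contigA", "test", "gene", "20000", "21000", ".", "+", ".",
                     "ID=x1;product=hypothetical protein", sep = "\t")), gff)
  ann <- readAnnotationGff(gff, genome_id = "gX")
  expect_equal(sort(ann$kind), c("integrase", "tRNA_gly"))
  expect_equal(ann$start[ann$kind == "integrase"], 8000)
})
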