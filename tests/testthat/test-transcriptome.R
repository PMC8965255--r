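test_that("GTF parse -> write -> parse round trip preserves the model", {
  ann <- fixture_txome()
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- parse_gtf(f)
  expect_equal(back$transcripts[order(back$transcripts$transcript_id), ],
               ann$transcripts[order(ann$transcripts$transcript_id), ])
  expect_equal(back$exons[order(back$exons$transcript_id, back$exons$start),
                          c("transcript_id", "chrom", "strand", "start", "end")],
               ann$exons[order(ann$exons$transcript_id, ann$exons$start),
                         c("transcript_id", "chrom", "strand", "start", "end")])
})

test_that("source labels are inferred from id conventions when absent", {
  f <- system.file("extdata", "mixed_sources.gtf", package = "isoqtl")
  ann <- parse_gtf(f)
  src <- setNames(ann$transcripts$source, ann$transcripts$transcript_id)
  expect_equal(src[["ENSRNOT00000024093"]], "ensembl")
  expect_equal(src[["ENSRNOT00000024093.1"]], "aptardi")  # suffix duplicate
  expect_equal(src[["MSTRG.6250.1"]], "stringtie")
})

test_that("exon sorting, spliced length, and validation errors", {
  ann <- fixture_txome()
  t1 <- ann$transcripts["ENSA1", ]
  expect_equal(t1$length, 101 + 101 + 101)
  ex1 <- ann$exons[ann$exons$transcript_id == "ENSA1", ]
  expect_false(is.unsorted(ex1$start))
  expect_error(txome(data.frame(transcript_id = "x", gene_id = "g",
                                chrom = "chr1", strand = "+",
                                start = c(1, 50), end = c(100, 120))),
               "overlapping")
  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id \"g\";"), bad)
  expect_error(parse_gtf(bad), "line")
})

test_that("3' termini are strand aware", {
  ann <- fixture_txome()
  tt <- three_prime_termini(ann)
  term <- setNames(tt$terminus, tt$transcript_id)
  expect_equal(term[["ENSA1"]], 1000)       # "+": last exon end
  expect_equal(term[["ENSA1.1"]], 1400)
  expect_equal(term[["ENSB1"]], 5000)       # "-": first exon start
  f <- system.file("extdata", "mixed_sources.gtf", package = "isoqtl")
  real <- three_prime_termini(parse_gtf(f))
  expect_equal(real$terminus[real$transcript_id == "ENSRNOT00000024093.1"],
               240561896)
  expect_equal(real$terminus[real$transcript_id == "ENSRNOT00000024093"],
               240562423)
})

test_that("terminus matching is inclusive, symmetric and tolerance-monotone", {
  expect_true(match_termini(100, 100))
  expect_true(match_termini(100, 200))          # |d| = 100: inclusive
  expect_false(match_termini(100, 201))         # |d| = 101
  expect_error(match_termini(1, 2, tolerance = -1), "non-negative")
  set.seed(1)
  a <- sample.int(1e6, 50); b <- sample.int(1e6, 50)
  expect_equal(match_termini(a, b), match_termini(b, a))
  t1 <- match_termini(a, b, 50)
  t2 <- match_termini(a, b, 500)
  expect_true(all(t2[t1]))                      # true at t stays true at t' > t
})

test_that("terminus pair ledger counts unique termini and matches", {
  ## four 3'-extension transcripts sharing one terminus
  ex <- do.call(rbind, lapply(1:4, function(i)
    data.frame(transcript_id = paste0("A", i, ".1"), gene_id = "G",
               chrom = "chr1", strand = "+", start = 100 * i,
               end = 5000, source = "aptardi")))
  led <- terminus_pair_ledger(txome(ex))
  expect_equal(led$n_unique_termini, 1)
  expect_equal(led$mean_transcripts_per_terminus, 4)

  ## an extension terminus 80 bases from a reference terminus matches;
  ## one 400 bases away does not
  ann <- fixture_txome()        # ensembl ENSA1 ends at 1000 on "+"
  led2 <- terminus_pair_ledger(txome(rbind(
    ann$exons[, c("transcript_id", "gene_id", "chrom", "strand",
                  "start", "end", "source")],
    data.frame(transcript_id = "NEAR.1", gene_id = "GA", chrom = "chr1",
               strand = "+", start = 950, end = 1080,
               source = "aptardi"))))
  p <- led2$pairs
  expect_true(p$matched[p$transcript_id == "NEAR.1"])
  expect_false(p$matched[p$transcript_id == "ENSA1.1"])  # 1400 vs 1000

  ## constructed fixture with exactly 20% matched
  mk <- function(id, term, src) {
    data.frame(transcript_id = id, gene_id = sub("\\..*", "", id),
               chrom = "chr1", strand = "+", start = term - 99, end = term,
               source = src, stringsAsFactors = FALSE)
  }
  ref <- mk("R1", 10000, "ensembl")
  apa <- do.call(rbind, c(
    list(mk("R1.1", 10080, "aptardi")),                  # within 100: matched
    lapply(1:4, function(i) mk(sprintf("N%d.1", i), 50000 + i * 10000,
                               "aptardi"))))             # far away
  led3 <- terminus_pair_ledger(txome(rbind(ref, apa)))
  expect_equal(led3$matched_fraction, 0.2)
  expect_equal(led3$n_transcripts, 5)
})

test_that("splice-junction association finds reference genes", {
  ann <- fixture_txome()
  ref <- subset_txome(ann, c("ENSA1", "ENSB1"))
  assoc <- shares_splice_junction(ann, ref)
  expect_equal(assoc[["ENSA1"]], "GA")            # identical chain
  ## exon-skipping isoform still shares its remaining junction? MSTRG.1.1
  ## junction (200, 900) is absent from ENSA1 (200,500 / 600,900): the
  ## skipped-exon isoform here shares no junction; ENSA1.1 shares both
  ## upstream junctions
  expect_equal(assoc[["ENSA1.1"]], "GA")
  expect_true(is.na(assoc[["ENSB1"]]) || assoc[["ENSB1"]] == "GB")
  ## single-exon transcript: no junctions, unassociated by default
  single <- txome(data.frame(transcript_id = "S1", gene_id = "GS",
                             chrom = "chr2", strand = "-", start = 5100,
                             end = 5600, source = "stringtie"))
  expect_true(is.na(shares_splice_junction(single, ref)[["S1"]]))
  ## opt-in exonic-overlap fallback associates it
  expect_equal(
    shares_splice_junction(single, ref, single_exon_overlap = TRUE)[["S1"]],
    "GB")
})

test_that("exon-skipping isoforms share the junctions they keep", {
  ## full isoform with 4 exons; skipping exon 3 keeps junctions 1-2 and
  ## joins 2-4 (novel); association still succeeds via junction 1-2
  full <- data.frame(transcript_id = "F", gene_id = "GF", chrom = "chr3",
                     strand = "+", start = c(1, 1000, 2000, 3000),
                     end = c(100, 1100, 2100, 3100), source = "ensembl")
  skip <- data.frame(transcript_id = "K", gene_id = "GF", chrom = "chr3",
                     strand = "+", start = c(1, 1000, 3000),
                     end = c(100, 1100, 3100), source = "stringtie")
  ann <- txome(rbind(full, skip))
  ref <- subset_txome(ann, "F")
  expect_equal(shares_splice_junction(ann, ref)[["K"]], "GF")
})

test_that("annotation summary reports counts, ratio and histogram", {
  ## 4 genes x 3 isoforms, sources 4/4/4
  ex <- do.call(rbind, lapply(1:4, function(g) do.call(rbind, lapply(1:3,
    function(i) data.frame(
      transcript_id = sprintf("T%d_%d", g, i), gene_id = paste0("G", g),
      chrom = "chr1", strand = "+", start = g * 1e4 + i * 100,
      end = g * 1e4 + i * 100 + 50,
      source = c("ensembl", "stringtie", "aptardi")[i])))))
  s <- summarize_annotation(txome(ex))
  expect_equal(s$n_genes, 4)
  expect_equal(s$n_transcripts, 12)
  expect_equal(s$transcript_gene_ratio, 3.00)
  expect_equal(s$by_source$percent, rep(33.3, 3))
  expect_equal(sum(s$by_source$n), 12)

  ## isoform histogram {1:1, 2:1, 3:1}
  ex2 <- do.call(rbind, lapply(1:3, function(g) do.call(rbind, lapply(
    seq_len(g), function(i) data.frame(
      transcript_id = sprintf("U%d_%d", g, i), gene_id = paste0("H", g),
      chrom = "chr1", strand = "+", start = g * 1e4 + i * 100,
      end = g * 1e4 + i * 100 + 50, source = "ensembl")))))
  h <- summarize_annotation(txome(ex2))$isoforms_per_gene
  expect_equal(as.integer(h), c(1, 1, 1))
  expect_equal(names(h), c("1", "2", "3"))
  expect_error(summarize_annotation(txome(ex[0, ])), "empty|lacks")
})

test_that("BED export of termini converts coordinates at the boundary", {
  ann <- fixture_txome()
  f <- withr::local_tempfile(fileext = ".bed")
  export_termini_bed(ann, f)
  bed <- read.delim(f, header = FALSE)
  row <- bed[bed$V4 == "ENSA1", ]
  expect_equal(row$V2, 999)     # 0-based half-open start = terminus - 1
  expect_equal(row$V3, 1000)
})
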