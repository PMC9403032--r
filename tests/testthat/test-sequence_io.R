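# FASTA/GFF3 fixtures are written on the fly to tempfiles.

write_fixture <- function(fasta_lines, gff_lines) {
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  writeLines(fasta_lines, fa)
  writeLines(c("##gff-version 3", gff_lines), gff)
  list(fasta = fa, gff = gff)
}

test_that("the longest cDNA is kept per gene, ties by transcript id", {
  seq_short <- strrep("ACGT", 300)   # 1200 nt
  seq_long <- strrep("ACGT", 375)    # 1500 nt
  fx <- write_fixture(
    c(">t1", seq_short, ">t2", seq_long, ">tB", seq_short, ">tA", seq_short),
    c("t1\tx\tmRNA\t1\t1200\t.\t+\t.\tID=transcript:t1;Parent=gene:gA",
      "t1\tx\tCDS\t1\t1200\t.\t+\t0\tParent=transcript:t1",
      "t2\tx\tmRNA\t1\t1500\t.\t+\t.\tID=transcript:t2;Parent=gene:gA",
      "t2\tx\tCDS\t1\t1500\t.\t+\t0\tParent=transcript:t2",
      "tB\tx\tmRNA\t1\t1200\t.\t+\t.\tID=transcript:tB;Parent=gene:gB",
      "tB\tx\tCDS\t1\t1200\t.\t+\t0\tParent=transcript:tB",
      "tA\tx\tmRNA\t1\t1200\t.\t+\t.\tID=transcript:tA;Parent=gene:gB",
      "tA\tx\tCDS\t1\t1200\t.\t+\t0\tParent=transcript:tA"))
  g <- load_transcripts(fx$fasta, fx$gff)
  rec <- g$records
  expect_identical(rec$transcript_id[rec$gene_id == "gA"], "t2")
  expect_identical(rec$cds[rec$gene_id == "gA"], seq_long)
  expect_identical(rec$transcript_id[rec$gene_id == "gB"], "tA")
})

test_that("minus-strand features are reverse-complemented into sense", {
  raw <- paste0(strrep("A", 9), "CATTTTGGC", strrep("A", 12))  # 30 nt
  fx <- write_fixture(
    c(">chr1", raw),
    c("chr1\tx\tmRNA\t1\t30\t.\t-\t.\tID=transcript:tm;Parent=gene:gm",
      "chr1\tx\tfive_prime_UTR\t19\t24\t.\t-\t.\tParent=transcript:tm",
      "chr1\tx\tCDS\t10\t18\t.\t-\t0\tParent=transcript:tm"))
  g <- load_transcripts(fx$fasta, fx$gff)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(g$records$cds, rc(substr(raw, 10, 18)))
  expect_identical(g$records$utr5, rc(substr(raw, 19, 24)))
  expect_identical(g$records$cds, "GCCAAAATG")
})

test_that("GFF transcripts missing from the FASTA are skipped and counted", {
  fx <- write_fixture(
    c(">t1", strrep("ATG", 10)),
    c("t1\tx\tCDS\t1\t30\t.\t+\t0\tParent=transcript:t1",
      "ghost\tx\tCDS\t1\t30\t.\t+\t0\tParent=transcript:ghost"))
  expect_message(g <- load_transcripts(fx$fasta, fx$gff), "skipped")
  expect_identical(nrow(g$records), 1L)
  expect_identical(attr(g, "n_skipped"), 1L)
})

test_that("unparseable GFF3 lines raise an error naming the line", {
  fx <- write_fixture(c(">t1", strrep("ATG", 10)),
                      c("t1\tx\tCDS\t1\t30\t.\t+\t0\tParent=transcript:t1",
                        "this is not gff"))
  expect_error(load_transcripts(fx$fasta, fx$gff), "line 3")
})

test_that("filter_valid applies length, frame and start-codon checks", {
  mk <- function(n_nt, start = "ATG") {
    paste0(start, strrep("GCT", (n_nt - 3) %/% 3),
           strrep("A", (n_nt - 3) %% 3))
  }
  g <- make_genome(c(mk(300), mk(900), mk(903), mk(900, "TTG"), mk(901)))
  out <- quiet(filter_valid(g))
  expect_identical(nrow(out$records), 2L)
  expect_setequal(out$records$cds_length_nt, c(900L, 903L))
  report <- attr(out, "filter_report")
  expect_identical(nrow(report), 3L)
  expect_true(any(grepl("too_short", report$reason)))
  expect_true(any(grepl("no_start_codon", report$reason)))
  expect_true(any(grepl("not_multiple_of_3", report$reason)))
  # start-codon check is configurable
  out2 <- quiet(filter_valid(g, require_start_codon = FALSE))
  expect_identical(nrow(out2$records), 3L)
  # idempotent
  out3 <- quiet(filter_valid(out))
  expect_identical(out3$records, out$records)
})

test_that("internal stop codons are retained but flagged", {
  cds <- paste0("ATG", "TAA", strrep("GCT", 299), "TAA")
  g <- make_genome(cds)
  expect_true(g$records$internal_stop)
  out <- quiet(filter_valid(g))
  expect_identical(nrow(out$records), 1L)
})

test_that("filter report round-trips through its TSV writer", {
  g <- make_genome(c(strrep("GCT", 10), paste0("ATG", strrep("GCT", 300))))
  out <- quiet(filter_valid(g))
  path <- tempfile(fileext = ".tsv")
  write_filter_report(out, path)
  back <- read.delim(path)
  expect_identical(back$gene_id, attr(out, "filter_report")$gene_id)
})

test_that("coding_gc pools counts across records and ignores N and order", {
  cds_40 <- paste0(strrep("G", 120), strrep("A", 180))      # 300 nt, 40%
  cds_60 <- paste0(strrep("C", 540), strrep("T", 360))      # 900 nt, 60%
  g <- make_genome(c(cds_40, cds_60))
  expect_equal(coding_gc(g), 55)
  g_rev <- make_genome(c(cds_60, cds_40))
  expect_equal(coding_gc(g_rev), coding_gc(g))
  expect_equal(coding_gc(make_genome(strrep("G", 30))), 100)
  # N excluded from numerator and denominator
  gN <- make_genome(paste0("GC", strrep("N", 10), "AT"))
  expect_equal(coding_gc(gN), 50)
  expect_error(coding_gc(make_genome(strrep("N", 9))), "countable")
})

test_that("synthetic writer output reloads to identical sequences", {
  sim <- quiet(generate_genome(synthetic_spec(n_genes = 8, utr5_len = 20,
                                              seed = 11)))
  d <- tempfile()
  paths <- write_outputs(sim, d)
  back <- load_transcripts(paths[["fasta"]], paths[["gff3"]])
  i <- match(sim$genome$records$gene_id, back$records$gene_id)
  expect_identical(back$records$cds[i], sim$genome$records$cds)
  expect_identical(back$records$utr5[i], sim$genome$records$utr5)
})
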