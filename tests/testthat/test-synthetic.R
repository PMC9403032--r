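test_that("the same seed reproduces byte-identical outputs", {
  spec <- synthetic_spec(n_genes = 15, utr5_len = 25, seed = 61)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_outputs(quiet(generate_genome(spec)), d1)
  p2 <- write_outputs(quiet(generate_genome(spec)), d2)
  for (f in c("fasta", "gff3", "expression")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), info = f)
  }
  # a different seed changes the sequences
  other <- quiet(generate_genome(synthetic_spec(n_genes = 15, utr5_len = 25,
                                                seed = 62)))
  expect_false(identical(readLines(p1[["fasta"]]),
                         readLines(write_outputs(other, tempfile())[["fasta"]])))
})

test_that("generated genes all pass the default validity filter", {
  sim <- quiet(generate_genome(synthetic_spec(n_genes = 50, seed = 63)))
  out <- filter_valid(sim$genome)
  expect_identical(nrow(out$records), 50L)
  expect_true(all(substr(out$records$cds, 1, 3) == "ATG"))
  expect_true(all(out$records$cds_length_nt %% 3 == 0))
  expect_true(all(out$records$cds_length_nt >= 900))
  expect_false(any(out$records$internal_stop))
})

test_that("GFF3 coordinates account for the 5'-UTR offset", {
  sim <- quiet(generate_genome(synthetic_spec(n_genes = 1, utr5_len = 20,
                                              seed = 64)))
  d <- tempfile()
  paths <- write_outputs(sim, d)
  gff <- readLines(paths[["gff3"]])
  cds_line <- grep("\tCDS\t", gff, value = TRUE)
  f <- strsplit(cds_line, "\t")[[1]]
  expect_identical(as.integer(f[4:5]), c(21L, 923L))  # 903-nt CDS after 20-nt UTR
  utr_line <- grep("five_prime_UTR", gff, value = TRUE)
  expect_identical(as.integer(strsplit(utr_line, "\t")[[1]][4:5]),
                   c(1L, 20L))
  # no UTR features when utr5_len = 0
  sim0 <- quiet(generate_genome(synthetic_spec(n_genes = 2, utr5_len = 0,
                                               seed = 65)))
  gff0 <- readLines(write_outputs(sim0, tempfile())[["gff3"]])
  expect_length(grep("five_prime_UTR", gff0), 0L)
})

test_that("realized per-position site-class GC tracks the spec's targets", {
  spec <- synthetic_spec(n_genes = 2000, seed = 66)
  sim <- quiet(generate_genome(spec))
  for (k in c("NS", "TWOFOLD", "FOURFOLD")) {
    prof <- positional_mean(sim$genome, "START", k)
    key <- c(NS = "expected_gc_ns", TWOFOLD = "expected_gc_2s",
             FOURFOLD = "expected_gc_4s")[[k]]
    expected <- sim$truth[[key]][match(2:100, sim$truth$position)]
    realized <- prof$mean_value[2:100]
    expect_true(all(abs(realized - expected) < 1.5), info = k)
  }
  # and the expectations themselves follow the configured linear gradients
  p <- 2:100
  expect_true(all(abs(sim$truth$expected_gc_ns[match(p, sim$truth$position)] -
                        (spec$gc_start_ns + spec$slope_ns * (p - 1) / 100)) <
                    1e-3))
})

test_that("null gradients generate flat profiles", {
  sim <- quiet(generate_genome(synthetic_spec(
    n_genes = 1000, gc_start_ns = 50, slope_ns = 0, seed = 67)))
  for (k in c("NS", "TWOFOLD", "FOURFOLD")) {
    fit <- fit_gradient(positional_mean(sim$genome, "START", k))
    expect_lt(abs(fit$slope_per100), 0.5, label = paste(k, "slope"))
  }
})

test_that("expression-coupled genomes order start-region GC by bin", {
  sim <- quiet(generate_genome(synthetic_spec(
    n_genes = 400, expression_gc_coupling = 2, seed = 68)))
  rec <- sim$genome$records
  bins <- setNames(sim$expression$bin, sim$expression$gene_id)
  start_gc <- vapply(seq_len(nrow(rec)), function(i) {
    mean(codon_gc(extract_fragment(rec$cds[i], "START")[2:100]))
  }, numeric(1))
  by_bin <- tapply(start_gc, bins[rec$gene_id], mean)
  expect_true(all(diff(by_bin) > 0))
})

test_that("infeasible GC targets are clamped with a warning", {
  spec <- synthetic_spec(n_genes = 5, gc_start_ns = 98, slope_ns = 0,
                         seed = 69)
  expect_warning(generate_genome(spec), "clamped")
})

test_that("a user codon-usage prior is honoured and validated", {
  usage <- human_codon_usage()
  expect_length(usage, 61L)
  sim <- quiet(generate_genome(synthetic_spec(
    n_genes = 20, codon_usage = usage, seed = 70)))
  expect_identical(nrow(filter_valid(sim$genome)$records), 20L)
  bad <- usage[1:10]
  expect_error(generate_genome(synthetic_spec(n_genes = 5,
                                              codon_usage = bad, seed = 1)),
               "61 sense codons")
})
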