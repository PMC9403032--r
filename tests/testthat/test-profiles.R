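test_that("fragments are placed at the start, centre and end of the CDS", {
  pool <- c("GCT", "GAA", "TTT", "CCG", "ATG", "AAA")
  set.seed(3)
  cv400 <- sample(pool, 400, replace = TRUE)
  cds <- paste0(paste(cv400, collapse = ""), "TAA")
  expect_identical(extract_fragment(cds, "START"), cv400[1:100])
  expect_identical(extract_fragment(cds, "MIDDLE"), cv400[151:250])
  expect_identical(extract_fragment(cds, "END"), cv400[301:400])

  cv301 <- sample(pool, 301, replace = TRUE)
  cds301 <- paste0(paste(cv301, collapse = ""), "TAA")
  expect_identical(extract_fragment(cds301, "MIDDLE"), cv301[101:200])

  # exactly 300 coding codons: fragments tile the CDS
  cv300 <- sample(pool, 300, replace = TRUE)
  cds300 <- paste0(paste(cv300, collapse = ""), "TAA")
  expect_identical(c(extract_fragment(cds300, "START"),
                     extract_fragment(cds300, "MIDDLE"),
                     extract_fragment(cds300, "END")), cv300)

  expect_error(extract_fragment(paste(cv301[1:50], collapse = ""), "START"),
               "coding codons")
})

test_that("codon_gc computes per-class GC values with NA where undefined", {
  expect_equal(codon_gc("GCG"), 100)
  expect_equal(codon_gc("GCA"), 200 / 3)
  expect_equal(codon_gc("GCA", "FOURFOLD"), 0)
  expect_equal(codon_gc("GCG", "FOURFOLD"), 100)
  expect_true(is.na(codon_gc("ATG", "FOURFOLD")))
  expect_true(is.na(codon_gc("GCN")))
  expect_true(is.na(codon_gc("TAA")))  # stop excluded from averaging
  # TTA: 2s sites at positions 1 and 3 (T, A) -> 0% GC at 2s
  expect_equal(codon_gc("TTA", "TWOFOLD"), 0)
  expect_equal(codon_gc("TTA", "NS"), 0)
})

test_that("positional means average codon GC across genes", {
  base <- strrep("GCT", 299)  # codons 2..300 identical across genes
  g <- make_genome(c(paste0("GGG", base, "TAA"),
                     paste0("AAA", base, "TAA")))
  prof <- positional_mean(g, "START", "ALL")
  expect_equal(prof$mean_value[1], 50)   # (100 + 0) / 2
  expect_equal(prof$n_genes[1], 2L)
  expect_equal(prof$mean_value[2], codon_gc("GCT"))

  # masking one gene's codon leaves the mean over the remaining gene
  g2 <- make_genome(c(paste0("ATG", "AAA", base2 <- strrep("GCT", 298), "TAA"),
                      paste0("ATG", "CCC", base2, "TAA")))
  prof2 <- positional_mean(g2, "START", "ALL", exclude_aas = "K")
  expect_equal(prof2$n_genes[2], 1L)
  expect_equal(prof2$mean_value[2], 100)  # only CCC (proline) remains
})

test_that("profiles are invariant to gene order and bounded by gene values", {
  sim <- quiet(generate_genome(synthetic_spec(n_genes = 30, seed = 9)))
  g <- sim$genome
  prof <- positional_mean(g, "START", "NS")
  g_perm <- genome_set(g$records[rev(seq_len(nrow(g$records))), ],
                       species_label = g$species_label)
  prof_perm <- positional_mean(g_perm, "START", "NS")
  expect_equal(prof$mean_value, prof_perm$mean_value)

  # per-position mean lies between the per-gene extremes
  vals <- sapply(seq_len(nrow(g$records)), function(i) {
    codon_gc(extract_fragment(g$records$cds[i], "START"), "NS")
  })
  mins <- apply(vals, 1, min, na.rm = TRUE)
  maxs <- apply(vals, 1, max, na.rm = TRUE)
  ok <- !is.na(prof$mean_value)
  expect_true(all(prof$mean_value[ok] >= mins[ok] - 1e-9))
  expect_true(all(prof$mean_value[ok] <= maxs[ok] + 1e-9))
})

test_that("ALL profile is recovered from class profiles and site counts", {
  # single-gene fixture: reconstruction is exact per position
  sim <- quiet(generate_genome(synthetic_spec(n_genes = 1, seed = 13)))
  g <- sim$genome
  prof_all <- positional_mean(g, "START", "ALL")
  parts <- lapply(c("NS", "TWOFOLD", "FOURFOLD"), function(k) {
    positional_mean(g, "START", k)$mean_value
  })
  tab <- site_class_table()
  counts <- lapply(c("NS", "TWOFOLD", "FOURFOLD"), function(k) {
    setNames(rowSums(tab[, c("pos1", "pos2", "pos3")] == k), tab$codon)
  })
  cod <- extract_fragment(g$records$cds[1], "START")
  recon <- rep(0, 100)
  for (k in 1:3) {
    v <- parts[[k]]
    v[is.na(v)] <- 0
    recon <- recon + v * counts[[k]][cod] / 3
  }
  expect_equal(unname(recon), prof_all$mean_value)
})

test_that("profile TSV writer emits the documented columns", {
  g <- make_genome(paste0("ATG", strrep("GCT", 299), "TAA"))
  prof <- positional_mean(g, "START", "ALL")
  path <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, path)
  back <- read.delim(path)
  expect_identical(names(back),
                   c("position", "mean_gc", "n_genes", "site_class",
                     "fragment"))
  expect_equal(nrow(back), 100L)
})
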