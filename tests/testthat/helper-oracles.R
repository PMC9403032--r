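# Independent oracles and small fixture builders shared across tests.

# Exhaustive single-substitution classification oracle, built on
# seqinr::translate (independent of the package's Biostrings-based tables).
oracle_classify <- function(codon) {
  tr <- function(cod) seqinr::translate(seqinr::s2c(cod))
  aa <- tr(codon)
  vapply(1:3, function(p) {
    alts <- setdiff(c("A", "C", "G", "T"), substr(codon, p, p))
    nsyn <- sum(vapply(alts, function(b) {
      alt <- codon
      substr(alt, p, p) <- b
      alt_aa <- tr(alt)
      if (aa == "*") alt_aa == "*" else (alt_aa == aa && alt_aa != "*")
    }, logical(1)))
    if (nsyn == 3L) "FOURFOLD" else if (nsyn >= 1L) "TWOFOLD" else "NS"
  }, character(1))
}

# Brute-force folding oracle: enumerates every set of mutually compatible
# (disjoint, non-crossing, loop >= min_loop) complementary pairs and takes
# the minimum summed pair score. Exponential; only for short sequences.
oracle_fold <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(s)
  pscore <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(-3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(-2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(-1)
    NA_real_
  }
  cand <- list()
  if (n > min_loop + 1) {
    for (i in 1:(n - min_loop - 1)) {
      for (j in (i + min_loop + 1):n) {
        sc <- pscore(s[i], s[j])
        if (!is.na(sc)) cand[[length(cand) + 1L]] <- c(i, j, sc)
      }
    }
  }
  best <- 0
  compatible <- function(p, chosen) {
    for (q in chosen) {
      if (any(p[1:2] %in% q[1:2])) return(FALSE)
      in1 <- p[1] > q[1] && p[1] < q[2]
      in2 <- p[2] > q[1] && p[2] < q[2]
      if (xor(in1, in2)) return(FALSE)  # crossing
    }
    TRUE
  }
  recurse <- function(start, chosen, score) {
    best <<- min(best, score)
    if (start > length(cand)) return(invisible())
    for (ci in start:length(cand)) {
      p <- cand[[ci]]
      if (compatible(p, chosen)) {
        recurse(ci + 1L, c(chosen, list(p)), score + p[3])
      }
    }
  }
  recurse(1L, list(), 0)
  best
}

# closed-form OLS oracle (explicit sums)
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# single-record genome around a given CDS (+ optional 5'-UTR)
make_record <- function(cds, utr5 = "", gene_id = "g1") {
  tibble::tibble(gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
                 cds = cds, utr5 = utr5)
}

make_genome <- function(cds_vec, utr5 = "", label = "fixture") {
  ids <- sprintf("g%03d", seq_along(cds_vec))
  genome_set(tibble::tibble(gene_id = ids,
                            transcript_id = paste0(ids, ".t1"),
                            cds = cds_vec, utr5 = utr5),
             species_label = label)
}

# deterministic CDS of n_codons coding codons (+TAA) from a codon pool
make_cds <- function(n_codons, pool = c("GCT", "GAA", "TTT", "CCG"),
                     seed = 1) {
  set.seed(seed)
  paste0(paste(sample(pool, n_codons, replace = TRUE), collapse = ""), "TAA")
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
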