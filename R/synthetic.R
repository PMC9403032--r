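# Synthetic genome generator: coding sequences whose expected per-position
# GC at ns/2s/4s sites follows specified linear gradients, with optional
# 5'-UTRs, lognormal expression abundances and expression-coupled start-region
# GC. Targets are hit in expectation by exponential tilting of the codon
# distribution; sampling is balanced per position so realized profiles track
# the targets tightly (see the methods vignette).

#' Specification of a synthetic genome
#'
#' All GC values are percentages; slopes are GC-percentage change per 100
#' codons along translation. The ns-site target at codon position `p` of the
#' start fragment is `gc_start_ns + slope_ns*(p-1)/100`; 2s and 4s targets
#' start from `baseline_gc` with their own slopes; positions beyond the
#' first 100 codons, middle/end fragments and 5'-UTRs sit at `baseline_gc`.
#' When `expression_gc_coupling` is nonzero, genes are ranked into
#' `n_bins` expression bins and every start-fragment target is shifted by
#' `expression_gc_coupling * (bin - 1)`. Targets are clamped to `[5, 95]`
#' with a warning.
#'
#' @param n_genes Number of genes (default 2000).
#' @param cds_len_codons Coding codons per gene, excluding the terminal stop
#'   (default 300, i.e. a 903-nt annotated CDS).
#' @param gc_start_ns ns-site GC % at codon position 1 (default 60).
#' @param slope_ns,slope_2s,slope_4s Gradients, % per 100 codons
#'   (defaults -5, 0, 0: the tetrapod-like condition).
#' @param baseline_gc Background GC % (default 50).
#' @param utr5_len 5'-UTR length in nt (default 50; 0 = no UTRs).
#' @param expression_mu,expression_sigma Lognormal meanlog/sdlog of
#'   abundances (defaults 2, 1.5, TPM-like).
#' @param expression_gc_coupling GC % shift at the start fragment per
#'   expression bin step (default 0).
#' @param n_bins Expression bins used for the coupling (default 4).
#' @param codon_usage Optional named numeric vector of relative usage over
#'   the 61 sense codons (the tilting prior); `NULL` = uniform. The bundled
#'   human-like table can be loaded with [human_codon_usage()].
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000, cds_len_codons = 300,
                           gc_start_ns = 60, slope_ns = -5, slope_2s = 0,
                           slope_4s = 0, baseline_gc = 50, utr5_len = 50,
                           expression_mu = 2, expression_sigma = 1.5,
                           expression_gc_coupling = 0, n_bins = 4,
                           codon_usage = NULL, seed = 1) {
  stopifnot(n_genes >= 1, cds_len_codons >= 300, utr5_len >= 0,
            n_bins >= 1, is.numeric(seed))
  spec <- list(n_genes = as.integer(n_genes),
               cds_len_codons = as.integer(cds_len_codons),
               gc_start_ns = gc_start_ns, slope_ns = slope_ns,
               slope_2s = slope_2s, slope_4s = slope_4s,
               baseline_gc = baseline_gc, utr5_len = as.integer(utr5_len),
               expression_mu = expression_mu,
               expression_sigma = expression_sigma,
               expression_gc_coupling = expression_gc_coupling,
               n_bins = as.integer(n_bins), codon_usage = codon_usage,
               seed = as.integer(seed))
  structure(spec, class = "synthetic_spec")
}

#' Bundled human-like codon usage table
#'
#' Relative codon usage (per-thousand frequencies, averaged human values)
#' over the 61 sense codons, usable as the generator's usage prior.
#'
#' @return Named numeric vector of length 61.
#' @export
human_codon_usage <- function() {
  path <- system.file("extdata", "codon_usage_human.tsv",
                      package = "gcgradient", mustWork = TRUE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(d$per_thousand), toupper(d$codon))
}

.tilt_cache <- new.env(parent = emptyenv())

# --- exponential tilting ---------------------------------------------------
# Weights over the 61 sense codons, w(c) prop. to q(c) * exp(sum_k par_k *
# g_k(c)) with g_k = number of G/C nucleotides at class-k sites, solved so
# that the conditional per-site-class GC expectations match `targets`
# (fractions, order ns/2s/4s).
.tilt_moments <- function(par, q, G, R, has) {
  w <- q * exp(as.vector(G %*% par))
  w <- w / sum(w)
  vapply(1:3, function(k) {
    sum(w[has[, k]] * R[has[, k], k]) / sum(w[has[, k]])
  }, numeric(1))
}

.solve_tilt <- function(targets, q, G, R, has) {
  fn <- function(par) sum((.tilt_moments(par, q, G, R, has) - targets)^2)
  fit <- optim(c(0, 0, 0), fn, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  if (fit$value > 1e-12) {
    fit <- optim(fit$par, fn, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  }
  if (fit$value > 1e-8) {
    warning("tilting solver residual ", signif(sqrt(fit$value), 3),
            " for targets ", paste(signif(targets, 4), collapse = "/"))
  }
  w <- q * exp(as.vector(G %*% fit$par))
  w / sum(w)
}

# Balanced draw of n codons from weights w: floor(n*w) deterministic counts
# plus a multinomial remainder on the fractional parts (expectation exactly
# n*w), randomly permuted across genes.
.balanced_draw <- function(w, n) {
  base <- floor(n * w)
  frac <- n * w - base
  rem <- n - sum(base)
  counts <- base
  if (rem > 0L) {
    extra <- sample.int(length(w), rem, replace = TRUE,
                        prob = frac / sum(frac))
    counts <- counts + tabulate(extra, nbins = length(w))
  }
  idx <- rep.int(seq_along(w), counts)
  if (length(idx) > 1L) idx <- sample(idx)
  idx
}

.clamp_targets <- function(t) pmin(0.95, pmax(0.05, t))

#' Generate a synthetic genome with known positional ground truth
#'
#' Samples, for every gene and codon position, a sense codon from a
#' position-specific reweighting of the codon-usage prior such that the
#' expected G/C fraction at ns, 2s and 4s sites matches the linear targets
#' of the spec. Codon 1 is fixed to `ATG`, internal stops are never sampled,
#' a terminal stop is appended, 5'-UTRs are sampled at `baseline_gc`, and
#' expression abundances are lognormal. All randomness flows from
#' `spec$seed`, so equal specs give byte-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_genome`: list with `genome` (a
#'   [genome_set()]), `expression` (tibble `gene_id`, `abundance`, `bin`),
#'   `truth` (tibble of expected per-position per-class GC by bin), and
#'   `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  tab <- .ct()
  sense <- tab$sense
  q <- if (is.null(spec$codon_usage)) {
    rep(1 / length(sense), length(sense))
  } else {
    u <- spec$codon_usage[tab$codons[sense]]
    if (anyNA(u)) stop("codon_usage must cover all 61 sense codons")
    unname(u / sum(u))
  }
  G <- tab$Gstat
  N <- tab$Nstat
  R <- ifelse(N > 0, G / N, NA_real_)
  has <- N > 0

  n <- spec$n_genes
  L <- spec$cds_len_codons
  gene_id <- sprintf("gene%05d", seq_len(n))
  transcript_id <- sprintf("tx%05d", seq_len(n))

  expr <- rlnorm(n, spec$expression_mu, spec$expression_sigma)
  if (spec$expression_gc_coupling != 0) {
    b <- bin_by_expression(setNames(expr, gene_id), spec$n_bins)
    bin <- unname(setNames(b$bin, b$gene_id)[gene_id])
  } else {
    bin <- rep(1L, n)
  }
  strata <- sort(unique(bin))

  clamped <- FALSE
  # tilt solutions depend only on (targets, prior); cache across calls
  qkey <- paste(signif(q, 8), collapse = ",")
  get_w <- function(targets) {
    key <- paste(qkey, paste(signif(targets, 10), collapse = "_"))
    if (is.null(.tilt_cache[[key]])) {
      .tilt_cache[[key]] <- .solve_tilt(targets, q, G, R, has)
    }
    .tilt_cache[[key]]
  }

  target_for <- function(p, bin_k) {
    shift <- if (p <= 100L) {
      spec$expression_gc_coupling * (bin_k - 1L)
    } else 0
    t <- if (p <= 100L) {
      c(spec$gc_start_ns + spec$slope_ns * (p - 1) / 100,
        spec$baseline_gc + spec$slope_2s * (p - 1) / 100,
        spec$baseline_gc + spec$slope_4s * (p - 1) / 100) + shift
    } else {
      rep(spec$baseline_gc, 3L)
    }
    t <- t / 100
    tc <- .clamp_targets(t)
    if (any(tc != t)) clamped <<- TRUE
    tc
  }

  m <- matrix(NA_integer_, n, L)  # indices into the 61 sense codons
  atg_sense <- match(match("ATG", tab$codons), sense)
  m[, 1L] <- atg_sense
  truth_rows <- list()
  for (p in 2:L) {
    distinct <- if (p <= 100L) strata else strata[1L]
    for (bk in distinct) {
      rows <- if (p <= 100L) which(bin == bk) else seq_len(n)
      w <- get_w(target_for(p, bk))
      m[rows, p] <- .balanced_draw(w, length(rows))
      if (p <= 100L) {
        e <- vapply(1:3, function(k) {
          sum(w[has[, k]] * R[has[, k], k]) / sum(w[has[, k]])
        }, numeric(1))
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          position = p, bin = bk,
          expected_gc_ns = 100 * e[1L], expected_gc_2s = 100 * e[2L],
          expected_gc_4s = 100 * e[3L])
      }
    }
  }
  truth <- do.call(rbind, truth_rows)

  codon_str <- tab$codons[sense]
  stops <- sample(.STOP_CODONS, n, replace = TRUE)
  cds <- vapply(seq_len(n), function(i) {
    paste0(paste(codon_str[m[i, ]], collapse = ""), stops[i])
  }, character(1))

  utr5 <- if (spec$utr5_len > 0L) {
    f <- spec$baseline_gc / 100
    probs <- c((1 - f) / 2, f / 2, f / 2, (1 - f) / 2)
    chars <- sample(c("A", "C", "G", "T"), n * spec$utr5_len,
                    replace = TRUE, prob = probs)
    apply(matrix(chars, nrow = n), 1L, paste, collapse = "")
  } else rep("", n)

  genome <- genome_set(
    tibble::tibble(gene_id = gene_id, transcript_id = transcript_id,
                   cds = cds, utr5 = utr5),
    species_label = sprintf("synthetic_seed%d", spec$seed)
  )
  if (clamped) {
    warning("some GC targets fell outside [5, 95] and were clamped")
  }
  structure(list(
    genome = genome,
    expression = tibble::tibble(gene_id = gene_id, abundance = expr,
                                bin = bin),
    truth = truth,
    spec = spec
  ), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d gene(s) x %d coding codons (seed %d, ns slope %+g)\n",
    x$spec$n_genes, x$spec$cds_len_codons, x$spec$seed, x$spec$slope_ns))
  invisible(x)
}

#' Write a synthetic genome to FASTA + GFF3 + expression TSV (+ truth JSON)
#'
#' The cDNA FASTA concatenates 5'-UTR and CDS per transcript; the GFF3 uses
#' transcript-relative 1-based inclusive coordinates with `mRNA`,
#' `five_prime_UTR` (omitted when empty) and `CDS` features grouped by
#' `Parent`. Files round-trip through [load_transcripts()] and
#' [load_expression()].
#'
#' @param sim A `synthetic_genome` from [generate_genome()] (or a plain
#'   [genome_set()], in which case only FASTA/GFF3 are written).
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(sim, out_dir) {
  genome <- if (inherits(sim, "synthetic_genome")) sim$genome else sim
  stopifnot(inherits(genome, "genome_set"))
  rec <- genome$records
  if (nrow(rec) == 0L) stop("genome set is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cdna <- Biostrings::DNAStringSet(paste0(rec$utr5, rec$cds))
  names(cdna) <- rec$transcript_id
  fasta_path <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(cdna, fasta_path)

  u <- nchar(rec$utr5)
  L <- nchar(rec$cds)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(rec))) {
    tid <- rec$transcript_id[i]
    gid <- rec$gene_id[i]
    tot <- u[i] + L[i]
    lines <- c(lines,
      sprintf("%s\tgcgradient\tgene\t1\t%d\t.\t+\t.\tID=gene:%s",
              tid, tot, gid),
      sprintf("%s\tgcgradient\tmRNA\t1\t%d\t.\t+\t.\tID=transcript:%s;Parent=gene:%s",
              tid, tot, tid, gid),
      if (u[i] > 0L) {
        sprintf("%s\tgcgradient\tfive_prime_UTR\t1\t%d\t.\t+\t.\tParent=transcript:%s",
                tid, u[i], tid)
      },
      sprintf("%s\tgcgradient\tCDS\t%d\t%d\t.\t+\t0\tParent=transcript:%s",
              tid, u[i] + 1L, u[i] + L[i], tid))
  }
  gff_path <- file.path(out_dir, "genome.gff3")
  writeLines(lines, gff_path)
  paths <- c(fasta = fasta_path, gff3 = gff_path)

  if (inherits(sim, "synthetic_genome")) {
    expr_path <- file.path(out_dir, "expression.tsv")
    write.table(as.data.frame(sim$expression[, c("gene_id", "abundance")]),
                expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
    truth_path <- file.path(out_dir, "ground_truth.json")
    spec_out <- sim$spec
    class(spec_out) <- NULL
    jsonlite::write_json(
      list(spec = spec_out, truth = sim$truth),
      truth_path, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- c(paths, expression = expr_path, truth = truth_path)
  }
  invisible(paths)
}
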