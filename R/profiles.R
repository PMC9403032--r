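# Positional GC profiles: start/middle/end 100-codon fragments and
# per-codon-position means across all valid genes of a genome.

.FRAGMENTS <- c("START", "MIDDLE", "END")

# 1-based start codon index of a fragment within L coding codons
.fragment_start <- function(which, L, len) {
  switch(which,
         START = 1L,
         MIDDLE = as.integer(floor((L - len) / 2) + 1L),
         END = L - len + 1L)
}

#' Extract a 100-codon fragment from a CDS
#'
#' Fragments are taken from the coding codons (annotated terminal stop
#' removed; codon 1 is the start codon): `START` = codons 1-100, `END` = the
#' last 100 codons, `MIDDLE` = 100 codons centred on the CDS midpoint
#' (start index `floor((L-100)/2)+1` for `L` coding codons). Sequence
#' between fragments is discarded.
#'
#' @param record A transcript record (list/row with `cds`) or CDS string.
#' @param which One of `"START"`, `"MIDDLE"`, `"END"`.
#' @param length_codons Fragment length in codons (default 100).
#' @return Character vector of `length_codons` codons.
#' @export
extract_fragment <- function(record, which = c("START", "MIDDLE", "END"),
                             length_codons = 100) {
  which <- match.arg(which)
  cds <- if (is.character(record)) record else record$cds
  cod <- .codons_of(.strip_stop(toupper(cds)))
  L <- length(cod)
  if (L < 3L * length_codons) {
    stop("CDS has ", L, " coding codons; need at least ",
         3L * length_codons, " (should have been filtered out)")
  }
  s <- .fragment_start(which, L, as.integer(length_codons))
  cod[s:(s + length_codons - 1L)]
}

#' Per-codon GC value for a site-class selector
#'
#' For `"ALL"` the value is the fraction of the codon's 3 nucleotides that
#' are G or C (x100). For a specific degeneracy class it is the G/C
#' indicator (0 or 100) averaged over the codon's positions of that class,
#' and `NA` when the codon has no such position. Stop codons and
#' N-containing codons return `NA`.
#'
#' @param codon Character vector of 3-letter codons.
#' @param site_class One of `"ALL"`, `"NS"`, `"TWOFOLD"`, `"FOURFOLD"`.
#' @return Numeric vector in `[0, 100]` with `NA` where undefined.
#' @examples
#' codon_gc("GCG")                 # 100
#' codon_gc("GCA", "FOURFOLD")     # 0: the third (4s) position is A
#' codon_gc("ATG", "FOURFOLD")     # NA: methionine has no 4s site
#' @export
codon_gc <- function(codon, site_class = c("ALL", "NS", "TWOFOLD",
                                           "FOURFOLD")) {
  site_class <- match.arg(site_class)
  .ct()$val[[site_class]][.codon_idx(toupper(codon))]
}

# integer codon-index matrix (genes x positions) for one fragment
.fragment_matrix <- function(genome, which, length_codons = 100) {
  rec <- genome$records
  n <- nrow(rec)
  m <- matrix(NA_integer_, n, length_codons)
  for (i in seq_len(n)) {
    m[i, ] <- .codon_idx(extract_fragment(rec$cds[i], which, length_codons))
  }
  m
}

#' Positional mean GC profile across a gene set
#'
#' For every codon position of the chosen fragment, averages [codon_gc()]
#' across all genes of the set, skipping undefined values and codons masked
#' by `exclude_aas` (masked positions are skipped, never renumbered).
#'
#' @param genome A [genome_set()] of valid records (all CDSs must cover the
#'   fragment).
#' @param fragment One of `"START"`, `"MIDDLE"`, `"END"`.
#' @inheritParams codon_gc
#' @param exclude_aas Optional character vector of 1-letter amino-acid codes
#'   whose codons are dropped from averaging.
#' @param length_codons Fragment length in codons (default 100).
#' @return A tibble of class `positional_profile` with columns `position`
#'   (1..`length_codons`), `mean_value` (GC %), `n_genes`, `site_class`,
#'   `fragment`; attribute `value_type = "gc_percent"`.
#' @export
positional_mean <- function(genome, fragment = c("START", "MIDDLE", "END"),
                            site_class = c("ALL", "NS", "TWOFOLD",
                                           "FOURFOLD"),
                            exclude_aas = NULL, length_codons = 100) {
  fragment <- match.arg(fragment)
  site_class <- match.arg(site_class)
  stopifnot(inherits(genome, "genome_set"))
  if (nrow(genome$records) == 0L) stop("genome set has no records")
  m <- .fragment_matrix(genome, fragment, length_codons)
  vals <- matrix(.ct()$val[[site_class]][m], nrow = nrow(m))
  if (!is.null(exclude_aas) && length(exclude_aas) > 0L) {
    valid_codes <- setdiff(unique(.ct()$aa), "*")
    bad <- setdiff(exclude_aas, valid_codes)
    if (length(bad) > 0L) {
      stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
    }
    drop <- matrix(.ct()$aa[m] %in% exclude_aas, nrow = nrow(m))
    vals[drop] <- NA_real_
  }
  .profile_from_values(vals, site_class, fragment, "gc_percent")
}

.profile_from_values <- function(vals, site_class, fragment, value_type) {
  n_genes <- colSums(!is.na(vals))
  mean_value <- colMeans(vals, na.rm = TRUE)
  mean_value[n_genes == 0L] <- NA_real_
  if (any(n_genes == 0L)) {
    message(sum(n_genes == 0L),
            " position(s) with no contributing genes (value set to NA)")
  }
  out <- tibble::tibble(position = seq_len(ncol(vals)),
                        mean_value = mean_value,
                        n_genes = as.integer(n_genes),
                        site_class = site_class, fragment = fragment)
  class(out) <- c("positional_profile", class(out))
  attr(out, "value_type") <- value_type
  out
}

#' Write positional profiles as TSV
#'
#' @param profiles A `positional_profile` tibble (or several row-bound
#'   together).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(profiles, path) {
  df <- as.data.frame(profiles)
  names(df)[names(df) == "mean_value"] <-
    if (identical(attr(profiles, "value_type"), "cost")) "mean_cost"
    else "mean_gc"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
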