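# Internal codon machinery: degeneracy classes per codon position and the
# per-codon GC lookup vectors the profiling code indexes into. Built lazily
# from Biostrings::GENETIC_CODE (standard code, NCBI table 1) on first use.

.codon_env <- new.env(parent = emptyenv())

.CODON_BASES <- c("T", "C", "A", "G")
.SITE_CLASSES <- c("NS", "TWOFOLD", "FOURFOLD")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.build_codon_tables <- function() {
  gcmap <- Biostrings::GENETIC_CODE
  codons <- names(gcmap)
  aa <- unname(gcmap)
  base_m <- matrix(unlist(strsplit(codons, "", fixed = TRUE)),
                   ncol = 3, byrow = TRUE)
  n <- length(codons)

  # count, for every codon position, the alternative nucleotides whose
  # substitution preserves the encoded amino acid; substitutions creating a
  # stop codon never count as synonymous for sense codons
  nsyn <- matrix(0L, n, 3)
  for (i in seq_len(n)) {
    for (p in 1:3) {
      for (b in setdiff(.CODON_BASES, base_m[i, p])) {
        alt <- base_m[i, ]
        alt[p] <- b
        alt_aa <- unname(gcmap[[paste(alt, collapse = "")]])
        syn <- if (aa[i] == "*") alt_aa == "*" else
          (alt_aa == aa[i] && alt_aa != "*")
        if (syn) nsyn[i, p] <- nsyn[i, p] + 1L
      }
    }
  }

  # default policy: 3 synonymous alternatives -> FOURFOLD, 1-2 -> TWOFOLD
  # (three-fold third positions folded into TWOFOLD), 0 -> NS
  cls <- matrix("NS", n, 3)
  cls[nsyn >= 1L] <- "TWOFOLD"
  cls[nsyn == 3L] <- "FOURFOLD"
  cls_sep <- cls
  cls_sep[nsyn == 2L] <- "THREEFOLD"

  gc_ind <- base_m == "G" | base_m == "C"
  is_stop <- aa == "*"

  # per-codon value for each class selector: G/C indicator (0/100) averaged
  # over this codon's positions of that class; NA when the codon has no such
  # position; stop codons NA everywhere (excluded from averaging)
  val <- list(ALL = ifelse(is_stop, NA_real_, 100 * rowSums(gc_ind) / 3))
  for (k in .SITE_CLASSES) {
    nk <- rowSums(cls == k)
    gk <- rowSums((cls == k) & gc_ind)
    v <- ifelse(nk > 0L, 100 * gk / nk, NA_real_)
    v[is_stop] <- NA_real_
    val[[k]] <- v
  }

  sense <- which(!is_stop)
  Gstat <- vapply(.SITE_CLASSES,
                  function(k) rowSums((cls == k) & gc_ind)[sense],
                  numeric(length(sense)))
  Nstat <- vapply(.SITE_CLASSES,
                  function(k) rowSums(cls == k)[sense],
                  numeric(length(sense)))

  list(codons = codons, aa = aa, base_m = base_m, nsyn = nsyn,
       cls = cls, cls_sep = cls_sep, gc_ind = gc_ind, is_stop = is_stop,
       val = val, sense = sense, Gstat = Gstat, Nstat = Nstat)
}

.ct <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .build_codon_tables()
  .codon_env$tab
}

# split a nucleotide string into codons (truncates a trailing partial codon)
.codons_of <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# codon strings -> row indices into the 64-codon table (NA for N-containing)
.codon_idx <- function(codons) match(codons, .ct()$codons)

# drop an annotated terminal stop codon, if present
.strip_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && n %% 3L == 0L &&
      substr(cds, n - 2L, n) %in% .STOP_CODONS) {
    return(substr(cds, 1L, n - 3L))
  }
  cds
}

.has_internal_stop <- function(cds) {
  cod <- .codons_of(.strip_stop(cds))
  any(cod %in% .STOP_CODONS)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
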