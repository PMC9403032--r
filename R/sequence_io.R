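# Reading FASTA + GFF3 into per-gene transcript records, validity filtering,
# and pooled coding GC content.

#' Construct a genome set
#'
#' A genome set holds one representative transcript record per gene for one
#' species: the CDS and 5'-UTR in sense (translated) orientation plus
#' metadata. It is the unit every profiling function operates on.
#'
#' @param records A data frame / tibble with columns `gene_id`,
#'   `transcript_id`, `cds`, `utr5`; `cds_length_nt`, `cdna_length_nt` and
#'   `internal_stop` are filled in when absent.
#' @param species_label Free-text species label.
#' @param taxon_group Optional free-text taxonomic group label (carried
#'   through to cross-genome tables, nothing more).
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(records, species_label = "unnamed",
                       taxon_group = NA_character_) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("gene_id", "transcript_id", "cds", "utr5") %in%
                  names(records)))
  records$cds <- toupper(records$cds)
  records$utr5 <- toupper(records$utr5)
  records$cds_length_nt <- nchar(records$cds)
  if (!"cdna_length_nt" %in% names(records)) {
    records$cdna_length_nt <- nchar(records$utr5) + records$cds_length_nt
  }
  if (!"internal_stop" %in% names(records)) {
    records$internal_stop <- vapply(records$cds, .has_internal_stop,
                                    logical(1), USE.NAMES = FALSE)
  }
  structure(list(species_label = species_label, taxon_group = taxon_group,
                 records = records),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %s: %d gene(s)", x$species_label,
              nrow(x$records)))
  if (!is.na(x$taxon_group)) cat(sprintf(" [%s]", x$taxon_group))
  cat("\n")
  rep_ <- attr(x, "filter_report")
  if (!is.null(rep_)) {
    cat(sprintf("  filtered: %d record(s) removed\n", nrow(rep_)))
  }
  invisible(x)
}

# minimal GFF3 attribute accessor: value of `key=` in column 9
.gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]*"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- lengths(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key,
                                                   "=[^;]*"), attrs))) > 0
  out[hit] <- sub(paste0("^.*", key, "="), "", m)
  out
}

.strip_id_prefix <- function(x) sub("^(transcript|gene|cds):", "", x)

# validate GFF3 feature lines so parse failures carry a line number
.check_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  feat <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in feat) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L ||
        is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("unparseable GFF3 line ", i, " in ", path, ": ",
           substr(lines[i], 1, 60))
    }
  }
  invisible(TRUE)
}

# extract and orient the concatenated slices of one feature group
.assemble_feature <- function(seq, starts, ends, strand) {
  o <- order(starts)
  parts <- substring(seq, starts[o], ends[o])
  s <- paste(parts, collapse = "")
  if (identical(strand, "-")) s <- .revcomp(s)
  s
}

#' Load one representative transcript per gene from FASTA + GFF3
#'
#' Reads transcript (cDNA) sequences from FASTA and `CDS` /
#' `five_prime_UTR` features from GFF3 (1-based inclusive coordinates,
#' features grouped by `Parent`), assembles each transcript's CDS and 5'-UTR
#' in sense orientation (minus-strand features are reverse-complemented),
#' and keeps, per gene, the transcript with the longest cDNA (ties broken by
#' lexicographically smallest transcript id).
#'
#' Transcripts present in the GFF3 but missing from the FASTA are skipped,
#' counted and reported via a message (count also attached as attribute
#' `n_skipped`). Unparseable GFF3 lines raise an error naming the line.
#'
#' @param fasta_path Path to a (multi-)FASTA of transcript sequences whose
#'   identifiers match the GFF3 `seqid` column.
#' @param gff_path Path to the GFF3 annotation.
#' @param species_label Species label stored in the result.
#' @param taxon_group Optional group label carried through.
#' @return A [genome_set()].
#' @export
load_transcripts <- function(fasta_path, gff_path,
                             species_label = basename(fasta_path),
                             taxon_group = NA_character_) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  .check_gff3(gff_path)
  gff <- ape::read.gff(gff_path, GFF3 = TRUE)
  gff$type <- as.character(gff$type)
  gff$seqid <- as.character(gff$seqid)
  gff$strand <- as.character(gff$strand)

  # transcript -> gene map from mRNA/transcript features, if present
  tx_feats <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx2gene <- setNames(
    .strip_id_prefix(.gff_attr(tx_feats$attributes, "Parent")),
    .strip_id_prefix(.gff_attr(tx_feats$attributes, "ID"))
  )

  cds_feats <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds_feats) == 0L) stop("no CDS features in ", gff_path)
  utr_feats <- gff[gff$type == "five_prime_UTR", , drop = FALSE]
  cds_parent <- .strip_id_prefix(.gff_attr(cds_feats$attributes, "Parent"))
  utr_parent <- .strip_id_prefix(.gff_attr(utr_feats$attributes, "Parent"))

  tids <- unique(cds_parent)
  n_skipped <- 0L
  rows <- vector("list", length(tids))
  for (k in seq_along(tids)) {
    tid <- tids[k]
    cf <- cds_feats[cds_parent == tid, , drop = FALSE]
    sid <- cf$seqid[1L]
    if (!sid %in% names(seqs)) {
      n_skipped <- n_skipped + 1L
      next
    }
    seq <- as.character(seqs[[sid]])
    strand <- cf$strand[1L]
    cds <- .assemble_feature(seq, cf$start, cf$end, strand)
    uf <- utr_feats[utr_parent == tid, , drop = FALSE]
    utr5 <- if (nrow(uf) > 0L) {
      .assemble_feature(seq, uf$start, uf$end, strand)
    } else ""
    gid <- unname(tx2gene[tid])
    if (length(gid) == 0L || is.na(gid)) gid <- tid
    rows[[k]] <- tibble::tibble(
      gene_id = gid, transcript_id = tid, cds = cds, utr5 = utr5,
      cdna_length_nt = nchar(seq)
    )
  }
  if (n_skipped > 0L) {
    message(n_skipped, " transcript(s) in GFF3 absent from FASTA; skipped")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no transcripts could be assembled")
  rec <- do.call(rbind, rows)

  # one transcript per gene: longest cDNA, ties by smallest transcript_id
  rec <- rec[order(rec$gene_id, -rec$cdna_length_nt, rec$transcript_id), ]
  rec <- rec[!duplicated(rec$gene_id), ]

  out <- genome_set(rec, species_label = species_label,
                    taxon_group = taxon_group)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter a genome set down to analysis-valid records
#'
#' A record is valid when its annotated CDS (terminal stop included) is at
#' least `min_cds_len` nucleotides, a multiple of 3, and (by default) starts
#' with `ATG`. Records with internal stop codons are retained but flagged in
#' the `internal_stop` column. Removal reasons are attached as attribute
#' `filter_report` (a tibble `gene_id`, `reason`) and summarised in a
#' message.
#'
#' @param genome A [genome_set()].
#' @param min_cds_len Minimum CDS length in nucleotides (default 900).
#' @param require_start_codon Drop records whose CDS does not begin with
#'   `ATG` (default `TRUE`).
#' @return A filtered [genome_set()] (idempotent).
#' @export
filter_valid <- function(genome, min_cds_len = 900,
                         require_start_codon = TRUE) {
  stopifnot(inherits(genome, "genome_set"))
  rec <- genome$records
  reasons <- character(nrow(rec))
  add <- function(reasons, bad, why) {
    ifelse(bad, ifelse(nzchar(reasons), paste(reasons, why, sep = ";"), why),
           reasons)
  }
  reasons <- add(reasons, rec$cds_length_nt < min_cds_len, "too_short")
  reasons <- add(reasons, rec$cds_length_nt %% 3L != 0L,
                 "not_multiple_of_3")
  if (require_start_codon) {
    reasons <- add(reasons, substr(rec$cds, 1L, 3L) != "ATG",
                   "no_start_codon")
  }
  keep <- !nzchar(reasons)
  report <- tibble::tibble(gene_id = rec$gene_id[!keep],
                           reason = reasons[!keep])
  out <- genome_set(rec[keep, , drop = FALSE],
                    species_label = genome$species_label,
                    taxon_group = genome$taxon_group)
  attr(out, "filter_report") <- report
  if (nrow(report) > 0L) {
    message("filter_valid: removed ", nrow(report), " of ", nrow(rec),
            " record(s)")
  }
  if (sum(keep) == 0L) warning("no valid records remain after filtering")
  out
}

#' Write the record-removal report of a filtered genome set as TSV
#'
#' @param genome A [genome_set()] produced by [filter_valid()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_filter_report <- function(genome, path) {
  report <- attr(genome, "filter_report")
  if (is.null(report)) {
    report <- tibble::tibble(gene_id = character(0), reason = character(0))
  }
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Pooled coding GC content of a genome set
#'
#' G+C over A+C+G+T across all CDS nucleotides of all records, as a
#' percentage; `N` characters are excluded from numerator and denominator.
#'
#' @param genome A [genome_set()] with at least one record.
#' @return GC percentage in `[0, 100]`.
#' @export
coding_gc <- function(genome) {
  stopifnot(inherits(genome, "genome_set"))
  if (nrow(genome$records) == 0L) stop("genome set has no records")
  s <- Biostrings::DNAStringSet(genome$records$cds)
  counts <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  tot <- sum(counts)
  if (tot == 0L) stop("no countable (non-N) nucleotides")
  100 * sum(counts[, c("C", "G")]) / tot
}
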