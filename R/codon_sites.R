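#' Classify the three positions of a codon by degeneracy
#'
#' Each position of a sense codon is classified by the number of alternative
#' nucleotides whose substitution leaves the encoded amino acid unchanged:
#' 3 synonymous alternatives give a four-fold degenerate site (`"FOURFOLD"`),
#' 1 or 2 give a two-fold site (`"TWOFOLD"`; three-fold third positions such
#' as isoleucine's are folded into `"TWOFOLD"` under the default policy), and
#' 0 give a nonsynonymous site (`"NS"`). Substitutions that create a stop
#' codon count as nonsynonymous.
#'
#' @param codon A 3-letter string over `A`, `C`, `G`, `T` (case-insensitive).
#'   Codons containing `N` return an all-unclassified marker (`NA` classes).
#' @param threefold `"twofold"` (default) folds three-fold degenerate sites
#'   into `"TWOFOLD"`; `"separate"` reports them as `"THREEFOLD"`.
#' @return An object of class `site_classification`: a list with `codon`,
#'   `amino_acid` (1-letter code, `"*"` for stop), `classes` (character
#'   vector of length 3), and `is_stop`.
#' @examples
#' classify_codon("GCA")$classes  # alanine: NS NS FOURFOLD
#' classify_codon("TTA")$classes  # leucine: TWOFOLD NS TWOFOLD
#' @export
classify_codon <- function(codon, threefold = c("twofold", "separate")) {
  threefold <- match.arg(threefold)
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L) {
    stop("codon must be exactly 3 nucleotides, got '", codon, "'")
  }
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c(.CODON_BASES, "N"))) {
    stop("codon must be over {A,C,G,T,N}, got '", codon, "'")
  }
  tab <- .ct()
  if (any(chars == "N")) {
    out <- list(codon = codon, amino_acid = NA_character_,
                classes = rep(NA_character_, 3L), is_stop = FALSE)
    return(structure(out, class = "site_classification"))
  }
  i <- match(codon, tab$codons)
  cls <- if (threefold == "twofold") tab$cls[i, ] else tab$cls_sep[i, ]
  structure(list(codon = codon, amino_acid = tab$aa[i],
                 classes = unname(cls), is_stop = tab$is_stop[i]),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  aa <- if (isTRUE(x$is_stop)) "STOP" else x$amino_acid
  cat(sprintf("codon %s (%s): %s\n", x$codon, aa,
              paste(x$classes, collapse = " / ")))
  invisible(x)
}

#' Site-class counts over the 61 sense codons
#'
#' Counts the 183 codon-site slots (61 sense codons x 3 positions) per
#' degeneracy class. Under the default policy this gives 116 nonsynonymous,
#' 35 two-fold and 32 four-fold slots, i.e. ~60% of codon sites are
#' nonsynonymous.
#'
#' @inheritParams classify_codon
#' @return Named integer vector of slot counts summing to 183.
#' @export
site_class_counts <- function(threefold = c("twofold", "separate")) {
  threefold <- match.arg(threefold)
  tab <- .ct()
  cls <- if (threefold == "twofold") tab$cls else tab$cls_sep
  cls <- cls[!tab$is_stop, , drop = FALSE]
  lev <- if (threefold == "twofold") .SITE_CLASSES else
    c("NS", "TWOFOLD", "THREEFOLD", "FOURFOLD")
  out <- vapply(lev, function(k) sum(cls == k), integer(1))
  stopifnot(sum(out) == 183L)
  out
}

#' Full 64-codon classification table
#'
#' One row per codon with the encoded amino acid and the degeneracy class of
#' each position; intended for audit/export.
#'
#' @inheritParams classify_codon
#' @return A tibble with columns `codon`, `amino_acid`, `pos1`, `pos2`,
#'   `pos3`, `is_stop`.
#' @export
site_class_table <- function(threefold = c("twofold", "separate")) {
  threefold <- match.arg(threefold)
  tab <- .ct()
  cls <- if (threefold == "twofold") tab$cls else tab$cls_sep
  tibble::tibble(codon = tab$codons, amino_acid = tab$aa,
                 pos1 = cls[, 1], pos2 = cls[, 2], pos3 = cls[, 3],
                 is_stop = tab$is_stop)
}

#' Write the 64-codon classification table as TSV
#'
#' @param path Output file path.
#' @inheritParams classify_codon
#' @return The path, invisibly.
#' @export
write_site_class_table <- function(path, threefold = c("twofold", "separate")) {
  tab <- site_class_table(threefold)
  write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Amino-acid property sets used for masking
#'
#' The nine dietarily essential amino acids (phenylalanine, valine,
#' threonine, tryptophan, methionine, leucine, isoleucine, lysine,
#' histidine), the positively charged residues, and proline. The charged set
#' and proline are the residues associated with ribosome pausing/stalling
#' near the start codon; masking them tests whether their avoidance drives
#' positional GC patterns.
#'
#' @return Named list of character vectors of 1-letter codes:
#'   `essential`, `positively_charged`, `proline`.
#' @export
aa_masks <- function() {
  list(
    essential = c("F", "V", "T", "W", "M", "L", "I", "K", "H"),
    positively_charged = c("K", "R", "H"),
    proline = "P"
  )
}

#' Keep/drop flags for codons encoding excluded amino acids
#'
#' Produces one logical flag per coding codon (`TRUE` = keep). Dropped codons
#' are skipped in positional averaging but positions are not renumbered.
#'
#' @param record A transcript record (list/row with a `cds` field) or a CDS
#'   nucleotide string; an annotated terminal stop codon is stripped first.
#' @param exclude_aas Character vector of 1-letter amino-acid codes to drop;
#'   empty set keeps everything.
#' @return Logical vector, one element per coding codon.
#' @export
mask_codons <- function(record, exclude_aas = character(0)) {
  cds <- if (is.character(record)) record else record$cds
  stopifnot(is.character(cds), length(cds) == 1L)
  valid_codes <- setdiff(unique(.ct()$aa), "*")
  bad <- setdiff(exclude_aas, valid_codes)
  if (length(bad) > 0) {
    stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  }
  cod <- .codons_of(.strip_stop(toupper(cds)))
  aa <- .ct()$aa[.codon_idx(cod)]
  keep <- !(aa %in% exclude_aas)
  # N-containing codons (NA amino acid) are kept here; they drop out of
  # averages downstream because their GC value is undefined
  keep[is.na(aa)] <- TRUE
  keep
}
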