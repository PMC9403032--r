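# Sliding-window minimum-free-energy analysis around the start codon, with a
# pluggable folding engine. The default window is 39 nt: one codon at the
# centre plus 18 nt flanking on each side, advancing 3 nt per codon; windows
# extending upstream of the CDS are filled from the 3' end of the 5'-UTR.

#' Bundled base-pair-maximisation folding surrogate
#'
#' A Nussinov-style dynamic program over nested pairings that minimises a
#' summed pair score (GC = -3, AU = -2, GU wobble = -1; minimum hairpin loop
#' of 3 unpaired nucleotides; N never pairs). Values are on a kcal/mol-like
#' scale (always <= 0) and are deterministic, but they are not thermodynamic
#' free energies: use them only comparatively (between positions or gene
#' bins), which is how every analysis in this package uses folding scores.
#'
#' @param seq Character vector of nucleotide strings over `A`, `C`, `G`,
#'   `U`/`T`, `N` (T is read as U).
#' @param min_loop Minimum number of unpaired nucleotides in a hairpin loop.
#' @return Numeric vector of optimal total pair scores (<= 0).
#' @examples
#' bundled_fold("AAAAAAAAA")   # 0: nothing can pair
#' bundled_fold("GGGAAAACCC")  # -9: three GC pairs
#' @export
bundled_fold <- function(seq, min_loop = 3) {
  stopifnot(is.character(seq))
  bad <- grepl("[^ACGTUN]", toupper(seq))
  if (any(bad)) stop("sequence contains characters outside {A,C,G,T,U,N}")
  .nussinov_mfe(toupper(seq), as.integer(min_loop))
}

#' Folding engines
#'
#' A folding engine wraps a deterministic function mapping nucleotide
#' strings (T read as U) to a minimum free energy in kcal/mol (<= 0; 0 for
#' sequences that cannot pair). `bundled_engine()` uses [bundled_fold()];
#' `vienna_engine()` shells out to the `RNAfold` executable with default
#' parameters when it is on the `PATH`; `default_engine()` picks the
#' thermodynamic engine when available and the bundled surrogate otherwise.
#'
#' @param min_loop Minimum hairpin-loop size for the bundled engine.
#' @return Object of class `folding_engine`: list with `name` and `fold`
#'   (a vectorised function `character -> numeric`).
#' @export
bundled_engine <- function(min_loop = 3) {
  structure(list(name = "bundled_nussinov",
                 fold = function(seqs) bundled_fold(seqs, min_loop)),
            class = "folding_engine")
}

#' @rdname bundled_engine
#' @export
vienna_engine <- function() {
  if (!nzchar(Sys.which("RNAfold"))) {
    stop("RNAfold executable not found on PATH")
  }
  fold <- function(seqs) {
    seqs <- chartr("Tt", "Uu", toupper(seqs))
    out <- system2("RNAfold", args = c("--noPS"), input = seqs,
                   stdout = TRUE)
    mfe_lines <- grep("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
    if (length(mfe_lines) != length(seqs)) {
      stop("RNAfold returned ", length(mfe_lines), " results for ",
           length(seqs), " sequences")
    }
    as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", mfe_lines))
  }
  structure(list(name = "viennarna_rnafold", fold = fold),
            class = "folding_engine")
}

#' @rdname bundled_engine
#' @export
default_engine <- function() {
  if (nzchar(Sys.which("RNAfold"))) vienna_engine() else bundled_engine()
}

#' @export
print.folding_engine <- function(x, ...) {
  cat(sprintf("<folding_engine> %s\n", x$name))
  invisible(x)
}

#' Folding window centred on one codon
#'
#' The window spans the codon (3 nt) plus `flank_nt` on each side in
#' transcript coordinates (39 nt for the default 18-nt flanks). Upstream
#' overhang beyond the CDS start is filled from the 3' end of the 5'-UTR;
#' when the UTR is too short the window is truncated at the transcript
#' 5' end and the truncation recorded.
#'
#' @param record A transcript record (list/row with `cds` and `utr5`).
#' @param codon_index 1-based codon index within the coding sequence.
#' @param flank_nt Flank length on each side, default 18.
#' @return List with `seq` (DNA string), `actual_len`, `used_utr_nt`,
#'   `truncated`.
#' @export
window_for_codon <- function(record, codon_index, flank_nt = 18) {
  flank_nt <- as.integer(flank_nt)
  codon_index <- as.integer(codon_index)
  cds <- .strip_stop(toupper(record$cds))
  utr5 <- toupper(if (is.null(record$utr5)) "" else record$utr5)
  n_codons <- nchar(cds) %/% 3L
  if (codon_index < 1L || codon_index > n_codons) {
    stop("codon_index ", codon_index, " outside CDS (", n_codons,
         " codons)")
  }
  from <- 3L * (codon_index - 1L) + 1L - flank_nt
  to <- min(3L * (codon_index - 1L) + 3L + flank_nt, nchar(cds))
  used_utr <- 0L
  left <- ""
  if (from < 1L) {
    need <- 1L - from
    used_utr <- min(need, nchar(utr5))
    if (used_utr > 0L) {
      left <- substr(utr5, nchar(utr5) - used_utr + 1L, nchar(utr5))
    }
    from <- 1L
  }
  seq <- paste0(left, substr(cds, from, to))
  nominal <- 2L * flank_nt + 3L
  list(seq = seq, actual_len = nchar(seq), used_utr_nt = used_utr,
       truncated = nchar(seq) < nominal)
}

#' Sliding-window MFE track for one transcript
#'
#' One folding value per codon centre from codon 1 to `max_codon`
#' (consecutive windows advance by exactly 3 nt). T is transliterated to U
#' before folding.
#'
#' @inheritParams window_for_codon
#' @param engine A `folding_engine`; default [default_engine()].
#' @param max_codon Last codon centre (default 100; capped at CDS length).
#' @return A tibble with columns `gene_id`, `codon_center`, `mfe`,
#'   `actual_len`, `used_utr_nt`, `truncated`; attribute `window_len_nt`.
#' @export
mfe_track <- function(record, engine = default_engine(), max_codon = 100,
                      flank_nt = 18) {
  stopifnot(inherits(engine, "folding_engine"))
  flank_nt <- as.integer(flank_nt)
  n_codons <- nchar(.strip_stop(toupper(record$cds))) %/% 3L
  centers <- seq_len(min(max_codon, n_codons))
  wins <- lapply(centers, function(ci) window_for_codon(record, ci, flank_nt))
  seqs <- vapply(wins, `[[`, character(1), "seq")
  mfe <- tryCatch(engine$fold(seqs), error = function(e) {
    message("folding engine failed (", conditionMessage(e),
            "); values set to NA")
    rep(NA_real_, length(seqs))
  })
  gene_id <- if (!is.null(record$gene_id)) record$gene_id else NA_character_
  out <- tibble::tibble(
    gene_id = gene_id, codon_center = centers, mfe = mfe,
    actual_len = vapply(wins, `[[`, integer(1), "actual_len"),
    used_utr_nt = vapply(wins, `[[`, integer(1), "used_utr_nt"),
    truncated = vapply(wins, `[[`, logical(1), "truncated")
  )
  attr(out, "window_len_nt") <- 2L * flank_nt + 3L
  out
}

#' Mean MFE per codon centre, optionally per gene bin
#'
#' Averages window MFE values across genes at each codon centre; when
#' `gene_bins` is supplied (e.g. expression bins), means are computed per
#' bin and genes without a bin are excluded. Truncated 5' windows are
#' excluded by default.
#'
#' @param tracks A tibble of row-bound [mfe_track()] results (or a list of
#'   them).
#' @param gene_bins Optional named vector or `expression_bins` tibble
#'   mapping `gene_id` to bin.
#' @param include_truncated Include truncated windows in means
#'   (default `FALSE`).
#' @return A tibble with columns `codon_center`, `bin`, `mean_mfe`,
#'   `n_genes`.
#' @export
mean_mfe_by_position <- function(tracks, gene_bins = NULL,
                                 include_truncated = FALSE) {
  if (is.list(tracks) && !is.data.frame(tracks)) {
    tracks <- do.call(rbind, tracks)
  }
  stopifnot(nrow(tracks) > 0L)
  d <- tracks
  if (!include_truncated) d <- d[!d$truncated, , drop = FALSE]
  d <- d[!is.na(d$mfe), , drop = FALSE]
  if (!is.null(gene_bins)) {
    if (is.data.frame(gene_bins)) {
      gene_bins <- setNames(gene_bins$bin, gene_bins$gene_id)
    }
    d$bin <- unname(gene_bins[d$gene_id])
    n_unbinned <- sum(is.na(d$bin))
    if (n_unbinned > 0L) {
      message("excluding ", n_unbinned, " window(s) from unbinned gene(s)")
    }
    d <- d[!is.na(d$bin), , drop = FALSE]
  } else {
    d$bin <- 1L
  }
  if (nrow(d) == 0L) stop("no windows left to average")
  agg <- aggregate(mfe ~ codon_center + bin, data = d, FUN = mean)
  cnt <- aggregate(mfe ~ codon_center + bin, data = d, FUN = length)
  out <- tibble::tibble(codon_center = agg$codon_center, bin = agg$bin,
                        mean_mfe = agg$mfe, n_genes = as.integer(cnt$mfe))
  out[order(out$bin, out$codon_center), ]
}
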