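# Expression abundances and equal-sized rank bins (bin 1 lowest to
# bin n_bins highest).

#' Load a gene-expression table
#'
#' Reads a two-column TSV (`gene_id`, abundance); a header line is detected
#' automatically. Duplicate gene ids and non-numeric abundances are errors
#' (the latter reported with the offending line number).
#'
#' @param tsv_path Path to the TSV.
#' @return Named numeric vector of abundances.
#' @export
load_expression <- function(tsv_path) {
  lines <- readLines(tsv_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty expression table: ", tsv_path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("expression table line ", which(lengths(fields) < 2L)[1L],
         " has fewer than 2 tab-separated fields")
  }
  first_val <- suppressWarnings(as.numeric(fields[[1L]][2L]))
  has_header <- is.na(first_val)
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("expression table has a header but no data")
  ids <- vapply(fields[start:length(fields)], `[[`, character(1), 1L)
  vals <- suppressWarnings(
    as.numeric(vapply(fields[start:length(fields)], `[[`, character(1), 2L)))
  if (anyNA(vals)) {
    stop("non-numeric abundance on line ", which(is.na(vals))[1L] + start - 1L,
         " of ", tsv_path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in expression table: ",
         ids[duplicated(ids)][1L])
  }
  setNames(vals, ids)
}

#' Assign genes to equal-sized expression bins
#'
#' Genes are sorted by abundance ascending (ties broken by gene id) and
#' split into `n_bins` contiguous rank blocks, bin 1 lowest to bin `n_bins`
#' highest; when sizes cannot be equal, earlier (lower) bins take the extra
#' gene. Zero-abundance genes are retained in the lowest bin.
#'
#' @param abundances Named numeric vector (names = gene ids).
#' @param n_bins Number of bins (default 4); must not exceed the number of
#'   genes.
#' @return A tibble of class `expression_bins` with columns `gene_id`,
#'   `abundance`, `bin`; attribute `n_bins`.
#' @export
bin_by_expression <- function(abundances, n_bins = 4) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)))
  n <- length(abundances)
  n_bins <- as.integer(n_bins)
  if (n < n_bins) {
    stop("need at least ", n_bins, " genes for ", n_bins, " bins, have ", n)
  }
  o <- order(abundances, names(abundances))
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins_sorted <- rep(seq_len(n_bins), times = sizes)
  out <- tibble::tibble(
    gene_id = names(abundances)[o],
    abundance = unname(abundances[o]),
    bin = bins_sorted
  )
  class(out) <- c("expression_bins", class(out))
  attr(out, "n_bins") <- n_bins
  out
}

#' Write expression-bin assignments as TSV
#'
#' @param bins An `expression_bins` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bins_tsv <- function(bins, path) {
  write.table(as.data.frame(bins)[, c("gene_id", "bin")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
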