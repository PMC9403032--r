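# Amino-acid biosynthetic-cost profiles along the CDS, the cost-gradient
# slope, and the saved-ATP statistic.

#' Load amino-acid and nucleotide cost tables
#'
#' Costs are configuration data in ATP equivalents (high-energy phosphate
#' bonds). The bundled amino-acid table carries the Akashi-type aerobic
#' de novo synthesis costs; the bundled nucleotide table is a constructed
#' stand-in (see `nt_costs_synthetic.tsv`) that preserves the defining
#' ordering — G and C more expensive than A and T — and is carried as
#' metadata only: no computation in this package consumes nucleotide costs.
#' Either file can be replaced by a user TSV with the same columns.
#'
#' @param aa_path TSV with columns `aa` (1-letter code) and `cost`;
#'   default = bundled Akashi-type table. All 20 amino acids are required.
#' @param nt_path TSV with columns `nt` and `cost`; default = bundled
#'   synthetic stand-in.
#' @param source_label Free-text provenance label.
#' @return Object of class `cost_table`: list with named numeric vectors
#'   `aa_cost` (length 20) and `nt_cost` (length 4), and `source_label`.
#' @export
load_cost_table <- function(aa_path = NULL, nt_path = NULL,
                            source_label = "bundled") {
  if (is.null(aa_path)) {
    aa_path <- system.file("extdata", "aa_costs_akashi.tsv",
                           package = "gcgradient", mustWork = TRUE)
  }
  if (is.null(nt_path)) {
    nt_path <- system.file("extdata", "nt_costs_synthetic.tsv",
                           package = "gcgradient", mustWork = TRUE)
  }
  aa <- read.delim(aa_path, stringsAsFactors = FALSE)
  nt <- read.delim(nt_path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "cost") %in% names(aa)),
            all(c("nt", "cost") %in% names(nt)))
  aa_cost <- setNames(as.numeric(aa$cost), toupper(aa$aa))
  nt_cost <- setNames(as.numeric(nt$cost), toupper(nt$nt))
  need <- setdiff(setdiff(unique(.ct()$aa), "*"), names(aa_cost))
  if (length(need) > 0L) {
    stop("amino acid(s) missing from cost table: ",
         paste(need, collapse = ", "))
  }
  if (any(aa_cost <= 0) || any(nt_cost <= 0)) stop("costs must be > 0")
  structure(list(aa_cost = aa_cost, nt_cost = nt_cost,
                 source_label = source_label), class = "cost_table")
}

#' @rdname load_cost_table
#' @export
default_cost_table <- function() load_cost_table()

#' Positional mean amino-acid cost profile
#'
#' For every codon position of the chosen fragment, averages the
#' biosynthetic cost of the encoded amino acid across genes. Stop codons and
#' N-containing codons are skipped.
#'
#' @inheritParams positional_mean
#' @param costs A `cost_table` (default = bundled table).
#' @return A `positional_profile` tibble in cost units
#'   (attribute `value_type = "cost"`, `site_class = "ALL"`).
#' @export
positional_cost <- function(genome, costs = default_cost_table(),
                            fragment = c("START", "MIDDLE", "END"),
                            length_codons = 100) {
  fragment <- match.arg(fragment)
  stopifnot(inherits(genome, "genome_set"), inherits(costs, "cost_table"))
  if (nrow(genome$records) == 0L) stop("genome set has no records")
  m <- .fragment_matrix(genome, fragment, length_codons)
  aa <- matrix(.ct()$aa[m], nrow = nrow(m))
  aa[aa == "*"] <- NA_character_
  vals <- matrix(unname(costs$aa_cost[aa]), nrow = nrow(m))
  .profile_from_values(vals, "ALL", fragment, "cost")
}

#' Fit the positional cost gradient
#'
#' OLS of per-position mean amino-acid cost on the raw codon position over
#' `fit_range`. Unlike [fit_gradient()], the slope is reported on the raw
#' per-codon scale (cost units per codon position): a positive slope means
#' cheaper amino acids are preferentially used toward the start codon.
#'
#' @param profile A `positional_profile` from [positional_cost()].
#' @param fit_range Inclusive codon interval, default `c(26, 100)`.
#' @return Object of class `cost_gradient_fit`: `slope_per_codon`,
#'   `intercept`, `r_squared`, `fit_range`, `n_points`.
#' @export
fit_cost_gradient <- function(profile, fit_range = c(26, 100)) {
  d <- .fit_points(profile, fit_range)
  m <- lm(mean_value ~ position, data = d)
  structure(list(
    slope_per_codon = unname(coef(m)[2L]),
    intercept = unname(coef(m)[1L]),
    r_squared = .r_squared(m, d$mean_value),
    fit_range = as.integer(fit_range),
    n_points = nrow(d)
  ), class = "cost_gradient_fit")
}

#' @export
print.cost_gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<cost_gradient_fit> slope = %+.5f cost units per codon (R2 %s, codons %d-%d)\n",
    x$slope_per_codon,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' ATP equivalents saved per protein by the positional cost gradient
#'
#' Evaluates `slope x n/2 x 100`: the average energy saved per protein over
#' the first 100 codons, relative to a flat cost profile, given the fitted
#' per-codon cost slope and the number of codon positions `n` used in the
#' regression (75 for the default 26-100 fit range).
#'
#' @param slope_per_codon Fitted cost slope, cost units per codon.
#' @param n Number of codons used in the regression (> 0); default 75.
#' @return ATP equivalents per protein.
#' @examples
#' saved_atp(0.0082, 75)  # 30.75
#' @export
saved_atp <- function(slope_per_codon, n = 75) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be a positive number of codons")
  }
  slope_per_codon * n / 2 * 100
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("<cost_table> [%s] 20 amino acids (%.1f-%.1f ~P), 4 nucleotides\n",
              x$source_label, min(x$aa_cost), max(x$aa_cost)))
  invisible(x)
}
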