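# End-to-end orchestration: per-genome profiling, cross-genome comparison,
# and expression-stratified MFE scans, with serialisable run configuration.

#' Run configuration for the pipeline entry points
#'
#' Collects the tunable parameters shared by [run_profile()],
#' [run_compare()] and [run_mfe()] so a run can be reproduced from its
#' serialized configuration (see [write_run_config()]).
#'
#' @param min_cds_len Minimum annotated CDS length in nt (default 900).
#' @param length_codons Fragment length in codons (default 100).
#' @param fit_range Gradient fit interval, inclusive codons
#'   (default `c(26, 100)`).
#' @param n_bins Expression bins (default 4).
#' @param flank_nt MFE window flank (default 18, i.e. 39-nt windows).
#' @param engine Folding engine name, `"bundled"` or `"vienna"`.
#' @param seed Integer seed recorded for provenance.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(min_cds_len = 900, length_codons = 100,
                       fit_range = c(26, 100), n_bins = 4, flank_nt = 18,
                       engine = c("bundled", "vienna"), seed = 1) {
  engine <- match.arg(engine)
  structure(list(min_cds_len = min_cds_len,
                 length_codons = as.integer(length_codons),
                 fit_range = as.integer(fit_range),
                 n_bins = as.integer(n_bins),
                 flank_nt = as.integer(flank_nt), engine = engine,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize a run configuration into an output directory
#'
#' @param config A [run_config()].
#' @param out_dir Directory (created if missing).
#' @return The JSON path, invisibly.
#' @export
write_run_config <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "run_config.json")
  x <- config
  class(x) <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.engine_from_config <- function(config) {
  if (identical(config$engine, "vienna")) vienna_engine() else
    bundled_engine()
}

#' Per-genome GC profiles and gradient fits
#'
#' Filters the genome, computes positional GC profiles for every site class
#' (`ALL`, `NS`, `TWOFOLD`, `FOURFOLD`) x fragment (`START`, `MIDDLE`,
#' `END`) and fits the gradient slope to each, logging gene counts at each
#' stage.
#'
#' @param genome A [genome_set()] (filtered internally with
#'   `config$min_cds_len`).
#' @param config A [run_config()].
#' @param exclude_aas Optional amino acids to mask from averaging.
#' @return List of class `profile_run`: `profiles` (row-bound
#'   `positional_profile` tibble), `fits` (tibble with one row per site
#'   class x fragment), `genome` (the filtered set), `config`.
#' @export
run_profile <- function(genome, config = run_config(),
                        exclude_aas = NULL) {
  stopifnot(inherits(genome, "genome_set"), inherits(config, "run_config"))
  n0 <- nrow(genome$records)
  valid <- filter_valid(genome, min_cds_len = config$min_cds_len)
  message("run_profile[", genome$species_label, "]: ", n0, " -> ",
          nrow(valid$records), " valid gene(s)")
  classes <- c("ALL", "NS", "TWOFOLD", "FOURFOLD")
  profiles <- list()
  fits <- list()
  for (fr in .FRAGMENTS) {
    for (cl in classes) {
      prof <- positional_mean(valid, fragment = fr, site_class = cl,
                              exclude_aas = exclude_aas,
                              length_codons = config$length_codons)
      fit <- fit_gradient(prof, fit_range = config$fit_range)
      profiles[[paste(fr, cl)]] <- prof
      fits[[paste(fr, cl)]] <- tibble::tibble(
        species = valid$species_label, site_class = cl, fragment = fr,
        slope_per100 = fit$slope_per100, intercept = fit$intercept,
        r_squared = fit$r_squared, n_points = fit$n_points)
    }
  }
  profiles_tbl <- do.call(rbind, profiles)
  attr(profiles_tbl, "value_type") <- "gc_percent"
  structure(list(profiles = profiles_tbl, fits = do.call(rbind, fits),
                 genome = valid, config = config),
            class = "profile_run")
}

#' Write the slope table of a profile run as TSV
#'
#' @param run A `profile_run`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_slope_tsv <- function(run, path) {
  write.table(as.data.frame(run$fits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Cross-genome comparison of gradient slopes
#'
#' Builds one row per genome (species, group, pooled coding GC, start-
#' fragment slope per site class) and regresses the chosen site class's
#' slope on coding GC within each group with at least 3 genomes (smaller
#' groups are skipped with a warning).
#'
#' @param genomes List of [genome_set()] objects (2 or more).
#' @param config A [run_config()].
#' @param site_class Site class whose slope is regressed (default `"NS"`).
#' @return List of class `compare_run`: `table` (per-genome tibble),
#'   `regressions` (named list of `cross_genome_fit` per group), `config`.
#' @export
run_compare <- function(genomes, config = run_config(),
                        site_class = "NS") {
  stopifnot(is.list(genomes), length(genomes) >= 2L)
  rows <- lapply(genomes, function(g) {
    valid <- filter_valid(g, min_cds_len = config$min_cds_len)
    run <- run_profile(valid, config)
    start_fits <- run$fits[run$fits$fragment == "START", ]
    slopes <- setNames(start_fits$slope_per100, start_fits$site_class)
    tibble::tibble(
      species = g$species_label,
      group = g$taxon_group,
      coding_gc_percent = coding_gc(valid),
      slope_all = slopes[["ALL"]], slope_ns = slopes[["NS"]],
      slope_2s = slopes[["TWOFOLD"]], slope_4s = slopes[["FOURFOLD"]])
  })
  tbl <- do.call(rbind, rows)
  col <- c(ALL = "slope_all", NS = "slope_ns", TWOFOLD = "slope_2s",
           FOURFOLD = "slope_4s")[[site_class]]
  grp <- ifelse(is.na(tbl$group), "ungrouped", tbl$group)
  regressions <- list()
  for (g in unique(grp)) {
    sub <- tbl[grp == g, ]
    if (nrow(sub) < 3L) {
      warning("group '", g, "' has ", nrow(sub),
              " genome(s); regression skipped")
      next
    }
    d <- data.frame(coding_gc_percent = sub$coding_gc_percent,
                    slope_per100 = sub[[col]])
    regressions[[g]] <- cross_genome_regression(d, group_label = g)
  }
  structure(list(table = tbl, regressions = regressions, config = config),
            class = "compare_run")
}

#' Expression-stratified MFE scan around start codons
#'
#' Computes sliding-window folding tracks for every valid gene and averages
#' them per codon centre within expression bins.
#'
#' @param genome A [genome_set()].
#' @param abundances Optional named abundance vector (see
#'   [load_expression()]); when supplied, genes are ranked into
#'   `config$n_bins` bins and genes without an abundance are excluded from
#'   the stratified summary. `NULL` = single bin over all genes.
#' @param config A [run_config()].
#' @param max_codon Last codon centre scanned (default 100).
#' @param include_truncated Include 5'-truncated windows in means.
#' @return List of class `mfe_run`: `summary` (tibble `codon_center`,
#'   `bin`, `mean_mfe`, `n_genes`), `tracks` (row-bound window tibble),
#'   `bins` (or `NULL`), `config`.
#' @export
run_mfe <- function(genome, abundances = NULL, config = run_config(),
                    max_codon = 100, include_truncated = FALSE) {
  stopifnot(inherits(genome, "genome_set"))
  valid <- filter_valid(genome, min_cds_len = config$min_cds_len)
  if (nrow(valid$records) == 0L) stop("no valid genes for MFE scan")
  engine <- .engine_from_config(config)
  bins <- NULL
  if (!is.null(abundances)) {
    bins <- bin_by_expression(abundances, n_bins = config$n_bins)
  }
  rec <- valid$records
  tracks <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    tracks[[i]] <- mfe_track(rec[i, ], engine = engine,
                             max_codon = max_codon,
                             flank_nt = config$flank_nt)
  }
  tracks <- do.call(rbind, tracks)
  summary <- mean_mfe_by_position(tracks, gene_bins = bins,
                                  include_truncated = include_truncated)
  structure(list(summary = summary, tracks = tracks, bins = bins,
                 config = config),
            class = "mfe_run")
}

#' Write the per-window MFE table as TSV
#'
#' Columns: `gene_id`, `codon_center`, `mfe`, `actual_len`, `used_utr_nt`,
#' `bin` (NA when unstratified).
#'
#' @param run An `mfe_run`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mfe_tsv <- function(run, path) {
  d <- as.data.frame(run$tracks)
  if (!is.null(run$bins)) {
    map <- setNames(run$bins$bin, run$bins$gene_id)
    d$bin <- unname(map[d$gene_id])
  } else {
    d$bin <- NA_integer_
  }
  d <- d[, c("gene_id", "codon_center", "mfe", "actual_len", "used_utr_nt",
             "bin")]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
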