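# The gradient slope statistic (GC change per 100 codons) and the
# cross-genome slope-vs-coding-GC regression.

#' Fit the GC gradient slope of a positional profile
#'
#' Ordinary least squares of the per-position mean GC (percent) on the raw
#' codon position index, restricted to `fit_range` (default codons 26-100;
#' the first 25 codons are excluded because they are under distinct
#' constraints near the start codon). The reported `slope_per100` is the
#' per-codon OLS coefficient rescaled x100, so a value of -5 means GC
#' content falls 5 percentage points per 100 codons along translation.
#'
#' @param profile A `positional_profile` (columns `position`, `mean_value`).
#' @param fit_range Length-2 integer vector, inclusive codon interval.
#' @return Object of class `gradient_fit`: `slope_per100`, `intercept`
#'   (GC% at position 0), `r_squared` (`NA` for a constant profile),
#'   `fit_range`, `n_points`, plus the profile's `site_class`/`fragment`
#'   when present.
#' @examples
#' prof <- tibble::tibble(position = 26:100,
#'                        mean_value = 60 - 0.05 * (26:100))
#' fit_gradient(prof)$slope_per100  # -5
#' @export
fit_gradient <- function(profile, fit_range = c(26, 100)) {
  d <- .fit_points(profile, fit_range)
  m <- lm(mean_value ~ position, data = d)
  structure(list(
    slope_per100 = unname(coef(m)[2L]) * 100,
    intercept = unname(coef(m)[1L]),
    r_squared = .r_squared(m, d$mean_value),
    fit_range = as.integer(fit_range),
    n_points = nrow(d),
    site_class = if ("site_class" %in% names(profile))
      profile$site_class[1L] else NA_character_,
    fragment = if ("fragment" %in% names(profile))
      profile$fragment[1L] else NA_character_
  ), class = "gradient_fit")
}

.fit_points <- function(profile, fit_range) {
  stopifnot(length(fit_range) == 2L, fit_range[1L] <= fit_range[2L],
            all(c("position", "mean_value") %in% names(profile)))
  d <- profile[profile$position >= fit_range[1L] &
                 profile$position <= fit_range[2L] &
                 !is.na(profile$mean_value), c("position", "mean_value")]
  if (nrow(d) < 3L) {
    stop("need at least 3 defined positions in fit range, have ", nrow(d))
  }
  d
}

.r_squared <- function(model, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  suppressWarnings(summary(model)$r.squared)
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<gradient_fit> slope = %+.3f GC%% per 100 codons (intercept %.2f, R2 %s, codons %d-%d, n = %d)\n",
    x$slope_per100, x$intercept,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$fit_range[1L], x$fit_range[2L], x$n_points))
  invisible(x)
}

#' Cross-genome regression of gradient slope on coding GC content
#'
#' OLS of per-genome `slope_per100` on pooled coding GC percentage, fitted
#' within a (taxonomic) group; quantifies how much of the between-species
#' variation in 5'-end GC gradients the overall coding GC content explains.
#'
#' @param fits A data frame with columns `coding_gc_percent` and
#'   `slope_per100`, one row per genome (at least 3).
#' @param group_label Free-text label stored with the fit.
#' @return Object of class `cross_genome_fit`: `slope` (change in
#'   slope_per100 per coding-GC point), `intercept`, `r_squared`,
#'   `n_species`, `group_label`.
#' @export
cross_genome_regression <- function(fits, group_label = NA_character_) {
  fits <- as.data.frame(fits)
  stopifnot(all(c("coding_gc_percent", "slope_per100") %in% names(fits)))
  fits <- fits[!is.na(fits$coding_gc_percent) & !is.na(fits$slope_per100), ]
  if (nrow(fits) < 3L) stop("need at least 3 genomes, have ", nrow(fits))
  if (length(unique(fits$coding_gc_percent)) < 2L) {
    stop("coding GC is constant across genomes; regression undefined")
  }
  m <- lm(slope_per100 ~ coding_gc_percent, data = fits)
  structure(list(
    slope = unname(coef(m)[2L]),
    intercept = unname(coef(m)[1L]),
    r_squared = .r_squared(m, fits$slope_per100),
    n_species = nrow(fits),
    group_label = group_label
  ), class = "cross_genome_fit")
}

#' @export
print.cross_genome_fit <- function(x, ...) {
  cat(sprintf(
    "<cross_genome_fit>%s slope = %+.4f per GC%%, intercept %.2f, R2 %s, n = %d\n",
    ifelse(is.na(x$group_label), "", paste0(" [", x$group_label, "]")),
    x$slope, x$intercept,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$n_species))
  invisible(x)
}

#' Coding GC content at which the predicted gradient slope is zero
#'
#' Root of the cross-genome regression line: the coding GC percentage
#' separating genomes with predicted positive gradients from those with
#' negative ones.
#'
#' @param fit A `cross_genome_fit`.
#' @return GC percentage (`-intercept/slope`); `NA` with a warning when the
#'   regression slope is zero.
#' @export
gc_threshold_crossing <- function(fit) {
  stopifnot(inherits(fit, "cross_genome_fit"))
  if (fit$slope == 0) {
    warning("regression slope is zero; threshold undefined")
    return(NA_real_)
  }
  -fit$intercept / fit$slope
}
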