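# Strain-level summaries, group comparisons, and Pearson correlation
# reports, including per-pixel band co-localisation.

#' Standard error of the mean
#'
#' @param values Numeric vector, length >= 2.
#' @return Sample SD divided by the square root of n.
#' @export
sem <- function(values) {
  if (length(values) < 2) stop("sem needs at least 2 values")
  stats::sd(values) / sqrt(length(values))
}

#' Pearson product-moment correlation
#'
#' Thin validating wrapper around the product-moment coefficient; by
#' convention a zero covariance returns r = 0 (rather than NA) when both
#' variances are positive.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return r in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in correlation input")
  stats::cor(x, y, method = "pearson")
}

#' Per-pixel co-localisation of two bands within a region
#'
#' Pearson correlation of per-pixel intensities of two co-registered frames
#' (e.g. the protein band at 1665 cm^-1 against the lipid band at
#' 2845 cm^-1) restricted to a mask, the standard co-localisation statistic
#' for claiming that two vibrational signatures image the same structure.
#'
#' @param frame_a,frame_b Co-registered intensity matrices.
#' @param region Logical mask.
#' @return r in `[-1, 1]`.
#' @export
band_colocalization <- function(frame_a, frame_b, region) {
  stopifnot(identical(dim(frame_a), dim(frame_b)),
            identical(dim(frame_a), dim(region)))
  if (sum(region) < 3) stop("region must contain at least 3 pixels")
  pearson(frame_a[region], frame_b[region])
}

#' Two-group comparison (Welch)
#'
#' Two-sided Welch unequal-variance t comparison.  The choice of test family
#' is an assumption of this package: it is robust to the unequal spreads
#' seen across strains.
#'
#' @param a,b Numeric vectors, each of length >= 2 and not both constant.
#' @return Two-sided p-value.
#' @seealso [p_stars()]
#' @export
group_compare <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (identical(mean(a), mean(b))) return(1)
    stop("degenerate groups: both constant with different means")
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Significance star coding
#'
#' Maps p-values to the conventional star codes: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE) |> as.character()
}

#' Correlations of strain metrics against egg number
#'
#' Computes the Pearson correlation of each metric's strain means against
#' the strain-mean egg number, optionally excluding named strains
#' (leave-one-out re-analysis).  Input is a wide per-strain summary table.
#'
#' @param summaries Data frame with a `strain` column, an `egg_number`
#'   column, and one column per metric.
#' @param metrics Metric column names to correlate (default: all numeric
#'   columns except `egg_number`).
#' @param exclude Character vector of strain names to drop before
#'   correlating.
#' @return List with `r` (named vector of correlations), `n` (strains used)
#'   and `data` (the scatter table actually used).
#' @export
correlation_report <- function(summaries, metrics = NULL, exclude = NULL) {
  stopifnot("strain" %in% names(summaries),
            "egg_number" %in% names(summaries))
  tab <- summaries[!summaries$strain %in% exclude, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 strains after exclusion")
  if (is.null(metrics)) {
    num <- vapply(tab, is.numeric, TRUE)
    metrics <- setdiff(names(tab)[num], "egg_number")
  }
  r <- vapply(metrics, function(m) pearson(tab[[m]], tab$egg_number), 0)
  list(r = r, n = nrow(tab), data = tab[, c("strain", "egg_number", metrics)])
}

#' Summarise a metric by strain
#'
#' @param values Numeric vector of per-worm values.
#' @param strain,metric Labels stored on the summary row.
#' @return One-row data frame: `strain`, `metric`, `mean`, `sem`, `n`.
#' @export
metric_summary <- function(values, strain, metric) {
  data.frame(strain = strain, metric = metric, mean = mean(values),
             sem = if (length(values) >= 2) sem(values) else NA_real_,
             n = length(values))
}
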