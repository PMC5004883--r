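#' Build a distance dataset
#'
#' Canonical flat table of per-allele inter-probe distances with the
#' grouping labels the statistics need: tissue, developmental stage,
#' imaging modality, tissue section and nucleus.
#'
#' @param d_nm Non-negative distances in nm.
#' @param tissue,stage,modality,section,nucleus,allele Labels, recycled to
#'   `length(d_nm)`. `section` is required for the across-section s.e.m.
#' @return `data.frame` of class `distance_dataset`.
#' @export
distance_dataset <- function(d_nm, tissue = "tissue", stage = "stage",
                             modality = "conventional", section = 1L,
                             nucleus = seq_along(d_nm), allele = 1L) {
  stopifnot(is.numeric(d_nm))
  if (any(!is.finite(d_nm)) || any(d_nm < 0))
    stop("distances must be finite and non-negative")
  n <- length(d_nm)
  rec <- function(x) if (n == 0L) x[0] else rep(x, length.out = n)
  out <- data.frame(tissue = rec(tissue), stage = rec(stage),
                    modality = rec(modality), section = rec(section),
                    nucleus = rec(nucleus), allele = rec(allele),
                    d_nm = as.numeric(d_nm))
  class(out) <- c("distance_dataset", "data.frame")
  out
}

as_distance_dataset <- function(df) {
  need <- c("tissue", "stage", "modality", "section", "nucleus", "allele", "d_nm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  distance_dataset(df$d_nm, df$tissue, df$stage, df$modality, df$section,
                   df$nucleus, df$allele)
}

#' Classify an inter-probe distance
#'
#' Probe pairs are colocalised below 200 nm, adjacent from 200 to 400 nm,
#' and separate at 400 nm and beyond. Bins are half-open: exactly 200 nm is
#' adjacent, not colocalised.
#'
#' @param d Vector of distances, nm (non-negative).
#' @return Factor with levels `colocalised`, `adjacent`, `separate`.
#' @examples
#' classify_distance(c(0, 250, 450))
#' @export
classify_distance <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be non-negative")
  cut(d, breaks = c(-Inf, 200, 400, Inf), right = FALSE,
      labels = c("colocalised", "adjacent", "separate"))
}

#' Bin distances into fixed-width classes with across-section s.e.m.
#'
#' Proportions per half-open bin `[k*w, (k+1)*w)` over all alleles pooled;
#' the error bar per bin is the standard error of the per-section
#' proportions (sd across sections / sqrt(number of sections)), the
#' convention used when error bars come from two or three tissue sections.
#' With a single section the s.e.m. is reported as `NA`.
#'
#' @param data A [distance_dataset()].
#' @param bin_width Bin width in nm, default 200.
#' @return `data.frame` of class `binned_distribution`: `bin_low, bin_high,
#'   proportion, sem`; attributes `n_alleles`, `n_sections`.
#' @export
bin_distances <- function(data, bin_width = 200) {
  stopifnot(bin_width > 0)
  if (nrow(data) == 0L) stop("empty dataset")
  nb <- max(1L, ceiling((max(data$d_nm) + 1e-9) / bin_width))
  edges <- (0:nb) * bin_width
  bin_of <- pmin(floor(data$d_nm / bin_width), nb - 1L) + 1L
  prop <- tabulate(bin_of, nb) / nrow(data)
  secs <- unique(data$section)
  if (length(secs) > 1L) {
    per <- sapply(secs, function(s) {
      i <- data$section == s
      tabulate(bin_of[i], nb) / sum(i)
    })
    sem <- apply(per, 1, stats::sd) / sqrt(length(secs))
  } else sem <- rep(NA_real_, nb)
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                    proportion = prop, sem = sem)
  attr(out, "n_alleles") <- nrow(data)
  attr(out, "n_sections") <- length(secs)
  class(out) <- c("binned_distribution", "data.frame")
  out
}

#' Colocalisation frequency with across-section s.e.m.
#'
#' Pooled fraction of alleles closer than `threshold_nm` (weighting alleles,
#' not sections), with the s.e.m. computed across per-section proportions.
#'
#' @param data A [distance_dataset()].
#' @param threshold_nm Colocalisation threshold, default 200 nm.
#' @return List: `proportion`, `sem` (`NA` for a single section), `n`
#'   (alleles), `n_sections`.
#' @export
coloc_frequency <- function(data, threshold_nm = 200) {
  if (nrow(data) == 0L) stop("empty dataset")
  hit <- data$d_nm < threshold_nm
  secs <- unique(data$section)
  sem <- if (length(secs) > 1L) {
    per <- vapply(secs, function(s) mean(hit[data$section == s]), numeric(1))
    stats::sd(per) / sqrt(length(secs))
  } else NA_real_
  list(proportion = mean(hit), sem = sem, n = nrow(data),
       n_sections = length(secs))
}

#' Per-cell allele colocalisation categories
#'
#' For nuclei in which both alleles were measured, classifies each nucleus
#' by how many of its two alleles are colocalised (< 200 nm): `both`, `one`
#' or `none`. Nuclei with a number of measured alleles other than two are
#' excluded and counted.
#'
#' @param data A [distance_dataset()] for one group.
#' @param threshold_nm Colocalisation threshold, nm.
#' @return List: `fractions` (named numeric, both/one/none, summing to 1),
#'   `n_nuclei` (used), `n_excluded`.
#' @export
allele_categories <- function(data, threshold_nm = 200) {
  if (nrow(data) == 0L) stop("empty dataset")
  key <- interaction(data$tissue, data$stage, data$modality, data$section,
                     data$nucleus, drop = TRUE)
  counts <- table(key)
  use <- names(counts)[counts == 2L]
  n_excluded <- sum(counts != 2L)
  if (length(use) == 0L)
    return(list(fractions = c(both = NA_real_, one = NA_real_, none = NA_real_),
                n_nuclei = 0L, n_excluded = n_excluded))
  ncol_per <- vapply(use, function(k)
    sum(data$d_nm[key == k] < threshold_nm), numeric(1))
  fr <- c(both = mean(ncol_per == 2), one = mean(ncol_per == 1),
          none = mean(ncol_per == 0))
  list(fractions = fr, n_nuclei = length(use), n_excluded = n_excluded)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within the
#' conventional 1 + 1e-7 relative tolerance). Computed by
#' [stats::fisher.test()]. A table with a zero margin carries no
#' information; its p-value is defined as 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows: colocalised / not; columns: group 1 / group 2).
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(5, 5, 5, 5), 2))   # 1
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value by enumeration of the rank-sum distribution when
#' the pooled sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie and continuity corrections. Computed by
#' [stats::wilcox.test()]; `U` is the Mann-Whitney statistic for `x`.
#'
#' @param x,y Non-empty numeric samples (e.g. distances of two groups).
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Boxplot summary of a distance distribution
#'
#' Median and interquartile range with whiskers at the 2.5 and 97.5
#' percentiles (a 95% range, not 1.5 IQR). Quantiles use the linear
#' interpolation convention (R type 7).
#'
#' @param data A [distance_dataset()] or numeric vector of distances.
#' @return List of class `boxplot_summary`: `median, q1, q3, whisker_low,
#'   whisker_high, n`.
#' @export
summarize_box <- function(data) {
  d <- if (is.data.frame(data)) data$d_nm else as.numeric(data)
  if (length(d) == 0L) stop("empty data")
  q <- stats::quantile(d, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                       type = 7)
  structure(list(median = q[3], q1 = q[2], q3 = q[4],
                 whisker_low = q[1], whisker_high = q[5], n = length(d)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf("median %.0f nm, IQR [%.0f, %.0f], 95%% range [%.0f, %.0f] (n = %d)\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, x$n))
  invisible(x)
}

#' Pairwise group comparisons of colocalisation and distances
#'
#' For every unordered pair of groups computes (i) Fisher's exact test on
#' the pooled colocalised / not-colocalised allele counts and (ii) the
#' Mann-Whitney U test on the raw distances. No multiple-testing correction
#' is applied; p-values are raw pairwise values.
#'
#' @param datasets Named list of [distance_dataset()] objects.
#' @param threshold_nm Colocalisation threshold, nm.
#' @return `data.frame`: `group1, group2, test, statistic, p`.
#' @export
compare_groups <- function(datasets, threshold_nm = 200) {
  stopifnot(is.list(datasets), length(datasets) >= 2L,
            !is.null(names(datasets)))
  gs <- names(datasets)
  rows <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    a <- datasets[[i]]; b <- datasets[[j]]
    ca <- sum(a$d_nm < threshold_nm); cb <- sum(b$d_nm < threshold_nm)
    tab <- matrix(c(ca, nrow(a) - ca, cb, nrow(b) - cb), 2)
    mw <- mann_whitney(a$d_nm, b$d_nm)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j],
      test = c("fisher_exact", "mann_whitney"),
      statistic = c(NA_real_, mw$U),
      p = c(fisher_exact(tab), mw$p))
  }
  do.call(rbind, rows)
}
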