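#' Rice-rule bin count
#'
#' Number of histogram bins by the Rice rule, twice the cube root of the
#' number of observations, rounded up and clamped to at most `n`.
#'
#' @param n number of observations (>= 1).
#' @return integer bin count.
#' @export
rice_bin_count <- function(n) {
  stopifnot(n >= 1)
  as.integer(pmin(ceiling(2 * n^(1 / 3)), n))
}

#' Equal-count (variable-width) bin assignment
#'
#' Splits the ranked values into `k` contiguous bins whose sizes differ by
#' at most one (`n %% k` leading bins get the extra element). Ties in value
#' may straddle a bin boundary; rank order is stable in input order.
#'
#' @param values numeric vector (no `NA`).
#' @param k number of bins, `1 <= k <= length(values)`.
#' @return integer vector of bin indices (1..k), parallel to `values`.
#' @export
equal_count_bins <- function(values, k) {
  n <- length(values)
  stopifnot(k >= 1, k <= n, !anyNA(values))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of_rank <- rep.int(seq_len(k), sizes)
  bins <- integer(n)
  bins[order(values)] <- bin_of_rank  # order() is stable for ties
  bins
}

#' Binned exceedance prevalence
#'
#' Ranks a parameter into equal-count bins and computes, per bin, the median
#' parameter value and the prevalence of the exceedance label.
#'
#' @param values numeric parameter vector; rows with `NA` are excluded
#'   (for this parameter only).
#' @param labels binary 0/1 exceedance labels, aligned with `values`.
#' @param k bin count; default is the Rice rule on the usable rows.
#' @return an object of class `binned_association`: list with
#'   `parameter` bin table (`bin`, `median`, `prevalence`, `size`), `n`, `k`
#'   (and `tau`/`p_value` slots filled by [kendall_tau_binned()]).
#' @export
binned_prevalence <- function(values, labels, k = NULL) {
  stopifnot(length(values) == length(labels))
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!length(values)) stop("no usable observations")
  stopifnot(all(labels %in% 0:1))
  if (is.null(k)) k <- rice_bin_count(length(values))
  bins <- equal_count_bins(values, k)
  tab <- data.frame(
    bin = seq_len(k),
    median = as.numeric(tapply(values, bins, stats::median)),
    prevalence = as.numeric(tapply(labels, bins, mean)),
    size = as.integer(table(factor(bins, levels = seq_len(k)))))
  structure(list(table = tab, n = length(values), k = as.integer(k),
                 tau = NA_real_, p_value = NA_real_),
            class = "binned_association")
}

#' Kendall rank correlation over binned prevalences
#'
#' Kendall's tau (tau-b, tie-corrected) between the per-bin median parameter
#' values and per-bin exceedance prevalences, with a two-sided p-value
#' (exact for small untied samples, normal approximation otherwise, as in
#' [stats::cor.test()]).
#'
#' @param medians per-bin median parameter values (>= 2 bins).
#' @param prevalences per-bin exceedance prevalences.
#' @return list with `tau` and `p_value`.
#' @export
kendall_tau_binned <- function(medians, prevalences) {
  stopifnot(length(medians) == length(prevalences), length(medians) >= 2)
  ct <- suppressWarnings(
    stats::cor.test(medians, prevalences, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value)
}

#' Binned-prevalence association of one parameter with exceedance
#'
#' Convenience chain: Rice-rule bin count, equal-count binning, per-bin
#' prevalence, and Kendall tau between bin medians and prevalences.
#'
#' @inheritParams binned_prevalence
#' @param name parameter name carried into the result.
#' @return a `binned_association` with `tau` and `p_value` filled in.
#' @export
binned_association <- function(values, labels, k = NULL, name = "parameter") {
  ba <- binned_prevalence(values, labels, k)
  kt <- kendall_tau_binned(ba$table$median, ba$table$prevalence)
  ba$tau <- kt$tau
  ba$p_value <- kt$p_value
  ba$parameter_name <- name
  ba
}

#' @export
print.binned_association <- function(x, ...) {
  cat(sprintf("<binned_association> %s: n = %d, k = %d bins, tau = %.3f (p = %.3g)\n",
              if (is.null(x$parameter_name)) "parameter" else x$parameter_name,
              x$n, x$k, x$tau, x$p_value))
  invisible(x)
}

#' Tukey boxplot statistics by exceedance class
#'
#' Five-number boxplot summaries of a parameter within the low (<= 1.5
#' mg/L) and high (> 1.5 mg/L) classes: hinges at the 25th/75th percentiles
#' (linear interpolation between order statistics, `type = 7`), whiskers at
#' the most extreme observation within 1.5 IQR of the hinge, outliers
#' listed.
#'
#' @param values numeric parameter vector (`NA` excluded).
#' @param labels binary 0/1 exceedance labels.
#' @return data.frame with one row per class (`class`, `n`, `median`,
#'   `q25`, `q75`, `whisker_low`, `whisker_high`) and outliers attached as
#'   attribute `"outliers"` (a list by class). Classes absent from the data
#'   are flagged in attribute `"missing_class"`.
#' @export
class_boxplots <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!length(values)) stop("no usable observations")
  classes <- c(`<=1.5` = 0, `>1.5` = 1)
  rows <- list(); outliers <- list()
  present <- names(classes)[classes %in% labels]
  for (cl in present) {
    v <- values[labels == classes[[cl]]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    in_fence <- v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr
    rows[[cl]] <- data.frame(class = cl, n = length(v), median = q[2],
                             q25 = q[1], q75 = q[3],
                             whisker_low = min(v[in_fence]),
                             whisker_high = max(v[in_fence]))
    outliers[[cl]] <- v[!in_fence]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outliers") <- outliers
  attr(out, "missing_class") <- setdiff(names(classes), present)
  out
}
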