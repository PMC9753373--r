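#' Compare onset-age variability between two groups
#'
#' When disease-state rates are built from variant frequencies estimated in
#' cohorts of people with and without a variant, the method assumes family
#' disease states evolve comparably over time in the two groups. That
#' assumption can be probed by checking whether age at onset is about equally
#' variable in carriers and non-carriers: this utility returns the ratio of
#' interquartile ranges of onset age between the two samples together with
#' empirical cumulative distribution coordinates for plotting. A ratio near
#' 1 is consistent with equal variability.
#'
#' @param a,b Numeric vectors of ages at onset (years, positive), at least 4
#'   values each so quartiles are meaningful.
#' @param labels Length-2 character vector naming the groups.
#' @param quartile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#'
#' @return An object of class `"onset_variability"`: list with `ratio`
#'   (`IQR(a) / IQR(b)`), per-group IQRs, a `degenerate` flag (`TRUE` when
#'   either IQR is zero), and `ecdf` — a data frame of `(group, age, cdf)`
#'   coordinates.
#' @examples
#' set.seed(1)
#' x <- rnorm(50, 60, 10); y <- rnorm(50, 55, 10)
#' onset_variability(x, y)$ratio
#' @export
onset_variability <- function(a, b, labels = c("a", "b"), quartile_type = 7) {
  for (v in list(a, b)) {
    if (!is.numeric(v) || length(v) < 4L)
      stop("each onset sample needs at least 4 ages")
    if (anyNA(v) || any(v <= 0)) stop("onset ages must be positive")
  }
  q <- function(v) stats::quantile(v, c(0.25, 0.75), type = quartile_type,
                                   names = FALSE)
  qa <- q(a); qb <- q(b)
  iqr_a <- qa[2] - qa[1]; iqr_b <- qb[2] - qb[1]
  degenerate <- iqr_a == 0 || iqr_b == 0
  if (degenerate)
    warning("zero interquartile range in at least one group; ",
            "ratio is degenerate")
  ratio <- if (iqr_b == 0) NA_real_ else iqr_a / iqr_b
  ec <- rbind(
    data.frame(group = labels[1], age = sort(a),
               cdf = seq_along(a) / length(a)),
    data.frame(group = labels[2], age = sort(b),
               cdf = seq_along(b) / length(b)))
  structure(list(ratio = ratio, iqr_a = iqr_a, iqr_b = iqr_b,
                 degenerate = degenerate, labels = labels, ecdf = ec),
            class = "onset_variability")
}

#' @export
print.onset_variability <- function(x, ...) {
  cat(sprintf("IQR(%s) = %.3g; IQR(%s) = %.3g; ratio = %.3g%s\n",
              x$labels[1], x$iqr_a, x$labels[2], x$iqr_b, x$ratio,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
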