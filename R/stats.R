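# Regression, Welch comparison, and paired before/after summaries.

#' Ordinary least-squares line fit with Pearson correlation
#'
#' Thin wrapper around [stats::lm()] returning the slope, intercept and
#' Pearson r of `y ~ x`, the regression displayed on ABP-versus-actin
#' scatter plots. A constant `y` returns slope 0 and r 0; a degenerate `x`
#' (no variance) is an error.
#'
#' @param x,y Numeric vectors (>= 3 finite points).
#' @return List with `slope`, `intercept`, `r`, `n`.
#' @export
linfit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need at least 3 finite points, got %d", length(x))
  if (stats::var(x) == 0) stopf("degenerate fit: `x` has zero variance")
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r = 0, n = length(x)))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(x, y), n = length(x))
}

#' Welch's unpaired two-sample t-test
#'
#' Unequal-variance t-test (Welch-Satterthwaite degrees of freedom,
#' two-sided p), the comparison used for pooled per-segment ratio
#' distributions across conditions. Wraps [stats::t.test()] after
#' validating that both groups have at least two values and positive
#' variance.
#'
#' @param group_a,group_b Numeric vectors.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_test <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("each group needs at least 2 finite values")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stopf("degenerate groups: both variances are zero")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Paired before/after comparison keyed by region
#'
#' Compares per-region mean ratio and mean F-actin intensity before and
#' after a treatment (e.g. ATP addition), keyed by stripe-gap region
#' rather than by segment, since segments rearrange once motors activate.
#' Regions present in only one table are listed and excluded.
#'
#' @param pre_table,post_table Segment tables (rows are segments) with the
#'   key column plus `ratio` and `mean_actin`.
#' @param key Region key column name.
#' @return List with `deltas` (one row per matched region: pre/post means,
#'   `d_ratio`, `d_actin`), `unmatched` keys, and `summary` (mean deltas
#'   and a paired t-test on the per-region ratios when >= 2 regions).
#' @export
paired_compare <- function(pre_table, post_table, key = "region_id") {
  for (tb in list(pre_table, post_table))
    if (!all(c(key, "ratio", "mean_actin") %in% names(tb)))
      stopf("tables need columns `%s`, `ratio`, `mean_actin`", key)
  agg <- function(tb) {
    valid <- if ("valid" %in% names(tb)) tb$valid else TRUE
    tb <- tb[valid & is.finite(tb$ratio), , drop = FALSE]
    data.frame(key = tapply(tb$ratio, tb[[key]], mean),
               actin = tapply(tb$mean_actin, tb[[key]], mean))
  }
  a <- agg(pre_table); b <- agg(post_table)
  ka <- rownames(a); kb <- rownames(b)
  common <- intersect(ka, kb)
  unmatched <- union(setdiff(ka, kb), setdiff(kb, ka))
  if (!length(common)) stopf("no matching `%s` keys between tables", key)
  deltas <- data.frame(
    region = common,
    ratio_pre = a[common, "key"], ratio_post = b[common, "key"],
    actin_pre = a[common, "actin"], actin_post = b[common, "actin"])
  deltas$d_ratio <- deltas$ratio_post - deltas$ratio_pre
  deltas$d_actin <- deltas$actin_post - deltas$actin_pre
  summary <- list(mean_d_ratio = mean(deltas$d_ratio),
                  mean_d_actin = mean(deltas$d_actin),
                  n_regions = nrow(deltas))
  if (nrow(deltas) >= 2L && stats::var(deltas$d_ratio) > 0) {
    # t.test rejects all-but-constant deltas; skip the paired test then
    ht <- tryCatch(stats::t.test(deltas$ratio_post, deltas$ratio_pre,
                                 paired = TRUE),
                   error = function(e) NULL)
    if (!is.null(ht)) {
      summary$t <- unname(ht$statistic)
      summary$p <- ht$p.value
    }
  }
  list(deltas = deltas, unmatched = unmatched, summary = summary)
}
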