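#' Two-sample Student's t-test (equal variance, two-tailed)
#'
#' The pooled-variance two-sample t-test with n1 + n2 - 2 degrees of
#' freedom, as used for group comparisons throughout the quantifications.
#' Swapping the groups negates t and leaves p unchanged.
#'
#' @param a,b numeric sample vectors (each n >= 2).
#' @return list: \code{t}, \code{df}, \code{p} (two-tailed).
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6))
#' @export
twoSampleT <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 values")
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (!is.finite(pooled) || pooled <= 0)
    stop("zero pooled variance; t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Per-group summary statistics with fold change versus a control
#'
#' @param table data.frame with columns \code{group} and \code{value} (one
#'   row per embryo/centrosome; per-group aggregation is mean-of-means, each
#'   embryo contributing one value).
#' @param control the control group label (fold changes are relative to its
#'   mean).
#' @return data.frame ordered by group label: \code{group}, \code{n},
#'   \code{mean}, \code{sd}, \code{sem}, \code{fold}.
#' @export
summarizeGroups <- function(table, control) {
  stopifnot(all(c("group", "value") %in% names(table)))
  groups <- sort(unique(as.character(table$group)))
  if (!control %in% groups || !sum(table$group == control))
    stop("control group '", control, "' is missing or empty")
  ctrlMean <- mean(table$value[table$group == control])
  rows <- lapply(groups, function(g) {
    v <- table$value[table$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               fold = mean(v) / ctrlMean, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
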