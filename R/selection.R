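# Exon-partition selected-site rates and the two-proportion z-test used to
# compare them between isoform-shared and isoform-specific exon sets.

#' Annotate site calls with their exon partition
#'
#' Each call is assigned the label of the partition whose interval contains
#' its position, or `"unassigned"` when no partition covers it. Partition
#' intervals are 1-based inclusive, so positions equal to an interval start or
#' end are assigned.
#'
#' @param calls A `site_call_set`.
#' @param partitions An `exon_partition_table`.
#' @return The calls data frame with an added `partition` column.
#' @export
map_sites_to_partitions <- function(calls, partitions) {
  stopifnot(inherits(calls, "site_call_set"),
            inherits(partitions, "exon_partition_table"))
  lab <- vapply(calls$position, function(p) {
    hit <- partitions$label[partitions$start <= p & p <= partitions$end]
    if (length(hit) == 0) return("unassigned")
    if (length(hit) > 1)
      stop("position ", p, " falls in overlapping partitions: ",
           paste(hit, collapse = ", "))
    hit
  }, character(1))
  out <- as.data.frame(calls)
  out$partition <- lab
  out
}

#' Per-partition selected-site counts and rates
#'
#' Counts positive- and negative-class calls falling inside each exon
#' partition and reports rates as `100 * count / partition length in aa`,
#' rounded to 1 decimal (the conventional reporting style, e.g. 17 negative
#' sites in 125 aa = 13.6%). Calls outside every partition are tallied in the
#' `"unassigned"` attribute, so counts are conserved.
#'
#' @param calls A `site_call_set`.
#' @param partitions An `exon_partition_table`.
#' @return A `partition_counts` data frame: `label`, `length_aa`,
#'   `n_positive`, `n_negative`, `rate_positive`, `rate_negative`; attribute
#'   `unassigned` holds the outside-partition counts per class.
#' @export
partition_rates <- function(calls, partitions) {
  ann <- map_sites_to_partitions(calls, partitions)
  labs <- unique(partitions$label)
  rows <- lapply(labs, function(L) {
    len <- sum(partitions$end[partitions$label == L] -
               partitions$start[partitions$label == L] + 1L)
    np <- sum(ann$partition == L & ann$class == "positive")
    nn <- sum(ann$partition == L & ann$class == "negative")
    data.frame(label = L, length_aa = len, n_positive = np, n_negative = nn,
               rate_positive = round(100 * np / len, 1),
               rate_negative = round(100 * nn / len, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  unassigned <- c(positive = sum(ann$partition == "unassigned" &
                                 ann$class == "positive"),
                  negative = sum(ann$partition == "unassigned" &
                                 ann$class == "negative"))
  structure(out, unassigned = unassigned,
            class = c("partition_counts", "data.frame"))
}

#' Partition share of the protein
#'
#' Percent of the protein length covered by each partition (e.g. the
#' isoform-shared exons of a 700-aa protein covering 575 aa are 82.1%).
#'
#' @param partitions An `exon_partition_table`.
#' @return Named numeric vector of percentages, 1 decimal.
#' @export
partition_shares <- function(partitions) {
  stopifnot(inherits(partitions, "exon_partition_table"))
  len <- attr(partitions, "protein_length")
  labs <- unique(partitions$label)
  shares <- vapply(labs, function(L)
    round(100 * sum(partitions$end[partitions$label == L] -
                    partitions$start[partitions$label == L] + 1L) / len, 1),
    numeric(1))
  setNames(shares, labs)
}

#' Two-proportion z-test (pooled, no continuity correction)
#'
#' Compares two sample proportions `x1/n1` and `x2/n2` with the classical
#' pooled-variance z statistic:
#' \deqn{z = \frac{\hat p_1 - \hat p_2}
#'   {\sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}},\quad
#'   \hat p = \frac{x_1 + x_2}{n_1 + n_2}}
#' with a two-tailed p-value from the standard normal distribution.
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @return A `prop_test_result`: list with `z`, `p_two_tailed`, `pooled_p`,
#'   `p1`, `p2`.
#' @examples
#' two_proportion_z(38, 575, 1, 125)  # p = 0.01 at 2-decimal reporting
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1)
    stop("two_proportion_z degenerate: pooled proportion is ", pooled,
         " (zero variance)")
  p1 <- x1 / n1
  p2 <- x2 / n2
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  structure(list(z = z, p_two_tailed = 2 * pnorm(-abs(z)),
                 pooled_p = pooled, p1 = p1, p2 = p2),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("Two-proportion z-test: p1=%.4f p2=%.4f z=%.3f P=%.2f\n",
              x$p1, x$p2, x$z, x$p_two_tailed))
  invisible(x)
}

#' Compare a selection class between two partitions
#'
#' Convenience wrapper: runs [two_proportion_z()] on the per-partition counts
#' of one selection class.
#'
#' @param counts A `partition_counts` from [partition_rates()].
#' @param class `"positive"` or `"negative"`.
#' @param labels Two partition labels to compare (defaults to the first two).
#' @return A `prop_test_result`.
#' @export
compare_partition_rates <- function(counts, class = c("positive", "negative"),
                                    labels = counts$label[1:2]) {
  class <- match.arg(class)
  stopifnot(length(labels) == 2, all(labels %in% counts$label))
  col <- paste0("n_", class)
  i <- match(labels, counts$label)
  two_proportion_z(counts[[col]][i[1]], counts$length_aa[i[1]],
                   counts[[col]][i[2]], counts$length_aa[i[2]])
}
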