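# The screen statistics: Identity Ratio (IR), Extended Identity Ratio (EIR),
# Tukey-fence distribution summary, and the per-gene-list screen driver.

#' Identity Ratio (IR)
#'
#' IR = pid(ref, focal) / pid(ref, base). Under a constant evolutionary rate
#' and a topology where the focal species is closer to the reference than the
#' baseline is, IR is expected to exceed 1; values well below 1 indicate
#' focal-lineage acceleration. Defaults use the human (reference) /
#' house mouse (focal) / bovine (baseline) roles.
#'
#' @param m An `identity_matrix`.
#' @param focal,ref,base Species tags present in `m`.
#' @return The ratio, full precision (report to 2 decimals).
#' @export
identity_ratio <- function(m, focal = "house_mouse", ref = "human",
                           base = "bovine") {
  sp <- c(focal, ref, base)
  missing_sp <- setdiff(sp, rownames(m))
  if (length(missing_sp) > 0)
    stop("identity matrix lacks species: ", paste(missing_sp, collapse = ", "))
  den <- m[ref, base]
  if (den == 0) stop("identity ratio undefined: pid(ref, base) is 0")
  m[ref, focal] / den
}

#' Extended Identity Ratio (EIR)
#'
#' EIR = sum of the focal species' percent identities to each member of a
#' reference trio, divided by the sum of the three pairwise identities among
#' the trio. The default trio is human, bovine, rabbit with house mouse as
#' the focal species.
#'
#' @param m An `identity_matrix`.
#' @param focal Focal species tag.
#' @param trio Character vector of exactly three species tags.
#' @return The ratio, full precision (report to 2 decimals).
#' @export
extended_identity_ratio <- function(m, focal = "house_mouse",
                                    trio = c("human", "bovine", "rabbit")) {
  stopifnot(length(trio) == 3)
  sp <- c(focal, trio)
  missing_sp <- setdiff(sp, rownames(m))
  if (length(missing_sp) > 0)
    stop("identity matrix lacks species: ", paste(missing_sp, collapse = ", "))
  num <- sum(m[focal, trio])
  den <- m[trio[1], trio[2]] + m[trio[1], trio[3]] + m[trio[2], trio[3]]
  if (den == 0) stop("extended identity ratio undefined: trio identities sum to 0")
  num / den
}

#' Tukey five-number summary with lower outlier fence
#'
#' Median and quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7), `iqr = Q3 - Q1`, and the Tukey lower fence
#' `Q1 - 1.5 * iqr`. Requires at least four finite values; with fewer the
#' fence is not meaningful.
#'
#' @param values Numeric vector of ratios.
#' @return List with `median`, `q1`, `q3`, `iqr`, `lower_fence`, `n`.
#' @examples
#' tukey_summary(c(0.9, 0.95, 1.0, 1.05, 1.1))
#' @export
tukey_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4)
    stop("tukey_summary needs at least 4 finite values")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       lower_fence = q[1] - 1.5 * iqr, n = length(values))
}

#' Run the divergence screen over ortholog groups
#'
#' Computes IR and EIR for every ortholog group with a complete species panel,
#' ranks genes ascending by the chosen ratio (ties broken by gene symbol),
#' summarizes the ratio distribution with [tukey_summary()], and flags genes
#' whose ratio falls below the Tukey lower fence. Groups missing panel species
#' are skipped and counted.
#'
#' @param groups List of `ortholog_group` objects.
#' @param panel Species panel (character). Defaults to the union of the
#'   screen roles.
#' @param scoring An [align_scoring()] object.
#' @param ratio Which statistic to rank and fence on: `"EIR"` or `"IR"`.
#' @param focal,ref,base IR roles, see [identity_ratio()].
#' @param trio EIR trio, see [extended_identity_ratio()].
#' @param denominator Identity denominator, see [percent_identity()].
#' @return A `screen_report`: list with `records` (data frame: `gene_symbol`,
#'   `ir`, `eir`, `n_species_used`, `rank`, `outlier`), `summary` (the Tukey
#'   summary of the chosen ratio), `ratio` (which one), and `skipped`
#'   (gene symbols lacking panel species).
#' @export
run_screen <- function(groups, panel = unique(c(ref, focal, base, trio)),
                       scoring = align_scoring(), ratio = c("EIR", "IR"),
                       focal = "house_mouse", ref = "human", base = "bovine",
                       trio = c("human", "bovine", "rabbit"),
                       denominator = c("alignment", "shorter")) {
  ratio <- match.arg(ratio)
  denominator <- match.arg(denominator)
  if (length(groups) == 0) stop("no ortholog groups supplied")
  complete <- vapply(groups, function(g)
    all(panel %in% names(g$members)), logical(1))
  skipped <- vapply(groups[!complete], function(g) g$gene_symbol, character(1))
  groups <- groups[complete]
  if (length(groups) == 0) stop("all ortholog groups are missing panel species")

  # one batched alignment call over every unordered species pair of every gene
  np <- length(panel)
  pair_i <- rep(1:(np - 1), times = (np - 1):1)
  pair_j <- unlist(lapply(1:(np - 1), function(i) (i + 1):np))
  a_vec <- character(0); b_vec <- character(0)
  for (g in groups) {
    a_vec <- c(a_vec, vapply(pair_i, function(i)
      g$members[[panel[i]]]$sequence, character(1)))
    b_vec <- c(b_vec, vapply(pair_j, function(j)
      g$members[[panel[j]]]$sequence, character(1)))
  }
  pids <- .pid_batch(a_vec, b_vec, scoring, denominator)
  npairs <- length(pair_i)
  rows <- lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    m <- matrix(100, np, np, dimnames = list(panel, panel))
    p <- pids[((k - 1) * npairs + 1):(k * npairs)]
    for (q in seq_len(npairs))
      m[pair_i[q], pair_j[q]] <- m[pair_j[q], pair_i[q]] <- p[q]
    class(m) <- c("identity_matrix", class(m))
    data.frame(gene_symbol = g$gene_symbol,
               ir = identity_ratio(m, focal, ref, base),
               eir = extended_identity_ratio(m, focal, trio),
               n_species_used = length(panel),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  val <- if (ratio == "EIR") rec$eir else rec$ir
  ord <- order(val, rec$gene_symbol)
  rec <- rec[ord, , drop = FALSE]
  val <- val[ord]
  rec$rank <- seq_len(nrow(rec))
  smry <- tukey_summary(val)
  rec$outlier <- val < smry$lower_fence
  rownames(rec) <- NULL
  structure(list(records = rec, summary = smry, ratio = ratio,
                 skipped = unname(skipped)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat("Divergence screen on ", nrow(x$records), " genes (", x$ratio,
      "-ranked); ", length(x$skipped), " skipped\n", sep = "")
  cat(sprintf("  median %.2f, Q1 %.2f, Q3 %.2f, lower fence %.2f\n",
              s$median, s$q1, s$q3, s$lower_fence))
  cat("  outliers below fence:", sum(x$records$outlier), "\n")
  print(utils::head(x$records, 10))
  invisible(x)
}

#' Write a screen report as TSV with a commented summary header
#'
#' @param report A `screen_report`.
#' @param path Output path.
#' @param provenance Optional named character vector added to the commented
#'   header (e.g. seed, config digest).
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path, provenance = NULL) {
  s <- report$summary
  hdr <- c(
    paste0("# orthoscreen screen report (", report$ratio, "-ranked)"),
    sprintf("# n=%d skipped=%d", nrow(report$records), length(report$skipped)),
    sprintf("# median=%.4f q1=%.4f q3=%.4f iqr=%.4f lower_fence=%.4f",
            s$median, s$q1, s$q3, s$iqr, s$lower_fence))
  if (!is.null(provenance))
    hdr <- c(hdr, paste0("# ", names(provenance), "=", provenance))
  rec <- report$records
  rec$ir <- sprintf("%.2f", rec$ir)
  rec$eir <- sprintf("%.2f", rec$eir)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
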