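# Global affine-gap protein alignment and percent-identity matrices.
# Alignment itself is delegated to Biostrings; this layer fixes the scoring
# conventions (BLAST protein defaults), the identity definition, and the
# treatment of the ambiguity letter X.

#' Alignment scoring parameters
#'
#' BLAST protein defaults: BLOSUM62 with gap open 11 / extend 1 (a gap of
#' length L costs 11 + L). The ambiguity letter `X` is rescored to 0 against
#' every residue and never counts as an identity.
#'
#' @param matrix Substitution matrix name (any matrix shipped with
#'   \pkg{Biostrings}, e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty per gapped position (positive).
#' @return An `align_scoring` object.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open > 0, gap_extend > 0)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  sm <- get(matrix, envir = e)
  if ("X" %in% rownames(sm)) {
    sm["X", ] <- 0L
    sm[, "X"] <- 0L
  }
  structure(list(name = matrix, matrix = sm,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties. Returns the
#' aligned (gapped) sequences, the optimal score, the count of identical
#' aligned columns and the total alignment length. Columns where either
#' residue is `X` never count as identities. An empty input sequence yields
#' the all-gap alignment against the other sequence.
#'
#' @param a,b Protein sequences (character scalars; residues in the 20-letter
#'   alphabet plus `X`).
#' @param scoring An [align_scoring()] object.
#' @return An `alignment_result`: list with `aligned_a`, `aligned_b`, `score`,
#'   `identities`, `alignment_length`.
#' @examples
#' global_align("MKT", "MKV")
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  a <- toupper(a); b <- toupper(b)
  for (s in c(a, b)) {
    chars <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(chars, rownames(scoring$matrix))
    if (length(bad) > 0)
      stop("no scoring matrix entry for residue(s): ", paste(bad, collapse = ""))
  }
  if (nchar(a) == 0 && nchar(b) == 0) {
    return(alignment_result("", "", 0))
  }
  if (nchar(a) == 0 || nchar(b) == 0) {
    n <- max(nchar(a), nchar(b))
    gaps <- strrep("-", n)
    sc <- -(scoring$gap_open + scoring$gap_extend * n)
    if (nchar(a) == 0) return(alignment_result(gaps, b, sc))
    return(alignment_result(a, gaps, sc))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  alignment_result(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa)),
                   Biostrings::score(pa))
}

alignment_result <- function(aligned_a, aligned_b, score) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  if (any(ca == "-" & cb == "-"))
    stop("internal error: alignment column with two gaps")
  ident <- sum(ca == cb & ca != "-" & ca != "X")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, identities = ident,
                 alignment_length = nchar(aligned_a)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("Global alignment: score ", x$score, ", ", x$identities, "/",
      x$alignment_length, " identities (",
      sprintf("%.2f", 100 * x$identities / max(1, x$alignment_length)),
      "%)\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' By default the BLAST reporting convention: identical columns divided by the
#' total number of alignment columns (gap columns included), times 100. The
#' alternative `"shorter"` denominator divides by the length of the shorter
#' ungapped sequence instead.
#'
#' @param r An `alignment_result` from [global_align()].
#' @param denominator `"alignment"` (default) or `"shorter"`.
#' @return Percent identity in `[0, 100]`, full precision (report to 2
#'   decimals).
#' @export
percent_identity <- function(r, denominator = c("alignment", "shorter")) {
  stopifnot(inherits(r, "alignment_result"))
  denominator <- match.arg(denominator)
  den <- if (denominator == "alignment") {
    r$alignment_length
  } else {
    min(nchar(gsub("-", "", r$aligned_a)), nchar(gsub("-", "", r$aligned_b)))
  }
  if (den == 0) stop("percent identity undefined for a zero-length alignment")
  100 * r$identities / den
}

#' Pairwise percent-identity matrix over a species panel
#'
#' Aligns every unordered species pair of an ortholog group once and fills a
#' symmetric matrix of percent identities; the diagonal is 100 by definition.
#'
#' @param group An `ortholog_group`.
#' @param panel Character vector of species tags; the group must have a member
#'   for each.
#' @param scoring An [align_scoring()] object.
#' @param denominator Identity denominator, see [percent_identity()].
#' @return An `identity_matrix`: numeric matrix with species dimnames.
#' @export
identity_matrix <- function(group, panel = names(group$members),
                            scoring = align_scoring(),
                            denominator = c("alignment", "shorter")) {
  stopifnot(inherits(group, "ortholog_group"))
  denominator <- match.arg(denominator)
  missing_sp <- setdiff(panel, names(group$members))
  if (length(missing_sp) > 0)
    stop("gene '", group$gene_symbol, "': missing ortholog for species: ",
         paste(missing_sp, collapse = ", "))
  n <- length(panel)
  m <- matrix(100, n, n, dimnames = list(panel, panel))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      r <- global_align(group$members[[panel[i]]]$sequence,
                        group$members[[panel[j]]]$sequence, scoring)
      m[i, j] <- m[j, i] <- percent_identity(r, denominator)
    }
  }
  structure(m, class = c("identity_matrix", class(m)))
}

# Batched percent identities for many sequence pairs in one alignment call.
# Elementwise pairing of pattern/subject sets gives scores and tracebacks
# identical to one-at-a-time global_align (covered by tests); empty sequences
# fall back to the scalar path.
.pid_batch <- function(a_vec, b_vec, scoring = align_scoring(),
                       denominator = "alignment") {
  stopifnot(length(a_vec) == length(b_vec))
  n <- length(a_vec)
  out <- numeric(n)
  scalar <- nchar(a_vec) == 0 | nchar(b_vec) == 0
  for (i in which(scalar))
    out[i] <- percent_identity(global_align(a_vec[i], b_vec[i], scoring),
                               denominator)
  has_x <- grepl("X", a_vec, fixed = TRUE) | grepl("X", b_vec, fixed = TRUE)
  # X-containing pairs go through the scalar path, which applies the
  # no-X-identity rule column by column
  for (i in which(has_x & !scalar))
    out[i] <- percent_identity(global_align(a_vec[i], b_vec[i], scoring),
                               denominator)
  idx <- which(!scalar & !has_x)
  if (length(idx) > 0) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a_vec[idx]), Biostrings::AAStringSet(b_vec[idx]),
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "global")
    ident <- Biostrings::nmatch(pa)
    den <- if (denominator == "alignment") {
      # every column is a match, mismatch or single-sequence gap, so
      # columns = len(a) + len(b) - matches - mismatches
      nchar(a_vec[idx]) + nchar(b_vec[idx]) - ident - Biostrings::nmismatch(pa)
    } else {
      pmin(nchar(a_vec[idx]), nchar(b_vec[idx]))
    }
    out[idx] <- 100 * ident / den
  }
  out
}

#' Write an identity matrix as a square TSV
#'
#' @param m An `identity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  df <- data.frame(species = rownames(m), round(unclass(m), 2),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identity matrix from a square TSV
#' @param path Path written by [write_identity_matrix()].
#' @return An `identity_matrix`.
#' @export
read_identity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("identity matrix TSV is not symmetric: ", path)
  structure(m, class = c("identity_matrix", class(m)))
}

#' Write an alignment in aligned-FASTA format
#' @param r An `alignment_result`.
#' @param path Output path.
#' @param names Character vector of two sequence names.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(r, path, names = c("a", "b")) {
  aas <- Biostrings::AAStringSet(c(r$aligned_a, r$aligned_b))
  names(aas) <- names
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}
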