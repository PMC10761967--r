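# Counting-method dN/dS (Nei & Gojobori 1986) with Jukes-Cantor correction.
# Synonymous/nonsynonymous site fractions are counted per codon with stop
# neighbors treated as nonsynonymous; multi-nucleotide codon differences are
# averaged over all minimal mutational paths, excluding paths that pass
# through a stop codon.

.genetic_code <- function() {
  # standard code (table 1), DNA alphabet
  Biostrings::GENETIC_CODE
}

.translate_codon <- function(codon, gc) {
  aa <- unname(gc[codon])
  if (is.na(aa)) stop("invalid codon: ", codon)
  aa
}

#' Construct a codon alignment from two coding sequences
#'
#' Both sequences must be gap-free, equal-length, a multiple of 3, and
#' translate without any stop codons (standard genetic code); the usual
#' curation is to strip gaps and the terminal stop before building the
#' alignment.
#'
#' @param seq1,seq2 Nucleotide coding sequences (character scalars, ACGT/U).
#' @return A `codon_alignment`: list with `seq1`, `seq2`, `n_codons`,
#'   `code = 1L`.
#' @export
codon_alignment <- function(seq1, seq2) {
  norm <- function(s) {
    s <- gsub("U", "T", toupper(s))
    if (grepl("-", s, fixed = TRUE)) stop("codon alignment must be gap-free")
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T"))
    if (length(bad) > 0)
      stop("non-ACGT character(s) in coding sequence: ",
           paste(bad, collapse = ""))
    s
  }
  seq1 <- norm(seq1); seq2 <- norm(seq2)
  if (nchar(seq1) != nchar(seq2))
    stop("coding sequences differ in length (", nchar(seq1), " vs ",
         nchar(seq2), ")")
  if (nchar(seq1) == 0 || nchar(seq1) %% 3 != 0)
    stop("coding sequence length must be a positive multiple of 3")
  gc <- .genetic_code()
  for (s in c(seq1, seq2)) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aas <- vapply(cods, .translate_codon, character(1), gc = gc)
    if (any(aas == "*"))
      stop("coding sequence contains a stop codon at codon ",
           which(aas == "*")[1], "; remove stops before analysis")
  }
  structure(list(seq1 = seq1, seq2 = seq2, n_codons = nchar(seq1) %/% 3,
                 code = 1L),
            class = "codon_alignment")
}

#' Read a paired codon alignment from FASTA
#'
#' The file must contain exactly two nucleotide sequences satisfying the
#' [codon_alignment()] invariants.
#'
#' @param path Path to FASTA with two entries.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) != 2)
    stop("codon alignment FASTA must contain exactly 2 sequences, found ",
         length(dna), ": ", path)
  codon_alignment(as.character(dna[[1]]), as.character(dna[[2]]))
}

# Synonymous/nonsynonymous site fractions for one codon. Each of the 9
# single-nucleotide neighbors is classified; neighbors that are stop codons
# count as nonsynonymous. Normalized so every codon contributes 3 sites.
.codon_sites <- function(codon, gc) {
  bases <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(bases, orig)) {
      nb <- codon
      substr(nb, pos, pos) <- b
      aa2 <- gc[[nb]]
      if (aa2 != "*" && aa2 == aa) s <- s + 1
    }
  }
  c(S = s / 3, N = 3 - s / 3)
}

# Average syn/nonsyn difference counts between two codons over all minimal
# mutational paths (permutations of the differing positions). Paths whose
# intermediate codons are stops are excluded; the remaining paths are weighted
# equally. If every path crosses a stop, all paths are used and the result is
# flagged by the caller via the returned attribute.
.codon_diffs <- function(c1, c2, gc) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0) return(c(Sd = 0, Nd = 0))
  perms <- switch(nd,
                  list(diff_pos),
                  list(diff_pos, rev(diff_pos)),
                  {
                    p <- list()
                    for (i in 1:3) for (j in setdiff(1:3, i))
                      p[[length(p) + 1]] <- diff_pos[c(i, j, setdiff(1:3, c(i, j)))]
                    p
                  })
  score_path <- function(ord) {
    cur <- c1
    sd <- ndn <- 0
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      aa1 <- gc[[cur]]; aa2 <- gc[[nxt]]
      if (aa2 == "*" && nxt != c2) return(NULL)  # path through a stop
      if (aa1 == aa2) sd <- sd + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd, ndn)
  }
  scored <- lapply(perms, score_path)
  ok <- !vapply(scored, is.null, logical(1))
  if (!any(ok)) {
    # no stop-free path; fall back to all paths, counting stop steps as
    # nonsynonymous (degenerate case, flagged upstream)
    scored <- lapply(perms, function(ord) {
      cur <- c1; sd <- ndn <- 0
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      c(sd, ndn)
    })
    ok <- rep(TRUE, length(scored))
  }
  mat <- do.call(rbind, scored[ok])
  c(Sd = mean(mat[, 1]), Nd = mean(mat[, 2]))
}

#' Counting-method dN/dS (NG86) for a pairwise codon alignment
#'
#' Nei-Gojobori (1986) counting estimator: synonymous (S) and nonsynonymous
#' (N) site counts are per-codon neighbor fractions averaged over the two
#' sequences (so `N + S = 3 * n_codons`); observed synonymous (Sd) and
#' nonsynonymous (Nd) differences average over all minimal mutational paths
#' between differing codons, excluding paths through stop codons. The raw
#' proportions `pS = Sd/S`, `pN = Nd/N` are corrected for multiple hits with
#' the Jukes-Cantor formula `d = -3/4 * log(1 - 4/3 * p)`, and
#' `omega = dN / dS`.
#'
#' `omega` is `NA` (with an explanatory flag) when `dS = 0` or when a
#' proportion reaches the Jukes-Cantor divergence limit `p >= 3/4`.
#'
#' @param aln A `codon_alignment`.
#' @return An `ng86_result`: list with `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `dN`, `dS`, `omega`, `n_codons`, `flags` (character vector, empty when
#'   the estimate is clean).
#' @examples
#' aln <- codon_alignment("ATGAAACCC", "ATGAAGCCA")
#' ng86_dnds(aln)
#' @export
ng86_dnds <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  gc <- .genetic_code()
  idx <- seq_len(aln$n_codons)
  cod1 <- substring(aln$seq1, 3 * idx - 2, 3 * idx)
  cod2 <- substring(aln$seq2, 3 * idx - 2, 3 * idx)

  sites1 <- rowSums(vapply(cod1, .codon_sites, numeric(2), gc = gc))
  sites2 <- rowSums(vapply(cod2, .codon_sites, numeric(2), gc = gc))
  S <- (sites1["S"] + sites2["S"]) / 2
  N <- (sites1["N"] + sites2["N"]) / 2

  diffs <- rowSums(vapply(seq_along(cod1), function(i)
    .codon_diffs(cod1[i], cod2[i], gc), numeric(2)))
  Sd <- diffs["Sd"]; Nd <- diffs["Nd"]

  pS <- as.numeric(Sd / S)
  pN <- as.numeric(Nd / N)
  flags <- character()
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    abs(-3 / 4 * log(1 - 4 / 3 * p))
  }
  dS <- jc(pS); dN <- jc(pN)
  if (is.na(dS) || is.na(dN))
    flags <- c(flags, "jukes_cantor_divergent")
  omega <- NA_real_
  if (!is.na(dS) && !is.na(dN)) {
    if (dS == 0) {
      flags <- c(flags, "dS_zero")
    } else {
      omega <- dN / dS
    }
  }
  structure(list(N = as.numeric(N), S = as.numeric(S),
                 Nd = as.numeric(Nd), Sd = as.numeric(Sd),
                 pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                 n_codons = aln$n_codons, flags = flags),
            class = "ng86_result")
}

#' @export
print.ng86_result <- function(x, ...) {
  cat(sprintf("NG86 dN/dS over %d codons\n", x$n_codons))
  cat(sprintf("  N=%.2f S=%.2f Nd=%.2f Sd=%.2f\n", x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  pN=%.4f pS=%.4f dN=%.4f dS=%.4f omega=%s\n",
              x$pN, x$pS,
              ifelse(is.na(x$dN), NaN, x$dN), ifelse(is.na(x$dS), NaN, x$dS),
              ifelse(is.na(x$omega), "undefined", sprintf("%.3f", x$omega))))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
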