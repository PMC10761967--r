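# Independent oracles used across the suite. These deliberately do not share
# code with the package: the aligner oracles are a hand-written affine-gap DP
# and an exhaustive alignment enumerator; the quantile oracle is a manual
# sort-and-interpolate.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

blosum62_x0 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  sm["X", ] <- 0L
  sm[, "X"] <- 0L
  sm
}

# Reference affine-gap global alignment score: memoized three-state recursion
# (match / gap-in-b / gap-in-a), BLAST gap convention: a gap of length L costs
# open + L * ext.
gotoh_score <- function(a, b, sm, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  if (n == 0 && m == 0) return(0)
  if (n == 0) return(-(open + ext * m))
  if (m == 0) return(-(open + ext * n))
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (a residue over gap)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 1:n) X[i + 1, 1] <- -(open + ext * i)
  for (j in 1:m) Y[1, j + 1] <- -(open + ext * j)
  for (i in 1:n) for (j in 1:m) {
    M[i + 1, j + 1] <- sm[ca[i], cb[j]] +
      max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                           X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                           Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration over all gapped alignments (no DP, no memoization);
# only usable for very short sequences. Validates gotoh_score itself.
enum_align_score <- function(a, b, sm, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, sm[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, 0L))
    if (i < n)
      best <- max(best,
                  -(if (prev == 1L) ext else open + ext) + rec(i + 1, j, 1L))
    if (j < m)
      best <- max(best,
                  -(if (prev == 2L) ext else open + ext) + rec(i, j + 1, 2L))
    best
  }
  rec(0L, 0L, 0L)
}

# Type-7 quantile by manual sort and linear interpolation.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Hand-built symmetric identity matrix from a named list of pair values.
make_idm <- function(species, pairs) {
  m <- matrix(100, length(species), length(species),
              dimnames = list(species, species))
  for (k in names(pairs)) {
    sp <- strsplit(k, ":")[[1]]
    m[sp[1], sp[2]] <- m[sp[2], sp[1]] <- pairs[[k]]
  }
  class(m) <- c("identity_matrix", class(m))
  m
}

# Protein records data frame builder.
recs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(accession = r[1], gene_symbol = r[2], species = r[3],
               sequence = r[4], stringsAsFactors = FALSE)))
}
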