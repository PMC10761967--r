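AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_ALPHABET20, "X")

#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a data frame of records with one row per
#' entry. Two header dialects are supported: `"pipe"` headers of the form
#' `accession|gene_symbol|species`, and `"plain"` headers carrying only the
#' accession, in which case gene symbol and species are looked up in a sidecar
#' metadata TSV (columns `accession`, `gene_symbol`, `species`).
#'
#' Sequences are uppercased and a single terminal stop (`*`) is stripped.
#' Only the 20 canonical amino-acid letters plus `X` are accepted.
#'
#' @param path Path to a FASTA file.
#' @param header_format `"pipe"` (default) or `"plain"`.
#' @param metadata For `header_format = "plain"`, path to the metadata TSV.
#' @return A data frame with columns `accession`, `gene_symbol`, `species`,
#'   `sequence`. An empty file yields a zero-row data frame.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1|GENE1|human", "MKTV"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, header_format = c("pipe", "plain"), metadata = NULL) {
  header_format <- match.arg(header_format)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  empty <- data.frame(accession = character(), gene_symbol = character(),
                      species = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0) return(empty)
  headers <- names(aas)
  seqs <- toupper(as.character(aas))
  # strip one terminal stop
  seqs <- sub("\\*$", "", seqs)

  if (header_format == "pipe") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 3L)
    if (length(bad) > 0)
      stop("malformed FASTA header (expected 'accession|gene|species') in entry ",
           bad[1], ": '", headers[bad[1]], "'")
    acc <- vapply(parts, `[`, character(1), 1L)
    gene <- vapply(parts, `[`, character(1), 2L)
    species <- vapply(parts, `[`, character(1), 3L)
  } else {
    if (is.null(metadata))
      stop("header_format = 'plain' requires a 'metadata' TSV path")
    acc <- sub("\\s.*$", "", headers)
    meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    need <- c("accession", "gene_symbol", "species")
    if (!all(need %in% names(meta)))
      stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
    idx <- match(acc, meta$accession)
    if (anyNA(idx))
      stop("accession(s) missing from metadata: ",
           paste(acc[is.na(idx)], collapse = ", "))
    gene <- meta$gene_symbol[idx]
    species <- meta$species[idx]
  }

  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0)
      stop("empty sequence for record '", acc[i], "'")
    chars <- strsplit(seqs[i], "")[[1]]
    illegal <- setdiff(unique(chars), AA_ALLOWED)
    if (length(illegal) > 0)
      stop("illegal residue character(s) ", paste(illegal, collapse = ""),
           " in record '", acc[i], "'")
  }
  data.frame(accession = acc, gene_symbol = gene, species = species,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Writes records (as returned by [read_fasta()]) back to disk using
#' `accession|gene_symbol|species` headers, wrapped at 60 columns.
#'
#' @param records Data frame with columns `accession`, `gene_symbol`,
#'   `species`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  aas <- Biostrings::AAStringSet(records$sequence)
  names(aas) <- paste(records$accession, records$gene_symbol,
                      records$species, sep = "|")
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Select the longest isoform for a gene in a species
#'
#' Among all records matching the given gene symbol and species, returns the
#' one with the longest sequence. Length ties are broken deterministically by
#' the lexicographically smallest accession.
#'
#' @param records Protein record data frame.
#' @param gene Gene symbol (matched case-insensitively).
#' @param species Species tag (matched exactly).
#' @return A one-row record data frame.
#' @export
select_longest_isoform <- function(records, gene, species) {
  hit <- records[toupper(records$gene_symbol) == toupper(gene) &
                 records$species == species, , drop = FALSE]
  if (nrow(hit) == 0)
    stop("no ortholog record for gene '", gene, "' in species '", species, "'")
  len <- nchar(hit$sequence)
  hit <- hit[order(-len, hit$accession), , drop = FALSE]
  hit[1, , drop = FALSE]
}

#' Assemble ortholog groups from protein records
#'
#' Groups records by gene symbol and, for each species of the panel, keeps the
#' longest isoform. Genes missing one or more panel species are still
#' returned; completeness is checked downstream where it matters.
#'
#' @param records Protein record data frame.
#' @param panel Character vector of species tags.
#' @return A named list of `ortholog_group` objects (one per gene symbol).
#' @export
build_ortholog_groups <- function(records, panel) {
  genes <- unique(toupper(records$gene_symbol))
  groups <- lapply(genes, function(g) {
    members <- list()
    for (sp in panel) {
      sub <- records[toupper(records$gene_symbol) == g & records$species == sp, ,
                     drop = FALSE]
      if (nrow(sub) > 0)
        members[[sp]] <- select_longest_isoform(records, g, sp)
    }
    ortholog_group(g, members)
  })
  names(groups) <- genes
  groups
}

#' Construct an ortholog group
#'
#' @param gene_symbol Gene symbol.
#' @param members Named list, species tag -> one-row protein record data frame.
#' @return An object of class `ortholog_group`.
#' @export
ortholog_group <- function(gene_symbol, members) {
  stopifnot(is.list(members))
  if (anyDuplicated(names(members)))
    stop("ortholog group '", gene_symbol, "' has more than one member for a species")
  structure(list(gene_symbol = toupper(gene_symbol), members = members),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat("Ortholog group:", x$gene_symbol, "\n")
  for (sp in names(x$members))
    cat("  ", sp, ": ", x$members[[sp]]$accession, " (",
        nchar(x$members[[sp]]$sequence), " aa)\n", sep = "")
  invisible(x)
}

#' Read a gene list from a TSV file
#'
#' The file must have a `symbol` column; other columns are ignored with a
#' warning. Symbols are uppercased; duplicates (after normalization) are
#' dropped, keeping first occurrence, so file order is preserved.
#'
#' @param path Path to TSV.
#' @param source_name Label for the list (defaults to the file name).
#' @return A `gene_list` object: list with `symbols` and `source_name`.
#' @export
read_gene_list <- function(path, source_name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"symbol" %in% names(df))
    stop("gene list TSV must have a 'symbol' column: ", path)
  extra <- setdiff(names(df), "symbol")
  if (length(extra) > 0)
    warning("ignoring undeclared column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  sym <- toupper(df$symbol)
  sym <- sym[!duplicated(sym)]
  gene_list(sym, source_name)
}

#' Construct a gene list
#' @param symbols Character vector of gene symbols (uppercased, deduplicated).
#' @param source_name Label.
#' @return A `gene_list` object.
#' @export
gene_list <- function(symbols, source_name = "gene_list") {
  sym <- toupper(as.character(symbols))
  sym <- sym[!duplicated(sym)]
  structure(list(symbols = sym, source_name = source_name), class = "gene_list")
}

#' Intersect two gene lists
#'
#' Case-insensitive symbol intersection, preserving the order of the first
#' list. An empty result is valid.
#'
#' @param a,b `gene_list` objects.
#' @return A `gene_list` with the shared symbols in `a`'s order.
#' @export
intersect_gene_lists <- function(a, b) {
  stopifnot(inherits(a, "gene_list"), inherits(b, "gene_list"))
  shared <- a$symbols[a$symbols %in% b$symbols]
  gene_list(shared, paste0(a$source_name, " ∩ ", b$source_name))
}

#' Read an exon partition map from TSV
#'
#' Columns: `label`, `start`, `end` (1-based inclusive residue intervals).
#' A label may span several rows (several intervals). Intervals must lie
#' within `[1, protein_length]` and must not overlap, within or across
#' partitions.
#'
#' @param path Path to TSV.
#' @param protein_length Protein length in residues.
#' @return An `exon_partition_table`: data frame of intervals with the
#'   protein length stored as an attribute.
#' @export
read_exon_map <- function(path, protein_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "start", "end")
  if (!all(need %in% names(df)))
    stop("exon map TSV must have columns: ", paste(need, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra) > 0)
    warning("ignoring undeclared column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  exon_partition_table(df[need], protein_length)
}

#' Construct and validate an exon partition table
#' @param partitions Data frame with columns `label`, `start`, `end`.
#' @param protein_length Protein length in residues.
#' @return Validated `exon_partition_table`.
#' @export
exon_partition_table <- function(partitions, protein_length) {
  stopifnot(is.data.frame(partitions),
            all(c("label", "start", "end") %in% names(partitions)))
  protein_length <- as.integer(protein_length)
  for (i in seq_len(nrow(partitions))) {
    s <- partitions$start[i]; e <- partitions$end[i]
    if (s < 1 || e > protein_length || s > e)
      stop("exon map row ", i, ": interval [", s, ",", e,
           "] outside [1,", protein_length, "] or inverted")
  }
  cov <- integer(protein_length)
  for (i in seq_len(nrow(partitions))) {
    idx <- partitions$start[i]:partitions$end[i]
    if (any(cov[idx] > 0))
      stop("exon map row ", i, ": interval overlaps a previous partition interval")
    cov[idx] <- i
  }
  structure(partitions, protein_length = protein_length,
            class = c("exon_partition_table", "data.frame"))
}

#' Read selection-site calls from TSV
#'
#' Columns: `position` (1-based residue index), `class` (`positive` or
#' `negative`), `method` (e.g. `MEME`, `FEL`, `FUBAR`). The
#' `(position, class, method)` triples must be unique and positions must lie
#' in `[1, protein_length]`.
#'
#' @param path Path to TSV.
#' @param protein_length Protein length in residues.
#' @return A `site_call_set`: data frame of calls with the protein length as
#'   an attribute.
#' @export
read_site_calls <- function(path, protein_length) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "class", "method")
  if (!all(need %in% names(df)))
    stop("site call TSV must have columns: ", paste(need, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra) > 0)
    warning("ignoring undeclared column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  site_call_set(df[need], protein_length)
}

#' Construct and validate a site call set
#' @param calls Data frame with columns `position`, `class`, `method`.
#' @param protein_length Protein length in residues.
#' @return Validated `site_call_set`.
#' @export
site_call_set <- function(calls, protein_length) {
  stopifnot(is.data.frame(calls),
            all(c("position", "class", "method") %in% names(calls)))
  protein_length <- as.integer(protein_length)
  bad <- which(calls$position < 1 | calls$position > protein_length)
  if (length(bad) > 0)
    stop("site call row ", bad[1], ": position ", calls$position[bad[1]],
         " outside [1,", protein_length, "]")
  if (!all(calls$class %in% c("positive", "negative")))
    stop("site call class must be 'positive' or 'negative'")
  key <- paste(calls$position, calls$class, calls$method)
  if (anyDuplicated(key))
    stop("duplicate (position, class, method) row: ",
         key[duplicated(key)][1])
  structure(calls, protein_length = protein_length,
            class = c("site_call_set", "data.frame"))
}

#' Predicted protein mass in kilodaltons
#'
#' Sum of average (isotope-abundance-weighted) residue masses plus one water,
#' the usual "predicted molecular weight" convention, in kDa. `X` and any
#' non-canonical letter are rejected.
#'
#' @param sequence Amino-acid sequence (character scalar).
#' @return Mass in kDa (full precision; round to the nearest integer for the
#'   conventional printed value).
#' @examples
#' protein_mass("G")   # 0.0750666 kDa
#' @export
protein_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET20)
  if (length(bad) > 0)
    stop("protein_mass: disallowed residue letter(s): ",
         paste(bad, collapse = ""))
  seqinr::pmw(chars) / 1000
}
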