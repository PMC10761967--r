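test_that("FASTA round trip preserves records and normalizes sequences", {
  f <- tempfile(fileext = ".fasta")
  r <- recs(c("ACC2", "GENEB", "bovine", paste(rep("ACDEFGHIKL", 10), collapse = "")),
            c("ACC1", "GENEA", "human", "MKTV"))
  write_fasta(r, f)
  back <- read_fasta(f)
  expect_equal(back, r, ignore_attr = TRUE)

  # a second write of the re-read records is byte-identical
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("FASTA parsing uppercases, strips terminal stops, rejects bad input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">P1|G1|human", "mktv*"), f)
  expect_equal(read_fasta(f)$sequence, "MKTV")

  file.create(fe <- tempfile(fileext = ".fasta"))
  expect_equal(nrow(read_fasta(fe)), 0)

  writeLines(c(">P1|G1", "MKTV"), f)
  expect_error(read_fasta(f), "malformed FASTA header")

  writeLines(c(">P1|G1|human", "MKTZV"), f)
  expect_error(read_fasta(f), "illegal residue.*P1")

  writeLines(c(">P1|G1|human", "MKTV", ">P1|G1|bovine", "MKTL"), f)
  expect_error(read_fasta(f), "duplicate accession")
})

test_that("plain headers resolve gene and species through the metadata sidecar", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">XP_1 some description", "MKTV"), f)
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("accession\tgene_symbol\tspecies", "XP_1\tFAM161A\thuman"), meta)
  r <- read_fasta(f, header_format = "plain", metadata = meta)
  expect_equal(r$gene_symbol, "FAM161A")
  expect_equal(r$species, "human")
  expect_error(read_fasta(f, header_format = "plain"), "metadata")
})

test_that("longest isoform selection is maximal, deterministic, and order-invariant", {
  set.seed(42)
  long <- random_aa(700)
  short <- random_aa(644)
  r <- recs(c("XP_006514893", "FAM161A", "house_mouse", short),
            c("XP_006514891", "FAM161A", "house_mouse", long),
            c("NP_001188472", "FAM161A", "human", random_aa(716)))
  pick <- select_longest_isoform(r, "FAM161A", "house_mouse")
  expect_equal(pick$accession, "XP_006514891")
  expect_equal(nchar(pick$sequence), 700)

  # singleton
  expect_equal(select_longest_isoform(r, "FAM161A", "human")$accession,
               "NP_001188472")

  # tie broken by lexicographically smallest accession
  tie <- recs(c("B_ACC", "G", "human", random_aa(100)),
              c("A_ACC", "G", "human", random_aa(100)))
  expect_equal(select_longest_isoform(tie, "G", "human")$accession, "A_ACC")

  # permutation invariance and idempotence
  perm <- r[c(3, 1, 2), ]
  expect_equal(select_longest_isoform(perm, "FAM161A", "house_mouse"),
               pick, ignore_attr = TRUE)
  expect_equal(select_longest_isoform(pick, "FAM161A", "house_mouse"),
               pick, ignore_attr = TRUE)

  expect_error(select_longest_isoform(r, "FAM161A", "bovine"),
               "FAM161A.*bovine")
})

test_that("gene list intersection is case-insensitive and preserves order", {
  a <- gene_list(c("A", "B"), "a")
  b <- gene_list(c("b", "C"), "b")
  expect_equal(intersect_gene_lists(a, b)$symbols, "B")
  expect_equal(intersect_gene_lists(gene_list(character()), a)$symbols,
               character())

  # 10-symbol lists with known overlap, against exhaustive membership
  set.seed(7)
  s1 <- paste0("GENE", sample(1:30, 10))
  s2 <- c(sample(s1, 4), paste0("OTHER", 1:6))
  g1 <- gene_list(s1); g2 <- gene_list(tolower(s2))
  got <- intersect_gene_lists(g1, g2)$symbols
  want <- s1[vapply(s1, function(x) x %in% toupper(s2), logical(1))]
  expect_equal(got, want)
  expect_length(got, 4)
})

test_that("gene list reader requires the symbol column and warns on extras", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("symbol\tnote", "fam161a\tx", "POC5\ty", "FAM161A\tz"), f)
  expect_warning(gl <- read_gene_list(f), "undeclared column")
  expect_equal(gl$symbols, c("FAM161A", "POC5"))
  writeLines(c("name", "FAM161A"), f)
  expect_error(suppressWarnings(read_gene_list(f)), "symbol")
})

test_that("exon partition tables validate ranges and overlap", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("label\tstart\tend",
               "shared\t1\t575",
               "type_specific\t576\t700"), f)
  tab <- read_exon_map(f, 700)
  expect_equal(attr(tab, "protein_length"), 700L)
  expect_equal(sum(tab$end - tab$start + 1), 700)

  writeLines(c("label\tstart\tend", "a\t1\t100", "b\t100\t200"), f)
  expect_error(read_exon_map(f, 200), "overlap")
  writeLines(c("label\tstart\tend", "a\t0\t100"), f)
  expect_error(read_exon_map(f, 200), "outside")
  writeLines(c("label\tstart\tend", "a\t1\t300"), f)
  expect_error(read_exon_map(f, 200), "outside")
})

test_that("site call sets validate positions, classes and uniqueness", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("position\tclass\tmethod", "10\tpositive\tMEME",
               "10\tnegative\tFEL"), f)
  sc <- read_site_calls(f, 100)
  expect_equal(nrow(sc), 2)

  writeLines(c("position\tclass\tmethod", "0\tpositive\tMEME"), f)
  expect_error(read_site_calls(f, 100), "outside")
  writeLines(c("position\tclass\tmethod", "10\tpositive\tMEME",
               "10\tpositive\tMEME"), f)
  expect_error(read_site_calls(f, 100), "duplicate")
  writeLines(c("position\tclass\tmethod", "10\tweird\tMEME"), f)
  expect_error(read_site_calls(f, 100), "positive.*negative")
})

test_that("protein mass follows the average-mass convention and is additive", {
  expect_equal(protein_mass("G"), 0.0750666, tolerance = 1e-6)
  expect_equal(protein_mass("GG"), 0.1321179, tolerance = 1e-6)

  # additivity: mass(s1 + s2) = mass(s1) + mass(s2) - water
  water_kda <- 0.0180153
  set.seed(3)
  for (i in 1:5) {
    s1 <- random_aa(sample(5:50, 1))
    s2 <- random_aa(sample(5:50, 1))
    expect_equal(protein_mass(paste0(s1, s2)),
                 protein_mass(s1) + protein_mass(s2) - water_kda,
                 tolerance = 1e-6)
  }

  expect_error(protein_mass("GXG"), "disallowed")
  expect_error(protein_mass("G1G"), "disallowed")
})

test_that("ortholog group assembly keeps one longest isoform per species", {
  set.seed(9)
  r <- recs(c("A1", "G1", "human", random_aa(50)),
            c("A2", "G1", "human", random_aa(80)),
            c("A3", "G1", "bovine", random_aa(60)),
            c("A4", "G2", "human", random_aa(40)))
  groups <- build_ortholog_groups(r, c("human", "bovine"))
  expect_named(groups, c("G1", "G2"))
  expect_equal(groups$G1$members$human$accession, "A2")
  expect_equal(names(groups$G1$members), c("human", "bovine"))
  expect_equal(names(groups$G2$members), "human")  # incomplete is allowed here
})
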