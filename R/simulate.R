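# Synthetic ortholog families and codon alignments with known ground truth.
#
# The protein model is deliberately simple: along a branch of effective length
# d (expected substitutions per site, times any branch multiplier), each site
# receives Poisson(d) substitution events, each replacing the residue
# uniformly among the other 19. This gives a closed-form expected identity
# between two leaves at total path length d:
#     P(identical) = 1/20 + (19/20) * exp(-20 d / 19)
# which the tests use as an exact oracle.

#' Default four-species toy tree
#'
#' A Glires-consistent topology: house mouse and rabbit group together, then
#' human, with bovine as the outgroup. Branch lengths are expected
#' substitutions per site and are chosen so the human-to-mouse path (0.20) is
#' shorter than the human-to-bovine path (0.22): under equal rates a screened
#' protein is then expected to have an Identity Ratio above 1, and only
#' focal-lineage acceleration pushes it below.
#'
#' @return An \pkg{ape} `phylo` tree with leaves `human`, `rabbit`,
#'   `house_mouse`, `bovine`.
#' @export
default_species_tree <- function() {
  ape::read.tree(
    text = "((human:0.09,(rabbit:0.08,house_mouse:0.09):0.02):0.02,bovine:0.11);")
}

#' Branch keys of a tree
#'
#' Every branch is identified by its child end: the tip label for terminal
#' branches, `"node<N>"` (ape node number) for internal branches. These keys
#' name entries of the branch-rate multiplier vector.
#'
#' @param tree A `phylo` tree.
#' @return Character vector, one key per edge (in `tree$edge` order).
#' @export
branch_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  vapply(tree$edge[, 2], function(child) {
    if (child <= ntip) tree$tip.label[child] else paste0("node", child)
  }, character(1))
}

.check_rates <- function(tree, rates) {
  if (is.null(rates)) return(invisible())
  keys <- branch_keys(tree)
  unknown <- setdiff(names(rates), keys)
  if (length(unknown) > 0)
    stop("unknown branch key(s) in rates: ", paste(unknown, collapse = ", "),
         " (valid: ", paste(keys, collapse = ", "), ")")
  if (any(rates <= 0)) stop("branch rate multipliers must be > 0")
  invisible()
}

# Evolve an integer-coded sequence (values 1..20) along a branch of effective
# length d under the uniform-replacement Poisson model.
.evolve_uniform <- function(seq_int, d) {
  if (d <= 0) return(seq_int)
  k <- rpois(length(seq_int), d)
  while (any(k > 0)) {
    idx <- which(k > 0)
    jump <- sample.int(19, length(idx), replace = TRUE)
    seq_int[idx] <- ((seq_int[idx] - 1 + jump) %% 20) + 1
    k[idx] <- k[idx] - 1
  }
  seq_int
}

#' Simulate one ortholog protein family along a species tree
#'
#' The root sequence is uniform over the 20 residues; each branch applies the
#' uniform-replacement Poisson model with effective length
#' `branch length * multiplier`. Identical seeds give identical output.
#'
#' @param tree A `phylo` species tree.
#' @param length Protein length in residues (>= 1).
#' @param rates Optional named numeric vector of branch multipliers, keyed as
#'   in [branch_keys()]; unnamed branches default to 1.
#' @param gene_symbol Symbol used for the emitted records.
#' @param seed Optional integer seed.
#' @return List with `group` (an `ortholog_group` with one member per leaf)
#'   and `truth` (list: `multipliers` per branch key, `seed`).
#' @export
simulate_protein_family <- function(tree, length, rates = NULL,
                                    gene_symbol = "SIMGENE", seed = NULL) {
  stopifnot(length >= 1)
  .check_rates(tree, rates)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parent precedes child
  keys <- branch_keys(tree)
  mult <- setNames(rep(1, nrow(tree$edge)), keys)
  if (!is.null(rates)) mult[names(rates)] <- rates

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(20, length, replace = TRUE)
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    d <- tree$edge.length[i] * mult[i]
    seqs[[child]] <- .evolve_uniform(seqs[[parent]], d)
  }
  members <- list()
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    members[[sp]] <- data.frame(
      accession = paste0("SIM_", gene_symbol, "_", sp),
      gene_symbol = gene_symbol, species = sp,
      sequence = paste(AA_ALPHABET20[seqs[[t]]], collapse = ""),
      stringsAsFactors = FALSE)
  }
  list(group = ortholog_group(gene_symbol, members),
       truth = list(multipliers = mult, seed = seed))
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_root_codons <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, .STOP_CODONS)
  sample(sense, n_codons, replace = TRUE)
}

# Evolve codons along a branch: nucleotide proposals arrive as a Poisson
# process (expected d per nucleotide site) with transition bias kappa;
# proposals creating stops are rejected; nonsynonymous proposals are accepted
# with probability min(1, omega) of the site's class.
.evolve_codons <- function(codons, d, kappa, site_omega, gc) {
  n_nt <- 3L * length(codons)
  n_events <- rpois(1, d * n_nt)
  if (n_events == 0) return(codons)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (e in seq_len(n_events)) {
    pos <- sample.int(n_nt, 1)
    ci <- (pos - 1L) %/% 3L + 1L
    off <- (pos - 1L) %% 3L + 1L
    cod <- codons[ci]
    base <- substr(cod, off, off)
    target <- if (runif(1) < kappa / (kappa + 2)) {
      transitions[[base]]
    } else {
      sample(transversions[[base]], 1)
    }
    new_cod <- cod
    substr(new_cod, off, off) <- target
    if (new_cod %in% .STOP_CODONS) next
    if (gc[[new_cod]] != gc[[cod]] && runif(1) >= min(1, site_omega[ci])) next
    codons[ci] <- new_cod
  }
  codons
}

#' Simulate a codon-level ortholog family with per-site selection classes
#'
#' Each codon site is assigned an omega class at the root (drawn once, fixed
#' along the whole tree). Along each branch, nucleotide proposals arrive at
#' rate `branch length` per nucleotide site with transition/transversion bias
#' `kappa`; proposals creating stop codons are rejected and nonsynonymous
#' proposals are accepted with probability `min(1, omega)`.
#'
#' @param tree A `phylo` species tree.
#' @param n_codons Number of codons (>= 1).
#' @param kappa Transition/transversion rate ratio (default 1, the regime the
#'   counting dN/dS estimator assumes).
#' @param omega_classes Data frame with columns `omega` (>= 0) and `prop`
#'   (proportions summing to 1).
#' @param seed Optional integer seed.
#' @return List with `sequences` (named character, one coding sequence per
#'   leaf) and `truth` (list: `site_class` index per codon, `site_omega`,
#'   `omega_classes`, `seed`).
#' @export
simulate_codon_family <- function(tree, n_codons, kappa = 1,
                                  omega_classes = data.frame(omega = 1, prop = 1),
                                  seed = NULL) {
  if (n_codons < 1) stop("n_codons must be >= 1")
  stopifnot(is.data.frame(omega_classes),
            all(c("omega", "prop") %in% names(omega_classes)))
  if (any(omega_classes$omega < 0)) stop("omega values must be >= 0")
  if (sum(omega_classes$prop) <= 0) stop("omega class proportions are all zero")
  if (abs(sum(omega_classes$prop) - 1) > 1e-8)
    stop("omega class proportions must sum to 1")
  if (kappa <= 0) stop("kappa must be > 0")
  if (!is.null(seed)) set.seed(seed)
  gc <- .genetic_code()
  tree <- ape::reorder.phylo(tree, "cladewise")

  site_class <- sample.int(nrow(omega_classes), n_codons, replace = TRUE,
                           prob = omega_classes$prop)
  site_omega <- omega_classes$omega[site_class]

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cods <- vector("list", nnode)
  cods[[ntip + 1L]] <- .random_root_codons(n_codons)
  for (i in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    cods[[child]] <- .evolve_codons(cods[[parent]], tree$edge.length[i],
                                    kappa, site_omega, gc)
  }
  sequences <- setNames(
    vapply(seq_len(ntip), function(t) paste(cods[[t]], collapse = ""),
           character(1)),
    tree$tip.label)
  list(sequences = sequences,
       truth = list(site_class = site_class, site_omega = site_omega,
                    omega_classes = omega_classes, seed = seed))
}

#' Extract a pairwise codon alignment from a codon-family simulation
#' @param sim Result of [simulate_codon_family()].
#' @param a,b Leaf names.
#' @return A `codon_alignment`.
#' @export
sim_codon_pair <- function(sim, a, b) {
  stopifnot(all(c(a, b) %in% names(sim$sequences)))
  codon_alignment(sim$sequences[[a]], sim$sequences[[b]])
}

#' Generate a synthetic divergence-screen dataset
#'
#' The synthetic twin of a proteome-scale screen: `n_genes` ortholog families
#' evolve along the tree; a fraction of genes (drawn without replacement)
#' carry a rate multiplier on the focal species' terminal branch. Per-gene
#' FASTA files, a truth TSV and a run manifest are written when `dir` is
#' given.
#'
#' @param n_genes Number of genes (>= 4; the screen fence is undefined below
#'   that).
#' @param frac_accelerated Fraction of genes with focal-branch acceleration,
#'   in `[0, 1]`.
#' @param acceleration Multiplier (>= 1) applied to the focal terminal branch
#'   of accelerated genes.
#' @param tree Species tree (default [default_species_tree()]).
#' @param length Protein length in residues (default 300).
#' @param focal Focal species tip label.
#' @param seed Optional integer seed; per-gene seeds are derived as
#'   `seed + gene index`.
#' @param dir Optional output directory for FASTA/truth/manifest files.
#' @return List with `groups` (list of `ortholog_group`), `truth` (data frame:
#'   `gene_symbol`, `accelerated`, `multiplier`, `seed`), and `dir`.
#' @export
generate_screen_dataset <- function(n_genes, frac_accelerated = 0.2,
                                    acceleration = 2,
                                    tree = default_species_tree(),
                                    length = 300, focal = "house_mouse",
                                    seed = NULL, dir = NULL) {
  if (n_genes < 4) stop("n_genes must be >= 4 (screen fence undefined below)")
  stopifnot(frac_accelerated >= 0, frac_accelerated <= 1, acceleration >= 1)
  if (!focal %in% tree$tip.label)
    stop("focal species '", focal, "' is not a leaf of the tree")
  if (!is.null(seed)) set.seed(seed)
  n_acc <- round(frac_accelerated * n_genes)
  acc_idx <- if (n_acc > 0) sort(sample.int(n_genes, n_acc)) else integer()

  groups <- vector("list", n_genes)
  truth <- data.frame(gene_symbol = sprintf("SIMG%04d", seq_len(n_genes)),
                      accelerated = seq_len(n_genes) %in% acc_idx,
                      multiplier = 1, seed = NA_integer_,
                      stringsAsFactors = FALSE)
  truth$multiplier[truth$accelerated] <- acceleration
  for (i in seq_len(n_genes)) {
    gseed <- if (is.null(seed)) NULL else seed + i
    truth$seed[i] <- if (is.null(gseed)) NA_integer_ else gseed
    rates <- if (truth$accelerated[i])
      setNames(acceleration, focal) else NULL
    sim <- simulate_protein_family(tree, length, rates,
                                   gene_symbol = truth$gene_symbol[i],
                                   seed = gseed)
    groups[[i]] <- sim$group
  }
  names(groups) <- truth$gene_symbol

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_genes)) {
      recs <- do.call(rbind, groups[[i]]$members)
      write_fasta(recs, file.path(dir, paste0(truth$gene_symbol[i], ".fasta")))
    }
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- c(
      paste0("tree=", ape::write.tree(tree)),
      paste0("n_genes=", n_genes),
      paste0("frac_accelerated=", frac_accelerated),
      paste0("acceleration=", acceleration),
      paste0("length=", length),
      paste0("focal=", focal),
      paste0("seed=", if (is.null(seed)) "NA" else seed))
    writeLines(manifest, file.path(dir, "manifest.txt"))
  }
  list(groups = groups, truth = truth, dir = dir)
}
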