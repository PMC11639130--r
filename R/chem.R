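# SMILES ingestion and featurization.
#
# Parsing, canonicalization, valence perception and SMARTS matching are
# delegated to the ChemmineR / ChemmineOB (OpenBabel) stack; this file
# turns their output into the light-weight molecule records the learning
# modules consume.

.re_cache <- new.env(parent = emptyenv())

#' Clear the package-level molecule cache
#'
#' Parsed molecules are memoized by canonical SMILES so that training,
#' ranking and feature export do not re-run substructure perception.
#' @return invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.re_cache))
  rm(list = ls(.re_cache), envir = .re_cache)
  invisible(n)
}

ob_canonical <- function(smiles) {
  key <- paste0("can:", smiles)
  hit <- .re_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) {
    stop_input("cannot parse SMILES: '", smiles, "'")
  }
  .re_cache[[key]] <- out
  out
}

# Batch canonicalization (one OpenBabel call for all cache misses).
# Only safe for SMILES known to be valid — invalid entries would
# misalign the output lines — so callers with untrusted input use
# ob_canonical() per molecule instead.
ob_canonical_batch <- function(smiles) {
  keys <- paste0("can:", smiles)
  miss <- which(vapply(keys, function(k) is.null(.re_cache[[k]]),
                       logical(1)))
  if (length(miss)) {
    um <- unique(smiles[miss])
    out <- ChemmineOB::convertFormat("SMI", "CAN",
                                     paste(um, collapse = "\n"))
    lines <- sub("[\t ].*$", "", strsplit(out, "\n", fixed = TRUE)[[1]])
    lines <- lines[nzchar(lines)]
    if (length(lines) != length(um)) {
      stop_input("batch canonicalization misaligned; invalid SMILES?")
    }
    for (i in seq_along(um)) .re_cache[[paste0("can:", um[i])]] <- lines[i]
  }
  vapply(smiles, ob_canonical, character(1), USE.NAMES = FALSE)
}

# Read the V2000 counts/atom/bond block that OpenBabel emits.  Only used
# for zero-bond molecules (single atoms, ionic fragments), which
# ChemmineR's SDF reader refuses; bonded molecules go through ChemmineR.
molfile_block <- function(smiles) {
  txt <- tryCatch(ChemmineOB::convertFormat("SMI", "SDF", smiles),
                  error = function(e) "")
  if (!nzchar(txt)) stop_input("cannot parse SMILES: '", smiles, "'")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  atoms <- lines[4 + seq_len(natoms)]
  elements <- trimws(substr(atoms, 32, 34))
  chg_code <- as.integer(substr(atoms, 37, 39))
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charges <- ifelse(chg_code %in% names(code_map),
                    code_map[as.character(chg_code)], 0L)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    fields <- as.integer(strsplit(trimws(substr(cl, 10, nchar(cl))), "\\s+")[[1]])
    k <- fields[1]
    for (i in seq_len(k)) {
      charges[fields[2 * i]] <- fields[2 * i + 1]
    }
  }
  edges <- matrix(integer(), 0, 3)
  if (nbonds > 0) {
    bl <- lines[4 + natoms + seq_len(nbonds)]
    edges <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  list(elements = elements, charges = as.integer(charges), edges = edges)
}

# standard organic-subset valences used to infer implicit hydrogen counts
.std_valence <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                  F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, Si = 4L, H = 1L)

implicit_h <- function(elements, used_valence, charges) {
  rule <- .std_valence[elements]
  rule[is.na(rule)] <- 0L
  # cations of N/P/O/S gain a bonding site, anions lose one; for carbon
  # and the rest both signs reduce the hydrogen count
  adj <- ifelse(elements %in% c("N", "P", "O", "S"), charges, -abs(charges))
  pmax(0L, as.integer(rule + adj - used_valence))
}

molecule_graph <- function(canonical) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(canonical, "m"))),
    error = function(e) NULL)
  valid <- !is.null(sdf) && isTRUE(ChemmineR::validSDF(sdf)[1])
  if (!valid) {
    # zero-bond molecules (e.g. "C", "[Na+].[Cl-]") land here
    blk <- molfile_block(canonical)
    n <- length(blk$elements)
    used <- integer(n)
    if (nrow(blk$edges)) {
      for (k in seq_len(nrow(blk$edges))) {
        used[blk$edges[k, 1]] <- used[blk$edges[k, 1]] + blk$edges[k, 3]
        used[blk$edges[k, 2]] <- used[blk$edges[k, 2]] + blk$edges[k, 3]
      }
    }
    return(list(elements = blk$elements,
                charges = blk$charges,
                aromatic = rep(FALSE, n),
                h_counts = implicit_h(blk$elements, used, blk$charges),
                edges = blk$edges[, 1:2, drop = FALSE]))
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bb <- ChemmineR::bondblock(mol)
  edges <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  vt <- ChemmineR::bonds(mol, type = "bonds")
  aromatic <- rep(FALSE, n)
  rg <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (!is.null(rg) && length(rg$RINGS)) {
    for (i in seq_along(rg$RINGS)) {
      if (isTRUE(rg$AROMATIC[[i]])) {
        idx <- as.integer(sub(".*_", "", rg$RINGS[[i]]))
        aromatic[idx] <- TRUE
      }
    }
  }
  list(elements = elements,
       charges = as.integer(vt$charge),
       aromatic = aromatic,
       h_counts = implicit_h(elements, as.integer(vt$Nbondcount),
                             as.integer(vt$charge)),
       edges = edges)
}

#' Atom feature vocabulary
#'
#' Frozen one-hot vocabularies for the four atom-feature families:
#' element type, formal charge, aromaticity, and attached-hydrogen count.
#' Out-of-vocabulary elements, charges and hydrogen counts fall into a
#' reserved overflow slot, so featurization never fails.
#'
#' @param elements character vector of in-vocabulary element symbols.
#' @param charges integer vector of in-vocabulary formal charges.
#' @param h_counts integer vector of in-vocabulary hydrogen counts.
#' @return an object of class `re_vocab`; its `dim` field is the total
#'   feature width F0 (one slot per vocabulary entry plus one overflow
#'   slot for elements, charges and hydrogen counts, plus a two-slot
#'   aromatic flag).
#' @export
feature_vocab <- function(elements = c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"),
                          charges = -2:2,
                          h_counts = 0:4) {
  v <- list(elements = elements, charges = as.integer(charges),
            h_counts = as.integer(h_counts),
            dim = length(elements) + 1L + length(charges) + 1L + 2L +
              length(h_counts) + 1L)
  class(v) <- "re_vocab"
  v
}

one_hot_block <- function(values, vocab_values) {
  k <- length(vocab_values) + 1L     # last slot = unknown/overflow
  idx <- match(values, vocab_values)
  idx[is.na(idx)] <- k
  out <- matrix(0, length(values), k)
  out[cbind(seq_along(values), idx)] <- 1
  out
}

#' One-hot atom feature matrix
#'
#' Each atom is encoded as the concatenation of four one-hot blocks:
#' element, formal charge, aromatic flag (`[1,0]` = non-aromatic,
#' `[0,1]` = aromatic), and hydrogen count.  Every row therefore has
#' exactly four ones.
#'
#' @param molecule a molecule from [parse_molecule()].
#' @param vocab a [feature_vocab()].
#' @return a numeric 0/1 matrix with one row per atom and
#'   `vocab$dim` columns.
#' @export
featurize_atoms <- function(molecule, vocab = feature_vocab()) {
  g <- molecule$graph
  arom <- cbind(as.numeric(!g$aromatic), as.numeric(g$aromatic))
  cbind(one_hot_block(g$elements, vocab$elements),
        one_hot_block(g$charges, vocab$charges),
        arom,
        one_hot_block(g$h_counts, vocab$h_counts))
}

#' Functional-group substructure patterns
#'
#' Reads a TSV catalog of named SMARTS patterns.  The default catalog
#' shipped with the package contains 39 common functional-group families
#' (hydroxyl, carboxylic acid, ester, amine, halogens, ...) and can be
#' replaced with any file of the same two-column `name<TAB>SMARTS`
#' layout.
#'
#' @param path path to a pattern TSV; defaults to the shipped catalog.
#' @return a tibble with columns `name` and `smarts`.
#' @export
read_fg_patterns <- function(path = default_fg_pattern_file()) {
  pat <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(pat))) {
    stop_input("pattern file must have columns 'name' and 'smarts'")
  }
  tibble::as_tibble(pat)
}

#' @rdname read_fg_patterns
#' @export
default_fg_pattern_file <- function() {
  system.file("extdata", "functional_groups.tsv", package = "reactembed",
              mustWork = TRUE)
}

fg_counts <- function(canonical, patterns) {
  counts <- ChemmineOB::forEachMol("SMILES", canonical, function(mol) {
    vapply(patterns$smarts,
           function(p) ChemmineOB::smartsSearch_OB(list(mol), p,
                                                   uniqueMatches = TRUE),
           numeric(1), USE.NAMES = FALSE)
  })
  # disconnected SMILES yield one OBMol per fragment; counts are additive
  out <- Reduce(`+`, counts)
  stats::setNames(as.integer(out), patterns$name)
}

#' Count functional-group occurrences
#'
#' Entry *k* of the returned vector is the number of (unique) matches of
#' SMARTS pattern *k* in the molecule.  This count vector is the initial
#' node feature of the molecule in the reaction-aware graph, i.e. the sum
#' of the one-hot embeddings of all functional groups present.
#'
#' @inheritParams featurize_atoms
#' @param fg_patterns a pattern tibble from [read_fg_patterns()].
#' @return a named non-negative integer vector, one entry per pattern.
#' @export
featurize_functional_groups <- function(molecule,
                                        fg_patterns = read_fg_patterns()) {
  fg_counts(molecule$canonical_smiles, fg_patterns)
}

#' Parse a molecule from SMILES
#'
#' Canonicalizes the SMILES, extracts the molecular graph (heavy atoms
#' and bonds; hydrogens are implicit and appear only as per-atom counts),
#' computes the 39-entry functional-group count vector, and records the
#' heavy-atom bond count and ring count (cyclomatic number).
#'
#' @param smiles a single SMILES string.
#' @param fg_patterns functional-group catalog, see [read_fg_patterns()].
#' @param vocab atom feature vocabulary, see [feature_vocab()].
#' @return an object of class `re_molecule` with fields
#'   `canonical_smiles`, `graph` (elements, charges, aromatic flags,
#'   hydrogen counts, edge matrix, atom feature matrix), `fg_vector`,
#'   `bond_count` and `ring_count`.
#' @examples
#' \donttest{
#' m <- parse_molecule("CCO")
#' m$bond_count     # 2 heavy-atom bonds
#' m$ring_count     # 0
#' }
#' @export
parse_molecule <- function(smiles, fg_patterns = read_fg_patterns(),
                           vocab = feature_vocab()) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop_input("'smiles' must be a single non-empty string")
  }
  canonical <- ob_canonical(smiles)
  key <- paste0(canonical, "#", paste(fg_patterns$smarts, collapse = ","))
  if (!is.null(.re_cache[[key]])) return(.re_cache[[key]])
  g <- molecule_graph(canonical)
  n <- length(g$elements)
  edges <- g$edges
  if (nrow(edges)) {
    # undirected, deduplicated, low index first
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
  }
  mol <- list(
    canonical_smiles = canonical,
    graph = c(g[c("elements", "charges", "aromatic", "h_counts")],
              list(edges = edges)),
    fg_vector = fg_counts(canonical, fg_patterns),
    bond_count = nrow(edges),
    ring_count = nrow(edges) - n + graph_components(n, edges))
  mol$graph$atom_features <- featurize_atoms(mol, vocab)
  class(mol) <- "re_molecule"
  .re_cache[[key]] <- mol
  mol
}

#' Parse a batch of SMILES into a molecule table
#'
#' @param smiles character vector of SMILES strings.
#' @inheritParams parse_molecule
#' @return a tibble with one row per input: `smiles`, `canonical_smiles`,
#'   `bond_count`, `ring_count`, `n_atoms`, and a list-column `molecule`
#'   holding the full [parse_molecule()] records.
#' @export
parse_molecules <- function(smiles, fg_patterns = read_fg_patterns(),
                            vocab = feature_vocab()) {
  mols <- lapply(smiles, parse_molecule, fg_patterns = fg_patterns,
                 vocab = vocab)
  tibble::tibble(
    smiles = smiles,
    canonical_smiles = vapply(mols, `[[`, character(1), "canonical_smiles"),
    bond_count = vapply(mols, `[[`, integer(1), "bond_count"),
    ring_count = vapply(mols, `[[`, integer(1), "ring_count"),
    n_atoms = vapply(mols, function(m) length(m$graph$elements), integer(1)),
    molecule = mols)
}

#' @export
print.re_molecule <- function(x, ...) {
  cat("<molecule> ", x$canonical_smiles, "\n",
      "  atoms: ", length(x$graph$elements),
      "  bonds: ", x$bond_count,
      "  rings: ", x$ring_count,
      "  functional groups: ", sum(x$fg_vector > 0), "\n", sep = "")
  invisible(x)
}
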