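# Synthetic reaction corpora.
#
# Molecules come from a small template grammar (alkyl fragments combined
# into alkanes, alcohols, acids, esters, terminal alkenes, cyclic ethers
# and diols), and reactions from four template families with
# family-constant bond/ring-count changes:
#
#   hydration        alkene + water  -> alcohol          (dNB +1, dNR  0)
#   ring_opening     cyclic ether + water -> diol        (dNB  0, dNR -1)
#   esterification   alcohol + acid  -> ester + water    (dNB  0, dNR  0)
#   cyclization      diol -> cyclic ether + water        (dNB  0, dNR +1)
#
# Product overlap (second-order neighbor structure in the reaction-aware
# graph) is injected through transesterifications that produce an ester
# some base esterification already produces.  Everything is valid
# SMILES by construction and deterministic per seed.

# integer partitions with at most `max_parts` parts (carbon valence:
# a fragment atom bonds its parent or the attachment point, so at most
# three subtrees hang off any atom)
partitions_of <- function(n, max_parts = 3) {
  if (n == 0) return(list(integer()))
  out <- list()
  recurse <- function(rest, maxpart, parts_left, acc) {
    if (rest == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    if (parts_left == 0) return(invisible())
    for (p in seq_len(min(rest, maxpart))) {
      recurse(rest - p, p, parts_left - 1, c(acc, p))
    }
  }
  recurse(n, n, max_parts, integer())
  out
}

# All rooted carbon trees with k atoms as SMILES fragments whose first
# atom is the attachment point.
rooted_alkyls <- local({
  cache <- list()
  gen <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- if (k == 1) "C" else {
      out <- character()
      for (part in partitions_of(k - 1)) {
        choice_sets <- lapply(part, gen)
        combos <- expand.grid(choice_sets, stringsAsFactors = FALSE)
        for (r in seq_len(nrow(combos))) {
          kids <- sort(unlist(combos[r, ], use.names = FALSE))
          n <- length(kids)
          smi <- paste0("C",
                        if (n > 1) paste0("(", kids[-n], ")", collapse = "") else "",
                        kids[n])
          out <- c(out, smi)
        }
      }
      unique(out)
    }
    cache[[key]] <<- res
    res
  }
  gen
})

alkyl_fragments <- function(max_carbons = 9) {
  unlist(lapply(seq_len(max_carbons), rooted_alkyls))
}

# ring/diol partner construction: substituent R (attached through its
# root atom) sits on the ring carbon adjacent to the ether oxygen, and
# the ring opens at that C-O bond
ring_pair <- function(R, size = c("oxetane", "thf", "thp")) {
  size <- match.arg(size)
  core <- switch(size, oxetane = "CCO", thf = "CCCO", thp = "CCCCO")
  c(ring = paste0("C1(", R, ")", core, "1"),
    diol = paste0("C(O)(", R, ")", core))
}

.family_names <- c("hydration", "ring_opening", "esterification",
                   "cyclization")

#' Specification of a synthetic reaction corpus
#'
#' @param n_molecules size of the molecule universe (>= 4).
#' @param n_reactions number of reactions to generate.
#' @param max_side_size maximum molecules per reaction side (the
#'   template families use at most 2).
#' @param overlap_degree number of transesterification companions that
#'   share a product with a base esterification, creating second-order
#'   neighbors in the reaction-aware graph; requires the esterification
#'   family.
#' @param family_count how many of the four template families to use
#'   (in the order hydration, ring opening, esterification,
#'   cyclization); each family has a distinct bond/ring-change
#'   signature except that transesterifications share the
#'   esterification signature.
#' @param seed integer seed; generation is fully deterministic.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 60, n_reactions = 100,
                         max_side_size = 2, overlap_degree = 0,
                         family_count = 4, seed = 1) {
  stopifnot(n_molecules >= 4, is_count(n_reactions), max_side_size >= 1,
            overlap_degree >= 0, family_count >= 1, family_count <= 4,
            overlap_degree <= n_reactions)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_reactions = as.integer(n_reactions),
                 max_side_size = as.integer(max_side_size),
                 overlap_degree = as.integer(overlap_degree),
                 family_count = as.integer(family_count),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate the molecule universe of a fixture
#'
#' Draws `n_molecules` valid SMILES from the template grammar:
#' water, a few alkanes, and role-bearing molecules (alcohols, acids,
#' terminal alkenes, cyclic ethers with their ring-opened diol partners)
#' allocated according to the reaction families the spec selects.
#'
#' @param spec a [fixture_spec()].
#' @return a tibble with columns `smiles`, `role` and `partner`
#'   (ring-opened partner for cyclic ethers and vice versa, `NA`
#'   otherwise).
#' @export
generate_molecule_universe <- function(spec) {
  fams <- .family_names[seq_len(spec$family_count)]
  alkyls <- with_seed(spec$seed, sample(alkyl_fragments()))
  # role quotas: one share per role a selected family consumes
  roles <- c(if ("hydration" %in% fams) "alkene",
             if ("ring_opening" %in% fams || "cyclization" %in% fams) "ring",
             if ("esterification" %in% fams) c("alcohol", "acid"))
  budget <- spec$n_molecules - 1L          # water is always included
  n_alkane <- min(2L, max(0L, budget - 2L * length(roles)))
  budget <- budget - n_alkane
  quota <- rep(budget %/% length(roles), length(roles))
  quota[seq_len(budget %% length(roles))] <-
    quota[seq_len(budget %% length(roles))] + 1L
  names(quota) <- roles

  rows <- list(tibble::tibble(smiles = "O", role = "water",
                              partner = NA_character_))
  take <- function(n) {
    out <- utils::head(alkyls, n)
    alkyls <<- alkyls[-seq_len(min(n, length(alkyls)))]
    out
  }
  if (n_alkane > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      smiles = take(n_alkane), role = "alkane", partner = NA_character_)
  }
  if ("ring" %in% roles) {
    n <- quota[["ring"]]
    sizes <- rep(c("thf", "oxetane", "thp"), length.out = n)
    rs <- take(n)
    pr <- mapply(function(R, sz) ring_pair(R, sz), rs, sizes)
    rows[[length(rows) + 1]] <- tibble::tibble(
      smiles = pr["ring", ], role = "ring", partner = pr["diol", ])
  }
  if ("alkene" %in% roles) {
    rs <- take(quota[["alkene"]])
    rows[[length(rows) + 1]] <- tibble::tibble(
      smiles = paste0("C=C", rs), role = "alkene",
      partner = paste0("CC(O)", rs))       # hydration product
  }
  if ("alcohol" %in% roles) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      smiles = paste0("O", take(quota[["alcohol"]])), role = "alcohol",
      partner = NA_character_)
  }
  if ("acid" %in% roles) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      smiles = paste0("OC(=O)", take(quota[["acid"]])), role = "acid",
      partner = NA_character_)
  }
  dplyr::bind_rows(rows)
}

ester_smiles <- function(alcohol, acid) {
  # alcohol "O<Ra>", acid "OC(=O)<Rc>"  ->  ester "O=C(O<Ra>)<Rc>"
  ra <- sub("^O", "", alcohol)
  rc <- sub("^OC\\(=O\\)", "", acid)
  paste0("O=C(O", ra, ")", rc)
}

#' Generate a synthetic reaction set
#'
#' Assembles `n_reactions` reactions from the spec's template families
#' (quotas as equal as capacity allows; esterification absorbs deficits
#' of the other families).  `overlap_degree` of them are
#' transesterifications that share their ester product with a base
#' esterification.  Reaction labels are the family index (1 hydration,
#' 2 ring opening, 3 esterification incl. transesterification,
#' 4 cyclization).
#'
#' @param spec a [fixture_spec()].
#' @param universe optionally a pre-generated
#'   [generate_molecule_universe()] tibble.
#' @return a reaction tibble in [read_reaction_file()] layout (all
#'   SMILES canonical).
#' @export
generate_reaction_set <- function(spec, universe = generate_molecule_universe(spec)) {
  fams <- .family_names[seq_len(spec$family_count)]
  if (spec$max_side_size < 2) {
    stop_input("infeasible spec: every template family needs sides of ",
               "up to 2 molecules")
  }
  if (spec$overlap_degree > 0 && !"esterification" %in% fams) {
    stop_input("infeasible spec: product overlap is generated through ",
               "transesterification and needs the esterification family")
  }
  get_role <- function(r) universe[universe$role == r, , drop = FALSE]
  alkenes <- get_role("alkene"); rings <- get_role("ring")
  alcohols <- get_role("alcohol"); acids <- get_role("acid")
  capacity <- c(hydration = nrow(alkenes), ring_opening = nrow(rings),
                esterification = nrow(alcohols) * nrow(acids),
                cyclization = nrow(rings))
  capacity <- capacity[fams]
  n_base <- spec$n_reactions - spec$overlap_degree
  quota <- rep(n_base %/% length(fams), length(fams))
  quota[seq_len(n_base %% length(fams))] <-
    quota[seq_len(n_base %% length(fams))] + 1L
  names(quota) <- fams
  over <- pmax(quota - capacity, 0)
  quota <- pmin(quota, capacity)
  deficit <- sum(over)
  if (deficit > 0) {
    if ("esterification" %in% fams &&
        capacity[["esterification"]] >= quota[["esterification"]] + deficit +
          spec$overlap_degree) {
      quota[["esterification"]] <- quota[["esterification"]] + deficit
    } else {
      stop_input("infeasible spec: requested ", spec$n_reactions,
                 " reactions but family capacity is ", sum(capacity))
    }
  }

  if (spec$overlap_degree > qget(quota, "esterification")) {
    stop_input("infeasible spec: overlap_degree exceeds the esterification",
               " quota whose products the companions must share")
  }
  # warm the canonicalization cache in one OpenBabel pass
  ob_canonical_batch(c("O", universe$smiles,
                       universe$partner[!is.na(universe$partner)]))
  acc <- new.env(parent = emptyenv())
  acc$reactants <- acc$products <- character()
  acc$label <- integer(); acc$trimmable <- logical()
  rxn <- function(reactants, products, label, trimmable = FALSE) {
    acc$reactants <- c(acc$reactants,
                       paste(vapply(reactants, ob_canonical, character(1)),
                             collapse = "."))
    acc$products <- c(acc$products,
                      paste(vapply(products, ob_canonical, character(1)),
                            collapse = "."))
    acc$label <- c(acc$label, as.integer(label))
    acc$trimmable <- c(acc$trimmable, trimmable)
  }
  with_seed(derive_seed(spec$seed, 3L), {
    if (qget(quota, "hydration") > 0) {
      pick <- sample_safe(seq_len(nrow(alkenes)), quota[["hydration"]])
      for (i in pick) {
        rxn(c(alkenes$smiles[i], "O"), alkenes$partner[i], 1L)
      }
    }
    if (qget(quota, "ring_opening") > 0) {
      pick <- sample_safe(seq_len(nrow(rings)), quota[["ring_opening"]])
      for (i in pick) {
        rxn(c(rings$smiles[i], "O"), rings$partner[i], 2L)
      }
    }
    ester_base <- NULL
    if (qget(quota, "esterification") > 0) {
      combos <- expand.grid(a = seq_len(nrow(alcohols)),
                            c = seq_len(nrow(acids)))
      # a few spare esterifications beyond the quota let the final
      # deduplication still deliver the requested reaction count
      n_pick <- min(nrow(combos), quota[["esterification"]] + 10L)
      ester_base <- combos[sample_safe(seq_len(nrow(combos)), n_pick), ,
                           drop = FALSE]
      ob_canonical_batch(mapply(function(a, cc) ester_smiles(a, cc),
                                alcohols$smiles[ester_base$a],
                                acids$smiles[ester_base$c]))
      for (r in seq_len(n_pick)) {
        a <- alcohols$smiles[ester_base$a[r]]
        cc <- acids$smiles[ester_base$c[r]]
        rxn(c(a, cc), c(ester_smiles(a, cc), "O"), 3L,
            trimmable = r > spec$overlap_degree)
      }
    }
    if (qget(quota, "cyclization") > 0) {
      pick <- sample_safe(seq_len(nrow(rings)), quota[["cyclization"]])
      for (i in pick) {
        rxn(rings$partner[i], c(rings$smiles[i], "O"), 4L)
      }
    }
    if (spec$overlap_degree > 0) {
      for (k in seq_len(spec$overlap_degree)) {
        # companion shares the ester product of base esterification k
        base <- ester_base[k, ]
        a1 <- alcohols$smiles[base$a]
        cc <- acids$smiles[base$c]
        other <- setdiff(seq_len(nrow(alcohols)), base$a)
        a2 <- alcohols$smiles[sample_safe(other, 1)]
        rxn(c(ester_smiles(a2, cc), a1), c(ester_smiles(a1, cc), a2), 3L)
      }
    }
    out <- tibble::tibble(reactants = acc$reactants,
                          products = acc$products,
                          label = acc$label, trimmable = acc$trimmable)
    out <- out[!duplicated(out[, c("reactants", "products")]), ]
    out <- out[!duplicated(out$products), ]        # unique product sides
    out <- out[out$reactants != out$products, ]
    excess <- nrow(out) - spec$n_reactions
    if (excess < 0) {
      stop_input("infeasible spec: only ", nrow(out),
                 " distinct reactions available, requested ",
                 spec$n_reactions)
    }
    if (excess > 0) {
      drop <- utils::tail(which(out$trimmable), excess)
      if (length(drop) < excess) {
        stop_input("infeasible spec: cannot trim to ", spec$n_reactions,
                   " reactions")
      }
      out <- out[-drop, ]
    }
    out$trimmable <- NULL
    out <- out[sample.int(nrow(out)), ]
  })
  out$n_reactants <- lengths(side_members(out$reactants))
  out$n_products <- lengths(side_members(out$products))
  tibble::add_column(out, id = seq_len(nrow(out)), .before = 1)
}

#' Write a fixture to the reaction file format
#'
#' @param records a reaction tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(records, path) write_reaction_file(records, path)

# frozen specs of the golden corpora
golden_fixture_spec <- function(name = c("tiny", "small", "medium")) {
  switch(match.arg(name),
    tiny = fixture_spec(n_molecules = 16, n_reactions = 8,
                        overlap_degree = 0, family_count = 4, seed = 11),
    small = fixture_spec(n_molecules = 200, n_reactions = 200,
                         overlap_degree = 10, family_count = 4, seed = 7),
    medium = fixture_spec(n_molecules = 200, n_reactions = 2000,
                          overlap_degree = 50, family_count = 4, seed = 13))
}

#' Golden synthetic corpora
#'
#' Three frozen corpora generated from fixed seeds: `tiny` (8
#' reactions), `small` (200) and `medium` (2000).  `tiny` and `small`
#' ship as files; `medium` is regenerated on demand (byte-identical per
#' seed).  `golden_fixture()` returns the records, reading the shipped
#' file when available.
#'
#' @param name `"tiny"`, `"small"` or `"medium"`.
#' @return a reaction tibble.
#' @export
golden_fixture <- function(name = c("tiny", "small", "medium")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0("reactions_", name, ".tsv"),
                      package = "reactembed")
  if (nzchar(file)) return(read_reaction_file(file))
  sp <- golden_fixture_spec(name)
  generate_reaction_set(sp)
}
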