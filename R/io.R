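# Reaction and property dataset I/O.
#
# Reaction file format: one reaction SMILES per line,
# "reactant1.reactant2>>product1.product2", optionally followed by a
# tab and an integer class label.  Molecules within a side are
# dot-separated; sides are deduplicated by canonical SMILES (reactions
# are set-valued: stoichiometry is ignored).

parse_side <- function(side) {
  mols <- strsplit(side, ".", fixed = TRUE)[[1]]
  mols <- mols[nzchar(mols)]
  unique(vapply(mols, ob_canonical, character(1), USE.NAMES = FALSE))
}

parse_reaction_line <- function(line) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  rxn <- parts[1]
  label <- NA_integer_
  if (length(parts) >= 2 && nzchar(trimws(parts[2]))) {
    label <- suppressWarnings(as.integer(parts[2]))
    if (is.na(label)) stop_input("label is not an integer: '", parts[2], "'")
  }
  sides <- strsplit(rxn, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2 || !grepl(">>", rxn, fixed = TRUE)) {
    stop_input("missing '>>' separator")
  }
  reactants <- parse_side(sides[1])
  products <- parse_side(sides[2])
  if (length(reactants) == 0) stop_input("empty reactant side")
  if (length(products) == 0) stop_input("empty product side")
  list(reactants = reactants, products = products, label = label)
}

#' Read a reaction SMILES file
#'
#' Parses, canonicalizes and deduplicates both sides of every reaction.
#' Invalid lines (missing `>>`, empty side, unparseable SMILES) are
#' skipped and reported with their line numbers; reactions whose two
#' sides are identical after canonicalization are dropped with a
#' warning, since they carry no reactant-to-product transformation.
#'
#' @param path path to a UTF-8 reaction file.
#' @param format only `"rxn_smiles_tsv"` is supported.
#' @return a tibble with columns `id`, `reactants`, `products` (each a
#'   dot-joined canonical SMILES string), `label` (integer or `NA`),
#'   `n_reactants` and `n_products`.  Per-line parse failures are
#'   attached as a tibble in `attr(, "errors")`.
#' @export
read_reaction_file <- function(path, format = "rxn_smiles_tsv") {
  stopifnot(format == "rxn_smiles_tsv")
  lines <- readLines(path, warn = FALSE)
  reaction_table(lines, source = path)
}

#' @rdname read_reaction_file
#' @param lines character vector of reaction lines (as in the file format).
#' @param source label used in messages.
#' @export
reaction_table <- function(lines, source = "input") {
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  recs <- vector("list", length(idx))
  errs <- list()
  for (k in seq_along(idx)) {
    r <- tryCatch(parse_reaction_line(lines[idx[k]]), error = function(e) e)
    if (inherits(r, "error")) {
      errs[[length(errs) + 1]] <-
        tibble::tibble(line = idx[k], message = conditionMessage(r))
    } else {
      recs[[k]] <- r
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- tibble::tibble(
    reactants = vapply(recs, function(r) paste(r$reactants, collapse = "."),
                       character(1)),
    products = vapply(recs, function(r) paste(r$products, collapse = "."),
                      character(1)),
    label = vapply(recs, `[[`, integer(1), "label"),
    n_reactants = vapply(recs, function(r) length(r$reactants), integer(1)),
    n_products = vapply(recs, function(r) length(r$products), integer(1)))
  identical_sides <- mapply(function(r, p) setequal(strsplit(r, ".", fixed = TRUE)[[1]],
                                                   strsplit(p, ".", fixed = TRUE)[[1]]),
                            out$reactants, out$products)
  if (any(identical_sides)) {
    warning(sum(identical_sides), " reaction(s) with identical sides dropped",
            call. = FALSE)
    out <- out[!identical_sides, , drop = FALSE]
  }
  out <- tibble::add_column(out, id = seq_len(nrow(out)), .before = 1)
  errors <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(line = integer(), message = character())
  if (nrow(errors)) {
    message(nrow(errors), " invalid line(s) in ", source,
            " (see attr(, 'errors'))")
  }
  attr(out, "errors") <- errors
  out
}

#' Write reactions to the reaction SMILES format
#'
#' @param reactions a reaction tibble (columns `reactants`, `products`,
#'   optionally `label`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reaction_file <- function(reactions, path) {
  lines <- paste0(reactions$reactants, ">>", reactions$products)
  if ("label" %in% names(reactions)) {
    has <- !is.na(reactions$label)
    lines[has] <- paste0(lines[has], "\t", reactions$label[has])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a molecule property CSV
#'
#' @param path CSV with header `smiles,label`, `label` in `{0, 1}`.
#' @return a tibble with columns `smiles` and `label`.
#' @export
read_property_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("smiles", "label") %in% names(df))) {
    stop_input("property file must have columns 'smiles' and 'label'")
  }
  tibble::as_tibble(df[, c("smiles", "label")])
}

#' Split a dataset into train / validation / test
#'
#' Deterministic seeded permutation followed by a largest-remainder
#' allocation of the requested ratios; every part receives at least one
#' record.  The default 8:1:1 split assigns 80/10/10 of 100 records.
#'
#' @param records a tibble (one record per row).
#' @param ratios positive numeric length-3 vector of part weights.
#' @param seed integer seed; the same seed always produces the same split.
#' @return `records` with an added factor column `split` with levels
#'   `train`, `valid`, `test`.
#' @export
split_dataset <- function(records, ratios = c(8, 1, 1), seed = 1) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  n <- nrow(records)
  if (n < 3) stop_input("need at least 3 records to split, got ", n)
  # largest-remainder apportionment, then guarantee one record per part
  share <- ratios / sum(ratios) * n
  sizes <- floor(share)
  rem <- n - sum(sizes)
  if (rem > 0) {
    order_rem <- order(share - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(rem)]] <- sizes[order_rem[seq_len(rem)]] + 1L
  }
  while (any(sizes == 0)) {
    big <- which.max(sizes)
    zero <- which(sizes == 0)[1]
    sizes[big] <- sizes[big] - 1L
    sizes[zero] <- 1L
  }
  perm <- with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "valid"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  records$split <- factor(split, levels = c("train", "valid", "test"))
  attr(records, "split_seed") <- as.integer(seed)
  records
}
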