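# Molecule parsing, featurization and dataset I/O.

test_that("parse_molecule recovers graph, bond and ring counts", {
  m <- tmol("C")
  expect_equal(length(m$graph$elements), 1L)
  expect_equal(m$bond_count, 0L)
  expect_equal(m$ring_count, 0L)
  expect_equal(m$graph$h_counts, 4L)

  # cyclopropane: 3 atoms, 3 bonds, cyclomatic number 3 - 3 + 1 = 1
  cp <- tmol("C1CC1")
  expect_equal(length(cp$graph$elements), 3L)
  expect_equal(nrow(cp$graph$edges), 3L)
  expect_equal(cp$bond_count, 3L)
  expect_equal(cp$ring_count, 1L)

  # two fused rings: bicyclohexane written as spiro-free fused pair
  expect_equal(tmol("C1CC2CCC12")$ring_count, 2L)

  expect_error(parse_molecule("notasmiles(("), "cannot parse")
  expect_error(parse_molecule(""), "non-empty")
})

test_that("canonicalization is idempotent and round-trips the graph", {
  a <- parse_molecule("CCO")
  b <- parse_molecule("OCC")
  expect_identical(a$canonical_smiles, b$canonical_smiles)
  c2 <- parse_molecule(a$canonical_smiles)
  expect_identical(a$canonical_smiles, c2$canonical_smiles)
  expect_equal(a$graph$elements, c2$graph$elements)
  expect_equal(a$graph$edges, c2$graph$edges)
})

test_that("canonicalization idempotence holds across a generated corpus", {
  u <- generate_molecule_universe(fixture_spec(n_molecules = 120, seed = 5))
  smiles <- c(u$smiles, u$partner[!is.na(u$partner)])
  expect_gte(length(smiles), 100)
  mols <- parse_molecules(smiles)
  again <- parse_molecules(mols$canonical_smiles)
  expect_identical(again$canonical_smiles, mols$canonical_smiles)
  expect_identical(again$bond_count, mols$bond_count)
  expect_identical(again$ring_count, mols$ring_count)
  expect_identical(again$n_atoms, mols$n_atoms)
})

test_that("atom features are four concatenated one-hot blocks", {
  vocab <- feature_vocab()
  X <- featurize_atoms(tmol("C"), vocab)
  expect_equal(ncol(X), vocab$dim)
  # element C is first in the default vocabulary
  expect_equal(X[1, 1], 1)
  # charge 0 sits mid-block; aromatic flag block reads [1, 0]
  off_charge <- length(vocab$elements) + 1L
  expect_equal(X[1, off_charge + match(0L, vocab$charges)], 1)
  off_arom <- off_charge + length(vocab$charges) + 1L
  expect_equal(unname(X[1, off_arom + 1:2]), c(1, 0))
  # methane carbon carries 4 hydrogens
  off_h <- off_arom + 2L
  expect_equal(X[1, off_h + match(4L, vocab$h_counts)], 1)

  # benzene carbons are flagged aromatic
  Xb <- featurize_atoms(tmol("c1ccccc1"), vocab)
  expect_equal(unname(Xb[1, off_arom + 1:2]), c(0, 1))
})

test_that("atom-feature rows always sum to four, unknowns use overflow slots", {
  for (s in c("C", "CCO", "c1ccccc1O", "C1CC1", "CC(=O)OCC", "O",
              "C=CC", "OC(=O)C(C)C")) {
    expect_equal(unname(rowSums(featurize_atoms(tmol(s)))),
                 rep(4, length(tmol(s)$graph$elements)))
  }
  # selenium is outside the element vocabulary: overflow, never a crash
  se <- parse_molecule("[SeH2]")
  Xs <- featurize_atoms(se)
  expect_equal(unname(rowSums(Xs)), rep(4, nrow(Xs)))
  expect_equal(Xs[1, length(feature_vocab()$elements) + 1L], 1)
})

test_that("functional-group counts match substructure content", {
  pats <- read_fg_patterns()
  expect_equal(nrow(pats), 39L)
  fg_ethane <- featurize_functional_groups(tmol("CC"), pats)
  # ethane has no functional groups beyond its two methyls
  expect_equal(sum(fg_ethane[setdiff(names(fg_ethane), "methyl")]), 0L)
  fg_etoh <- featurize_functional_groups(tmol("CCO"), pats)
  expect_gte(fg_etoh[["hydroxyl"]], 1L)
  expect_equal(unname(fg_etoh[c("thiol", "chloro", "bromo", "iodo")]),
               rep(0L, 4))
  fg_diol <- featurize_functional_groups(tmol("OCCO"), pats)
  expect_equal(fg_diol[["hydroxyl"]], 2L * fg_etoh[["hydroxyl"]])
})

test_that("fg vectors are additive over disconnected unions", {
  expect_equal(tmol("CCO.CCO")$fg_vector, 2L * tmol("CCO")$fg_vector)
})

test_that("reaction files parse with per-line error reporting", {
  lines <- c("CCO>>CC=O",
             "CCO.CC(=O)O>>CCOC(C)=O.O\t12",
             "no-separator-here",
             ">>CCO",
             "CCO>>",
             "CCO>>CCO")          # identical sides, dropped with warning
  f <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  expect_warning(rx <- read_reaction_file(f), "identical sides")
  expect_equal(nrow(rx), 2L)
  expect_equal(rx$n_reactants, c(1L, 2L))
  expect_equal(rx$n_products, c(1L, 2L))
  expect_equal(rx$label, c(NA_integer_, 12L))
  errs <- attr(rx, "errors")
  expect_equal(nrow(errs), 3L)
  expect_setequal(errs$line, 3:5)
})

test_that("reaction sides are deduplicated by canonical SMILES", {
  rx <- reaction_table("CCO.OCC.CCO>>CC=O")
  expect_equal(rx$n_reactants, 1L)
})

test_that("splits are deterministic, exhaustive and 8:1:1", {
  recs <- tibble::tibble(id = 1:100)
  s1 <- split_dataset(recs, seed = 42)
  s2 <- split_dataset(recs, seed = 42)
  expect_identical(s1$split, s2$split)
  expect_equal(unname(table(s1$split)), c(80L, 10L, 10L),
               ignore_attr = TRUE)
  s3 <- split_dataset(tibble::tibble(id = 1:10), seed = 1)
  expect_equal(unname(table(s3$split)), c(8L, 1L, 1L), ignore_attr = TRUE)
  expect_false(identical(split_dataset(recs, seed = 43)$split, s1$split))
  expect_error(split_dataset(tibble::tibble(id = 1:2)), "at least 3")
  # every part non-empty even when a naive floor would zero one out
  s5 <- split_dataset(tibble::tibble(id = 1:5), seed = 1)
  expect_true(all(table(s5$split) >= 1))
})

test_that("property files read as smiles/label tibbles", {
  f <- withr::local_tempfile(lines = c("smiles,label", "CCO,1", "CC,0"),
                             fileext = ".csv")
  d <- read_property_file(f)
  expect_equal(names(d), c("smiles", "label"))
  expect_equal(d$label, c(1L, 0L))
})
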