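test_that("SMILES parsing builds the expected graphs", {
  g <- parse_structure("O=[N+]([O-])c1ccccc1") # nitrobenzene
  expect_equal(n_atoms(g), 9)
  expect_equal(n_bonds(g), 9)
  a <- atoms(g)
  expect_equal(sum(a$element == "C"), 6)
  expect_equal(sort(a$charge[a$element %in% c("N", "O")]), c(-1L, 0L, 1L))

  b <- parse_structure("c1ccccc1")
  expect_equal(n_atoms(b), 6)
  expect_equal(n_bonds(b), 6)
  expect_true(all(bonds(b)$type == "aromatic"))
  expect_true(all(atoms(b)$aromatic))
})

test_that("malformed or impossible SMILES raise parse errors", {
  for (bad in invalid_smiles_fixture()) {
    expect_error(parse_structure(bad))
  }
  expect_error(parse_structure("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_structure("[Zz]ccc"), "parse")
})

test_that("canonical form collapses aromatic perception and atom order", {
  expect_identical(canonical_form(parse_structure("C1=CC=CC=C1")),
                   canonical_form(parse_structure("c1ccccc1")))

  # atom-order permutations of p-nitroaniline all canonicalize identically
  spellings <- c("Nc1ccc(cc1)[N+](=O)[O-]",
                 "[O-][N+](=O)c1ccc(N)cc1",
                 "c1cc(N)ccc1[N+]([O-])=O")
  ref <- canonical_form(parse_structure(spellings[1]))
  g <- parse_structure(spellings[1])
  perms <- withr::with_seed(1, replicate(50, sample(n_atoms(g)),
                                         simplify = FALSE))
  for (p in perms) {
    inv <- order(p)
    a <- atoms(g)[p, ]
    b <- bonds(g)
    b$i2 <- inv[b$i]; b$j2 <- inv[b$j]
    g2 <- mol_graph(a, tibble::tibble(i = pmin(b$i2, b$j2),
                                      j = pmax(b$i2, b$j2), type = b$type))
    expect_identical(canonical_form(g2), ref)
  }
  for (s in spellings) {
    expect_identical(canonical_form(parse_structure(s)), ref)
  }

  # idempotence: canonical of canonical is canonical
  for (s in c("c1ccccc1", "CC(=O)Oc1ccccc1C(O)=O", "C=Cc1ccccc1")) {
    can <- canonical_form(parse_structure(s))
    expect_identical(canonical_form(parse_structure(can)), can)
  }
})

test_that("valence validation accepts real chemistry and rejects junk", {
  expect_true(validate_valence(parse_structure("c1ccccc1")))
  # nitro-group nitrogen: formal charge +1 with four bonds
  nitro <- parse_structure("O=[N+]([O-])c1ccccc1")
  expect_true(validate_valence(nitro))
  for (s in valid_smiles_fixture()) {
    expect_true(validate_valence(parse_structure(s)), label = s)
  }
  # hand-built invalid graphs: pentavalent carbon
  g <- mol_graph(
    tibble::tibble(element = rep("C", 6), charge = 0L,
                   h_explicit = NA_integer_, aromatic = FALSE),
    tibble::tibble(i = 1L, j = 2:6, type = "single"))
  v <- validate_valence(g)
  expect_false(v)
  expect_gte(nrow(attr(v, "diagnostics")), 1)
  expect_true(1 %in% attr(v, "diagnostics")$atom)
  # dangling aromatic bond
  g2 <- mol_graph(
    tibble::tibble(element = c("C", "C"), charge = 0L,
                   h_explicit = NA_integer_, aromatic = TRUE),
    tibble::tibble(i = 1L, j = 2L, type = "aromatic"))
  expect_false(validate_valence(g2))
})

test_that("conjugated components follow the sp/sp2 bridging rule", {
  expect_length(conjugated_components(parse_structure("CC")), 0)
  benz <- conjugated_components(parse_structure("c1ccccc1"))
  expect_length(benz, 1)
  expect_length(benz[[1]], 6)
  # styrene: ring + vinyl + the bridging single bond form one system
  sty <- parse_structure("C=Cc1ccccc1")
  comp <- conjugated_components(sty)
  expect_length(comp, 1)
  b <- bonds(sty)
  conj_oracle <- {
    multi <- b$type != "single"
    pi_at <- unique(c(b$i[multi], b$j[multi]))
    which(multi | (b$i %in% pi_at & b$j %in% pi_at))
  }
  expect_setequal(comp[[1]], conj_oracle)
  # isolated systems stay separate: divinyl ether has two C=C across sp3 O?
  two <- conjugated_components(parse_structure("C=CCCC=C"))
  expect_length(two, 2)
})

test_that("parse/write round trip preserves canonical form", {
  for (s in valid_smiles_fixture()) {
    g <- parse_structure(s)
    expect_identical(canonical_form(parse_structure(write_structure(g))),
                     canonical_form(g), label = s)
  }
  # and for randomly sampled synthetic molecules
  mols <- sample_molecules(40, seed = 99)
  for (g in mols) {
    expect_identical(canonical_form(parse_structure(write_structure(g))),
                     canonical_form(g))
  }
})

test_that("implicit hydrogens complete valences", {
  expect_equal(implicit_h_counts(parse_structure("C")), 4L)
  expect_equal(implicit_h_counts(parse_structure("c1ccccc1")),
               rep(1L, 6))
  pyr <- parse_structure("c1cc[nH]c1")
  ih <- implicit_h_counts(pyr)
  expect_equal(ih[atoms(pyr)$element == "N"], 0L) # explicit H pinned
})
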