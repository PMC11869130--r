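test_that("validity/uniqueness/novelty follow the stated conventions", {
  # constructed fixture: 10 strings, 8 valid, 6 distinct among valid,
  # 3 of those not in the training set
  generated <- c(
    "c1ccccc1", "C1=CC=CC=C1",   # same molecule, two spellings
    "CCO", "OCC",                 # same molecule, two spellings
    "CC", "C=C", "C#N", "CCC",    # four more distinct molecules
    "C(", "C1CC")                 # two invalid strings
  training <- canonical_form(c("c1ccccc1", "CCO", "CC"))
  mr <- generation_metrics(generated, training)
  expect_equal(mr$validity, 0.8)
  expect_equal(mr$uniqueness, 0.75)
  expect_equal(mr$novelty, 0.5)
  expect_match(mr$novelty_convention, "distinct canonical")

  # all-identical valid outputs
  same <- generation_metrics(rep("CCO", 5), character(0))
  expect_equal(same$uniqueness, 1 / 5)
  expect_equal(same$novelty, 1)

  # generated set contained in the training set has zero novelty
  sub <- generation_metrics(c("CCO", "CC"), training)
  expect_equal(sub$novelty, 0)
  expect_error(generation_metrics(character(0)), "empty")
})

test_that("duplicating the generated list leaves validity fixed and halves uniqueness", {
  gen <- c("CCO", "CC", "C1CC") # 2 valid, 2 distinct
  m1 <- generation_metrics(gen, character(0))
  m2 <- generation_metrics(c(gen, gen), character(0))
  expect_equal(m2$validity, m1$validity)
  expect_equal(m2$uniqueness, m1$uniqueness / 2)
  expect_equal(m2$novelty, m1$novelty)
})

test_that("fraction within target applies the joint seven-property criterion", {
  orc <- make_oracle()
  target <- c(as.list(oracle_properties("c1ccccc1", "toluene")),
              solvent = "toluene")
  # molecules scored exactly at target always count
  hit <- fraction_within_target(list("c1ccccc1"), orc, target)
  expect_equal(hit$fraction, 1)
  # zero-width-like windows on continuously scored molecules exclude others
  tiny <- property_window(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9)
  off <- fraction_within_target(list("CCCCC", "CCOCC"), orc, target, tiny)
  expect_equal(off$fraction, 0)
  # constructed k of n: count against a brute-force window check
  mols <- c("c1ccccc1", "c1ccc2ccccc2c1", "CCCCC", "C=CC=C", "CCO")
  w <- property_window()
  res <- fraction_within_target(mols, orc, target, w)
  manual <- vapply(mols, function(s) {
    p <- orc(s, "toluene")
    all(abs(p$lambda_abs - target$lambda_abs) <= w$lambda_abs,
        abs(p$sigma_abs - target$sigma_abs) <= w$sigma_abs,
        abs(p$log_eps - target$log_eps) <= w$log_eps,
        abs(p$lambda_emi - target$lambda_emi) <= w$lambda_emi,
        abs(p$sigma_emi - target$sigma_emi) <= w$sigma_emi,
        abs(p$phi - target$phi) <= w$phi,
        abs(p$tau - target$tau) <= w$tau_rel * target$tau)
  }, logical(1))
  expect_equal(res$fraction, mean(manual))
  expect_equal(sort(res$members$index), which(manual), ignore_attr = TRUE)
  # monotone in the window half-widths
  wider <- property_window(50, 1400, 0.7, 50, 1400, 0.24, 1)
  res2 <- fraction_within_target(mols, orc, target, wider)
  expect_gte(res2$fraction, res$fraction)
  # oracle failures are excluded and reported
  failing <- function(g, s) if (identical(g, "CCO")) stop("no") else orc(g, s)
  res3 <- fraction_within_target(c("c1ccccc1", "CCO"), failing, target)
  expect_equal(res3$n_scored, 1)
  expect_equal(res3$failed, 2L)
})

test_that("Stokes shifts subtract absorption from emission", {
  expect_equal(stokes_shift(550, 380), 170, ignore_attr = TRUE)
  expect_equal(stokes_shift(440, 440), 0, ignore_attr = TRUE)
  # the same chromophore in two solvents gives two records
  shifts <- stokes_shift(c(80 + 400, 187 + 400), c(400, 400))
  expect_equal(as.numeric(shifts), c(80, 187))
  neg <- stokes_shift(c(500, 300), c(400, 400))
  expect_equal(attr(neg, "flagged_negative"), 2L)
})

test_that("degree of conjugation matches an independent all-pairs BFS", {
  expect_equal(degree_of_conjugation(parse_structure("CC"))$doc, 0L)
  expect_equal(degree_of_conjugation(parse_structure("c1ccccc1"))$doc, 3L)
  expect_equal(degree_of_conjugation(parse_structure("C=CC=C"))$doc, 3L)
  mols <- sample_molecules(60, seed = 1234)
  for (g in mols) {
    expect_equal(degree_of_conjugation(g)$doc, bfs_doc_oracle(g))
  }
  # the reported pair actually achieves the reported distance
  sty <- parse_structure("C=Cc1ccccc1")
  d <- degree_of_conjugation(sty)
  expect_equal(d$doc, bfs_doc_oracle(sty))
  expect_length(d$pair, 2)
})

test_that("log P is deterministic and orders hydrophilic below hydrophobic", {
  hydrophilic <- "OCC(O)CO"      # glycerol
  hydrophobic <- "CCCCCCCCCC"    # decane
  lp <- logp(c(hydrophilic, hydrophobic))
  expect_lt(lp[1], lp[2])
  expect_identical(logp(hydrophilic), logp(hydrophilic))
  g <- parse_structure("c1ccccc1")
  expect_length(logp(g), 1)
})

test_that("fingerprints and the chemical-space map behave structurally", {
  fps <- morgan_fingerprints(c("CCO", "OCC", "c1ccccc1"))
  expect_identical(fps[1, ], fps[2, ]) # same molecule, same fingerprint
  expect_false(all(fps[1, ] == fps[3, ]))

  # two structurally disjoint families: aromatics vs aliphatic ethers
  fam_a <- c("c1ccccc1", "Cc1ccccc1", "c1ccc2ccccc2c1", "C=Cc1ccccc1",
             "Clc1ccccc1")
  fam_b <- c("CCOCC", "CCOC", "COCCOC", "CCCOC", "CCOCCO")
  fps2 <- morgan_fingerprints(c(fam_a, fam_b))
  tanimoto <- function(x, y) {
    ab <- sum(x & y); if (ab == 0) 0 else ab / sum(x | y)
  }
  ia <- seq_along(fam_a); ib <- length(fam_a) + seq_along(fam_b)
  within <- c(apply(utils::combn(ia, 2), 2,
                    function(p) tanimoto(fps2[p[1], ], fps2[p[2], ])),
              apply(utils::combn(ib, 2), 2,
                    function(p) tanimoto(fps2[p[1], ], fps2[p[2], ])))
  between <- as.vector(outer(ia, ib, Vectorize(function(a, b)
    tanimoto(fps2[a, ], fps2[b, ]))))
  expect_lt(mean(between), mean(within))

  map1 <- chemical_space_map(fam_a, fam_b, seed = 3, perplexity = 2)
  map2 <- chemical_space_map(fam_a, fam_b, seed = 3, perplexity = 2)
  expect_identical(map1$x, map2$x)
  expect_setequal(unique(map1$group), c("reference", "generated"))
  expect_error(chemical_space_map("CCO", c("CC")), "at least 10")
})

test_that("reference lookup matches on canonical form", {
  db <- test_db()
  ref <- db[1:20, ]
  # query the first molecule under a different spelling
  alt <- write_structure(parse_structure(ref$smiles[1]))
  hits <- find_in_reference(c(alt, "C#CC#CC#C"), ref)
  expect_true(nrow(hits) >= 1)
  expect_true(all(canonical_form(hits$smiles) %in%
                    canonical_form(ref$smiles)))
  none <- find_in_reference("C#CC#CC#CC#C", ref)
  expect_equal(nrow(none), 0)
  # two spellings of one molecule yield a single match
  two <- find_in_reference(c(ref$smiles[1], alt), ref)
  expect_equal(nrow(two), nrow(dplyr::distinct(two, smiles, solvent)))
})
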