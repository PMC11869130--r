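test_that("molecule sampling is valid, seeded and spans conjugation lengths", {
  mols <- sample_molecules(60, seed = 1)
  expect_length(mols, 60)
  expect_true(all(vapply(mols, molecule_ok, logical(1))))
  mols2 <- sample_molecules(60, seed = 1)
  expect_identical(lapply(mols, write_structure),
                   lapply(mols2, write_structure))
  docs <- vapply(mols, function(g) degree_of_conjugation(g)$doc, integer(1))
  expect_gte(length(unique(docs)), 5)
  expect_true(any(docs == 0) && any(docs >= 5))
})

test_that("the surrogate oracle is deterministic with the stated structure", {
  g <- parse_structure("Nc1ccc(cc1)[N+](=O)[O-]")
  a <- oracle_properties(g, "water")
  b <- oracle_properties(g, "water")
  expect_identical(a, b)

  # noiseless mode: an unconjugated molecule sits at the baseline
  p0 <- oracle_params(noise_scale = 0)
  flat <- oracle_properties(parse_structure("CCCC"), "toluene", p0)
  expect_equal(flat$lambda_abs, p0$lambda_base)
  # conjugation shifts absorption bathochromically
  benz <- oracle_properties(parse_structure("c1ccccc1"), "toluene", p0)
  expect_equal(benz$lambda_abs, p0$lambda_base + 3 * p0$lambda_per_doc)

  # a charge-transfer molecule gains Stokes shift in the polar solvent
  tol <- oracle_properties(g, "toluene", p0)
  acn <- oracle_properties(g, "acetonitrile", p0)
  expect_gt(acn$lambda_emi - acn$lambda_abs, tol$lambda_emi - tol$lambda_abs)
  # a molecule without acceptors gets no polarity response
  plain <- parse_structure("c1ccccc1")
  ptol <- oracle_properties(plain, "toluene", p0)
  pacn <- oracle_properties(plain, "acetonitrile", p0)
  expect_equal(pacn$lambda_emi - pacn$lambda_abs,
               ptol$lambda_emi - ptol$lambda_abs)
})

test_that("database records respect physical ranges and correlations", {
  db <- test_db()
  expect_true(all(db$lambda_abs >= 250 & db$lambda_abs <= 1000))
  expect_true(all(db$lambda_emi > db$lambda_abs)) # strict Stokes positivity
  expect_true(all(db$phi >= 0 & db$phi <= 1))
  expect_true(all(db$tau > 0))
  expect_true(all(db$sigma_abs > 0 & db$sigma_emi > 0))
  expect_gt(stats::cor(db$lambda_abs, db$lambda_emi), 0.8)
  expect_gt(stats::cor(db$sigma_abs, db$sigma_emi), 0.8)
  expect_lt(abs(stats::cor(db$phi, db$lambda_emi)), 0.25)
  # hydrophilicity coupling: water records skew to lower log P than toluene
  mw <- mean(db$log_p[db$solvent == "water"])
  mt <- mean(db$log_p[db$solvent == "toluene"])
  expect_lt(mw, mt)
})

test_that("structure-based splits are exact, leak-free and reproducible", {
  db10 <- tibble::tibble(
    smiles = rep(sprintf("mol%02d", 1:10), each = 2),
    solvent = rep(c("water", "toluene"), 10))
  sp <- split_by_structure(db10, ratio = 0.9, seed = 3)
  expect_length(unique(sp$train$smiles), 9)
  expect_length(unique(sp$test$smiles), 1)
  expect_length(intersect(sp$train$smiles, sp$test$smiles), 0)
  # every solvent record of a molecule lands on the same side
  expect_equal(nrow(sp$test), 2)
  sp2 <- split_by_structure(db10, ratio = 0.9, seed = 3)
  expect_identical(sp2$test$smiles, sp$test$smiles)
  expect_error(split_by_structure(db10[1:2, ], 0.9, 1), "unique")
})

test_that("missing property cells are filled by the oracle with provenance", {
  db <- test_db()[1:8, ]
  db$tau[1] <- NA; db$phi[3] <- NA; db$lambda_abs[3] <- NA
  n_missing <- sum(is.na(db[fluogen:::PROPERTY_NAMES]))
  filled <- fill_missing(db, make_oracle())
  expect_equal(sum(is.na(filled[fluogen:::PROPERTY_NAMES])), 0)
  expect_equal(filled$filled[1], "tau")
  expect_setequal(strsplit(filled$filled[3], ",")[[1]],
                  c("phi", "lambda_abs"))
  # untouched rows and untouched cells stay identical
  expect_identical(filled$lambda_emi, db$lambda_emi)
  expect_identical(filled[2, ], db[2, ])
  n_filled <- sum(nzchar(filled$filled) *
                    lengths(strsplit(filled$filled, ",")))
  expect_equal(n_filled, n_missing)
  # filled values equal what the oracle says for that molecule/solvent
  pred <- make_oracle()(filled$smiles[1], filled$solvent[1])
  expect_equal(filled$tau[1], pred$tau)
})

test_that("the property-database CSV dialect round-trips", {
  db <- test_db()[1:10, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_property_db(db, path)
  header <- readLines(path, n = 1)
  expect_match(header, "lambda_abs_nm")
  expect_match(header, "tau_ns")
  back <- read_property_db(path)
  expect_equal(back$lambda_abs, db$lambda_abs, tolerance = 1e-5)
  expect_identical(back$smiles, db$smiles)
  expect_identical(back$solvent, db$solvent)
})
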