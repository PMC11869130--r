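fig2_condition <- function(solvent = "water") {
  list(lambda_abs = 380, sigma_abs = 4700, log_eps = 3.6, lambda_emi = 550,
       sigma_emi = 3800, phi = 0.01, tau = 2.0, solvent = solvent)
}

test_that("condition encoding z-scores properties and represents the solvent", {
  db <- test_db()
  stats <- fit_condition_stats(db)
  # a property at its training mean lands at z-score zero
  cond <- fig2_condition()
  cond$lambda_abs <- stats$mean[["lambda_abs"]]
  enc <- encode_condition(cond, stats)
  expect_equal(unname(enc[["lambda_abs"]]), 0)
  expect_length(enc, 7 + nrow(default_solvents()) + 1)
  expect_true(all(is.finite(encode_condition(fig2_condition(), stats))))
  expect_equal(unname(enc[["solvent_water"]]), 1)
  # unknown solvent: dielectric-only fallback, or an error when disabled
  odd <- fig2_condition("glycerol"); odd$dielectric <- 42.5
  enc2 <- encode_condition(odd, stats)
  expect_true(all(enc2[grep("^solvent_", names(enc2))] == 0))
  expect_error(encode_condition(odd, stats, fallback = FALSE), "unknown")
  noeps <- fig2_condition("glycerol")
  expect_error(encode_condition(noeps, stats), "dielectric")
})

test_that("condition validation rejects out-of-range values", {
  bad <- fig2_condition(); bad$phi <- 1.4
  expect_error(as_condition(bad), "phi")
  bad <- fig2_condition(); bad$tau <- -1
  expect_error(as_condition(bad), "tau")
  expect_error(as_condition(list(lambda_abs = 1)), "missing")
})

test_that("action distributions are masked softmaxes over legal actions", {
  m <- test_model()
  db <- test_db()
  cond <- median_condition(db)
  states <- list(parse_structure("c1ccccc1"),
                 replay(decompose(parse_structure("CCO"), 1)),
                 mol_graph())
  for (st in states) {
    d <- action_distribution(st, cond, m)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(d$prob[!d$legal] == 0))
    expect_true(all(d$prob >= 0))
  }
  # zero weights give a uniform distribution over legal actions
  m0 <- m; m0$W[] <- 0
  d0 <- action_distribution(states[[1]], cond, m0)
  pl <- d0$prob[d0$legal]
  expect_lt(max(pl) - min(pl), 1e-12)
})

test_that("training reduces the teacher-forcing loss and is reproducible", {
  db <- test_db()[1:60, ]
  cfg <- model_config(epochs = 3, seed = 5)
  m1 <- train_generator(db, cfg, quiet = TRUE)
  expect_lt(dplyr::last(m1$history$nll), m1$history$nll[1])
  m2 <- train_generator(db, cfg, quiet = TRUE)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$W, m2$W)
  expect_error(train_generator(db[0, ]), "empty")
})

test_that("a single fixed trajectory can be fit to near-certainty", {
  db1 <- tibble::tibble(
    smiles = "Nc1ccc(cc1)[N+](=O)[O-]", lambda_abs = 380, sigma_abs = 4700,
    log_eps = 3.6, lambda_emi = 550, sigma_emi = 3800, phi = 0.01,
    tau = 2, solvent = "water")
  m <- train_generator(
    db1, model_config(epochs = 250, learning_rate = 0.3, batch_size = 1,
                      seed = 3, augment = FALSE), quiet = TRUE)
  expect_lt(dplyr::last(m$history$nll), 0.01)
  traj <- decompose(parse_structure(db1$smiles),
                    fluogen:::derive_seed(3, "dfs", 1))
  cond <- as.list(db1[1, ])
  for (k in seq_len(nrow(traj$actions))) {
    d <- action_distribution(traj$states[[k]], cond, m)
    y <- fluogen:::match_action(d, traj$actions[k, ])
    expect_gt(d$prob[y], 0.95)
  }
})

test_that("the loss depends only on construction-order states, not labels", {
  # the per-step inputs of the model are the replayed states of the action
  # sequence; rebuilding those states from the actions alone (no reference
  # to the source molecule's atom order) gives identical probabilities
  m <- test_model()
  cond <- median_condition(test_db())
  g <- parse_structure("CC(=O)Oc1ccccc1C(O)=O")
  traj <- decompose(g, 11)
  st <- mol_graph()
  for (k in seq_len(nrow(traj$actions))) {
    d1 <- action_distribution(traj$states[[k]], cond, m)
    d2 <- action_distribution(st, cond, m)
    expect_identical(d1$prob, d2$prob)
    st <- apply_action(st, traj$actions[k, ], strict = FALSE)
  }
})

test_that("checkpoints restore the model bit-identically", {
  m <- test_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_identical(m2$W, m$W)
  expect_identical(m2$vocab, m$vocab)
  cond <- median_condition(test_db())
  st <- parse_structure("C=Cc1ccccc1")
  expect_identical(action_distribution(st, cond, m2)$prob,
                   action_distribution(st, cond, m)$prob)
})

test_that("tidy and glance summarize the fitted model", {
  m <- test_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("feature", "condition", "weight"))
  expect_equal(nrow(td), length(m$W))
  gl <- glance(m)
  expect_equal(gl$n_parameters, length(m$W))
  expect_equal(gl$epochs, nrow(m$history))
})
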