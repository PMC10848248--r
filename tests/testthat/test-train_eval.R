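# Split protocol, head training, metrics, ensembling, robustness diagnostic.

test_that("split plans honor the 10% test / 8:1 train-val protocol", {
  ids <- sprintf("m%03d", 1:100)
  plan <- make_split_plan(ids, master_seed = 7L)
  expect_length(plan$test_ids, 10L)
  for (rep in plan$repeats) {
    expect_length(rep$train_ids, 80L)
    expect_length(rep$val_ids, 10L)
    expect_length(intersect(plan$test_ids, c(rep$train_ids, rep$val_ids)), 0L)
    expect_length(intersect(rep$train_ids, rep$val_ids), 0L)
  }
  # deterministic per seed, and the test set is fixed across repeats
  plan2 <- make_split_plan(ids, master_seed = 7L)
  expect_identical(plan, plan2)
  # different repeats re-shuffle the validation set
  expect_false(setequal(plan$repeats[[1L]]$val_ids, plan$repeats[[2L]]$val_ids))
  expect_error(make_split_plan(sprintf("m%d", 1:10), 1L), "at least 20")
})

test_that("split leak-freedom holds across seeds and sizes", {
  for (seed in c(1L, 23L, 999L)) {
    for (n in c(37L, 100L, 253L)) {
      plan <- make_split_plan(sprintf("x%04d", seq_len(n)), seed, n_repeats = 3L)
      expect_true(check_split_plan(plan))
    }
  }
})

test_that("training rejects molecules whose conformers disagree on the target", {
  mol <- fixture_mol("butane")
  confs <- embed_conformers(mol, n = 2L, seed = 1L)
  records <- featurize_dataset(list(mol), list(confs))
  records[[1L]]$target <- 1.0
  records[[2L]]$target <- 2.0
  config <- make_train_config(make_encoder_config("graph_2d", hidden_dim = 8L))
  expect_error(
    train_model("lambda_direct", records, NULL, config),
    "share one target"
  )
})

test_that("zero training epochs return the initialized head unchanged", {
  mols <- fixture_rotatable_pool(6L)
  confs <- embed_conformers_batch(mols, n = 1L, seed = 2L)
  targets <- stats::setNames(seq_along(mols) / 10, vapply(mols, `[[`, "", "id"))
  records <- featurize_dataset(mols, confs, targets)
  config <- make_train_config(
    make_encoder_config("graph_2d", hidden_dim = 8L, init_seed = 4L),
    max_epochs = 0L
  )
  model <- train_model("lambda_direct", records, NULL, config)
  fresh <- make_model(config$encoder_config, "lambda_direct", head_dim = config$head_dim)
  expect_identical(model$head$W1, fresh$head$W1)
  expect_identical(model$head$w2, fresh$head$w2)
})

test_that("the head optimizer fits targets linear in the embeddings", {
  mols <- gen_molecules(make_fixture_spec(60L, seed = 5L))
  confs <- embed_conformers_batch(mols, n = 1L, seed = 6L)
  config <- make_encoder_config("graph_2d", hidden_dim = 24L, init_seed = 11L)
  probe <- make_model(config)
  records <- featurize_dataset(mols, confs)
  E <- t(vapply(records, function(r) embed_record(probe, r), numeric(24L)))
  set.seed(3)
  w_true <- stats::rnorm(24L, sd = 0.3)
  y <- scale(E, scale = FALSE) %*% w_true / 10
  for (k in seq_along(records)) records[[k]]$target <- y[[k]]
  tconfig <- make_train_config(config, max_epochs = 200L, patience = 200L)
  model <- train_model("lambda_direct", records, NULL, tconfig, seed = 8L)
  final_mae <- utils::tail(model$log$train_mae, 1L)
  expect_lt(final_mae, 0.05 * stats::sd(y))
  expect_true(all(diff(model$log$epoch) == 1L))
})

test_that("metrics match closed-form cases", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mae_eV, 0)
  expect_equal(m$rmse_eV, 0)
  expect_equal(m$r2, 1)

  obs <- c(0, 1, 2, 5)
  mean_pred <- regression_metrics(rep(mean(obs), 4L), obs)
  expect_equal(mean_pred$r2, 0)

  m2 <- regression_metrics(c(0, 1), c(0, 2))
  expect_equal(m2$mae_eV, 0.5)
  expect_equal(m2$rmse_eV, sqrt(0.5))

  worse <- regression_metrics(c(10, -10, 10), c(0, 1, 2))
  expect_lt(worse$r2, 0)

  expect_true(m2$rmse_eV >= m2$mae_eV)
})

test_that("ensembling averages member predictions", {
  mol <- fixture_mol("ethanol")
  rec <- list(make_record(mol, fixture_conformer("ethanol", seed = 1L)[[1L]], target = 1))
  members <- lapply(c(1, 2, 3), constant_model)
  expect_equal(ensemble_predict(members, rec), 2)
  one <- constant_model(1.7)
  expect_equal(ensemble_predict(list(one), rec), predict_records(one, rec))

  bad <- constant_model(1)
  bad$featurization_version <- "reorglam-feat-0"
  expect_error(ensemble_predict(list(one, bad), rec), "featurization")
})

test_that("evaluate scores per-molecule conformer averages and variance", {
  mols <- list(fixture_mol("butane"), fixture_mol("ethanol"))
  confs <- lapply(list("butane", "ethanol"), function(n) fixture_conformer(n, n = 3L, seed = 5L))
  targets <- c(butane = 1.5, ethanol = 0.5)
  records <- featurize_dataset(mols, confs, targets)
  const <- constant_model(1.0)
  m <- evaluate(const, records, scheme = "average")
  expect_equal(m$mae_eV, 0.5) # |1 - 1.5|, |1 - 0.5| averaged over molecules
  expect_equal(m$mean_conformer_variance_eV2, 0)
  expect_equal(m$n, 2L)
  per_conf <- evaluate(const, records, scheme = "per_conformer")
  expect_equal(per_conf$n, 6L)
  expect_error(evaluate(const, list()), "empty")
})

test_that("conformer robustness reports zero variance for conformer-blind models", {
  mols <- fixture_rotatable_pool(4L)
  model_2d <- make_model(make_encoder_config("graph_2d", hidden_dim = 12L, init_seed = 3L))
  out <- conformer_robustness(model_2d, mols, n_conformers = 3L, seed = 2L)
  expect_true(all(out$per_molecule$variance_eV2 == 0))
  expect_equal(out$summary$mean_variance_eV2, 0)
  expect_equal(out$n_failed, 0L)

  const <- constant_model(2, kind = "bond_invariant_3d")
  out_const <- conformer_robustness(const, mols, n_conformers = 3L, seed = 2L)
  expect_true(all(out_const$per_molecule$variance_eV2 == 0))
})
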