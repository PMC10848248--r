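# Desk-scale benchmark drivers: the synthetic analogue of the full-scale
# encoder comparison. One function runs the complete pipeline for one master
# seed (fixed test split, conformer-augmented training, evaluation on
# distance-geometry conformers plus the cross-conformer variance diagnostic);
# a second runs the split-repeat ensembling protocol.

#' Generate the synthetic benchmark set (molecules + labels)
#'
#' @param n_molecules Number of molecules (the desk-scale dataset size).
#' @param dataset_seed Seed for molecule generation. The dataset is fixed
#'   across experiment repetitions; only splits, conformers and training vary
#'   with the experiment's master seed.
#' @return `list(mols, labels)`.
#' @export
make_benchmark_set <- function(n_molecules, dataset_seed = 101L) {
  spec <- make_fixture_spec(n_molecules, seed = dataset_seed)
  mols <- gen_molecules(spec)
  labels <- gen_lambda_labels(mols, spec)
  list(mols = mols, labels = labels, spec = spec)
}

#' Compare encoder symmetry classes for one master seed
#'
#' Runs the direct-lambda protocol once per encoder kind under identical
#' conditions: a fixed 10% molecule-level test split, training augmented
#' with `n_conformers` distance-geometry conformers per molecule (all
#' carrying the molecule's single label), early-stopped head training, and
#' evaluation on fresh distance-geometry conformers of the unseen test
#' molecules. Reports test MAE/RMSE/R2 and the mean cross-conformer
#' prediction variance per kind.
#'
#' @param mols,labels A benchmark set from [make_benchmark_set()].
#' @param master_seed Seed driving the split, conformer embedding, weight
#'   initialization and minibatch order.
#' @param kinds Encoder kinds to compare.
#' @param n_conformers Conformers per molecule (train augmentation and test).
#' @param hidden_dim,n_layers Encoder size.
#' @param max_epochs,patience,batch_size Head-training schedule.
#' @return Named list (per kind) of `reorg_metrics`, each with the trained
#'   model attached as attribute `"model"`.
#' @export
benchmark_symmetry_classes <- function(mols, labels, master_seed,
                                       kinds = c("bond_invariant_3d", "distance_3d"),
                                       n_conformers = 5L, hidden_dim = 48L,
                                       n_layers = 2L, max_epochs = 80L,
                                       patience = 15L, batch_size = 32L) {
  ids <- labels$molecule_id
  plan <- make_split_plan(ids, master_seed, n_repeats = 1L)
  lambda <- stats::setNames(labels$lambda_eV, labels$molecule_id)

  is_test <- vapply(mols, function(m) m$id %in% plan$test_ids, logical(1))
  train_confs <- embed_conformers_batch(mols[!is_test],
    n = n_conformers, seed = master_seed * 10L + 1L
  )
  test_confs <- embed_conformers_batch(mols[is_test],
    n = n_conformers, seed = master_seed * 10L + 500003L
  )
  train_records <- featurize_dataset(mols[!is_test], train_confs, lambda)
  test_records <- featurize_dataset(mols[is_test], test_confs, lambda)

  out <- list()
  for (kind in kinds) {
    config <- make_encoder_config(kind,
      hidden_dim = hidden_dim, n_layers = n_layers,
      init_seed = master_seed
    )
    tconfig <- make_train_config(config,
      batch_size = batch_size, max_epochs = max_epochs, patience = patience,
      n_conformers_per_molecule = n_conformers
    )
    model <- train_model("lambda_direct", train_records, plan$repeats[[1L]],
      tconfig,
      seed = master_seed + 77L
    )
    metrics <- evaluate(model, test_records, scheme = "average")
    attr(metrics, "model") <- model
    out[[kind]] <- metrics
  }
  out
}

#' Split-repeat ensembling benchmark for one master seed
#'
#' Trains one model per train/validation re-split (the split-repeat
#' protocol), then compares the test MAE of the unweighted prediction
#' ensemble against the average single-member test MAE.
#'
#' @inheritParams benchmark_symmetry_classes
#' @param kind Encoder kind for the ensemble members.
#' @param n_repeats Number of split repeats / ensemble members.
#' @return List: `ensemble_mae_eV`, `mean_member_mae_eV`, `member_mae_eV`.
#' @export
benchmark_ensembling <- function(mols, labels, master_seed, kind = "graph_2d",
                                 n_repeats = 5L, n_conformers = 1L,
                                 hidden_dim = 48L, n_layers = 2L,
                                 max_epochs = 60L, patience = 15L) {
  ids <- labels$molecule_id
  plan <- make_split_plan(ids, master_seed, n_repeats = n_repeats)
  lambda <- stats::setNames(labels$lambda_eV, labels$molecule_id)
  is_test <- vapply(mols, function(m) m$id %in% plan$test_ids, logical(1))
  train_confs <- embed_conformers_batch(mols[!is_test],
    n = n_conformers, seed = master_seed * 10L + 1L
  )
  test_confs <- embed_conformers_batch(mols[is_test],
    n = n_conformers, seed = master_seed * 10L + 500003L
  )
  train_records <- featurize_dataset(mols[!is_test], train_confs, lambda)
  test_records <- featurize_dataset(mols[is_test], test_confs, lambda)

  models <- lapply(seq_len(n_repeats), function(r) {
    config <- make_encoder_config(kind,
      hidden_dim = hidden_dim, n_layers = n_layers,
      init_seed = master_seed * 100L + r
    )
    tconfig <- make_train_config(config, max_epochs = max_epochs, patience = patience)
    train_model("lambda_direct", train_records, plan$repeats[[r]], tconfig,
      seed = master_seed * 100L + r
    )
  })
  member_mae <- vapply(models, function(m) {
    evaluate(m, test_records, scheme = "average")$mae_eV
  }, numeric(1))
  ens <- evaluate(models, test_records, scheme = "average")
  list(
    ensemble_mae_eV = ens$mae_eV,
    mean_member_mae_eV = mean(member_mae),
    member_mae_eV = member_mae
  )
}
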