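# Experiment protocol: molecule-level splits (fixed 10% test, repeated 8:1
# train/validation over the remainder), conformer-augmented head training,
# metrics, split-repeat ensembling, and the cross-conformer robustness
# diagnostic.

#' Build a split plan
#'
#' Holds out a fixed fraction of molecule ids as the test set, then splits
#' the remainder into train/validation at the requested ratio, once per
#' repeat. Splits are by molecule id, never by conformer, so conformers of
#' one molecule can never leak across partitions.
#'
#' @param ids Character vector of unique molecule ids (>= 20).
#' @param master_seed Integer seed; the whole plan is deterministic in it.
#' @param n_repeats Number of train/validation re-splits (default 5).
#' @param test_frac Test fraction (default 0.10).
#' @param train_val_ratio Target train:validation ratio (default 8).
#' @return A `split_plan`: `test_ids` plus a list of
#'   `repeats[[r]] = list(train_ids, val_ids)`.
#' @export
make_split_plan <- function(ids, master_seed, n_repeats = 5L, test_frac = 0.10,
                            train_val_ratio = 8) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  n <- length(ids)
  if (n < 20L) stop("need at least 20 molecules to build a split plan, got ", n)
  test_ids <- local_seed(master_seed, sample(ids, round(test_frac * n)))
  rest <- setdiff(ids, test_ids)
  n_val <- round(length(rest) / (train_val_ratio + 1))
  repeats <- lapply(seq_len(n_repeats), function(r) {
    perm <- local_seed(master_seed + r, sample(rest))
    list(train_ids = perm[-seq_len(n_val)], val_ids = perm[seq_len(n_val)])
  })
  plan <- structure(
    list(
      test_ids = test_ids, repeats = repeats, n_repeats = as.integer(n_repeats),
      master_seed = as.integer(master_seed)
    ),
    class = "split_plan"
  )
  check_split_plan(plan)
  plan
}

#' Verify split-plan invariants (leak-freedom, ratio)
#' @param plan A `split_plan`.
#' @export
check_split_plan <- function(plan) {
  for (rep in plan$repeats) {
    if (length(intersect(plan$test_ids, c(rep$train_ids, rep$val_ids))) > 0L) {
      stop("split leak: test ids appear in a train/validation partition")
    }
    if (length(intersect(rep$train_ids, rep$val_ids)) > 0L) {
      stop("split leak: train and validation partitions overlap")
    }
    if (abs(length(rep$train_ids) / length(rep$val_ids) - 8) > 1) {
      stop("train:validation ratio departs from 8:1 by more than 1")
    }
  }
  invisible(TRUE)
}

#' Training configuration
#'
#' @param encoder_config An `encoder_config`.
#' @param learning_rate Starting learning rate. Defaults to 1e-3, lowered to
#'   1e-4 for the distance-sensitive encoder, whose loss surface on raw
#'   distance-geometry conformers is prone to gradient divergence at the
#'   higher rate.
#' @param batch_size Minibatch size (default 32).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience on validation MAE (default 20).
#' @param n_conformers_per_molecule Conformer-ensemble augmentation factor
#'   (default 5).
#' @param head_dim Regression-head hidden width.
#' @return A `train_config`.
#' @export
make_train_config <- function(encoder_config, learning_rate = NULL,
                              batch_size = 32L, max_epochs = 100L,
                              patience = 20L, n_conformers_per_molecule = 5L,
                              head_dim = 32L) {
  if (is.null(learning_rate)) {
    learning_rate <- if (encoder_config$kind == "distance_3d") 1e-4 else 1e-3
  }
  stopifnot(
    learning_rate > 0, batch_size >= 1L, max_epochs >= 0L, patience >= 1L,
    n_conformers_per_molecule >= 1L, head_dim >= 1L
  )
  structure(
    list(
      encoder_config = encoder_config,
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      patience = as.integer(patience),
      n_conformers_per_molecule = as.integer(n_conformers_per_molecule),
      head_dim = as.integer(head_dim)
    ),
    class = "train_config"
  )
}

record_targets <- function(records) {
  ids <- vapply(records, function(r) r$molecule_id, character(1))
  targets <- vapply(records, function(r) r$target, numeric(1))
  if (anyNA(targets)) stop("records carry missing targets")
  by_mol <- split(targets, ids)
  bad <- names(by_mol)[vapply(by_mol, function(v) max(v) - min(v) > 1e-12, logical(1))]
  if (length(bad) > 0L) {
    stop(
      "conformers of one molecule must share one target; violated by: ",
      paste(utils::head(bad, 5L), collapse = ", ")
    )
  }
  targets
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (!all(is.finite(g))) {
      stop(
        "non-finite gradient in head parameter '", nm,
        "' (gradient divergence; consider a smaller starting learning rate)"
      )
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

head_forward <- function(par, X) {
  A <- tanh(sweep(X %*% par$W1, 2L, par$b1, `+`))
  list(A = A, y = as.numeric(A %*% par$w2 + par$b2))
}

head_gradients <- function(par, X, target) {
  fwd <- head_forward(par, X)
  dy <- 2 * (fwd$y - target) / length(target)
  dA <- outer(dy, par$w2)
  dZ <- dA * (1 - fwd$A^2)
  list(
    W1 = crossprod(X, dZ),
    b1 = colSums(dZ),
    w2 = as.numeric(crossprod(fwd$A, dy)),
    b2 = sum(dy)
  )
}

#' Train a model on featurized conformer records
#'
#' Encoder weights stay fixed at their seeded random draw; the regression
#' head is trained with Adam on a mean-squared-error loss, with early
#' stopping on validation MAE, returning the best-validation checkpoint.
#' Every conformer of a molecule is trained toward the molecule's single
#' target (conformer-ensemble augmentation): a precondition enforced before
#' training.
#'
#' @param task `"vertical_ip"`, `"vertical_ea"`, or `"lambda_direct"`.
#' @param records Featurized `reorg_record`s with targets (train + val pool).
#' @param split `list(train_ids, val_ids)` of molecule ids (one repeat of a
#'   [make_split_plan()]), or NULL to train on everything without early
#'   stopping.
#' @param config A `train_config`.
#' @param seed Seed for minibatch shuffling.
#' @return A trained `reorg_model`; `model$log` holds per-epoch train and
#'   validation MAE.
#' @export
train_model <- function(task, records, split, config, seed = 1L) {
  stopifnot(inherits(config, "train_config"))
  targets <- record_targets(records)
  ids <- vapply(records, function(r) r$molecule_id, character(1))
  if (is.null(split)) {
    split <- list(train_ids = unique(ids), val_ids = character())
  }
  tr <- which(ids %in% split$train_ids)
  va <- which(ids %in% split$val_ids)
  if (length(tr) == 0L) stop("no training records after applying the split")

  model <- make_model(config$encoder_config, task = task, head_dim = config$head_dim)
  E_all <- embedding_matrix(model, records)
  center <- colMeans(E_all[tr, , drop = FALSE])
  scale <- pmax(apply(E_all[tr, , drop = FALSE], 2L, stats::sd), 1e-8)
  model$scaler <- list(center = center, scale = scale)
  Xtr <- sweep(sweep(E_all[tr, , drop = FALSE], 2L, center), 2L, scale, `/`)
  Xva <- sweep(sweep(E_all[va, , drop = FALSE], 2L, center), 2L, scale, `/`)
  ytr <- targets[tr]
  yva <- targets[va]

  par <- model$head
  par$b2 <- mean(ytr)
  state <- list(
    par = par,
    m = lapply(par, function(p) p * 0),
    v = lapply(par, function(p) p * 0)
  )
  best <- list(par = par, val_mae = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(), train_mae = numeric(), val_mae = numeric())
  t_global <- 0L

  local_seed(seed, {
    epochs_since_best <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample(length(ytr))
      batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
      for (b in batches) {
        t_global <- t_global + 1L
        grads <- head_gradients(state$par, Xtr[b, , drop = FALSE], ytr[b])
        state <- adam_step(state, grads, config$learning_rate, t_global)
      }
      train_mae <- mean(abs(head_forward(state$par, Xtr)$y - ytr))
      val_mae <- if (length(va) > 0L) {
        mean(abs(head_forward(state$par, Xva)$y - yva))
      } else {
        train_mae
      }
      log <- rbind(log, data.frame(epoch = epoch, train_mae = train_mae, val_mae = val_mae))
      if (val_mae < best$val_mae - 1e-12) {
        best <- list(par = state$par, val_mae = val_mae, epoch = epoch)
        epochs_since_best <- 0L
      } else {
        epochs_since_best <- epochs_since_best + 1L
        if (epochs_since_best >= config$patience) break
      }
    }
  })

  model$head <- if (config$max_epochs > 0L) best$par else model$head
  model$log <- log
  model$task <- task
  model
}

#' Regression metrics
#'
#' MAE, RMSE, and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (which can be negative for predictors worse
#' than the mean).
#'
#' @param pred Predictions (eV).
#' @param obs Observed targets (eV).
#' @return Named list: `mae_eV`, `rmse_eV`, `r2`, `n`.
#' @export
regression_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) > 0L)
  res <- pred - obs
  list(
    mae_eV = mean(abs(res)),
    rmse_eV = sqrt(mean(res^2)),
    r2 = 1 - sum(res^2) / sum((obs - mean(obs))^2),
    n = length(obs)
  )
}

model_members <- function(model_or_ensemble) {
  if (inherits(model_or_ensemble, "reorg_model")) {
    return(list(model_or_ensemble))
  }
  stopifnot(is.list(model_or_ensemble), length(model_or_ensemble) >= 1L)
  versions <- unique(vapply(
    model_or_ensemble, function(m) m$featurization_version, character(1)
  ))
  if (length(versions) != 1L) {
    stop("ensemble members mix featurization versions: ", paste(versions, collapse = ", "))
  }
  model_or_ensemble
}

#' Ensemble prediction (unweighted mean of member outputs)
#'
#' @param models List of trained `reorg_model`s (>= 1) sharing one
#'   featurization version.
#' @param records Featurized records.
#' @return Numeric vector of mean predictions, one per record.
#' @export
ensemble_predict <- function(models, records) {
  members <- model_members(models)
  preds <- vapply(members, function(m) predict_records(m, records),
    numeric(length(records))
  )
  if (length(records) == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' Evaluate a model or ensemble on held-out conformer records
#'
#' @param model_or_ensemble A `reorg_model` or list of them.
#' @param test_records Featurized records with targets; molecules must be
#'   unseen during training.
#' @param scheme `"average"` scores the per-molecule mean over conformers
#'   (the deployment scheme); `"per_conformer"` scores every conformer
#'   independently.
#' @return `Metrics` list: `mae_eV`, `rmse_eV`, `r2`,
#'   `mean_conformer_variance_eV2`, `n`.
#' @export
evaluate <- function(model_or_ensemble, test_records,
                     scheme = c("average", "per_conformer")) {
  scheme <- match.arg(scheme)
  if (length(test_records) == 0L) stop("empty test set")
  targets <- record_targets(test_records)
  preds <- ensemble_predict(model_or_ensemble, test_records)
  groups <- group_by_molecule(test_records)
  ids <- vapply(test_records, function(r) r$molecule_id, character(1))
  pred_by_mol <- split(preds, factor(ids, levels = names(groups)))
  conf_var <- vapply(pred_by_mol, pop_var, numeric(1))
  if (scheme == "average") {
    mol_pred <- vapply(pred_by_mol, mean, numeric(1))
    mol_obs <- vapply(
      split(targets, factor(ids, levels = names(groups))),
      function(v) v[[1L]], numeric(1)
    )
    out <- regression_metrics(mol_pred, mol_obs)
  } else {
    out <- regression_metrics(preds, targets)
  }
  out$mean_conformer_variance_eV2 <- mean(conf_var)
  class(out) <- c("reorg_metrics", "list")
  out
}

#' @export
print.reorg_metrics <- function(x, ...) {
  cat(sprintf(
    "MAE %.4f eV | RMSE %.4f eV | R2 %.4f | mean conformer variance %.3e eV^2 | n = %d\n",
    x$mae_eV, x$rmse_eV, x$r2, x$mean_conformer_variance_eV2, x$n
  ))
  invisible(x)
}

#' Cross-conformer robustness diagnostic
#'
#' Embeds `n_conformers` fresh distance-geometry conformers per molecule,
#' predicts with the model, and reports the population variance of the
#' predictions per molecule plus summaries (eV^2 internally; meV^2 and the
#' meV standard deviation in the summary, since the headline diagnostic is
#' quoted at meV scale).
#'
#' @param model A trained `reorg_model`.
#' @param mols List of `molecule_record`s.
#' @param n_conformers Conformers per molecule (default 5).
#' @param seed Embedding seed.
#' @return List with `per_molecule` (data.frame: molecule_id, variance_eV2,
#'   n_conformers), `summary` (mean/max variance in eV^2 and meV^2, mean sd
#'   in meV), and `n_failed` embedding failures (excluded molecules).
#' @export
conformer_robustness <- function(model, mols, n_conformers = 5L, seed = 1L) {
  conf_sets <- vector("list", length(mols))
  failed <- character()
  batch <- tryCatch(
    embed_conformers_batch(mols, n = n_conformers, seed = seed),
    error = function(e) NULL
  )
  if (!is.null(batch)) {
    conf_sets <- batch
  } else {
    for (k in seq_along(mols)) {
      conf_sets[[k]] <- tryCatch(
        embed_conformers(mols[[k]], n = n_conformers, seed = seed + k - 1L),
        error = function(e) {
          failed <<- c(failed, mols[[k]]$id)
          NULL
        }
      )
    }
  }
  keep <- !vapply(conf_sets, is.null, logical(1))
  records <- featurize_dataset(mols[keep], conf_sets[keep])
  preds <- predict_records(model, records)
  ids <- vapply(records, function(r) r$molecule_id, character(1))
  v <- vapply(split(preds, factor(ids, levels = unique(ids))), pop_var, numeric(1))
  per_molecule <- data.frame(
    molecule_id = names(v), variance_eV2 = unname(v),
    n_conformers = n_conformers, row.names = NULL
  )
  list(
    per_molecule = per_molecule,
    summary = list(
      mean_variance_eV2 = mean(v),
      max_variance_eV2 = max(v),
      mean_variance_meV2 = mean(v) * 1e6,
      mean_sd_meV = mean(sqrt(v)) * 1e3
    ),
    n_failed = length(failed),
    failed_ids = failed
  )
}
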