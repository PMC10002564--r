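# End-to-end cold-start experiment: pretrain the unsupervised drug
# representations, split at the drug level, train the pair classifier per
# fold and report Task-1 (known-new) and Task-2 (new-new) metrics.

#' Desk-scale experiment profile
#'
#' The package's default problem-size profile for laptop/CI-scale runs:
#' hidden width 32, 25 epochs, batch 64, Adam learning rate 1e-3, TransE
#' width 64 and notation-embedding width 32. The reference profile
#' (`profile = "paper"`) keeps the full-scale settings: hidden width 64,
#' 350 epochs, batch 512, learning rate 1e-4.
#'
#' @param Nl Number of event classes.
#' @param profile `"desk"` or `"paper"`.
#' @param seed Base seed used for every component.
#' @return List with `model_cfg`, `train_cfg`, `transe_cfg`, `w2v_cfg`.
#' @export
experiment_profile <- function(Nl, profile = c("desk", "paper"), seed = 1) {
  profile <- match.arg(profile)
  seed <- as.integer(seed)
  if (profile == "desk") {
    list(model_cfg = mseddi_config(dim = 32, Nl = Nl, dim_cse = 32,
                                   seed = seed),
         train_cfg = train_config(batch_size = 64, epochs = 25, lr = 1e-3,
                                  seed = seed),
         transe_cfg = transe_config(dim_kge = 64, epochs = 300, seed = seed),
         w2v_cfg = w2v_config(dim_sne = 32, epochs = 30, seed = seed))
  } else {
    list(model_cfg = mseddi_config(dim = 64, Nl = Nl, seed = seed),
         train_cfg = train_config(seed = seed),
         transe_cfg = transe_config(seed = seed),
         w2v_cfg = w2v_config(seed = seed))
  }
}

#' Run the cold-start experiment on a dataset bundle
#'
#' Pretrains TransE on the knowledge graph and the CBOW notation embedder on
#' all drugs' SMILES (both label-free, so using all drugs leaks no event
#' information), splits the drugs into `k` cold-start folds, trains the pair
#' classifier on each fold's known-known pairs and evaluates Task 1
#' (known-new) and Task 2 (new-new).
#'
#' @param bundle A `ddi_bundle`.
#' @param k Number of folds.
#' @param profile Settings from [experiment_profile()] (or a compatible
#'   list); default desk profile.
#' @param folds Optional integer vector restricting which folds to run.
#' @param seed Seed for the drug split.
#' @param keep_fits Keep the per-fold fitted models in the result.
#' @param verbose Print per-fold progress.
#' @return An `mseddi_experiment`: list with `per_fold` (tibble of metrics
#'   per fold and task), `summary` (mean and sd per task), and optionally
#'   `fits`.
#' @export
run_experiment <- function(bundle, k = 5, profile = NULL, folds = NULL,
                           seed = 1, keep_fits = FALSE, verbose = FALSE) {
  if (is.null(profile)) profile <- experiment_profile(bundle$events$Nl,
                                                      seed = seed)
  stopifnot(profile$model_cfg$Nl == bundle$events$Nl)
  transe <- train_transe(bundle$triplets, profile$transe_cfg)
  cbow <- train_cbow(lapply(bundle$drugs$smiles, tokenize_smiles),
                     profile$w2v_cfg)
  features <- drug_features(bundle, transe, cbow)
  splits <- cold_start_split(bundle, k = k, seed = seed)
  if (is.null(folds)) folds <- seq_len(k)
  rows <- list()
  fits <- list()
  for (f in folds) {
    split <- splits[[f]]
    fit <- train_model(split, features, profile$model_cfg,
                       profile$train_cfg)
    for (task in c("task1", "task2")) {
      pairs <- split[[paste0(task, "_pairs")]]
      if (nrow(pairs) == 0L) next
      m <- evaluate(fit, pairs)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = f, task = task, n = m$n, acc = m$acc,
        aupr_micro = m$aupr_micro, auc_micro = m$auc_micro,
        f1_macro = m$f1_macro)
      if (verbose) {
        message(sprintf("fold %d %s: ACC %.3f AUPR %.3f AUC %.3f F1 %.3f",
                        f, task, m$acc, m$aupr_micro, m$auc_micro,
                        m$f1_macro))
      }
    }
    if (keep_fits) fits[[as.character(f)]] <- fit
  }
  per_fold <- dplyr::bind_rows(rows)
  summary <- per_fold |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(dplyr::across(c("acc", "aupr_micro", "auc_micro",
                                     "f1_macro"),
                                   list(mean = mean, sd = stats::sd)),
                     .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary,
                 transe = transe, cbow = cbow,
                 fits = if (keep_fits) fits else NULL),
            class = "mseddi_experiment")
}

#' @export
print.mseddi_experiment <- function(x, ...) {
  cat("<mseddi_experiment>\n")
  print(x$summary)
  invisible(x)
}
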