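#' Build the three feature blocks of a synthetic study
#'
#' Latent block: embedding composition of the compound names from the
#' fixture's vector table. Interaction block: restart-walk stationary
#' vectors restricted to the disease-related proteins, reduced by a
#' principal-component model fitted on the *training* rows only. Chemical
#' block: descriptor encoding with Z-score statistics fitted on the
#' training rows only.
#'
#' @param fixture Output of [generate_fixture()].
#' @param train_ids Compound ids used to fit the reduction and scaling
#'   models (all compounds by default; pass the training split to avoid
#'   leakage in evaluation settings).
#' @param pca_threshold Cumulative explained-variance threshold of the
#'   interaction reduction (default 0.8).
#' @return List with `features` (a `feature_matrix`), `reduction` and
#'   `scaling` (the fitted models).
#' @export
fixture_feature_matrix <- function(fixture, train_ids = names(fixture$profiles),
                                   pca_threshold = 0.8) {
  ids <- names(fixture$profiles)
  lb <- latent_block(ids, ids, fixture$embedding)
  disease_proteins <- unique(unlist(fixture$modules))
  raw <- interaction_raw_features(fixture$network, fixture$profiles,
                                  disease_proteins)
  reduction <- fit_reduction(raw[train_ids, , drop = FALSE],
                             threshold = pca_threshold)
  ib <- apply_reduction(reduction, raw)
  scaling <- fit_scaling(fixture$descriptors, fixture_descriptor_schema(),
                         training_ids = train_ids)
  cb <- encode_descriptors(fixture$descriptors, scaling)
  features <- assemble_features(
    list(latent = lb, interaction = ib, chemical = cb[ids, , drop = FALSE]),
    row_ids = ids
  )
  list(features = features, reduction = reduction, scaling = scaling)
}

#' Mask spec proportional to assembled block widths
#'
#' Convenience constructor for desk-scale models: per-block hidden widths
#' are a fixed fraction of the input widths (at least 4 units per block).
#'
#' @param features A `feature_matrix` from [assemble_features()].
#' @param hidden_frac Hidden/input width ratio (default 0.5).
#' @return A [pcnn_mask_spec()].
#' @export
proportional_mask_spec <- function(features, hidden_frac = 0.5) {
  widths <- attr(features, "block_spans")
  pcnn_mask_spec(widths, pmax(4L, as.integer(ceiling(widths * hidden_frac))))
}

#' Largest masked-out weight magnitude of a trained model
#'
#' Partial layers must keep masked entries at exactly zero through training;
#' this returns the maximum absolute value found on masked-out positions
#' (0 for a healthy model).
#'
#' @param model A `pcnn_model`.
#' @return Scalar, `max |W * (1 - mask)|` over the masked layers.
#' @export
mask_violation <- function(model) {
  viol <- vapply(model$layers, function(ly) {
    if (is.null(ly$mask)) return(0)
    max(abs(ly$W * (1 - ly$mask)))
  }, numeric(1))
  max(viol)
}

train_eval_core <- function(features, labels, strat, seed, tc, fc_widths,
                            hidden_frac) {
  ids <- rownames(features)
  plan <- make_split(ids, c(6, 2, 2), seed = seed, labels = strat)
  spec <- proportional_mask_spec(features, hidden_frac)
  train_idx <- match(plan$splits$train, ids)
  val_idx <- match(plan$splits$validation, ids)
  test_idx <- match(plan$splits$test, ids)
  models <- lapply(colnames(labels), function(dz) {
    pcnn_train(features, labels[ids, dz], spec, config = tc,
               fc_widths = fc_widths, val_idx = val_idx,
               train_idx = train_idx)
  })
  names(models) <- colnames(labels)
  scores <- predict_disease_models(models, features[test_idx, , drop = FALSE])
  per_disease <- vapply(colnames(labels), function(dz) {
    auroc(scores[, dz], labels[plan$splits$test, dz])
  }, numeric(1))
  list(models = models, split = plan, scores = scores,
       per_disease_auroc = per_disease,
       mean_auroc = mean(per_disease),
       max_mask_violation = max(vapply(models, mask_violation, numeric(1))))
}

#' End-to-end synthetic-study pipeline
#'
#' Generates a fixture, builds all three feature blocks (reduction and
#' scaling fitted on the training split), trains one partially connected
#' model per disease, and reports the held-out (test-split) AUROC per
#' disease and its macro average. The split is stratified by the planted
#' disease assignment so every disease's positives appear in all three
#' partitions.
#'
#' @param config A [fixture_config()].
#' @param tc A [train_config()]; defaults to the standard settings with the
#'   fixture's seed.
#' @param fc_widths Fully connected hidden widths at fixture scale
#'   (default `c(32, 16)`).
#' @param hidden_frac Per-block partial-layer width ratio (default 0.5).
#' @param pca_threshold Interaction-reduction variance threshold.
#' @return List with `per_disease_auroc`, `mean_auroc`, `models`, `split`,
#'   `scores`, `max_mask_violation`, `features`, `fixture`.
#' @export
run_fixture_pipeline <- function(config = fixture_config(),
                                 tc = train_config(seed = config$seed),
                                 fc_widths = c(32L, 16L),
                                 hidden_frac = 0.5, pca_threshold = 0.8) {
  fixture <- generate_fixture(config)
  ids <- names(fixture$profiles)
  strat <- ifelse(is.na(fixture$assignment), "none", fixture$assignment)
  plan0 <- make_split(ids, c(6, 2, 2), seed = config$seed, labels = strat)
  fb <- fixture_feature_matrix(fixture, train_ids = plan0$splits$train,
                               pca_threshold = pca_threshold)
  res <- train_eval_core(fb$features, fixture$labels, strat, config$seed,
                         tc, fc_widths, hidden_frac)
  c(res, list(features = fb$features, fixture = fixture))
}

#' Label-permutation control of the synthetic-study pipeline
#'
#' Repeats the pipeline evaluation with compound labels randomly permuted
#' (features untouched), destroying any feature-label association; the
#' macro-average held-out AUROC should sit near 0.5. The permutation null
#' is averaged over `n_perm` independent permutations to stabilize the
#' estimate at the small per-disease test sizes of the default fixture.
#'
#' @param config A [fixture_config()].
#' @param tc A [train_config()].
#' @param n_perm Number of independent label permutations (default 5).
#' @param ... Passed to the shared training core (`fc_widths`,
#'   `hidden_frac`).
#' @return List with `mean_auroc` (grand mean over permutations),
#'   `per_perm_auroc` and `max_mask_violation`.
#' @export
run_permuted_control <- function(config = fixture_config(),
                                 tc = train_config(seed = config$seed),
                                 n_perm = 5L, fc_widths = c(32L, 16L),
                                 hidden_frac = 0.5) {
  fixture <- generate_fixture(config)
  ids <- names(fixture$profiles)
  strat <- ifelse(is.na(fixture$assignment), "none", fixture$assignment)
  plan0 <- make_split(ids, c(6, 2, 2), seed = config$seed, labels = strat)
  fb <- fixture_feature_matrix(fixture, train_ids = plan0$splits$train)
  per_perm <- numeric(n_perm)
  worst_mask <- 0
  for (k in seq_len(n_perm)) {
    set.seed(config$seed * 1000L + k)
    perm <- sample(length(ids))
    labels_p <- fixture$labels[perm, , drop = FALSE]
    rownames(labels_p) <- ids
    strat_p <- strat[perm]
    tc_k <- tc
    tc_k$seed <- tc$seed + k
    res <- train_eval_core(fb$features, labels_p, strat_p,
                           config$seed + k, tc_k, fc_widths, hidden_frac)
    per_perm[k] <- res$mean_auroc
    worst_mask <- max(worst_mask, res$max_mask_violation)
  }
  list(mean_auroc = mean(per_perm), per_perm_auroc = per_perm,
       max_mask_violation = worst_mask)
}
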