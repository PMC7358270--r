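#' Build a stratified cross-validation fold plan
#'
#' Subjects are stratified by site: within each site the order is shuffled
#' (seeded) and subjects are dealt round-robin into `k` disjoint test folds,
#' so per-site proportions in every fold match the cohort within one subject.
#' For each fold, `val_fraction` of the non-test subjects (rounded to
#' nearest) is split off as the validation set — for 90 subjects at k = 6
#' that is 15 test, 60 training and 15 validation subjects per fold.
#'
#' @param subject_ids Character vector of subject identifiers.
#' @param sites Matching site labels.
#' @param k Number of folds (default 6).
#' @param val_fraction Validation fraction of the non-test subjects
#'   (default 0.20).
#' @param seed Integer seed.
#' @return A `fold_plan`: list of `k` folds, each with `train`, `validation`
#'   and `test` id vectors.
#' @export
make_folds <- function(subject_ids, sites, k = 6, val_fraction = 0.20,
                       seed = 1) {
  stopifnot(k >= 2, length(subject_ids) >= k,
            length(subject_ids) == length(sites),
            !anyDuplicated(subject_ids))
  site_tab <- table(sites)
  if (any(site_tab < k))
    warning("a site has fewer subjects than folds; stratification is best-effort")
  folds <- with_seed(seed, {
    assignment <- integer(length(subject_ids))
    offset <- 0L
    for (s in names(sort(site_tab, decreasing = TRUE))) {
      idx <- which(sites == s)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    lapply(seq_len(k), function(f) {
      test <- subject_ids[assignment == f]
      rest <- subject_ids[assignment != f]
      rest_sites <- sites[assignment != f]
      n_val <- round(val_fraction * length(rest))
      if (n_val > 0) {
        # order by site then shuffle within site; evenly spaced picks keep
        # the validation set spread across sites
        ord <- order(rest_sites, sample.int(length(rest)))
        pos <- unique(round(seq(1, length(rest), length.out = n_val)))
        while (length(pos) < n_val)
          pos <- c(pos, setdiff(seq_along(rest), pos)[1])
        val_pick <- rest[ord][sort(pos)]
      } else val_pick <- character(0)
      list(train = setdiff(rest, val_pick), validation = val_pick,
           test = test)
    })
  })
  structure(folds, class = "fold_plan", k = k, val_fraction = val_fraction,
            seed = seed, subject_ids = subject_ids, sites = sites)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: %d folds over %d subjects\n", attr(x, "k"),
              length(attr(x, "subject_ids"))))
  for (f in seq_along(x))
    cat(sprintf("  fold %d: %d train / %d validation / %d test\n", f,
                length(x[[f]]$train), length(x[[f]]$validation),
                length(x[[f]]$test)))
  invisible(x)
}

#' Validation-set size for a train/validation split
#'
#' Nearest-integer rounding of `val_fraction * n_train`: 20% of 54 subjects
#' gives 11 validation cases.
#'
#' @param n_train Number of training-cohort subjects.
#' @param val_fraction Fraction held out for validation.
#' @return Integer validation count.
#' @export
validation_count <- function(n_train, val_fraction = 0.20) {
  as.integer(round(val_fraction * n_train))
}

cases_by_id <- function(cases) {
  ids <- vapply(cases, function(cs) cs$subject_id, character(1))
  names(cases) <- ids
  cases
}

run_one_arm <- function(train_cases, val_cases, test_cases, train_config,
                        arch_spec, fold_seed, min_voxels = 3,
                        connectivity = 18, verbose = FALSE) {
  cfg <- train_config
  cfg$seed <- fold_seed
  model <- build_model(arch_spec, init_seed = fold_seed)
  fit <- train(model, train_cases, val_cases, cfg, verbose = verbose)
  norm_case <- function(cs) {
    cs$flair <- zscore_normalize(cs$flair)
    cs$mp2rage <- zscore_normalize(cs$mp2rage)
    cs
  }
  val_probs <- lapply(val_cases, function(cs)
    predict_volume(fit$model, norm_case(cs), threshold = 0.5,
                   input_side = cfg$input_side)$prob)
  val_gts <- lapply(val_cases, function(cs) cs$gt)
  thr <- select_threshold(val_probs, val_gts, min_voxels = min_voxels,
                          connectivity = connectivity)
  rows <- lapply(test_cases, function(cs) {
    pred <- predict_volume(fit$model, norm_case(cs), threshold = thr,
                           input_side = cfg$input_side)
    evaluate_case(pred$mask, cs$gt, min_voxels = min_voxels,
                  connectivity = connectivity, subject_id = cs$subject_id)
  })
  list(fit = fit, threshold = thr, per_subject = do.call(rbind, rows))
}

#' Run a stratified cross-validation experiment
#'
#' For each fold: train a fresh model on the training split (fold-specific
#' seed derived from `master_seed`), pick the probability threshold on the
#' validation split with [select_threshold()], and evaluate the full metric
#' suite on the test split. Per-subject test rows of all folds are pooled
#' into one [metrics_report()].
#'
#' @param cohort List of [subject_case()]s (e.g. `$case` of [make_cohort()]
#'   phantoms).
#' @param fold_plan A [make_folds()] plan over the cohort's subject ids.
#' @param train_config A [train_config()].
#' @param arch_spec A [unet_spec()].
#' @param master_seed Master seed from which fold seeds are derived.
#' @param min_voxels,connectivity Evaluation parameters.
#' @param verbose Print progress?
#' @return List with `report` (pooled [metrics_report()]), `thresholds` and
#'   `per_fold` details.
#' @export
run_cross_validation <- function(cohort, fold_plan, train_config, arch_spec,
                                 master_seed = 1, min_voxels = 3,
                                 connectivity = 18, verbose = FALSE) {
  cohort <- cases_by_id(cohort)
  per_fold <- vector("list", length(fold_plan))
  for (f in seq_along(fold_plan)) {
    fp <- fold_plan[[f]]
    if (verbose) message(sprintf("fold %d/%d", f, length(fold_plan)))
    per_fold[[f]] <- run_one_arm(cohort[fp$train], cohort[fp$validation],
                                 cohort[fp$test], train_config, arch_spec,
                                 fold_seed = derive_seed(master_seed, f),
                                 min_voxels = min_voxels,
                                 connectivity = connectivity,
                                 verbose = verbose)
  }
  pooled <- do.call(rbind, lapply(per_fold, function(x) x$per_subject))
  list(report = metrics_report(pooled),
       thresholds = vapply(per_fold, function(x) x$threshold, numeric(1)),
       per_fold = per_fold)
}

#' Run a cross-site train/test experiment
#'
#' Trains on one cohort (keeping `val_fraction` of it, rounded to nearest,
#' as validation — 20% of 54 subjects gives n = 11) and evaluates on a
#' disjoint test cohort, mirroring a two-hospital generalization study.
#'
#' @param train_cohort,test_cohort Disjoint lists of [subject_case()]s.
#' @param train_config,arch_spec As in [run_cross_validation()].
#' @param val_fraction Validation fraction of the training cohort.
#' @param master_seed Seed for the validation split and training.
#' @param min_voxels,connectivity Evaluation parameters.
#' @param verbose Print progress?
#' @return List with `report`, `threshold` and the fitted model.
#' @export
run_split_experiment <- function(train_cohort, test_cohort, train_config,
                                 arch_spec, val_fraction = 0.20,
                                 master_seed = 1, min_voxels = 3,
                                 connectivity = 18, verbose = FALSE) {
  train_cohort <- cases_by_id(train_cohort)
  test_cohort <- cases_by_id(test_cohort)
  if (length(intersect(names(train_cohort), names(test_cohort))) > 0)
    stop("overlapping subject ids between train and test cohorts")
  n_val <- validation_count(length(train_cohort), val_fraction)
  if (n_val < 1) stop("validation split is empty; increase val_fraction")
  val_ids <- with_seed(derive_seed(master_seed, 0),
                       sample(names(train_cohort), n_val))
  arm <- run_one_arm(train_cohort[setdiff(names(train_cohort), val_ids)],
                     train_cohort[val_ids], test_cohort, train_config,
                     arch_spec, fold_seed = derive_seed(master_seed, 1),
                     min_voxels = min_voxels, connectivity = connectivity,
                     verbose = verbose)
  list(report = metrics_report(arm$per_subject), threshold = arm$threshold,
       fit = arm$fit)
}
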