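# Prediction-run manifests (replicates x seeds x models), the pluggable
# predictor-backend contract, and collection of per-task outputs into a
# conformer ensemble. Neural-network inference itself always lives behind
# a backend; dropout rates and recycle counts are pass-through metadata
# that command-line adapters translate into tool flags.

#' Default inference dropout rates
#'
#' 10% for the Evoformer stack and 25% for the structure module — the
#' rates found to improve conformational sampling when dropout is kept
#' enabled at inference time.
#' @export
default_dropout <- function() {
  list(evoformer_rate = 0.10, structure_module_rate = 0.25)
}

#' Build a prediction manifest
#'
#' Enumerates the full cross product of replicates, seeds and models in
#' (replicate, seed, model) lexicographic order. The standard protocol is
#' 3 replicates x 32 seeds x 5 models = 480 predictions per test (160 per
#' replicate), 3 recycles each. Per-task seeds are derived
#' deterministically from `params$rng_seed` by a frozen integer mixing
#' function, so re-building a manifest reproduces every seed.
#'
#' @param n_replicates,n_seeds,n_models positive integers.
#' @param params a [subsampling_params()]; its `rng_seed` is the master
#'   seed.
#' @param recycles non-negative integer (default 3).
#' @param dropout list with `evoformer_rate` and `structure_module_rate`
#'   (default [default_dropout()]).
#' @return object of class `prediction_manifest`: `tasks` data.frame
#'   (task_id, replicate, seed_index, seed, model), `params`, `recycles`,
#'   `dropout`.
#' @export
build_manifest <- function(n_replicates, n_seeds, n_models,
                           params = subsampling_params(),
                           recycles = 3L, dropout = default_dropout()) {
  for (v in c(n_replicates, n_seeds, n_models)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      stop_validation("replicate/seed/model counts must be positive integers")
    }
  }
  if (recycles < 0) stop_validation("recycles must be >= 0")
  stopifnot(inherits(params, "subsampling_params"))
  tasks <- expand.grid(model = seq_len(n_models),
                       seed_index = seq_len(n_seeds),
                       replicate = seq_len(n_replicates))
  tasks <- tasks[, c("replicate", "seed_index", "model")]
  tasks <- tasks[order(tasks$replicate, tasks$seed_index, tasks$model), ]
  tasks$seed <- mix_seed(params$rng_seed, tasks$replicate, tasks$seed_index)
  tasks$task_id <- seq_len(nrow(tasks))
  rownames(tasks) <- NULL
  tasks <- tasks[, c("task_id", "replicate", "seed_index", "seed", "model")]
  # seeds must be unique within each replicate
  collided <- vapply(split(tasks, tasks$replicate), function(d) {
    anyDuplicated(unique(d$seed[!duplicated(d$seed_index)])) > 0 ||
      length(unique(d$seed)) != length(unique(d$seed_index))
  }, logical(1))
  if (any(collided)) stop("seed derivation produced a collision")
  structure(list(tasks = tasks, params = params,
                 recycles = as.integer(recycles), dropout = dropout),
            class = "prediction_manifest")
}

#' @export
print.prediction_manifest <- function(x, ...) {
  cat(sprintf(
    "prediction_manifest: %d tasks (%d replicates x %d seeds x %d models), %d recycles, dropout %s/%s, max_seq:extra_seq %d:%d\n",
    nrow(x$tasks), length(unique(x$tasks$replicate)),
    length(unique(x$tasks$seed_index)), length(unique(x$tasks$model)),
    x$recycles, x$dropout$evoformer_rate, x$dropout$structure_module_rate,
    x$params$max_seq, x$params$extra_seq))
  invisible(x)
}

#' Serialize a manifest as a TSV table
#' @param manifest a `prediction_manifest`.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  t <- manifest$tasks
  t$max_seq <- manifest$params$max_seq
  t$extra_seq <- manifest$params$extra_seq
  t$recycles <- manifest$recycles
  t$evoformer_dropout <- manifest$dropout$evoformer_rate
  t$structure_dropout <- manifest$dropout$structure_module_rate
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a predictor backend
#'
#' A backend wraps whatever produces one structure from one featurized
#' (subsampled) alignment — an external structure-prediction tool, or the
#' package's own [mock_backend()] for testing. The contract: `predict_fn`
#' is called as `predict_fn(subsampled_msa, seed, model_id)` and must
#' return a `protein_structure` with per-residue confidence; identical
#' inputs and seed must give identical output.
#'
#' @param name backend label.
#' @param predict_fn prediction function (see above).
#' @param honors_dropout,honors_recycles capability flags (metadata).
#' @return object of class `predictor_backend`.
#' @export
predictor_backend <- function(name, predict_fn, honors_dropout = FALSE,
                              honors_recycles = FALSE) {
  if (!is.function(predict_fn)) stop_validation("predict_fn must be a function")
  structure(list(name = name, predict_fn = predict_fn,
                 capabilities = list(dropout = honors_dropout,
                                     recycles = honors_recycles)),
            class = "predictor_backend")
}

#' Run all tasks of a manifest through a backend
#'
#' For each task, the source alignment is re-subsampled with that task's
#' derived seed (so every prediction sees its own random cluster-center
#' draw), the backend is called, and the resulting structure is tagged
#' with (replicate, seed, model). Failing tasks are quarantined with
#' their error message rather than aborting the run.
#'
#' @param manifest a [build_manifest()] result.
#' @param backend a [predictor_backend()].
#' @param msa the source `msa`.
#' @return a `conformer_ensemble`; failed tasks are listed in
#'   `$failures`.
#' @export
run_predictions <- function(manifest, backend, msa) {
  stopifnot(inherits(manifest, "prediction_manifest"),
            inherits(msa, "msa"))
  if (!inherits(backend, "predictor_backend")) {
    stop(structure(class = c("subfold_config_error", "error", "condition"),
                   list(message = "backend does not satisfy the predictor contract",
                        call = sys.call())))
  }
  tasks <- manifest$tasks
  structures <- vector("list", nrow(tasks))
  fail <- list()
  for (i in seq_len(nrow(tasks))) {
    tk <- tasks[i, ]
    res <- tryCatch({
      params <- subsampling_params(manifest$params$max_seq,
                                   manifest$params$extra_seq,
                                   rng_seed = tk$seed)
      sub <- withCallingHandlers(
        subsample_msa(msa, params),
        warning = function(w) invokeRestart("muffleWarning"))
      s <- backend$predict_fn(sub, tk$seed, tk$model)
      s$provenance <- list(replicate = tk$replicate, seed = tk$seed,
                           model = tk$model)
      s
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail[[length(fail) + 1L]] <- data.frame(
        task_id = tk$task_id, replicate = tk$replicate, seed = tk$seed,
        model = tk$model, reason = conditionMessage(res))
    } else {
      structures[[i]] <- res
    }
  }
  structures <- structures[!vapply(structures, is.null, logical(1))]
  failures <- if (length(fail)) do.call(rbind, fail) else NULL
  if (length(structures) == 0L) {
    stop("all prediction tasks failed; first reason: ", failures$reason[1])
  }
  conformer_ensemble(structures, failures)
}

#' Write an ensemble as one PDB per task
#'
#' Files are named `{replicate}_{seed}_{model}.pdb` so provenance
#' round-trips through [read_ensemble()].
#'
#' @param ens a `conformer_ensemble`.
#' @param dir output directory, created if needed.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- ensemble_provenance(ens)
  for (i in seq_along(ens$structures)) {
    fn <- if (!is.na(pr$replicate[i])) {
      sprintf("%d_%d_%d.pdb", pr$replicate[i], pr$seed[i], pr$model[i])
    } else {
      paste0(pr$id[i], ".pdb")
    }
    write_pdb(ens$structures[[i]], file.path(dir, fn))
  }
  invisible(dir)
}
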