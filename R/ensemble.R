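# Conformer-ensemble container and the ensemble analysis: RMSD projection
# onto two reference states, state binning, relative state populations
# with across-replicate SEM, region RMSD distributions, unfolded-structure
# detection, and subsampling-parameter scans.

#' Construct a conformer ensemble
#'
#' @param structures list of `protein_structure` objects, each carrying
#'   provenance (replicate/seed/model or a label).
#' @param failures data.frame of failed prediction tasks
#'   (task_id, replicate, seed, model, reason) or NULL.
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(structures, failures = NULL) {
  stopifnot(all(vapply(structures, inherits, logical(1), "protein_structure")))
  if (is.null(failures)) {
    failures <- data.frame(task_id = integer(0), replicate = integer(0),
                           seed = integer(0), model = integer(0),
                           reason = character(0))
  }
  structure(list(structures = structures, failures = failures),
            class = "conformer_ensemble")
}

#' @export
length.conformer_ensemble <- function(x) length(x$structures)

#' @export
print.conformer_ensemble <- function(x, ...) {
  pr <- ensemble_provenance(x)
  cat(sprintf("conformer_ensemble: %d structures (%d replicates), %d failed tasks\n",
              length(x), length(unique(pr$replicate)), nrow(x$failures)))
  invisible(x)
}

#' Provenance table of an ensemble
#' @param ens a `conformer_ensemble`.
#' @return data.frame with one row per conformer: id, replicate, seed, model.
#' @export
ensemble_provenance <- function(ens) {
  get1 <- function(s, f) {
    v <- s$provenance[[f]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }
  data.frame(
    id = vapply(seq_along(ens$structures), function(i) {
      lab <- ens$structures[[i]]$provenance$label
      if (!is.null(lab)) as.character(lab) else sprintf("conformer_%04d", i)
    }, character(1)),
    replicate = vapply(ens$structures, get1, integer(1), "replicate"),
    seed = vapply(ens$structures, get1, integer(1), "seed"),
    model = vapply(ens$structures, get1, integer(1), "model")
  )
}

#' Read an ensemble of predicted structures
#'
#' @param paths vector of PDB file paths, or a single directory in which
#'   case all `*.pdb` files are read in lexicographic order.
#' @param check_range optional residue range; structures missing backbone
#'   atoms there are excluded with a warning (they cannot enter RMSD
#'   analyses).
#' @return a `conformer_ensemble`.
#' @export
read_ensemble <- function(paths, check_range = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.pdb$", full.names = TRUE))
  }
  if (length(paths) == 0L) stop_validation("no structure files to read")
  structures <- lapply(paths, read_pdb)
  if (!is.null(check_range)) {
    rng <- parse_residue_range(check_range)
    ok <- vapply(structures, function(s) {
      bb <- s$atoms[s$atoms$residue_number %in% rng &
                      s$atoms$atom_name %in% BACKBONE_ATOMS, ]
      nrow(bb) >= 4L * length(intersect(rng, residue_numbers(s)))
    }, logical(1))
    if (any(!ok)) {
      warning(sum(!ok), " structure(s) missing backbone atoms in the ",
              "analyzed range were excluded")
      structures <- structures[ok]
    }
  }
  conformer_ensemble(structures)
}

#' Project an ensemble onto two reference states
#'
#' For every conformer, computes the backbone RMSD to reference A and to
#' reference B (each fitted on its own `fit_range`, measured on its
#' `calc_range`) plus the mean CA pLDDT over reference A's `calc_range`.
#' This is the two-dimensional projection conventionally used to display
#' a predicted ensemble between an active and an inactive state.
#'
#' @param ens a `conformer_ensemble`.
#' @param ref_a,ref_b [reference_state()] objects with matching
#'   `calc_range` semantics.
#' @return data.frame: id, replicate, seed, model, rmsd_to_A, rmsd_to_B,
#'   mean_plddt.
#' @export
project_ensemble <- function(ens, ref_a, ref_b) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  pr <- ensemble_provenance(ens)
  pr$rmsd_to_A <- vapply(ens$structures, backbone_rmsd, numeric(1), ref = ref_a)
  pr$rmsd_to_B <- vapply(ens$structures, backbone_rmsd, numeric(1), ref = ref_b)
  pr$mean_plddt <- vapply(ens$structures, mean_plddt, numeric(1),
                          residues = ref_a$calc_range)
  pr
}

#' State-binning scheme
#'
#' Nearest-reference binning with absolute cutoffs and a separation
#' margin. A conformer is `state_A` when its RMSD to A is at most
#' `cutoff_A` and exceeds the RMSD to B by at least `margin` (and
#' symmetrically for `state_B`); everything else is `intermediate`.
#' Defaults (3.5 / 3.5 / 1.0 Angstrom) are deliberately conservative and
#' should be tuned per system.
#'
#' @param cutoff_A,cutoff_B absolute RMSD cutoffs in Angstrom.
#' @param margin required RMSD separation in Angstrom.
#' @export
binning_scheme <- function(cutoff_A = 3.5, cutoff_B = 3.5, margin = 1.0) {
  if (cutoff_A < 0 || cutoff_B < 0 || margin < 0) {
    stop_validation("binning scheme cutoffs and margin must be non-negative")
  }
  structure(list(cutoff_A = cutoff_A, cutoff_B = cutoff_B, margin = margin),
            class = "binning_scheme")
}

#' Bin projected conformers into states
#'
#' @param points projection data.frame from [project_ensemble()].
#' @param scheme a [binning_scheme()].
#' @param unfolded optional logical vector from [detect_unfolded()];
#'   flagged conformers are labelled `unfolded` before thresholding.
#' @return `points` with an added factor column `label` with levels
#'   `state_A`, `state_B`, `intermediate`, `unfolded`, `other`; the scheme
#'   is attached as attribute `"scheme"`.
#' @export
assign_states <- function(points, scheme = binning_scheme(), unfolded = NULL) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (is.null(unfolded)) unfolded <- rep(FALSE, nrow(points))
  if (length(unfolded) != nrow(points)) {
    stop_validation("unfolded flag length does not match points")
  }
  da <- points$rmsd_to_A; db <- points$rmsd_to_B
  lab <- rep("intermediate", nrow(points))
  lab[da <= scheme$cutoff_A & (db - da) >= scheme$margin] <- "state_A"
  lab[db <= scheme$cutoff_B & (da - db) >= scheme$margin] <- "state_B"
  lab[unfolded] <- "unfolded"
  points$label <- factor(lab, levels = c("state_A", "state_B", "intermediate",
                                         "unfolded", "other"))
  attr(points, "scheme") <- scheme
  points
}

#' Relative state populations with across-replicate SEM
#'
#' Within each replicate the fraction of conformers in each state is
#' computed; the estimate is the across-replicate mean with its standard
#' error (sample standard deviation over replicates, n-1 denominator,
#' divided by sqrt(n_replicates)). This mirrors reporting populations as
#' mean +/- SEM over three independent prediction runs.
#'
#' @param assignments output of [assign_states()] (must carry a
#'   `replicate` column).
#' @param include_unfolded if TRUE (default) unfolded conformers stay in
#'   the denominator as their own state; if FALSE they are dropped before
#'   fractions are computed.
#' @return object of class `population_estimate`: list with `per_state`
#'   (replicate x state fraction matrix), `mean`, `sem`, `n_replicates`.
#' @export
population_estimate <- function(assignments, include_unfolded = TRUE) {
  if (!"label" %in% names(assignments)) {
    stop_validation("assignments must come from assign_states()")
  }
  if (!"replicate" %in% names(assignments) || anyNA(assignments$replicate)) {
    stop_validation("assignments must carry replicate provenance")
  }
  if (!include_unfolded) {
    assignments <- assignments[assignments$label != "unfolded", ]
  }
  reps <- sort(unique(assignments$replicate))
  if (length(reps) == 0L) stop_validation("no replicates present")
  counts <- table(assignments$replicate, assignments$label)
  if (any(rowSums(counts) == 0L)) stop_validation("empty replicate group")
  frac <- sweep(unclass(counts), 1L, rowSums(counts), "/")
  mean_pop <- colMeans(frac)
  n <- nrow(frac)
  if (n == 1L) {
    warning("single replicate: SEM reported as 0")
    sem <- stats::setNames(rep(0, ncol(frac)), colnames(frac))
  } else {
    sem <- apply(frac, 2L, stats::sd) / sqrt(n)
  }
  structure(list(per_state = frac, mean = mean_pop, sem = sem,
                 n_replicates = n),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat(sprintf("population_estimate over %d replicate(s):\n", x$n_replicates))
  for (s in colnames(x$per_state)) {
    if (x$mean[[s]] > 0 || s %in% c("state_A", "state_B")) {
      cat(sprintf("  %-12s %.3f +/- %.3f\n", s, x$mean[[s]], x$sem[[s]]))
    }
  }
  invisible(x)
}

#' Distribution of backbone RMSD over a region
#'
#' Per-conformer backbone RMSD against the reference (fit on the
#' reference's `fit_range`, measured on `region`), summarized the way a
#' box plot is: median (midpoint interpolation for even counts),
#' quartiles, extremes.
#'
#' @param ens a `conformer_ensemble`.
#' @param ref a [reference_state()]; its `fit_range` is used for the fit.
#' @param region residues measured, e.g. `"80-90"` or `"110-125"`.
#' @return list with `values`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
region_rmsd_distribution <- function(ens, ref, region) {
  region_ref <- reference_state(ref$label, ref$structure, ref$fit_range,
                                calc_range = region)
  values <- vapply(ens$structures, backbone_rmsd, numeric(1), ref = region_ref)
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(values = values, median = qs[2], q1 = qs[1], q3 = qs[3],
       min = min(values), max = max(values))
}

#' Flag partially unfolded conformers
#'
#' A conformer is flagged when its backbone radius of gyration exceeds
#' `rg_ratio_max` times the reference's, or when its global backbone RMSD
#' to the reference (fit and measured over all shared residues) exceeds
#' `global_rmsd_max`. Aggressive subsampling of shallow alignments
#' occasionally yields such structures with no experimental analog; they
#' are reported separately so populations can be computed with or without
#' them.
#'
#' @param ens a `conformer_ensemble`.
#' @param ref a [reference_state()] (only its structure is used).
#' @param criteria list with `rg_ratio_max` (default 1.25) and
#'   `global_rmsd_max` in Angstrom (default 10).
#' @return logical vector, one flag per conformer.
#' @export
detect_unfolded <- function(ens, ref,
                            criteria = list(rg_ratio_max = 1.25,
                                            global_rmsd_max = 10)) {
  if (is.null(criteria$rg_ratio_max) || is.null(criteria$global_rmsd_max)) {
    stop_validation("criteria must give rg_ratio_max and global_rmsd_max")
  }
  all_res <- residue_numbers(ref$structure)
  global_ref <- reference_state(ref$label, ref$structure, all_res, all_res)
  rg_ref <- radius_of_gyration(ref$structure)
  vapply(ens$structures, function(s) {
    rg_ratio <- radius_of_gyration(s) / rg_ref
    if (rg_ratio > criteria$rg_ratio_max) return(TRUE)
    backbone_rmsd(s, global_ref) > criteria$global_rmsd_max
  }, logical(1))
}

#' Scan subsampling parameters for ensemble diversity
#'
#' Runs the full pipeline (manifest, per-task subsampling, backend
#' prediction, projection) for each `(max_seq, extra_seq)` pair and ranks
#' the pairs by conformational diversity, measured as the standard
#' deviation of the calc-range RMSD to `ref_a` across the ensemble after
#' excluding unfolded-flagged conformers. The unfolded fraction is
#' reported alongside so aggressive settings that trade diversity for
#' artefacts are visible.
#'
#' @param msa an `msa`.
#' @param backend a [predictor_backend()].
#' @param grid data.frame with columns `max_seq`, `extra_seq`.
#' @param template named list of manifest settings: `n_replicates`,
#'   `n_seeds`, `n_models`, `recycles`, `dropout`, `master_seed`.
#' @param ref_a a [reference_state()] used for the diversity axis.
#' @param criteria unfolded-detection criteria (see [detect_unfolded()]).
#' @return data.frame sorted by `diversity` descending: max_seq,
#'   extra_seq, diversity, unfolded_fraction, n_ok, n_failed.
#' @export
scan_parameters <- function(msa, backend, grid, template, ref_a,
                            criteria = list(rg_ratio_max = 1.25,
                                            global_rmsd_max = 10)) {
  if (nrow(grid) == 0L) stop_validation("empty parameter grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    params <- subsampling_params(grid$max_seq[i], grid$extra_seq[i],
                                 rng_seed = template$master_seed)
    man <- build_manifest(template$n_replicates, template$n_seeds,
                          template$n_models, params,
                          recycles = template$recycles,
                          dropout = template$dropout)
    ens <- tryCatch(run_predictions(man, backend, msa), error = function(e) NULL)
    if (is.null(ens) || length(ens) == 0L) {
      return(data.frame(max_seq = grid$max_seq[i], extra_seq = grid$extra_seq[i],
                        diversity = NA_real_, unfolded_fraction = NA_real_,
                        n_ok = 0L, n_failed = if (is.null(ens)) NA_integer_ else nrow(ens$failures)))
    }
    unf <- detect_unfolded(ens, ref_a, criteria)
    rmsd <- vapply(ens$structures, backbone_rmsd, numeric(1), ref = ref_a)
    data.frame(max_seq = grid$max_seq[i], extra_seq = grid$extra_seq[i],
               diversity = stats::sd(rmsd[!unf]),
               unfolded_fraction = mean(unf),
               n_ok = length(ens), n_failed = nrow(ens$failures))
  })
  out <- do.call(rbind, rows)
  out[order(-out$diversity), , drop = FALSE]
}

#' Write projection, population and scan tables
#'
#' @param x a projection/assignment data.frame, `population_estimate`, or
#'   scan table.
#' @param path output TSV path.
#' @export
write_analysis_tsv <- function(x, path) {
  if (inherits(x, "population_estimate")) {
    df <- data.frame(state = colnames(x$per_state),
                     t(x$per_state), mean = x$mean, sem = x$sem,
                     check.names = FALSE)
    names(df)[2:(1 + nrow(x$per_state))] <-
      paste0("replicate_", rownames(x$per_state))
    x <- df
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML with blocks naming the reference states (`label`, `path`,
#' `fit_range`, `calc_range`), the binning scheme, and unfolded-detection
#' criteria. Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    binning = list(cutoff_A = 3.5, cutoff_B = 3.5, margin = 1.0),
    unfolded = list(rg_ratio_max = 1.25, global_rmsd_max = 10),
    include_unfolded = TRUE
  )
  utils::modifyList(defaults, cfg)
}
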