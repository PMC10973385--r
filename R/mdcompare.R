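# Comparison of predicted ensembles against molecular-dynamics snapshot
# series: structural observables along a trajectory, per-snapshot
# prediction comparisons, and transition-pathway coverage.

#' Define a structural observable
#'
#' @param name label used in output tables.
#' @param kind one of `"region_rmsd"`, `"atom_pair_distance"`,
#'   `"dihedral"`.
#' @param region residues for `region_rmsd` (vector or range string).
#' @param a,b atom specs `c(residue_number, atom_name)` for
#'   `atom_pair_distance`.
#' @param atoms list of four atom specs for `dihedral`.
#' @return object of class `observable_spec`.
#' @export
observable_spec <- function(name, kind = c("region_rmsd", "atom_pair_distance",
                                           "dihedral"),
                            region = NULL, a = NULL, b = NULL, atoms = NULL) {
  kind <- match.arg(kind)
  ok <- switch(kind,
               region_rmsd = !is.null(region),
               atom_pair_distance = !is.null(a) && !is.null(b),
               dihedral = !is.null(atoms) && length(atoms) == 4L)
  if (!ok) stop_validation("incomplete parameters for observable kind ", kind)
  structure(list(name = name, kind = kind,
                 region = if (!is.null(region)) parse_residue_range(region),
                 a = a, b = b, atoms = atoms),
            class = "observable_spec")
}

# Evaluate one observable on one structure; region_rmsd is measured
# against `ref` (fit on ref$fit_range, calc on the spec's region).
eval_observable <- function(s, spec, ref = NULL) {
  switch(spec$kind,
         region_rmsd = {
           if (is.null(ref)) stop_validation("region_rmsd needs a reference state")
           backbone_rmsd(s, reference_state(ref$label, ref$structure,
                                            ref$fit_range, spec$region))
         },
         atom_pair_distance = atom_pair_distance(s, spec$a, spec$b),
         dihedral = dihedral(s, spec$atoms))
}

#' Evaluate observables across a snapshot series
#'
#' Computes each observable on each trajectory snapshot, e.g. the four
#' quantities tracked across an inactive-state transition (core RMSD,
#' loop RMSD, two backbone-oxygen distances). Snapshots with missing
#' atoms get NA for the affected observable, with a warning.
#'
#' @param snapshots list of `protein_structure` objects in time order.
#' @param specs list of [observable_spec()] objects.
#' @param ref [reference_state()] used by `region_rmsd` observables.
#' @param times optional strictly increasing numeric snapshot times
#'   (frame index used when omitted).
#' @return data.frame: time, then one column per observable name; class
#'   `observable_series`.
#' @export
observable_series <- function(snapshots, specs, ref = NULL, times = NULL) {
  if (is.null(times)) times <- seq_along(snapshots)
  if (length(times) != length(snapshots) ||
      is.unsorted(times, strictly = TRUE)) {
    stop_validation("times must be strictly increasing, one per snapshot")
  }
  out <- data.frame(time = times)
  for (spec in specs) {
    out[[spec$name]] <- vapply(snapshots, function(s) {
      tryCatch(eval_observable(s, spec, ref), error = function(e) {
        warning("observable '", spec$name, "' missing in a snapshot: ",
                conditionMessage(e))
        NA_real_
      })
    }, numeric(1))
  }
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Compare an ensemble against MD snapshots
#'
#' For every (snapshot, conformer) pair: backbone RMSD of the conformer's
#' core against the snapshot's core, backbone RMSD of the region of
#' interest (e.g. an activation loop) measured in the core-fitted frame,
#' and for each distance spec the signed delta (conformer distance minus
#' snapshot distance).
#'
#' @param ens a `conformer_ensemble`.
#' @param snapshots list of `protein_structure` objects.
#' @param core_range residues of the stable core (fit + core RMSD).
#' @param region_range residues of the mobile region.
#' @param distance_specs list of [observable_spec()] objects of kind
#'   `atom_pair_distance` (may be empty).
#' @return long data.frame: snapshot, conformer, core_rmsd, region_rmsd,
#'   then one `delta_<name>` column per distance spec.
#' @export
compare_to_snapshots <- function(ens, snapshots, core_range, region_range,
                                 distance_specs = list()) {
  core_range <- parse_residue_range(core_range)
  region_range <- parse_residue_range(region_range)
  ens_res <- residue_numbers(ens$structures[[1]])
  snap_res <- residue_numbers(snapshots[[1]])
  if (!length(intersect(intersect(core_range, ens_res), snap_res))) {
    stop_validation("residue numbering mismatch between predictions and snapshots")
  }
  ens_dist <- lapply(distance_specs, function(sp)
    vapply(ens$structures, eval_observable, numeric(1), spec = sp))
  rows <- lapply(seq_along(snapshots), function(si) {
    snap <- snapshots[[si]]
    core_ref <- reference_state("snapshot", snap, core_range, core_range)
    region_ref <- reference_state("snapshot", snap, core_range, region_range)
    df <- data.frame(
      snapshot = si,
      conformer = seq_along(ens$structures),
      core_rmsd = vapply(ens$structures, backbone_rmsd, numeric(1),
                         ref = core_ref),
      region_rmsd = vapply(ens$structures, backbone_rmsd, numeric(1),
                           ref = region_ref))
    for (k in seq_along(distance_specs)) {
      snap_d <- eval_observable(snap, distance_specs[[k]])
      df[[paste0("delta_", distance_specs[[k]]$name)]] <- ens_dist[[k]] - snap_d
    }
    df
  })
  do.call(rbind, rows)
}

#' Transition-pathway coverage of an ensemble
#'
#' Partitions the range spanned by an observable along an MD trajectory
#' into `n_bins` equal-width bins and reports the fraction of bins that
#' contain at least one predicted conformer. High coverage indicates the
#' predictions populate the putative pathway between two states rather
#' than only its endpoints; values outside the trajectory's range are
#' clamped to the nearest terminal bin.
#'
#' @param values one observable value per conformer.
#' @param series_values the same observable evaluated on the trajectory
#'   snapshots (an [observable_series()] column).
#' @param n_bins positive integer number of bins (default 10).
#' @return coverage fraction in \[0, 1\].
#' @export
pathway_coverage <- function(values, series_values, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop_validation("n_bins must be >= 1")
  series_values <- series_values[is.finite(series_values)]
  lo <- min(series_values); hi <- max(series_values)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
    stop_validation("degenerate observable range: min equals max")
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n_bins)     # clamp out-of-range to terminal bins
  length(unique(idx)) / n_bins
}

#' Read MD snapshots from PDB frames
#'
#' @param dir directory of PDB frames.
#' @param manifest optional data.frame or TSV path with columns `frame`
#'   (file name) and `time_ps`; defaults to lexicographic file order with
#'   frame-index times.
#' @return list with `snapshots` (list of structures) and `times`.
#' @export
read_snapshots <- function(dir, manifest = NULL) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, sep = "\t")
  }
  if (is.null(manifest)) {
    files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
    times <- seq_along(files)
  } else {
    files <- file.path(dir, manifest$frame)
    times <- manifest$time_ps
  }
  if (length(files) == 0L) stop_validation("no snapshot frames found")
  list(snapshots = lapply(files, read_pdb), times = times)
}
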