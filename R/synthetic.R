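# Synthetic fixtures with known ground truth: ideal-geometry toy folds,
# two-state and transition-path ensembles, planted-cluster alignments,
# and a mock predictor backend. Every generator is bit-reproducible
# under its seed, so end-to-end pipeline tests need no external
# predictor or downloads.

# Ideal backbone geometry (conventional values, Angstrom / degrees).
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.5,
  omega = 180,
  phi = c(helix = -57, loop = -120),
  psi = c(helix = -47, loop = 130)
)

# Place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg): natural extension reference frame.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Specify a toy two-state fold
#'
#' Describes an ideal-geometry backbone assembled from helix and loop
#' segments, one of which is designated mobile: in state B that segment
#' is rigidly displaced by `displacement`, emulating a large loop
#' rearrangement such as a kinase activation-loop flip (over 15 Angstrom
#' in the system that motivates the defaults).
#'
#' @param segments data.frame with columns `type` (`"helix"` or
#'   `"loop"`), `length` (residues) and `mobile` (logical; exactly one
#'   TRUE). Default: helix 20 / mobile loop 17 / helix 20.
#' @param displacement numeric length-3 Angstrom offset applied to the
#'   mobile segment in state B (default `c(15, 0, 0)`).
#' @param rng_seed integer seed (reserved for future stochastic geometry;
#'   the builder itself is deterministic).
#' @return object of class `toy_fold_spec`.
#' @export
toy_fold_spec <- function(segments = data.frame(
                            type = c("helix", "loop", "helix"),
                            length = c(20L, 17L, 20L),
                            mobile = c(FALSE, TRUE, FALSE)),
                          displacement = c(15, 0, 0), rng_seed = 1L) {
  if (!all(segments$type %in% c("helix", "loop"))) {
    stop_validation("segment types must be 'helix' or 'loop'")
  }
  if (any(segments$length < 1L)) stop_validation("segment lengths must be >= 1")
  if (sum(segments$mobile) != 1L) {
    stop_validation("exactly one segment must be mobile")
  }
  if (length(displacement) != 3L || !all(is.finite(displacement))) {
    stop_validation("displacement must be a finite length-3 vector")
  }
  structure(list(segments = segments, n_residues = sum(segments$length),
                 displacement = as.numeric(displacement),
                 rng_seed = as.integer(rng_seed)),
            class = "toy_fold_spec")
}

# Build an ideal-geometry backbone (N, CA, C, O per residue) from
# per-residue phi/psi assignments.
build_backbone <- function(types) {
  n <- length(types)
  phi <- GEOM$phi[types]; psi <- GEOM$psi[types]
  coords <- matrix(0, nrow = 3L * n, ncol = 3L)   # N, CA, C per residue
  # seed the first residue explicitly
  coords[1, ] <- c(0, 0, 0)                                  # N1
  coords[2, ] <- c(GEOM$b_n_ca, 0, 0)                        # CA1
  a <- GEOM$a_n_ca_c * pi / 180
  coords[3, ] <- coords[2, ] + GEOM$b_ca_c * c(-cos(a), sin(a), 0)  # C1
  for (i in seq_len(n)) {
    iN <- 3L * i - 2L; iCA <- 3L * i - 1L; iC <- 3L * i
    if (i > 1L) {
      pN <- iN - 3L; pCA <- iCA - 3L; pC <- iC - 3L
      coords[iN, ] <- place_atom(coords[pN, ], coords[pCA, ], coords[pC, ],
                                 GEOM$b_c_n, GEOM$a_ca_c_n, psi[i - 1L])
      coords[iCA, ] <- place_atom(coords[pCA, ], coords[pC, ], coords[iN, ],
                                  GEOM$b_n_ca, GEOM$a_c_n_ca, GEOM$omega)
      coords[iC, ] <- place_atom(coords[pC, ], coords[iN, ], coords[iCA, ],
                                 GEOM$b_ca_c, GEOM$a_n_ca_c, phi[i])
    }
  }
  # carbonyl oxygens: anti to the next residue's N (trans peptide plane)
  o <- matrix(0, nrow = n, ncol = 3L)
  for (i in seq_len(n)) {
    iN <- 3L * i - 2L; iCA <- 3L * i - 1L; iC <- 3L * i
    tor <- if (i < n) psi[i] + 180 else 0
    o[i, ] <- place_atom(coords[iN, ], coords[iCA, ], coords[iC, ],
                         GEOM$b_c_o, GEOM$a_ca_c_o, tor)
  }
  list(n_ca_c = coords, o = o)
}

#' Build a two-state reference pair with ideal geometry
#'
#' State A is an ideal backbone (N, CA, C, O per residue) built from the
#' spec's segments; state B is identical except that the mobile segment
#' is rigidly displaced by the spec's displacement vector. Both share
#' residue numbering 1..n, so they pair exactly in superposition and
#' RMSD operations.
#'
#' @param spec a [toy_fold_spec()].
#' @return list with `A` and `B` (`protein_structure`), plus attributes
#'   `mobile_residues` and `fixed_residues`.
#' @export
make_reference_pair <- function(spec) {
  stopifnot(inherits(spec, "toy_fold_spec"))
  types <- rep(spec$segments$type, spec$segments$length)
  bb <- build_backbone(types)
  n <- length(types)
  atoms <- data.frame(
    residue_number = rep(seq_len(n), each = 4L),
    residue_name = rep(ifelse(types == "helix", "ALA", "GLY"), each = 4L),
    atom_name = rep(c("N", "CA", "C", "O"), n),
    x = 0, y = 0, z = 0, plddt = 90
  )
  xyz <- matrix(0, nrow = 4L * n, ncol = 3L)
  for (i in seq_len(n)) {
    xyz[4L * i - 3L, ] <- bb$n_ca_c[3L * i - 2L, ]
    xyz[4L * i - 2L, ] <- bb$n_ca_c[3L * i - 1L, ]
    xyz[4L * i - 1L, ] <- bb$n_ca_c[3L * i, ]
    xyz[4L * i, ] <- bb$o[i, ]
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  a <- new_structure(atoms, provenance = list(label = "state_A"))
  seg_end <- cumsum(spec$segments$length)
  seg_start <- c(1L, utils::head(seg_end, -1L) + 1L)
  mob_seg <- which(spec$segments$mobile)
  mobile_res <- seq(seg_start[mob_seg], seg_end[mob_seg])
  b <- a
  sel <- b$atoms$residue_number %in% mobile_res
  b$atoms$x[sel] <- b$atoms$x[sel] + spec$displacement[1]
  b$atoms$y[sel] <- b$atoms$y[sel] + spec$displacement[2]
  b$atoms$z[sel] <- b$atoms$z[sel] + spec$displacement[3]
  b$provenance <- list(label = "state_B")
  structure(list(A = a, B = b),
            mobile_residues = mobile_res,
            fixed_residues = setdiff(seq_len(n), mobile_res))
}

#' Recipe for a synthetic two-state ensemble
#'
#' The defaults mirror a standard prediction campaign: 3 replicates x 160
#' conformers (480 total), a ground-state population of 0.9 (the regime
#' of a kinase that occupies its active state near 90% of the time), 0.3
#' Angstrom coordinate noise, and no unfolded decoys.
#'
#' @param p_ground probability of the ground state (state A).
#' @param n_replicates,n_per_replicate replicate structure; total
#'   conformers = product.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @param unfolded_fraction fraction of expanded decoys.
#' @param sampling `"exact"` for deterministic per-replicate counts
#'   (non-flaky small-n tests) or `"bernoulli"` for true multinomial
#'   draws (statistical tests).
#' @param rng_seed integer seed.
#' @export
ensemble_recipe <- function(p_ground = 0.9, n_replicates = 3L,
                            n_per_replicate = 160L, noise_sigma = 0.3,
                            unfolded_fraction = 0,
                            sampling = c("exact", "bernoulli"),
                            rng_seed = 1L) {
  sampling <- match.arg(sampling)
  if (p_ground < 0 || p_ground > 1 || unfolded_fraction < 0 ||
      p_ground + unfolded_fraction > 1 + 1e-9) {
    stop_validation("need 0 <= p_ground, unfolded_fraction and p_ground + unfolded_fraction <= 1")
  }
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0")
  structure(list(p_ground = p_ground, n_replicates = as.integer(n_replicates),
                 n_per_replicate = as.integer(n_per_replicate),
                 noise_sigma = noise_sigma,
                 unfolded_fraction = unfolded_fraction,
                 sampling = sampling, rng_seed = as.integer(rng_seed)),
            class = "ensemble_recipe")
}

# One noisy copy of a base structure; optionally expanded x2 about its
# centroid (unfolded decoy, guaranteed to trip the default Rg criterion).
perturb_structure <- function(base, sigma, unfolded = FALSE) {
  s <- base
  xyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  if (unfolded) {
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2L, ctr) * 2, 2L, ctr, "+")
  }
  if (sigma > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sigma),
                                     ncol = 3L)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s$atoms$plddt <- if (unfolded) 40 else 90
  s
}

#' Generate a two-state ensemble with planted populations
#'
#' Each conformer is the A or B reference plus isotropic Gaussian
#' coordinate noise; with probability `unfolded_fraction` it is instead
#' an expanded decoy (coordinates scaled x2 about the centroid, pLDDT
#' 40). Under `"exact"` sampling every replicate receives
#' round-to-nearest counts of each class; under `"bernoulli"` each
#' conformer's class is drawn independently.
#'
#' @param refs list with `A` and `B` from [make_reference_pair()].
#' @param recipe an [ensemble_recipe()].
#' @return list with `ensemble` (a `conformer_ensemble`) and `truth`
#'   (data.frame: replicate, index, label in
#'   \{ground, alternative, unfolded\}).
#' @export
make_two_state_ensemble <- function(refs, recipe = ensemble_recipe()) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  with_seed(recipe$rng_seed, {
    structures <- list(); truth <- list()
    for (r in seq_len(recipe$n_replicates)) {
      n <- recipe$n_per_replicate
      if (recipe$sampling == "exact") {
        n_unf <- round(recipe$unfolded_fraction * n)
        n_ground <- round(recipe$p_ground * n)
        n_alt <- n - n_ground - n_unf
        if (n_alt < 0L) { n_ground <- n_ground + n_alt; n_alt <- 0L }
        labels <- sample(rep(c("ground", "alternative", "unfolded"),
                             c(n_ground, n_alt, n_unf)))
      } else {
        p_alt <- max(0, 1 - recipe$p_ground - recipe$unfolded_fraction)
        labels <- sample(c("ground", "alternative", "unfolded"), n,
                         replace = TRUE,
                         prob = c(recipe$p_ground, p_alt,
                                  recipe$unfolded_fraction))
      }
      for (i in seq_len(n)) {
        base <- if (labels[i] == "alternative") refs$B else refs$A
        s <- perturb_structure(base, recipe$noise_sigma,
                               unfolded = labels[i] == "unfolded")
        s$provenance <- list(replicate = r, seed = i, model = 1L)
        structures[[length(structures) + 1L]] <- s
      }
      truth[[r]] <- data.frame(replicate = r, index = seq_len(n),
                               label = labels)
    }
    list(ensemble = conformer_ensemble(structures),
         truth = do.call(rbind, truth))
  })
}

#' Generate a transition-path ensemble
#'
#' Conformer i interpolates linearly between state A and state B at
#' fraction (i-1)/(n-1) (the two references differ only in the mobile
#' segment, so this moves that segment along a straight path), plus
#' optional Gaussian noise. Both endpoints are always present.
#'
#' @param refs list with `A` and `B` from [make_reference_pair()].
#' @param n number of conformers (>= 2).
#' @param noise_sigma Angstrom noise scale (default 0).
#' @param rng_seed integer seed.
#' @return a `conformer_ensemble`.
#' @export
make_path_ensemble <- function(refs, n, noise_sigma = 0, rng_seed = 1L) {
  if (n < 2L) stop_validation("path ensemble needs n >= 2")
  xa <- cbind(refs$A$atoms$x, refs$A$atoms$y, refs$A$atoms$z)
  xb <- cbind(refs$B$atoms$x, refs$B$atoms$y, refs$B$atoms$z)
  with_seed(rng_seed, {
    structures <- lapply(seq_len(n), function(i) {
      t <- (i - 1) / (n - 1)
      xyz <- (1 - t) * xa + t * xb
      if (noise_sigma > 0) {
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                            ncol = 3L)
      }
      s <- refs$A
      s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
      s$atoms$plddt <- 90
      s$provenance <- list(replicate = 1L, seed = i, model = 1L)
      s
    })
    conformer_ensemble(structures)
  })
}

#' Generate an alignment with planted cluster structure
#'
#' Cluster seeds are created by mutating the query at `between_mut_rate`;
#' members by mutating their seed at `within_mut_rate`. With
#' `within_mut_rate` well below `between_mut_rate`, nearest-center
#' Hamming assignment recovers the planted partition exactly. The query
#' is row 1, unmutated; each cluster contributes `per_cluster` rows, of
#' which the first is its seed.
#'
#' @param query amino-acid string (no gaps).
#' @param n_clusters,per_cluster planted structure (total rows =
#'   1 + n_clusters * per_cluster).
#' @param within_mut_rate,between_mut_rate per-position mutation
#'   probabilities, `0 <= within < between <= 1`.
#' @param rng_seed integer seed.
#' @return an `msa` with attributes `planted_cluster` (integer per row, 0
#'   for the query) and `seed_rows` (row index of each cluster's seed).
#' @export
make_synthetic_msa <- function(query, n_clusters, per_cluster,
                               within_mut_rate = 0.02,
                               between_mut_rate = 0.4, rng_seed = 1L) {
  if (!(within_mut_rate >= 0 && within_mut_rate < between_mut_rate &&
        between_mut_rate <= 1)) {
    stop_validation("need 0 <= within_mut_rate < between_mut_rate <= 1")
  }
  aa <- AA_ALPHABET[1:20]
  mutate <- function(seq_chars, rate) {
    hit <- stats::runif(length(seq_chars)) < rate
    if (any(hit)) {
      seq_chars[hit] <- vapply(seq_chars[hit], function(ch)
        sample(setdiff(aa, ch), 1L), character(1))
    }
    seq_chars
  }
  qc <- strsplit(toupper(query), "")[[1]]
  if (!all(qc %in% aa)) stop_validation("query must use the 20 amino acids only")
  with_seed(rng_seed, {
    seqs <- list(paste(qc, collapse = ""))
    ids <- "query"
    planted <- 0L
    seed_rows <- integer(n_clusters)
    for (k in seq_len(n_clusters)) {
      seed_chars <- mutate(qc, between_mut_rate)
      seed_rows[k] <- length(seqs) + 1L
      for (j in seq_len(per_cluster)) {
        member <- if (j == 1L) seed_chars else mutate(seed_chars, within_mut_rate)
        seqs[[length(seqs) + 1L]] <- paste(member, collapse = "")
        ids <- c(ids, sprintf("c%02d_m%03d", k, j))
        planted <- c(planted, k)
      }
    }
    msa <- new_msa(unlist(seqs), ids = ids, query_index = 1L)
    attr(msa, "planted_cluster") <- planted
    attr(msa, "seed_rows") <- seed_rows
    msa
  })
}

#' Mock predictor backend driven by planted populations
#'
#' A deterministic-under-seed test double for the neural-network
#' predictor: for a task whose subsampling used `max_seq = m`, it samples
#' state A with the probability and coordinate noise that `response`
#' assigns to `m`, emulating the empirical pattern that smaller
#' subsamples yield more diverse (and eventually noisier) ensembles.
#'
#' @param refs list with `A` and `B` from [make_reference_pair()].
#' @param response named list keyed by max_seq value (as character), each
#'   entry a list with `p_ground` and `noise_sigma`.
#' @return a [predictor_backend()].
#' @export
mock_backend <- function(refs, response) {
  predict_fn <- function(sub, seed, model_id) {
    key <- as.character(sub$params$max_seq)
    resp <- response[[key]]
    if (is.null(resp)) {
      stop(structure(class = c("subfold_config_error", "error", "condition"),
                     list(message = paste0("mock backend has no response for max_seq=", key),
                          call = sys.call())))
    }
    with_seed(mix_seed(seed, model_id, 1L), {
      base <- if (stats::runif(1) < resp$p_ground) refs$A else refs$B
      perturb_structure(base, resp$noise_sigma)
    })
  }
  predictor_backend("mock", predict_fn)
}

#' Write a complete synthetic fixture set
#'
#' Writes reference PDBs (`ref_A.pdb`, `ref_B.pdb`), an ensemble
#' directory with `{replicate}_{seed}_{model}.pdb` files, the planted
#' truth table (`truth.tsv`) and a synthetic alignment (`msa.a3m`).
#'
#' @param dir output directory.
#' @param spec a [toy_fold_spec()].
#' @param recipe an [ensemble_recipe()].
#' @param msa_args list of arguments for [make_synthetic_msa()] (a
#'   default query is supplied from the toy fold length).
#' @return invisibly, a list of the generated objects.
#' @export
write_fixture_set <- function(dir, spec = toy_fold_spec(),
                              recipe = ensemble_recipe(),
                              msa_args = list(n_clusters = 4L,
                                              per_cluster = 25L)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- make_reference_pair(spec)
  write_pdb(refs$A, file.path(dir, "ref_A.pdb"))
  write_pdb(refs$B, file.path(dir, "ref_B.pdb"))
  two <- make_two_state_ensemble(refs, recipe)
  write_ensemble(two$ensemble, file.path(dir, "ensemble"))
  utils::write.table(two$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is.null(msa_args$query)) {
    msa_args$query <- paste(rep(c("A", "C", "D", "E", "F", "G", "H", "I",
                                  "K", "L"), length.out = spec$n_residues),
                            collapse = "")
  }
  if (is.null(msa_args$rng_seed)) msa_args$rng_seed <- recipe$rng_seed
  msa <- do.call(make_synthetic_msa, msa_args)
  write_msa_fasta(msa, file.path(dir, "msa.a3m"))
  invisible(list(refs = refs, ensemble = two$ensemble, truth = two$truth,
                 msa = msa))
}
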