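# Ensemble analysis: projection, binning, populations, region
# distributions, unfolded detection, and the parameter scan.

test_that("projection of a reference against the pair is (0, pair distance)", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  ens <- conformer_ensemble(list(refs$A, refs$B))
  proj <- project_ensemble(ens, st$A, st$B)
  d_ab <- backbone_rmsd(refs$A, st$B)
  expect_equal(proj$rmsd_to_A, c(0, d_ab), tolerance = 1e-6)
  expect_equal(proj$rmsd_to_B, c(d_ab, 0), tolerance = 1e-6)
  # swapping the references swaps the coordinates
  swapped <- project_ensemble(ens, st$B, st$A)
  expect_equal(swapped$rmsd_to_A, proj$rmsd_to_B, tolerance = 1e-9)
  expect_equal(swapped$rmsd_to_B, proj$rmsd_to_A, tolerance = 1e-9)
  # pair symmetry: rmsd_to_A(refB) == rmsd_to_B(refA)
  expect_equal(backbone_rmsd(refs$B, st$A), backbone_rmsd(refs$A, st$B),
               tolerance = 1e-6)
  expect_equal(proj$mean_plddt, c(90, 90))
})

test_that("path ensembles project monotonically between the references", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  path <- make_path_ensemble(refs, n = 11, noise_sigma = 0)
  proj <- project_ensemble(path, st$A, st$B)
  expect_false(is.unsorted(proj$rmsd_to_A))
  expect_false(is.unsorted(rev(proj$rmsd_to_B)))
  # per-conformer brute-force oracle: rigid loop translation scales linearly
  expect_equal(proj$rmsd_to_A, seq(0, 12, length.out = 11), tolerance = 1e-6)
})

test_that("state binning follows the cutoff-plus-margin rule", {
  pts <- data.frame(replicate = 1L,
                    rmsd_to_A = c(0.5, 3.0, 8.0, 3.4, 2.0),
                    rmsd_to_B = c(8.0, 3.0, 0.5, 3.6, 2.5))
  asn <- assign_states(pts, binning_scheme(3.5, 3.5, 1.0))
  expect_equal(as.character(asn$label),
               c("state_A", "intermediate", "state_B", "intermediate",
                 "intermediate"))
  # unfolded flags take precedence over thresholding
  asn2 <- assign_states(pts, binning_scheme(3.5, 3.5, 1.0),
                        unfolded = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(as.character(asn2$label)[1], "unfolded")
  expect_error(binning_scheme(-1, 3.5, 1), "non-negative")
  expect_error(assign_states(pts, binning_scheme(), unfolded = TRUE), "length")
})

test_that("planted two-state labels are recovered at moderate noise", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  two <- make_two_state_ensemble(refs, ensemble_recipe(
    p_ground = 0.7, n_replicates = 2, n_per_replicate = 60,
    noise_sigma = 0.3, rng_seed = 5))
  proj <- project_ensemble(two$ensemble, st$A, st$B)
  asn <- assign_states(proj)
  planted <- ifelse(two$truth$label == "ground", "state_A", "state_B")
  expect_gte(mean(as.character(asn$label) == planted), 0.99)
})

test_that("shrinking noise drives label agreement to 100%", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  agree <- vapply(c(1.0, 0.3, 0.0), function(sig) {
    two <- make_two_state_ensemble(refs, ensemble_recipe(
      p_ground = 0.6, n_replicates = 1, n_per_replicate = 40,
      noise_sigma = sig, rng_seed = 9))
    proj <- project_ensemble(two$ensemble, st$A, st$B)
    asn <- suppressWarnings(assign_states(proj))
    planted <- ifelse(two$truth$label == "ground", "state_A", "state_B")
    mean(as.character(asn$label) == planted)
  }, numeric(1))
  expect_true(all(diff(agree) >= 0))
  expect_equal(agree[3], 1.0)
})

test_that("population mean and SEM follow the replicate formulas", {
  # replicate fractions 0.9/0.9/0.9 -> SEM exactly 0
  pts <- data.frame(replicate = rep(1:3, each = 10),
                    rmsd_to_A = rep(c(rep(0.5, 9), 8), 3),
                    rmsd_to_B = rep(c(rep(8, 9), 0.5), 3))
  pop <- population_estimate(assign_states(pts))
  expect_equal(unname(pop$mean[["state_A"]]), 0.9)
  expect_equal(unname(pop$sem[["state_A"]]), 0)
  # fractions 0.8 / 0.9 / 1.0 -> mean 0.9, sem = sd/sqrt(3)
  mk <- function(nA, n) data.frame(
    rmsd_to_A = c(rep(0.5, nA), rep(8, n - nA)),
    rmsd_to_B = c(rep(8, nA), rep(0.5, n - nA)))
  pts2 <- rbind(cbind(replicate = 1L, mk(8, 10)),
                cbind(replicate = 2L, mk(9, 10)),
                cbind(replicate = 3L, mk(10, 10)))
  pop2 <- population_estimate(assign_states(pts2))
  expect_equal(unname(pop2$mean[["state_A"]]), 0.9)
  expect_equal(unname(pop2$sem[["state_A"]]), sd(c(0.8, 0.9, 1.0)) / sqrt(3))
  expect_equal(unname(pop2$sem[["state_A"]]), 0.1 / sqrt(3), tolerance = 1e-12)
  # per-replicate fractions sum to 1
  expect_equal(unname(rowSums(pop2$per_state)), rep(1, 3), tolerance = 1e-9)
})

test_that("single-replicate estimates warn and report SEM 0", {
  pts <- data.frame(replicate = 1L, rmsd_to_A = c(0.5, 8), rmsd_to_B = c(8, 0.5))
  expect_warning(pop <- population_estimate(assign_states(pts)), "single replicate")
  expect_equal(unname(pop$sem[["state_A"]]), 0)
  expect_error(population_estimate(data.frame(x = 1)), "assign_states")
})

test_that("unfolded conformers can be excluded from the denominator", {
  pts <- data.frame(replicate = rep(1:2, each = 10),
                    rmsd_to_A = rep(c(rep(0.5, 8), 8, 20), 2),
                    rmsd_to_B = rep(c(rep(8, 8), 0.5, 20), 2))
  unf <- rep(c(rep(FALSE, 9), TRUE), 2)
  asn <- assign_states(pts, unfolded = unf)
  with_unf <- population_estimate(asn, include_unfolded = TRUE)
  without <- population_estimate(asn, include_unfolded = FALSE)
  expect_equal(unname(with_unf$mean[["state_A"]]), 0.8)
  expect_equal(unname(with_unf$mean[["unfolded"]]), 0.1)
  expect_equal(unname(without$mean[["state_A"]]), 8 / 9, tolerance = 1e-9)
})

test_that("region RMSD distributions use midpoint medians", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  mob <- attr(refs, "mobile_residues")
  # exact copies of the reference: all values 0
  copies <- conformer_ensemble(list(refs$A, refs$A, refs$A))
  dist0 <- region_rmsd_distribution(copies, st$A, mob)
  expect_equal(dist0$values, rep(0, 3), tolerance = 1e-9)
  expect_equal(dist0$median, 0, tolerance = 1e-9)
  # noiseless 4-point path: region RMSDs 0, 4, 8, 12 -> median 6 (midpoint)
  path4 <- make_path_ensemble(refs, n = 4, noise_sigma = 0)
  dist4 <- region_rmsd_distribution(path4, st$A, mob)
  expect_equal(dist4$values, c(0, 4, 8, 12), tolerance = 1e-6)
  expect_equal(dist4$median, 6, tolerance = 1e-6)
  expect_equal(dist4$min, 0, tolerance = 1e-6)
  expect_equal(dist4$max, 12, tolerance = 1e-6)
  # independent per-conformer oracle on a noisy ensemble
  noisy <- make_path_ensemble(refs, n = 7, noise_sigma = 0.4, rng_seed = 3)
  dist7 <- region_rmsd_distribution(noisy, st$A, mob)
  oracle <- sort(vapply(noisy$structures, backbone_rmsd, numeric(1),
                        ref = reference_state("A", refs$A,
                                              attr(refs, "fixed_residues"), mob)))
  expect_equal(sort(dist7$values), oracle, tolerance = 1e-9)
  expect_equal(dist7$median, median(dist7$values))
})

test_that("unfolded detection flags expansion but not the reference", {
  refs <- tiny_refs()
  st <- tiny_states(refs)
  s3 <- refs$A
  xyz <- cbind(s3$atoms$x, s3$atoms$y, s3$atoms$z)
  ctr <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, ctr) * 3, 2, ctr, "+")
  s3$atoms$x <- xyz[, 1]; s3$atoms$y <- xyz[, 2]; s3$atoms$z <- xyz[, 3]
  ens <- conformer_ensemble(list(refs$A, s3))
  flags <- detect_unfolded(ens, st$A)
  expect_equal(flags, c(FALSE, TRUE))
  expect_error(detect_unfolded(ens, st$A, criteria = list(rg_ratio_max = 1.2)),
               "global_rmsd_max")
})

test_that("planted unfolded decoys are flagged with no false positives", {
  refs <- tiny_refs()
  st <- tiny_states(refs)
  two <- make_two_state_ensemble(refs, ensemble_recipe(
    p_ground = 0.85, n_replicates = 1, n_per_replicate = 80,
    noise_sigma = 0.3, unfolded_fraction = 0.1, rng_seed = 21))
  flags <- detect_unfolded(two$ensemble, st$A)
  planted <- two$truth$label == "unfolded"
  expect_equal(flags, planted)
})

test_that("parameter scan ranks by diversity with unfolded fractions attached", {
  refs <- tiny_refs(displacement = c(12, 0, 0))
  st <- tiny_states(refs)
  msa <- random_msa(40, 12, seed = 14)
  # ensemble spread strictly decreases as max_seq grows
  backend <- mock_backend(refs, list(
    `4` = list(p_ground = 0.5, noise_sigma = 0.0),
    `8` = list(p_ground = 0.9, noise_sigma = 0.0),
    `16` = list(p_ground = 1.0, noise_sigma = 0.0)))
  grid <- data.frame(max_seq = c(8, 16, 4), extra_seq = c(16, 32, 8))
  template <- list(n_replicates = 1, n_seeds = 12, n_models = 2,
                   recycles = 3, dropout = default_dropout(), master_seed = 2)
  tab <- scan_parameters(msa, backend, grid, template, st$A)
  expect_equal(tab$max_seq, c(4, 8, 16))     # anti-monotone in max_seq
  expect_true(all(diff(tab$diversity) <= 0))
  expect_equal(tab$diversity[tab$max_seq == 16], 0, tolerance = 1e-9)
  expect_true(all(tab$unfolded_fraction == 0))
  expect_error(scan_parameters(msa, backend, grid[0, ], template, st$A),
               "empty")
})

test_that("a one-cell scan returns a one-row table", {
  refs <- tiny_refs()
  st <- tiny_states(refs)
  msa <- random_msa(20, 10, seed = 15)
  backend <- mock_backend(refs, list(`4` = list(p_ground = 0.8, noise_sigma = 0.1)))
  tab <- scan_parameters(msa, backend,
                         data.frame(max_seq = 4, extra_seq = 8),
                         list(n_replicates = 1, n_seeds = 4, n_models = 1,
                              recycles = 3, dropout = default_dropout(),
                              master_seed = 1),
                         st$A)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_ok, 4L)
})

test_that("analysis tables and YAML configs round-trip", {
  pts <- data.frame(replicate = rep(1:2, each = 5),
                    rmsd_to_A = rep(c(rep(0.5, 4), 8), 2),
                    rmsd_to_B = rep(c(rep(8, 4), 0.5), 2))
  pop <- population_estimate(assign_states(pts))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_analysis_tsv(pop, tf)
  t <- read.delim(tf)
  expect_equal(t$mean[t$state == "state_A"], 0.8)
  cfgf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("binning:", "  cutoff_A: 2.0", "  cutoff_B: 2.0",
               "  margin: 0.5", "include_unfolded: false"), cfgf)
  cfg <- read_analysis_config(cfgf)
  expect_equal(cfg$binning$cutoff_A, 2.0)
  expect_false(cfg$include_unfolded)
  expect_equal(cfg$unfolded$rg_ratio_max, 1.25)   # default preserved
})
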