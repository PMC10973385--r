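# Alignment container, readers, coverage, Hamming distance, and the
# cluster-center subsampling heuristic.

test_that("aligned FASTA and Stockholm readers agree and round-trip", {
  msa <- new_msa(c("ACDEF", "AC-EF", "GCDEF"),
                 ids = c("query", "homo1", "homo2"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_msa_fasta(msa, fa)
  back <- read_msa(fa, format = "fasta")
  expect_identical(back$sequences, msa$sequences)
  expect_identical(back$ids, msa$ids)
  expect_equal(back$n_columns, 5L)
  expect_equal(back$query_index, 1L)

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "", "query  ACDEF", "homo1  AC-EF",
               "homo2  GCDEF", "//"), sto)
  from_sto <- read_msa(sto, format = "stockholm")
  expect_identical(from_sto$sequences, msa$sequences)
  expect_identical(from_sto$ids, msa$ids)
})

test_that("A3M lowercase insertion columns are removed on read", {
  a3m <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">query", "ACD", ">hit", "AkCD"), a3m)
  msa <- read_msa(a3m)   # format guessed from extension
  expect_identical(msa$sequences, c("ACD", "ACD"))
  expect_equal(msa$n_columns, 3L)
})

test_that("malformed alignments are rejected with clear errors", {
  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "AC"), ragged)
  expect_error(read_msa(ragged), "ragged")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_msa(empty), "empty|parse")
  expect_error(read_msa("/nonexistent/file.fasta"), "not found")
  expect_error(new_msa(c("----", "ACDE"), query_index = 1), "no residues")
  expect_error(new_msa("ACDE", query_index = 3), "out of range")
})

test_that("per-position coverage matches a brute-force tally", {
  msa <- new_msa(c("ACDEF", "AC-EF", "GCDEF", "A--E-"))
  cov <- per_position_coverage(msa)
  expect_equal(cov$depth, 4L)
  expect_equal(cov$per_column_count[1], 4L)  # no gaps in column 1
  # brute force on a random planted-gap MSA
  rmsa <- random_msa(40, 30, gap_prob = 0.3, seed = 11)
  cov <- per_position_coverage(rmsa)
  chars <- do.call(rbind, strsplit(rmsa$sequences, ""))
  expect_equal(cov$per_column_count, unname(colSums(chars != "-")))
  expect_true(all(cov$per_column_count >= 1L))  # query has no gaps here
  expect_true(all(cov$per_column_count <= cov$depth))
})

test_that("column gapped everywhere except the query counts 1", {
  msa <- new_msa(c("AC", "A-", "A-", "A-", "A-"))
  expect_equal(per_position_coverage(msa)$per_column_count, c(5L, 1L))
})

test_that("Hamming distance treats the gap as an ordinary symbol", {
  expect_equal(hamming_distance("ACD", "ACD"), 0)
  expect_equal(hamming_distance("ACD", "AYD"), 1)
  expect_equal(hamming_distance("A-D", "AAD"), 1)
  expect_equal(hamming_distance("---", "---"), 0)
  expect_error(hamming_distance("AC", "ACD"), "unequal")
})

test_that("subsampling yields a deterministic partition with the query pinned", {
  msa <- random_msa(60, 25, gap_prob = 0.1, seed = 3)
  params <- subsampling_params(max_seq = 8, extra_seq = 10, rng_seed = 42)
  sub <- subsample_msa(msa, params)
  expect_length(sub$center_indices, 8L)
  expect_true(msa$query_index %in% sub$center_indices)
  # partition: every row is exactly one of center / assigned
  expect_setequal(c(sub$center_indices, sub$assignment$row), seq_len(60))
  expect_false(anyDuplicated(sub$assignment$row) > 0)
  # extras disjoint from centers, no duplicates
  expect_length(intersect(sub$extra_indices, sub$center_indices), 0L)
  expect_false(anyDuplicated(sub$extra_indices) > 0)
  expect_length(sub$extra_indices, 10L)
  # bitwise determinism
  expect_identical(sub, subsample_msa(msa, params))
  # different seed, different draw
  sub2 <- subsample_msa(msa, subsampling_params(8, 10, rng_seed = 43))
  expect_false(identical(sub$center_indices, sub2$center_indices))
})

test_that("query is a center for every seed", {
  msa <- random_msa(30, 15, seed = 5)
  for (seed in 1:100) {
    sub <- subsample_msa(msa, subsampling_params(5, 0, rng_seed = seed))
    expect_true(msa$query_index %in% sub$center_indices)
  }
})

test_that("shallow alignments make every row a center, with a warning", {
  msa <- random_msa(10, 12, seed = 9)
  expect_warning(
    sub <- subsample_msa(msa, subsampling_params(16, 512, rng_seed = 1)),
    "no subsampling effect")
  expect_length(sub$center_indices, 10L)
  expect_equal(nrow(sub$assignment), 0L)
  expect_length(sub$extra_indices, 0L)
})

test_that("every assigned row minimizes Hamming distance over centers", {
  for (seed in 1:5) {
    msa <- random_msa(50, 20, gap_prob = 0.15, seed = seed)
    sub <- subsample_msa(msa, subsampling_params(6, 0, rng_seed = seed))
    for (i in seq_len(nrow(sub$assignment))) {
      row <- sub$assignment$row[i]
      d_assigned <- hamming_distance(msa$sequences[row],
                                     msa$sequences[sub$assignment$center[i]])
      expect_equal(d_assigned, sub$assignment$hamming[i])
      d_all <- vapply(sub$center_indices, function(cc)
        hamming_distance(msa$sequences[row], msa$sequences[cc]), numeric(1))
      expect_equal(d_assigned, min(d_all))
    }
  }
})

test_that("planted cluster structure is recovered by nearest-center assignment", {
  msa <- make_synthetic_msa(paste(rep("ACDEFGHIKL", 6), collapse = ""),
                            n_clusters = 4, per_cluster = 25,
                            within_mut_rate = 0.02, between_mut_rate = 0.4,
                            rng_seed = 17)
  planted <- attr(msa, "planted_cluster")
  sub <- subsample_msa(msa, subsampling_params(12, 0, rng_seed = 23))
  center_cluster <- planted[sub$assignment$center]
  row_cluster <- planted[sub$assignment$row]
  # rows whose planted cluster has at least one center must be assigned
  # within their own cluster (within-distance << between-distance)
  covered <- row_cluster %in% planted[sub$center_indices]
  expect_true(any(covered))
  expect_true(all(center_cluster[covered & row_cluster > 0] ==
                    row_cluster[covered & row_cluster > 0]))
})

test_that("cluster profiles are normalized frequency tables", {
  # cluster of a single sequence: point-mass columns
  one <- new_msa("AC")
  sub <- suppressWarnings(subsample_msa(one, subsampling_params(1, 0, rng_seed = 1)))
  prof <- cluster_profile(sub, one, 1L)
  expect_equal(colSums(prof), c(1, 1), ignore_attr = TRUE)
  expect_equal(unname(prof["A", 1]), 1)
  expect_equal(unname(prof["C", 2]), 1)
  # brute-force recount on a random cluster
  rmsa <- random_msa(30, 12, seed = 7)
  sub <- subsample_msa(rmsa, subsampling_params(3, 0, rng_seed = 7))
  cc <- sub$center_indices[2]
  members <- c(cc, sub$assignment$row[sub$assignment$center == cc])
  chars <- do.call(rbind, strsplit(rmsa$sequences[members], ""))
  prof <- cluster_profile(sub, rmsa, cc)
  for (j in seq_len(ncol(chars))) {
    tab <- table(chars[, j]) / length(members)
    for (sym in names(tab)) expect_equal(unname(prof[sym, j]), unname(tab[[sym]]))
  }
  expect_true(all(abs(colSums(prof) - 1) < 1e-9))
  expect_error(cluster_profile(sub, rmsa, 9999), "unknown")
})

test_that("a two-sequence cluster has 0.5/0.5 column frequencies", {
  msa <- new_msa(c("AC", "AG"))
  sub <- suppressWarnings(subsample_msa(msa, subsampling_params(1, 0, rng_seed = 2)))
  prof <- cluster_profile(sub, msa, 1L)
  expect_equal(unname(prof["C", 2]), 0.5)
  expect_equal(unname(prof["G", 2]), 0.5)
})

test_that("subsampled MSA serializes to the documented directory layout", {
  msa <- random_msa(25, 10, seed = 13)
  sub <- subsample_msa(msa, subsampling_params(4, 5, rng_seed = 13))
  dir <- withr::local_tempdir()
  write_subsampled_msa(sub, msa, dir)
  expect_true(all(file.exists(file.path(
    dir, c("centers.fasta", "extras.fasta", "assignments.tsv", "profiles.tsv")))))
  ctr <- read_msa(file.path(dir, "centers.fasta"), format = "fasta")
  expect_equal(msa_depth(ctr), 4L)
  asn <- read.delim(file.path(dir, "assignments.tsv"))
  expect_equal(nrow(asn), 25L - 4L)
  expect_true(all(asn$hamming >= 0))
})
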