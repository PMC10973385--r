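# MSA container, readers, depth/coverage statistics, and the
# cluster-center subsampling heuristic (max_seq centers, Hamming-distance
# assignment, extra_seq sampling).

#' Construct a multiple sequence alignment object
#'
#' An `msa` holds equal-length aligned sequences over the 20 amino acids
#' plus the gap symbol `-`, one id per sequence, and the index of the query
#' (target) row. The query row is pinned: it is always retained as a
#' cluster center by [subsample_msa()].
#'
#' @param sequences character vector of aligned rows (equal length).
#' @param ids character vector of labels, one per sequence.
#' @param query_index 1-based index of the query row (default 1).
#' @return An object of class `msa` with fields `sequences`, `ids`,
#'   `query_index` and `n_columns`.
#' @export
new_msa <- function(sequences, ids = NULL, query_index = 1L) {
  if (length(sequences) == 0L) stop_validation("MSA must contain at least one sequence")
  sequences <- toupper(as.character(sequences))
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop_validation("ragged alignment: sequence lengths differ (",
                    paste(unique(widths), collapse = ", "), ")")
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (length(ids) != length(sequences)) {
    stop_validation("ids and sequences lengths differ")
  }
  query_index <- as.integer(query_index)
  if (query_index < 1L || query_index > length(sequences)) {
    stop_validation("query_index out of range")
  }
  if (!grepl("[^-]", sequences[query_index])) {
    stop_validation("query row contains no residues")
  }
  structure(
    list(sequences = sequences, ids = as.character(ids),
         query_index = query_index, n_columns = widths[1]),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns (query row %d: %s)\n",
              length(x$sequences), x$n_columns, x$query_index,
              x$ids[x$query_index]))
  invisible(x)
}

#' Number of sequences in an alignment
#' @param x an `msa`.
#' @export
msa_depth <- function(x) length(x$sequences)

# Integer code matrix (N x L), codes 1..22 into AA_ALPHABET; anything not
# in the alphabet maps to the "X" bucket.
msa_codes <- function(msa) {
  lut <- integer(256)
  lut[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_along(AA_ALPHABET)
  raw <- vapply(msa$sequences, function(s) utf8ToInt(s), integer(msa$n_columns),
                USE.NAMES = FALSE)
  codes <- lut[raw]                      # L x N after vapply
  codes[codes == 0L] <- length(AA_ALPHABET)   # unknown -> X bucket
  matrix(codes, nrow = length(msa$sequences), ncol = msa$n_columns, byrow = TRUE)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, Stockholm, and A3M. In A3M files lowercase
#' letters mark insertions relative to the query; these columns are
#' removed on read so every row shares the query's column frame.
#'
#' @param path file path.
#' @param format one of `"a3m"`, `"fasta"`, `"stockholm"`. Default guesses
#'   from the file extension (`.a3m`, `.sto`/`.stk`, else FASTA).
#' @param query_index 1-based index of the query row (default 1, the first
#'   record, following the convention of alignment-building tools).
#' @return an [new_msa()] object.
#' @export
read_msa <- function(path, format = c("auto", "a3m", "fasta", "stockholm"),
                     query_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, a3m = "a3m", sto = "stockholm", stk = "stockholm",
                     "fasta")
  }
  res <- switch(
    format,
    fasta = {
      set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                      error = function(e) stop_format("cannot parse FASTA: ", conditionMessage(e)))
      list(seqs = as.character(set), ids = sub("\\s.*$", "", names(set)))
    },
    stockholm = {
      aln <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
                      error = function(e) stop_format("cannot parse Stockholm: ", conditionMessage(e)))
      chr <- as.character(aln)
      list(seqs = unname(chr), ids = names(chr))
    },
    a3m = read_a3m_records(path)
  )
  if (length(res$seqs) == 0L) stop_validation("empty alignment file: ", path)
  seqs <- gsub("\\.", "-", res$seqs)
  new_msa(seqs, ids = res$ids, query_index = query_index)
}

# A3M: FASTA-like records; lowercase letters are insertions relative to
# the query column frame and are dropped; '.' padding is dropped too.
read_a3m_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[#;]", lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop_format("no FASTA records in A3M file: ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- gsub("[a-z.]", "", seqs)   # remove insertion columns
  list(seqs = seqs, ids = ids)
}

#' Write an alignment as aligned FASTA
#' @param msa an `msa`.
#' @param path output file path.
#' @export
write_msa_fasta <- function(msa, path) {
  out <- character(2L * length(msa$sequences))
  out[c(TRUE, FALSE)] <- paste0(">", msa$ids)
  out[c(FALSE, TRUE)] <- msa$sequences
  writeLines(out, path)
  invisible(path)
}

#' Per-column alignment coverage
#'
#' Counts, for each alignment column, the number of sequences carrying a
#' non-gap residue. Deep alignments (e.g., a kinase with >600,000
#' homologs) and shallow ones (e.g., a cytokine with ~112) differ sharply
#' in this profile, which bears on how aggressively they can be
#' subsampled.
#'
#' @param msa an `msa`.
#' @return list with `per_column_count` (integer, length `n_columns`) and
#'   `depth` (number of sequences), class `coverage_profile`.
#' @export
per_position_coverage <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  codes <- msa_codes(msa)
  structure(
    list(per_column_count = as.integer(colSums(codes != GAP_CODE)),
         depth = nrow(codes)),
    class = "coverage_profile"
  )
}

#' Hamming distance between two aligned sequences
#'
#' Number of columns at which the two rows differ. The gap symbol is
#' treated as an ordinary 21st symbol: two gaps match, gap vs residue is a
#' mismatch.
#'
#' @param a,b equal-length aligned sequence strings.
#' @return non-negative integer count of differing columns.
#' @export
hamming_distance <- function(a, b) {
  ai <- utf8ToInt(toupper(a)); bi <- utf8ToInt(toupper(b))
  if (length(ai) != length(bi)) {
    stop_validation("sequences have unequal lengths (", length(ai), " vs ",
                    length(bi), ")")
  }
  sum(ai != bi)
}

#' Subsampling parameters
#'
#' `max_seq` is the number of cluster centers randomly drawn from the
#' alignment (the query is always one of them); `extra_seq` is the size of
#' the additional sample of non-center sequences passed alongside the
#' cluster features. The combination 256:512 was found to give the most
#' diverse activation-loop ensembles for the Abl1 kinase core.
#'
#' @param max_seq positive integer number of cluster centers.
#' @param extra_seq non-negative integer extra-sample size.
#' @param rng_seed integer seed controlling all random draws.
#' @export
subsampling_params <- function(max_seq = 256L, extra_seq = 512L, rng_seed = 1L) {
  max_seq <- as.integer(max_seq); extra_seq <- as.integer(extra_seq)
  if (is.na(max_seq) || max_seq < 1L) stop_validation("max_seq must be >= 1")
  if (is.na(extra_seq) || extra_seq < 0L) stop_validation("extra_seq must be >= 0")
  structure(list(max_seq = max_seq, extra_seq = extra_seq,
                 rng_seed = as.integer(rng_seed)),
            class = "subsampling_params")
}

#' Subsample an alignment by cluster-center selection
#'
#' Implements the clustering heuristic that a subsampled structure
#' predictor applies to its input alignment: draw `max_seq` rows uniformly
#' without replacement as cluster centers (the query row is always
#' included), assign every remaining row to its nearest center by
#' [hamming_distance()] (ties broken towards the earliest center in
#' `center_indices`), featurize each cluster as per-column symbol
#' frequencies, and draw `extra_seq` additional non-center rows uniformly
#' without replacement. Fully deterministic given `params$rng_seed`.
#'
#' @param msa an `msa`.
#' @param params a [subsampling_params()] object.
#' @return object of class `subsampled_msa` with fields `center_indices`,
#'   `assignment` (data.frame: row, center, hamming), `cluster_profiles`
#'   (list of per-column frequency matrices keyed by center index),
#'   `extra_indices`, and the originating `params`.
#' @export
subsample_msa <- function(msa, params) {
  stopifnot(inherits(msa, "msa"), inherits(params, "subsampling_params"))
  n <- msa_depth(msa)
  k <- min(params$max_seq, n)
  if (n <= params$max_seq) {
    warning("MSA depth (", n, ") <= max_seq (", params$max_seq,
            "): all rows become centers, no subsampling effect")
  }
  codes <- msa_codes(msa)
  others <- setdiff(seq_len(n), msa$query_index)

  picks <- with_seed(params$rng_seed, {
    centers <- c(msa$query_index,
                 if (k > 1L) sample(others, k - 1L) else integer(0))
    non_centers <- setdiff(seq_len(n), centers)
    n_extra <- min(params$extra_seq, length(non_centers))
    extras <- if (n_extra > 0L) sample(non_centers, n_extra) else integer(0)
    list(centers = centers, extras = extras)
  })
  centers <- picks$centers
  non_centers <- setdiff(seq_len(n), centers)

  assignment <- data.frame(row = integer(0), center = integer(0),
                           hamming = integer(0))
  if (length(non_centers) > 0L) {
    # K x M distance matrix, rows in center_indices order so that
    # which.min's first-minimum rule breaks ties towards the earliest
    # center position.
    dmat <- vapply(non_centers, function(r) {
      as.integer(rowSums(codes[centers, , drop = FALSE] !=
                           matrix(codes[r, ], nrow = length(centers),
                                  ncol = ncol(codes), byrow = TRUE)))
    }, integer(length(centers)))
    dmat <- matrix(dmat, nrow = length(centers))
    best <- apply(dmat, 2L, which.min)
    assignment <- data.frame(
      row = non_centers,
      center = centers[best],
      hamming = dmat[cbind(best, seq_along(non_centers))]
    )
  }

  sub <- structure(
    list(center_indices = centers, assignment = assignment,
         cluster_profiles = NULL, extra_indices = picks$extras,
         params = params),
    class = "subsampled_msa"
  )
  sub$cluster_profiles <- lapply(stats::setNames(centers, centers),
                                 function(cc) cluster_profile(sub, msa, cc))
  sub
}

#' @export
print.subsampled_msa <- function(x, ...) {
  cat(sprintf(
    "subsampled_msa: %d centers, %d assigned rows, %d extras (max_seq=%d, extra_seq=%d, seed=%d)\n",
    length(x$center_indices), nrow(x$assignment), length(x$extra_indices),
    x$params$max_seq, x$params$extra_seq, x$params$rng_seed))
  invisible(x)
}

#' Per-column residue frequencies of one cluster
#'
#' The frequency table covers the center and all rows assigned to it, over
#' the 20 amino acids, the gap symbol, and an `X` bucket for non-canonical
#' letters. Each column sums to 1.
#'
#' @param sub a `subsampled_msa`.
#' @param msa the source `msa`.
#' @param center a center row index present in `sub$center_indices`.
#' @return numeric matrix, `length(AA_ALPHABET)` rows x `n_columns`.
#' @export
cluster_profile <- function(sub, msa, center) {
  stopifnot(inherits(sub, "subsampled_msa"), inherits(msa, "msa"))
  center <- as.integer(center)
  if (!center %in% sub$center_indices) {
    stop_validation("unknown cluster center: ", center)
  }
  members <- c(center, sub$assignment$row[sub$assignment$center == center])
  codes <- msa_codes(msa)[members, , drop = FALSE]
  counts <- vapply(seq_len(ncol(codes)),
                   function(j) tabulate(codes[, j], nbins = length(AA_ALPHABET)),
                   numeric(length(AA_ALPHABET)))
  prof <- counts / length(members)
  rownames(prof) <- AA_ALPHABET
  prof
}

#' Serialize a subsampled alignment to a directory
#'
#' Writes `centers.fasta`, `extras.fasta`, `assignments.tsv`
#' (row_id, center_id, hamming) and `profiles.tsv` (long per-column table:
#' center_id, column, symbol, frequency; zero frequencies omitted).
#'
#' @param sub a `subsampled_msa`.
#' @param msa the source `msa`.
#' @param dir output directory, created if needed.
#' @export
write_subsampled_msa <- function(sub, msa, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ctr <- new_msa(msa$sequences[sub$center_indices],
                 ids = msa$ids[sub$center_indices],
                 query_index = match(msa$query_index, sub$center_indices))
  write_msa_fasta(ctr, file.path(dir, "centers.fasta"))
  if (length(sub$extra_indices) > 0L) {
    ext <- new_msa(msa$sequences[sub$extra_indices],
                   ids = msa$ids[sub$extra_indices])
    write_msa_fasta(ext, file.path(dir, "extras.fasta"))
  } else {
    writeLines(character(0), file.path(dir, "extras.fasta"))
  }
  asn <- data.frame(row_id = msa$ids[sub$assignment$row],
                    center_id = msa$ids[sub$assignment$center],
                    hamming = sub$assignment$hamming)
  utils::write.table(asn, file.path(dir, "assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  prof_rows <- do.call(rbind, lapply(names(sub$cluster_profiles), function(cc) {
    p <- sub$cluster_profiles[[cc]]
    nz <- which(p > 0, arr.ind = TRUE)
    data.frame(center_id = msa$ids[as.integer(cc)],
               column = nz[, 2L],
               symbol = rownames(p)[nz[, 1L]],
               frequency = p[nz])
  }))
  utils::write.table(prof_rows, file.path(dir, "profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
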