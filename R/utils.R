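# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Canonical alphabet: 20 amino acids, gap, and an "X" bucket for any
# non-canonical letter found in real alignments.
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X")
GAP_CODE <- 21L

stop_validation <- function(...) {
  stop(structure(
    class = c("subfold_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("subfold_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer mixing used to derive per-task seeds from a master
# seed. Frozen: changing these constants changes every downstream ensemble.
# Distinct (replicate, index) pairs map to distinct seeds for any realistic
# manifest size; results stay inside 32-bit integer range.
mix_seed <- function(master, replicate, index) {
  m <- 2147483647
  v <- ((as.double(master) %% 100000) * 20011 +
          as.double(replicate) * 7919 +
          as.double(index) * 104729) %% m
  as.integer(v) + 1L
}

# Parse "242-459" / "242-459,500-510" / numeric vectors into a sorted
# integer vector of residue numbers (1-based author numbering, inclusive).
parse_residue_range <- function(x) {
  if (is.numeric(x)) return(sort(unique(as.integer(x))))
  if (!is.character(x) || length(x) != 1L) {
    stop_validation("residue range must be numeric or a single string like '242-459'")
  }
  parts <- strsplit(gsub("\\s", "", x), ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    ends <- as.integer(strsplit(p, "-")[[1]])
    if (anyNA(ends) || length(ends) > 2L) {
      stop_validation("cannot parse residue range component: ", p)
    }
    if (length(ends) == 1L) ends else seq(ends[1], ends[2])
  }))
  sort(unique(out))
}
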