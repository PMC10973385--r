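# Small in-code fixtures shared across test files.

tiny_fold_spec <- function(displacement = c(12, 0, 0)) {
  toy_fold_spec(
    segments = data.frame(type = c("helix", "loop", "helix"),
                          length = c(8L, 5L, 8L),
                          mobile = c(FALSE, TRUE, FALSE)),
    displacement = displacement
  )
}

tiny_refs <- function(displacement = c(12, 0, 0)) {
  make_reference_pair(tiny_fold_spec(displacement))
}

# reference_state pair fitted on the fixed segments, measured on the
# mobile loop
tiny_states <- function(refs) {
  fixed <- attr(refs, "fixed_residues")
  mob <- attr(refs, "mobile_residues")
  list(A = reference_state("A", refs$A, fixed, mob),
       B = reference_state("B", refs$B, fixed, mob))
}

# random uniformly-gapped MSA for coverage / subsampling tests
random_msa <- function(n, ncol, gap_prob = 0.2, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    rows <- vapply(seq_len(n), function(i) {
      chars <- sample(aa, ncol, replace = TRUE)
      if (i > 1L) {
        chars[stats::runif(ncol) < gap_prob] <- "-"
      }
      paste(chars, collapse = "")
    }, character(1))
    new_msa(rows)
  })
}

# rotation matrix from ZYZ Euler angles in degrees
rot_euler <- function(a, b, c) {
  r <- function(th, axis) {
    th <- th * pi / 180; co <- cos(th); si <- sin(th)
    if (axis == "z") matrix(c(co, -si, 0, si, co, 0, 0, 0, 1), 3, byrow = TRUE)
    else matrix(c(co, 0, si, 0, 1, 0, -si, 0, co), 3, byrow = TRUE)
  }
  r(a, "z") %*% r(b, "y") %*% r(c, "z")
}

# apply a rigid rotation + translation to a structure's coordinates
rigid_move <- function(s, angles = c(30, 45, 60), shift = c(5, -3, 2)) {
  rot <- rot_euler(angles[1], angles[2], angles[3])
  xyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% t(rot)
  xyz <- sweep(xyz, 2L, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}
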