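# Independent oracles used to check the package implementations.
# These deliberately use naive, exhaustive formulations.

# Smith-Waterman with affine gaps (Gotoh), gap of length k costs
# open + k * ext.  Quadratic-space, plain loops; scores only.
oracle_local_align <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in A (move along B)
  F <- matrix(NEG, n + 1, m + 1)  # gap in B (move along A)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Exhaustive a/d recount of a heptad register: assign heptad letters by
# walking back from the DXLT end of the linker and count stabilisers on the
# 'a' and 'd' letters.
oracle_phase_score <- function(linker, phase, stabilisers) {
  chars <- strsplit(linker, "")[[1]]
  n <- length(chars)
  heptad <- c("a", "b", "c", "d", "e", "f", "g")
  letters_at <- vapply(seq_len(n) - 1L, function(i) {
    heptad[((i - n - phase) %% 7) + 1L]
  }, character(1))
  slots <- letters_at %in% c("a", "d")
  sum(chars[slots] %in% stabilisers) / sum(slots)
}

# Exhaustive overwind scoring: for every breakpoint b, positions left of b
# are scored in the ancestral frame (4 more residues assumed downstream).
oracle_overwind <- function(linker, stabilisers) {
  chars <- strsplit(linker, "")[[1]]
  n <- length(chars)
  heptad <- c("a", "b", "c", "d", "e", "f", "g")
  score_pb <- function(p, b) {
    idx <- seq_len(n) - 1L
    eff_n <- ifelse(idx < b, n + 4L, n)
    lets <- heptad[((idx - eff_n - p) %% 7) + 1L]
    slots <- lets %in% c("a", "d")
    sum(chars[slots] %in% stabilisers) / sum(slots)
  }
  sc <- outer(0:6, 0:n, Vectorize(score_pb))
  best <- max(sc)
  list(best = best,
       breakpoint = min(which(apply(sc == best, 2, any))) - 1L,
       scores = apply(sc, 1, max))
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# small simulated dataset shared by several tests
small_specs <- function(divergence = 0.1) {
  dplyr::bind_rows(
    family_spec("sfam_m7", -7L, has_eal = TRUE, pde_active = TRUE,
                n_members = 3L, within_divergence = divergence,
                taxonomy_class = "Betaproteobacteria"),
    family_spec("sfam_0", 0L, n_members = 3L,
                within_divergence = divergence,
                taxonomy_class = "Gammaproteobacteria"),
    family_spec("sfam_m4", -4L, n_members = 3L,
                within_divergence = divergence,
                taxonomy_class = "Actinobacteria")
  )
}

# 0-based half-open substring (tests avoid package internals)
sub0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)
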