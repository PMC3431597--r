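# Independent oracles used across the suite; deliberately written without
# reference to the package implementation.

# Optimal global alignment score with affine gap penalties (Gotoh): a gap of
# length L costs gap_open + L * gap_ext.  Plain O(nm) dynamic programme.
gotoh_score <- function(a, b, match = 1, mismatch = -1,
                        gap_open = 2, gap_ext = 0.5) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in a match/mismatch
  Ix <- matrix(NEG, n + 1L, m + 1L)  # ends in a gap in y (x consumed)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # ends in a gap in x (y consumed)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(gap_open + gap_ext * i)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(gap_open + gap_ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_ext,
                                Ix[i, j + 1L] - gap_ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_ext,
                                Iy[i + 1L, j] - gap_ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate `k` distinct positions of a sequence (substitutions only)
mutate_subs <- function(seq, k) {
  x <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1L)
  paste(x, collapse = "")
}

# two-gene variant map used by the inference unit tests
tiny_map <- function() {
  strain_variant_map(
    data.frame(gene = c("b9", "b9", "b19"),
               position = c(2350L, 2420L, 2350L),
               base_A = c("A", "C", "G"), base_B = c("G", "T", "A"),
               stringsAsFactors = FALSE),
    data.frame(gene = c("b9", "b19"), position = c(2500L, 2500L),
               weight = c(1, 1), stringsAsFactors = FALSE)
  )
}

# Exhaustive enumeration: a truly biallelic product with exactly one captured
# molecule per allele, split over k tubes (k^2 equally likely assignments,
# amplification always succeeds).  Returns the fraction of assignments whose
# product is k/k positive AND reads as monoallelic under the het threshold h.
enumerate_two_molecule_artifact <- function(k, h = 0.2) {
  artifact <- 0L
  for (tA in seq_len(k)) {
    for (tB in seq_len(k)) {
      nA <- tabulate(tA, nbins = k)
      nB <- tabulate(tB, nbins = k)
      pos <- (nA + nB) > 0L
      if (!all(pos)) next                      # not a k/k product
      minor <- pmin(nA, nB) / (nA + nB)
      if (any(minor >= h & pmin(nA, nB) > 0L)) next  # het tube -> biallelic
      verdict <- ifelse(nA >= nB, "A", "B")
      if (length(unique(verdict)) == 1L) artifact <- artifact + 1L
    }
  }
  artifact / k^2
}

# enumeration oracle for the single-molecule null: all 2^k equally likely
# allele assignments of one molecule per tube
enumerate_single_molecule_null <- function(k) {
  grids <- as.matrix(expand.grid(rep(list(0:1), k)))
  mean(rowSums(grids) %in% c(0L, k))
}
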