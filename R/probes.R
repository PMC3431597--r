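# Sequence computations behind the assay design: probe-window identity scans
# (pan-family vs isoform-specific), strain-variant discovery by pairwise
# alignment, polyadenylation-signal search and 3'-terminus clustering.
#
# "Similarity" is operationalised as percent identity.  Whole-sequence
# comparisons use a global pairwise alignment (Biostrings) with match +1,
# mismatch -1, gap open -2, gap extend -0.5, identity = matches / alignment
# columns with terminal gaps excluded.  Window scans are ungapped (probes
# hybridise contiguously): a window's identity to a sequence is the best
# ungapped match fraction over all placements of the window in the sequence.

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -1
ALIGN_GAP_OPEN <- 2       # Biostrings penalties are positive
ALIGN_GAP_EXTEND <- 0.5

check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty string")
  }
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside {A,C,G,T,N}")
  }
  x
}

align_pair <- function(seq_a, seq_b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = ALIGN_MATCH, mismatch = ALIGN_MISMATCH, baseOnly = FALSE
  )
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND
  )
}

#' Global percent identity between two nucleotide sequences
#'
#' Aligns the two sequences globally (match +1, mismatch -1, gap open -2,
#' gap extend -0.5) and reports `100 * matches / alignment columns`, with
#' columns inside terminal gaps excluded.  The measure is symmetric and a
#' sequence is 100\% identical to itself.
#'
#' @param seq_a,seq_b Nucleotide strings over `{A,C,G,T,N}` (case
#'   insensitive).
#' @return Percent identity in `[0, 100]`.
#' @examples
#' global_percent_identity("ACGTACGT", "ACGAACGT")   # 87.5
#' @export
global_percent_identity <- function(seq_a, seq_b) {
  seq_a <- check_dna(seq_a, "seq_a")
  seq_b <- check_dna(seq_b, "seq_b")
  aln <- align_pair(seq_a, seq_b)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- a == "-" | b == "-"
  # exclude terminal gap runs (leading/trailing columns where one side is gap)
  inner <- which(!gap)
  if (!length(inner)) return(0)
  keep <- seq(min(inner), max(inner))
  100 * sum(a[keep] == b[keep]) / length(keep)
}

# per-window best ungapped identity of every window of `ref` within `mem`:
# for each diagonal shift d, a window starting at s matches
# sum(ref[s..s+W-1] == mem[s+d..s+d+W-1]); maximise over d via cumsums.
best_window_identity <- function(ref_chars, mem_chars, window_length) {
  Lr <- length(ref_chars)
  Lm <- length(mem_chars)
  W <- window_length
  n_win <- Lr - W + 1L
  if (n_win < 1L || Lm < W) {
    stop("window_length must not exceed either sequence")
  }
  best <- rep(0, n_win)
  for (d in (1L - n_win):(Lm - W)) {
    s_lo <- max(1L, 1L - d)
    s_hi <- min(n_win, Lm - W + 1L - d)
    if (s_lo > s_hi) next
    i <- s_lo:(s_hi + W - 1L)
    v <- as.integer(ref_chars[i] == mem_chars[i + d])
    cs <- c(0L, cumsum(v))
    wins <- (cs[(W + 1L):length(cs)] - cs[1L:(length(cs) - W)]) / W
    idx <- s_lo:s_hi
    best[idx] <- pmax(best[idx], wins)
  }
  100 * best
}

scan_windows <- function(sequences, reference, window_length) {
  sequences <- vapply(sequences, check_dna, "", what = "sequence")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be named")
  }
  if (!reference %in% names(sequences)) {
    stop("reference '", reference, "' not among the sequences")
  }
  ref <- strsplit(sequences[[reference]], "")[[1]]
  others <- setdiff(names(sequences), reference)
  mat <- vapply(others, function(nm) {
    best_window_identity(ref, strsplit(sequences[[nm]], "")[[1]],
                         window_length)
  }, numeric(length(ref) - window_length + 1L))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(others))
  mat  # windows x comparison sequences
}

#' Find pan-family probe windows
#'
#' Scans windows of `window_length` along a reference family member and keeps
#' those whose worst-case (minimum) ungapped identity against every other
#' family member is at least `min_identity` — candidate regions for a probe
#' hybridising to the whole family, such as a pan-cluster probe against a
#' conserved ectodomain block.
#'
#' @param family Named character vector (or list) of family member sequences.
#' @param window_length Probe window length in nt.
#' @param min_identity Minimum percent identity required against every member.
#' @param reference Name of the member windows are taken from (default the
#'   first).
#' @return data.frame of qualifying windows (`gene`, `start`, `end`,
#'   `min_identity`), 1-based inclusive coordinates on the reference, sorted
#'   by `min_identity` descending.  Zero rows when no window qualifies.
#' @examples
#' fam <- c(x = "ACGTACGTACGT", y = "ACGTACGTACGT", z = "ACGTACGTACGT")
#' find_pan_probe_region(fam, 8, 90)
#' @export
find_pan_probe_region <- function(family, window_length, min_identity,
                                  reference = names(family)[1L]) {
  family <- unlist(family)
  if (length(family) < 2L) stop("need at least two family members")
  mat <- scan_windows(family, reference, window_length)
  mins <- apply(mat, 1L, min)
  keep <- which(mins >= min_identity)
  out <- data.frame(
    gene = rep(reference, length(keep)), start = keep,
    end = keep + window_length - 1L,
    min_identity = mins[keep], stringsAsFactors = FALSE
  )
  out[order(-out$min_identity, out$start), , drop = FALSE]
}

#' Find isoform-specific probe windows
#'
#' Scans windows of `window_length` along the target and keeps those whose
#' best-case (maximum) ungapped identity to every off-target sequence is at
#' most `max_identity` — candidate regions for a probe labelling one isoform
#' only.
#'
#' @param target Target sequence (single string).
#' @param offtargets Named character vector (or list) of off-target sequences;
#'   must be non-empty (specificity is undefined without a comparison set).
#' @param window_length Probe window length in nt.
#' @param max_identity Maximum percent identity tolerated to any off-target.
#' @param target_name Label used in the output.
#' @return data.frame of qualifying windows (`gene`, `start`, `end`,
#'   `max_identity`), sorted by `max_identity` ascending.
#' @examples
#' find_specific_probe_region("ACGTTTTTGGGGCCCC", c(off = "ACGTACGTACGT"),
#'                            8, 65)
#' @export
find_specific_probe_region <- function(target, offtargets, window_length,
                                       max_identity, target_name = "target") {
  offtargets <- unlist(offtargets)
  if (!length(offtargets)) stop("off-target set must be non-empty")
  if (is.null(names(offtargets)) || any(names(offtargets) == "")) {
    names(offtargets) <- paste0("offtarget", seq_along(offtargets))
  }
  seqs <- c(stats::setNames(target, target_name), offtargets)
  mat <- scan_windows(seqs, target_name, window_length)
  maxs <- apply(mat, 1L, max)
  keep <- which(maxs <= max_identity)
  out <- data.frame(
    gene = rep(target_name, length(keep)), start = keep,
    end = keep + window_length - 1L,
    max_identity = maxs[keep], stringsAsFactors = FALSE
  )
  out[order(out$max_identity, out$start), , drop = FALSE]
}

#' Discover strain-discriminating variant sites between two alleles
#'
#' Globally aligns the two parental-strain sequences over a region and
#' reports every differing aligned position: substitutions site by site,
#' runs of gap columns merged into single insertion/deletion events.
#' Positions are 1-based coordinates on the strain-A sequence (indels are
#' anchored to the last aligned A position before the gap).
#'
#' @param seq_strain_A,seq_strain_B Nucleotide strings for the two strains.
#' @param region Optional length-2 integer vector `(start, end)` restricting
#'   the comparison to that 1-based inclusive interval of both inputs.
#' @return data.frame with columns `position` (on strain A), `type`
#'   (`"substitution"`, `"insertion"` = extra bases in B, `"deletion"` =
#'   bases missing from B), `base_A`, `base_B` (gap runs concatenated; `""`
#'   on the gapped side).  Zero rows when the sequences are identical —
#'   callers must then reject the gene for allele calling.
#' @examples
#' find_discriminating_variants("ACGTACGT", "ACGAACGT")
#' @export
find_discriminating_variants <- function(seq_strain_A, seq_strain_B,
                                         region = NULL) {
  seq_strain_A <- check_dna(seq_strain_A, "seq_strain_A")
  seq_strain_B <- check_dna(seq_strain_B, "seq_strain_B")
  offset <- 0L
  if (!is.null(region)) {
    stopifnot(length(region) == 2L, region[1L] >= 1L,
              region[2L] >= region[1L])
    seq_strain_A <- substr(seq_strain_A, region[1L], region[2L])
    seq_strain_B <- substr(seq_strain_B, region[1L], region[2L])
    offset <- region[1L] - 1L
  }
  aln <- align_pair(seq_strain_A, seq_strain_B)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos_a <- cumsum(a != "-")  # A coordinate at each column
  out <- list()
  i <- 1L
  while (i <= length(a)) {
    if (a[i] != "-" && b[i] != "-") {
      if (a[i] != b[i]) {
        out[[length(out) + 1L]] <- data.frame(
          position = pos_a[i] + offset, type = "substitution",
          base_A = a[i], base_B = b[i], stringsAsFactors = FALSE
        )
      }
      i <- i + 1L
    } else {
      gap_in_a <- a[i] == "-"
      j <- i
      while (j <= length(a) && (if (gap_in_a) a[j] == "-" else b[j] == "-")) {
        j <- j + 1L
      }
      run <- i:(j - 1L)
      out[[length(out) + 1L]] <- data.frame(
        position = max(pos_a[i], 1L) + offset,
        type = if (gap_in_a) "insertion" else "deletion",
        base_A = paste(a[run][a[run] != "-"], collapse = ""),
        base_B = paste(b[run][b[run] != "-"], collapse = ""),
        stringsAsFactors = FALSE
      )
      i <- j
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), type = character(),
                      base_A = character(), base_B = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find polyadenylation signal hexamers upstream of a cleavage site
#'
#' Scans for the canonical polyadenylation signal hexamers (`AATAAA`,
#' `ATTAAA`) lying wholly within 10--40 nt upstream of a cleavage position,
#' nearest signal first.
#'
#' @param sequence Nucleotide string (sense strand).
#' @param cleavage_position 1-based cleavage/poly(A)-addition position within
#'   the sequence.
#' @param hexamers Signal hexamers searched for.
#' @param window Distance bounds (nt upstream of cleavage) the whole hexamer
#'   must fall within; default `c(10, 40)`.
#' @return data.frame with columns `hexamer`, `start` (1-based), `distance`
#'   (cleavage position minus hexamer end), ordered by distance ascending.
#'   Zero rows when no signal is found.
#' @examples
#' seq <- paste0(strrep("C", 30), "AATAAA", strrep("C", 14), "G")
#' find_polya_signals(seq, 51)
#' @export
find_polya_signals <- function(sequence, cleavage_position,
                               hexamers = c("AATAAA", "ATTAAA"),
                               window = c(10, 40)) {
  sequence <- check_dna(sequence, "sequence")
  cp <- as.integer(cleavage_position)
  if (is.na(cp) || cp < 1L || cp > nchar(sequence)) {
    stop("cleavage_position must fall within the sequence")
  }
  hits <- list()
  for (h in hexamers) {
    starts <- gregexpr(h, sequence, fixed = TRUE)[[1]]
    starts <- starts[starts > 0L]
    for (s in starts) {
      hex_end <- s + nchar(h) - 1L
      dist <- cp - hex_end
      # whole hexamer within [cp - window[2], cp - window[1]]
      if (dist >= window[1L] && s >= cp - window[2L]) {
        hits[[length(hits) + 1L]] <- data.frame(
          hexamer = h, start = s, distance = dist, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(hexamer = character(), start = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$distance, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster 3'-terminus cleavage positions
#'
#' Single-linkage clustering of observed cleavage positions: sorted positions
#' are walked left to right and a gap larger than `tolerance` starts a new
#' cluster.  The number of clusters is the number of distinct 3'-termini;
#' `tolerance = 0` distinguishes adjacent-nucleotide heterogeneity (same
#' signal, cleavage shifted by one base) from genuinely distinct sites, while
#' a small positive tolerance merges it.
#'
#' @param positions Integer vector of observed cleavage positions (>= 1
#'   value; duplicates allowed).
#' @param tolerance Maximum within-cluster gap between neighbouring positions
#'   (nt, >= 0).
#' @return data.frame with one row per cluster: `representative` (the most
#'   frequent member position, smallest on ties), `n_members`, `min_position`,
#'   `max_position`, ordered by position.
#' @examples
#' cluster_3prime_termini(c(2301, 2302, 2450), tolerance = 0)  # 3 termini
#' cluster_3prime_termini(c(2301, 2302, 2450), tolerance = 1)  # 2 termini
#' @export
cluster_3prime_termini <- function(positions, tolerance = 0) {
  if (!length(positions)) stop("need at least one position")
  if (!is.numeric(tolerance) || tolerance < 0) stop("tolerance must be >= 0")
  p <- sort(as.integer(positions))
  breaks <- c(0L, cumsum(diff(p) > tolerance))
  rows <- lapply(split(p, breaks), function(m) {
    tab <- table(m)
    rep_pos <- as.integer(names(tab)[which.max(tab)])  # ties -> smallest
    data.frame(representative = rep_pos, n_members = length(m),
               min_position = min(m), max_position = max(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
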