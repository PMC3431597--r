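# Statistical core of the split-tube assay: the single-molecule artifact
# null, its Monte-Carlo generalisation, the chi-square comparison, the
# per-cell repertoire estimator and the combinatorial diversity arithmetic.

#' Artifactual all-tubes-same-allele probability (single-molecule null)
#'
#' Under the worst-case null model for a truly biallelic, low-copy transcript
#' — each of the `k` split tubes amplifies exactly one cDNA molecule whose
#' parental allele is an independent fair draw — the product looks monoallelic
#' whenever all `k` tubes happen to draw the same allele.  That happens with
#' probability `2 * (1/2)^k`: 25\% for the standard three-tube split.  The
#' observed monoallelic fraction is tested against this null.
#'
#' @param k Number of tubes (integer >= 1).
#' @return Probability that all `k` single-molecule tubes read the same
#'   parental allele.
#' @examples
#' artifact_null_probability(3)   # 0.25
#' artifact_null_probability(1)   # 1: one tube can only ever show one allele
#' @export
artifact_null_probability <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be an integer >= 1")
  2 * (1 / 2)^k
}

#' Monte-Carlo artifactual monoallelic rate
#'
#' Simulates truly biallelic cells through the tube-split readout and reports
#' the fraction called fully consistent (`k/k` positive) and monoallelic.
#' Two regimes:
#' \describe{
#'   \item{`"single-molecule"`}{each tube amplifies exactly one molecule of a
#'     random parental allele — the analytic null of
#'     [artifact_null_probability()].}
#'   \item{`"general"`}{a fixed number of captured molecules per allele is
#'     split multinomially across tubes, tubes amplify with probability
#'     `amp_prob` given any template, and per-tube base calls follow the
#'     heterozygous-call threshold `het_min_frac`; the rate counts cells whose
#'     product is `k/k` positive with a monoallelic call.}
#' }
#'
#' @param k Number of tubes.
#' @param n_reps Number of simulated cells (>= 100).
#' @param regime `"single-molecule"` or `"general"`.
#' @param molecules_per_allele Captured molecules per allele (general regime).
#' @param amp_prob,het_min_frac Amplification success probability and
#'   heterozygous-call threshold (general regime).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `rate`, `se` (binomial standard error) and `n_reps`.
#' @examples
#' monte_carlo_artifact_rate(3, 10000, seed = 1)$rate   # ~0.25
#' @export
monte_carlo_artifact_rate <- function(k, n_reps = 100000L,
                                      regime = c("single-molecule", "general"),
                                      molecules_per_allele = 1L,
                                      amp_prob = 1, het_min_frac = 0.2,
                                      seed = NULL) {
  regime <- match.arg(regime)
  k <- as.integer(k)
  n_reps <- as.integer(n_reps)
  if (n_reps < 100L) stop("n_reps must be >= 100")
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (regime == "single-molecule") {
    # k iid fair allele draws per cell; artifact iff all equal
    draws <- matrix(rbinom(n_reps * k, 1L, 0.5), nrow = n_reps)
    same <- rowSums(draws) %in% c(0L, k)
    rate <- mean(same)
  } else {
    m <- as.integer(molecules_per_allele)
    if (m < 1L) stop("molecules_per_allele must be >= 1")
    artifact <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      tube_A <- tabulate(sample.int(k, m, replace = TRUE), nbins = k)
      tube_B <- tabulate(sample.int(k, m, replace = TRUE), nbins = k)
      tot <- tube_A + tube_B
      pos <- tot > 0L & rbinom(k, 1L, amp_prob) == 1L
      if (!all(pos)) next  # not a k/k product
      minor <- pmin(tube_A, tube_B) / tot
      het <- minor >= het_min_frac & pmin(tube_A, tube_B) > 0L
      if (any(het)) next                    # biallelic via heterozygous tube
      verdict <- ifelse(tube_A >= tube_B, "A", "B")
      artifact[r] <- length(unique(verdict)) == 1L  # opposite tubes => biallelic
    }
    rate <- mean(artifact)
  }
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps), n_reps = n_reps)
}

#' Chi-square test of monoallelic counts against a null rate
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' (monoallelic, biallelic) counts against expectations
#' `(N * null_rate, N * (1 - null_rate))`, without continuity correction.
#'
#' @param n_mono,n_bi Observed monoallelic and biallelic product counts.
#' @param null_rate Null monoallelic probability in (0, 1), e.g. the 0.25
#'   single-molecule artifact null for a three-tube split.
#' @return List with `statistic`, `p_value`, `expected` (length-2 vector).
#' @examples
#' chi_square_monoallelic(17, 1, 0.25)    # p well below 1e-4
#' @export
chi_square_monoallelic <- function(n_mono, n_bi, null_rate) {
  if (!is.numeric(null_rate) || null_rate <= 0 || null_rate >= 1) {
    stop("null_rate must lie strictly between 0 and 1")
  }
  n <- n_mono + n_bi
  if (n < 1) stop("need at least one product")
  # plain Pearson statistic by design; suppress the small-expected-count
  # advisory (expected counts are part of the stated test)
  ht <- suppressWarnings(
    chisq.test(c(n_mono, n_bi), p = c(null_rate, 1 - null_rate),
               correct = FALSE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       expected = unname(ht$expected))
}

#' Genes expressed per cell within the assayed set
#'
#' The per-cell expression rate over an assayed gene subset: the number of
#' positive observations divided by the number of cells, reported to two
#' decimal places (e.g. 18 fully consistent products over 28 cells = 0.64
#' genes per cell for a six-gene panel).
#'
#' @param n_positive Number of positive observations (products reaching the
#'   fully consistent tube pattern across the assayed genes).
#' @param n_cells Number of QC-passed cells (>= 1).
#' @param digits Decimal places for reporting (default 2).
#' @return Rate `n_positive / n_cells`, rounded.
#' @examples
#' genes_per_cell(18, 28)   # 0.64
#' @export
genes_per_cell <- function(n_positive, n_cells, digits = 2) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("n_cells must be >= 1")
  if (!is.numeric(n_positive) || n_positive < 0) {
    stop("n_positive must be a non-negative count")
  }
  round(n_positive / n_cells, digits)
}

#' Extrapolate the per-cell repertoire to the whole cluster
#'
#' Scales a per-cell expression rate measured on `n_assayed` genes up to the
#' full cluster of `n_total` genes, assuming no frequency distortion between
#' isoforms: `rate * n_total / n_assayed`, reported to one decimal place
#' (0.64 genes per cell over 6 assayed genes extrapolates to 2.3 of the 22
#' beta-cluster genes per cell).
#'
#' @param rate Per-cell rate over the assayed genes (from [genes_per_cell()]).
#' @param n_assayed Number of genes in the assayed panel (>= 1).
#' @param n_total Total genes in the cluster (>= n_assayed).
#' @param digits Decimal places for reporting (default 1).
#' @return Extrapolated genes expressed per cell.
#' @examples
#' extrapolate_repertoire(0.64, 6, 22)   # 2.3
#' @export
extrapolate_repertoire <- function(rate, n_assayed, n_total, digits = 1) {
  if (!is.numeric(n_assayed) || n_assayed < 1) stop("n_assayed must be >= 1")
  if (!is.numeric(n_total) || n_total < n_assayed) {
    stop("n_total must be >= n_assayed")
  }
  round(rate * n_total / n_assayed, digits)
}

#' Ordered allele-pair combinations within one cluster
#'
#' With one isoform expressed from each of the two parental alleles and the
#' two alleles distinguishable, a cluster of `n` isoforms offers
#' `n * (n - 1)` ordered pairs of distinct isoforms: 462 for the 22-gene beta
#' cluster, 132 for the 12 alpha isoforms, 342 for the 19 gamma isoforms.
#'
#' @param n_isoforms Number of isoforms in the cluster (>= 1).
#' @return `n * (n - 1)` as a numeric count.
#' @examples
#' cluster_pair_combinations(22)   # 462
#' @export
cluster_pair_combinations <- function(n_isoforms) {
  n <- as.numeric(n_isoforms)
  if (length(n) != 1L || is.na(n) || n < 1) stop("n_isoforms must be >= 1")
  n * (n - 1)
}

#' Combinatorial diversity across clusters
#'
#' Product of [cluster_pair_combinations()] over several clusters: the number
#' of distinct cross-cluster identities available when each cluster
#' contributes one isoform per allele.  For the mouse protocadherin clusters
#' (12, 22, 19 isoforms) this exceeds 20 million.
#'
#' @param n_isoforms Numeric vector of per-cluster isoform counts.
#' @return Exact product (numeric; exact for all realistic cluster sizes, and
#'   checked against the 2^53 double-precision integer limit).
#' @examples
#' total_diversity(c(12, 22, 19))   # 20,858,688
#' @export
total_diversity <- function(n_isoforms) {
  if (!length(n_isoforms)) return(1)
  n <- as.numeric(n_isoforms)
  if (any(is.na(n)) || any(n < 0)) stop("counts must be >= 0")
  combos <- ifelse(n < 1, 0, n * (n - 1))  # an empty cluster offers no pairs
  out <- prod(combos)
  if (out > 2^53) stop("product exceeds exact double-precision range")
  out
}
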