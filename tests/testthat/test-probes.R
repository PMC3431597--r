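# Probe-window identity scans, variant discovery, polyA signals, termini.

test_that("global percent identity is reflexive, symmetric and exact", {
  set.seed(21)
  s <- random_dna(120)
  expect_equal(global_percent_identity(s, s), 100)
  expect_equal(global_percent_identity("ACGTACGT", "ACGAACGT"), 87.5)
  t <- mutate_subs(s, 10)
  expect_equal(global_percent_identity(s, t),
               global_percent_identity(t, s))
  expect_error(global_percent_identity("", "ACGT"), "non-empty")
  expect_error(global_percent_identity("ACGT", "ACXT"), "outside")
})

test_that("alignment scores equal an independent dynamic-programming oracle", {
  set.seed(31)
  for (i in 1:5) {
    a <- random_dna(70)
    # mix of substitutions and a short indel
    b <- mutate_subs(a, sample(3:10, 1))
    if (i > 2) {
      cut <- sample(10:60, 1)
      b <- paste0(substr(b, 1, cut), substr(b, cut + sample(1:3, 1) + 1,
                                            nchar(b)))
    }
    aln <- splitrace:::align_pair(a, b)
    expect_equal(Biostrings::score(aln), gotoh_score(a, b))
  }
})

test_that("substitution-only pairs score identity as the match fraction", {
  # with match +1 / mismatch -1 / gap open -2, equal-length pairs differing
  # only by substitutions align without gaps, so identity = hamming matches
  set.seed(41)
  for (i in 1:5) {
    a <- random_dna(200)
    k <- sample(c(5, 20, 50), 1)
    b <- mutate_subs(a, k)
    expect_equal(global_percent_identity(a, b), 100 * (200 - k) / 200)
  }
})

test_that("pan-probe scan returns exactly the conserved windows", {
  set.seed(51)
  # identical family: every window qualifies at 100%
  fam <- c(a = random_dna(60))
  fam <- c(fam, b = unname(fam[1]), c = unname(fam[1]))
  res <- find_pan_probe_region(fam, 20, 100)
  expect_identical(nrow(res), 60L - 20L + 1L)
  expect_true(all(res$min_identity == 100))
  # plant one shared 40-nt block inside otherwise random 200-nt backgrounds
  block <- random_dna(40)
  plant <- function() {
    paste0(random_dna(80), block, random_dna(80))
  }
  fam2 <- c(ref = plant(), m1 = plant(), m2 = plant())
  res2 <- find_pan_probe_region(fam2, 40, 90, reference = "ref")
  expect_gte(nrow(res2), 1L)
  expect_true(any(res2$start == 81 & res2$end == 120))
  # every qualifying window must overlap the planted block
  expect_true(all(res2$end >= 81 & res2$start <= 120))
  # results are sorted by worst-case identity, best first
  expect_true(!is.unsorted(rev(res2$min_identity)))
})

test_that("specific-probe scan excludes windows matching off-targets", {
  set.seed(61)
  target <- random_dna(150)
  # unrelated off-target: essentially all windows qualify at a lax threshold
  res <- find_specific_probe_region(target, c(off = random_dna(150)), 30, 80)
  expect_gt(nrow(res), 100L)
  # target identical to an off-target: nothing is specific
  res2 <- find_specific_probe_region(target, c(off = target), 30, 65)
  expect_identical(nrow(res2), 0L)
  # conserved paralogs with one planted divergent block: only the block works
  core <- random_dna(200)
  divergent <- random_dna(50)
  tgt <- paste0(substr(core, 1, 100), divergent, substr(core, 101, 200))
  off <- c(p1 = paste0(substr(core, 1, 100), random_dna(50),
                       substr(core, 101, 200)))
  res3 <- find_specific_probe_region(tgt, off, 50, 65)
  expect_gte(nrow(res3), 1L)
  expect_true(all(res3$end >= 101 & res3$start <= 150))
  expect_error(find_specific_probe_region(target, character(0), 30, 65),
               "non-empty")
})

test_that("pan and specific thresholds are mutually exclusive", {
  # a window cannot be >= 84% identical to every member of a set and at the
  # same time <= 65% identical to every member of the same set
  set.seed(71)
  base <- random_dna(150)
  fam <- c(ref = base, m1 = mutate_subs(base, 15), m2 = mutate_subs(base, 40))
  pan <- find_pan_probe_region(fam, 40, 84, reference = "ref")
  spec <- find_specific_probe_region(base, fam[c("m1", "m2")], 40, 65,
                                     target_name = "ref")
  expect_identical(intersect(pan$start, spec$start), integer(0))
})

test_that("strain variant discovery reports substitutions and indels", {
  set.seed(81)
  a <- random_dna(120)
  expect_identical(nrow(find_discriminating_variants(a, a)), 0L)
  # single engineered substitution
  b <- a
  substr(b, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 60, 60))[1]
  v <- find_discriminating_variants(a, b)
  expect_identical(nrow(v), 1L)
  expect_identical(v$position, 60L)
  expect_identical(v$type, "substitution")
  # 2-nt deletion from strain B plus 3 substitutions -> 4 sites
  c_ <- a
  for (p in c(20L, 50L, 100L)) {
    substr(c_, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  }
  c_ <- paste0(substr(c_, 1, 74), substr(c_, 77, 120))  # drop bases 75-76
  v2 <- find_discriminating_variants(a, c_)
  expect_identical(nrow(v2), 4L)
  expect_identical(sum(v2$type == "substitution"), 3L)
  expect_identical(sum(v2$type == "deletion"), 1L)
  del <- v2[v2$type == "deletion", ]
  expect_identical(nchar(del$base_A), 2L)
  expect_identical(del$base_B, "")
  expect_setequal(v2$position[v2$type == "substitution"], c(20L, 50L, 100L))
})

test_that("polyA signal search respects the 10-40 nt upstream window", {
  seq1 <- paste0(strrep("C", 30), "AATAAA", strrep("C", 14), "G")
  hit <- find_polya_signals(seq1, 51)  # hexamer at 31-36, 15 nt upstream
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$hexamer, "AATAAA")
  expect_identical(hit$start, 31L)
  expect_identical(hit$distance, 15L)
  # no hexamer in the window -> empty
  expect_identical(nrow(find_polya_signals(strrep("C", 60), 50)), 0L)
  # a signal too close to the cleavage site (< 10 nt) is ignored
  seq2 <- paste0(strrep("C", 40), "AATAAA", "CCCC", "G")
  expect_identical(nrow(find_polya_signals(seq2, 51)), 0L)
  # two hexamers in range, ordered nearest first
  seq3 <- paste0(strrep("C", 12), "ATTAAA", strrep("C", 10), "AATAAA",
                 strrep("C", 14), "G")
  two <- find_polya_signals(seq3, 49)
  expect_identical(two$hexamer, c("AATAAA", "ATTAAA"))
  expect_true(!is.unsorted(two$distance))
})

test_that("3'-terminus clustering counts distinct cleavage sites", {
  one <- cluster_3prime_termini(2301)
  expect_identical(nrow(one), 1L)
  expect_identical(one$representative, 2301L)
  # adjacent-nucleotide heterogeneity: split at tolerance 0, merged at 1
  expect_identical(nrow(cluster_3prime_termini(c(2301, 2302, 2450), 0)), 3L)
  expect_identical(nrow(cluster_3prime_termini(c(2301, 2302, 2450), 1)), 2L)
  # cluster count is non-increasing in tolerance
  set.seed(91)
  pos <- sample(2300:2600, 40, replace = TRUE)
  counts <- vapply(c(0, 1, 2, 5, 10, 50, 500), function(tol) {
    nrow(cluster_3prime_termini(pos, tol))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[length(counts)], 1)
})

test_that("deeply sampled simulated genes recover their three polyA sites", {
  vm <- default_variant_map()
  spec <- cluster_spec("beta", n_isoforms = 1)
  set.seed(101)
  tr <- simulate_cell_truth(spec, sim_params(expression_prob = 1,
                                             copies_mean = 500), vm)
  cl <- cluster_3prime_termini(tr$molecules$polya_site, tolerance = 1)
  expect_identical(nrow(cl), 3L)
  expect_setequal(cl$representative, polya_sites(vm, "b1")$position)
})
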