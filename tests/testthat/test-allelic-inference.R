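# Product classification, allele calling, QC gate and aggregation.

test_that("tube positivity patterns are counted correctly", {
  expect_identical(classify_tube_pattern(c(TRUE, TRUE, TRUE)), "3/3")
  expect_identical(classify_tube_pattern(c(FALSE, FALSE, FALSE)), "0/3")
  expect_identical(classify_tube_pattern(c(TRUE, FALSE, TRUE)), "2/3")
  expect_identical(classify_tube_pattern(c(1, 0)), "1/2")
  expect_error(classify_tube_pattern(logical(0)), "non-empty")
})

test_that("allele calling follows the split-design consistency rules", {
  vm <- tiny_map()  # b9: 2350 A/G, 2420 C/T (allele A first)
  pureA <- "2350:A;2420:C"
  pureB <- "2350:G;2420:T"
  # unanimous pure tubes -> monoallelic
  expect_identical(call_product_allele(rep(pureB, 3), vm, "b9"),
                   "monoallelic-B")
  expect_identical(call_product_allele(c(pureA, ".", pureA), vm, "b9"),
                   "monoallelic-A")
  # opposite clean tubes: both alleles present in the pooled cDNA
  expect_identical(call_product_allele(c(pureA, pureB, "."), vm, "b9"),
                   "biallelic")
  # any heterozygous site -> biallelic (the actin-control situation)
  expect_identical(call_product_allele(c("2350:A/G;2420:C", ".", "."),
                                       vm, "b9"), "biallelic")
  # sites within one tube disagreeing on the allele -> inconsistent
  expect_identical(call_product_allele(c("2350:A;2420:T", pureA, pureA),
                                       vm, "b9"), "inconsistent")
  # bases matching neither allele are sequencing errors; all excluded ->
  # insufficient
  expect_identical(call_product_allele(c("2350:C;2420:G", "."), vm, "b9"),
                   "insufficient")
  # an error site is excluded but a clean site still carries the call
  expect_identical(call_product_allele(c("2350:C;2420:T", "."), vm, "b9"),
                   "monoallelic-B")
  expect_error(call_product_allele(pureA, vm, "nope"), "variant sites")
})

test_that("every product falls in exactly one call class", {
  vm <- default_variant_map()
  ex <- simulate_experiment(60, seed = 19)
  calls <- call_alleles(ex$dataset, vm)
  classes <- c("monoallelic-A", "monoallelic-B", "biallelic",
               "inconsistent", "insufficient")
  expect_true(all(calls$allele_call %in% classes))
  agg <- aggregate_monoallelic_fraction(calls, pattern_filter = NULL)
  kept <- calls[!calls$gene %in% c("Pcp2", "actin") &
                  !startsWith(calls$pattern, "0/"), ]
  expect_identical(agg$n_monoallelic + agg$n_biallelic +
                     agg$n_inconsistent + agg$n_insufficient, nrow(kept))
})

test_that("the QC gate requires Pcp2, actin and actin biallelism", {
  mk <- function(cell, gene, pattern, call) {
    data.frame(cell_id = cell, gene = gene, pattern = pattern,
               allele_call = call, parental_allele = NA_character_,
               stringsAsFactors = FALSE)
  }
  good <- rbind(mk("c1", "Pcp2", "3/3", "biallelic"),
                mk("c1", "actin", "3/3", "biallelic"),
                mk("c1", "b9", "3/3", "monoallelic-A"))
  no_pcp2 <- rbind(mk("c2", "actin", "3/3", "biallelic"))
  actin_mono <- rbind(mk("c3", "Pcp2", "3/3", "biallelic"),
                      mk("c3", "actin", "3/3", "monoallelic-B"))
  qc <- qc_gate(rbind(good, no_pcp2, actin_mono),
                cell_ids = c("c1", "c2", "c3", "ctrl"))
  expect_identical(qc$passed, c(TRUE, FALSE, FALSE, FALSE))
  # the no-cell control fails through having no products at all
  expect_false(qc$pcp2_positive[qc$cell_id == "ctrl"])
})

test_that("monoallelic fraction counts only clean calls in the denominator", {
  calls <- data.frame(
    cell_id = "c", gene = paste0("b", 1:6), pattern = "3/3",
    allele_call = c("monoallelic-A", "monoallelic-B", "biallelic",
                    "inconsistent", "insufficient", "monoallelic"),
    stringsAsFactors = FALSE
  )
  agg <- aggregate_monoallelic_fraction(calls)
  expect_identical(agg$n_monoallelic, 3L)
  expect_identical(agg$n_biallelic, 1L)
  expect_identical(agg$n_inconsistent, 1L)
  expect_identical(agg$n_insufficient, 1L)
  expect_equal(agg$fraction, 3 / 4)
  # all-biallelic -> fraction 0; empty denominator -> explicit NA
  allbi <- transform(calls, allele_call = "biallelic")
  expect_equal(aggregate_monoallelic_fraction(allbi)$fraction, 0)
  empty <- aggregate_monoallelic_fraction(calls[0, ])
  expect_true(is.na(empty$fraction))
})

test_that("deep-capture biallelic truth is almost never called monoallelic", {
  # force biallelic truth (q = 1) at 30 copies per allele with no dropout
  spec <- cluster_spec("beta", n_isoforms = 2)
  vm <- default_variant_map(spec)
  params <- sim_params(expression_prob = 1, copies_mean = 30, amp_prob = 1)
  ex <- simulate_experiment(100, spec, vm, params, seed = 50,
                            include_controls = FALSE)
  calls <- call_alleles(ex$dataset, vm)
  agg <- aggregate_monoallelic_fraction(calls)
  expect_gt(agg$n_monoallelic + agg$n_biallelic, 150)
  expect_lte(agg$fraction, 0.05)
})

test_that("inference matches the truth table exactly at high capture", {
  vm <- default_variant_map()
  params <- sim_params(copies_mean = 30, amp_prob = 1)
  ex <- simulate_experiment(200, params = params, seed = 71,
                            include_controls = FALSE)
  calls <- call_alleles(ex$dataset, vm)
  full <- calls[calls$pattern == "3/3", ]
  m <- merge(full, ex$truth, by = c("cell_id", "gene"))
  expect_identical(nrow(m), nrow(full))
  # per-product agreement and therefore identical aggregate fractions
  expect_identical(m$allele_call, m$truth_class)
  agg <- aggregate_monoallelic_fraction(calls)
  truth_frac <- mean(m$truth_class %in% c("monoallelic-A", "monoallelic-B"))
  expect_equal(agg$fraction, truth_frac)
})

test_that("lowering the het threshold only moves calls towards biallelic", {
  vm <- default_variant_map()
  ex <- simulate_experiment(60, seed = 13, include_controls = FALSE)
  d <- ex$dataset
  recall <- function(h) {
    d2 <- d
    for (r in seq_len(nrow(d2))) {
      if (d2$positive[r] == 1L) {
        d2$site_calls[r] <- splitrace:::call_tube_bases(
          d2$n_A[r], d2$n_B[r], variant_sites(vm, d2$gene[r]), h)
      }
    }
    call_alleles(d2, vm)
  }
  hs <- c(0.45, 0.30, 0.15, 0.05)
  calls <- lapply(hs, recall)
  for (i in seq_len(length(hs) - 1L)) {
    hi <- calls[[i]]; lo <- calls[[i + 1L]]  # lo has the smaller threshold
    expect_identical(hi[c("cell_id", "gene")], lo[c("cell_id", "gene")])
    moved <- hi$allele_call != lo$allele_call
    expect_true(all(startsWith(hi$allele_call[moved], "monoallelic")))
    expect_true(all(lo$allele_call[moved] == "biallelic"))
  }
})

test_that("allele balance uses an exact two-sided binomial test", {
  # the reference totals, 7 vs 10, show no parental distortion
  calls <- data.frame(
    allele_call = rep(c("monoallelic-A", "monoallelic-B"), c(7, 10)),
    parental_allele = rep(c("B6", "JF1"), c(7, 10)),
    stringsAsFactors = FALSE
  )
  bal <- allele_balance(calls)
  expect_identical(bal$n_allele_A, 7L)
  expect_identical(bal$n_allele_B, 10L)
  expect_gt(bal$p_value, 0.05)
  # 20 vs 0 is an extreme skew: p = 2 * 0.5^20
  skew <- data.frame(allele_call = rep("monoallelic-A", 20),
                     parental_allele = rep("B6", 20),
                     stringsAsFactors = FALSE)
  expect_equal(allele_balance(skew)$p_value, 2 * 0.5^20)
  expect_lt(allele_balance(skew)$p_value, 1e-4)
  # no monoallelic products -> explicit empty result
  none <- allele_balance(calls[0, ])
  expect_identical(none$n_allele_A, 0L)
  expect_true(is.na(none$p_value))
})
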