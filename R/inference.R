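# Allele calling on split 3'-RACE tables.  A product (one gene in one cell)
# is read out in up to n_tubes independent PCR tubes; direct sequencing of
# each positive tube at the strain-discriminating variant sites yields a pure
# allele-A, pure allele-B or heterozygous base call per site.

#' Classify a tube positivity pattern
#'
#' @param tube_positives Logical (or 0/1) vector, one element per tube.
#' @return A string `"k/n"` where `k` is the number of positive tubes and `n`
#'   the total number of tubes, e.g. `"3/3"`.
#' @examples
#' classify_tube_pattern(c(TRUE, TRUE, TRUE))   # "3/3"
#' classify_tube_pattern(c(TRUE, FALSE, TRUE))  # "2/3"
#' @export
classify_tube_pattern <- function(tube_positives) {
  if (length(tube_positives) == 0L) stop("tube_positives must be non-empty")
  tp <- as.logical(tube_positives)
  if (anyNA(tp)) stop("tube_positives must be TRUE/FALSE or 0/1")
  paste0(sum(tp), "/", length(tp))
}

# parse one tube's site_calls string ("2350:A;2420:G", het "2350:A/G",
# "." = negative/no reads) into a data.frame(position, call)
parse_site_calls <- function(s) {
  if (is.na(s) || s == "." || s == "") {
    return(data.frame(position = integer(), call = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             call = toupper(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

# map one tube's site calls onto alleles: "A", "B", "het" per readable site;
# sites whose base matches neither allele are sequencing errors and excluded
tube_allele_reads <- function(calls, sites) {
  m <- merge(calls, sites, by = "position")
  if (!nrow(m)) return(character(0))
  read <- character(nrow(m))
  het <- grepl("/", m$call, fixed = TRUE)
  read[het] <- "het"
  read[!het & m$call == m$base_A] <- "A"
  read[!het & m$call == m$base_B] <- "B"
  read[read != ""]  # drop sequencing-error sites
}

#' Call the allelic origin of one 3'-RACE product
#'
#' Applies the consistency rules of the split design to the per-tube base
#' calls of one (cell, gene) product:
#' \itemize{
#'   \item `"biallelic"` if any positive tube is heterozygous at any variant
#'     site, or if different clean tubes yield opposite pure alleles (both
#'     alleles demonstrably present in the cell's pooled cDNA);
#'   \item `"monoallelic-A"` / `"monoallelic-B"` if every readable tube reads
#'     one pure allele at all sites;
#'   \item `"inconsistent"` if sites within a single tube disagree on the
#'     allele assignment;
#'   \item `"insufficient"` if no tube has a readable variant site (all sites
#'     missing or flagged as sequencing errors).
#' }
#'
#' @param site_calls Character vector of per-tube site-call strings
#'   (`"pos:base"` joined by `";"`; heterozygous as `"pos:bA/bB"`; `"."` for a
#'   negative or unread tube).
#' @param variants A [strain_variant_map()].
#' @param gene Gene label, used to look up its variant sites.
#' @return One of `"monoallelic-A"`, `"monoallelic-B"`, `"biallelic"`,
#'   `"inconsistent"`, `"insufficient"`.
#' @examples
#' vm <- strain_variant_map(
#'   data.frame(gene = "b9", position = c(2350, 2420),
#'              base_A = c("A", "C"), base_B = c("G", "T")),
#'   data.frame(gene = "b9", position = 2500, weight = 1)
#' )
#' call_product_allele(c("2350:G;2420:T", "2350:G;2420:T", "2350:G;2420:T"),
#'                     vm, "b9")   # "monoallelic-B"
#' call_product_allele(c("2350:A/G;2420:C", ".", "."), vm, "b9") # "biallelic"
#' @export
call_product_allele <- function(site_calls, variants, gene) {
  stopifnot(inherits(variants, "strain_variant_map"))
  sites <- variant_sites(variants, gene)
  if (!nrow(sites)) stop("no variant sites known for gene ", gene)
  per_tube <- lapply(site_calls, function(s) {
    tube_allele_reads(parse_site_calls(s), sites)
  })
  per_tube <- per_tube[lengths(per_tube) > 0L]
  if (!length(per_tube)) return("insufficient")
  verdicts <- vapply(per_tube, function(r) {
    if (any(r == "het")) return("het")
    u <- unique(r)
    if (length(u) == 1L) u else "conflict"
  }, "")
  if (any(verdicts == "conflict")) return("inconsistent")
  if (any(verdicts == "het")) return("biallelic")
  pure <- unique(verdicts)
  if (length(pure) > 1L) return("biallelic")  # opposite tubes, both clean
  paste0("monoallelic-", pure)
}

#' Call alleles and tube patterns for every product in a dataset
#'
#' Product-level reduction of a tube-level split 3'-RACE table: one output row
#' per (cell, gene) with any recorded tube, carrying the positivity pattern
#' and the allele call of [call_product_allele()].
#'
#' @param dataset Tube-level data.frame with columns `cell_id`, `gene`,
#'   `tube_index`, `positive`, `site_calls` (the [simulate_experiment()]
#'   dataset schema).
#' @param variants A [strain_variant_map()].
#' @return data.frame with columns `cell_id`, `gene`, `pattern` (e.g.
#'   `"3/3"`), `allele_call`, and `parental_allele` (the strain name for
#'   monoallelic calls, `NA` otherwise).
#' @examples
#' ex <- simulate_experiment(5, seed = 7)
#' calls <- call_alleles(ex$dataset, default_variant_map())
#' head(calls)
#' @export
call_alleles <- function(dataset, variants) {
  stopifnot(is.data.frame(dataset), inherits(variants, "strain_variant_map"))
  need <- c("cell_id", "gene", "tube_index", "positive", "site_calls")
  if (!all(need %in% names(dataset))) {
    stop("dataset needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(dataset)) {
    return(data.frame(cell_id = character(), gene = character(),
                      pattern = character(), allele_call = character(),
                      parental_allele = character(), stringsAsFactors = FALSE))
  }
  key <- interaction(dataset$cell_id, dataset$gene, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(dataset)), key), function(idx) {
    d <- dataset[idx, , drop = FALSE]
    d <- d[order(d$tube_index), , drop = FALSE]
    pattern <- classify_tube_pattern(d$positive == 1L)
    if (!any(d$positive == 1L)) {
      call <- "insufficient"  # 0/n products carry no allele call
    } else {
      call <- call_product_allele(d$site_calls[d$positive == 1L], variants,
                                  d$gene[1L])
    }
    parental <- NA_character_
    if (call == "monoallelic-A") parental <- variants$alleles[1L]
    if (call == "monoallelic-B") parental <- variants$alleles[2L]
    data.frame(cell_id = d$cell_id[1L], gene = d$gene[1L], pattern = pattern,
               allele_call = call, parental_allele = parental,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell quality-control gate on control transcripts
#'
#' A cell enters the downstream statistics only if its RT worked and it really
#' is a single intact Purkinje cell: the Purkinje marker `Pcp2` must amplify
#' in every tube, and the abundant `actin` control must amplify in every tube
#' AND read biallelic (an abundant transcript read monoallelic would flag an
#' artifact-prone sample).  No-cell negative controls, having no products at
#' all, necessarily fail.
#'
#' @param calls Product-level data.frame from [call_alleles()].
#' @param cell_ids Optional character vector of all sample identifiers
#'   (including no-cell controls that produced no rows); defaults to the cells
#'   present in `calls`.
#' @param n_tubes Number of tubes in the assay (default 3).
#' @param pcp2_gene,actin_gene Control transcript labels.
#' @return data.frame with one row per cell: `cell_id`, `pcp2_positive`,
#'   `actin_positive`, `actin_biallelic`, `passed`.
#' @examples
#' ex <- simulate_experiment(8, seed = 3)
#' calls <- call_alleles(ex$dataset, default_variant_map())
#' qc_gate(calls, cell_ids = ex$cells$cell_id)
#' @export
qc_gate <- function(calls, cell_ids = NULL, n_tubes = 3L,
                    pcp2_gene = "Pcp2", actin_gene = "actin") {
  stopifnot(is.data.frame(calls))
  if (is.null(cell_ids)) cell_ids <- unique(calls$cell_id)
  full <- paste0(n_tubes, "/", n_tubes)
  rows <- lapply(cell_ids, function(id) {
    cc <- calls[calls$cell_id == id, , drop = FALSE]
    p <- cc[cc$gene == pcp2_gene, , drop = FALSE]
    a <- cc[cc$gene == actin_gene, , drop = FALSE]
    pcp2_pos <- nrow(p) > 0L && any(p$pattern == full)
    actin_pos <- nrow(a) > 0L && any(a$pattern == full)
    actin_bi <- actin_pos && any(a$allele_call[a$pattern == full] ==
                                   "biallelic")
    data.frame(cell_id = id, pcp2_positive = pcp2_pos,
               actin_positive = actin_pos, actin_biallelic = actin_bi,
               passed = pcp2_pos && actin_pos && actin_bi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monoallelic fraction among products of a given tube pattern
#'
#' Counts monoallelic versus biallelic allele calls among products whose tube
#' pattern matches `pattern_filter` (default `"3/3"`, the fully consistent
#' products the headline fraction is restricted to).  `inconsistent` and
#' `insufficient` products are reported separately and never enter either bin
#' or the denominator.  Control transcripts are excluded.
#'
#' @param calls Product-level data.frame from [call_alleles()] (ideally
#'   already restricted to QC-passed cells).
#' @param pattern_filter Tube pattern to keep, e.g. `"3/3"`; use `NULL` to
#'   keep every pattern with at least one positive tube.
#' @param exclude_genes Genes dropped before counting (default the controls).
#' @return List with `n_monoallelic`, `n_biallelic`, `n_inconsistent`,
#'   `n_insufficient`, `fraction` (monoallelic / (monoallelic + biallelic);
#'   `NA` if the denominator is empty) and `percent` (fraction rounded to the
#'   nearest integer percent).
#' @examples
#' ex <- simulate_experiment(30, seed = 11)
#' calls <- call_alleles(ex$dataset, default_variant_map())
#' aggregate_monoallelic_fraction(calls)
#' @export
aggregate_monoallelic_fraction <- function(calls, pattern_filter = "3/3",
                                           exclude_genes = c("Pcp2",
                                                             "actin")) {
  stopifnot(is.data.frame(calls))
  cc <- calls[!calls$gene %in% exclude_genes, , drop = FALSE]
  if (!is.null(pattern_filter)) {
    cc <- cc[cc$pattern %in% pattern_filter, , drop = FALSE]
  } else {
    cc <- cc[!startsWith(cc$pattern, "0/"), , drop = FALSE]
  }
  # "monoallelic" without a parental suffix (origin not recorded) counts too
  n_mono <- sum(cc$allele_call %in% c("monoallelic-A", "monoallelic-B",
                                      "monoallelic"))
  n_bi <- sum(cc$allele_call == "biallelic")
  n_inc <- sum(cc$allele_call == "inconsistent")
  n_ins <- sum(cc$allele_call == "insufficient")
  denom <- n_mono + n_bi
  frac <- if (denom > 0L) n_mono / denom else NA_real_
  list(n_monoallelic = n_mono, n_biallelic = n_bi, n_inconsistent = n_inc,
       n_insufficient = n_ins, fraction = frac,
       percent = if (is.na(frac)) NA_real_ else round(100 * frac))
}

#' Parental-allele balance among monoallelic products
#'
#' Counts monoallelic products per parental allele and tests the split
#' against the 50:50 expectation with a two-sided exact binomial test; a
#' non-significant result means no parental (imprinting-like) distortion.
#'
#' @param calls Product-level data.frame from [call_alleles()]; only rows
#'   with a monoallelic `allele_call` are used.
#' @param alleles Length-2 parental strain names (default `c("B6", "JF1")`).
#' @return List with `n_allele_A`, `n_allele_B`, `p_value` (two-sided exact
#'   binomial against 0.5; `NA` when there are no monoallelic products).
#' @examples
#' allele_balance(data.frame(
#'   allele_call = rep(c("monoallelic-A", "monoallelic-B"), c(7, 10)),
#'   parental_allele = rep(c("B6", "JF1"), c(7, 10))))
#' @export
allele_balance <- function(calls, alleles = c("B6", "JF1")) {
  stopifnot(is.data.frame(calls))
  mono <- calls[calls$allele_call %in% c("monoallelic-A", "monoallelic-B"),
                , drop = FALSE]
  if ("parental_allele" %in% names(mono) && !all(is.na(mono$parental_allele))) {
    n_A <- sum(mono$parental_allele == alleles[1L], na.rm = TRUE)
    n_B <- sum(mono$parental_allele == alleles[2L], na.rm = TRUE)
  } else {
    n_A <- sum(mono$allele_call == "monoallelic-A")
    n_B <- sum(mono$allele_call == "monoallelic-B")
  }
  if (n_A + n_B == 0L) {
    return(list(n_allele_A = 0L, n_allele_B = 0L, p_value = NA_real_))
  }
  list(n_allele_A = n_A, n_allele_B = n_B,
       p_value = binom.test(n_A, n_A + n_B, p = 0.5)$p.value)
}
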