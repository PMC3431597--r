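# Generative model: each allele independently expresses each isoform with
# probability q; expressed (allele, isoform) pairs capture a zero-truncated
# Poisson(mu) number of cDNA molecules; each molecule picks a polyA site by
# usage weight, is split uniformly into one of n_tubes, and a tube amplifies
# (Bernoulli a) iff it received at least one template.

# zero-truncated Poisson sampler via the inverse-CDF restricted above P(0)
rztpois <- function(n, mu) {
  if (n == 0L) return(integer(0))
  p0 <- dpois(0, mu)
  qpois(runif(n, min = p0, max = 1), mu)
}

#' Simulate the ground-truth expression state of one diploid cell
#'
#' Draws, for each parental allele independently, the set of expressed
#' isoforms (Bernoulli `q` per isoform), the number of captured cDNA molecules
#' per expressed (allele, isoform) pair (zero-truncated Poisson `mu`), and a
#' polyadenylation site for every molecule (sampled by usage weight from
#' `variants`, when supplied).
#'
#' @param spec A [cluster_spec()].
#' @param params A [sim_params()].
#' @param variants Optional [strain_variant_map()]; if supplied, each molecule
#'   is assigned a cleavage position drawn from the gene's polyA-site usage
#'   weights, otherwise the position is recorded as `NA`.
#' @param cell_id Identifier stored on the result.
#' @return An object of class `cell_truth`: list with `cell_id`, `molecules`
#'   (data.frame: `gene`, `allele` ("A"/"B"), `polya_site`, one row per
#'   captured molecule), `expressed` (list of per-allele isoform sets) and
#'   `truth_class` (named character vector over all isoforms:
#'   `"monoallelic-A"`, `"monoallelic-B"`, `"biallelic"` or `"silent"`).
#' @examples
#' set.seed(1)
#' tr <- simulate_cell_truth(cluster_spec("beta"), sim_params())
#' table(tr$truth_class)
#' @export
simulate_cell_truth <- function(spec, params = sim_params(), variants = NULL,
                                cell_id = "cell1") {
  stopifnot(inherits(spec, "cluster_spec"), inherits(params, "sim_params"))
  q <- params$expression_prob
  ids <- spec$isoform_ids
  on_A <- ids[rbinom(spec$n_isoforms, 1L, q) == 1L]
  on_B <- ids[rbinom(spec$n_isoforms, 1L, q) == 1L]
  truth_class <- rep("silent", spec$n_isoforms)
  names(truth_class) <- ids
  truth_class[ids %in% on_A & !(ids %in% on_B)] <- "monoallelic-A"
  truth_class[!(ids %in% on_A) & ids %in% on_B] <- "monoallelic-B"
  truth_class[ids %in% on_A & ids %in% on_B] <- "biallelic"

  pair_gene <- c(on_A, on_B)
  pair_allele <- c(rep("A", length(on_A)), rep("B", length(on_B)))
  copies <- rztpois(length(pair_gene), params$copies_mean)
  gene_col <- rep(pair_gene, times = copies)
  molecules <- data.frame(
    gene = gene_col,
    allele = rep(pair_allele, times = copies),
    polya_site = rep(NA_integer_, length(gene_col)),
    stringsAsFactors = FALSE
  )
  if (!is.null(variants) && nrow(molecules)) {
    stopifnot(inherits(variants, "strain_variant_map"))
    for (g in unique(molecules$gene)) {
      ps <- polya_sites(variants, g)
      sel <- molecules$gene == g
      if (nrow(ps)) {
        molecules$polya_site[sel] <- sample(ps$position, sum(sel),
                                            replace = TRUE, prob = ps$weight)
      }
    }
  }
  structure(
    list(cell_id = cell_id, molecules = molecules,
         expressed = list(A = on_A, B = on_B), truth_class = truth_class),
    class = "cell_truth"
  )
}

#' @export
print.cell_truth <- function(x, ...) {
  on <- x$truth_class[x$truth_class != "silent"]
  cat("cell_truth ", x$cell_id, ": ", nrow(x$molecules),
      " molecules; expressed: ",
      if (length(on)) paste(names(on), "(", on, ")", collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

# direct-sequencing base call for one tube at one variant site, given the
# tube's template counts per allele.  Returns "pos:b" for a pure call or
# "pos:bA/bB" when the minor allele's template fraction reaches h.
call_tube_bases <- function(n_A, n_B, sites, het_min_frac) {
  tot <- n_A + n_B
  if (tot == 0L) return(".")
  minor <- min(n_A, n_B) / tot
  if (minor >= het_min_frac && min(n_A, n_B) > 0L) {
    calls <- paste0(sites$position, ":", sites$base_A, "/", sites$base_B)
  } else if (n_A >= n_B) {
    calls <- paste0(sites$position, ":", sites$base_A)
  } else {
    calls <- paste0(sites$position, ":", sites$base_B)
  }
  paste(calls, collapse = ";")
}

#' Split a cell's cDNA across tubes and amplify
#'
#' Assigns every captured molecule to one of `n_tubes` uniformly and
#' independently (multinomial splitting of equal aliquots), marks a tube
#' positive for a gene iff it received at least one template molecule of that
#' gene AND an independent Bernoulli(`amp_prob`) amplification succeeds, and
#' emits per-tube direct-sequencing base calls at the gene's variant sites: a
#' site reads heterozygous when the minor allele's template fraction in that
#' tube is at least `het_min_frac`, else it reads the majority allele's base.
#'
#' @param truth A [simulate_cell_truth()] result.
#' @param variants A [strain_variant_map()] covering every simulated gene.
#' @param params A [sim_params()].
#' @return data.frame with one row per (gene, tube) for every gene with at
#'   least one positive tube: `cell_id`, `gene`, `tube_index`, `positive`
#'   (0/1), `site_calls` (semicolon-joined `pos:base`, `"."` if negative), and
#'   the simulation-truth template counts `n_A`, `n_B` (used for parameter
#'   sweeps; dropped by the TSV writer's public schema).
#' @examples
#' set.seed(1)
#' vm <- default_variant_map()
#' tr <- simulate_cell_truth(cluster_spec("beta"), sim_params(), vm)
#' split_and_amplify(tr, vm, sim_params())
#' @export
split_and_amplify <- function(truth, variants, params = sim_params()) {
  stopifnot(inherits(truth, "cell_truth"),
            inherits(variants, "strain_variant_map"),
            inherits(params, "sim_params"))
  mol <- truth$molecules
  genes <- unique(mol$gene)
  missing_var <- genes[!genes %in% unique(variants$variant_sites$gene)]
  if (length(missing_var)) {
    stop("no variant sites for gene(s): ", paste(missing_var, collapse = ", "))
  }
  k <- params$n_tubes
  out <- vector("list", length(genes))
  if (nrow(mol)) mol$tube <- sample.int(k, nrow(mol), replace = TRUE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    gm <- mol[mol$gene == g, , drop = FALSE]
    sites <- variant_sites(variants, g)
    n_A <- tabulate(gm$tube[gm$allele == "A"], nbins = k)
    n_B <- tabulate(gm$tube[gm$allele == "B"], nbins = k)
    has_template <- (n_A + n_B) > 0L
    amplified <- has_template & (rbinom(k, 1L, params$amp_prob) == 1L)
    if (!any(amplified)) next
    site_calls <- rep(".", k)
    for (t in which(amplified)) {
      site_calls[t] <- call_tube_bases(n_A[t], n_B[t], sites,
                                       params$het_min_frac)
    }
    out[[i]] <- data.frame(
      cell_id = truth$cell_id, gene = g, tube_index = seq_len(k),
      positive = as.integer(amplified), site_calls = site_calls,
      n_A = n_A, n_B = n_B, stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(cell_id = character(), gene = character(),
                      tube_index = integer(), positive = integer(),
                      site_calls = character(), n_A = integer(),
                      n_B = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# control transcripts: Pcp2 and beta-actin are abundant and biallelic in a
# real cell; both alleles capture Poisson(control_copies_mean) molecules.
simulate_control_molecules <- function(params, controls = c("Pcp2", "actin")) {
  copies <- rpois(2L * length(controls), params$control_copies_mean)
  data.frame(
    gene = rep(controls, each = 2L),
    allele = rep(c("A", "B"), times = length(controls)),
    polya_site = NA_integer_,
    stringsAsFactors = FALSE
  )[rep(seq_len(2L * length(controls)), times = copies), , drop = FALSE]
}

#' Simulate a full split single-cell 3'-RACE experiment
#'
#' Batch wrapper: simulates `n_cells` diploid cells (plus interleaved no-cell
#' negative controls emitting no products), runs capture, tube splitting and
#' amplification for the cluster isoforms and the two abundant control
#' transcripts (`Pcp2`, `actin`), and returns both the observable dataset
#' table and the ground-truth table needed for recovery tests.
#'
#' Cell identifiers follow the plate convention `"1-1"`, `"1-2"`, ...; every
#' `(controls_per_cells + 1)`-th position is a no-cell control.
#'
#' @param n_cells Number of real cells (>= 0).
#' @param spec A [cluster_spec()].
#' @param variants A [strain_variant_map()]; default [default_variant_map()].
#' @param params A [sim_params()].
#' @param seed Integer seed; the run is fully reproducible given it.
#' @param include_controls Simulate control transcripts per cell (default TRUE).
#' @return List with class `race_experiment`:
#'   \item{dataset}{tube-level data.frame (`cell_id`, `gene`, `tube_index`,
#'     `positive`, `site_calls`, `n_A`, `n_B`), including all-negative rows
#'     for no-cell controls.}
#'   \item{truth}{data.frame keyed by (`cell_id`, `gene`) with `truth_class`
#'     and per-allele captured copy counts (`copies_A`, `copies_B`).}
#'   \item{cells}{data.frame of `cell_id`, `is_control`.}
#'   \item{spec, params, seed}{inputs echoed for provenance.}
#' @examples
#' ex <- simulate_experiment(10, seed = 42)
#' head(ex$dataset)
#' table(ex$truth$truth_class)
#' @export
simulate_experiment <- function(n_cells, spec = cluster_spec("beta"),
                                variants = default_variant_map(spec),
                                params = sim_params(), seed = 1L,
                                include_controls = TRUE) {
  stopifnot(is.numeric(n_cells), n_cells >= 0)
  n_cells <- as.integer(n_cells)
  set.seed(seed)
  per <- params$controls_per_cells
  n_controls <- n_cells %/% per
  n_slots <- n_cells + n_controls
  slot_ids <- if (n_slots) paste0("1-", seq_len(n_slots)) else character(0)
  is_control <- (seq_len(n_slots) %% (per + 1L)) == 0L
  # guard against rounding: keep exactly n_controls control slots
  is_control[cumsum(is_control) > n_controls] <- FALSE

  datasets <- list()
  truths <- list()
  ids <- spec$isoform_ids
  for (s in seq_len(n_slots)) {
    id <- slot_ids[s]
    if (is_control[s]) next  # no cell, no template, no products
    tr <- simulate_cell_truth(spec, params, variants, cell_id = id)
    if (include_controls) {
      ctrl <- simulate_control_molecules(params)
      if (nrow(ctrl)) tr$molecules <- rbind(tr$molecules, ctrl)
    }
    datasets[[id]] <- split_and_amplify(tr, variants, params)
    cm <- tr$molecules[tr$molecules$gene %in% ids, , drop = FALSE]
    copies_A <- tabulate(factor(cm$gene[cm$allele == "A"], levels = ids),
                         nbins = length(ids))
    copies_B <- tabulate(factor(cm$gene[cm$allele == "B"], levels = ids),
                         nbins = length(ids))
    truths[[id]] <- data.frame(
      cell_id = id, gene = ids, truth_class = unname(tr$truth_class[ids]),
      copies_A = copies_A, copies_B = copies_B, stringsAsFactors = FALSE
    )
  }
  empty_ds <- data.frame(cell_id = character(), gene = character(),
                         tube_index = integer(), positive = integer(),
                         site_calls = character(), n_A = integer(),
                         n_B = integer(), stringsAsFactors = FALSE)
  dataset <- if (length(datasets)) do.call(rbind, c(datasets, list(empty_ds)))
             else empty_ds
  rownames(dataset) <- NULL
  truth <- if (length(truths)) do.call(rbind, truths)
           else data.frame(cell_id = character(), gene = character(),
                           truth_class = character(), copies_A = integer(),
                           copies_B = integer(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(
    list(dataset = dataset, truth = truth,
         cells = data.frame(cell_id = slot_ids, is_control = is_control,
                            stringsAsFactors = FALSE),
         spec = spec, params = params, seed = seed),
    class = "race_experiment"
  )
}

#' @export
print.race_experiment <- function(x, ...) {
  cat("race_experiment: ", sum(!x$cells$is_control), " cells + ",
      sum(x$cells$is_control), " no-cell controls, seed ", x$seed, "\n",
      "  dataset: ", nrow(x$dataset), " tube rows over ",
      length(unique(x$dataset$cell_id)), " samples\n", sep = "")
  invisible(x)
}
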