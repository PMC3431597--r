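# End-to-end pipeline: simulate -> call alleles -> QC -> statistics, with
# every intermediate written as TSV and the seed/parameters logged.

pipeline_log <- function(...) message("[splitrace] ", ...)

#' Summary statistics for a called split 3'-RACE dataset
#'
#' Applies the QC gate, restricts to QC-passed cells, and computes the
#' headline statistics: monoallelic fraction among fully consistent products,
#' chi-square against the single-molecule artifact null, parental-allele
#' balance, and the repertoire estimate extrapolated from the assayed panel
#' to the whole cluster.
#'
#' @param calls Product-level data.frame from [call_alleles()].
#' @param cell_ids All sample identifiers (including no-cell controls).
#' @param n_tubes Number of split tubes.
#' @param assayed_genes Genes in the assayed panel; defaults to all non-control
#'   genes present.
#' @param n_total_genes Cluster size the repertoire is extrapolated to
#'   (default 22).
#' @param alleles Parental strain names.
#' @return Named list: `qc` (per-cell gate table), `n_cells_passed`,
#'   `monoallelic`, `artifact_null`, `chi_square`, `allele_balance`,
#'   `rate_per_panel`, `repertoire_per_cell`.
#' @examples
#' ex <- simulate_experiment(20, seed = 5)
#' calls <- call_alleles(ex$dataset, default_variant_map())
#' summarize_calls(calls, cell_ids = ex$cells$cell_id)
#' @export
summarize_calls <- function(calls, cell_ids = NULL, n_tubes = 3L,
                            assayed_genes = NULL, n_total_genes = 22L,
                            alleles = c("B6", "JF1")) {
  qc <- qc_gate(calls, cell_ids = cell_ids, n_tubes = n_tubes)
  passed <- qc$cell_id[qc$passed]
  kept <- calls[calls$cell_id %in% passed, , drop = FALSE]
  if (is.null(assayed_genes)) {
    assayed_genes <- setdiff(unique(calls$gene), c("Pcp2", "actin"))
  }
  kept <- kept[kept$gene %in% assayed_genes, , drop = FALSE]
  full <- paste0(n_tubes, "/", n_tubes)
  mono <- aggregate_monoallelic_fraction(kept, pattern_filter = full)
  null <- artifact_null_probability(n_tubes)
  chi <- if (mono$n_monoallelic + mono$n_biallelic > 0L) {
    chi_square_monoallelic(mono$n_monoallelic, mono$n_biallelic, null)
  } else NULL
  bal <- allele_balance(kept, alleles = alleles)
  n_products_full <- sum(kept$pattern == full)
  rate <- if (length(passed)) {
    genes_per_cell(n_products_full, length(passed))
  } else NA_real_
  rep_cell <- if (!is.na(rate)) {
    extrapolate_repertoire(rate, length(assayed_genes), n_total_genes)
  } else NA_real_
  list(qc = qc, n_cells_passed = length(passed), monoallelic = mono,
       artifact_null = null, chi_square = chi, allele_balance = bal,
       rate_per_panel = rate, repertoire_per_cell = rep_cell)
}

#' Run the full simulate-call-summarise pipeline
#'
#' Chains [simulate_experiment()], [call_alleles()] and [summarize_calls()],
#' writing every intermediate (dataset, truth, calls, summary) as TSV into
#' `out_dir`.  Any stage failure aborts with a stage-tagged message.
#'
#' @param config Named list (or path to a `key: value` config file) with
#'   optional entries `n_cells`, `seed` and any [sim_params()] argument.
#' @param out_dir Output directory, created if needed; `NULL` skips writing.
#' @return List with `experiment`, `calls`, `summary`, `files`.
#' @examples
#' res <- run_pipeline(list(n_cells = 10, seed = 2))
#' res$summary$monoallelic$fraction
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  params <- stage("config", params_from_config(config))
  n_cells <- if (!is.null(config$n_cells)) as.integer(config$n_cells) else 28L
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  pipeline_log("simulate: ", n_cells, " cells, seed ", seed)
  spec <- cluster_spec("beta")
  variants <- default_variant_map(spec)
  ex <- stage("simulate",
              simulate_experiment(n_cells, spec, variants, params, seed))
  pipeline_log("call: ", nrow(ex$dataset), " tube rows")
  calls <- stage("call", call_alleles(ex$dataset, variants))
  pipeline_log("stats: ", nrow(calls), " products")
  summ <- stage("stats", summarize_calls(calls, cell_ids = ex$cells$cell_id,
                                         n_tubes = params$n_tubes))
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      dataset = write_dataset(ex$dataset, file.path(out_dir, "dataset.tsv"),
                              seed = seed, params = params),
      truth = write_tsv_table(ex$truth, file.path(out_dir, "truth.tsv")),
      calls = write_tsv_table(calls, file.path(out_dir, "calls.tsv")),
      summary = write_tsv_table(summary_to_table(summ),
                                file.path(out_dir, "summary.tsv"))
    )
    pipeline_log("wrote ", length(files), " tables to ", out_dir)
  }
  list(experiment = ex, calls = calls, summary = summ, files = files)
}

# flatten the summary list into a two-column key/value table for TSV output
summary_to_table <- function(summ) {
  kv <- c(
    n_cells_passed = summ$n_cells_passed,
    n_monoallelic = summ$monoallelic$n_monoallelic,
    n_biallelic = summ$monoallelic$n_biallelic,
    n_inconsistent = summ$monoallelic$n_inconsistent,
    n_insufficient = summ$monoallelic$n_insufficient,
    monoallelic_fraction = summ$monoallelic$fraction,
    monoallelic_percent = summ$monoallelic$percent,
    artifact_null = summ$artifact_null,
    chi_square_statistic = if (is.null(summ$chi_square)) NA else
      summ$chi_square$statistic,
    chi_square_p = if (is.null(summ$chi_square)) NA else
      summ$chi_square$p_value,
    n_allele_A = summ$allele_balance$n_allele_A,
    n_allele_B = summ$allele_balance$n_allele_B,
    allele_balance_p = summ$allele_balance$p_value,
    rate_per_panel = summ$rate_per_panel,
    repertoire_per_cell = summ$repertoire_per_cell
  )
  data.frame(key = names(kv), value = unname(unlist(kv)),
             stringsAsFactors = FALSE)
}
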