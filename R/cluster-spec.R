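#' Isoform cluster specification
#'
#' Describes one clustered gene family: its name and the identities of its
#' variable isoforms.  The mouse clustered protocadherins are the motivating
#' case: 12 variable Pcdh-alpha isoforms, 22 single-exon Pcdh-beta genes and
#' 19 variable Pcdh-gamma isoforms.  Calling `cluster_spec("beta")` (or
#' `"alpha"`/`"gamma"`) fills in those defaults; arbitrary families can be
#' described by passing `n_isoforms` and/or `isoform_ids` explicitly.
#'
#' @param cluster_name Family label; `"alpha"`, `"beta"` and `"gamma"` carry
#'   default isoform counts (12, 22, 19).
#' @param n_isoforms Number of variable isoforms (positive integer).
#' @param isoform_ids Character vector of unique isoform labels; defaults to
#'   the first letter of the cluster name followed by 1..n (e.g. "b1".."b22").
#' @return An object of class `cluster_spec`: a list with elements
#'   `cluster_name`, `n_isoforms`, `isoform_ids`.
#' @examples
#' beta <- cluster_spec("beta")
#' beta$n_isoforms            # 22
#' cluster_spec("alpha")$isoform_ids[1:3]
#' @export
cluster_spec <- function(cluster_name = c("beta", "alpha", "gamma"),
                         n_isoforms = NULL, isoform_ids = NULL) {
  if (length(cluster_name) != 1L || !is.character(cluster_name)) {
    cluster_name <- match.arg(cluster_name)
  }
  defaults <- c(alpha = 12L, beta = 22L, gamma = 19L)
  if (is.null(n_isoforms)) {
    if (!is.null(isoform_ids)) {
      n_isoforms <- length(isoform_ids)
    } else if (cluster_name %in% names(defaults)) {
      n_isoforms <- defaults[[cluster_name]]
    } else {
      stop("n_isoforms must be given for cluster '", cluster_name, "'")
    }
  }
  n_isoforms <- as.integer(n_isoforms)
  if (is.na(n_isoforms) || n_isoforms < 1L) {
    stop("n_isoforms must be a positive integer")
  }
  if (is.null(isoform_ids)) {
    isoform_ids <- paste0(substr(cluster_name, 1L, 1L), seq_len(n_isoforms))
  }
  isoform_ids <- as.character(isoform_ids)
  if (length(isoform_ids) != n_isoforms) {
    stop("length(isoform_ids) must equal n_isoforms")
  }
  if (anyDuplicated(isoform_ids)) {
    stop("isoform_ids must be unique")
  }
  structure(
    list(cluster_name = cluster_name, n_isoforms = n_isoforms,
         isoform_ids = isoform_ids),
    class = "cluster_spec"
  )
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat("cluster_spec: Pcdh-", x$cluster_name, " (", x$n_isoforms,
      " isoforms: ", x$isoform_ids[1L], "..",
      x$isoform_ids[x$n_isoforms], ")\n", sep = "")
  invisible(x)
}

#' Strain variant map
#'
#' Holds, per gene, the polymorphic sites that distinguish the two parental
#' alleles (e.g. laboratory strain B6 versus wild-derived JF1 in an F1 hybrid)
#' and the gene's polyadenylation sites with usage weights.  Allele calling is
#' impossible for a gene without at least one variant site, so such genes are
#' rejected at construction.
#'
#' @param variant_sites data.frame with columns `gene`, `position` (1-based on
#'   the gene's 3' region), `base_A`, `base_B` (single bases, unequal per row).
#' @param polya_sites data.frame with columns `gene`, `position` (1-based
#'   cleavage position), `weight` (usage probability; normalised per gene).
#' @param alleles Length-2 character vector naming the parental strains
#'   (default `c("B6", "JF1")`; the first is allele A).
#' @return An object of class `strain_variant_map`.
#' @seealso [default_variant_map()] for a ready-made synthetic map.
#' @examples
#' vm <- strain_variant_map(
#'   data.frame(gene = "b1", position = 2400, base_A = "A", base_B = "G"),
#'   data.frame(gene = "b1", position = 2500, weight = 1)
#' )
#' variant_sites(vm, "b1")
#' @export
strain_variant_map <- function(variant_sites, polya_sites,
                               alleles = c("B6", "JF1")) {
  stopifnot(is.data.frame(variant_sites), is.data.frame(polya_sites),
            length(alleles) == 2L, alleles[1L] != alleles[2L])
  need_v <- c("gene", "position", "base_A", "base_B")
  if (!all(need_v %in% names(variant_sites))) {
    stop("variant_sites needs columns: ", paste(need_v, collapse = ", "))
  }
  need_p <- c("gene", "position", "weight")
  if (!all(need_p %in% names(polya_sites))) {
    stop("polya_sites needs columns: ", paste(need_p, collapse = ", "))
  }
  variant_sites$gene <- as.character(variant_sites$gene)
  variant_sites$base_A <- toupper(as.character(variant_sites$base_A))
  variant_sites$base_B <- toupper(as.character(variant_sites$base_B))
  if (any(variant_sites$base_A == variant_sites$base_B)) {
    stop("alleles must differ at every variant site")
  }
  polya_sites$gene <- as.character(polya_sites$gene)
  if (any(polya_sites$weight < 0) || nrow(polya_sites) == 0L) {
    stop("polyA usage weights must be non-negative and non-empty")
  }
  # normalise usage weights within each gene
  tot <- tapply(polya_sites$weight, polya_sites$gene, sum)
  if (any(tot <= 0)) stop("polyA usage weights must sum to > 0 per gene")
  polya_sites$weight <- polya_sites$weight / tot[polya_sites$gene]
  genes <- unique(polya_sites$gene)
  missing_var <- setdiff(genes, unique(variant_sites$gene))
  if (length(missing_var)) {
    stop("gene(s) without variant sites cannot be allele-called: ",
         paste(missing_var, collapse = ", "))
  }
  structure(
    list(variant_sites = variant_sites, polya_sites = polya_sites,
         alleles = as.character(alleles)),
    class = "strain_variant_map"
  )
}

#' @export
print.strain_variant_map <- function(x, ...) {
  cat("strain_variant_map: ", length(unique(x$variant_sites$gene)),
      " genes, alleles ", x$alleles[1L], "/", x$alleles[2L], "\n", sep = "")
  invisible(x)
}

#' Variant sites for one gene
#'
#' @param map A [strain_variant_map()].
#' @param gene Gene label.
#' @return data.frame of the gene's variant sites (possibly 0 rows).
#' @export
variant_sites <- function(map, gene) {
  stopifnot(inherits(map, "strain_variant_map"))
  map$variant_sites[map$variant_sites$gene == gene, , drop = FALSE]
}

#' polyA sites for one gene
#'
#' @inheritParams variant_sites
#' @return data.frame of the gene's cleavage positions and usage weights.
#' @export
polya_sites <- function(map, gene) {
  stopifnot(inherits(map, "strain_variant_map"))
  map$polya_sites[map$polya_sites$gene == gene, , drop = FALSE]
}

#' Default synthetic strain variant map for a cluster
#'
#' Builds a deterministic variant/polyA map covering every isoform of `spec`
#' plus the two control transcripts (`Pcp2`, `actin`).  Each gene carries two
#' strain-discriminating substitutions near its 3' end and three
#' polyadenylation sites: a major site, a minor site 4 nt away (same signal,
#' different cleavage nucleotide) and a rarer distal site driven by a second
#' signal, mirroring the within-cell 3'-terminus heterogeneity seen in real
#' Purkinje cells.
#'
#' @param spec A [cluster_spec()].
#' @param alleles Parental strain names, first = allele A.
#' @param controls Control transcript labels always appended.
#' @return A [strain_variant_map()].
#' @export
default_variant_map <- function(spec = cluster_spec("beta"),
                                alleles = c("B6", "JF1"),
                                controls = c("Pcp2", "actin")) {
  stopifnot(inherits(spec, "cluster_spec"))
  genes <- c(spec$isoform_ids, controls)
  bases <- c("A", "C", "G", "T")
  i <- seq_along(genes)
  b1 <- bases[(i - 1L) %% 4L + 1L]
  b2 <- bases[i %% 4L + 1L]           # offset by one => always != b1
  vs <- data.frame(
    gene = rep(genes, each = 2L),
    position = rep(c(2350L, 2420L), times = length(genes)),
    base_A = as.vector(rbind(b1, b2)),
    base_B = as.vector(rbind(b2, b1)),
    stringsAsFactors = FALSE
  )
  ps <- data.frame(
    gene = rep(genes, each = 3L),
    position = rep(c(2480L, 2484L, 2550L), times = length(genes)),
    weight = rep(c(0.6, 0.25, 0.15), times = length(genes)),
    stringsAsFactors = FALSE
  )
  strain_variant_map(vs, ps, alleles = alleles)
}

#' Simulation parameters for the split 3'-RACE generator
#'
#' @param n_tubes Number of PCR tubes the cell's cDNA is split into
#'   (default 3, matching equal 3.3-ul aliquots of a 10-ul RT reaction).
#' @param expression_prob Probability `q` that a given allele expresses a given
#'   isoform (default 0.052, calibrated so a diploid cell expresses on average
#'   `22 * (1 - (1 - q)^2) ~ 2.2` distinct beta-cluster genes).
#' @param copies_mean Mean `mu` of the zero-truncated Poisson number of
#'   captured cDNA molecules per expressed (allele, isoform) pair (default 3).
#' @param amp_prob Per-tube amplification success probability `a` given at
#'   least one template molecule in the tube (default 0.95).
#' @param het_min_frac Minimum minor-allele template fraction `h` for a
#'   heterozygous base call in direct sequencing (default 0.20, a conventional
#'   Sanger minor-peak sensitivity bound).
#' @param control_copies_mean Mean captured copies per allele for the abundant
#'   control transcripts Pcp2 and beta-actin (default 50).
#' @param controls_per_cells One no-cell negative control is interleaved per
#'   this many cells in [simulate_experiment()] (default 7, i.e. every eighth
#'   tube position is a no-cell control).
#' @return An object of class `sim_params`.
#' @examples
#' sim_params()                      # assay defaults
#' sim_params(copies_mean = 30, amp_prob = 1)   # high-capture regime
#' @export
sim_params <- function(n_tubes = 3L, expression_prob = 0.052,
                       copies_mean = 3, amp_prob = 0.95,
                       het_min_frac = 0.20, control_copies_mean = 50,
                       controls_per_cells = 7L) {
  n_tubes <- as.integer(n_tubes)
  if (is.na(n_tubes) || n_tubes < 1L) stop("n_tubes must be >= 1")
  if (!is.numeric(expression_prob) || expression_prob < 0 ||
      expression_prob > 1) {
    stop("expression_prob must lie in [0, 1]")
  }
  if (!is.numeric(copies_mean) || copies_mean <= 0) {
    stop("copies_mean must be > 0")
  }
  if (!is.numeric(amp_prob) || amp_prob <= 0 || amp_prob > 1) {
    stop("amp_prob must lie in (0, 1]")
  }
  if (!is.numeric(het_min_frac) || het_min_frac < 0 || het_min_frac > 0.5) {
    stop("het_min_frac must lie in [0, 0.5]")
  }
  if (!is.numeric(control_copies_mean) || control_copies_mean <= 0) {
    stop("control_copies_mean must be > 0")
  }
  controls_per_cells <- as.integer(controls_per_cells)
  if (is.na(controls_per_cells) || controls_per_cells < 1L) {
    stop("controls_per_cells must be >= 1")
  }
  structure(
    list(n_tubes = n_tubes, expression_prob = expression_prob,
         copies_mean = copies_mean, amp_prob = amp_prob,
         het_min_frac = het_min_frac,
         control_copies_mean = control_copies_mean,
         controls_per_cells = controls_per_cells),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("sim_params: ", x$n_tubes, " tubes, q=", x$expression_prob,
      ", mu=", x$copies_mean, ", a=", x$amp_prob, ", h=", x$het_min_frac,
      "\n", sep = "")
  invisible(x)
}
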