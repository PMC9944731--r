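#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort: group sizes, gene/CpG layout,
#' sequencing-depth model, background methylation, planted differential
#' methylation, the protein-protein interaction (PPI) graph, pathway sets and
#' the planted methylation-hemodynamics correlations. The defaults emulate a
#' small discovery cohort of 7 cases vs 7 controls profiled at ~30x mean
#' coverage over a promoter-focused CpG panel (220 genes x 10 CpGs; 20 planted
#' differentially methylated genes, i.e. 200 planted sites over 2000 null
#' sites, with a planted group difference of 40 percentage points).
#'
#' @param n_cases,n_controls Number of case / control samples (>= 1).
#' @param n_genes Number of genes placed on the synthetic chromosome.
#' @param n_cpg_per_gene CpG sites simulated per gene promoter.
#' @param genome_length Chromosome length in bp; must be large enough to
#'   place `n_genes` non-overlapping genes.
#' @param mean_coverage Negative-binomial mean read depth per site per sample.
#' @param coverage_dispersion Negative-binomial size parameter; smaller values
#'   give more overdispersed (RRBS-like) coverage. The default (20) keeps
#'   coverage almost always above a 10x analysis filter at 30x mean.
#' @param baseline_beta_params Length-2 positive vector: Beta distribution of
#'   the background per-site methylation proportion, shared across samples.
#'   The default Beta(2, 4) reflects the predominantly low-to-intermediate
#'   methylation of promoter CpGs and leaves room for the planted shift, so
#'   clipping at the proportion boundaries stays negligible.
#' @param planted_fraction Fraction of genes carrying a planted methylation
#'   shift in cases (all promoter CpGs of a planted gene shift together).
#' @param planted_delta Target |Delta M| of planted sites, percentage points
#'   in (0, 100]; case-group proportions are clipped to [0.01, 0.99].
#' @param ppi_attachment Preferential-attachment parameter m of the
#'   Barabasi-Albert PPI graph (each new node attaches m edges).
#' @param n_pathways,pathway_size_range Number and size range of synthetic
#'   pathway gene sets; early pathways are seeded with planted genes so
#'   overrepresentation analysis has signal.
#' @param cgi_promoter_fraction Fraction of gene promoters overlapped by a
#'   CpG island.
#' @param hemo_effect_r Planted population correlation (in [-1, 1]) between
#'   promoter methylation score and the linked hemodynamic variable.
#' @param n_hub_planted Number of planted genes wired into the disease
#'   catalog as guaranteed network hubs.
#' @param hub_wiring Number of (>= 2 publication) disease-catalog genes each
#'   designated hub gene is wired to; must be >= the downstream hub threshold
#'   for the planted hubs to be recoverable.
#' @param platform_b_site_fraction Fraction of CpG sites also measured on the
#'   second (array-like) platform.
#' @param platform_b_noise Gaussian noise sd added to second-platform beta
#'   values (0 gives noise-free betas).
#' @param expression_fc Planted fold change of target-gene expression in
#'   cases for the synthetic qPCR table.
#' @param seed Master integer seed; one RNG stream per output family is
#'   derived from it, so identical configs give bit-identical outputs.
#'
#' @return An object of class `methnet_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 20, n_cpg_per_gene = 4, genome_length = 4e5)
#' cfg$n_cases
#' @export
sim_config <- function(n_cases = 7, n_controls = 7,
                       n_genes = 220, n_cpg_per_gene = 10,
                       genome_length = 3e6,
                       mean_coverage = 30, coverage_dispersion = 20,
                       baseline_beta_params = c(2, 4),
                       planted_fraction = 0.091, planted_delta = 40,
                       ppi_attachment = 2,
                       n_pathways = 25, pathway_size_range = c(10, 40),
                       cgi_promoter_fraction = 0.6,
                       hemo_effect_r = 0.7,
                       n_hub_planted = 3, hub_wiring = 12,
                       platform_b_site_fraction = 0.7,
                       platform_b_noise = 0.05,
                       expression_fc = 2,
                       seed = 1L) {
  stopifnot_scalar_number(n_cases, "n_cases", min = 1)
  stopifnot_scalar_number(n_controls, "n_controls", min = 1)
  stopifnot_scalar_number(n_genes, "n_genes", min = 0)
  stopifnot_scalar_number(n_cpg_per_gene, "n_cpg_per_gene", min = 1)
  stopifnot_scalar_number(genome_length, "genome_length", min = 1)
  stopifnot_scalar_number(mean_coverage, "mean_coverage", min = 1)
  stopifnot_scalar_number(coverage_dispersion, "coverage_dispersion",
                          min = .Machine$double.eps)
  if (length(baseline_beta_params) != 2L || any(baseline_beta_params <= 0))
    stop("baseline_beta_params must be two positive reals")
  stopifnot_scalar_number(planted_fraction, "planted_fraction", 0, 1)
  stopifnot_scalar_number(planted_delta, "planted_delta", min = 1e-9, max = 100)
  stopifnot_scalar_number(ppi_attachment, "ppi_attachment", min = 1)
  stopifnot_scalar_number(n_pathways, "n_pathways", min = 0)
  if (length(pathway_size_range) != 2L || pathway_size_range[1] > pathway_size_range[2])
    stop("pathway_size_range must be an ordered integer pair")
  stopifnot_scalar_number(cgi_promoter_fraction, "cgi_promoter_fraction", 0, 1)
  if (abs(hemo_effect_r) > 1)
    stop("|hemo_effect_r| must be <= 1 (got ", hemo_effect_r, ")")
  stopifnot_scalar_number(platform_b_site_fraction, "platform_b_site_fraction", 0, 1)
  stopifnot_scalar_number(platform_b_noise, "platform_b_noise", min = 0)
  stopifnot_scalar_number(expression_fc, "expression_fc", min = 1e-9)
  stopifnot_scalar_number(seed, "seed")

  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), n_cpg_per_gene = as.integer(n_cpg_per_gene),
    genome_length = as.integer(genome_length),
    mean_coverage = mean_coverage, coverage_dispersion = coverage_dispersion,
    baseline_beta_params = as.numeric(baseline_beta_params),
    planted_fraction = planted_fraction, planted_delta = planted_delta,
    ppi_attachment = as.integer(ppi_attachment),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    cgi_promoter_fraction = cgi_promoter_fraction,
    hemo_effect_r = hemo_effect_r,
    n_hub_planted = as.integer(n_hub_planted),
    hub_wiring = as.integer(hub_wiring),
    platform_b_site_fraction = platform_b_site_fraction,
    platform_b_noise = platform_b_noise,
    expression_fc = expression_fc,
    seed = as.integer(seed)
  )
  class(cfg) <- "methnet_config"
  cfg
}

#' @export
print.methnet_config <- function(x, ...) {
  cat("methnet synthetic study configuration\n")
  cat(sprintf("  cohort: %d cases vs %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  panel:  %d genes x %d CpGs, genome %d bp\n",
              x$n_genes, x$n_cpg_per_gene, x$genome_length))
  cat(sprintf("  depth:  NegBin(mean=%g, size=%g)\n",
              x$mean_coverage, x$coverage_dispersion))
  cat(sprintf("  planted: %.1f%% of genes at |DeltaM|=%g pp; hemo r=%g; seed=%d\n",
              100 * x$planted_fraction, x$planted_delta, x$hemo_effect_r, x$seed))
  invisible(x)
}
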