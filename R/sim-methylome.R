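#' Simulate per-sample CpG count tables with planted differential methylation
#'
#' Draws a background methylation proportion for every CpG from a Beta
#' distribution (shared across samples), places each gene's CpGs inside its
#' promoter (TSS +- 1 kb), and simulates per-sample coverage from a negative
#' binomial and methylated read counts from a binomial. A `planted_fraction`
#' share of genes receives a constant case-group shift of
#' `planted_delta`/100 on the proportion scale at every promoter CpG,
#' clipped to [0.01, 0.99]; the shift direction per gene is whichever of
#' hyper-/hypomethylation loses less of the planted effect to clipping over
#' the gene's sites (ties go to hyper), so the planted |Delta M| survives
#' clipping almost everywhere.
#' Clipped sites are counted in the ground truth (`n_clipped`), not dropped.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param config The same [sim_config()] used for the annotation.
#' @return A list of class `methnet_methylome`:
#'   \describe{
#'     \item{samples}{named list of per-sample data.frames
#'       (chrom, pos, strand, n_meth, n_total), Bismark-coverage-like.}
#'     \item{groups}{named character vector, `"case"`/`"control"` per sample.}
#'     \item{sites}{data.frame of all simulated sites with gene_id and the
#'       true background proportion.}
#'     \item{ground_truth}{list: `planted_dmcpg` (site-level truth with
#'       direction), `planted_genes` (gene-level truth), `n_clipped`.}
#'   }
#' @examples
#' cfg <- sim_config(n_genes = 10, n_cpg_per_gene = 3, genome_length = 2e5)
#' meth <- simulate_methylome(simulate_annotation(cfg), cfg)
#' head(meth$samples[[1]])
#' @export
simulate_methylome <- function(annotation, config) {
  stopifnot(inherits(annotation, "methnet_annotation"),
            inherits(config, "methnet_config"))
  genes <- annotation$genes
  n_genes <- nrow(genes)
  k <- config$n_cpg_per_gene
  sample_ids <- c(sprintf("PAH_%02d", seq_len(config$n_cases)),
                  sprintf("CTRL_%02d", seq_len(config$n_controls)))
  groups <- stats::setNames(
    rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sample_ids)

  empty_truth <- list(
    planted_dmcpg = data.frame(site_id = character(), chrom = character(),
                               pos = integer(), strand = character(),
                               gene_id = character(), direction = character(),
                               stringsAsFactors = FALSE),
    planted_genes = data.frame(gene_id = character(), direction = character(),
                               stringsAsFactors = FALSE),
    n_clipped = 0L)

  if (n_genes == 0L) {
    empty_tab <- data.frame(chrom = character(), pos = integer(),
                            strand = character(), n_meth = integer(),
                            n_total = integer(), stringsAsFactors = FALSE)
    out <- list(samples = stats::setNames(rep(list(empty_tab), length(sample_ids)),
                                          sample_ids),
                groups = groups,
                sites = data.frame(site_id = character(), gene_id = character(),
                                   pi0 = numeric(), stringsAsFactors = FALSE),
                ground_truth = empty_truth)
    class(out) <- "methnet_methylome"
    return(out)
  }

  with_seed(stream_seed(config$seed, "methylome"), {
    # CpG positions: k draws without replacement inside each promoter window
    pos_list <- lapply(seq_len(n_genes), function(i) {
      win <- (genes$tss[i] - 1000L):(genes$tss[i] + 1000L)
      sort(sample(win, k))
    })
    sites <- data.frame(
      chrom = rep(genes$chrom, each = k),
      pos = as.integer(unlist(pos_list)),
      strand = "+",
      gene_id = rep(genes$gene_id, each = k),
      stringsAsFactors = FALSE)
    sites$site_id <- site_key(sites$chrom, sites$pos, sites$strand)
    n_sites <- nrow(sites)

    pi0 <- stats::rbeta(n_sites, config$baseline_beta_params[1],
                        config$baseline_beta_params[2])

    n_planted_genes <- round(config$planted_fraction * n_genes)
    planted_gene_ids <- character()
    direction_by_gene <- character()
    pi_case <- pi0
    n_clipped <- 0L
    if (n_planted_genes > 0) {
      planted_gene_ids <- sort(sample(genes$gene_id, n_planted_genes))
      delta <- config$planted_delta / 100
      for (g in planted_gene_ids) {
        idx <- which(sites$gene_id == g)
        loss_hyper <- sum(pmax(pi0[idx] + delta - 0.99, 0))
        loss_hypo <- sum(pmax(0.01 - (pi0[idx] - delta), 0))
        dir_g <- if (loss_hyper <= loss_hypo) "hyper" else "hypo"
        direction_by_gene[g] <- dir_g
        shifted <- pi0[idx] + if (dir_g == "hyper") delta else -delta
        n_clipped <- n_clipped + sum(shifted < 0.01 | shifted > 0.99)
        pi_case[idx] <- pmin(0.99, pmax(0.01, shifted))
      }
    }

    planted_idx <- sites$gene_id %in% planted_gene_ids
    truth <- list(
      planted_dmcpg = data.frame(
        site_id = sites$site_id[planted_idx],
        chrom = sites$chrom[planted_idx],
        pos = sites$pos[planted_idx],
        strand = sites$strand[planted_idx],
        gene_id = sites$gene_id[planted_idx],
        direction = unname(direction_by_gene[sites$gene_id[planted_idx]]),
        stringsAsFactors = FALSE),
      planted_genes = data.frame(
        gene_id = planted_gene_ids,
        direction = unname(direction_by_gene[planted_gene_ids]),
        stringsAsFactors = FALSE),
      n_clipped = n_clipped)
    if (n_clipped > 0)
      message("simulate_methylome: ", n_clipped,
              " planted site(s) clipped to [0.01, 0.99]")

    samples <- lapply(sample_ids, function(s) {
      p <- if (groups[[s]] == "case") pi_case else pi0
      cov <- pmax(1L, stats::rnbinom(n_sites, mu = config$mean_coverage,
                                     size = config$coverage_dispersion))
      m <- stats::rbinom(n_sites, cov, p)
      data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
                 n_meth = as.integer(m), n_total = as.integer(cov),
                 stringsAsFactors = FALSE)
    })
    names(samples) <- sample_ids

    out <- list(samples = samples, groups = groups,
                sites = data.frame(site_id = sites$site_id,
                                   chrom = sites$chrom, pos = sites$pos,
                                   strand = sites$strand,
                                   gene_id = sites$gene_id, pi0 = pi0,
                                   pi_case = pi_case,
                                   stringsAsFactors = FALSE),
                ground_truth = truth)
    class(out) <- "methnet_methylome"
    out
  })
}
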