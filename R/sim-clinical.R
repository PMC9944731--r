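#' Simulate the patient table, qPCR Ct table and second-platform beta matrix
#'
#' Builds one clinical record per methylome sample. Case patients satisfy the
#' right-heart-catheterization diagnostic thresholds (mPAP >= 25 mmHg,
#' PVR >= 240 dyn.s.cm-5); controls are drawn below them. Two planted genes
#' (designated network hubs when available) are linked to hemodynamics: right
#' atrial pressure (RAP) is generated as a decreasing and cardiac index (CI)
#' as an increasing linear function of the patient's promoter methylation
#' score, with Gaussian noise calibrated so the population correlation is
#' `-hemo_effect_r` and `+hemo_effect_r` respectively. The Ct table encodes a
#' planted `expression_fc`-fold upregulation of up to five planted genes
#' against an `RPS18` reference, in duplicate. The platform-B matrix reports
#' per-site beta values (the true group proportion plus Gaussian noise,
#' clipped to [0, 1]) for a random subset of sites.
#'
#' @param methylome A [simulate_methylome()] result (same config/seed).
#' @param annotation The matching [simulate_annotation()] result.
#' @param ground_truth Ground truth from the methylome (with
#'   `planted_hub_genes` if the network stage already ran).
#' @param config The shared [sim_config()].
#' @return List with `patients` (data.frame), `ct` (long data.frame
#'   sample/gene/replicate/ct), `beta` (sites x samples matrix),
#'   `hemo_linked_genes` (data.frame gene_id/variable/target_r).
#' @export
simulate_clinical <- function(methylome, annotation, ground_truth, config) {
  stopifnot(inherits(methylome, "methnet_methylome"),
            inherits(config, "methnet_config"))
  if (abs(config$hemo_effect_r) > 1)
    stop("|hemo_effect_r| must be <= 1")
  groups <- methylome$groups
  ids <- names(groups)
  case_ids <- ids[groups == "case"]
  ctrl_ids <- ids[groups == "control"]
  nc <- length(case_ids); nk <- length(ctrl_ids)

  planted <- ground_truth$planted_genes$gene_id
  hubs <- ground_truth$planted_hub_genes %||% character()
  link_pool <- c(hubs, setdiff(planted, hubs))

  with_seed(stream_seed(config$seed, "clinical"), {
    n_ipah <- ceiling(0.6 * nc)
    patients <- data.frame(
      patient_id = c(case_ids, ctrl_ids),
      subgroup = c(rep("IPAH", n_ipah), rep("Associated-PAH", nc - n_ipah),
                   rep("CTRL", nk)),
      age = round(c(stats::rnorm(nc, 52, 12), stats::rnorm(nk, 42, 10))),
      mPAP = c(stats::runif(nc, 25, 85), stats::runif(nk, 10, 20)),
      PVR = c(stats::runif(nc, 240, 1500), stats::runif(nk, 50, 200)),
      RAP = c(stats::runif(nc, 2, 18), stats::runif(nk, 1, 7)),
      CI = c(stats::runif(nc, 1.6, 4.2), stats::runif(nk, 2.6, 4.5)),
      NYHA = c(sample(c("I", "II", "III", "IV"), nc, replace = TRUE,
                      prob = c(0.15, 0.35, 0.35, 0.15)),
               rep("I", nk)),
      six_mwd = round(c(stats::runif(nc, 120, 600), stats::runif(nk, 450, 700))),
      stringsAsFactors = FALSE)
    patients$age <- pmin(85, pmax(18, patients$age))

    # Plant methylation-score -> hemodynamics correlations in cases.
    links <- data.frame(gene_id = character(), variable = character(),
                        target_r = numeric(), stringsAsFactors = FALSE)
    if (length(link_pool) >= 1 && config$hemo_effect_r != 0) {
      link_vars <- c("RAP", "CI")
      link_sign <- c(-1, 1)
      scale_mean <- c(RAP = 9, CI = 2.6)
      scale_sd <- c(RAP = 2.5, CI = 0.45)
      n_links <- min(2L, length(link_pool))
      for (j in seq_len(n_links)) {
        g <- link_pool[j]
        r <- link_sign[j] * config$hemo_effect_r
        sc <- planted_promoter_score(methylome, g, case_ids)
        if (stats::sd(sc) == 0) {
          warning("degenerate methylation score for ", g,
                  "; hemodynamic link skipped")
          next
        }
        z <- as.numeric(scale(sc))
        y <- r * z + sqrt(1 - r^2) * stats::rnorm(nc)
        v <- link_vars[j]
        patients[[v]][seq_len(nc)] <- scale_mean[[v]] + scale_sd[[v]] * y
        links <- rbind(links, data.frame(gene_id = g, variable = v,
                                         target_r = r, stringsAsFactors = FALSE))
      }
    }
    patients$CI <- pmax(0.8, patients$CI)
    patients$RAP <- pmax(0.5, patients$RAP)

    # qPCR Ct table: reference RPS18 plus up to five planted targets,
    # upregulated in cases by expression_fc (delta-Ct shift of log2 FC).
    targets <- utils::head(link_pool, 5L)
    ct <- NULL
    if (length(targets) > 0) {
      base_dct <- stats::setNames(stats::runif(length(targets), -8, -2), targets)
      rows <- list()
      for (s in ids) {
        ct_ref <- stats::rnorm(1, 18, 0.4)
        for (rep_i in 1:2)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, gene = "RPS18", replicate = rep_i,
            ct = ct_ref + stats::rnorm(1, 0, 0.1), stringsAsFactors = FALSE)
        for (g in targets) {
          dct <- base_dct[[g]] +
            (if (groups[[s]] == "case") log2(config$expression_fc) else 0) +
            stats::rnorm(1, 0, 0.25)
          for (rep_i in 1:2)
            rows[[length(rows) + 1L]] <- data.frame(
              sample = s, gene = g, replicate = rep_i,
              ct = ct_ref - dct + stats::rnorm(1, 0, 0.1),
              stringsAsFactors = FALSE)
        }
      }
      ct <- do.call(rbind, rows)
    }

    # Platform-B beta values on a random site subset.
    sites <- methylome$sites
    n_b <- round(config$platform_b_site_fraction * nrow(sites))
    beta <- NULL
    if (n_b > 0) {
      b_idx <- sort(sample.int(nrow(sites), n_b))
      truth_p <- cbind(matrix(rep(sites$pi_case[b_idx], nc), ncol = nc),
                       matrix(rep(sites$pi0[b_idx], nk), ncol = nk))
      noise <- matrix(stats::rnorm(n_b * (nc + nk), 0, config$platform_b_noise),
                      nrow = n_b)
      beta <- pmin(pmax(truth_p + noise, 0), 1)
      dimnames(beta) <- list(sites$site_id[b_idx], c(case_ids, ctrl_ids))
    }

    list(patients = patients, ct = ct, beta = beta, hemo_linked_genes = links)
  })
}

# Coverage-pooled promoter methylation score (%) per sample for one gene,
# computed directly from the simulated count tables.
planted_promoter_score <- function(methylome, gene, sample_ids) {
  idx <- which(methylome$sites$gene_id == gene)
  vapply(sample_ids, function(s) {
    tab <- methylome$samples[[s]]
    100 * sum(tab$n_meth[idx]) / sum(tab$n_total[idx])
  }, numeric(1))
}

#' Generate a complete synthetic study
#'
#' Runs all four generator stages under one master seed and returns every
#' pipeline input plus the planted ground truth. Identical configs give
#' bit-identical studies (one RNG stream per output family).
#'
#' @param config A [sim_config()].
#' @return List of class `methnet_study`: `config`, `annotation`, `methylome`,
#'   `network` (ppi/catalog/pathways), `clinical`, `ground_truth` (with
#'   `planted_hub_genes` and `hemo_linked_genes` merged in).
#' @examples
#' st <- simulate_study(sim_config(n_genes = 30, n_cpg_per_gene = 4,
#'                                 genome_length = 5e5, n_pathways = 5))
#' names(st)
#' @export
simulate_study <- function(config) {
  ann <- simulate_annotation(config)
  meth <- simulate_methylome(ann, config)
  truth <- meth$ground_truth
  net <- simulate_ppi_and_catalogs(ann, truth, config)
  truth$planted_hub_genes <- net$planted_hub_genes
  clin <- simulate_clinical(meth, ann, truth, config)
  truth$hemo_linked_genes <- clin$hemo_linked_genes
  out <- list(config = config, annotation = ann, methylome = meth,
              network = net[c("ppi", "catalog", "pathways")],
              clinical = clin, ground_truth = truth)
  class(out) <- "methnet_study"
  out
}
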