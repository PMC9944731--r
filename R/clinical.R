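#' Per-sample promoter methylation score for a gene
#'
#' The coverage-weighted mean methylation percentage over the gene's
#' promoter dmCpGs, per sample (weights = per-site coverage, i.e. the pooled
#' methylated/total ratio over those sites).
#'
#' @param gene Gene id.
#' @param annotated Annotated dmCpG table ([annotate_dmcpgs()]); the gene
#'   must have at least one promoter dmCpG.
#' @param united A [filter_and_unite()] result holding the count matrices.
#' @return Named numeric vector, percent methylation per sample.
#' @export
promoter_score <- function(gene, annotated, united) {
  sel <- !is.na(annotated$gene_id) & annotated$gene_id == gene &
    annotated$feature == "promoter"
  if (!any(sel)) stop("gene ", gene, " has no promoter dmCpG")
  keys <- site_key(annotated$chrom[sel], annotated$pos[sel],
                   annotated$strand[sel])
  ukeys <- site_key(united$sites$chrom, united$sites$pos, united$sites$strand)
  idx <- match(keys, ukeys)
  if (anyNA(idx)) stop("promoter dmCpGs of ", gene,
                       " missing from the united count matrix")
  100 * colSums(united$meth[idx, , drop = FALSE]) /
    colSums(united$total[idx, , drop = FALSE])
}

#' Correlate promoter methylation scores with hemodynamic parameters
#'
#' For every gene and hemodynamic variable (mPAP, PVR, RAP, CI by default),
#' tests normality of both variables with Shapiro-Wilk and uses Pearson
#' correlation when both pass (p > 0.05), Spearman otherwise. Correlations
#' with |r| >= 0.6 are flagged strong; significance is declared at
#' p <= 0.05. Zero-variance inputs give a degenerate-flagged row rather
#' than a silent NaN.
#'
#' @param scores Gene x patient matrix (or data.frame) of promoter scores;
#'   columns named by patient id.
#' @param patients Patient data.frame with patient_id, subgroup and the
#'   hemodynamic columns.
#' @param subgroup Subgroup(s) to correlate within (e.g. `"IPAH"`, or
#'   `c("IPAH", "Associated-PAH")` for all cases); needs at least 3 patients.
#' @param variables Hemodynamic variables to test.
#' @return data.frame: gene_id, variable, method, r, abs_r, p_value,
#'   strong_flag, significant, degenerate, n.
#' @export
correlate_hemodynamics <- function(scores, patients, subgroup,
                                   variables = c("mPAP", "PVR", "RAP", "CI")) {
  ids <- patients$patient_id[patients$subgroup %in% subgroup]
  ids <- intersect(ids, colnames(scores))
  if (length(ids) < 3)
    stop("need >= 3 patients in subgroup ", paste(subgroup, collapse = "/"))
  pats <- patients[match(ids, patients$patient_id), , drop = FALSE]

  rows <- list()
  for (g in rownames(scores)) {
    x <- as.numeric(scores[g, ids])
    for (v in variables) {
      y <- pats[[v]]
      degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
      if (degenerate) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, variable = v, method = NA_character_, r = NA_real_,
          abs_r = NA_real_, p_value = NA_real_, strong_flag = NA,
          significant = NA, degenerate = TRUE, n = length(ids),
          stringsAsFactors = FALSE)
        next
      }
      norm_ok <- stats::shapiro.test(x)$p.value > 0.05 &&
        stats::shapiro.test(y)$p.value > 0.05
      method <- if (norm_ok) "pearson" else "spearman"
      ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                             exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, variable = v, method = method,
        r = unname(ct$estimate), abs_r = abs(unname(ct$estimate)),
        p_value = ct$p.value,
        strong_flag = abs(ct$estimate) >= 0.6,
        significant = ct$p.value <= 0.05, degenerate = FALSE,
        n = length(ids), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Site-by-group mean methylation matrix
#'
#' Coverage-weighted mean methylation percentage of each site within each
#' pre-classified sample group (the heatmap input). Rows follow the site
#' order of the united matrix restricted to `sites`; columns follow the
#' order of first appearance in `group_labels` sorted alphabetically.
#'
#' @param sites data.frame of sites (chrom/pos/strand), e.g. annotated
#'   dmCpGs.
#' @param united A [filter_and_unite()] result.
#' @param group_labels Named character vector: sample id -> group label.
#' @return Numeric matrix, sites x groups, percent methylation.
#' @export
group_mean_matrix <- function(sites, united, group_labels) {
  samples <- colnames(united$meth)
  if (!all(samples %in% names(group_labels)))
    stop("every sample needs a group label")
  labs <- group_labels[samples]
  groups <- sort(unique(labs))
  if (any(table(factor(labs, levels = groups)) == 0))
    stop("group with zero samples")
  keys <- site_key(sites$chrom, sites$pos, sites$strand)
  ukeys <- site_key(united$sites$chrom, united$sites$pos, united$sites$strand)
  idx <- match(keys, ukeys)
  if (anyNA(idx)) stop("site(s) missing from the united matrix")
  out <- sapply(groups, function(gr) {
    cols <- samples[labs == gr]
    100 * rowSums(united$meth[idx, cols, drop = FALSE]) /
      rowSums(united$total[idx, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = length(idx),
                dimnames = list(keys, groups))
  out
}

#' Simplified four-criterion risk stratification
#'
#' Counts low-risk criteria exactly as the clinical tool defines them:
#' NYHA/WHO class I-II, six-minute walk distance > 440 m (strict), right
#' atrial pressure < 8 mmHg (strict), cardiac index > 2.5 L/min/m2
#' (strict). 3-4 criteria -> low risk, 2 -> intermediate, 0-1 -> high.
#'
#' @param patient A one-row data.frame or list with NYHA, six_mwd, RAP, CI.
#' @return List with `criteria_met` (0-4) and `risk`
#'   (`"low"`/`"intermediate"`/`"high"`).
#' @examples
#' risk_stratify(list(NYHA = "II", six_mwd = 500, RAP = 5, CI = 3.0))
#' @export
risk_stratify <- function(patient) {
  need <- c("NYHA", "six_mwd", "RAP", "CI")
  missing <- need[vapply(need, function(f)
    is.null(patient[[f]]) || is.na(patient[[f]]), logical(1))]
  if (length(missing) > 0)
    stop("missing risk criteria field(s): ", paste(missing, collapse = ", "))
  met <- sum(patient$NYHA %in% c("I", "II"),
             patient$six_mwd > 440,
             patient$RAP < 8,
             patient$CI > 2.5)
  risk <- if (met >= 3) "low" else if (met == 2) "intermediate" else "high"
  list(criteria_met = as.integer(met), risk = risk)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged first. Per sample and target gene,
#' delta Ct = Ct(reference) - Ct(target); delta-delta Ct = mean delta Ct of
#' the control group minus the sample's delta Ct; fold change = 2^(-ddCt),
#' so targets expressed one cycle higher than the control mean get FC = 2.
#' Case-vs-control significance of the per-sample fold changes is assessed
#' with [compare_groups()].
#'
#' @param ct Long data.frame: sample, gene, replicate, ct.
#' @param groups Named character vector, sample -> `"case"`/`"control"`.
#' @param reference_gene Housekeeping gene id measured in every sample.
#' @param control_group Label of the reference group (default `"control"`).
#' @return List of class `methnet_expression`: `per_sample` (sample, gene,
#'   delta_ct, delta_delta_ct, fold_change, group) and `per_gene` (gene,
#'   mean_fc_case, mean_fc_control, test, p_value).
#' @export
fold_change <- function(ct, groups, reference_gene,
                        control_group = "control") {
  agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  targets <- setdiff(unique(agg$gene), reference_gene)
  all_samples <- unique(agg$sample)
  if (!all(all_samples %in% ref$sample))
    stop("reference gene ", reference_gene, " missing for sample(s): ",
         paste(setdiff(all_samples, ref$sample), collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample)

  per_sample <- do.call(rbind, lapply(targets, function(g) {
    d <- agg[agg$gene == g, , drop = FALSE]
    dct <- ref_ct[d$sample] - d$ct
    ctrl_mean <- mean(dct[groups[d$sample] == control_group])
    ddct <- ctrl_mean - dct
    data.frame(sample = d$sample, gene = g, delta_ct = unname(dct),
               delta_delta_ct = unname(ddct),
               fold_change = 2^(-unname(ddct)),
               group = unname(groups[d$sample]), stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL

  per_gene <- do.call(rbind, lapply(targets, function(g) {
    d <- per_sample[per_sample$gene == g, , drop = FALSE]
    fc_case <- d$fold_change[d$group != control_group]
    fc_ctrl <- d$fold_change[d$group == control_group]
    cmp <- tryCatch(compare_groups(fc_case, fc_ctrl),
                    error = function(e) list(test = NA_character_,
                                             p_value = NA_real_))
    data.frame(gene = g, mean_fc_case = mean(fc_case),
               mean_fc_control = mean(fc_ctrl), test = cmp$test,
               p_value = cmp$p_value, stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  out <- list(per_sample = per_sample, per_gene = per_gene)
  class(out) <- "methnet_expression"
  out
}

#' Assumption-guided two-group comparison
#'
#' Shapiro-Wilk normality on each group and an F test of variance
#' homogeneity decide the test: pooled two-tailed t-test when both groups
#' are normal with homogeneous variances, Welch t-test when normal with
#' unequal variances, otherwise the two-sided Wilcoxon rank sum test (exact
#' for n <= 50 per group without ties, normal approximation with tie
#' correction otherwise). `force` overrides the decision.
#'
#' @param x,y Numeric vectors, at least 3 values each.
#' @param alpha Assumption-test level (default 0.05).
#' @param force Optional: `"wilcoxon"`, `"t"` or `"welch"` to skip the
#'   decision rule.
#' @return List: `test` (name), `p_value`.
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(5, 6, 7, 9), force = "wilcoxon")
#' @export
compare_groups <- function(x, y, alpha = 0.05, force = NULL) {
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations per group")
  choice <- force
  if (is.null(choice)) {
    normal <- !anyNA(c(tryCatch(stats::shapiro.test(x)$p.value,
                                error = function(e) NA),
                       tryCatch(stats::shapiro.test(y)$p.value,
                                error = function(e) NA))) &&
      stats::shapiro.test(x)$p.value > alpha &&
      stats::shapiro.test(y)$p.value > alpha
    if (normal) {
      var_hom <- stats::var.test(x, y)$p.value > alpha
      choice <- if (var_hom) "t" else "welch"
    } else choice <- "wilcoxon"
  }
  if (choice == "t") {
    p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    list(test = "t", p_value = p)
  } else if (choice == "welch") {
    p <- stats::t.test(x, y, var.equal = FALSE)$p.value
    list(test = "welch", p_value = p)
  } else {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && length(x) <= 50 && length(y) <= 50
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
    list(test = if (exact) "wilcoxon-exact" else "wilcoxon-approx",
         p_value = p)
  }
}

#' Classic quantile normalization of a beta-value matrix
#'
#' Every column is mapped onto the empirical distribution of the row-wise
#' means of the column-sorted values, preserving within-column ranks; ties
#' receive the average of the values they span. Thin wrapper over
#' `limma::normalizeQuantiles` with input validation.
#'
#' @param x Numeric matrix, columns = samples.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (any(colSums(!is.na(x)) == 0)) stop("all-missing column in beta matrix")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Cross-platform direction concordance per gene
#'
#' For every gene with dmCpGs measured on both platforms, the percentage of
#' overlapping CpGs whose platform-B case-minus-control beta difference has
#' the same sign as the RRBS direction (hyper = positive). A delta of
#' exactly zero counts as non-confirming (strict sign match). Genes with no
#' overlapping CpG are reported as not evaluable (NA).
#'
#' @param annotated Annotated dmCpG calls (site_id or chrom/pos/strand,
#'   gene_id, direction).
#' @param beta Platform-B beta matrix, rownames = site ids
#'   (`chrom:pos:strand`).
#' @param groups Named character vector, sample -> `"case"`/`"control"`,
#'   covering the beta columns.
#' @return data.frame: gene_id, n_overlap, n_confirmed, pct_confirmed
#'   (NA when not evaluable).
#' @export
concordance <- function(annotated, beta, groups) {
  if (is.null(beta) || nrow(beta) == 0) stop("empty platform-B site map")
  keys <- if ("site_id" %in% names(annotated)) annotated$site_id
          else site_key(annotated$chrom, annotated$pos, annotated$strand)
  case_cols <- colnames(beta)[groups[colnames(beta)] == "case"]
  ctrl_cols <- colnames(beta)[groups[colnames(beta)] == "control"]
  delta_b <- rowMeans(beta[, case_cols, drop = FALSE]) -
    rowMeans(beta[, ctrl_cols, drop = FALSE])

  genes <- sort(unique(annotated$gene_id[!is.na(annotated$gene_id)]))
  out <- do.call(rbind, lapply(genes, function(g) {
    sel <- which(!is.na(annotated$gene_id) & annotated$gene_id == g)
    k <- keys[sel]
    hit <- k %in% rownames(beta)
    n_ov <- sum(hit)
    if (n_ov == 0)
      return(data.frame(gene_id = g, n_overlap = 0L, n_confirmed = 0L,
                        pct_confirmed = NA_real_, stringsAsFactors = FALSE))
    db <- delta_b[k[hit]]
    dir_sign <- ifelse(annotated$direction[sel][hit] == "hyper", 1, -1)
    conf <- sum(sign(db) == dir_sign & db != 0)
    data.frame(gene_id = g, n_overlap = n_ov, n_confirmed = as.integer(conf),
               pct_confirmed = 100 * conf / n_ov, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene linear regression of methylation score on age
#'
#' Ordinary least squares of each gene's promoter methylation score on
#' patient age; the slope p-value comes from the standard t statistic.
#' Flags whether age significantly predicts the score (confounding check).
#'
#' @param scores Gene x patient matrix of promoter scores.
#' @param patients Patient data.frame with patient_id and age; at least 4
#'   subjects with age, which must not be constant.
#' @return data.frame: gene_id, slope, p_value, significant.
#' @export
age_confound_check <- function(scores, patients) {
  ids <- intersect(colnames(scores), patients$patient_id)
  age <- patients$age[match(ids, patients$patient_id)]
  ok <- !is.na(age)
  ids <- ids[ok]; age <- age[ok]
  if (length(ids) < 4) stop("need >= 4 subjects with age")
  if (stats::sd(age) == 0) stop("age is constant; regression undefined")
  out <- do.call(rbind, lapply(rownames(scores), function(g) {
    fit <- stats::lm(as.numeric(scores[g, ids]) ~ age)
    co <- summary(fit)$coefficients
    data.frame(gene_id = g, slope = co["age", "Estimate"],
               p_value = co["age", "Pr(>|t|)"],
               significant = co["age", "Pr(>|t|)"] <= 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
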