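#' Unite per-sample count tables over well-covered CpGs
#'
#' Keeps only sites observed in every sample, with coverage of at least
#' `min_coverage` in every sample and no higher than each sample's
#' `max_coverage_percentile` quantile (PCR-duplicate guard; 100 disables the
#' upper cut).
#'
#' @param tables Named list of per-sample count data.frames
#'   (chrom, pos, strand, n_meth, n_total), e.g. from [read_coverage()] or a
#'   [simulate_methylome()] result's `samples`.
#' @param groups Named character vector mapping sample id to
#'   `"case"`/`"control"`; at least one sample per group.
#' @param min_coverage Minimum per-sample read depth (default 10).
#' @param max_coverage_percentile Upper coverage percentile cut
#'   (default 99.9).
#' @return List of class `methnet_united`: `sites` (chrom/pos/strand),
#'   `meth` and `total` (site x sample integer matrices), `groups`.
#' @export
filter_and_unite <- function(tables, groups, min_coverage = 10,
                             max_coverage_percentile = 99.9) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  groups <- groups[names(tables)]
  if (any(is.na(groups))) stop("every sample needs a group label")
  if (length(unique(groups)) < 2)
    stop("need at least one sample in each of two groups")

  keys <- lapply(tables, function(t) site_key(t$chrom, t$pos, t$strand))
  common <- Reduce(intersect, keys)
  if (length(common) == 0) stop("no CpG site is present in all samples")

  meth <- total <- matrix(0L, nrow = length(common), ncol = length(tables),
                          dimnames = list(common, names(tables)))
  for (s in names(tables)) {
    idx <- match(common, keys[[s]])
    meth[, s] <- tables[[s]]$n_meth[idx]
    total[, s] <- tables[[s]]$n_total[idx]
  }
  keep <- rep(TRUE, length(common))
  for (s in names(tables)) {
    keep <- keep & total[, s] >= min_coverage
    if (max_coverage_percentile < 100) {
      hi <- stats::quantile(tables[[s]]$n_total,
                            max_coverage_percentile / 100, names = FALSE)
      keep <- keep & total[, s] <= hi
    }
  }
  if (!any(keep))
    stop("no CpG site survives the coverage filters (min_coverage = ",
         min_coverage, ", upper percentile = ", max_coverage_percentile, ")")

  first <- tables[[1]]
  idx1 <- match(common[keep], keys[[1]])
  out <- list(
    sites = data.frame(chrom = first$chrom[idx1], pos = first$pos[idx1],
                       strand = first$strand[idx1], stringsAsFactors = FALSE),
    meth = meth[keep, , drop = FALSE],
    total = total[keep, , drop = FALSE],
    groups = groups)
  class(out) <- "methnet_united"
  out
}

#' Median-based coverage normalization
#'
#' Scales every sample's coverage so that all samples share the largest
#' per-sample median depth: sample s is multiplied by
#' max(medians) / median(s). Totals are rounded to integers and methylated
#' counts re-derived from the original per-site proportion, so each site's
#' proportion moves by at most 0.5/new_total.
#'
#' @param united A [filter_and_unite()] result.
#' @return The united object with rescaled `meth`/`total` and attribute
#'   `scale_factors`.
#' @export
normalize_coverage <- function(united) {
  stopifnot(inherits(united, "methnet_united"))
  med <- apply(united$total, 2, stats::median)
  if (any(med == 0)) stop("sample with zero median coverage: ",
                          paste(colnames(united$total)[med == 0], collapse = ", "))
  f <- max(med) / med
  prop <- united$meth / united$total
  new_total <- round(sweep(united$total, 2, f, `*`))
  new_meth <- round(new_total * prop)
  storage.mode(new_total) <- "integer"
  storage.mode(new_meth) <- "integer"
  united$meth <- pmin(new_meth, new_total)
  united$total <- new_total
  attr(united, "scale_factors") <- f
  united
}

#' Per-site binomial likelihood-ratio test of group differential methylation
#'
#' For each site, the methylation difference Delta M is 100 times the
#' difference of coverage-pooled group proportions (case minus control), and
#' the p-value comes from a likelihood-ratio test of a binomial regression of
#' per-sample counts on the group indicator against the intercept-only model
#' (chi-square, 1 df). With a single binary covariate the alternative MLE is
#' the pooled per-group proportion and the null MLE the overall pooled
#' proportion, so the deviance difference has closed form; the closed form is
#' checked against an independent `glm` fit in the test suite.
#'
#' Sites with zero total reads in either group are skipped with a message and
#' returned with NA statistics.
#'
#' @param united A (possibly normalized) [filter_and_unite()] result.
#' @return data.frame: chrom, pos, strand, delta_m (percentage points),
#'   p_value.
#' @export
test_sites <- function(united) {
  stopifnot(inherits(united, "methnet_united"))
  case <- united$groups == "case"
  ctrl <- united$groups == "control"
  M1 <- rowSums(united$meth[, case, drop = FALSE])
  T1 <- rowSums(united$total[, case, drop = FALSE])
  M0 <- rowSums(united$meth[, ctrl, drop = FALSE])
  T0 <- rowSums(united$total[, ctrl, drop = FALSE])

  skip <- T1 == 0 | T0 == 0
  if (any(skip))
    message("test_sites: skipping ", sum(skip), " site(s) with zero group coverage")

  p1 <- M1 / T1
  p0 <- M0 / T0
  pp <- (M1 + M0) / (T1 + T0)
  # 2 * (loglik at group proportions - loglik at pooled proportion);
  # x*log(x) terms with x = 0 contribute 0.
  xlog <- function(x, p) ifelse(x == 0, 0, x * log(p))
  ll <- function(M, T_, p) xlog(M, p) + xlog(T_ - M, 1 - p)
  lrt <- 2 * (ll(M1, T1, p1) + ll(M0, T0, p0) -
              ll(M1, T1, pp) - ll(M0, T0, pp))
  lrt <- pmax(lrt, 0)
  out <- data.frame(
    chrom = united$sites$chrom, pos = united$sites$pos,
    strand = united$sites$strand,
    delta_m = 100 * (p1 - p0),
    p_value = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    stringsAsFactors = FALSE)
  out$delta_m[skip] <- NA_real_
  out$p_value[skip] <- NA_real_
  out
}

#' Adjust p-values and call differentially methylated CpGs
#'
#' Benjamini-Hochberg q-values over all tested sites; a site is called when
#' |Delta M| strictly exceeds `delta_threshold` and q is strictly below
#' `q_threshold`. Calls are sorted by q, then |Delta M| descending, then
#' genomic coordinate.
#'
#' @param results A [test_sites()] data.frame.
#' @param delta_threshold Minimum |Delta M| in percentage points, strict
#'   (default 20).
#' @param q_threshold Maximum q, strict (default 0.05).
#' @return data.frame of calls with columns site_id, chrom, pos, strand,
#'   delta_m, p_value, q_value, direction; attribute
#'   `adjust_method = "BH"` and `n_tested`.
#' @export
adjust_and_call <- function(results, delta_threshold = 20, q_threshold = 0.05) {
  tested <- results[!is.na(results$p_value), , drop = FALSE]
  empty <- data.frame(site_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      delta_m = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (nrow(tested) == 0) {
    attr(empty, "adjust_method") <- "BH"
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  tested$q_value <- stats::p.adjust(tested$p_value, method = "BH")
  hit <- abs(tested$delta_m) > delta_threshold & tested$q_value < q_threshold
  calls <- tested[hit, , drop = FALSE]
  if (nrow(calls) > 0) {
    calls$direction <- ifelse(calls$delta_m > 0, "hyper", "hypo")
    calls$site_id <- site_key(calls$chrom, calls$pos, calls$strand)
    ord <- order(calls$q_value, -abs(calls$delta_m), calls$chrom, calls$pos)
    calls <- calls[ord, c("site_id", "chrom", "pos", "strand", "delta_m",
                          "p_value", "q_value", "direction")]
    rownames(calls) <- NULL
  } else calls <- empty
  attr(calls, "adjust_method") <- "BH"
  attr(calls, "n_tested") <- nrow(tested)
  calls
}

#' Two-group differential methylation pipeline
#'
#' Convenience wrapper: unite, normalize coverage, test every site, adjust and
#' call. Returns all intermediate results.
#'
#' @inheritParams filter_and_unite
#' @inheritParams adjust_and_call
#' @param normalize Apply [normalize_coverage()] (default TRUE).
#' @return List of class `methnet_dm`: `united`, `results` (all tested sites
#'   with q-values), `calls`, `params`.
#' @examples
#' st <- simulate_study(sim_config(n_genes = 40, n_cpg_per_gene = 4,
#'                                 genome_length = 6e5, planted_fraction = 0.2))
#' dm <- diff_methylation(st$methylome$samples, st$methylome$groups)
#' dm
#' @export
diff_methylation <- function(tables, groups, min_coverage = 10,
                             max_coverage_percentile = 99.9,
                             delta_threshold = 20, q_threshold = 0.05,
                             normalize = TRUE) {
  united <- filter_and_unite(tables, groups, min_coverage,
                             max_coverage_percentile)
  if (normalize) united <- normalize_coverage(united)
  results <- test_sites(united)
  results$q_value <- NA_real_
  tested <- !is.na(results$p_value)
  results$q_value[tested] <- stats::p.adjust(results$p_value[tested], "BH")
  calls <- adjust_and_call(results[, c("chrom", "pos", "strand", "delta_m",
                                       "p_value")],
                           delta_threshold, q_threshold)
  out <- list(united = united, results = results, calls = calls,
              params = list(min_coverage = min_coverage,
                            max_coverage_percentile = max_coverage_percentile,
                            delta_threshold = delta_threshold,
                            q_threshold = q_threshold,
                            adjust_method = "BH", normalize = normalize))
  class(out) <- "methnet_dm"
  out
}

#' @export
print.methnet_dm <- function(x, ...) {
  cat("methnet differential methylation\n")
  cat(sprintf("  %d sites tested in %d samples (%d case, %d control)\n",
              nrow(x$results), length(x$united$groups),
              sum(x$united$groups == "case"),
              sum(x$united$groups == "control")))
  nh <- sum(x$calls$direction == "hyper")
  nl <- sum(x$calls$direction == "hypo")
  cat(sprintf("  %d dmCpGs at |DeltaM| > %g & q < %g (%s): %d hyper, %d hypo\n",
              nrow(x$calls), x$params$delta_threshold, x$params$q_threshold,
              x$params$adjust_method, nh, nl))
  invisible(x)
}
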