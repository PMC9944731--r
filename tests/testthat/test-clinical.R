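mk_united_counts <- function(meth, total, samples = NULL) {
  n_sites <- nrow(meth)
  samples <- samples %||% paste0("s", seq_len(ncol(meth)))
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites), strand = "+",
                      stringsAsFactors = FALSE)
  keys <- paste("chr1", seq_len(n_sites), "+", sep = ":")
  dimnames(meth) <- dimnames(total) <- list(keys, samples)
  u <- list(sites = sites, meth = meth, total = total,
            groups = setNames(rep("case", length(samples)), samples))
  class(u) <- "methnet_united"
  u
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_annotated <- function(n_sites, gene = "G1", direction = "hyper") {
  data.frame(chrom = "chr1", pos = seq_len(n_sites), strand = "+",
             direction = rep(direction, length.out = n_sites),
             feature = "promoter", gene_id = gene, stringsAsFactors = FALSE)
}

test_that("promoter score is the coverage-weighted mean percentage", {
  # one site, 8/10 -> 80%
  u <- mk_united_counts(matrix(8, 1, 1), matrix(10, 1, 1))
  expect_equal(unname(promoter_score("G1", mk_annotated(1), u)), 80)
  # two sites 50% and 100% at equal coverage -> 75%
  u2 <- mk_united_counts(matrix(c(5, 10), 2, 1), matrix(c(10, 10), 2, 1))
  expect_equal(unname(promoter_score("G1", mk_annotated(2), u2)), 75)
  # weights follow coverage: (cov 10, 100%) + (cov 30, 0%) -> 25%
  u3 <- mk_united_counts(matrix(c(10, 0), 2, 1), matrix(c(10, 30), 2, 1))
  expect_equal(unname(promoter_score("G1", mk_annotated(2), u3)), 25)
  expect_error(promoter_score("nope", mk_annotated(2), u3), "no promoter dmCpG")
})

test_that("hemodynamic correlations switch method and flag strength", {
  pats <- data.frame(patient_id = paste0("p", 1:8), subgroup = "IPAH",
                     age = 40:47,
                     mPAP = c(30, 45, 50, 38, 60, 41, 47, 52),
                     PVR = c(300, 700, 800, 420, 900, 500, 650, 730),
                     RAP = c(4, 9, 11, 6, 14, 7, 10, 12),
                     CI = c(3.5, 2.4, 2.1, 3.0, 1.8, 2.8, 2.2, 2.0),
                     stringsAsFactors = FALSE)
  # perfect linear relation: r = 1 on mPAP
  sc <- matrix(2 * pats$mPAP + 1, 1, 8,
               dimnames = list("G1", pats$patient_id))
  res <- correlate_hemodynamics(sc, pats, "IPAH", variables = "mPAP")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_true(res$strong_flag)
  # hand-computed Pearson on x=(1,2,3), y=(1,3,2): r = 0.5
  pats3 <- pats[1:3, ]
  pats3$mPAP <- c(1, 3, 2)
  sc3 <- matrix(c(1, 2, 3), 1, 3, dimnames = list("G1", pats3$patient_id))
  res3 <- correlate_hemodynamics(sc3, pats3, "IPAH", variables = "mPAP")
  expect_equal(res3$r, 0.5, tolerance = 1e-12)
  # constant variable -> degenerate flag, not NaN
  pats$RAP <- 7
  resd <- correlate_hemodynamics(sc, pats, "IPAH", variables = "RAP")
  expect_true(resd$degenerate)
  expect_true(is.na(resd$r))
  expect_error(correlate_hemodynamics(sc, pats[1:2, ], "IPAH"), ">= 3")
})

test_that("group mean matrix averages with coverage weights per group", {
  meth <- matrix(c(2, 8, 4, 4, 0, 10), 2, 3) # 2 sites x 3 samples
  total <- matrix(c(10, 10, 10, 10, 10, 10), 2, 3)
  u <- mk_united_counts(meth, total, samples = c("a", "b", "c"))
  labs <- c(a = "CTRL", b = "IPAH", c = "IPAH")
  gm <- group_mean_matrix(u$sites, u, labs)
  expect_equal(dim(gm), c(2L, 2L))
  expect_equal(unname(gm[, "CTRL"]), c(20, 80))
  expect_equal(unname(gm[, "IPAH"]), c(100 * (4 + 0) / 20, 100 * (4 + 10) / 20))
  # unequal coverage weights
  total2 <- matrix(c(10, 10, 10, 10, 30, 10), 2, 3)
  u2 <- mk_united_counts(meth, total2, samples = c("a", "b", "c"))
  gm2 <- group_mean_matrix(u2$sites, u2, labs)
  expect_equal(unname(gm2[1, "IPAH"]), 100 * (4 + 0) / 40)
  expect_error(group_mean_matrix(u$sites, u, c(a = "CTRL", b = "IPAH")),
               "group label")
})

test_that("risk stratification counts the four criteria strictly", {
  expect_equal(risk_stratify(list(NYHA = "II", six_mwd = 500, RAP = 5,
                                  CI = 3.0)),
               list(criteria_met = 4L, risk = "low"))
  # exactly 2 criteria -> intermediate
  expect_equal(risk_stratify(list(NYHA = "III", six_mwd = 500, RAP = 5,
                                  CI = 2.0))$risk, "intermediate")
  # boundaries are strict: 440 m, 8 mmHg, 2.5 L/min/m2 all fail
  r <- risk_stratify(list(NYHA = "III", six_mwd = 440, RAP = 8, CI = 2.5))
  expect_equal(r$criteria_met, 0L)
  expect_equal(r$risk, "high")
  expect_equal(risk_stratify(list(NYHA = "I", six_mwd = 100, RAP = 20,
                                  CI = 1.5))$risk, "high")
  expect_error(risk_stratify(list(NYHA = "II", six_mwd = NA, RAP = 5,
                                  CI = 3)), "six_mwd")
})

test_that("delta-delta-Ct fold changes follow the stated conventions", {
  # controls mean delta Ct = -5; a case at delta Ct = -4 (one cycle more
  # expression) must give FC = 2
  ct <- rbind(
    data.frame(sample = rep(c("c1", "c2", "k1", "k2", "k3"), each = 2),
               gene = "REF", replicate = rep(1:2, 5),
               ct = 20, stringsAsFactors = FALSE),
    data.frame(sample = rep(c("c1", "c2", "k1", "k2", "k3"), each = 2),
               gene = "TG", replicate = rep(1:2, 5),
               ct = rep(c(24, 24, 25, 25, 25), each = 2),
               stringsAsFactors = FALSE))
  groups <- c(c1 = "case", c2 = "case", k1 = "control", k2 = "control",
              k3 = "control")
  fc <- fold_change(ct, groups, "REF")
  ps <- fc$per_sample
  expect_equal(ps$delta_ct[ps$sample == "k1"], -5)
  expect_equal(ps$fold_change[ps$sample == "c1"], 2)
  expect_equal(ps$delta_delta_ct[ps$sample == "c1"], -1)
  # samples at the control mean give FC = 1
  expect_equal(ps$fold_change[ps$sample == "k2"], 1)
  expect_true(all(ps$fold_change > 0))
  # reference == target -> delta Ct 0 everywhere, FC 1
  ct_self <- rbind(ct[ct$gene == "REF", ],
                   transform(ct[ct$gene == "REF", ], gene = "TG2"))
  fc2 <- fold_change(ct_self, groups, "REF")
  expect_true(all(fc2$per_sample$delta_ct == 0))
  expect_true(all(fc2$per_sample$fold_change == 1))
  # adding a constant to every Ct leaves FC unchanged (equivariance)
  ct_shift <- ct
  ct_shift$ct <- ct_shift$ct + 3.7
  fc3 <- fold_change(ct_shift, groups, "REF")
  expect_equal(fc3$per_sample$fold_change, fc$per_sample$fold_change,
               tolerance = 1e-12)
  # missing reference errors
  expect_error(fold_change(ct[ct$gene != "REF" | ct$sample != "c1", ],
                           groups, "REF"), "missing for sample")
})

test_that("group comparison follows the assumption cascade and exact Wilcoxon", {
  # forced Wilcoxon on fully separated triples: exact p = 0.1
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6), force = "wilcoxon")
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$test, "wilcoxon-exact")
  # exact p agrees with enumeration for all small no-tie inputs
  set.seed(3)
  for (trial in 1:20) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    v <- sample(seq_len(40), n1 + n2)
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    cmp <- compare_groups(x, y, force = "wilcoxon")
    expect_equal(cmp$p_value, wilcox_enum(x, y), tolerance = 1e-12)
  }
  # identical groups: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3),
                              force = "wilcoxon")$p_value, 1)
  expect_equal(compare_groups(rnorm(5) + 100, rnorm(5) + 100,
                              force = "t")$p_value >= 0, TRUE)
  # clear shift at n = 10: significant
  set.seed(4)
  x <- rnorm(10); y <- rnorm(10) + 5
  expect_lt(compare_groups(x, y)$p_value, 0.05)
  # normal data with equal variances -> pooled t
  set.seed(6)
  expect_equal(compare_groups(rnorm(20), rnorm(20))$test, "t")
  # gross variance inequality on normal data -> Welch
  set.seed(8)
  expect_equal(compare_groups(rnorm(30, sd = 1), rnorm(30, sd = 12))$test,
               "welch")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("quantile normalization matches the 2x2 hand computation", {
  x <- matrix(c(5, 1, 2, 4), 2, 2)
  qn <- quantile_normalize(x)
  expect_equal(qn, matrix(c(4.5, 1.5, 1.5, 4.5), 2, 2))
  # identical columns unchanged
  y <- matrix(c(3, 7, 9, 3, 7, 9), 3, 2)
  expect_equal(quantile_normalize(y), y)
  # idempotence
  set.seed(9)
  z <- matrix(runif(40), 10, 4)
  expect_equal(quantile_normalize(quantile_normalize(z)),
               quantile_normalize(z), tolerance = 1e-12)
  bad <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(quantile_normalize(bad), "all-missing")
})

test_that("concordance counts strict sign agreement per gene", {
  ann <- data.frame(chrom = "chr1", pos = 1:5, strand = "+",
                    gene_id = c("A", "A", "A", "A", "B"),
                    direction = c(rep("hyper", 4), "hypo"),
                    stringsAsFactors = FALSE)
  keys <- paste("chr1", 1:5, "+", sep = ":")
  beta <- matrix(0.5, 5, 4, dimnames = list(keys, c("c1", "c2", "k1", "k2")))
  groups <- c(c1 = "case", c2 = "case", k1 = "control", k2 = "control")
  # gene A: 3 of 4 overlapping sites confirm hyper; one goes the other way
  beta[1:3, c("c1", "c2")] <- 0.8
  beta[4, c("c1", "c2")] <- 0.2
  # gene B: delta exactly zero -> non-confirming
  conc <- concordance(ann, beta, groups)
  expect_equal(conc$pct_confirmed[conc$gene_id == "A"], 75)
  expect_equal(conc$pct_confirmed[conc$gene_id == "B"], 0)
  # zero overlap -> not evaluable
  conc2 <- concordance(ann, beta[1:4, , drop = FALSE], groups)
  expect_true(is.na(conc2$pct_confirmed[conc2$gene_id == "B"]))
  expect_error(concordance(ann, beta[0, , drop = FALSE], groups), "empty")
})

test_that("age regression recovers exact dependence and stays calibrated", {
  pats <- data.frame(patient_id = paste0("p", 1:12), age = c(30:40, 55),
                     stringsAsFactors = FALSE)
  sc <- matrix(pats$age, 1, 12, dimnames = list("G1", pats$patient_id))
  # perfect fit: lm's summary warns about unreliability, which is the point
  res <- suppressWarnings(age_confound_check(sc, pats))
  expect_equal(res$slope, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-12)
  # null calibration: ~5% significant over many independent genes
  set.seed(12)
  scn <- matrix(rnorm(400 * 12), 400, 12,
                dimnames = list(paste0("g", 1:400), pats$patient_id))
  resn <- age_confound_check(scn, pats)
  expect_lt(abs(mean(resn$significant) - 0.05), 0.035)
  # two distinct ages, n = 4: valid fit
  p4 <- data.frame(patient_id = paste0("q", 1:4), age = c(30, 30, 50, 50))
  s4 <- matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("G1", p4$patient_id))
  expect_silent(age_confound_check(s4, p4))
  expect_error(age_confound_check(s4, transform(p4, age = 40)), "constant")
})
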