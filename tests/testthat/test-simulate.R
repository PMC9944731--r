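test_that("annotation respects strand convention, empty case and packing limits", {
  cfg <- sim_config(n_genes = 2, genome_length = 40000, seed = 7)
  ann <- simulate_annotation(cfg)
  g <- ann$genes
  expect_equal(nrow(g), 2)
  expect_true(all(ifelse(g$strand == "+", g$tss == g$start, g$tss == g$end)))
  # non-overlap
  expect_true(g$start[2] > g$end[1])

  empty <- simulate_annotation(sim_config(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$cgi), 0)

  expect_error(simulate_annotation(sim_config(n_genes = 100,
                                              genome_length = 10000)),
               "genome_length too small")
})

test_that("generator is deterministic and streams are independent", {
  cfg <- sim_config(n_genes = 25, n_cpg_per_gene = 3, genome_length = 4e5,
                    planted_fraction = 0.2, n_pathways = 5, seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$methylome$samples, s2$methylome$samples)
  expect_identical(s1$network, s2$network)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$ground_truth, s2$ground_truth)

  # different master seed changes outputs
  s3 <- simulate_study(sim_config(n_genes = 25, n_cpg_per_gene = 3,
                                  genome_length = 4e5, planted_fraction = 0.2,
                                  n_pathways = 5, seed = 12))
  expect_false(identical(s1$methylome$samples, s3$methylome$samples))
})

test_that("methylome counts conserve coverage and record planted truth", {
  cfg <- sim_config(n_genes = 30, n_cpg_per_gene = 4, genome_length = 5e5,
                    planted_fraction = 0.2, seed = 3)
  meth <- simulate_methylome(simulate_annotation(cfg), cfg)
  for (tab in meth$samples) {
    expect_true(all(tab$n_meth >= 0 & tab$n_meth <= tab$n_total))
    expect_true(all(tab$n_total >= 1))
  }
  truth <- meth$ground_truth
  expect_equal(nrow(truth$planted_genes), round(0.2 * 30))
  # every planted site maps to exactly one gene and exists in every sample
  expect_false(any(duplicated(truth$planted_dmcpg$site_id)))
  all_keys <- paste(meth$samples[[1]]$chrom, meth$samples[[1]]$pos,
                    meth$samples[[1]]$strand, sep = ":")
  expect_true(all(truth$planted_dmcpg$site_id %in% all_keys))
})

test_that("planted_fraction = 0 gives no truth and near-zero group deltas", {
  cfg <- sim_config(n_genes = 50, n_cpg_per_gene = 4, genome_length = 8e5,
                    planted_fraction = 0, seed = 5)
  meth <- simulate_methylome(simulate_annotation(cfg), cfg)
  expect_equal(nrow(meth$ground_truth$planted_dmcpg), 0)
  case <- names(meth$groups)[meth$groups == "case"]
  ctrl <- names(meth$groups)[meth$groups == "control"]
  prop <- function(ids) {
    m <- rowSums(sapply(ids, function(s) meth$samples[[s]]$n_meth))
    t <- rowSums(sapply(ids, function(s) meth$samples[[s]]$n_total))
    m / t
  }
  deltas <- 100 * (prop(case) - prop(ctrl))
  expect_lt(abs(mean(deltas)), 2)
})

test_that("planted sites show the configured group difference on average", {
  # Monte-Carlo check of the generative model: pooled case-control DeltaM at
  # planted sites should average the planted 40 pp within +-3.
  cfg <- sim_config(seed = 17) # defaults: 200 planted sites, delta 40
  meth <- simulate_methylome(simulate_annotation(cfg), cfg)
  truth <- meth$ground_truth
  expect_gte(nrow(truth$planted_dmcpg), 200)
  keys <- paste(meth$samples[[1]]$chrom, meth$samples[[1]]$pos,
                meth$samples[[1]]$strand, sep = ":")
  idx <- match(truth$planted_dmcpg$site_id, keys)
  case <- names(meth$groups)[meth$groups == "case"]
  ctrl <- names(meth$groups)[meth$groups == "control"]
  pool <- function(ids) {
    m <- rowSums(sapply(ids, function(s) meth$samples[[s]]$n_meth[idx]))
    t <- rowSums(sapply(ids, function(s) meth$samples[[s]]$n_total[idx]))
    m / t
  }
  dm <- 100 * (pool(case) - pool(ctrl))
  signed <- ifelse(truth$planted_dmcpg$direction == "hyper", dm, -dm)
  expect_lt(abs(mean(signed) - 40), 3)
})

test_that("preferential-attachment graph has the closed-form edge count", {
  cfg <- sim_config(n_genes = 10, n_cpg_per_gene = 2, genome_length = 2e5,
                    planted_fraction = 0, ppi_attachment = 2, n_pathways = 0,
                    seed = 2)
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylome(ann, cfg)
  net <- simulate_ppi_and_catalogs(ann, meth$ground_truth, cfg)
  # started from m isolated nodes: m * (n - m) edges
  expect_equal(nrow(net$ppi), 2 * (10 - 2))
  expect_false(any(net$ppi$geneA == net$ppi$geneB))
  key <- paste(pmin(net$ppi$geneA, net$ppi$geneB),
               pmax(net$ppi$geneA, net$ppi$geneB))
  expect_false(any(duplicated(key)))
  # scale-free-ish: max degree at least the average degree
  deg <- table(c(net$ppi$geneA, net$ppi$geneB))
  expect_gte(max(deg), mean(deg))
})

test_that("catalog exercises the publication filter and hub wiring is planted", {
  cfg <- sim_config(n_genes = 60, n_cpg_per_gene = 2, genome_length = 1e6,
                    planted_fraction = 0.15, seed = 9)
  ann <- simulate_annotation(cfg)
  meth <- simulate_methylome(ann, cfg)
  net <- simulate_ppi_and_catalogs(ann, meth$ground_truth, cfg)
  expect_true(any(net$catalog$n_publications == 1))
  expect_true(all(net$catalog$n_publications >= 1))
  expect_length(net$planted_hub_genes, 3)
  strong <- filter_disease_catalog(net$catalog)
  for (h in net$planted_hub_genes) {
    nb <- unique(c(net$ppi$geneB[net$ppi$geneA == h],
                   net$ppi$geneA[net$ppi$geneB == h]))
    expect_gte(sum(nb %in% strong$gene), 10)
  }
})

test_that("all-singleton catalog empties under the >=2-publication filter", {
  cat1 <- data.frame(gene = c("a", "b"), n_publications = c(1L, 1L))
  expect_equal(nrow(filter_disease_catalog(cat1)), 0)
})

test_that("clinical tables respect diagnostic ranges and planted links", {
  cfg <- sim_config(n_genes = 30, n_cpg_per_gene = 4, genome_length = 5e5,
                    planted_fraction = 0.2, seed = 21)
  st <- simulate_study(cfg)
  pat <- st$clinical$patients
  cases <- pat[pat$subgroup != "CTRL", ]
  ctrls <- pat[pat$subgroup == "CTRL", ]
  expect_true(all(cases$mPAP >= 25))
  expect_true(all(cases$PVR >= 240))
  expect_true(all(ctrls$mPAP < 25))
  expect_equal(nrow(st$ground_truth$hemo_linked_genes), 2)
  expect_true(all(st$ground_truth$hemo_linked_genes$gene_id %in%
                  st$ground_truth$planted_genes$gene_id))
})

test_that("noise-free limits: |r| = 1 links and exact platform-B betas", {
  cfg <- sim_config(n_genes = 20, n_cpg_per_gene = 4, genome_length = 4e5,
                    planted_fraction = 0.3, hemo_effect_r = 1,
                    platform_b_noise = 0, platform_b_site_fraction = 1,
                    seed = 4)
  st <- simulate_study(cfg)
  links <- st$ground_truth$hemo_linked_genes
  pat <- st$clinical$patients
  case_ids <- pat$patient_id[pat$subgroup != "CTRL"]
  for (i in seq_len(nrow(links))) {
    g <- links$gene_id[i]
    idx <- which(st$methylome$sites$gene_id == g)
    sc <- vapply(case_ids, function(s) {
      tab <- st$methylome$samples[[s]]
      100 * sum(tab$n_meth[idx]) / sum(tab$n_total[idx])
    }, numeric(1))
    v <- pat[[links$variable[i]]][match(case_ids, pat$patient_id)]
    expect_equal(unname(cor(sc, v)), links$target_r[i], tolerance = 1e-12)
  }
  # sigma = 0 and full site overlap: concordance 100% for every planted gene
  ann_calls <- st$ground_truth$planted_dmcpg
  conc <- concordance(ann_calls, st$clinical$beta, st$methylome$groups)
  planted <- st$ground_truth$planted_genes$gene_id
  expect_true(all(conc$pct_confirmed[conc$gene_id %in% planted] == 100))
})

test_that("hemo_effect_r = 0 leaves hemodynamics unlinked", {
  # Monte-Carlo: with no planted link the score-variable correlation is
  # centred at 0 (|mean r| small, spread ~ 1/sqrt(n)).
  rs <- sapply(1:30, function(s) {
    cfg <- sim_config(n_genes = 15, n_cpg_per_gene = 3, genome_length = 3e5,
                      planted_fraction = 0.3, hemo_effect_r = 0, seed = s)
    st <- simulate_study(cfg)
    pat <- st$clinical$patients
    case_ids <- pat$patient_id[pat$subgroup != "CTRL"]
    g <- st$ground_truth$planted_genes$gene_id[1]
    idx <- which(st$methylome$sites$gene_id == g)
    sc <- vapply(case_ids, function(smp) {
      tab <- st$methylome$samples[[smp]]
      100 * sum(tab$n_meth[idx]) / sum(tab$n_total[idx])
    }, numeric(1))
    cor(sc, pat$RAP[match(case_ids, pat$patient_id)])
  })
  expect_lt(abs(mean(rs)), 0.3) # ~4 sd of the mean of 30 null correlations
})

test_that("hemo_effect_r outside [-1, 1] is rejected", {
  expect_error(sim_config(hemo_effect_r = 1.2), "hemo_effect_r")
})

test_that("written study round-trips through the readers", {
  cfg <- sim_config(n_genes = 12, n_cpg_per_gene = 3, genome_length = 2e5,
                    planted_fraction = 0.25, n_pathways = 4, seed = 6)
  st <- simulate_study(cfg)
  dir <- tempfile("study")
  write_study(st, dir)
  s1 <- names(st$methylome$samples)[1]
  back <- read_coverage(file.path(dir, paste0(s1, ".cov")))
  expect_equal(back$pos, st$methylome$samples[[s1]]$pos)
  expect_equal(back$n_meth, st$methylome$samples[[s1]]$n_meth)
  expect_equal(back$n_total, st$methylome$samples[[s1]]$n_total)
  cgi <- read_bed(file.path(dir, "cgi.bed"))
  expect_equal(cgi$start, st$annotation$cgi$start)
  expect_equal(cgi$end, st$annotation$cgi$end)
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_identical(gmt, st$network$pathways)
  # byte-identical regeneration under the same seed
  dir2 <- tempfile("study")
  write_study(simulate_study(cfg), dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
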