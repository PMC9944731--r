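#' Assign a genomic feature to each dmCpG
#'
#' Features are chosen by a fixed precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal_intergenic.
#' The promoter is the TSS +- `promoter_flank` window, both ends inclusive
#' (symmetric, so strand only matters for the downstream window). UTR
#' intervals are optional columns (`utr5_start`/`utr5_end`,
#' `utr3_start`/`utr3_end`) of the gene-model table; without them, sites in
#' the gene body fall to exon/intron. Ties among genes at equal precedence go
#' to the nearest TSS, then the lexicographically smaller gene id.
#'
#' @param sites data.frame with chrom and pos (e.g. dmCpG calls).
#' @param gene_models Gene-model data.frame as produced by
#'   [simulate_annotation()] (gene_id, chrom, strand, start, end, tss,
#'   gene_type, exon_starts, exon_ends; optional UTR columns).
#' @param promoter_flank Promoter half-width in bp (default 1000).
#' @param downstream_window Downstream window past the gene end in bp
#'   (default 3000).
#' @return data.frame `sites` with added `feature` and `gene_id` columns
#'   (gene_id is NA for distal_intergenic).
#' @export
classify_feature <- function(sites, gene_models, promoter_flank = 1000,
                             downstream_window = 3000) {
  feats <- c("promoter", "5'UTR", "3'UTR", "exon", "intron", "downstream",
             "distal_intergenic")
  n <- nrow(sites)
  feature <- rep("distal_intergenic", n)
  gene_id <- rep(NA_character_, n)
  gm <- gene_models
  has_utr5 <- all(c("utr5_start", "utr5_end") %in% names(gm))
  has_utr3 <- all(c("utr3_start", "utr3_end") %in% names(gm))

  for (i in seq_len(n)) {
    pos <- sites$pos[i]
    g <- gm[gm$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    best_rank <- 7L
    best_gene <- NA_character_
    best_dist <- Inf
    for (j in seq_len(nrow(g))) {
      rank_j <- 7L
      if (abs(pos - g$tss[j]) <= promoter_flank) {
        rank_j <- 1L
      } else if (pos >= g$start[j] && pos <= g$end[j]) {
        if (has_utr5 && !is.na(g$utr5_start[j]) &&
            pos >= g$utr5_start[j] && pos <= g$utr5_end[j]) {
          rank_j <- 2L
        } else if (has_utr3 && !is.na(g$utr3_start[j]) &&
                   pos >= g$utr3_start[j] && pos <= g$utr3_end[j]) {
          rank_j <- 3L
        } else {
          ex_s <- as.integer(strsplit(g$exon_starts[j], ",")[[1]])
          ex_e <- as.integer(strsplit(g$exon_ends[j], ",")[[1]])
          rank_j <- if (any(pos >= ex_s & pos <= ex_e)) 4L else 5L
        }
      } else {
        down <- if (g$strand[j] == "+")
          pos > g$end[j] && pos <= g$end[j] + downstream_window
        else
          pos < g$start[j] && pos >= g$start[j] - downstream_window
        if (down) rank_j <- 6L
      }
      if (rank_j == 7L) next
      d <- abs(pos - g$tss[j])
      better <- rank_j < best_rank ||
        (rank_j == best_rank &&
           (d < best_dist ||
              (d == best_dist && (is.na(best_gene) || g$gene_id[j] < best_gene))))
      if (better) {
        best_rank <- rank_j; best_gene <- g$gene_id[j]; best_dist <- d
      }
    }
    feature[i] <- feats[best_rank]
    if (best_rank < 7L) gene_id[i] <- best_gene
  }
  sites$feature <- feature
  sites$gene_id <- gene_id
  sites
}

#' Classify dmCpGs by CpG-island context
#'
#' `island` inside a (merged) CGI, `shore` within `shore_width` bp of a CGI
#' edge, `open_sea` otherwise.
#'
#' @param sites data.frame with chrom and pos.
#' @param cgi_intervals data.frame chrom/start/end, 1-based inclusive
#'   (use [read_bed()] for BED input).
#' @param shore_width Shore width in bp (default 2000).
#' @return `sites` with an added `cgi_context` column.
#' @export
classify_cgi <- function(sites, cgi_intervals, shore_width = 2000) {
  cgi <- merge_intervals(cgi_intervals)
  ctx <- rep("open_sea", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cc <- cgi[cgi$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(cc) == 0) next
    pos <- sites$pos[i]
    if (any(pos >= cc$start & pos <= cc$end)) ctx[i] <- "island"
    else if (any(pos >= cc$start - shore_width & pos <= cc$end + shore_width))
      ctx[i] <- "shore"
  }
  sites$cgi_context <- ctx
  sites
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv$chrom[i] == out$chrom[k] && iv$start[i] <= out$end[k] + 1L)
      out$end[k] <- max(out$end[k], iv$end[i])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Annotate dmCpG calls with feature and CGI context
#'
#' @param calls dmCpG calls from [adjust_and_call()] (needs chrom, pos,
#'   direction).
#' @param annotation A [simulate_annotation()]-style list with `genes` and
#'   `cgi`, or pass `gene_models`/`cgi_intervals` directly.
#' @inheritParams classify_feature
#' @inheritParams classify_cgi
#' @return Annotated calls data.frame (adds feature, gene_id, cgi_context).
#' @export
annotate_dmcpgs <- function(calls, annotation, promoter_flank = 1000,
                            downstream_window = 3000, shore_width = 2000) {
  out <- classify_feature(calls, annotation$genes, promoter_flank,
                          downstream_window)
  classify_cgi(out, annotation$cgi, shore_width)
}

#' Collate annotated dmCpGs into differentially methylated genes
#'
#' One row per gene carrying at least one dmCpG, with its direction set
#' (`hyper`, `hypo`, or `both`), dmCpG count, promoter flag and gene type,
#' plus a reporting summary: hyper/hypo DMG counts and their combined total,
#' dmCpG direction percentages, feature percentages, the CGI-context x
#' feature cross-tabulation (with the share of island dmCpGs in promoters),
#' gene-type ranking and per-chromosome dmCpG counts. Percentages are
#' rounded to whole percent as conventionally reported.
#'
#' @param annotated An [annotate_dmcpgs()] data.frame (needs gene_id,
#'   direction, feature, cgi_context; chrom for the per-chromosome table).
#' @param gene_models Optional gene-model table used to attach gene types.
#' @return List of class `methnet_dmg`: `table` (the DMG data.frame) and
#'   `summary` (list of the reported counts/percentages).
#' @export
collate_dmgs <- function(annotated, gene_models = NULL) {
  a <- annotated
  n_sites <- nrow(a)
  n_hyper_sites <- sum(a$direction == "hyper")
  n_hypo_sites <- sum(a$direction == "hypo")

  with_gene <- a[!is.na(a$gene_id), , drop = FALSE]
  tab <- NULL
  if (nrow(with_gene) > 0) {
    sp <- split(with_gene, with_gene$gene_id)
    tab <- do.call(rbind, lapply(sp, function(d) {
      dirs <- unique(d$direction)
      data.frame(
        gene_id = d$gene_id[1],
        direction = if (length(dirs) > 1) "both" else dirs,
        n_dmcpgs = nrow(d),
        promoter_flag = any(d$feature == "promoter"),
        stringsAsFactors = FALSE)
    }))
    rownames(tab) <- NULL
    tab <- tab[order(tab$gene_id), , drop = FALSE]
    if (!is.null(gene_models))
      tab$gene_type <- gene_models$gene_type[match(tab$gene_id,
                                                   gene_models$gene_id)]
  } else {
    tab <- data.frame(gene_id = character(), direction = character(),
                      n_dmcpgs = integer(), promoter_flag = logical(),
                      stringsAsFactors = FALSE)
  }

  n_hyper_dmgs <- sum(tab$direction %in% c("hyper", "both"))
  n_hypo_dmgs <- sum(tab$direction %in% c("hypo", "both"))
  pct <- function(x, n) if (n > 0) round(100 * x / n) else NA_real_

  feat_pct <- NULL
  if (n_sites > 0) {
    ft <- table(a$feature)
    feat_pct <- round(100 * as.numeric(ft) / n_sites, 2)
    names(feat_pct) <- names(ft)
  }
  cgi_feat <- if (n_sites > 0) table(a$cgi_context, a$feature) else NULL
  n_island <- sum(a$cgi_context == "island")
  n_island_promoter <- sum(a$cgi_context == "island" & a$feature == "promoter")

  gene_type_rank <- NULL
  if (!is.null(tab$gene_type))
    gene_type_rank <- sort(table(tab$gene_type), decreasing = TRUE)

  summary <- list(
    n_dmcpgs = n_sites,
    n_hyper_dmcpgs = n_hyper_sites,
    n_hypo_dmcpgs = n_hypo_sites,
    pct_hyper_dmcpgs = pct(n_hyper_sites, n_sites),
    pct_hypo_dmcpgs = pct(n_hypo_sites, n_sites),
    n_hyper_dmgs = n_hyper_dmgs,
    n_hypo_dmgs = n_hypo_dmgs,
    n_both_dmgs = sum(tab$direction == "both"),
    n_dmgs_combined = n_hyper_dmgs + n_hypo_dmgs,
    feature_pct = feat_pct,
    cgi_feature_table = cgi_feat,
    n_island_dmcpgs = n_island,
    n_island_promoter_dmcpgs = n_island_promoter,
    pct_island_in_promoter = pct(n_island_promoter, n_island),
    gene_type_rank = gene_type_rank,
    per_chromosome = if (n_sites > 0 && "chrom" %in% names(a))
      table(a$chrom) else NULL)

  out <- list(table = tab, summary = summary)
  class(out) <- "methnet_dmg"
  out
}

#' @export
print.methnet_dmg <- function(x, ...) {
  s <- x$summary
  cat("methnet differentially methylated genes\n")
  cat(sprintf("  %d dmCpGs: %d hyper (%s%%), %d hypo (%s%%)\n",
              s$n_dmcpgs, s$n_hyper_dmcpgs, s$pct_hyper_dmcpgs,
              s$n_hypo_dmcpgs, s$pct_hypo_dmcpgs))
  cat(sprintf("  DMGs: %d hyper + %d hypo = %d (both directions: %d)\n",
              s$n_hyper_dmgs, s$n_hypo_dmgs, s$n_dmgs_combined, s$n_both_dmgs))
  if (!is.na(s$pct_island_in_promoter))
    cat(sprintf("  CGI dmCpGs in promoters: %d/%d (%s%%)\n",
                s$n_island_promoter_dmcpgs, s$n_island_dmcpgs,
                s$pct_island_in_promoter))
  invisible(x)
}
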