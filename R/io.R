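#' Read a Bismark-style coverage file
#'
#' Expects six tab-separated columns: chrom, start, end, methylation
#' percentage, count methylated, count unmethylated (1-based inclusive
#' coordinates). The percentage column is ignored in favour of the counts.
#' Malformed lines are rejected with their line number.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample label attached to the result (defaults to the file
#'   name without extension).
#' @return data.frame with columns chrom, pos, strand (`"+"`; the dialect is
#'   unstranded per-cytosine), n_meth, n_total, plus attribute `sample_id`.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\t100\t80\t8\t2", f)
#' read_coverage(f)
#' @export
read_coverage <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty coverage file: ", path)
    out <- data.frame(chrom = character(), pos = integer(), strand = character(),
                      n_meth = integer(), n_total = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0)
    stop("malformed coverage line ", bad[1], " in ", path,
         ": expected 6 tab-separated columns")
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  n_meth <- suppressWarnings(as.integer(m[, 5]))
  n_unmeth <- suppressWarnings(as.integer(m[, 6]))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad) > 0)
    stop("malformed coverage line ", bad[1], " in ", path,
         ": non-numeric coordinate or count")
  bad <- which(n_meth < 0 | n_unmeth < 0)
  if (length(bad) > 0)
    stop("coverage line ", bad[1], " in ", path, ": negative read count")
  out <- data.frame(chrom = m[, 1], pos = pos, strand = "+",
                    n_meth = n_meth, n_total = n_meth + n_unmeth,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  out
}

#' Write a count table in Bismark coverage format
#'
#' @param tab data.frame with chrom, pos, n_meth, n_total.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(tab, path) {
  pct <- ifelse(tab$n_total > 0, 100 * tab$n_meth / tab$n_total, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", tab$chrom, tab$pos, tab$pos,
                   format(pct, trim = TRUE, digits = 15),
                   tab$n_meth, tab$n_total - tab$n_meth)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; start is shifted by +1 on read.
#' @param path Path to a 3+ column BED file.
#' @return data.frame chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = tab[[1]], start = as.integer(tab[[2]]) + 1L,
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}

#' Write 1-based inclusive intervals as BED (0-based half-open)
#' @param intervals data.frame chrom, start, end (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  utils::write.table(
    data.frame(intervals$chrom, intervals$start - 1L, intervals$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene-set collections in GMT format
#'
#' @param path GMT path (name, description, then member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write every artifact of a synthetic study to a directory
#'
#' Emits the full on-disk study: per-sample Bismark coverage files, gene
#' models TSV, CGI BED, PPI edge TSV, disease-catalog TSV, pathways GMT,
#' clinical CSV, Ct CSV, platform-B beta TSV and ground-truth TSVs. All
#' outputs are plain text and byte-stable for a fixed config.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "methnet_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wt <- function(x, name, ...) {
    p <- file.path(dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE, ...)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  for (s in names(study$methylome$samples)) {
    p <- file.path(dir, paste0(s, ".cov"))
    write_coverage(study$methylome$samples[[s]], p)
    paths[[length(paths) + 1L]] <- p
  }
  wt(study$annotation$genes, "gene_models.tsv")
  write_bed(study$annotation$cgi, file.path(dir, "cgi.bed"))
  paths[[length(paths) + 1L]] <- file.path(dir, "cgi.bed")
  wt(study$network$ppi, "ppi_edges.tsv")
  wt(study$network$catalog, "disease_catalog.tsv")
  write_gmt(study$network$pathways, file.path(dir, "pathways.gmt"))
  paths[[length(paths) + 1L]] <- file.path(dir, "pathways.gmt")
  p <- file.path(dir, "clinical.csv")
  utils::write.csv(study$clinical$patients, p, row.names = FALSE, quote = FALSE)
  paths[[length(paths) + 1L]] <- p
  if (!is.null(study$clinical$ct)) {
    p <- file.path(dir, "ct_values.csv")
    utils::write.csv(study$clinical$ct, p, row.names = FALSE, quote = FALSE)
    paths[[length(paths) + 1L]] <- p
  }
  if (!is.null(study$clinical$beta))
    wt(data.frame(site_id = rownames(study$clinical$beta),
                  study$clinical$beta, check.names = FALSE),
       "platform_b_beta.tsv")
  wt(study$ground_truth$planted_dmcpg, "truth_planted_dmcpg.tsv")
  wt(study$ground_truth$planted_genes, "truth_planted_genes.tsv")
  sheet <- data.frame(sample_id = names(study$methylome$groups),
                      group = unname(study$methylome$groups),
                      path = paste0(names(study$methylome$groups), ".cov"),
                      stringsAsFactors = FALSE)
  wt(sheet, "samples.tsv")
  invisible(paths)
}
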