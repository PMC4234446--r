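# Promoter extraction, co-regulated gene selection, motif occurrence
# scanning and the in-silico expression (drought enrichment) filter.
#
# Genes at least 2-fold induced versus the untreated control count as
# up-regulated; a motif passes the expression filter when at least two
# drought-associated conditions rank among its top three enriched
# conditions (hypergeometric tail).

#' Construct an expression matrix of fold changes
#'
#' @param fold_change genes x conditions matrix of positive
#'   treatment/control ratios, with gene ids as row names.
#' @param conditions data frame with columns `condition_id`, `tissue`,
#'   `timepoint`, `is_drought` (logical), one row per matrix column.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(fold_change, conditions) {
  fold_change <- as.matrix(fold_change)
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop("fold changes must be finite and > 0")
  need <- c("condition_id", "tissue", "timepoint", "is_drought")
  if (!all(need %in% names(conditions)))
    stop("conditions must have columns: ", paste(need, collapse = ", "))
  if (nrow(conditions) != ncol(fold_change))
    stop("one conditions row per fold-change column required")
  colnames(fold_change) <- conditions$condition_id
  structure(list(fold_change = fold_change,
                 conditions = as.data.frame(conditions)),
            class = "expression_matrix")
}

#' Read / write an expression TSV
#'
#' The file carries a condition-metadata header block (lines starting
#' `#condition`) with the drought flags, followed by a gene x condition
#' fold-change table.
#'
#' @param path file path.
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#condition\t")]
  if (!length(meta)) stop("missing #condition metadata header block")
  cond <- do.call(rbind, lapply(strsplit(meta, "\t"), function(f)
    data.frame(condition_id = f[2], tissue = f[3], timepoint = f[4],
               is_drought = as.logical(f[5]), stringsAsFactors = FALSE)))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           row.names = 1, check.names = FALSE)
  expression_matrix(as.matrix(tab)[, cond$condition_id, drop = FALSE], cond)
}

#' @rdname read_expression
#' @param expr an `expression_matrix` to write.
#' @export
write_expression <- function(expr, path) {
  meta <- sprintf("#condition\t%s\t%s\t%s\t%s",
                  expr$conditions$condition_id, expr$conditions$tissue,
                  expr$conditions$timepoint, expr$conditions$is_drought)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("gene_id", colnames(expr$fold_change)),
                   collapse = "\t"), con)
  writeLines(paste(rownames(expr$fold_change),
                   apply(expr$fold_change, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Select up-regulated genes in one condition
#'
#' Genes with `fold_change >= fold_min` (inclusive, "at least") and,
#' when `fold_max` is given, `fold_change < fold_max`.
#'
#' @param expr an `expression_matrix`.
#' @param condition_id condition to select in.
#' @param fold_min inclusive lower fold-change bound (default 2).
#' @param fold_max optional exclusive upper bound.
#' @return character vector of gene ids.
#' @export
select_upregulated <- function(expr, condition_id, fold_min = 2.0,
                               fold_max = NULL) {
  if (fold_min <= 0) stop("fold_min must be > 0")
  if (!condition_id %in% colnames(expr$fold_change))
    stop("unknown condition: ", condition_id)
  fc <- expr$fold_change[, condition_id]
  keep <- fc >= fold_min
  if (!is.null(fold_max)) keep <- keep & fc < fold_max
  rownames(expr$fold_change)[keep]
}

#' Extract upstream (promoter) sequences
#'
#' Takes the `length` bases 5' of the transcription start site (or of the
#' ATG start codon when no TSS is annotated), reverse-complemented for
#' minus-strand genes; windows running off the contig edge are truncated,
#' not padded, and flagged.
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param ann data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (may be NA), `atg` (1-based coordinates).
#' @param length upstream window size (default 1000).
#' @return data frame with `gene_id`, `sequence`, `length`, `truncated`.
#' @export
extract_upstream <- function(genome, ann, length = 1000L) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    g <- ann[i, ]
    if (!g$chrom %in% names(genome)) stop("gene ", g$gene_id,
                                          " on unknown contig ", g$chrom)
    contig <- genome[[g$chrom]]
    anchor <- if (!is.na(g$tss)) g$tss else g$atg
    if (anchor < 1 || anchor > Biostrings::nchar(contig))
      stop("gene ", g$gene_id, " anchor off contig")
    if (g$strand == "+") {
      from <- max(1L, anchor - length); to <- anchor - 1L
    } else if (g$strand == "-") {
      from <- anchor + 1L
      to <- min(Biostrings::nchar(contig), anchor + length)
    } else stop("invalid strand for gene ", g$gene_id)
    if (to < from) stop("empty upstream window for gene ", g$gene_id)
    s <- Biostrings::subseq(contig, from, to)
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    data.frame(gene_id = g$gene_id, sequence = as.character(s),
               length = to - from + 1L,
               truncated = (to - from + 1L) < length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a gene annotation table
#'
#' Either a TSV with columns `gene_id`, `chrom`, `strand`, `tss`, `atg`,
#' or a GFF3 file whose `gene` features supply the coordinates (feature
#' start/end become TSS and ATG anchor by strand).
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @return annotation data frame.
#' @export
read_gene_annotation <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv")
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))]
  do.call(rbind, lapply(f, function(x) {
    id <- sub(".*ID=([^;]+).*", "\\1", x[9])
    start <- as.integer(x[4]); end <- as.integer(x[5])
    tss <- if (x[7] == "+") start else end
    data.frame(gene_id = id, chrom = x[1], strand = x[7], tss = tss,
               atg = tss, stringsAsFactors = FALSE)
  }))
}

#' Scan promoters for a pattern
#'
#' Exhaustively matches an exact or IUPAC-degenerate pattern against each
#' promoter, optionally on both strands.
#'
#' @param query pattern string (IUPAC allowed).
#' @param promoters named character vector of promoter sequences, or the
#'   data frame returned by [extract_upstream].
#' @param both_strands scan both strands (default `TRUE`).
#' @param id pattern id for the occurrence table (default the pattern).
#' @return occurrence data frame with `pattern_id`, `gene_id`,
#'   `position` (1-based start), `strand`, `match`.
#' @export
scan_promoters <- function(query, promoters, both_strands = TRUE, id = NULL) {
  if (is.data.frame(promoters))
    promoters <- stats::setNames(promoters$sequence, promoters$gene_id)
  if (length(promoters) == 0L) stop("promoters must be nonempty")
  id <- id %||% as.character(query)
  rows <- lapply(names(promoters), function(g) {
    hits <- iupac_scan(query, promoters[[g]], both_strands = both_strands)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(pattern_id = id, gene_id = g, position = hits$start,
               strand = hits$strand, match = hits$match,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pattern_id = character(), gene_id = character(),
                      position = integer(), strand = character(),
                      match = character(), stringsAsFactors = FALSE)
  out
}

#' Rank conditions by enrichment of motif-containing genes
#'
#' For each condition the score is the hypergeometric tail probability of
#' drawing at least `k` motif-containing genes in the condition's
#' up-regulated set, with all genes of the expression matrix as the
#' population; per-gene presence (not occurrence counts) is used. Lower
#' scores rank first; ties break by larger up-regulated overlap, then
#' condition id.
#'
#' @param occ occurrence table from [scan_promoters].
#' @param expr an `expression_matrix`.
#' @param fold_min up-regulation cutoff passed to [select_upregulated].
#' @return ordered data frame with `condition_id`, `score`, `n_up`,
#'   `n_overlap`, `is_drought`.
#' @export
rank_conditions <- function(occ, expr, fold_min = 2.0) {
  genes <- rownames(expr$fold_change)
  with_motif <- intersect(unique(occ$gene_id), genes)
  if (length(setdiff(unique(occ$gene_id), genes)))
    stop("occurrence table references genes absent from the expression matrix")
  N <- length(genes); K <- length(with_motif)
  rows <- lapply(seq_len(nrow(expr$conditions)), function(i) {
    cid <- expr$conditions$condition_id[i]
    up <- select_upregulated(expr, cid, fold_min = fold_min)
    k <- length(intersect(up, with_motif))
    score <- stats::phyper(k - 1, K, N - K, length(up), lower.tail = FALSE)
    data.frame(condition_id = cid, score = score, n_up = length(up),
               n_overlap = k, is_drought = expr$conditions$is_drought[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$score, -out$n_overlap, out$condition_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drought-association filter over ranked conditions
#'
#' Passes iff at least `min_drought` of the first `top_n` ranked
#' conditions are drought-associated.
#'
#' @param ranked output of [rank_conditions] (or any data frame ordered
#'   best-first with an `is_drought` column).
#' @param labels optional named logical vector of drought flags by
#'   condition id (overrides the `is_drought` column).
#' @param top_n number of top conditions examined (default 3).
#' @param min_drought required drought conditions among them (default 2).
#' @return logical flag.
#' @export
drought_filter <- function(ranked, labels = NULL, top_n = 3L,
                           min_drought = 2L) {
  if (top_n < min_drought) stop("top_n must be >= min_drought")
  if (nrow(ranked) == 0L) stop("ranked conditions must be nonempty")
  flags <- if (!is.null(labels)) unname(labels[ranked$condition_id])
           else ranked$is_drought
  sum(utils::head(flags, top_n), na.rm = TRUE) >= min_drought
}
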