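# Gold-standard handling and benchmarking.
#
# The packaged gold standard transcribes the yeast one-hybrid (Y1H)
# interaction tables: per screened cis-sequence, the TFs (locus ids and
# families) that activated the screened sequence but not its mutated
# version. Predictions are scored against it by locus id.

#' Load the Y1H gold standard
#'
#' @param path TSV with columns `motif_group`, `flagged`, `screened_seq`,
#'   `mutated_seq`, `tf_gene_id`, `family`, `tf_name`; defaults to the
#'   packaged transcription of the verified-interaction table.
#' @return object of class `gold_standard` with the `entries` data frame
#'   and the derived `elements` (distinct screened sequences, including
#'   those with zero interactors).
#' @export
load_gold_standard <- function(path = system.file(
  "extdata", "table3_gold_standard.tsv", package = "cistf")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  for (col in c("flagged", "tf_gene_id", "family", "tf_name"))
    if (!col %in% names(tab)) tab[[col]] <- ""
  tab[is.na(tab)] <- ""
  bad <- nzchar(tab$mutated_seq) &
    nchar(tab$mutated_seq) != nchar(tab$screened_seq)
  if (any(bad))
    stop(sprintf("%s:%d: mutated sequence length differs from screened",
                 path, which(bad)[1L] + 1L))
  structure(list(entries = tab, elements = unique(tab$screened_seq)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("<gold_standard> %d elements, %d (element, TF) interactions\n",
              length(x$elements), sum(nzchar(x$entries$tf_gene_id))))
  invisible(x)
}

#' Load the selected cis-sequence table
#'
#' @param path TSV fixture of the selected cis-elements (defaults to the
#'   packaged table).
#' @return data frame with `seq_nr`, `element`, `motif_group`,
#'   `query_id`, `gene`, `position`.
#' @export
load_cis_sequences <- function(path = system.file(
  "extdata", "table1_cis_sequences.tsv", package = "cistf")) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

.gold_rows <- function(gold, element) {
  if (!element %in% gold$elements) stop("unknown element: ", element)
  e <- gold$entries
  e[e$screened_seq == element & nzchar(e$tf_gene_id), , drop = FALSE]
}

#' Per-family interactor counts for one element
#'
#' @param gold a `gold_standard`.
#' @param element screened cis-sequence.
#' @return named integer vector: family -> number of distinct TF locus
#'   ids (empty for zero-interactor elements).
#' @export
family_counts <- function(gold, element) {
  rows <- .gold_rows(gold, element)
  if (nrow(rows) == 0L) return(stats::setNames(integer(), character()))
  rows <- rows[!duplicated(rows$tf_gene_id), , drop = FALSE]
  tab <- table(rows$family)
  stats::setNames(as.integer(tab), names(tab))
}

#' Interactor-set overlap between two elements
#'
#' Distinct-locus set algebra, optionally restricted to one TF family.
#' Percentages are reported to one decimal.
#'
#' @param gold a `gold_standard`.
#' @param elem_a,elem_b screened cis-sequences.
#' @param family optional family restriction (e.g. `"R2R3-MYB"`).
#' @return list with `set_a_size`, `set_b_size`, `intersection`, `union`,
#'   `pct_of_a` (shared as % of A) and `pct_of_union`.
#' @export
overlap_stats <- function(gold, elem_a, elem_b, family = NULL) {
  pick <- function(el) {
    rows <- .gold_rows(gold, el)
    if (!is.null(family)) rows <- rows[rows$family == family, , drop = FALSE]
    unique(rows$tf_gene_id)
  }
  a <- pick(elem_a); b <- pick(elem_b)
  inter <- length(intersect(a, b)); uni <- length(union(a, b))
  list(set_a_size = length(a), set_b_size = length(b),
       intersection = inter, union = uni,
       pct_of_a = if (length(a)) round(100 * inter / length(a), 1) else NA,
       pct_of_union = if (uni) round(100 * inter / uni, 1) else NA)
}

#' Is an element predictable from a database?
#'
#' An element is predictable when the database holds at least one motif
#' significantly similar to it (E-value within the motif threshold) whose
#' cognate TF is homologous (homology E-value within the threshold) to at
#' least one experimentally identified interactor of that element.
#' Elements without gold interactors return `FALSE` by convention.
#'
#' @param element screened cis-sequence.
#' @param db a `motif_tf_db`.
#' @param gold a `gold_standard`.
#' @param gold_proteome named character vector supplying protein
#'   sequences for the gold TF locus ids (missing ids are skipped).
#' @param params a [prediction_params].
#' @param null optional `motif_null`; built (seeded) when missing.
#' @param seed seed for the null construction.
#' @return logical flag.
#' @export
classify_predictable <- function(element, db, gold, gold_proteome,
                                 params = prediction_params(), null = NULL,
                                 seed = 1L) {
  gold_ids <- unique(.gold_rows(gold, element)$tf_gene_id)
  gold_ids <- intersect(gold_ids, names(gold_proteome))
  if (length(gold_ids) == 0L) return(FALSE)
  qm <- .as_query_motif(element)
  if (is.null(null))
    null <- build_null(db$motifs, motif_width(qm), seed = seed)
  hits <- search_similar_motifs(qm, db, params, null)
  if (nrow(hits) == 0L) return(FALSE)
  mat <- blosum62()
  db_residues <- sum(nchar(gold_proteome))
  for (mid in hits$motif_id) for (tid in db$links[[mid]]) {
    tf <- db$tfs[[tid]]
    for (gid in gold_ids) {
      aln <- local_protein_align(tf$protein_seq, gold_proteome[[gid]],
                                 matrix = mat)
      if (protein_evalue(aln, nchar(tf$protein_seq), db_residues) <=
          params$blast_evalue_max) return(TRUE)
    }
  }
  FALSE
}

#' Benchmark predictions against the gold standard
#'
#' A true positive is a predicted candidate whose id equals a gold TF
#' locus id for that element. Sensitivity is TP over all gold
#' (element, TF) interactions; specificity is computed per element over a
#' candidate universe (emulating the cloned TF library) and pooled:
#' TN / (TN + FP). Zero-interactor elements contribute to neither the
#' sensitivity numerator nor denominator but are reported per element.
#'
#' @param predictions named list: element -> character vector of
#'   predicted candidate ids (or a prediction data frame with a
#'   `candidate_protein_id` column).
#' @param gold a `gold_standard`.
#' @param universe character vector of all candidate TF ids
#'   (the negative universe for specificity).
#' @param predictable optional named logical vector per element.
#' @return object of class `benchmark_report`: `per_element` data frame
#'   and `totals` (sensitivity, specificity, predictions_per_validated,
#'   counts).
#' @export
evaluate_predictions <- function(predictions, gold, universe,
                                 predictable = NULL) {
  per <- lapply(names(predictions), function(el) {
    pred <- predictions[[el]]
    if (is.data.frame(pred)) pred <- pred$candidate_protein_id
    pred <- unique(as.character(pred))
    gold_ids <- unique(.gold_rows(gold, el)$tf_gene_id)
    tp <- length(intersect(pred, gold_ids))
    neg <- setdiff(universe, gold_ids)
    fp <- length(intersect(pred, neg))
    data.frame(element = el,
               predictable = if (!is.null(predictable))
                 predictable[[el]] else NA,
               n_gold = length(gold_ids), n_predictions = length(pred),
               n_true_positive = tp, n_false_positive = fp,
               n_true_negative = length(neg) - fp,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  total_gold <- sum(per$n_gold)
  tp <- sum(per$n_true_positive)
  fp <- sum(per$n_false_positive)
  tn <- sum(per$n_true_negative)
  npred <- sum(per$n_predictions)
  totals <- list(
    sensitivity = if (total_gold) tp / total_gold else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    predictions_per_validated = if (tp) npred / tp else NA_real_,
    n_gold = total_gold, n_predictions = npred, n_true_positive = tp)
  structure(list(per_element = per, totals = totals),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("<benchmark_report> %d elements | sensitivity %.3f",
                     " | specificity %.3f | %s predictions/validated\n"),
              nrow(x$per_element), t$sensitivity, t$specificity,
              if (is.na(t$predictions_per_validated)) "NA"
              else sprintf("%.1f", t$predictions_per_validated)))
  invisible(x)
}

#' Sweep prediction thresholds and benchmark each setting
#'
#' Runs the full prediction pipeline for every element under every
#' parameter combination in `grid` and evaluates each against the gold
#' standard. Deterministic under a fixed seed.
#'
#' @param grid data frame whose columns are [prediction_params] fields
#'   (missing columns take the defaults); one row per setting.
#' @param elements character vector of query cis-sequences.
#' @param db a `motif_tf_db`.
#' @param proteome named character vector of candidate proteins.
#' @param gold a `gold_standard`.
#' @param universe candidate universe for specificity (default: proteome
#'   ids).
#' @param seed seed for the alignment null.
#' @return data frame: one row per grid point with the thresholds and the
#'   benchmark totals.
#' @export
parameter_sweep <- function(grid, elements, db, proteome, gold,
                            universe = names(proteome), seed = 1L) {
  if (nrow(grid) == 0L) stop("grid must be nonempty")
  nulls <- new.env()
  get_null <- function(w) {
    key <- as.character(w)
    if (is.null(nulls[[key]]))
      nulls[[key]] <- build_null(db$motifs, w, seed = seed)
    nulls[[key]]
  }
  defaults <- prediction_params()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- defaults
    for (f in intersect(names(grid), names(defaults))) p[[f]] <- grid[[f]][i]
    preds <- lapply(stats::setNames(elements, elements), function(el) {
      qm <- .as_query_motif(el)
      predict_tfs(qm, db, proteome, params = p,
                  null = get_null(motif_width(qm)))
    })
    rep <- evaluate_predictions(preds, gold, universe)
    gi <- grid[i, , drop = FALSE]
    rownames(gi) <- NULL
    cbind(gi,
          data.frame(sensitivity = rep$totals$sensitivity,
                     specificity = rep$totals$specificity,
                     n_predictions = rep$totals$n_predictions,
                     n_true_positive = rep$totals$n_true_positive))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
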