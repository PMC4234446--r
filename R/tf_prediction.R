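# The prediction engine: query cis-element/motif -> similar database
# motifs -> cognate TFs -> proteome homologs -> interface filter ->
# ranked, deduplicated predictions.

#' Construct a TF record
#'
#' @param tf_id identifier (locus id for plant TFs).
#' @param name display name.
#' @param family TF family label (e.g. bHLH, NAC, R2R3-MYB, bZIP).
#' @param species species label.
#' @param protein_seq amino-acid sequence.
#' @param motif_ids ids of the binding motifs linked to this TF.
#' @param interface optional [interface_annotation] on `protein_seq`.
#' @return object of class `tf_record`.
#' @export
tf_record <- function(tf_id, name, family, species, protein_seq, motif_ids,
                      interface = NULL) {
  if (!nzchar(protein_seq)) stop("protein_seq must be nonempty")
  if (!is.null(interface) && length(interface$positions) &&
      max(interface$positions) > nchar(protein_seq))
    stop("interface positions exceed protein length for ", tf_id)
  structure(list(tf_id = as.character(tf_id), name = name, family = family,
                 species = species, protein_seq = protein_seq,
                 motif_ids = as.character(motif_ids), interface = interface),
            class = "tf_record")
}

#' Construct a motif-TF database
#'
#' Links are derived from each TF record's `motif_ids` and validated:
#' every referenced motif must exist.
#'
#' @param motifs list of [nucleotide_motif].
#' @param tfs list of [tf_record].
#' @return object of class `motif_tf_db` with `motifs`, `tfs` and the
#'   `links` mapping (motif id -> TF ids).
#' @export
motif_tf_database <- function(motifs, tfs) {
  motif_ids <- vapply(motifs, `[[`, character(1), "id")
  tf_ids <- vapply(tfs, `[[`, character(1), "tf_id")
  if (anyDuplicated(motif_ids)) stop("duplicate motif ids")
  if (anyDuplicated(tf_ids)) stop("duplicate TF ids")
  names(motifs) <- motif_ids
  names(tfs) <- tf_ids
  dangling <- setdiff(unlist(lapply(tfs, `[[`, "motif_ids")), motif_ids)
  if (length(dangling))
    stop("TF records link to unknown motif ids: ",
         paste(dangling, collapse = ", "))
  links <- lapply(stats::setNames(motif_ids, motif_ids), function(mid)
    tf_ids[vapply(tfs, function(tf) mid %in% tf$motif_ids, logical(1))])
  structure(list(motifs = motifs, tfs = tfs, links = links),
            class = "motif_tf_db")
}

#' @export
print.motif_tf_db <- function(x, ...) {
  cat(sprintf("<motif_tf_db> %d motifs, %d TFs (%d families)\n",
              length(x$motifs), length(x$tfs),
              length(unique(vapply(x$tfs, `[[`, character(1), "family")))))
  invisible(x)
}

#' Prediction thresholds
#'
#' Defaults are the pipeline's standard settings: motif-similarity E-value
#' at most 1e-3, homology E-value at most 1e-10 and interface similarity
#' at least 50%.
#'
#' @param stamp_evalue_max motif-similarity E-value cutoff.
#' @param blast_evalue_max homology E-value cutoff.
#' @param interface_min interface similarity cutoff (percent, inclusive).
#' @param require_interface apply the interface filter where an
#'   annotation exists (TFs without one pass with similarity `NA`).
#' @param strict_interface drop TFs lacking an interface annotation.
#' @return object of class `prediction_params`.
#' @export
prediction_params <- function(stamp_evalue_max = 1e-3,
                              blast_evalue_max = 1e-10,
                              interface_min = 50,
                              require_interface = TRUE,
                              strict_interface = FALSE) {
  stopifnot(stamp_evalue_max > 0, blast_evalue_max > 0, interface_min >= 0)
  structure(list(stamp_evalue_max = stamp_evalue_max,
                 blast_evalue_max = blast_evalue_max,
                 interface_min = interface_min,
                 require_interface = isTRUE(require_interface),
                 strict_interface = isTRUE(strict_interface)),
            class = "prediction_params")
}

#' Load a motif-TF database from files
#'
#' @param motif_path motif file readable by [read_motifs].
#' @param tf_table_path TSV with columns `tf_id`, `name`, `family`,
#'   `species`, `motif_ids` (semicolon-separated).
#' @param protein_fasta_path FASTA of TF protein sequences keyed by
#'   `tf_id`.
#' @param interface_json_path optional JSON mapping `tf_id` to 1-based
#'   interface positions.
#' @param motif_format format token for [read_motifs].
#' @return a `motif_tf_db`.
#' @export
load_database <- function(motif_path, tf_table_path, protein_fasta_path,
                          interface_json_path = NULL,
                          motif_format = "transfac") {
  motifs <- read_motifs(motif_path, motif_format)
  tab <- utils::read.delim(tf_table_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("tf_id", "name", "family", "species", "motif_ids")
  if (!all(need %in% names(tab)))
    stop("TF table must have columns: ", paste(need, collapse = ", "))
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  names(aa) <- sub("\\s.*", "", names(aa))
  iface <- if (!is.null(interface_json_path))
    jsonlite::read_json(interface_json_path, simplifyVector = TRUE)
  else list()
  tfs <- lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$tf_id[i]
    if (!id %in% names(aa))
      stop("no protein sequence for TF ", id, " in ", protein_fasta_path)
    ann <- if (id %in% names(iface))
      interface_annotation(id, as.integer(iface[[id]]))
    tf_record(id, tab$name[i], tab$family[i], tab$species[i],
              as.character(aa[[id]]),
              strsplit(tab$motif_ids[i], ";")[[1]], interface = ann)
  })
  motif_tf_database(motifs, tfs)
}

#' Write a motif-TF database (plus proteome) to a directory
#'
#' Emits exactly the files [load_database] reads: `motifs.transfac`,
#' `tfs.tsv`, `proteins.faa` and `interface.json`.
#'
#' @param db a `motif_tf_db`.
#' @param dir output directory (created if needed).
#' @param proteome optional named character vector written as
#'   `proteome.faa`.
#' @return invisibly, the directory path.
#' @export
write_database <- function(db, dir, proteome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_motifs(db$motifs, file.path(dir, "motifs.transfac"), "transfac")
  tab <- data.frame(
    tf_id = names(db$tfs),
    name = vapply(db$tfs, `[[`, character(1), "name"),
    family = vapply(db$tfs, `[[`, character(1), "family"),
    species = vapply(db$tfs, `[[`, character(1), "species"),
    motif_ids = vapply(db$tfs, function(tf)
      paste(tf$motif_ids, collapse = ";"), character(1)))
  utils::write.table(tab, file.path(dir, "tfs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(db$tfs, `[[`, character(1),
                                         "protein_seq"))
  Biostrings::writeXStringSet(seqs, file.path(dir, "proteins.faa"))
  iface <- Filter(Negate(is.null),
                  lapply(db$tfs, function(tf)
                    if (!is.null(tf$interface)) tf$interface$positions))
  jsonlite::write_json(iface, file.path(dir, "interface.json"))
  if (!is.null(proteome))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome),
                                file.path(dir, "proteome.faa"))
  invisible(dir)
}

#' Search a database for motifs similar to a query
#'
#' Aligns the query against every database motif (both strands) and
#' keeps those whose E-value under the null is at most
#' `params$stamp_evalue_max`, in ascending E-value order.
#'
#' @param query a [nucleotide_motif].
#' @param db a `motif_tf_db`.
#' @param params a [prediction_params].
#' @param null a `motif_null` built for this database and query width.
#' @return data frame with `motif_id`, `offset`, `orientation`, `ncols`,
#'   `score`, `e_value`.
#' @export
search_similar_motifs <- function(query, db, params = prediction_params(),
                                  null) {
  rows <- lapply(db$motifs, function(m) {
    aln <- align_motifs(query, m,
                        min_overlap = min(5L, motif_width(query),
                                          motif_width(m)))
    data.frame(motif_id = m$id, offset = aln$offset,
               orientation = aln$orientation, ncols = aln$ncols,
               score = aln$score,
               e_value = motif_evalue(aln, null, length(db$motifs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$e_value <= params$stamp_evalue_max, , drop = FALSE]
  out <- out[order(out$e_value, -out$score, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find proteome homologs of a database TF
#'
#' Local-aligns the TF protein against every proteome entry, keeps hits
#' with homology E-value at most `params$blast_evalue_max`, and -- when
#' the TF carries an interface annotation and `params$require_interface`
#' is on -- computes interface similarity through the reported alignment
#' and filters at `params$interface_min` (inclusive).
#'
#' @param tf a [tf_record].
#' @param proteome named character vector of protein sequences.
#' @param params a [prediction_params].
#' @param keep_failed keep interface-filter failures (flagged) instead of
#'   dropping them.
#' @return data frame with `protein_id`, `score`, `e_value`,
#'   `interface_similarity` (NA when no annotation) and `passed_interface`,
#'   in ascending E-value order.
#' @export
find_homologs <- function(tf, proteome, params = prediction_params(),
                          keep_failed = FALSE) {
  empty <- data.frame(protein_id = character(), score = numeric(),
                      e_value = numeric(), interface_similarity = numeric(),
                      passed_interface = logical(), stringsAsFactors = FALSE)
  if (length(proteome) == 0L) return(empty)
  if (params$strict_interface && is.null(tf$interface)) return(empty)
  mat <- blosum62()
  db_residues <- sum(nchar(proteome))
  # fast score-only pass over the whole proteome, full alignments only
  # for entries whose E-value can pass the threshold
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(proteome),
    Biostrings::AAString(tf$protein_seq),
    substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
    type = "local", scoreOnly = TRUE)
  sc <- pmax(sc, 0)
  cand <- names(proteome)[protein_evalue(sc, nchar(tf$protein_seq),
                                         db_residues) <=
                            params$blast_evalue_max]
  rows <- lapply(cand, function(pid) {
    aln <- local_protein_align(tf$protein_seq, proteome[[pid]], matrix = mat,
                               query_id = tf$tf_id, target_id = pid)
    e <- protein_evalue(aln, nchar(tf$protein_seq), db_residues)
    if (e > params$blast_evalue_max) return(NULL)
    sim <- NA_real_
    pass <- TRUE
    if (!is.null(tf$interface) && length(tf$interface$positions)) {
      sim <- interface_similarity(tf$protein_seq, proteome[[pid]],
                                  tf$interface, aln, matrix = mat)
      if (params$require_interface) pass <- sim >= params$interface_min
    }
    data.frame(protein_id = pid, score = aln$score, e_value = e,
               interface_similarity = sim, passed_interface = pass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  if (!keep_failed) out <- out[out$passed_interface, , drop = FALSE]
  out <- out[order(out$e_value, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Coerce a query (cis-sequence string, cis_sequence record or motif) to a
# motif. A bare cis-sequence becomes a single-copy column-pure motif.
.as_query_motif <- function(query, id = NULL) {
  if (inherits(query, "nucleotide_motif")) return(query)
  if (inherits(query, "cis_sequence"))
    return(motif_from_sequences(query$element,
                                id %||% paste0("seq", query$seq_nr)))
  motif_from_sequences(as.character(query), id %||% as.character(query))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict transcription factors binding a cis-sequence or motif
#'
#' Runs the full chain: motif-similarity search, motif-to-TF links,
#' homology search with interface filtering; deduplicates by candidate
#' protein keeping the best `(motif E-value, homology E-value)` chain.
#'
#' @param query a cis-sequence string, [cis_sequence] or
#'   [nucleotide_motif].
#' @param db a `motif_tf_db`.
#' @param proteome named character vector of target protein sequences.
#' @param params a [prediction_params].
#' @param null optional pre-built `motif_null`; built from the database
#'   (seeded) when missing.
#' @param seed seed for the null construction.
#' @param keep_failed keep interface-filter failures, flagged
#'   `passed_filters = FALSE`.
#' @return data frame with one row per prediction: `query_id`,
#'   `db_motif_id`, `motif_evalue`, `db_tf_id`, `candidate_protein_id`,
#'   `homology_evalue`, `interface_similarity`, `passed_filters`.
#' @export
predict_tfs <- function(query, db, proteome, params = prediction_params(),
                        null = NULL, seed = 1L, keep_failed = FALSE) {
  qm <- .as_query_motif(query)
  if (is.null(null))
    null <- build_null(db$motifs, motif_width(qm), seed = seed)
  hits <- search_similar_motifs(qm, db, params, null)
  empty <- data.frame(query_id = character(), db_motif_id = character(),
                      motif_evalue = numeric(), db_tf_id = character(),
                      candidate_protein_id = character(),
                      homology_evalue = numeric(),
                      interface_similarity = numeric(),
                      passed_filters = logical(), stringsAsFactors = FALSE)
  if (length(proteome) == 0L || nrow(hits) == 0L) return(empty)
  rows <- list()
  hom_cache <- list()
  for (i in seq_len(nrow(hits))) {
    for (tid in db$links[[hits$motif_id[i]]]) {
      hom <- hom_cache[[tid]]
      if (is.null(hom))
        hom <- hom_cache[[tid]] <- find_homologs(db$tfs[[tid]], proteome,
                                                 params,
                                                 keep_failed = keep_failed)
      if (nrow(hom) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qm$id, db_motif_id = hits$motif_id[i],
        motif_evalue = hits$e_value[i], db_tf_id = tid,
        candidate_protein_id = hom$protein_id,
        homology_evalue = hom$e_value,
        interface_similarity = hom$interface_similarity,
        passed_filters = hom$passed_interface, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$motif_evalue, out$homology_evalue,
                   out$candidate_protein_id), , drop = FALSE]
  out <- out[!duplicated(out$candidate_protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write predictions to a TSV file
#'
#' @param predictions data frame from [predict_tfs].
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
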