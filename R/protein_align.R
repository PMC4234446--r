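# Exact local protein alignment with Karlin-Altschul style E-values.
#
# The homology-search step of the prediction pipeline: optimal
# Smith-Waterman alignment under BLOSUM62 with affine gaps (open 11,
# extend 1), scored for significance with E = K * m * n * exp(-lambda * S)
# using the conventional gapped-BLOSUM62 constants.

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under an affine gap scheme; one optimal path
#' is reported. A best score of 0 (nothing aligns positively) yields an
#' empty alignment.
#'
#' @param a,b amino-acid strings (query and target).
#' @param matrix substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap opening / extension penalties
#'   (positive costs; defaults 11 and 1).
#' @param query_id,target_id optional identifiers.
#' @return object of class `protein_alignment` with the aligned strings
#'   (`q_aln`, `t_aln`, gaps as `-`), 1-based coordinates (`q_start`,
#'   `q_end`, `t_start`, `t_end`) and the raw `score`.
#' @export
local_protein_align <- function(a, b, matrix = NULL, gap_open = 11,
                                gap_extend = 1,
                                query_id = NA_character_,
                                target_id = NA_character_) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  if (is.null(matrix)) matrix <- blosum62()
  ok <- setdiff(rownames(matrix), "*")
  for (s in c(a, b)) {
    bad <- setdiff(strsplit(s, "")[[1]], ok)
    if (length(bad))
      stop("non-amino-acid characters: ", paste(unique(bad), collapse = ""))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(structure(list(query_id = query_id, target_id = target_id,
                          q_aln = "", t_aln = "", q_start = 0L, q_end = -1L,
                          t_start = 0L, t_end = -1L, score = 0,
                          e_value = NULL),
                     class = "protein_alignment"))
  }
  structure(list(
    query_id = query_id, target_id = target_id,
    q_aln = as.character(Biostrings::alignedPattern(pa)),
    t_aln = as.character(Biostrings::alignedSubject(pa)),
    q_start = Biostrings::start(pa@pattern@range),
    q_end = Biostrings::end(pa@pattern@range),
    t_start = Biostrings::start(pa@subject@range),
    t_end = Biostrings::end(pa@subject@range),
    score = sc, e_value = NULL),
    class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> score=%g q[%d-%d] t[%d-%d]%s\n",
              x$score, x$q_start, x$q_end, x$t_start, x$t_end,
              if (is.null(x$e_value)) "" else sprintf(" E=%.3g", x$e_value)))
  invisible(x)
}

#' Position map of a local protein alignment
#'
#' @param alignment a `protein_alignment`.
#' @return data frame with `qpos` and `tpos`, one row per alignment column
#'   where both sequences contribute a residue (gap columns dropped).
#' @export
alignment_map <- function(alignment) {
  if (!nzchar(alignment$q_aln))
    return(data.frame(qpos = integer(), tpos = integer()))
  qc <- strsplit(alignment$q_aln, "")[[1]]
  tc <- strsplit(alignment$t_aln, "")[[1]]
  qpos <- alignment$q_start - 1L + cumsum(qc != "-")
  tpos <- alignment$t_start - 1L + cumsum(tc != "-")
  keep <- qc != "-" & tc != "-"
  data.frame(qpos = qpos[keep], tpos = tpos[keep])
}

#' Karlin-Altschul style E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the conventional gapped
#' BLOSUM62 constants as defaults; monotone decreasing in the score and
#' linear in the database size.
#'
#' @param aln a `protein_alignment` (or a bare numeric raw score).
#' @param query_len query length `m`.
#' @param db_residues total residues `n` in the searched database.
#' @param lambda,K Karlin-Altschul parameters (defaults 0.267 and 0.041,
#'   the conventional gapped BLOSUM62 11/1 values).
#' @return the E-value.
#' @export
protein_evalue <- function(aln, query_len, db_residues, lambda = 0.267,
                           K = 0.041) {
  if (query_len <= 0 || db_residues <= 0) stop("lengths must be positive")
  s <- if (is.numeric(aln)) aln else aln$score
  K * query_len * db_residues * exp(-lambda * s)
}
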