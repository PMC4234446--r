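# Core motif / cis-sequence data model.
#
# A nucleotide motif is a W x 4 count (or weighted-count) matrix in fixed
# A,C,G,T column order -- the position frequency matrices used throughout
# the package for motif comparison, scanning and TF prediction.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide codes, keyed by the sorted base set.
IUPAC_BY_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)
IUPAC_SETS <- stats::setNames(names(IUPAC_BY_SET), IUPAC_BY_SET)

#' Construct a nucleotide motif
#'
#' A motif is a width-W by 4 matrix of non-negative counts in fixed
#' A,C,G,T column order, with an identifier, the number of contributing
#' sites and optionally the aligned source sequences it was built from.
#'
#' @param id motif identifier.
#' @param counts numeric matrix, W rows (positions) x 4 columns (A,C,G,T).
#' @param nsites positive number of contributing sequences; defaults to the
#'   maximum row sum of `counts`.
#' @param source_seqs optional character vector of equal-length nucleotide
#'   strings whose per-position base counts must equal `counts`.
#' @param description optional free-text description.
#' @return an object of class `nucleotide_motif`.
#' @export
nucleotide_motif <- function(id, counts, nsites = NULL, source_seqs = NULL,
                             description = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif counts must have 4 columns (A,C,G,T); got ", ncol(counts))
  if (nrow(counts) < 1L) stop("motif width must be >= 1")
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("motif counts must be finite and non-negative")
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("every motif row must have positive total count (row ",
         which(rs <= 0)[1L], " does not)")
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  if (is.null(nsites)) nsites <- max(rs)
  if (!is.numeric(nsites) || length(nsites) != 1L || nsites <= 0)
    stop("nsites must be a positive number")
  if (!is.null(source_seqs)) {
    if (any(nchar(source_seqs) != nrow(counts)))
      stop("source sequences must all have length ", nrow(counts))
    expected <- .count_matrix(source_seqs)
    if (max(abs(expected - counts)) > 1e-6)
      stop("source sequence base counts disagree with `counts`")
  }
  structure(
    list(id = as.character(id), counts = counts, nsites = as.numeric(nsites),
         source_seqs = source_seqs, description = description),
    class = "nucleotide_motif"
  )
}

#' @export
print.nucleotide_motif <- function(x, ...) {
  cat(sprintf("<nucleotide_motif> %s  width=%d  nsites=%g  consensus=%s\n",
              x$id, motif_width(x), x$nsites, consensus_string(x)))
  invisible(x)
}

#' Motif width (number of positions)
#' @param m a `nucleotide_motif`.
#' @return integer width.
#' @export
motif_width <- function(m) nrow(m$counts)

.check_acgt <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("sequences must contain only A/C/G/T: ", seqs[bad][1L])
}

.count_matrix <- function(seqs) {
  # per-position base counts via Biostrings consensusMatrix
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  m <- matrix(0, nrow = nchar(seqs[1L]), ncol = 4L,
              dimnames = list(NULL, DNA_BASES))
  for (b in DNA_BASES) if (b %in% rownames(cm)) m[, b] <- cm[b, ]
  m
}

#' Build a motif from aligned site sequences
#'
#' `counts[i, b]` is the number of sequences carrying base `b` at
#' position `i`; `nsites` is the number of sequences.
#'
#' @param seqs character vector of equal-length A/C/G/T strings.
#' @param id motif identifier.
#' @return a `nucleotide_motif`.
#' @export
motif_from_sequences <- function(seqs, id) {
  if (length(seqs) < 1L) stop("need at least one sequence")
  seqs <- toupper(as.character(seqs))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must all have the same length")
  .check_acgt(seqs)
  nucleotide_motif(id, .count_matrix(seqs), nsites = length(seqs),
                   source_seqs = seqs)
}

#' Normalise a motif to a position weight matrix of frequencies
#'
#' Each output row is `(count + pseudocount * background) /
#' (rowsum + pseudocount)` and sums to 1.
#'
#' @param m a `nucleotide_motif`.
#' @param pseudocount non-negative pseudocount mass distributed according
#'   to `background`.
#' @param background length-4 base composition summing to 1.
#' @return W x 4 matrix of frequencies.
#' @export
normalize_to_pwm <- function(m, pseudocount = 0.01,
                             background = rep(0.25, 4)) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a non-negative number")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("background must be a 4-vector summing to 1")
  if (pseudocount > 0 && any(background <= 0))
    stop("background must be strictly positive when pseudocount > 0")
  counts <- m$counts
  rs <- rowSums(counts)
  pwm <- sweep(counts, 1, rs + pseudocount, "/") +
    outer(pseudocount / (rs + pseudocount), background)
  dimnames(pwm) <- dimnames(counts)
  pwm
}

#' Reverse complement of a motif
#'
#' Rows are reversed and columns permuted A<->T, C<->G; applying it twice
#' returns the original motif.
#'
#' @param m a `nucleotide_motif`.
#' @return a `nucleotide_motif`.
#' @export
motif_revcomp <- function(m) {
  counts <- m$counts[rev(seq_len(nrow(m$counts))), c("T", "G", "C", "A"),
                     drop = FALSE]
  colnames(counts) <- DNA_BASES
  src <- m$source_seqs
  if (!is.null(src))
    src <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(src)))
  nucleotide_motif(m$id, counts, nsites = m$nsites, source_seqs = src,
                   description = m$description)
}

#' IUPAC consensus string of a motif
#'
#' A position with a single base above 50% frequency reports that base;
#' otherwise the smallest set of bases each at >= 25% frequency and jointly
#' holding >= 50% is reported as its IUPAC code; failing that, `N`.
#'
#' @param m a `nucleotide_motif`.
#' @return consensus string over the IUPAC alphabet.
#' @export
consensus_string <- function(m) {
  pwm <- normalize_to_pwm(m, pseudocount = 0)
  paste(vapply(seq_len(nrow(pwm)), function(i) {
    p <- pwm[i, ]
    if (max(p) > 0.5) return(DNA_BASES[which.max(p)])
    members <- DNA_BASES[p >= 0.25]
    if (length(members) >= 1L && sum(p[members]) >= 0.5)
      return(IUPAC_BY_SET[[paste(members, collapse = "")]])
    "N"
  }, character(1)), collapse = "")
}

#' Scan a sequence with an IUPAC degenerate pattern
#'
#' Reports every window matching the pattern's degeneracy sets, optionally
#' on both strands. Coordinates are 1-based and inclusive; minus-strand
#' matches are reported at the start of the window on the forward strand.
#'
#' @param pattern IUPAC pattern string (e.g. `"CANNTG"`).
#' @param seq nucleotide string to scan.
#' @param both_strands also scan the reverse strand (default `TRUE`).
#' @return data frame with columns `start`, `end`, `strand`, `match`.
#' @export
iupac_scan <- function(pattern, seq, both_strands = TRUE) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern) || grepl("[^ACGTMRWSYKVHDBN]", pattern))
    stop("pattern must be a nonempty IUPAC nucleotide string")
  subject <- Biostrings::DNAString(toupper(seq))
  hits_one <- function(pat, strand) {
    mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                   fixed = FALSE)
    if (length(mt) == 0L)
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), match = character(),
                        stringsAsFactors = FALSE))
    data.frame(start = Biostrings::start(mt), end = Biostrings::end(mt),
               strand = strand, match = as.character(mt),
               stringsAsFactors = FALSE)
  }
  out <- hits_one(pattern, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    out <- rbind(out, hits_one(rc, "-"))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Tandem repetition of a sequence
#'
#' Concatemerises `seq` `n` times -- the construction used for multimerised
#' one-hybrid baits (hexamers), which can create composite sites such as
#' E-boxes at repeat junctions.
#'
#' @param seq nucleotide string.
#' @param n positive integer repeat count.
#' @return the repeated string of length `n * nchar(seq)`.
#' @export
concatemer <- function(seq, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer")
  strrep(seq, n)
}

#' Construct a cis-sequence record
#'
#' One selected cis-regulatory element: its short sequence, the motif group
#' it belongs to, the discovery query and the locus/position it came from.
#'
#' @param seq_nr label such as `"7"` or `"12a"`.
#' @param element nucleotide string (5-11 nt).
#' @param motif_group one of the Roman numerals I-VII.
#' @param query_id discovery query identifier.
#' @param gene locus identifier.
#' @param position signed upstream coordinate (first one if multiple).
#' @return an object of class `cis_sequence`.
#' @export
cis_sequence <- function(seq_nr, element, motif_group, query_id = NA,
                         gene = NA, position = NA) {
  element <- toupper(element)
  .check_acgt(element)
  if (nchar(element) < 5L || nchar(element) > 11L)
    stop("cis-element length must be between 5 and 11 nt")
  if (!motif_group %in% as.character(utils::as.roman(1:7)))
    stop("motif_group must be one of I..VII")
  structure(list(seq_nr = as.character(seq_nr), element = element,
                 motif_group = motif_group, query_id = query_id,
                 gene = gene, position = position),
            class = "cis_sequence")
}
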