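# Protein-DNA interface annotation.
#
# Interface residues of a transcription factor are those protein residues
# whose heavy atoms lie within a distance cutoff (default 4.5 Angstroms,
# inclusive) of at least one DNA nitrogen-base atom in a protein-DNA
# complex structure. Interface similarity between a database TF and a
# candidate homolog is the percentage of annotated interface positions
# that align to a residue with a positive substitution-matrix score.

# Base-moiety atom names per deoxyribonucleotide; sugar and phosphate
# atoms are deliberately excluded (contacts must involve the base).
.BASE_ATOMS <- list(
  DA = c("N1", "C2", "N3", "C4", "C5", "C6", "N6", "N7", "C8", "N9"),
  DG = c("N1", "C2", "N2", "N3", "C4", "C5", "C6", "O6", "N7", "C8", "N9"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Parse a protein-DNA complex from PDB-format text
#'
#' Reads ATOM/HETATM records (via `bio3d`), keeps alternate location 'A'
#' or blank, and separates protein residues from DNA residues (codes
#' DA/DC/DG/DT) by residue name. Hydrogens are dropped on the protein
#' side ("heavy atoms only").
#'
#' @param pdb path to a PDB file, or a character vector/string of PDB
#'   lines.
#' @return object of class `complex_structure` holding an `atoms` data
#'   frame (`kind`, `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`,
#'   `seqpos`) and a `protein_residues` data frame in sequence order.
#' @export
parse_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb) || grepl("^(ATOM|HETATM)", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(pdb) == 1L) strsplit(pdb, "\n")[[1]] else pdb, path)
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  is_protein <- at$resid %in% .AA3
  is_dna <- at$resid %in% names(.BASE_ATOMS)
  at <- at[is_protein | is_dna, , drop = FALSE]
  at$kind <- ifelse(at$resid %in% .AA3, "protein", "dna")
  at <- at[!(at$kind == "protein" & at$elesy %in% "H"), , drop = FALSE]
  if (!any(at$kind == "protein")) stop("no protein chain in structure")
  if (!any(at$kind == "dna")) stop("no nucleic chain in structure")
  prot_key <- paste(at$chain, at$resno)[at$kind == "protein"]
  res <- at[at$kind == "protein", c("chain", "resno", "resid")]
  res <- res[!duplicated(prot_key), , drop = FALSE]
  res$seqpos <- seq_len(nrow(res))
  at$seqpos <- NA_integer_
  at$seqpos[at$kind == "protein"] <- res$seqpos[match(prot_key,
    paste(res$chain, res$resno))]
  structure(list(
    atoms = at[, c("kind", "chain", "resno", "resid", "elety", "elesy",
                   "x", "y", "z", "seqpos")],
    protein_residues = res),
    class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat(sprintf("<complex_structure> %d protein residues, %d DNA residues\n",
              nrow(x$protein_residues),
              length(unique(paste(x$atoms$chain, x$atoms$resno)[
                x$atoms$kind == "dna"]))))
  invisible(x)
}

#' Base-moiety atoms of a DNA residue
#'
#' Filters a residue's atom table down to the nitrogen-base atoms
#' (N1/C2/.../O6 as appropriate for the base), excluding the sugar and
#' phosphate backbone.
#'
#' @param residue data frame of atoms for one DNA residue, with columns
#'   `resid` and `elety`.
#' @return the rows of `residue` that belong to the base moiety.
#' @export
dna_base_atoms <- function(residue) {
  code <- unique(residue$resid)
  if (length(code) != 1L || !code %in% names(.BASE_ATOMS))
    stop("unknown DNA residue code: ", paste(code, collapse = ","))
  nm <- if (!is.null(residue$elety)) residue$elety else residue$name
  residue[nm %in% .BASE_ATOMS[[code]], , drop = FALSE]
}

#' Annotate DNA-contacting interface residues
#'
#' A protein residue is an interface residue iff the minimum Euclidean
#' distance between any of its heavy atoms and any DNA base atom in the
#' complex is at most `cutoff` (inclusive).
#'
#' @param c a `complex_structure`.
#' @param cutoff contact distance in Angstroms (default 4.5).
#' @param tf_id identifier stored on the annotation.
#' @return object of class `interface_annotation` with `tf_id` and the
#'   sorted `positions` (1-based indices into the protein sequence).
#' @export
interface_residues <- function(c, cutoff = 4.5, tf_id = NA_character_) {
  dna <- c$atoms[c$atoms$kind == "dna", , drop = FALSE]
  base <- do.call(rbind, lapply(
    split(dna, paste(dna$chain, dna$resno)), dna_base_atoms))
  prot <- c$atoms[c$atoms$kind == "protein", , drop = FALSE]
  if (nrow(base) == 0L)
    return(interface_annotation(tf_id, integer()))
  B <- as.matrix(base[, c("x", "y", "z")])
  P <- as.matrix(prot[, c("x", "y", "z")])
  # squared distances protein-atoms x base-atoms
  d2 <- outer(rowSums(P^2), rowSums(B^2), "+") - 2 * P %*% t(B)
  hit <- apply(d2, 1L, min) <= cutoff^2 + 1e-9
  interface_annotation(tf_id, sort(unique(prot$seqpos[hit])))
}

#' Construct an interface annotation
#'
#' @param tf_id TF identifier the positions refer to.
#' @param positions 1-based residue positions in the TF protein sequence.
#' @return object of class `interface_annotation`.
#' @export
interface_annotation <- function(tf_id, positions) {
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 1L)) stop("interface positions must be >= 1")
  structure(list(tf_id = tf_id, positions = positions),
            class = "interface_annotation")
}

#' Interface similarity between a database TF and a candidate homolog
#'
#' Over the annotated interface positions of the database TF, a position
#' counts as conserved when the pairwise alignment maps it to a candidate
#' residue (not a gap, not outside the aligned region) whose substitution
#' score with the database residue is strictly positive. The similarity is
#' `100 * conserved / n_positions`.
#'
#' @param db_tf_seq database TF protein sequence.
#' @param candidate_seq candidate protein sequence.
#' @param annotation an `interface_annotation` on `db_tf_seq`.
#' @param alignment a `protein_alignment` of `db_tf_seq` (query) against
#'   `candidate_seq` (target), as returned by [local_protein_align].
#' @param matrix substitution matrix (default BLOSUM62).
#' @return similarity percentage in `[0, 100]`.
#' @export
interface_similarity <- function(db_tf_seq, candidate_seq, annotation,
                                 alignment, matrix = NULL) {
  if (length(annotation$positions) == 0L) stop("no interface annotated")
  if (any(annotation$positions > nchar(db_tf_seq)))
    stop("interface positions exceed the database TF sequence length")
  if (is.null(matrix)) matrix <- blosum62()
  map <- alignment_map(alignment)
  qres <- strsplit(db_tf_seq, "")[[1]]
  tres <- strsplit(candidate_seq, "")[[1]]
  conserved <- vapply(annotation$positions, function(p) {
    t <- map$tpos[match(p, map$qpos)]
    !is.na(t) && matrix[qres[p], tres[t]] > 0
  }, logical(1))
  100 * sum(conserved) / length(conserved)
}

#' The BLOSUM62 substitution matrix
#'
#' @return the BLOSUM62 integer matrix (from Biostrings).
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
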