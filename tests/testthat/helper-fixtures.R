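# Shared fixtures and independent oracles. Oracles are deliberately
# written from scratch (plain loops, no reuse of package internals) so
# that they stay independent of the code paths they check.

rand_motif <- function(width, id = "m", sharp = FALSE) {
  counts <- t(vapply(seq_len(width), function(i) {
    if (sharp) {
      v <- rep(0.5, 4); v[sample.int(4, 1)] <- 20; v
    } else as.numeric(rmultinom(1, 20, runif(4)))
  }, numeric(4)))
  counts[rowSums(counts) == 0, 1] <- 1
  nucleotide_motif(id, counts)
}

# Brute-force motif alignment: enumerate every offset and orientation,
# score with plain stats::cor, apply the documented tie-breaks.
bf_align <- function(a, b, min_overlap = 5, both_strands = TRUE) {
  freq <- function(m) m$counts / rowSums(m$counts)
  rc <- function(f) {
    out <- f[rev(seq_len(nrow(f))), c(4, 3, 2, 1), drop = FALSE]
    colnames(out) <- colnames(f)
    out
  }
  pcc <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)
  }
  fa <- freq(a)
  wa <- nrow(fa); wb <- nrow(b$counts)
  best <- NULL
  oris <- c("forward", if (both_strands) "revcomp")
  for (ori in oris) {
    fb <- if (ori == "forward") freq(b) else rc(freq(b))
    for (off in (-(wb - min_overlap)):(wa - min_overlap)) {
      qi <- max(1, 1 + off); qj <- min(wa, wb + off)
      k <- qj - qi + 1
      s <- mean(sapply(0:(k - 1), function(d)
        pcc(fa[qi + d, ], fb[qi + d - off, ])))
      cand <- list(offset = off, orientation = ori, ncols = k, score = s)
      if (is.null(best) || s > best$score + 1e-12 ||
          (abs(s - best$score) <= 1e-12 &&
             (k > best$ncols ||
                (k == best$ncols &&
                   (abs(off) < abs(best$offset) ||
                      (abs(off) == abs(best$offset) && ori == "forward" &&
                         best$orientation != "forward"))))))
        best <- cand
    }
  }
  best
}

# Independent affine-gap Smith-Waterman (Gotoh), score only.
bf_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in x (deletion in query)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in y
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                   E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                   F[i - 1, j] - gap_extend)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[x[i - 1], y[j - 1]],
                   E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

rand_protein <- function(n) paste(sample(c("A", "R", "N", "D", "C", "Q",
  "E", "G", "H", "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  n, TRUE), collapse = "")

# Minimal PDB text from an atom table (name, resid, chain, resno, x, y, z,
# element).
synth_pdb <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    nm <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
    sprintf("ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm, a$resid, a$chain, a$resno, a$x, a$y, a$z, a$element)
  }, character(1))
  c(lines, "END")
}

atom_row <- function(name, resid, chain, resno, x, y, z,
                     element = substr(gsub("[0-9']", "", name), 1, 1)) {
  data.frame(name = name, resid = resid, chain = chain, resno = resno,
             x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}

# One amino-acid residue (GLY backbone: N, CA, C, O) centred near a point.
gly_residue <- function(chain, resno, x, y, z) {
  rbind(atom_row("N",  "GLY", chain, resno, x,     y,     z),
        atom_row("CA", "GLY", chain, resno, x + 1, y,     z),
        atom_row("C",  "GLY", chain, resno, x + 2, y,     z),
        atom_row("O",  "GLY", chain, resno, x + 2, y + 1, z))
}

# One DA nucleotide with a base atom (N1) at the given point plus
# backbone P and sugar C1'.
da_residue <- function(chain, resno, x, y, z) {
  rbind(atom_row("P",   "DA", chain, resno, x - 6, y, z, "P"),
        atom_row("C1'", "DA", chain, resno, x - 3, y, z, "C"),
        atom_row("N1",  "DA", chain, resno, x, y, z, "N"),
        atom_row("C2",  "DA", chain, resno, x + 1, y, z, "C"))
}

# Cached synthetic study instances, one per seed (generation is a couple
# of seconds; several test files share them).
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(seed = 7, ...) {
  key <- paste(seed, ..., sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_database(synth_config(seed = seed, ...))
  .sim_cache[[key]]
}

.null_cache <- new.env(parent = emptyenv())
get_null <- function(sim_seed = 7, width = 8) {
  key <- paste(sim_seed, width)
  if (is.null(.null_cache[[key]]))
    .null_cache[[key]] <- build_null(get_sim(sim_seed)$db$motifs, width,
                                     seed = sim_seed)
  .null_cache[[key]]
}
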