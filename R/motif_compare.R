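# Pairwise motif alignment and clustering.
#
# Motifs are compared column-by-column with the Pearson correlation of
# base frequencies, maximised over ungapped offsets and both orientations.
# Significance comes from a seeded null of column-shuffled decoy motifs
# (Gumbel fit by moments with an empirical-tail floor). All-vs-all
# distances feed a UPGMA tree, which is cut into motif groups at a
# branch-length threshold.

#' Pearson correlation between two frequency columns
#'
#' Columns with zero variance (e.g. the uniform column) score 0 against
#' anything, avoiding an undefined correlation.
#'
#' @param col_a,col_b length-4 frequency vectors summing to 1.
#' @return correlation in `[-1, 1]`.
#' @export
column_pcc <- function(col_a, col_b) {
  if (length(col_a) != 4L || length(col_b) != 4L ||
      abs(sum(col_a) - 1) > 1e-6 || abs(sum(col_b) - 1) > 1e-6)
    stop("columns must be length-4 frequency vectors summing to 1")
  if (stats::sd(col_a) == 0 || stats::sd(col_b) == 0) return(0)
  stats::cor(col_a, col_b)
}

# Row-wise Pearson correlation between two k x 4 frequency matrices;
# zero-variance rows give 0.
.rowwise_pcc <- function(A, B) {
  Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
  va <- rowSums(Ac^2);   vb <- rowSums(Bc^2)
  r <- numeric(nrow(A))
  ok <- va > 1e-24 & vb > 1e-24
  r[ok] <- rowSums(Ac * Bc)[ok] / sqrt(va[ok] * vb[ok])
  r
}

#' Best ungapped alignment of two motifs
#'
#' Scores every offset with at least `min_overlap` overlapping columns, in
#' forward and (optionally) reverse-complement orientation; the score is
#' the mean per-column Pearson correlation over the overlap. Ties are
#' broken by larger overlap, then smaller absolute offset, then forward
#' orientation.
#'
#' @param a,b [nucleotide_motif] objects (the query and the target).
#' @param min_overlap minimum number of overlapping columns (default 5).
#' @param both_strands also try the reverse complement of `b`.
#' @return object of class `motif_alignment` with fields `query_id`,
#'   `target_id`, `offset` (target start relative to query start),
#'   `orientation` (`"forward"` or `"revcomp"`), `ncols`, `score`.
#' @export
align_motifs <- function(a, b, min_overlap = 5L, both_strands = TRUE) {
  wa <- motif_width(a); wb <- motif_width(b)
  if (min_overlap > min(wa, wb))
    stop("min_overlap (", min_overlap, ") exceeds the smaller motif width")
  Pa <- normalize_to_pwm(a, pseudocount = 0)
  cand <- list(forward = normalize_to_pwm(b, pseudocount = 0))
  if (both_strands) cand$revcomp <- normalize_to_pwm(motif_revcomp(b),
                                                     pseudocount = 0)
  best <- NULL
  for (ori in names(cand)) {
    Pb <- cand[[ori]]
    for (off in seq(-(wb - min_overlap), wa - min_overlap)) {
      qi <- max(1L, 1L + off); qj <- min(wa, wb + off)
      ncols <- qj - qi + 1L
      sc <- mean(.rowwise_pcc(Pa[qi:qj, , drop = FALSE],
                              Pb[(qi - off):(qj - off), , drop = FALSE]))
      better <- is.null(best) || sc > best$score + 1e-12 ||
        (abs(sc - best$score) <= 1e-12 &&
           (ncols > best$ncols ||
              (ncols == best$ncols &&
                 (abs(off) < abs(best$offset) ||
                    (abs(off) == abs(best$offset) && ori == "forward" &&
                       best$orientation != "forward")))))
      if (better)
        best <- list(query_id = a$id, target_id = b$id, offset = off,
                     orientation = ori, ncols = ncols, score = sc,
                     query_width = wa, target_width = wb,
                     min_overlap = as.integer(min_overlap),
                     both_strands = isTRUE(both_strands), e_value = NULL)
    }
  }
  structure(best, class = "motif_alignment")
}

#' @export
print.motif_alignment <- function(x, ...) {
  cat(sprintf("<motif_alignment> %s vs %s  offset=%+d %s ncols=%d score=%.4f%s\n",
              x$query_id, x$target_id, x$offset, x$orientation, x$ncols,
              x$score,
              if (is.null(x$e_value)) "" else sprintf(" E=%.3g", x$e_value)))
  invisible(x)
}

# Permute the positions (rows) of a motif's count matrix.
.shuffle_columns <- function(m) {
  nucleotide_motif(m$id, m$counts[sample.int(nrow(m$counts)), , drop = FALSE],
                   nsites = m$nsites)
}

# Build a decoy motif of a given width from a source motif's columns.
.resample_width <- function(m, width) {
  idx <- sample.int(nrow(m$counts), width, replace = TRUE)
  nucleotide_motif(m$id, m$counts[idx, , drop = FALSE], nsites = m$nsites)
}

#' Build an empirical null model for motif alignment scores
#'
#' Decoys are column-shuffled database motifs, each aligned against a
#' random column-resampled motif of the query's width; the best-alignment
#' scores (mean per-column correlation) and their summed-similarity
#' counterparts (`score * ncols`, the significance statistic) are
#' recorded, together with the per-column correlation distribution of
#' random decoy column pairs, discretised for exact convolution in
#' [motif_evalue]. A Gumbel (extreme value) fit by moments of the summed
#' scores is stored as a diagnostic.
#'
#' @param db list of [nucleotide_motif] (the database).
#' @param query_width width of the query motif the null is built for.
#' @param n_decoys number of decoy alignments (default 1000).
#' @param seed integer seed; the same seed reproduces the scores exactly.
#' @param min_overlap,both_strands alignment parameters, as in
#'   [align_motifs].
#' @return object of class `motif_null` with sorted `scores` and
#'   `sum_scores`, the column-score probability mass `col_pmf` (bin width
#'   0.01 on `[-1, 1]`), `n_decoys`, `seed` and the Gumbel `fit`
#'   (location, scale) of the summed scores.
#' @export
build_null <- function(db, query_width, n_decoys = 1000L, seed = 1L,
                       min_overlap = 5L, both_strands = TRUE) {
  if (length(db) == 0L) stop("database is empty")
  if (n_decoys < 100L) stop("n_decoys must be >= 100")
  res <- withr::with_seed(seed, {
    alns <- lapply(seq_len(n_decoys), function(i) {
      target <- .shuffle_columns(db[[sample.int(length(db), 1L)]])
      qdecoy <- .resample_width(db[[sample.int(length(db), 1L)]], query_width)
      a <- align_motifs(qdecoy, target, min_overlap = min_overlap,
                        both_strands = both_strands)
      c(a$score, a$score * a$ncols)
    })
    # column-score null: correlations of random decoy column pairs
    pick_col <- function() {
      m <- db[[sample.int(length(db), 1L)]]
      f <- m$counts[sample.int(nrow(m$counts), 1L), ]
      f / sum(f)
    }
    n_cols <- 2000L
    A <- t(vapply(seq_len(n_cols), function(i) pick_col(), numeric(4)))
    B <- t(vapply(seq_len(n_cols), function(i) pick_col(), numeric(4)))
    list(alns = do.call(rbind, alns), colscores = .rowwise_pcc(A, B))
  })
  scores <- res$alns[, 1]; sums <- res$alns[, 2]
  breaks <- seq(-1.005, 1.005, by = 0.01)
  pmf <- tabulate(findInterval(pmin(pmax(res$colscores, -1), 1),
                               breaks, all.inside = TRUE),
                  nbins = length(breaks) - 1L)
  pmf <- pmf / sum(pmf)
  s <- stats::sd(sums)
  beta <- max(s * sqrt(6) / pi, 1e-9)
  mu <- mean(sums) - 0.5772156649 * beta
  structure(list(scores = sort(scores), sum_scores = sort(sums),
                 col_pmf = pmf, col_mids = (utils::head(breaks, -1L) +
                                              0.005),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 query_width = as.integer(query_width),
                 min_overlap = as.integer(min_overlap),
                 both_strands = isTRUE(both_strands),
                 fit = c(location = mu, scale = beta),
                 conv_cache = new.env(parent = emptyenv())),
            class = "motif_null")
}

# Tail probability P(sum of k null column scores >= s), by exact
# convolution of the discretised column-score distribution.
.sum_tail <- function(null, k, s) {
  key <- as.character(k)
  conv <- null$conv_cache[[key]]
  if (is.null(conv)) {
    pmf <- null$col_pmf
    conv <- pmf
    if (k > 1L) for (i in seq_len(k - 1L))
      conv <- stats::convolve(conv, rev(pmf), type = "open")
    conv[conv < 0] <- 0
    null$conv_cache[[key]] <- conv
  }
  # support of the k-fold sum: k * [-1, 1] on a 0.01 grid
  mids <- seq(-k, k, by = 0.01)[seq_along(conv)]
  sum(conv[mids >= s - 5e-3])
}

#' E-value of a motif alignment under a fitted null
#'
#' The significance statistic is the summed column similarity
#' `score * ncols`. Its tail probability is computed exactly under the
#' null of independent column scores (convolution of the empirical
#' column-score distribution), summed over every admissible offset and
#' orientation (a union bound over the alignment search space), and
#' floored at the rank-based empirical tail `k / (n_decoys + 1)` whenever
#' at least one decoy alignment reaches the statistic. `E = db_size * p`:
#' monotone non-increasing in score and linear in `db_size`.
#'
#' @param aln a `motif_alignment` (or a bare numeric mean score, taken
#'   over a full-width alignment of the null's query width).
#' @param null a `motif_null` from [build_null].
#' @param db_size number of motifs in the searched database.
#' @return the E-value.
#' @export
motif_evalue <- function(aln, null, db_size) {
  if (is.numeric(aln))
    aln <- list(score = aln, ncols = null$query_width,
                query_width = null$query_width,
                target_width = null$query_width,
                min_overlap = null$min_overlap,
                both_strands = null$both_strands)
  s_sum <- aln$score * aln$ncols
  wq <- aln$query_width; wt <- aln$target_width
  mo <- aln$min_overlap %||% 5L
  n_ori <- if (isTRUE(aln$both_strands)) 2L else 1L
  p <- 0
  for (off in seq(-(wt - mo), wq - mo)) {
    k <- min(wq, wt + off) - max(1L, 1L + off) + 1L
    if (k < s_sum - 1e-9) next
    p <- p + n_ori * .sum_tail(null, k, s_sum)
  }
  kcnt <- sum(null$sum_scores >= s_sum - 1e-12)
  p <- max(p, kcnt / (null$n_decoys + 1))
  db_size * min(p, 1)
}

#' All-vs-all motif distance matrix
#'
#' `d(i, j) = (1 - score(align_motifs(i, j))) / 2`, mapping alignment
#' scores in `[-1, 1]` onto distances in `[0, 1]`.
#'
#' @param motifs list of at least two [nucleotide_motif] with unique ids.
#' @param min_overlap,both_strands alignment parameters.
#' @return symmetric matrix with motif ids as dimnames.
#' @export
pairwise_distance_matrix <- function(motifs, min_overlap = 5L,
                                     both_strands = TRUE) {
  n <- length(motifs)
  if (n < 2L) stop("need at least 2 motifs")
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("motif ids must be unique")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    s <- align_motifs(motifs[[i]], motifs[[j]], min_overlap = min_overlap,
                      both_strands = both_strands)$score
    d[i, j] <- d[j, i] <- (1 - s) / 2
  }
  d
}

#' UPGMA similarity tree of motifs
#'
#' Average-linkage agglomeration of the distance matrix into an ultrametric
#' tree. Leaves are ordered lexicographically before clustering so that
#' ties resolve deterministically.
#'
#' @param dist symmetric distance matrix with id dimnames.
#' @param ids optional leaf ids (default the matrix dimnames).
#' @return object of class `motif_tree` with the `newick` string, the
#'   `leaf_ids` and the underlying `ape` phylo object.
#' @export
upgma_tree <- function(dist, ids = rownames(dist)) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix must be square")
  if (is.null(ids)) stop("leaf ids are required")
  dimnames(dist) <- list(ids, ids)
  ord <- order(ids)
  dist <- dist[ord, ord, drop = FALSE]
  phy <- ape::as.phylo(stats::hclust(stats::as.dist(dist),
                                     method = "average"))
  structure(list(newick = ape::write.tree(phy), leaf_ids = sort(ids),
                 phylo = phy),
            class = "motif_tree")
}

#' Cut a motif tree into groups at a branch-length threshold
#'
#' Removes every branch of length `>= branch_threshold` and groups the
#' leaves of each remaining connected component, so that motifs joined
#' only through short branches cluster together. Groups are labelled with
#' Roman numerals in decreasing size, ties by first-leaf order. A manual
#' `override` mapping (motif id -> group label) reassigns individual
#' motifs after cutting.
#'
#' @param tree a `motif_tree` (or a Newick string).
#' @param branch_threshold branch-length cutoff (default 0.05).
#' @param override optional named character vector, motif id -> group label.
#' @return data frame with columns `motif_id` and `group`.
#' @export
cut_tree_groups <- function(tree, branch_threshold = 0.05, override = NULL) {
  phy <- if (inherits(tree, "motif_tree")) tree$phylo
         else ape::read.tree(text = tree)
  n_tip <- length(phy$tip.label)
  n_node <- n_tip + phy$Nnode
  parent <- seq_len(n_node)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- phy$edge.length < branch_threshold
  for (e in which(keep)) {
    a <- find(phy$edge[e, 1]); b <- find(phy$edge[e, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n_tip), find, integer(1))
  members <- split(phy$tip.label, comp)
  # decreasing size, then order of first leaf in the tree
  first_leaf <- vapply(members, function(m)
    min(match(m, phy$tip.label)), integer(1))
  members <- members[order(-lengths(members), first_leaf)]
  out <- data.frame(
    motif_id = unlist(members, use.names = FALSE),
    group = rep(as.character(utils::as.roman(seq_along(members))),
                lengths(members)),
    stringsAsFactors = FALSE)
  if (!is.null(override)) {
    idx <- match(names(override), out$motif_id)
    if (anyNA(idx)) stop("override names unknown: ",
                         paste(names(override)[is.na(idx)], collapse = ", "))
    out$group[idx] <- unname(override)
  }
  rownames(out) <- NULL
  out[order(match(out$group, unique(out$group))), , drop = FALSE]
}
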