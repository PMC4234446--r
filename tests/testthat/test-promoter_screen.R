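# Promoter extraction, occurrence scanning and the in-silico expression
# (drought enrichment) filter.

make_expr <- function(fc, drought = c(TRUE, TRUE, FALSE)) {
  conds <- data.frame(condition_id = colnames(fc),
                      tissue = "roots", timepoint = "1h",
                      is_drought = drought, stringsAsFactors = FALSE)
  expression_matrix(fc, conds)
}

test_that("select_upregulated uses an inclusive 2-fold lower bound", {
  fc <- matrix(c(2.0, 1.99, 12, 1.0), 4, 1,
               dimnames = list(paste0("g", 1:4), "c1"))
  expr <- make_expr(fc, TRUE)
  expect_equal(select_upregulated(expr, "c1"), c("g1", "g3"))
  # the two- to tenfold window excludes a 12-fold gene
  expect_equal(select_upregulated(expr, "c1", 2, 10), "g1")
  all_flat <- make_expr(matrix(1, 4, 1,
                               dimnames = list(paste0("g", 1:4), "c1")),
                        TRUE)
  expect_equal(select_upregulated(all_flat, "c1"), character(0))
  expect_error(select_upregulated(expr, "c1", fold_min = 0), "> 0")
  expect_error(select_upregulated(expr, "nope"), "unknown condition")
})

test_that("extract_upstream takes the strand-aware 5' window", {
  set.seed(99)
  contig <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  genome <- c(chr1 = contig)
  ann <- data.frame(gene_id = c("plus", "minus", "short"),
                    chrom = "chr1", strand = c("+", "-", "+"),
                    tss = c(2001L, 1000L, 500L), atg = c(2100L, 900L, 600L),
                    stringsAsFactors = FALSE)
  pr <- extract_upstream(genome, ann, 1000)
  expect_equal(pr$sequence[1], substr(contig, 1001, 2000))
  expect_equal(pr$sequence[2], as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      substr(contig, 1001, 2000)))))
  # truncation at the contig edge, flagged
  expect_equal(pr$length[3], 499)
  expect_true(pr$truncated[3])
  expect_false(any(pr$truncated[1:2]))
  # ATG fallback when the TSS is unknown
  ann$tss[1] <- NA
  pr2 <- extract_upstream(genome, ann[1, ], 1000)
  expect_equal(pr2$sequence, substr(contig, 1100, 2099))
  expect_error(extract_upstream(genome,
                                data.frame(gene_id = "x", chrom = "chr9",
                                           strand = "+", tss = 10, atg = 10)),
               "unknown contig")
})

test_that("scan_promoters reports 1-based occurrence coordinates", {
  set.seed(12)
  bg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE,
                     prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  # plant the selected element at upstream position -26 (26 bp from the
  # promoter 3' end): starts at base 975 of a 1000-bp promoter
  site <- "ACCAAACAT"
  prom <- paste0(substr(bg, 1, 974), site, substr(bg, 984, 1000))
  occ <- scan_promoters(site, c(gene1 = prom), both_strands = FALSE)
  expect_true(975 %in% occ$position)
  expect_equal(occ$match[occ$position == 975], site)
  none <- scan_promoters("GCGCGCGCGCG", c(gene1 = "ATATATATATAT"))
  expect_equal(nrow(none), 0)
  one <- scan_promoters("CACCTAAC", c(g = "TTTCACCTAACTTT"),
                        both_strands = FALSE)
  expect_equal(one$position, 4)
})

test_that("rank_conditions equals brute-force hypergeometric enumeration", {
  genes <- paste0("g", 1:20)
  set.seed(8)
  fc <- matrix(1, 20, 3, dimnames = list(genes, paste0("c", 1:3)))
  fc[1:6, 1] <- 5       # c1 up-regulates the motif genes
  fc[5:12, 2] <- 5
  fc[13:20, 3] <- 5
  expr <- make_expr(fc)
  occ <- data.frame(pattern_id = "p", gene_id = paste0("g", 1:6),
                    position = 1, strand = "+", match = "x")
  ranked <- rank_conditions(occ, expr)
  expect_equal(ranked$condition_id[1], "c1")
  # independent oracle: explicit combinatorial tail sum
  tail_p <- function(k, K, N, n)
    sum(sapply(k:min(K, n), function(j)
      choose(K, j) * choose(N - K, n - j))) / choose(N, n)
  for (i in seq_len(nrow(ranked))) {
    r <- ranked[i, ]
    expect_equal(r$score, tail_p(r$n_overlap, 6, 20, r$n_up),
                 tolerance = 1e-12)
  }
  # scores do not depend on gene order
  ranked2 <- rank_conditions(occ[sample(6), ], expr)
  expect_equal(ranked2$score, ranked$score)
  # motif in all genes: every condition ties, order falls back to the id
  occ_all <- data.frame(pattern_id = "p", gene_id = genes, position = 1,
                        strand = "+", match = "x")
  tied <- rank_conditions(occ_all, expr)
  expect_equal(length(unique(tied$score)), 1)
  expect_error(rank_conditions(data.frame(pattern_id = "p",
                                          gene_id = "nope", position = 1,
                                          strand = "+", match = "x"),
                               expr), "absent")
})

test_that("the drought filter requires two drought hits in the top three", {
  ranked <- data.frame(condition_id = c("a", "b", "c", "d"),
                       is_drought = c(TRUE, TRUE, FALSE, TRUE))
  expect_true(drought_filter(ranked))                       # d, d, other
  ranked$is_drought <- c(TRUE, FALSE, FALSE, TRUE)
  expect_false(drought_filter(ranked))                      # d, other, other
  ranked$is_drought <- c(TRUE, FALSE, TRUE, FALSE)
  expect_true(drought_filter(ranked))                       # exactly two
  expect_error(drought_filter(ranked[0, ]), "nonempty")
  expect_error(drought_filter(ranked, top_n = 1, min_drought = 2),
               "top_n")
  # labels argument overrides the column
  expect_false(drought_filter(ranked,
                              labels = c(a = FALSE, b = FALSE, c = FALSE,
                                         d = TRUE)))
})

test_that("a motif planted in drought-up genes passes the filter", {
  cfg <- synth_config(seed = 21, n_promoters = 40, planted_fraction = 0.5)
  motif <- motif_from_sequences(rep("GCACGTGGAG", 4), "planted")
  pp <- generate_promoter_set(cfg, motif)
  drought_up <- pp$truth$gene_id[pp$truth$planted]
  expr <- generate_expression_matrix(cfg, pp$truth$gene_id, drought_up)
  occ <- scan_promoters(consensus_string(motif), pp$promoters)
  ranked <- rank_conditions(occ, expr)
  expect_true(drought_filter(ranked))
})

test_that("expression tables round-trip through the TSV format", {
  fc <- matrix(c(2.5, 1.1, 0.8, 3.3, 1.9, 6.0), 3, 2,
               dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  expr <- make_expr(fc, c(TRUE, FALSE))
  f <- withr::local_tempfile()
  write_expression(expr, f)
  back <- read_expression(f)
  expect_equal(back$fold_change, expr$fold_change)
  expect_equal(back$conditions$is_drought, c(TRUE, FALSE))
})
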