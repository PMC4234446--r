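# Gold-standard handling, predictability classification and benchmark
# metrics.

test_that("the packaged gold standard loads with full coverage", {
  gold <- load_gold_standard()
  expect_setequal(unique(gold$entries$motif_group),
                  c("I", "II", "III", "IV", "V", "VI", "VII"))
  # a specific verified interaction
  row <- gold$entries[gold$entries$screened_seq == "CACCTAAC" &
                        gold$entries$tf_gene_id == "AT1G09540", ]
  expect_equal(row$family, "R2R3-MYB")
  expect_equal(row$tf_name, "MYB061")
  # zero-interactor elements are present with empty TF fields
  expect_true(all(c("TCGGACCAA", "CCTCCTTCT") %in% gold$elements))
  expect_equal(nrow(.subset2(gold, "entries")[
    gold$entries$screened_seq == "TCGGACCAA" &
      nzchar(gold$entries$tf_gene_id), ]), 0)
  # mutated sequences always match the screened length
  f <- withr::local_tempfile()
  writeLines(c("motif_group\tflagged\tscreened_seq\tmutated_seq\ttf_gene_id\tfamily\ttf_name",
               "I\t\tACGTACGT\tACGTAC\tAT1G01010\tbHLH\tx"), f)
  expect_error(load_gold_standard(f), ":2:")
})

test_that("family_counts gives distinct loci per family", {
  gold <- load_gold_standard()
  expect_equal(family_counts(gold, "GCCACGTCAGC"), c(NAC = 1L))
  expect_equal(length(family_counts(gold, "TCGGACCAA")), 0)
  # counts partition the distinct loci of an element
  for (el in c("AACGTGGG", "CTCTCTCAC", "CCAACTAA")) {
    rows <- gold$entries[gold$entries$screened_seq == el &
                           nzchar(gold$entries$tf_gene_id), ]
    expect_equal(sum(family_counts(gold, el)),
                 length(unique(rows$tf_gene_id)))
  }
  expect_error(family_counts(gold, "AAAAAAA"), "unknown element")
})

test_that("overlap_stats computes distinct-locus set algebra", {
  gold <- load_gold_standard()
  self <- overlap_stats(gold, "CACCTAAC", "CACCTAAC", "R2R3-MYB")
  expect_equal(self$pct_of_a, 100)
  expect_equal(self$intersection, self$union)
  disjoint <- overlap_stats(gold, "GCACGTGGAG", "GCCACGTCAGC")
  expect_equal(disjoint$intersection, 0)
  expect_equal(disjoint$union,
               disjoint$set_a_size + disjoint$set_b_size)
})

test_that("classify_predictable needs a similar motif and a homologous TF", {
  tiny <- local({
    set.seed(3)
    dbd <- rand_protein(50)
    db <- motif_tf_database(
      list(motif_from_sequences(rep("GCACGTGGAG", 6), "gbox")),
      list(tf_record("BHLH1", "b", "bHLH", "plant",
                     paste0(rand_protein(30), dbd, rand_protein(30)),
                     "gbox")))
    list(db = db, dbd = dbd)
  })
  gold_tab <- data.frame(
    motif_group = "I", flagged = "",
    screened_seq = c("GCACGTGGAG", "TCGGACCAA"),
    mutated_seq = c("GCAGCTGGAG", "TCGGGTCAA"),
    tf_gene_id = c("AT1G00001", ""), family = c("bHLH", ""),
    tf_name = c("x", ""), stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  utils::write.table(gold_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gold <- load_gold_standard(f)
  null <- build_null(tiny$db$motifs, 10, n_decoys = 300, seed = 3)
  set.seed(4)
  related <- c(AT1G00001 = paste0(rand_protein(20), tiny$dbd,
                                  rand_protein(20)))
  unrelated <- c(AT1G00001 = rand_protein(90))
  expect_true(classify_predictable("GCACGTGGAG", tiny$db, gold, related,
                                   null = null))
  expect_false(classify_predictable("GCACGTGGAG", tiny$db, gold,
                                    unrelated, null = null))
  # no gold interactors: never predictable
  expect_false(classify_predictable("TCGGACCAA", tiny$db, gold, related,
                                    null = null))
})

test_that("evaluate_predictions matches brute-force confusion counts", {
  gold <- load_gold_standard()
  universe <- unique(gold$entries$tf_gene_id[
    nzchar(gold$entries$tf_gene_id)])
  gold_of <- function(el) unique(gold$entries$tf_gene_id[
    gold$entries$screened_seq == el & nzchar(gold$entries$tf_gene_id)])
  # predicting exactly the gold set: perfect sensitivity
  els <- c("GCACGTGGAG", "CACCTAAC", "TCGGACCAA")
  exact <- stats::setNames(lapply(els, gold_of), els)
  rep1 <- evaluate_predictions(exact, gold, universe)
  expect_equal(rep1$totals$sensitivity, 1)
  expect_equal(rep1$totals$predictions_per_validated, 1)
  # no predictions at all: sensitivity 0, specificity 1
  none <- stats::setNames(lapply(els, function(e) character()), els)
  rep0 <- evaluate_predictions(none, gold, universe)
  expect_equal(rep0$totals$sensitivity, 0)
  expect_equal(rep0$totals$specificity, 1)
  expect_true(is.na(rep0$totals$predictions_per_validated))
  # randomised toy predictions equal an independent count
  set.seed(17)
  preds <- stats::setNames(lapply(els, function(e)
    sample(universe, 8)), els)
  rep2 <- evaluate_predictions(preds, gold, universe)
  tp <- fp <- tn <- ng <- 0
  for (el in els) {
    g <- gold_of(el)
    tp <- tp + length(intersect(preds[[el]], g))
    fp <- fp + length(setdiff(preds[[el]], g))
    tn <- tn + length(setdiff(universe, union(g, preds[[el]])))
    ng <- ng + length(g)
  }
  expect_equal(rep2$totals$sensitivity, tp / ng)
  expect_equal(rep2$totals$specificity, tn / (tn + fp))
  expect_true(all(rep2$per_element$n_true_positive <=
                    pmin(rep2$per_element$n_gold,
                         rep2$per_element$n_predictions)))
})

test_that("parameter sweeps are monotone in the documented directions", {
  sim <- get_sim(7)
  # synthetic gold: each family consensus element is bound by its
  # planted homologs
  els <- unname(vapply(sim$truth, `[[`, character(1), "consensus")[1:3])
  fams <- names(sim$truth)[1:3]
  gold_tab <- do.call(rbind, lapply(seq_along(els), function(i)
    data.frame(motif_group = "I", flagged = "", screened_seq = els[i],
               mutated_seq = els[i],
               tf_gene_id = sim$truth[[fams[i]]]$homolog_ids,
               family = fams[i], tf_name = "", stringsAsFactors = FALSE)))
  f <- withr::local_tempfile()
  utils::write.table(gold_tab, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gold <- load_gold_standard(f)
  grid <- data.frame(stamp_evalue_max = c(1e-5, 1e-3))
  sweep <- parameter_sweep(grid, unname(els), sim$db, sim$proteome, gold,
                           seed = 7)
  expect_equal(nrow(sweep), 2)
  expect_lte(sweep$sensitivity[1], sweep$sensitivity[2])
  grid2 <- data.frame(interface_min = c(0, 50, 100))
  sweep2 <- parameter_sweep(grid2, unname(els), sim$db, sim$proteome,
                            gold, seed = 7)
  expect_true(all(diff(sweep2$n_predictions) <= 0))
  expect_error(parameter_sweep(grid[0, , drop = FALSE], els, sim$db,
                               sim$proteome, gold), "nonempty")
})
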