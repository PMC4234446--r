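# The prediction engine: database handling, motif search, homolog
# finding with the interface filter, and the full prediction chain.

make_tiny_db <- function() {
  # one bHLH whose motif is the G-box-containing element, one unrelated TF
  set.seed(3)
  bhlh_dbd <- rand_protein(50)
  bhlh <- paste0(rand_protein(30), bhlh_dbd, rand_protein(30))
  other <- paste0(rand_protein(40), rand_protein(50), rand_protein(30))
  db <- motif_tf_database(
    list(motif_from_sequences(rep("GCACGTGGAG", 6), "gbox"),
         motif_from_sequences(rep("TGACCGTTCA", 6), "wbox")),
    list(tf_record("BHLH1", "bHLH one", "bHLH", "plant", bhlh, "gbox",
                   interface = interface_annotation("BHLH1", 31:42)),
         tf_record("OTHER1", "other", "WRKY", "plant", other, "wbox")))
  homolog <- paste0(rand_protein(25), bhlh_dbd, rand_protein(35))
  proteome <- c(HOM_BHLH = homolog,
                DECOY1 = rand_protein(110), DECOY2 = rand_protein(110))
  list(db = db, proteome = proteome, bhlh = bhlh, dbd = bhlh_dbd)
}

test_that("databases validate links and round-trip through files", {
  tiny <- make_tiny_db()
  expect_length(tiny$db$links[["gbox"]], 1)
  expect_error(
    motif_tf_database(list(motif_from_sequences("ACGTACGT", "m1")),
                      list(tf_record("T1", "t", "f", "sp", "MKLV",
                                     c("m1", "missing")))),
    "missing")
  dir <- withr::local_tempdir()
  write_database(tiny$db, dir, proteome = tiny$proteome)
  back <- load_database(file.path(dir, "motifs.transfac"),
                        file.path(dir, "tfs.tsv"),
                        file.path(dir, "proteins.faa"),
                        file.path(dir, "interface.json"))
  expect_equal(names(back$motifs), names(tiny$db$motifs))
  expect_equal(back$tfs[["BHLH1"]]$protein_seq, tiny$bhlh)
  expect_equal(back$tfs[["BHLH1"]]$interface$positions, 31:42)
  expect_equal(back$links, tiny$db$links)
})

test_that("motif search returns the matching motif first and respects
          thresholds", {
  sim <- get_sim(7)
  null <- get_null(7, 8)
  q <- sim$db$motifs[[1]]
  hits <- search_similar_motifs(q, sim$db, prediction_params(), null)
  expect_equal(hits$motif_id[1], q$id)
  expect_lt(hits$e_value[1], 1e-3)
  # a query of uniform columns finds nothing at 1e-3
  flat <- nucleotide_motif("flat", matrix(1, 8, 4))
  expect_equal(nrow(search_similar_motifs(flat, sim$db,
                                          prediction_params(), null)), 0)
  # loosening the threshold can only add hits
  loose <- search_similar_motifs(q, sim$db,
                                 prediction_params(stamp_evalue_max = 1),
                                 null)
  expect_true(all(hits$motif_id %in% loose$motif_id))
})

test_that("homolog search applies the interface filter", {
  tiny <- make_tiny_db()
  tf <- tiny$db$tfs[["BHLH1"]]
  # the TF itself is a perfect self-hit
  hom <- find_homologs(tf, c(SELF = tf$protein_seq, tiny$proteome))
  expect_equal(hom$protein_id[1], "SELF")
  expect_equal(hom$interface_similarity[1], 100)
  # mutate every interface residue of the homolog to a dissimilar one
  mut <- strsplit(tiny$proteome[["HOM_BHLH"]], "")[[1]]
  b62 <- blosum62()
  ipos_hom <- 25 - 30 + tf$interface$positions  # homolog flank is 25 long
  mut[ipos_hom] <- vapply(mut[ipos_hom], function(r)
    names(which.min(b62[r, colnames(b62) %in% LETTERS]))[1], character(1))
  broken <- c(BROKEN = paste(mut, collapse = ""))
  expect_equal(nrow(find_homologs(tf, broken)), 0)
  kept <- find_homologs(tf, broken,
                        prediction_params(require_interface = FALSE))
  expect_equal(kept$protein_id, "BROKEN")
  flagged <- find_homologs(tf, broken, keep_failed = TRUE)
  expect_false(flagged$passed_interface[1])
  expect_lt(flagged$interface_similarity[1], 50)
})

test_that("predict_tfs recovers the planted bHLH for the G-box element", {
  tiny <- make_tiny_db()
  null <- build_null(tiny$db$motifs, 10, n_decoys = 300, seed = 3)
  pred <- predict_tfs("GCACGTGGAG", tiny$db, tiny$proteome, null = null)
  expect_equal(pred$candidate_protein_id, "HOM_BHLH")
  expect_equal(pred$db_tf_id, "BHLH1")
  expect_true(all(pred$passed_filters))
  # an empty proteome gives empty predictions, not an error
  expect_equal(nrow(predict_tfs("GCACGTGGAG", tiny$db, character(),
                                null = null)), 0)
  # querying a database motif returns its own cognate TF first
  self <- predict_tfs(tiny$db$motifs[["gbox"]], tiny$db,
                      c(SELF = tiny$bhlh), null = null)
  expect_equal(self$db_tf_id[1], "BHLH1")
  expect_equal(self$candidate_protein_id[1], "SELF")
})

test_that("every returned prediction satisfies all thresholds", {
  sim <- get_sim(7)
  null <- get_null(7, 8)
  p <- prediction_params()
  pred <- predict_tfs(sim$truth$FAM01$consensus_query, sim$db,
                      sim$proteome, params = p, null = null)
  expect_gt(nrow(pred), 0)
  expect_true(all(pred$motif_evalue <= p$stamp_evalue_max))
  expect_true(all(pred$homology_evalue <= p$blast_evalue_max))
  expect_true(all(is.na(pred$interface_similarity) |
                    pred$interface_similarity >= p$interface_min))
  expect_true(all(pred$passed_filters))
})

test_that("tightening any threshold never adds predictions", {
  sim <- get_sim(7)
  null <- get_null(7, 8)
  q <- sim$truth$FAM01$consensus_query
  base <- predict_tfs(q, sim$db, sim$proteome, null = null)
  tighter <- list(
    prediction_params(stamp_evalue_max = 1e-5),
    prediction_params(blast_evalue_max = 1e-20),
    prediction_params(interface_min = 90))
  for (p in tighter) {
    sub <- predict_tfs(q, sim$db, sim$proteome, params = p, null = null)
    expect_true(all(sub$candidate_protein_id %in%
                      base$candidate_protein_id))
  }
})
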