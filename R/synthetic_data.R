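# Seeded generators for motif-TF databases, proteomes with planted
# homologs, promoter sets with planted sites and fold-change expression
# matrices. These define the statistical structure the package's tests
# and benchmarks assume: TF families share a conserved DNA-binding
# domain (DBD) and a characteristic binding motif; the target proteome
# contains one planted homolog per database TF among unrelated decoys.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Synthetic-data configuration
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param n_families number of TF families.
#' @param members_per_family TFs per family.
#' @param dbd_length length of the shared DNA-binding domain.
#' @param dbd_divergence per-site substitution probability applied to the
#'   family DBD for each member and each planted homolog.
#' @param interface_fraction fraction of DBD positions annotated as
#'   DNA-contacting interface residues.
#' @param motif_width binding-motif width, within 5-10.
#' @param motif_info column sharpness: probability of the consensus base
#'   at each motif position.
#' @param n_promoters,promoter_length promoter set dimensions.
#' @param planted_fraction fraction of promoters receiving one planted
#'   motif site.
#' @param n_conditions,drought_conditions expression conditions and how
#'   many of them are drought-associated.
#' @param fold_range fold-change range (low, high) for up-regulated genes.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_families = 5L, members_per_family = 4L,
                         dbd_length = 60L, dbd_divergence = 0.1,
                         interface_fraction = 0.2, motif_width = 8L,
                         motif_info = 0.9, n_promoters = 50L,
                         promoter_length = 1000L, planted_fraction = 0.5,
                         n_conditions = 6L, drought_conditions = 3L,
                         fold_range = c(2, 10)) {
  stopifnot(n_families >= 1, members_per_family >= 1,
            dbd_divergence >= 0, dbd_divergence <= 1,
            interface_fraction > 0, interface_fraction <= 1,
            motif_width >= 5, motif_width <= 10,
            motif_info > 0.25, motif_info <= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            drought_conditions <= n_conditions,
            length(fold_range) == 2L, fold_range[1] > 1,
            fold_range[2] >= fold_range[1])
  structure(as.list(environment()), class = "synth_config")
}

.rand_seq <- function(n, alphabet) paste(sample(alphabet, n, TRUE),
                                         collapse = "")

.mutate_seq <- function(seq, p, alphabet) {
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < p
  ch[hit] <- vapply(ch[hit], function(x)
    sample(setdiff(alphabet, x), 1L), character(1))
  paste(ch, collapse = "")
}

# Sample one site string from a motif's per-column frequencies.
.sample_site <- function(m) {
  pwm <- normalize_to_pwm(m, pseudocount = 0)
  paste(vapply(seq_len(nrow(pwm)), function(i)
    sample(DNA_BASES, 1L, prob = pwm[i, ]), character(1)), collapse = "")
}

#' Generate a synthetic motif-TF database with a planted proteome
#'
#' Each family gets a consensus binding motif and a family DBD; members
#' carry noisy motif variants (per-column multinomial around the
#' consensus, sharpness `motif_info`) and a mutated copy of the family
#' DBD embedded in random flanks. Interface positions are sampled within
#' the DBD and carried over to every member. The proteome holds one
#' planted homolog per TF (same DBD lineage, new flanks) plus one
#' unrelated decoy protein per TF. Byte-identical outputs under the same
#' seed.
#'
#' @param cfg a [synth_config].
#' @return list with `db` (a `motif_tf_db`), `proteome` (named character
#'   vector) and `truth` -- per family: consensus, sharp consensus query
#'   motif, a site query string, a soft "discovered" whole-motif query
#'   with noisy flanking columns, and the member/homolog ids to recover.
#' @export
generate_database <- function(cfg) {
  if (cfg$n_families < 1L) stop("degenerate config: 0 families")
  withr::with_seed(cfg$seed, {
    n_if <- max(3L, round(cfg$interface_fraction * cfg$dbd_length))
    motifs <- list(); tfs <- list(); proteome <- character()
    families <- sprintf("FAM%02d", seq_len(cfg$n_families))
    truth <- list()
    for (f in seq_len(cfg$n_families)) {
      fam <- families[f]
      consensus <- .rand_seq(cfg$motif_width, DNA_BASES)
      fam_dbd <- .rand_seq(cfg$dbd_length, AA_ALPHABET)
      if_pos <- sort(sample.int(cfg$dbd_length, n_if))
      member_tfs <- character(); homolog_ids <- character()
      for (m in seq_len(cfg$members_per_family)) {
        mid <- sprintf("MOT%02d_%02d", f, m)
        tid <- sprintf("TF%02d_%02d", f, m)
        # member motif: multinomial counts around the consensus
        cons <- strsplit(consensus, "")[[1]]
        counts <- t(vapply(cons, function(b) {
          p <- rep((1 - cfg$motif_info) / 3, 4)
          p[match(b, DNA_BASES)] <- cfg$motif_info
          as.numeric(stats::rmultinom(1L, 20L, p))
        }, numeric(4)))
        motifs[[mid]] <- nucleotide_motif(mid, counts, nsites = 20)
        dbd <- .mutate_seq(fam_dbd, cfg$dbd_divergence, AA_ALPHABET)
        fl1 <- .rand_seq(sample(30:70, 1L), AA_ALPHABET)
        fl2 <- .rand_seq(sample(30:70, 1L), AA_ALPHABET)
        tfs[[tid]] <- tf_record(
          tid, name = tid, family = fam, species = "synthetic",
          protein_seq = paste0(fl1, dbd, fl2), motif_ids = mid,
          interface = interface_annotation(tid, nchar(fl1) + if_pos))
        # planted homolog: same DBD lineage in different flanks
        hid <- paste0("HOM_", tid)
        hdbd <- .mutate_seq(fam_dbd, cfg$dbd_divergence, AA_ALPHABET)
        proteome[hid] <- paste0(.rand_seq(sample(30:70, 1L), AA_ALPHABET),
                                hdbd,
                                .rand_seq(sample(30:70, 1L), AA_ALPHABET))
        member_tfs <- c(member_tfs, tid)
        homolog_ids <- c(homolog_ids, hid)
      }
      # soft whole-motif query: member-like columns plus 2 noisy flanking
      # columns per side (emulating de-novo discovery output)
      cons <- strsplit(consensus, "")[[1]]
      soft <- t(vapply(cons, function(b) {
        p <- rep((1 - cfg$motif_info) / 3, 4)
        p[match(b, DNA_BASES)] <- cfg$motif_info
        as.numeric(stats::rmultinom(1L, 20L, p))
      }, numeric(4)))
      flank <- function() t(stats::rmultinom(2L, 20L, rep(0.25, 4)))
      motif_query <- nucleotide_motif(paste0("query_motif_", fam),
                                      rbind(flank(), soft, flank()),
                                      nsites = 20)
      truth[[fam]] <- list(
        family = fam, consensus = consensus,
        consensus_query = motif_from_sequences(consensus,
                                               paste0("query_", fam)),
        site_query = consensus, motif_query = motif_query,
        tf_ids = member_tfs, homolog_ids = homolog_ids,
        interface_positions = if_pos)
    }
    # unrelated decoys, one per TF
    for (d in seq_len(cfg$n_families * cfg$members_per_family))
      proteome[sprintf("DEC_%02d", d)] <-
        .rand_seq(sample(120:200, 1L), AA_ALPHABET)
    list(db = motif_tf_database(motifs, tfs), proteome = proteome,
         truth = truth)
  })
}

#' Generate a promoter set with planted motif sites
#'
#' Background promoters are iid uniform nucleotides; a `planted_fraction`
#' of them receive one site sampled from the motif at a uniform random
#' position.
#'
#' @param cfg a [synth_config].
#' @param motif the [nucleotide_motif] to plant.
#' @return list with `promoters` (named character vector) and `truth`
#'   data frame (`gene_id`, `planted`, `position`).
#' @export
generate_promoter_set <- function(cfg, motif) {
  w <- motif_width(motif)
  if (w > cfg$promoter_length) stop("motif wider than promoter")
  withr::with_seed(cfg$seed + 1L, {
    ids <- sprintf("gene%03d", seq_len(cfg$n_promoters))
    planted <- seq_len(cfg$n_promoters) <=
      round(cfg$planted_fraction * cfg$n_promoters)
    pos <- rep(NA_integer_, cfg$n_promoters)
    seqs <- vapply(seq_len(cfg$n_promoters), function(i) {
      s <- strsplit(.rand_seq(cfg$promoter_length, DNA_BASES), "")[[1]]
      if (planted[i]) {
        p <- sample.int(cfg$promoter_length - w + 1L, 1L)
        s[p:(p + w - 1L)] <- strsplit(.sample_site(motif), "")[[1]]
        pos[i] <<- p
      }
      paste(s, collapse = "")
    }, character(1))
    list(promoters = stats::setNames(seqs, ids),
         truth = data.frame(gene_id = ids, planted = planted,
                            position = pos, stringsAsFactors = FALSE))
  })
}

#' Generate a fold-change expression matrix with a planted drought signal
#'
#' Drought-associated conditions give the `drought_up` genes fold changes
#' uniform in `fold_range` and the rest log-normal noise around 1;
#' non-drought conditions up-regulate an independently sampled gene set
#' of the same size.
#'
#' @param cfg a [synth_config].
#' @param gene_ids gene identifiers.
#' @param drought_up subset of `gene_ids` truly drought-induced.
#' @return an [expression_matrix].
#' @export
generate_expression_matrix <- function(cfg, gene_ids, drought_up) {
  if (length(gene_ids) == 0L) stop("empty gene list")
  if (!all(drought_up %in% gene_ids))
    stop("drought_up must be a subset of gene_ids")
  withr::with_seed(cfg$seed + 2L, {
    conds <- data.frame(
      condition_id = sprintf("cond%02d", seq_len(cfg$n_conditions)),
      tissue = rep(c("roots", "shoots"),
                   length.out = cfg$n_conditions),
      timepoint = sprintf("%dh", seq_len(cfg$n_conditions)),
      is_drought = seq_len(cfg$n_conditions) <= cfg$drought_conditions,
      stringsAsFactors = FALSE)
    fc <- matrix(stats::rlnorm(length(gene_ids) * cfg$n_conditions,
                               0, 0.3),
                 nrow = length(gene_ids),
                 dimnames = list(gene_ids, conds$condition_id))
    for (j in seq_len(cfg$n_conditions)) {
      up <- if (conds$is_drought[j]) drought_up
            else sample(gene_ids, length(drought_up))
      fc[up, j] <- stats::runif(length(up), cfg$fold_range[1],
                                cfg$fold_range[2])
    }
    expression_matrix(fc, conds)
  })
}
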