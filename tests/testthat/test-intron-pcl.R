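# helper: a small annotated genome whose cox1 carries introns at the
# given spliced offsets (offsets in the supplied spliced CDS)
genome_with_introns <- function(id, spliced, offsets, intron_len = 120,
                                strand = "+", lead = 200, trail = 200) {
  set.seed(sum(utf8ToInt(id)))
  pieces <- list()
  bounds <- c(0, offsets, nchar(spliced))
  for (i in seq_len(length(bounds) - 1))
    pieces[[length(pieces) + 1]] <- substr(spliced, bounds[i] + 1,
                                           bounds[i + 1])
  full_tx <- character(0)
  exon_lens <- integer(0)
  for (i in seq_along(pieces)) {
    full_tx <- c(full_tx, pieces[[i]])
    exon_lens <- c(exon_lens, nchar(pieces[[i]]))
    if (i < length(pieces))
      full_tx <- c(full_tx, oracle_random_dna(intron_len))
  }
  frag_tx <- paste(full_tx, collapse = "")
  frag <- if (strand == "+") frag_tx else revcomp(frag_tx)
  seq <- paste0(oracle_random_dna(lead), frag, oracle_random_dna(trail))
  # exon coordinates within the fragment (transcription order)
  lens <- nchar(full_tx)
  cum <- cumsum(lens)
  exon_rows <- lapply(seq(1, length(lens), 2), function(t) {
    tx_from <- cum[t] - lens[t] + 1
    tx_to <- cum[t]
    F <- sum(lens)
    if (strand == "+") c(lead + tx_from, lead + tx_to)
    else c(lead + F - tx_to + 1, lead + F - tx_from + 1)
  })
  ex <- do.call(rbind, exon_rows)
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  mito_genome(id, seq, "circular",
              list(gene_feature("cox1", "CDS", strand, ex)))
}

test_that("intron sites are cumulative spliced lengths in transcription order", {
  set.seed(131)
  spliced <- random_test_cds(259)  # 777 nt
  g0 <- genome_with_introns("NONE", spliced, integer(0))
  expect_identical(nrow(intron_sites(g0, "cox1")), 0L)

  g <- genome_with_introns("TWO", spliced, c(300, 700))
  st <- intron_sites(g, "cox1")
  expect_identical(st$spliced_offset, c(300L, 700L))

  gm <- genome_with_introns("MINUS", spliced, c(300, 700), strand = "-")
  stm <- intron_sites(gm, "cox1")
  expect_identical(stm$spliced_offset, c(300L, 700L))
})

test_that("planted insertion sites map to their reference offsets", {
  set.seed(137)
  ref_nt <- random_test_cds(531)  # cox1-sized, 1593 nt
  ref <- as_cds(ref_nt, gene = "cox1", genome_id = "REF")

  # identity projection: reference genome with an intron at 706
  g_self <- genome_with_introns("SELF", ref_nt, 706)
  asg <- assign_pcls(list(g_self), "cox1", ref)
  expect_identical(asg$pcl_name, "P706")

  # two diverged genomes with introns at 383 and 706
  g1 <- genome_with_introns("DIV1", mutate_k2p(ref_nt, 0.05, seed = 1),
                            c(383, 706))
  g2 <- genome_with_introns("DIV2", mutate_k2p(ref_nt, 0.05, seed = 2),
                            c(383, 706), strand = "-")
  asg2 <- assign_pcls(list(g1, g2), "cox1", ref)
  expect_identical(sort(unique(asg2$pcl_name)), c("P383", "P706"))
  expect_identical(nrow(asg2), 4L)

  # a 9-nt deletion upstream of the intron is absorbed by projection
  del_nt <- paste0(substr(ref_nt, 1, 120), substr(ref_nt, 130, nchar(ref_nt)))
  g3 <- genome_with_introns("DEL", del_nt, 383 - 9)
  asg3 <- assign_pcls(list(g3), "cox1", ref)
  expect_identical(asg3$pcl_name, "P383")
})

test_that("mutated CDS bodies do not need introns to be recoverable", {
  # divergence 0.2 with codon indels: planted offsets still recovered
  set.seed(139)
  ok <- 0L; total <- 0L
  for (s in 1:5) {
    panel <- build_panel(synthetic_spec(
      n_genomes = 2, genome_length = 23500, divergence = 0.2,
      indel_rate = 0.02,
      intron_plan = data.frame(genome = c(1, 2, 2),
                               gene = "cox1",
                               offset = c(706, 383, 706),
                               length = c(150, 150, 180)),
      seed = 500 + s))
    anc <- panel$truth$ancestor$genes$cox1
    ref <- as_cds(anc, gene = "cox1", genome_id = "ANC")
    asg <- assign_pcls(panel$genomes, "cox1", ref)
    want <- c(P383 = "P383", P706 = "P706")
    total <- total + nrow(asg)
    ok <- ok + sum(asg$pcl_name[asg$genome_id == "SYN01"] == "P706") +
      sum(asg$pcl_name[asg$genome_id == "SYN02"] %in% want)
  }
  expect_gte(ok / total, 0.95)
})

test_that("assignments within the tolerance merge into the smallest-offset Pcl", {
  set.seed(149)
  ref_nt <- random_test_cds(300)
  ref <- as_cds(ref_nt, gene = "cox1", genome_id = "REF")
  g1 <- genome_with_introns("TOL1", ref_nt, 450)
  g2 <- genome_with_introns("TOL2", ref_nt, 452)
  loose <- assign_pcls(list(g1, g2), "cox1", ref, tolerance = 3)
  expect_identical(unique(loose$pcl_name), "P450")
  strict <- assign_pcls(list(g1, g2), "cox1", ref, tolerance = 0)
  expect_setequal(unique(strict$pcl_name), c("P450", "P452"))
})

test_that("common/rare labels follow the strict one-fifth rule", {
  mk_assign <- function(counts, n) {
    rows <- list()
    for (p in seq_along(counts))
      for (g in seq_len(counts[p]))
        rows[[length(rows) + 1]] <- data.frame(
          genome_id = paste0("G", g), host_gene = "cox1",
          intron_index = p, spliced_offset = 100 * p,
          ref_offset = 100 * p, pcl_name = paste0("P", 100 * p),
          mappable = TRUE, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }
  # n = 17: presence in 4 species is common (4 > 3.4), 3 is rare
  m17 <- classify_common_rare(mk_assign(c(4, 3), 17), n_species = 17)
  expect_identical(unname(m17$labels[c("P100", "P200")]),
                   c("common", "rare"))
  # n = 5: presence in 1 species is rare (1 > 1 is false)
  m5 <- classify_common_rare(mk_assign(1, 5), n_species = 5)
  expect_identical(unname(m5$labels[["P100"]]), "rare")
})

test_that("matrix row sums equal per-genome mappable intron counts", {
  set.seed(151)
  ref_nt <- random_test_cds(400)
  ref <- as_cds(ref_nt, gene = "cox1", genome_id = "REF")
  g1 <- genome_with_introns("MS1", mutate_k2p(ref_nt, 0.03, seed = 5),
                            c(200, 500, 900))
  g2 <- genome_with_introns("MS2", mutate_k2p(ref_nt, 0.03, seed = 6),
                            500)
  asg <- assign_pcls(list(g1, g2), "cox1", ref)
  m <- classify_common_rare(asg, 2)
  counts <- tapply(asg$mappable, asg$genome_id, sum)
  expect_equal(unname(rowSums(m$matrix)[names(counts)]),
               as.vector(counts))
})

test_that("Pcl assignment does not depend on genome processing order", {
  set.seed(157)
  ref_nt <- random_test_cds(350)
  ref <- as_cds(ref_nt, gene = "cox1", genome_id = "REF")
  g1 <- genome_with_introns("ORD1", mutate_k2p(ref_nt, 0.05, seed = 7),
                            c(300, 800))
  g2 <- genome_with_introns("ORD2", mutate_k2p(ref_nt, 0.05, seed = 8),
                            800)
  a12 <- assign_pcls(list(g1, g2), "cox1", ref)
  a21 <- assign_pcls(list(g2, g1), "cox1", ref)
  key <- function(df) {
    df <- df[order(df$genome_id, df$intron_index),
             c("genome_id", "pcl_name")]
    rownames(df) <- NULL
    df
  }
  expect_identical(key(a12), key(a21))
})
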