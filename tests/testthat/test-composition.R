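test_that("skew formulas reproduce hand-computed values", {
  s <- base_composition("AATT")
  expect_equal(s$at_skew, 0)
  expect_equal(s$gc_skew, 0)
  expect_false(s$gc_skew_defined)  # G + C == 0: null skew, flagged
  expect_equal(s$gc_content, 0)

  expect_equal(base_composition("AAT")$at_skew, (2 - 1) / 3)

  g <- base_composition("GGC")
  expect_equal(g$gc_skew, (2 - 1) / 3)
  expect_equal(g$gc_content, 100)

  # skews bounded, N excluded from denominators
  n <- base_composition("ANNNT")
  expect_equal(n$counts[["A"]] + n$counts[["T"]], 2)
  expect_equal(n$n_ambiguous, 3)
})

test_that("composition is additive over any two-way split", {
  set.seed(61)
  seq <- oracle_random_dna(500, gc = 0.3)
  whole <- base_composition(seq)
  for (cut in c(1, 100, 499)) {
    left <- base_composition(substr(seq, 1, cut))
    right <- base_composition(substr(seq, cut + 1, 500))
    expect_identical(whole$counts, left$counts + right$counts)
  }
})

test_that("region partition assigns every position once under the precedence rule", {
  # one 300-bp CDS on a 1-kb circle
  g <- mito_genome("P1", oracle_random_dna(1000), "circular", list(
    gene_feature("cox1", "CDS", "+", matrix(c(101, 400), 1))))
  p <- partition_regions(g)
  expect_equal(p$totals[["protein_coding_exon"]], 300)
  expect_equal(p$totals[["intergenic"]], 700)
  expect_equal(sum(p$totals), 1000)

  # a CDS with a 100-bp intron: intronic counted, not double-counted
  g2 <- mito_genome("P2", oracle_random_dna(1000), "circular", list(
    gene_feature("cob", "CDS", "+",
                 matrix(c(101, 200, 301, 400), 2, byrow = TRUE))))
  p2 <- partition_regions(g2)
  expect_equal(p2$totals[["protein_coding_exon"]], 200)
  expect_equal(p2$totals[["intronic"]], 100)
  expect_equal(sum(p2$totals), 1000)

  # two CDS overlapping by 19 bp: overlap counted once
  g3 <- mito_genome("P3", oracle_random_dna(1000), "circular", list(
    gene_feature("cox3", "CDS", "+", matrix(c(101, 400), 1)),
    gene_feature("orf201", "CDS", "+", matrix(c(382, 700), 1))))
  p3 <- partition_regions(g3)
  expect_equal(p3$totals[["protein_coding_exon"]], 600 - 0)
  expect_equal(sum(p3$totals), 1000)

  # exon beats intron beats rRNA: tRNA inside a CDS intron is intronic
  g4 <- mito_genome("P4", oracle_random_dna(1000), "circular", list(
    gene_feature("nad5", "CDS", "+",
                 matrix(c(101, 200, 501, 600), 2, byrow = TRUE)),
    gene_feature("trnK", "tRNA", "+", matrix(c(301, 372), 1))))
  p4 <- partition_regions(g4)
  expect_equal(p4$totals[["intronic"]], 300)
  expect_equal(p4$totals[["tRNA"]], 0)
  expect_equal(sum(p4$totals), 1000)
})

test_that("partition totals equal an exhaustive position-level count on synthetic genomes", {
  panel <- build_panel(synthetic_spec(
    n_genomes = 2, genome_length = 24000, divergence = 0.01,
    intron_plan = data.frame(genome = 1:2, gene = "cox1",
                             offset = 500, length = 300),
    seed = 67))
  for (g in panel$genomes) {
    p <- partition_regions(g)
    expect_equal(sum(p$totals), g$length)
    # independent position-level tally of non-intergenic coverage
    covered <- rep(FALSE, g$length)
    for (f in g$features) for (i in seq_len(nrow(f$exons))) {
      e <- f$exons[i, ]
      pos <- if (e[1] <= e[2]) e[1]:e[2] else c(e[1]:g$length, 1:e[2])
      covered[pos] <- TRUE
    }
    # intergenic + intronic positions are exactly the uncovered ones
    # plus intron interiors; exon-category totals match coverage
    exonic <- p$totals[["protein_coding_exon"]] + p$totals[["rRNA"]] +
      p$totals[["tRNA"]] + p$totals[["rnpB"]]
    expect_equal(exonic, sum(covered))
  }
})

test_that("contribution rates follow the size-difference formula and sum to 100", {
  mk <- function(id, totals) {
    structure(list(totals = totals, genome_length = sum(totals),
                   genome_id = id), class = "RegionPartition")
  }
  base <- c(protein_coding_exon = 10000, intronic = 2000, rRNA = 3000,
            tRNA = 1500, rnpB = 300, intergenic = 3200)
  # only intergenic grows
  only <- base; only["intergenic"] <- only["intergenic"] + 1000
  r <- contribution_rates(mk("s", base), mk("l", only))
  expect_equal(r[["intergenic"]], 100)
  expect_equal(sum(abs(r[setdiff(names(r), "intergenic")])), 0)

  # mixed growth mirroring an intron-driven genome expansion
  grown <- base + c(956, 8148, 0, 0, 10, 906)
  grown["rnpB"] <- base[["rnpB"]] - 10  # one category shrinks
  grown["protein_coding_exon"] <- base[["protein_coding_exon"]] + 956
  grown["intronic"] <- base[["intronic"]] + 8148
  grown["intergenic"] <- base[["intergenic"]] + 906
  grown["rRNA"] <- base[["rRNA"]]; grown["tRNA"] <- base[["tRNA"]]
  r2 <- contribution_rates(mk("s", base), mk("l", grown))
  expect_equal(r2[["intronic"]], 81.48)
  expect_equal(r2[["protein_coding_exon"]], 9.56)
  expect_equal(r2[["intergenic"]], 9.06)
  expect_equal(r2[["rnpB"]], -0.10)
  expect_equal(sum(r2), 100)

  # argument order is irrelevant and equal lengths are rejected
  expect_equal(contribution_rates(mk("l", grown), mk("s", base)), r2)
  expect_error(contribution_rates(mk("a", base), mk("b", base)),
               "undefined")
})

test_that("contribution rates sum to 100 for every generated genome pair", {
  panel <- build_panel(synthetic_spec(
    n_genomes = 3, genome_length = 24000, divergence = 0.05,
    intron_plan = data.frame(genome = 2, gene = "cox1", offset = 400,
                             length = 2500),
    seed = 71))
  parts <- lapply(panel$genomes, partition_regions)
  for (i in 1:2) for (j in (i + 1):3) {
    if (parts[[i]]$genome_length == parts[[j]]$genome_length) next
    expect_equal(sum(contribution_rates(parts[[i]], parts[[j]])), 100,
                 tolerance = 1e-9)
  }
})

test_that("codon usage counts codons on the mRNA strand with stops tallied apart", {
  cu <- codon_counts(list("ATGTGTTAA"))
  tab <- cu$table
  expect_equal(tab$count[tab$codon == "ATG"], 1)
  expect_equal(tab$count[tab$codon == "TGT"], 1)
  expect_equal(sum(tab$count), 2)
  expect_equal(cu$stop_counts[["TAA"]], 1)

  empty <- codon_counts(list())
  expect_equal(sum(empty$table$count), 0)

  set.seed(73)
  cds <- random_test_cds(333)
  cu2 <- codon_counts(list(cds))
  expect_equal(sum(cu2$table$frequency), 1, tolerance = 1e-9)
  # TGA is tryptophan under code 4, never a stop here
  expect_identical(cu2$table$aa[cu2$table$codon == "TGA"], "W")

  # codons containing N are skipped and tallied
  cu3 <- codon_counts(list("ATGANTTAA"))
  expect_equal(cu3$n_skipped, 1)
  expect_equal(sum(cu3$table$count), 1)
})

test_that("start/stop table reports first and last codons verbatim", {
  mk_genome <- function(id, starts) {
    feats <- list()
    seqs <- character(0)
    pos <- 0
    for (i in seq_along(starts)) {
      nt <- paste0(starts[i], "CCTGGT", c("TAA", "TAG")[2 - i %% 2])
      feats[[i]] <- gene_feature(c("cox1", "cox2")[i], "CDS", "+",
                                 matrix(c(pos + 1, pos + nchar(nt)), 1))
      seqs <- c(seqs, nt)
      pos <- pos + nchar(nt)
    }
    mito_genome(id, paste(seqs, collapse = ""), "circular", feats)
  }
  g1 <- mk_genome("G1", c("ATG", "GTG"))
  g2 <- mk_genome("G2", c("TTG", "ATG"))
  tab <- start_stop_table(list(g1, g2), c("cox1", "cox2", "rps3"))
  expect_identical(tab$start_codon[tab$genome_id == "G1" &
                                     tab$gene == "cox2"], "GTG")
  expect_identical(tab$start_codon[tab$genome_id == "G2" &
                                     tab$gene == "cox1"], "TTG")
  expect_identical(tab$stop_codon[tab$genome_id == "G1" &
                                    tab$gene == "cox1"], "TAA")
  # absent gene flagged, not an error
  expect_false(any(tab$present[tab$gene == "rps3"]))
})
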