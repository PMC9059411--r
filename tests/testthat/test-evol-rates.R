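test_that("K2P distance matches closed-form hand values and the ape oracle", {
  ident <- k2p_distance(list(a_row = "ACGTACGT", b_row = "ACGTACGT"))
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  expect_equal(ident$k2p, 0)

  ts <- k2p_distance(list(a_row = "AAAA", b_row = "AAAG"))
  expect_equal(ts$P, 0.25)
  expect_equal(ts$Q, 0)
  expect_equal(ts$k2p, -0.5 * log(1 - 2 * 0.25), tolerance = 1e-4)

  tv <- k2p_distance(list(a_row = "AAAA", b_row = "AAAC"))
  expect_equal(tv$P, 0)
  expect_equal(tv$Q, 0.25)
  expect_equal(tv$k2p,
               -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.5),
               tolerance = 1e-4)

  # independent oracle: ape::dist.dna(model = "K80") on random pairs
  set.seed(81)
  for (k in 1:10) {
    x <- oracle_random_dna(600)
    y <- mutate_k2p(x, runif(1, 0.01, 0.4), kappa = 2, seed = k)
    ours <- k2p_distance(list(a_row = x, b_row = y))$k2p
    bin <- ape::as.DNAbin(rbind(a = strsplit(x, "")[[1]],
                                b = strsplit(y, "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("gap and N columns are excluded pairwise and saturation is flagged", {
  d <- k2p_distance(list(a_row = "AC-GTN", b_row = "ACAGTA"))
  expect_equal(d$n_sites, 4)
  expect_error(k2p_distance(list(a_row = "---", b_row = "AAA")),
               "comparable")
  sat <- k2p_distance(list(a_row = "ACGTACGT", b_row = "CATGCATG"))
  expect_true(sat$saturated)
  expect_identical(sat$k2p, Inf)
})

test_that("K2P distance is monotone in P and Q where defined", {
  base <- strrep("A", 100)
  d_of <- function(nts, ntv) {
    b <- c(rep("G", nts), rep("C", ntv), rep("A", 100 - nts - ntv))
    k2p_distance(list(a_row = base, b_row = paste(b, collapse = "")))$k2p
  }
  expect_true(d_of(10, 5) < d_of(15, 5))
  expect_true(d_of(10, 5) < d_of(10, 10))
})

test_that("NG86 synonymy agrees with the code-4 translation oracle on all one-step codon pairs", {
  code4 <- Biostrings::getGeneticCode("4")
  env_codons <- names(code4)
  stops <- env_codons[code4 == "*"]
  bases <- c("A", "C", "G", "T")
  for (c1 in env_codons) {
    if (c1 %in% stops) next
    for (p in 1:3) for (b in setdiff(bases, substr(c1, p, p))) {
      c2 <- c1
      substr(c2, p, p) <- b
      if (c2 %in% stops) next
      # pad with identical context so p never saturates
      ctx <- strrep("GGT", 30)
      kk <- ng86_ka_ks(list(a_row = paste0(ctx, c1),
                            b_row = paste0(ctx, c2)))
      is_syn <- code4[[c1]] == code4[[c2]]
      expect_equal(kk$syn_diffs, as.numeric(is_syn),
                   info = paste(c1, c2))
      expect_equal(kk$nonsyn_diffs, as.numeric(!is_syn),
                   info = paste(c1, c2))
    }
  }
})

test_that("TGA/TGG is a synonymous difference under code 4 but not the standard code", {
  ctx <- strrep("GGT", 30)
  aln <- list(a_row = paste0(ctx, "TGA"), b_row = paste0(ctx, "TGG"))
  kk4 <- ng86_ka_ks(aln)
  expect_equal(kk4$syn_diffs, 1)
  expect_equal(kk4$ka, 0)
  expect_gt(kk4$ks, 0)
  # under the standard code TGA is a stop and the codon pair is skipped
  kk1 <- ng86_ka_ks(aln, genetic_code = Biostrings::getGeneticCode("1"))
  expect_equal(kk1$syn_diffs + kk1$nonsyn_diffs, 0)
})

test_that("identical coding sequences give ka = ks = 0 with a null ratio", {
  set.seed(83)
  nt <- random_test_cds(50)
  aln <- codon_aware_align(as_cds(nt), as_cds(nt))
  kk <- ng86_ka_ks(aln)
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_true(is.na(kk$ka_ks))
})

test_that("NG86 site counts conserve: S + N = 3 x counted codons", {
  set.seed(87)
  for (k in 1:5) {
    x <- random_test_cds(60)
    y <- mutate_k2p(x, 0.05, seed = k)
    aln <- list(a_row = x, b_row = y)
    kk <- tryCatch(ng86_ka_ks(aln), error = function(e) NULL)
    if (is.null(kk)) next
    expect_equal(kk$syn_sites + kk$nonsyn_sites, 3 * kk$n_codons,
                 tolerance = 1e-9)
  }
})

test_that("synonymous-only divergence yields ka = 0 and nonsynonymous bias drives ka/ks above 1", {
  set.seed(89)
  nt <- random_test_cds(200)
  cods <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  body <- seq(2, length(cods) - 1)

  # synonymous mask: third-position changes that preserve the residue
  syn <- cods
  for (i in body) {
    alts <- paste0(substr(cods[i], 1, 2), c("A", "C", "G", "T"))
    alts <- alts[vapply(alts, translate_cds, "") ==
                   translate_cds(cods[i]) & !alts %in% c("TAA", "TAG") &
                   alts != cods[i]]
    if (length(alts) > 0 && runif(1) < 0.5) syn[i] <- sample(alts, 1)
  }
  kk_syn <- ng86_ka_ks(codon_aware_align(
    as_cds(nt), as_cds(paste(syn, collapse = ""))))
  expect_equal(kk_syn$ka, 0)
  expect_gt(kk_syn$ks, 0)

  # nonsynonymous-biased mask: many residue-changing substitutions and
  # exactly two synonymous ones (a nonzero Ks keeps the ratio defined)
  nonsyn <- cods
  for (i in body) {
    alts <- c(paste0(c("A", "C", "G", "T"), substr(cods[i], 2, 3)))
    alts <- alts[vapply(alts, translate_cds, "") !=
                   translate_cds(cods[i]) & !alts %in% c("TAA", "TAG")]
    if (length(alts) > 0 && runif(1) < 0.3) nonsyn[i] <- sample(alts, 1)
  }
  n_syn_added <- 0
  for (i in body) {
    if (n_syn_added >= 2) break
    if (nonsyn[i] != cods[i]) next
    alts <- paste0(substr(cods[i], 1, 2), c("A", "C", "G", "T"))
    alts <- alts[vapply(alts, translate_cds, "") ==
                   translate_cds(cods[i]) & !alts %in% c("TAA", "TAG") &
                   alts != cods[i]]
    if (length(alts) > 0) {
      nonsyn[i] <- alts[1]
      n_syn_added <- n_syn_added + 1
    }
  }
  kk_non <- ng86_ka_ks(codon_aware_align(
    as_cds(nt), as_cds(paste(nonsyn, collapse = ""))))
  expect_gt(kk_non$ka_ks, 1)
})

test_that("simulated K2P divergence is re-estimated with small bias", {
  set.seed(97)
  anc <- oracle_random_dna(10000, gc = 0.35)
  for (d in c(0.01, 0.05, 0.2)) {
    ests <- vapply(1:20, function(r) {
      a <- mutate_k2p(anc, d / 2, kappa = 2, seed = round(1000 * d) + r)
      b <- mutate_k2p(anc, d / 2, kappa = 2, seed = round(2000 * d) + r)
      k2p_distance(list(a_row = a, b_row = b))$k2p
    }, 0)
    expect_lt(abs(mean(ests) - d) / d, 0.05)
  }
})

test_that("panel summaries average unordered pairs and handle planted divergence", {
  # identical panel: all means zero
  p0 <- build_panel(synthetic_spec(n_genomes = 3, genome_length = 23500,
                                   divergence = 0, seed = 101))
  s0 <- panel_rate_summary(p0$genomes, "cox1")
  expect_equal(s0$mean_k2p, 0)
  expect_equal(s0$mean_ka, 0)
  expect_equal(s0$n_pairs, 3)

  # planted pairwise divergence recovered within Monte-Carlo noise
  p1 <- build_panel(synthetic_spec(n_genomes = 3, genome_length = 23500,
                                   divergence = 0.05, seed = 103))
  s1 <- panel_rate_summary(p1$genomes, "nad5")
  # binomial SE of the K2P estimate on a 1980-nt gene is ~0.005
  expect_lt(abs(s1$mean_k2p - 0.05), 3 * 0.005)
  expect_error(panel_rate_summary(p1$genomes[1], "cox1"), "fewer than 2")
})
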