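# Independent oracles used across the suite. Deliberately written as
# different algorithms from the package implementations.

# three-matrix affine-gap global alignment DP, scores only; the package
# delegates alignment to Biostrings, so this is an independent check.
# Convention: gap of length L costs open + L * extend.
oracle_align_score <- function(a, b, params = align_params()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  sub <- function(x, y) {
    if (x == "N" || y == "N") 0
    else if (x == y) params$match else params$mismatch
  }
  M <- matrix(NEG, n + 1, m + 1)   # last column: aligned pair
  GA <- matrix(NEG, n + 1, m + 1)  # last column: gap in a (consumes b)
  GB <- matrix(NEG, n + 1, m + 1)  # last column: gap in b (consumes a)
  M[1, 1] <- 0
  if (m > 0) for (j in 2:(m + 1))
    GA[1, j] <- params$gap_open + (j - 1) * params$gap_extend
  if (n > 0) for (i in 2:(n + 1))
    GB[i, 1] <- params$gap_open + (i - 1) * params$gap_extend
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    s <- sub(av[i - 1], bv[j - 1])
    M[i, j] <- max(M[i - 1, j - 1], GA[i - 1, j - 1], GB[i - 1, j - 1]) + s
    GA[i, j] <- max(M[i, j - 1] + params$gap_open + params$gap_extend,
                    GA[i, j - 1] + params$gap_extend,
                    GB[i, j - 1] + params$gap_open + params$gap_extend)
    GB[i, j] <- max(M[i - 1, j] + params$gap_open + params$gap_extend,
                    GB[i - 1, j] + params$gap_extend,
                    GA[i - 1, j] + params$gap_open + params$gap_extend)
  }
  max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
}

oracle_random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# adjacency set of a circular order by explicit enumeration
oracle_adjacencies <- function(genes) {
  n <- length(genes)
  out <- character(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pair <- sort(c(genes[i], genes[j]))
    out <- c(out, paste(pair[1], pair[2]))
  }
  unique(out)
}

oracle_breakpoints <- function(a, b) {
  length(setdiff(oracle_adjacencies(a), oracle_adjacencies(b)))
}

# random unrooted tree with strictly positive branch lengths and its
# additive leaf-to-leaf distance matrix
oracle_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  D <- cophenetic(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(tree = tr, D = D)
}

# a CodingSequence object from a raw nt string
as_cds <- function(nt, gene = "toy", genome_id = "X",
                   intron_offsets = integer(0)) {
  structure(list(gene = gene, genome_id = genome_id, nt = nt,
                 aa = translate_cds(nt), intron_offsets = intron_offsets,
                 partial = FALSE, internal_stop = FALSE),
            class = "CodingSequence")
}

# random stop-free CDS of n_codons (including ATG start and TAA stop)
random_test_cds <- function(n_codons, gc = 0.4) {
  body <- character(n_codons - 2)
  for (i in seq_along(body)) {
    repeat {
      c3 <- oracle_random_dna(3, gc)
      if (!c3 %in% c("TAA", "TAG")) break
    }
    body[i] <- c3
  }
  paste0("ATG", paste(body, collapse = ""), "TAA")
}
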