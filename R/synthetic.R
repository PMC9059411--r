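# Synthetic annotated mitogenome panels with recorded ground truth.
#
# Genomes are built from a layout (ordered gene and spacer elements),
# so planted mutations, introns, repeats and gene relocations stay
# coordinate-consistent: the genome sequence and feature table are
# assembled from the layout in one pass.

# typical core-gene lengths (bp, multiples of 3 for CDS) loosely
# matching conserved basidiomycete mitogenomes
default_gene_table <- function() {
  cds <- c(atp6 = 750, atp8 = 150, atp9 = 225, cob = 1170, cox1 = 1593,
           cox2 = 750, cox3 = 810, nad1 = 975, nad2 = 1650, nad3 = 360,
           nad4 = 1470, nad4L = 270, nad5 = 1980, nad6 = 600, rps3 = 1350)
  aa1 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")
  trna <- setNames(rep(72L, 22L),
                   c(paste0("trn", aa1), "trnS2", "trnL2"))
  rbind(
    data.frame(name = names(cds), ftype = "CDS", length = unname(cds),
               stringsAsFactors = FALSE),
    data.frame(name = c("rnl", "rns"), ftype = "rRNA",
               length = c(3000L, 1500L), stringsAsFactors = FALSE),
    data.frame(name = "rnpB", ftype = "rnpB", length = 350L,
               stringsAsFactors = FALSE),
    data.frame(name = names(trna), ftype = "tRNA", length = unname(trna),
               stringsAsFactors = FALSE))
}

#' Specification of a synthetic mitogenome panel
#'
#' Defaults emulate the compared basidiomycete panels: a circular
#' genome around 30 kb carrying the 15 core PCGs, two rRNAs, rnpB and
#' 22 tRNAs at ~35% GC, with pairwise sequence divergence `divergence`
#' substitutions/site under a K2P process with transition/transversion
#' rate ratio `kappa`.
#'
#' @param n_genomes number of genomes in the panel
#' @param genome_length target genome length (bp)
#' @param gene_table data.frame name/ftype/length describing the gene
#'   complement
#' @param divergence expected pairwise substitutions/site between any
#'   two panel genomes (each genome sits at `divergence/2` from the
#'   common ancestor)
#' @param kappa transition/transversion rate ratio (> 0)
#' @param indel_rate per-codon probability of a codon insertion or
#'   deletion in CDS bodies
#' @param gc target GC fraction of generated sequence
#' @param intron_plan data.frame genome/gene/offset/length: plant an
#'   intron of `length` bp into `gene` of panel genome number `genome`,
#'   inserting after spliced-CDS position `offset` of the ancestor
#' @param repeat_plan data.frame genome/length/identity/strandedness:
#'   plant an interspersed repeat pair into intergenic spacers
#' @param order_moves number of random gene relocations per genome
#' @param seed RNG seed; every realization is reproducible from it
#' @return object of class `SyntheticSpec`
#' @export
synthetic_spec <- function(n_genomes = 5L, genome_length = 30000L,
                           gene_table = default_gene_table(),
                           divergence = 0.05, kappa = 2,
                           indel_rate = 0, gc = 0.35,
                           intron_plan = NULL, repeat_plan = NULL,
                           order_moves = 0L, seed = 1L) {
  stopifnot(divergence >= 0, kappa > 0, indel_rate >= 0, indel_rate < 1,
            gc > 0, gc < 1, n_genomes >= 1L)
  if (!is.null(intron_plan)) {
    stopifnot(all(c("genome", "gene", "offset", "length") %in%
                    names(intron_plan)))
    for (r in seq_len(nrow(intron_plan))) {
      len <- gene_table$length[gene_table$name == intron_plan$gene[r]]
      if (length(len) != 1L || intron_plan$offset[r] < 1L ||
          intron_plan$offset[r] >= len)
        stop("intron_plan row ", r, ": offset outside gene")
    }
  }
  if (!is.null(repeat_plan))
    stopifnot(all(c("genome", "length", "identity", "strandedness") %in%
                    names(repeat_plan)))
  structure(list(n_genomes = as.integer(n_genomes),
                 genome_length = as.integer(genome_length),
                 gene_table = gene_table, divergence = divergence,
                 kappa = kappa, indel_rate = indel_rate, gc = gc,
                 intron_plan = intron_plan, repeat_plan = repeat_plan,
                 order_moves = as.integer(order_moves),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

random_dna <- function(n, gc = 0.35) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random CDS of n_codons total (ATG start, TAA stop, stop-free body)
random_cds <- function(n_codons, gc = 0.35) {
  body <- n_codons - 2L
  cods <- character(body)
  for (i in seq_len(body)) {
    repeat {
      c3 <- random_dna(3L, gc)
      if (!c3 %in% c("TAA", "TAG")) break
    }
    cods[i] <- c3
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}

# K2P per-site substitution probabilities at distance d
k2p_site_probs <- function(d, kappa) {
  at <- d * kappa / (kappa + 2)   # alpha * t
  bt <- d / (kappa + 2)           # beta * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)  # both transversion targets together
  c(ts = p_ts, tv = p_tv)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# mutate a character vector of bases in place under K2P (no seeding)
mutate_chars <- function(v, d, kappa) {
  if (d == 0 || length(v) == 0L) return(v)
  pr <- k2p_site_probs(d, kappa)
  u <- runif(length(v))
  ts <- u < pr[["ts"]]
  tv <- !ts & u < pr[["ts"]] + pr[["tv"]]
  if (any(ts)) v[ts] <- TS_PARTNER[v[ts]]
  if (any(tv)) {
    which_tv <- which(tv)
    pick <- runif(length(which_tv)) < 0.5
    v[which_tv] <- vapply(seq_along(which_tv), function(k)
      TV_PARTNERS[[v[which_tv[k]]]][if (pick[k]) 1L else 2L], "")
  }
  v
}

#' Mutate a sequence under the K2P substitution process
#'
#' Per-site substitutions are drawn so the expected number of
#' substitutions per site equals `d`, with transition:transversion rate
#' ratio `kappa`. Deterministic for a given seed.
#'
#' @param seq DNA string
#' @param d branch length in expected substitutions/site
#' @param kappa transition/transversion rate ratio
#' @param seed RNG seed
#' @return mutated DNA string
#' @export
mutate_k2p <- function(seq, d, kappa = 2, seed = 1L) {
  check_dna(seq)
  with_seed(seed, paste(mutate_chars(.chars(seq), d, kappa), collapse = ""))
}

# mutate a CDS body codon-wise, resampling draws that create stops
mutate_cds_body <- function(cods, d, kappa) {
  if (d == 0 || length(cods) == 0L) return(cods)
  v <- mutate_chars(.chars(paste(cods, collapse = "")), d, kappa)
  out <- .codons(paste(v, collapse = ""))
  bad <- which(out %in% c("TAA", "TAG"))
  for (i in bad) {
    for (try in 1:20) {
      c3 <- paste(mutate_chars(.chars(cods[i]), d, kappa), collapse = "")
      if (!c3 %in% c("TAA", "TAG")) { out[i] <- c3; break }
      if (try == 20L) out[i] <- cods[i]  # give up: keep ancestral codon
    }
  }
  out
}

# --- panel construction ------------------------------------------------

#' Generate a synthetic mitogenome panel with ground truth
#'
#' Builds a common ancestor with the specified gene complement, then
#' derives each panel genome by codon-aware K2P mutation of CDS bodies
#' (start and terminal stop codons are held fixed and no internal stop
#' is introduced), unconstrained mutation of non-coding sequence,
#' optional codon indels, planted introns (annotated as multi-exon
#' features), planted interspersed repeats, and random gene
#' relocations. Every realization is recorded in the returned truth
#' object.
#'
#' @param spec a `SyntheticSpec`
#' @return list of class `SyntheticPanel`: `genomes` (list of
#'   `MitoGenome`), `truth` (ancestor sequences plus per-genome realized
#'   orders, intron sites, substitution counts and repeat positions),
#'   `spec`
#' @export
build_panel <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  with_seed(spec$seed, build_panel_impl(spec))
}

build_panel_impl <- function(spec) {
  gt <- spec$gene_table
  n_genes <- nrow(gt)
  gene_total <- sum(gt$length)
  spacer_total <- spec$genome_length - gene_total
  if (spacer_total < n_genes * 2L)
    stop("genome_length too small for the gene complement (need > ",
         gene_total + 2L * n_genes, " bp)")

  # ancestor: shuffled gene order, random strands
  order_idx <- sample.int(n_genes)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE,
                    prob = c(0.8, 0.2))
  anc_genes <- setNames(vector("list", n_genes), gt$name)
  for (i in seq_len(n_genes)) {
    anc_genes[[gt$name[i]]] <- if (gt$ftype[i] == "CDS")
      random_cds(gt$length[i] %/% 3L, spec$gc)
    else random_dna(gt$length[i], spec$gc)
  }
  mu_spacer <- spacer_total / n_genes
  sp_lens <- pmax(2L, as.integer(rnbinom(n_genes, mu = mu_spacer,
                                         size = 4L)))
  anc_spacers <- lapply(sp_lens, random_dna, gc = spec$gc)
  ancestor <- list(order = gt$name[order_idx],
                   strands = setNames(strands, gt$name[order_idx]),
                   genes = anc_genes,
                   spacers = anc_spacers,
                   ftypes = setNames(gt$ftype, gt$name))

  genomes <- vector("list", spec$n_genomes)
  truth_genomes <- vector("list", spec$n_genomes)
  for (gi in seq_len(spec$n_genomes)) {
    id <- sprintf("SYN%02d", gi)
    res <- derive_genome(id, gi, ancestor, spec)
    genomes[[gi]] <- res$genome
    truth_genomes[[gi]] <- res$truth
  }
  structure(list(genomes = genomes,
                 truth = list(schema_version = "1.0",
                              ancestor = ancestor,
                              genomes = truth_genomes),
                 spec = spec),
            class = "SyntheticPanel")
}

derive_genome <- function(id, gi, ancestor, spec) {
  branch <- spec$divergence / 2
  plan_i <- if (!is.null(spec$intron_plan))
    spec$intron_plan[spec$intron_plan$genome == gi, , drop = FALSE]
  else NULL
  elements <- list()
  truth_introns <- list()
  subs <- integer(0)

  slot_no <- 0L
  for (name in ancestor$order) {
    slot_no <- slot_no + 1L
    ftype <- ancestor$ftypes[[name]]
    anc_nt <- ancestor$genes[[name]]
    gplan <- if (!is.null(plan_i))
      plan_i[plan_i$gene == name, , drop = FALSE] else NULL
    if (ftype == "CDS") {
      cods <- .codons(anc_nt)
      body <- cods[2:(length(cods) - 1L)]
      mut <- mutate_cds_body(body, branch, spec$kappa)
      nsub <- sum(.chars(paste(body, collapse = "")) !=
                    .chars(paste(mut, collapse = "")))
      # codon indels, protecting codons holding planted intron sites
      protected <- if (!is.null(gplan) && nrow(gplan) > 0L)
        unique(ceiling(gplan$offset / 3) - 1L) else integer(0)  # body index
      ind <- apply_codon_indels(mut, spec$indel_rate, protected, spec$gc)
      nt <- paste0(cods[1L], paste(ind$codons, collapse = ""),
                   cods[length(cods)])
      # realized spliced offsets of planted introns
      pieces <- list(nt)
      offs <- integer(0)
      anc_offs <- integer(0)
      if (!is.null(gplan) && nrow(gplan) > 0L) {
        gplan <- gplan[order(gplan$offset), , drop = FALSE]
        real <- vapply(gplan$offset, function(k) {
          body_codon <- ceiling(k / 3) - 1L  # codon index within body
          # indels strictly before the codon holding the site shift it
          as.integer(k + 3L * ind$shift_before(body_codon - 1L))
        }, 1L)
        pieces <- split_at(nt, real)
        introns <- vapply(gplan$length, function(L)
          random_dna(L, spec$gc), "")
        pieces <- interleave(pieces, introns)
        offs <- real
        anc_offs <- gplan$offset
        for (k in seq_along(real))
          truth_introns[[length(truth_introns) + 1L]] <- list(
            gene = name, ancestor_offset = gplan$offset[k],
            realized_offset = real[k], length = gplan$length[k])
      }
      elements[[length(elements) + 1L]] <- list(
        kind = "gene", name = name, ftype = "CDS",
        strand = ancestor$strands[[name]], pieces = pieces)
      subs[name] <- nsub
    } else {
      v <- mutate_chars(.chars(anc_nt), branch, spec$kappa)
      nt <- paste(v, collapse = "")
      subs[name] <- sum(v != .chars(anc_nt))
      pieces <- list(nt)
      if (!is.null(gplan) && nrow(gplan) > 0L) {
        gplan <- gplan[order(gplan$offset), , drop = FALSE]
        pieces <- split_at(nt, gplan$offset)
        introns <- vapply(gplan$length, function(L)
          random_dna(L, spec$gc), "")
        pieces <- interleave(pieces, introns)
        for (k in seq_len(nrow(gplan)))
          truth_introns[[length(truth_introns) + 1L]] <- list(
            gene = name, ancestor_offset = gplan$offset[k],
            realized_offset = gplan$offset[k], length = gplan$length[k])
      }
      elements[[length(elements) + 1L]] <- list(
        kind = "gene", name = name, ftype = ftype,
        strand = ancestor$strands[[name]], pieces = pieces)
    }
    # spacer after each gene: the ancestral spacer, mutated
    sp <- paste(mutate_chars(.chars(ancestor$spacers[[slot_no]]),
                             branch, spec$kappa), collapse = "")
    elements[[length(elements) + 1L]] <- list(kind = "spacer", nt = sp)
  }

  # gene relocations
  moved <- character(0)
  if (spec$order_moves > 0L) {
    gene_slots <- which(vapply(elements, function(e) e$kind == "gene", TRUE))
    pick <- sample(gene_slots, min(spec$order_moves, length(gene_slots)))
    for (slot in pick) {
      el <- elements[[slot]]
      moved <- c(moved, el$name)
      elements <- elements[-slot]
      at <- sample.int(length(elements) + 1L, 1L)
      elements <- append(elements, list(el), after = at - 1L)
      gene_slots <- which(vapply(elements, function(e) e$kind == "gene", TRUE))
    }
  }

  # planted repeats: pairs of (near-)identical segments in two spacers
  rep_truth <- list()
  rplan <- if (!is.null(spec$repeat_plan))
    spec$repeat_plan[spec$repeat_plan$genome == gi, , drop = FALSE]
  else NULL
  if (!is.null(rplan) && nrow(rplan) > 0L) {
    spacer_slots <- which(vapply(elements, function(e)
      e$kind == "spacer", TRUE))
    for (r in seq_len(nrow(rplan))) {
      seg <- random_dna(rplan$length[r], spec$gc)
      copy <- seg
      nmut <- round(nchar(seg) * (100 - rplan$identity[r]) / 100)
      if (nmut > 0L) {
        v <- .chars(copy)
        at <- sample.int(length(v), nmut)
        v[at] <- vapply(v[at], function(b)
          sample(setdiff(DNA_BASES, b), 1L), "")
        copy <- paste(v, collapse = "")
      }
      if (rplan$strandedness[r] == "inverted") copy <- revcomp(copy)
      slots <- sample(spacer_slots, 2L)
      marks <- list(list(slot = slots[1L], seg = seg),
                    list(slot = slots[2L], seg = copy))
      for (m in marks) {
        e <- elements[[m$slot]]
        # append at the spacer end so earlier marks keep their offsets
        off <- nchar(e$nt) + 1L
        e$nt <- paste0(e$nt, m$seg)
        e$marks <- c(e$marks, list(list(offset = off,
                                        length = nchar(m$seg))))
        elements[[m$slot]] <- e
      }
      rep_truth[[length(rep_truth) + 1L]] <- list(
        length = rplan$length[r], identity = rplan$identity[r],
        strandedness = rplan$strandedness[r])
    }
  }

  asm <- assemble_layout(id, elements)
  realized_order <- asm$order
  truth <- list(id = id,
                order = realized_order,
                moved = moved,
                introns = truth_introns,
                substitutions = as.list(subs),
                repeats = asm$marks,
                length = asm$genome$length)
  list(genome = asm$genome, truth = truth)
}

# split a string after the given offsets
split_at <- function(nt, offsets) {
  bounds <- c(0L, offsets, nchar(nt))
  lapply(seq_len(length(bounds) - 1L), function(i)
    substr(nt, bounds[i] + 1L, bounds[i + 1L]))
}

# interleave exon pieces with introns: e1 i1 e2 i2 ... en
interleave <- function(exons, introns) {
  out <- list()
  for (i in seq_along(exons)) {
    out[[length(out) + 1L]] <- exons[[i]]
    if (i <= length(introns)) out[[length(out) + 1L]] <- introns[[i]]
  }
  out
}

# apply codon insertions/deletions; returns new codon list and a
# function giving the net codon shift before a body-codon index
apply_codon_indels <- function(cods, rate, protected, gc) {
  if (rate == 0 || length(cods) == 0L) {
    return(list(codons = cods, shift_before = function(i) 0L))
  }
  events <- integer(0)  # +index = insertion after, -index = deletion
  out <- list()
  shifts <- numeric(0)
  for (i in seq_along(cods)) {
    u <- runif(1L)
    if (u < rate / 2 && !(i %in% protected)) {
      events <- c(events, -i)  # deletion
      next
    }
    out[[length(out) + 1L]] <- cods[i]
    if (u >= rate / 2 && u < rate) {
      repeat {
        c3 <- random_dna(3L, gc)
        if (!c3 %in% c("TAA", "TAG")) break
      }
      out[[length(out) + 1L]] <- c3
      events <- c(events, i)
    }
  }
  list(codons = unlist(out),
       shift_before = function(i) {
         if (i < 1L) return(0L)
         sum(events > 0L & events <= i) - sum(events < 0L & -events <= i)
       })
}

# assemble a MitoGenome (and truth bookkeeping) from a layout
assemble_layout <- function(id, elements) {
  seq_parts <- character(0)
  features <- list()
  marks <- list()
  order <- list()
  pos <- 0L
  for (e in elements) {
    if (e$kind == "spacer") {
      if (!is.null(e$marks)) for (m in e$marks)
        marks[[length(marks) + 1L]] <- list(
          start = pos + m$offset, end = pos + m$offset + m$length - 1L)
      seq_parts <- c(seq_parts, e$nt)
      pos <- pos + nchar(e$nt)
      next
    }
    lens <- nchar(unlist(e$pieces))
    F <- sum(lens)
    frag_tx <- paste(unlist(e$pieces), collapse = "")
    frag <- if (e$strand == "+") frag_tx else revcomp(frag_tx)
    # exon pieces are the odd entries of the piece list
    exon_idx <- seq(1L, length(lens), 2L)
    cum <- cumsum(lens)
    exrows <- lapply(exon_idx, function(t) {
      tx_from <- cum[t] - lens[t] + 1L
      tx_to <- cum[t]
      if (e$strand == "+") c(pos + tx_from, pos + tx_to)
      else c(pos + F - tx_to + 1L, pos + F - tx_from + 1L)
    })
    ex <- do.call(rbind, exrows)
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    features[[length(features) + 1L]] <-
      gene_feature(e$name, e$ftype, e$strand, ex)
    order[[length(order) + 1L]] <- list(name = e$name, strand = e$strand)
    seq_parts <- c(seq_parts, frag)
    pos <- pos + F
  }
  genome <- mito_genome(id, paste(seq_parts, collapse = ""), "circular",
                        features)
  list(genome = genome,
       order = list(name = vapply(order, `[[`, "", "name"),
                    strand = vapply(order, `[[`, "", "strand")),
       marks = marks)
}

#' Write a synthetic panel to disk
#'
#' GenBank flat file (all records), one FASTA, and the truth record as
#' JSON; regenerating with the same spec yields byte-identical files.
#'
#' @param panel a `SyntheticPanel` from [build_panel()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_fixture_set <- function(panel, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  gb <- file.path(dir, "panel.gbk")
  fa <- file.path(dir, "panel.fasta")
  tj <- file.path(dir, "truth.json")
  write_genbank(panel$genomes, gb)
  write_fasta(setNames(lapply(panel$genomes, `[[`, "sequence"),
                       vapply(panel$genomes, `[[`, "", "id")), fa)
  jsonlite::write_json(panel$truth, tj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(genbank = gb, fasta = fa, truth = tj))
}
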