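# Base composition, strand skews, region partitioning with
# size-expansion contribution rates, codon usage and start/stop tables.

REGION_CATEGORIES <- c("protein_coding_exon", "intronic", "rRNA", "tRNA",
                       "rnpB", "intergenic")

#' Base composition and strand skews
#'
#' AT skew = (A - T)/(A + T) and GC skew = (G - C)/(G + C); GC content
#' is the percentage of G+C over the unambiguous bases. N bases are
#' excluded from every denominator. A zero denominator yields a skew of
#' 0 with the corresponding `*_skew_defined` flag set to `FALSE`.
#'
#' @param seq DNA string
#' @return object of class `SkewStats`: counts, `gc_content` (percent),
#'   `at_skew`, `gc_skew`, definedness flags
#' @export
base_composition <- function(seq) {
  stopifnot(nchar(seq) > 0L)
  check_dna(seq)
  v <- .chars(seq)
  counts <- vapply(c(DNA_BASES, "N"), function(b) sum(v == b), 1L)
  A <- counts[["A"]]; C <- counts[["C"]]
  G <- counts[["G"]]; T <- counts[["T"]]
  at_def <- (A + T) > 0L; gc_def <- (G + C) > 0L
  structure(list(
    counts = counts[DNA_BASES], n_ambiguous = counts[["N"]],
    gc_content = if (A + C + G + T > 0L) 100 * (G + C) / (A + C + G + T) else 0,
    at_skew = if (at_def) (A - T) / (A + T) else 0,
    gc_skew = if (gc_def) (G - C) / (G + C) else 0,
    at_skew_defined = at_def, gc_skew_defined = gc_def),
    class = "SkewStats")
}

#' @export
print.SkewStats <- function(x, ...) {
  cat(sprintf("SkewStats: GC %.2f%%, AT skew %.4f, GC skew %.4f\n",
              x$gc_content, x$at_skew, x$gc_skew))
  invisible(x)
}

# genome positions covered by the exons / introns of one feature, in
# plus-strand coordinates, honoring origin wrap
feature_positions <- function(f, L) {
  exon_pos <- integer(0)
  spans <- list()
  for (i in seq_len(nrow(f$exons))) {
    s <- f$exons[i, "start"]; e <- f$exons[i, "end"]
    p <- if (s <= e) s:e else c(s:L, 1:e)
    spans[[i]] <- p
    exon_pos <- c(exon_pos, p)
  }
  # introns: gaps between consecutive exons in transcription order
  ord <- if (f$strand == "-") rev(seq_along(spans)) else seq_along(spans)
  intron_pos <- integer(0)
  if (length(ord) > 1L) {
    for (i in seq_len(length(ord) - 1L)) {
      a <- spans[[ord[i]]]; b <- spans[[ord[i + 1L]]]
      if (f$strand == "+") {
        from <- a[length(a)] + 1L; to <- b[1L] - 1L
      } else {
        from <- b[length(b)] + 1L; to <- a[1L] - 1L
      }
      p <- if (from > L) integer(0)
      else if (from <= to) from:to
      else c(from:L, 1:to)  # intron spans the origin
      intron_pos <- c(intron_pos, p)
    }
  }
  list(exon = exon_pos, intron = intron_pos)
}

#' Partition a genome into annotation categories
#'
#' Every genomic position is assigned to exactly one category under the
#' precedence rule protein-coding exon > intron > rRNA > tRNA > rnpB >
#' intergenic (overlapping positions are counted once, in the
#' higher-precedence category). ORF CDS count as protein-coding; the
#' introns of any feature (including rRNA genes) count as intronic.
#'
#' @param genome a `MitoGenome`
#' @return object of class `RegionPartition`: named bp totals per
#'   category plus `genome_length`; totals sum to the genome length
#' @export
partition_regions <- function(genome) {
  L <- genome$length
  # rank 0 = intergenic; higher rank wins
  rank <- c(intergenic = 0L, rnpB = 1L, tRNA = 2L, rRNA = 3L,
            intronic = 4L, protein_coding_exon = 5L)
  cat_of <- rep.int(0L, L)
  assign_cat <- function(pos, r) {
    if (length(pos) == 0L) return()
    upd <- pos[rank[[r]] > cat_of[pos]]
    cat_of[upd] <<- rank[[r]]
  }
  for (f in genome$features) {
    fp <- feature_positions(f, L)
    exon_cat <- switch(f$ftype, CDS = , orf = "protein_coding_exon",
                       rRNA = "rRNA", tRNA = "tRNA", rnpB = "rnpB")
    assign_cat(fp$intron, "intronic")
    assign_cat(fp$exon, exon_cat)
  }
  totals <- vapply(REGION_CATEGORIES, function(r)
    sum(cat_of == rank[[r]]), 1L)
  structure(list(totals = totals, genome_length = L, genome_id = genome$id),
            class = "RegionPartition")
}

#' @export
print.RegionPartition <- function(x, ...) {
  cat("RegionPartition", x$genome_id, paste0("(", x$genome_length, " bp):\n"))
  pct <- 100 * x$totals / x$genome_length
  for (r in names(x$totals))
    cat(sprintf("  %-20s %8d bp  %6.2f%%\n", r, x$totals[[r]], pct[[r]]))
  invisible(x)
}

#' Contribution of each region category to a genome-size difference
#'
#' For two partitions of different total length, the contribution rate
#' of a category is (large bp - small bp) / (large length - small
#' length) x 100. The categories tile both genomes, so the rates sum to
#' exactly 100.
#'
#' @param part_small,part_large `RegionPartition` objects; `part_large`
#'   should be the larger genome (they are swapped if not)
#' @return named numeric vector of percentages, one per category
#' @export
contribution_rates <- function(part_small, part_large) {
  if (part_small$genome_length == part_large$genome_length)
    stop("contribution rates are undefined for equal genome lengths")
  if (part_small$genome_length > part_large$genome_length) {
    tmp <- part_small; part_small <- part_large; part_large <- tmp
  }
  dl <- part_large$genome_length - part_small$genome_length
  100 * (part_large$totals - part_small$totals) / dl
}

#' Codon usage over a set of coding sequences
#'
#' Codons are counted over the mRNA (plus) strand of every coding
#' sequence. The terminal stop codon of each CDS is tallied separately
#' and excluded from the 64-codon frequency normalization; codons
#' containing N are skipped and counted in `n_skipped`.
#'
#' @param cds_set list of `CodingSequence` objects (or DNA strings with
#'   length divisible by 3)
#' @param genetic_code codon-to-amino-acid map; default table 4
#' @return object of class `CodonUsageTable`: data.frame `table` with
#'   columns codon, aa, count, frequency; `stop_counts`; `n_skipped`
#' @export
codon_counts <- function(cds_set, genetic_code = CODE4) {
  all_codons <- sort(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES)[, 3:1],
                           1L, paste, collapse = ""))
  counts <- setNames(rep.int(0L, 64L), all_codons)
  stop_counts <- setNames(rep.int(0L, 2L), c("TAA", "TAG"))
  n_skipped <- 0L
  for (x in cds_set) {
    nt <- cds_nt(x)
    n <- nchar(nt)
    if (n %% 3L != 0L) nt <- substr(nt, 1L, n - n %% 3L)  # trim partials
    cod <- .codons(nt)
    if (length(cod) == 0L) next
    last <- cod[length(cod)]
    if (genetic_code[last] %in% "*") {
      stop_counts[last] <- stop_counts[last] + 1L
      cod <- cod[-length(cod)]
    }
    hasN <- grepl("N", cod, fixed = TRUE)
    n_skipped <- n_skipped + sum(hasN)
    tab <- table(cod[!hasN])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  total <- sum(counts)
  tab <- data.frame(codon = all_codons,
                    aa = unname(genetic_code[all_codons]),
                    count = unname(counts),
                    frequency = if (total > 0L) unname(counts) / total
                                else rep.int(0, 64L),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, stop_counts = stop_counts,
                 n_skipped = n_skipped, n_codons = total),
            class = "CodonUsageTable")
}

#' Start and stop codons of core genes across a genome panel
#'
#' Reports the first and last codon of each spliced CDS verbatim. A
#' missing gene is flagged absent rather than raising an error.
#'
#' @param genomes list of `MitoGenome`
#' @param core_genes gene names to report (default the 15 core PCGs)
#' @return data.frame: genome_id, gene, start_codon, stop_codon, present
#' @export
start_stop_table <- function(genomes, core_genes = CORE_PCGS) {
  rows <- list()
  for (g in genomes) for (gene in core_genes) {
    cds <- tryCatch(suppressWarnings(extract_cds(g, gene)),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <- if (is.null(cds)) {
      data.frame(genome_id = g$id, gene = gene, start_codon = NA_character_,
                 stop_codon = NA_character_, present = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      n <- nchar(cds$nt)
      data.frame(genome_id = g$id, gene = gene,
                 start_codon = substr(cds$nt, 1L, 3L),
                 stop_codon = substr(cds$nt, n - 2L, n), present = TRUE,
                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-genome composition summary table
#'
#' @param genomes list of `MitoGenome`
#' @return data.frame: genome_id, length_bp, gc_content, at_skew,
#'   gc_skew, and per-category region percentages
#' @export
composition_table <- function(genomes) {
  rows <- lapply(genomes, function(g) {
    sk <- base_composition(g$sequence)
    part <- partition_regions(g)
    pct <- setNames(as.list(100 * part$totals / part$genome_length),
                    paste0("pct_", names(part$totals)))
    cbind(data.frame(genome_id = g$id, length_bp = g$length,
                     gc_content = sk$gc_content, at_skew = sk$at_skew,
                     gc_skew = sk$gc_skew, stringsAsFactors = FALSE),
          as.data.frame(pct))
  })
  do.call(rbind, rows)
}
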