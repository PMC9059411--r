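# Data model for circular annotated mitochondrial genomes.
#
# Coordinates are 1-based inclusive throughout (GenBank convention).
# Exons of a feature are stored in genome (plus-strand ascending) order;
# transcription order is derived from the strand. On circular genomes an
# exon may wrap the origin, encoded as start > end.

#' Construct a gene feature
#'
#' @param name gene name (e.g. `"cox1"`, `"rnl"`, `"trnS"`, `"orf201"`)
#' @param ftype feature type, one of `"CDS"`, `"rRNA"`, `"tRNA"`,
#'   `"orf"`, `"rnpB"`
#' @param strand `"+"` or `"-"`
#' @param exons two-column integer matrix of `[start, end]` 1-based
#'   inclusive intervals in genome order; a row with `start > end` wraps
#'   the origin of a circular genome
#' @param product free-text product description
#' @return an object of class `GeneFeature`
#' @export
gene_feature <- function(name, ftype, strand, exons, product = "") {
  stopifnot(is_string(name), nchar(name) > 0L)
  ftype <- match.arg(ftype, c("CDS", "rRNA", "tRNA", "orf", "rnpB"))
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("feature '", name, "' has no exons")
  structure(list(name = name, ftype = ftype, strand = strand,
                 exons = exons, product = product),
            class = "GeneFeature")
}

#' Construct an annotated mitochondrial genome
#'
#' @param id accession or name, unique within a genome set
#' @param sequence uppercase DNA string over A,C,G,T,N
#' @param topology `"circular"` or `"linear"`
#' @param features list of [gene_feature()] objects
#' @return an object of class `MitoGenome`
#' @export
mito_genome <- function(id, sequence, topology = c("circular", "linear"),
                        features = list()) {
  stopifnot(is_string(id), nchar(id) > 0L, is_string(sequence))
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  check_dna(sequence, paste0("genome ", id))
  L <- nchar(sequence)
  if (L == 0L) stop("genome '", id, "' has an empty sequence")
  g <- structure(list(id = id, sequence = sequence, topology = topology,
                      features = features, length = L),
                 class = "MitoGenome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  for (f in g$features) {
    ex <- f$exons
    if (any(ex < 1L) || any(ex > g$length))
      stop("feature '", f$name, "' of genome '", g$id,
           "' has coordinates outside [1, ", g$length, "]")
    if (any(ex[, "start"] > ex[, "end"]) && g$topology != "circular")
      stop("feature '", f$name, "' wraps the origin of linear genome '",
           g$id, "'")
  }
  invisible(g)
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat(sprintf("MitoGenome %s: %d bp, %s, %d features\n",
              x$id, x$length, x$topology, length(x$features)))
  invisible(x)
}

exon_length <- function(exon, genome_length) {
  s <- exon[[1L]]; e <- exon[[2L]]
  if (s <= e) e - s + 1L else genome_length - s + 1L + e
}

feature_length <- function(f, genome_length) {
  sum(vapply(seq_len(nrow(f$exons)),
             function(i) exon_length(f$exons[i, ], genome_length), 1L))
}

# first genome coordinate of a feature (start of its first exon in
# genome order); used for ordering genes around the circle
feature_start <- function(f) f$exons[1L, "start"]

#' Extract a genomic subsequence
#'
#' 1-based inclusive coordinates; `start > end` requests a wrap through
#' the origin, allowed only on circular genomes. The minus strand
#' returns the reverse complement of the plus-strand stretch.
#'
#' @param genome a `MitoGenome`
#' @param start,end 1-based inclusive coordinates
#' @param strand `"+"` or `"-"`
#' @return DNA string
#' @export
subsequence <- function(genome, start, end, strand = "+") {
  strand <- match.arg(strand, c("+", "-"))
  L <- genome$length
  if (start < 1L || start > L || end < 1L || end > L)
    stop("coordinates (", start, ", ", end, ") outside [1, ", L, "]")
  if (start <= end) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (genome$topology != "circular")
      stop("wrap-around subsequence requested on linear genome '",
           genome$id, "'")
    s <- paste0(substr(genome$sequence, start, L),
                substr(genome$sequence, 1L, end))
  }
  if (strand == "-") revcomp(s) else s
}

# exon rows in transcription order (minus strand reads the last genome-
# order exon first)
transcription_exons <- function(f) {
  ex <- f$exons
  if (f$strand == "-") ex[rev(seq_len(nrow(ex))), , drop = FALSE] else ex
}

#' Extract a spliced coding sequence
#'
#' Concatenates the exons of the named CDS in transcription order,
#' reverse-complementing minus-strand features, translates under the
#' mold mitochondrial code (table 4) and records the spliced-CDS
#' nucleotide offsets at which introns interrupt the gene (cumulative
#' spliced exon lengths at each exon junction).
#'
#' @param genome a `MitoGenome`
#' @param gene gene name; must be annotated as CDS (or orf)
#' @return an object of class `CodingSequence` with fields `gene`,
#'   `genome_id`, `nt`, `aa`, `intron_offsets`, `partial`,
#'   `internal_stop`
#' @export
extract_cds <- function(genome, gene) {
  hit <- Filter(function(f) f$name == gene && f$ftype %in% c("CDS", "orf"),
                genome$features)
  if (length(hit) == 0L)
    stop("no CDS feature named '", gene, "' in genome '", genome$id, "'")
  f <- hit[[1L]]
  ex <- transcription_exons(f)
  pieces <- vapply(seq_len(nrow(ex)), function(i)
    subsequence(genome, ex[i, "start"], ex[i, "end"], f$strand), "")
  nt <- paste(pieces, collapse = "")
  lens <- nchar(pieces)
  offsets <- if (length(lens) > 1L) cumsum(lens)[-length(lens)] else integer(0)
  partial <- nchar(nt) %% 3L != 0L
  aa <- if (partial) {
    translate_cds(substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L))
  } else translate_cds(nt)
  body <- if (nchar(aa) > 1L) substr(aa, 1L, nchar(aa) - 1L) else ""
  internal_stop <- grepl("*", body, fixed = TRUE)
  if (internal_stop)
    warning("in-frame stop before the terminal codon in ", gene,
            " of ", genome$id, call. = FALSE)
  structure(list(gene = gene, genome_id = genome$id, nt = nt, aa = aa,
                 intron_offsets = as.integer(offsets), partial = partial,
                 internal_stop = internal_stop),
            class = "CodingSequence")
}

#' Tabulate the features of one or more genomes
#'
#' @param genomes a `MitoGenome` or list of them
#' @return data.frame with columns `genome_id`, `gene`, `ftype`,
#'   `strand`, `n_exons`, `exons` (interval list as text), `length_bp`
#' @export
features_table <- function(genomes) {
  if (inherits(genomes, "MitoGenome")) genomes <- list(genomes)
  rows <- list()
  for (g in genomes) for (f in g$features) {
    iv <- apply(f$exons, 1L, function(e) paste0(e[1L], "..", e[2L]))
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = g$id, gene = f$name, ftype = f$ftype, strand = f$strand,
      n_exons = nrow(f$exons), exons = paste(iv, collapse = ","),
      length_bp = feature_length(f, g$length), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(0), gene = character(0),
                      ftype = character(0), strand = character(0),
                      n_exons = integer(0), exons = character(0),
                      length_bp = integer(0)))
  do.call(rbind, rows)
}

#' Write a features table as TSV
#'
#' @param genomes a `MitoGenome` or list of them
#' @param path output file
#' @export
write_features_tsv <- function(genomes, path) {
  write.table(features_table(genomes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
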