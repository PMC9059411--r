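# Intron position-class (Pcl) homology: map intron insertion sites of a
# host gene (canonically cox1) onto a reference spliced CDS, name the
# classes P<nt>, and label them common or rare across a genome panel.

#' Intron insertion sites of a gene
#'
#' Offsets are cumulative spliced-CDS lengths at each exon junction, in
#' transcription order ("the intron inserts after spliced position k").
#'
#' @param genome a `MitoGenome`
#' @param gene gene name
#' @return data.frame: intron_index (1-based along the gene),
#'   spliced_offset
#' @export
intron_sites <- function(genome, gene) {
  cds <- suppressWarnings(extract_cds(genome, gene))
  data.frame(intron_index = seq_along(cds$intron_offsets),
             spliced_offset = cds$intron_offsets)
}

#' Assign introns to position classes on a reference CDS
#'
#' Each genome's spliced CDS is codon-aware-aligned to the reference;
#' every intron's spliced offset is projected through the alignment to
#' an ungapped reference position, and assignments within `tolerance`
#' nt of each other are merged into one Pcl named after the smallest
#' member offset (`P<nt>`). Introns whose insertion point projects into
#' a reference gap are flagged unmappable and reported, never silently
#' dropped.
#'
#' @param genomes list of `MitoGenome`
#' @param gene host gene name (e.g. `"cox1"`)
#' @param reference a `CodingSequence` (intronless or spliced) used as
#'   the coordinate system, e.g. the cox1 CDS of a reference species
#' @param tolerance merge radius in nt (default 0: exact aligned
#'   position)
#' @return data.frame of `PclAssignment` rows: genome_id, host_gene,
#'   intron_index, spliced_offset, ref_offset (NA if unmappable),
#'   pcl_name, mappable
#' @export
assign_pcls <- function(genomes, gene, reference, tolerance = 0L) {
  rows <- list()
  for (g in genomes) {
    cds <- tryCatch(suppressWarnings(extract_cds(g, gene)),
                    error = function(e) NULL)
    if (is.null(cds)) next
    if (length(cds$intron_offsets) == 0L) next
    aln <- codon_aware_align(cds, reference)
    for (i in seq_along(cds$intron_offsets)) {
      off <- cds$intron_offsets[i]
      ref_off <- project_site(aln, off)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g$id, host_gene = gene, intron_index = i,
        spliced_offset = off,
        ref_offset = if (is.null(ref_off)) NA_integer_ else ref_off,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(0), host_gene = character(0),
                      intron_index = integer(0), spliced_offset = integer(0),
                      ref_offset = integer(0), pcl_name = character(0),
                      mappable = logical(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$mappable <- !is.na(df$ref_offset)
  df$pcl_name <- NA_character_
  if (any(df$mappable)) {
    offs <- sort(unique(df$ref_offset[df$mappable]))
    # cluster offsets within tolerance; each cluster named by its
    # smallest member
    cluster_rep <- offs
    if (tolerance > 0L && length(offs) > 1L) {
      rep_cur <- offs[1L]
      for (k in 2L:length(offs)) {
        if (offs[k] - rep_cur <= tolerance) cluster_rep[k] <- rep_cur
        else rep_cur <- offs[k]
      }
    }
    names(cluster_rep) <- as.character(offs)
    rep_off <- cluster_rep[as.character(df$ref_offset[df$mappable])]
    df$pcl_name[df$mappable] <- paste0("P", rep_off)
    df$ref_offset[df$mappable] <- as.integer(rep_off)
  }
  df
}

# project an insertion point (after spliced position `off` of the
# ungapped a-row) onto the ungapped b-row; NULL when unmappable
project_site <- function(aln, off) {
  p <- tryCatch(project_position(aln, off), error = function(e) GAP)
  if (!is_gap(p)) return(p)
  NULL
}

#' Presence/absence Pcl matrix with common/rare labels
#'
#' A Pcl is labeled common when it occurs in strictly more than
#' `n_species / 5` of the compared species, rare otherwise.
#'
#' @param assignments data.frame from [assign_pcls()]
#' @param n_species number of species compared (defaults to the number
#'   of distinct genomes in `assignments`)
#' @return object of class `PclMatrix`: logical `matrix`
#'   (genomes x Pcls, columns ordered by reference offset), `labels`
#'   (`common`/`rare` per column), `unmappable` (per-genome counts)
#' @export
classify_common_rare <- function(assignments,
                                 n_species = length(unique(assignments$genome_id))) {
  stopifnot(n_species >= 1L)
  ok <- assignments[assignments$mappable, , drop = FALSE]
  genomes <- unique(assignments$genome_id)
  pcls <- unique(ok[order(ok$ref_offset), c("pcl_name", "ref_offset")])
  m <- matrix(FALSE, nrow = length(genomes), ncol = nrow(pcls),
              dimnames = list(genomes, pcls$pcl_name))
  for (i in seq_len(nrow(ok)))
    m[ok$genome_id[i], ok$pcl_name[i]] <- TRUE
  counts <- colSums(m)
  labels <- ifelse(counts > n_species / 5, "common", "rare")
  unmappable <- tapply(!assignments$mappable, assignments$genome_id, sum)
  structure(list(matrix = m, labels = labels, counts = counts,
                 n_species = n_species,
                 unmappable = unmappable[genomes]),
            class = "PclMatrix")
}

#' @export
print.PclMatrix <- function(x, ...) {
  cat(sprintf("PclMatrix: %d genomes x %d Pcls (%d common, %d rare)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "common"), sum(x$labels == "rare")))
  invisible(x)
}

#' Write a Pcl matrix as TSV
#'
#' Genomes in rows, Pcls in columns (1/0 presence), with a final label
#' row marking each Pcl common or rare.
#'
#' @param pcl a `PclMatrix`
#' @param path output file
#' @export
write_pcl_tsv <- function(pcl, path) {
  body <- matrix(as.character(pcl$matrix * 1L), nrow = nrow(pcl$matrix),
                 dimnames = dimnames(pcl$matrix))
  out <- rbind(body, label = pcl$labels[colnames(body)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("genome_id", colnames(body)), collapse = "\t"), con)
  for (r in rownames(out))
    writeLines(paste(c(r, out[r, ]), collapse = "\t"), con)
  invisible(path)
}
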