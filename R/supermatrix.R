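# Concatenated core-gene supermatrix, K2P distance matrix, and a
# neighbor-joining tree (deterministic tie-breaks, clamped branch
# lengths) as a desk-scale distance-based phylogeny stage.

#' Build a concatenated supermatrix from per-gene alignments
#'
#' @param per_gene_alignments named list: gene -> named character vector
#'   of equal-length gapped rows (taxon -> row). Taxa may be missing
#'   from individual genes; their blocks are gap-filled.
#' @return object of class `Supermatrix`: `taxa`, `matrix` (named
#'   character vector of concatenated rows), `partitions` (data.frame
#'   gene/start/end, 1-based inclusive column ranges)
#' @export
build_supermatrix <- function(per_gene_alignments) {
  stopifnot(length(per_gene_alignments) >= 1L)
  genes <- names(per_gene_alignments)
  taxa <- character(0)
  for (g in genes) {
    rows <- per_gene_alignments[[g]]
    if (anyDuplicated(names(rows)))
      stop("duplicate taxon within gene '", g, "'")
    if (length(unique(nchar(rows))) > 1L)
      stop("unequal row lengths within gene '", g, "'")
    taxa <- union(taxa, names(rows))
  }
  widths <- vapply(per_gene_alignments, function(r) nchar(r[[1L]]), 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  partitions <- data.frame(gene = genes, start = unname(starts),
                           end = unname(ends), stringsAsFactors = FALSE)
  mat <- setNames(rep("", length(taxa)), taxa)
  for (g in genes) {
    rows <- per_gene_alignments[[g]]
    blank <- strrep("-", widths[[g]])
    for (tx in taxa)
      mat[tx] <- paste0(mat[tx], if (tx %in% names(rows)) rows[[tx]] else blank)
  }
  structure(list(taxa = taxa, matrix = mat, partitions = partitions),
            class = "Supermatrix")
}

#' @export
print.Supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), nchar(x$matrix[[1L]]), nrow(x$partitions)))
  invisible(x)
}

#' Reference-anchored per-gene alignment of a genome panel
#'
#' Aligns each taxon's CDS codon-aware to a designated reference taxon
#' and merges rows by reference coordinates: each row has one column
#' per reference nucleotide (insertions relative to the reference are
#' dropped, deletions appear as gaps). A pseudo-MSA adequate for
#' distance-based trees of conserved genes.
#'
#' @param genomes list of `MitoGenome`
#' @param gene gene name
#' @param reference_id genome id of the reference taxon (default: the
#'   first genome carrying the gene)
#' @return named character vector taxon -> gapped row
#' @export
align_gene_panel <- function(genomes, gene, reference_id = NULL) {
  cds <- list()
  for (g in genomes) {
    x <- tryCatch(suppressWarnings(extract_cds(g, gene)),
                  error = function(e) NULL)
    if (!is.null(x)) cds[[g$id]] <- x
  }
  if (length(cds) == 0L) stop("gene '", gene, "' absent from all genomes")
  if (is.null(reference_id)) reference_id <- names(cds)[1L]
  if (!reference_id %in% names(cds))
    stop("reference taxon '", reference_id, "' lacks gene '", gene, "'")
  ref_nt <- strip_terminal_stop(cds[[reference_id]]$nt)
  width <- nchar(ref_nt)
  rows <- setNames(rep(NA_character_, length(cds)), names(cds))
  rows[reference_id] <- ref_nt
  for (tx in setdiff(names(cds), reference_id)) {
    aln <- codon_aware_align(cds[[reference_id]], cds[[tx]])
    rv <- .chars(aln$a_row); tv <- .chars(aln$b_row)
    keep <- rv != "-"          # columns that are reference positions
    rows[tx] <- paste(tv[keep], collapse = "")
    stopifnot(nchar(rows[tx]) == width)
  }
  rows
}

#' Pairwise K2P distance matrix from a supermatrix
#'
#' K2P on pairwise-complete columns (gaps and N removed per pair).
#'
#' @param sm a `Supermatrix` (or named character vector of equal-length
#'   rows)
#' @return symmetric numeric matrix, zero diagonal
#' @export
k2p_matrix <- function(sm) {
  rows <- if (inherits(sm, "Supermatrix")) sm$matrix else sm
  stopifnot(length(rows) >= 2L)
  ids <- names(rows)
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    kd <- tryCatch(
      k2p_distance(list(a_row = rows[[i]], b_row = rows[[j]])),
      error = function(e)
        stop("no comparable columns between '", ids[i], "' and '",
             ids[j], "'", call. = FALSE))
    D[i, j] <- D[j, i] <- kd$k2p
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Saitou & Nei) with a deterministic
#' tie-break (lowest index pair wins) and negative branch lengths
#' clamped to zero (flagged via the `clamped` attribute). On an
#' additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D symmetric numeric matrix with zero diagonal and taxon
#'   dimnames, n >= 3
#' @return an unrooted `ape::phylo` tree (attribute `clamped` counts
#'   negative branch lengths clamped to 0)
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  nodes <- labels                     # newick fragment per active node
  active <- seq_len(n)
  clamped <- 0L
  bl <- function(v) {
    if (v < 0) { clamped <<- clamped + 1L; v <- 0 }
    sprintf("%.10g", v)
  }
  while (length(active) > 3L) {
    m <- length(active)
    d <- D[active, active, drop = FALSE]
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest linear index among minima -> deterministic lowest (j,i)
    k <- which(q == min(q))[1L]
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_lab <- paste0("(", nodes[active[i]], ":", bl(vi), ",",
                      nodes[active[j]], ":", bl(vj), ")")
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    ai <- active[i]; aj <- active[j]
    D[ai, active] <- newd
    D[active, ai] <- newd
    D[ai, ai] <- 0
    nodes[ai] <- new_lab
    active <- active[-j]
  }
  a <- active
  d <- D[a, a]
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", nodes[a[1]], ":", bl(v1), ",", nodes[a[2]], ":",
                bl(v2), ",", nodes[a[3]], ":", bl(v3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a supermatrix as relaxed PHYLIP plus a partition file
#'
#' @param sm a `Supermatrix`
#' @param phylip_path output PHYLIP file
#' @param partition_path optional RAxML-style partition file
#' @export
write_phylip <- function(sm, phylip_path, partition_path = NULL) {
  con <- file(phylip_path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$matrix[[1L]])), con)
  for (tx in sm$taxa)
    writeLines(paste(tx, sm$matrix[[tx]]), con)
  if (!is.null(partition_path)) {
    writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                       sm$partitions$start, sm$partitions$end),
               partition_path)
  }
  invisible(phylip_path)
}

#' End-to-end supermatrix phylogeny over a genome panel
#'
#' Builds reference-anchored per-gene alignments, concatenates them,
#' computes the K2P matrix and returns the NJ tree.
#'
#' @param genomes list of `MitoGenome` (>= 3 carrying the genes)
#' @param genes genes to concatenate (default 15 core PCGs)
#' @param reference_id reference taxon id (default first genome)
#' @return list: `supermatrix`, `distances`, `tree`
#' @export
supermatrix_nj <- function(genomes, genes = CORE_PCGS,
                           reference_id = genomes[[1L]]$id) {
  alns <- list()
  for (g in genes) {
    a <- tryCatch(align_gene_panel(genomes, g, reference_id),
                  error = function(e) NULL)
    if (!is.null(a) && length(a) >= 2L) alns[[g]] <- a
  }
  if (length(alns) == 0L) stop("no alignable genes in the panel")
  sm <- build_supermatrix(alns)
  D <- k2p_matrix(sm)
  list(supermatrix = sm, distances = D, tree = neighbor_joining(D))
}
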