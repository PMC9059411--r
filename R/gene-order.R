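# Circular gene orders (core PCGs + rRNAs) and rearrangement
# statistics: adjacency breakpoints, per-gene positional changes, and
# grouping of identical arrangements up to rotation/reflection.

#' Extract the circular gene order of a genome
#'
#' Genes of `gene_set` ordered by increasing start coordinate from the
#' annotated origin. A duplicated gene of the set is an error; absent
#' genes are listed.
#'
#' @param genome a `MitoGenome`
#' @param gene_set gene names forming the order (default: 15 core PCGs
#'   plus rnl and rns)
#' @return object of class `GeneOrder`: `genome_id`, `genes`
#'   (data.frame name/strand in circular order), `missing`
#' @export
extract_gene_order <- function(genome, gene_set = ORDER_GENE_SET) {
  feats <- Filter(function(f) f$name %in% gene_set, genome$features)
  nm <- vapply(feats, function(f) f$name, "")
  if (anyDuplicated(nm))
    stop("duplicate core gene annotation in '", genome$id, "': ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  ord <- order(vapply(feats, feature_start, 1L))
  genes <- data.frame(
    name = nm[ord],
    strand = vapply(feats[ord], function(f) f$strand, ""),
    start = vapply(feats[ord], feature_start, 1L),
    stringsAsFactors = FALSE)
  structure(list(genome_id = genome$id, genes = genes,
                 missing = setdiff(gene_set, nm)),
            class = "GeneOrder")
}

#' Construct a gene order directly from names and strands
#' @param genome_id identifier
#' @param names gene names in circular order
#' @param strands strand vector (`+`/`-`), recycled
#' @export
gene_order <- function(genome_id, names, strands = "+") {
  if (anyDuplicated(names)) stop("duplicate gene in order")
  structure(list(genome_id = genome_id,
                 genes = data.frame(name = names,
                                    strand = rep_len(strands, length(names)),
                                    stringsAsFactors = FALSE),
                 missing = character(0)),
            class = "GeneOrder")
}

#' @export
print.GeneOrder <- function(x, ...) {
  cat(sprintf("GeneOrder %s: %s\n", x$genome_id,
              paste0(ifelse(x$genes$strand == "-", "-", ""),
                     x$genes$name, collapse = " ")))
  invisible(x)
}

# circular order restricted to a gene subset, preserving circular order
restrict_order <- function(ord, subset) {
  keep <- ord$genes$name %in% subset
  ord$genes$name[keep]
}

# unordered neighbor-pair (adjacency) set of a circular gene list
adjacency_set <- function(genes) {
  n <- length(genes)
  if (n < 2L) return(character(0))
  nxt <- c(genes[-1L], genes[1L])
  unique(vapply(seq_len(n), function(i)
    paste(sort(c(genes[i], nxt[i])), collapse = "|"), ""))
}

#' Adjacency breakpoints between two circular gene orders
#'
#' Number of adjacencies (unordered neighbor pairs on the circle,
#' strand-insensitive) present in `a` but not in `b`, computed over the
#' intersection of the two gene sets.
#'
#' @param a,b `GeneOrder` objects sharing at least 3 genes
#' @return integer breakpoint count
#' @export
adjacency_breakpoints <- function(a, b) {
  common <- intersect(a$genes$name, b$genes$name)
  if (length(common) < 3L)
    stop("gene-set intersection has fewer than 3 genes")
  ga <- restrict_order(a, common)
  gb <- restrict_order(b, common)
  length(setdiff(adjacency_set(ga), adjacency_set(gb)))
}

#' Count genes whose neighborhood changed between two orders
#'
#' A gene counts as positionally changed when its unordered neighbor
#' pair \{left, right\} on the circle differs between the two orders
#' (computed over the shared gene set).
#'
#' @param a,b `GeneOrder` objects sharing at least 3 genes
#' @return integer count of changed genes
#' @export
positional_changes <- function(a, b) {
  common <- intersect(a$genes$name, b$genes$name)
  if (length(common) < 3L)
    stop("gene-set intersection has fewer than 3 genes")
  ga <- restrict_order(a, common)
  gb <- restrict_order(b, common)
  nb <- function(genes) {
    n <- length(genes)
    left <- c(genes[n], genes[-n])
    right <- c(genes[-1L], genes[1L])
    setNames(vapply(seq_len(n), function(i)
      paste(sort(c(left[i], right[i])), collapse = "|"), ""), genes)
  }
  na_ <- nb(ga); nb_ <- nb(gb)
  sum(na_[common] != nb_[common])
}

# canonical string of a circular order up to rotation (and optionally
# reflection)
canonical_order <- function(genes, reflection = TRUE) {
  rot <- function(v) {
    n <- length(v)
    cands <- vapply(seq_len(n), function(i)
      paste(v[c(i:n, seq_len(i - 1L))], collapse = "\r"), "")
    sort(cands)[1L]
  }
  best <- rot(genes)
  if (reflection) {
    r <- rot(rev(genes))
    if (r < best) best <- r
  }
  best
}

#' Group genomes by identical circular gene arrangement
#'
#' Orders are compared up to rotation, and by default also reflection
#' (circular genomes carry no canonical strand); strand labels are
#' ignored.
#'
#' @param orders list of `GeneOrder`
#' @param reflection treat mirror-image orders as identical
#' @return list of character vectors, each one group of genome ids
#' @export
identical_arrangement_groups <- function(orders, reflection = TRUE) {
  stopifnot(length(orders) >= 2L)
  keys <- vapply(orders, function(o)
    canonical_order(o$genes$name, reflection), "")
  ids <- vapply(orders, function(o) o$genome_id, "")
  unname(split(ids, keys))
}

#' Pairwise rearrangement matrices for a genome panel
#'
#' @param orders list of `GeneOrder`
#' @param stat `"breakpoints"` or `"positional"`
#' @return symmetric integer matrix with genome ids as dimnames
#' @export
gene_order_matrix <- function(orders, stat = c("breakpoints", "positional")) {
  stat <- match.arg(stat)
  fn <- if (stat == "breakpoints") adjacency_breakpoints else positional_changes
  ids <- vapply(orders, function(o) o$genome_id, "")
  n <- length(orders)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- fn(orders[[i]], orders[[j]])
    m[i, j] <- v; m[j, i] <- v
  }
  m
}
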