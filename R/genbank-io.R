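# GenBank flat-file and FASTA input/output.
#
# The parser covers the subset of the format produced for annotated
# organellar deposits: LOCUS topology, CDS/tRNA/rRNA/ncRNA features with
# join()/complement() locations, /gene and /product qualifiers, ORIGIN
# sequence block. Ambiguity codes other than N are rejected.

# default gene-name normalization applied at parse time
DEFAULT_NAME_MAP <- c(
  nad4l = "nad4L", NAD4L = "nad4L", rrnL = "rnl", rrnS = "rns",
  rnL = "rnl", rnS = "rns", "l-rRNA" = "rnl", "s-rRNA" = "rns",
  COB = "cob", cytb = "cob"
)

normalize_gene_name <- function(name, name_map = DEFAULT_NAME_MAP) {
  if (name %in% names(name_map)) unname(name_map[[name]]) else name
}

# parse one GenBank location string into (strand, exon matrix)
parse_location <- function(loc, feature_key) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  if (grepl("[(<>]", loc))
    stop("malformed or unsupported location '", loc, "' in ",
         feature_key, " feature")
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  ex <- t(vapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else stop("malformed location segment '", p, "' in ",
                feature_key, " feature")
  }, integer(2)))
  dimnames(ex) <- list(NULL, c("start", "end"))
  list(strand = strand, exons = ex)
}

# merge a split at the circular origin (…x..L, 1..y…) into one wrapped
# exon; segments are in file order
merge_origin_split <- function(ex, genome_length, circular) {
  if (!circular || nrow(ex) < 2L) return(ex)
  out <- ex[1L, , drop = FALSE]
  for (i in 2L:nrow(ex)) {
    last <- nrow(out)
    if (out[last, "end"] == genome_length && ex[i, "start"] == 1L) {
      out[last, "end"] <- ex[i, "end"]  # start > end encodes the wrap
    } else out <- rbind(out, ex[i, , drop = FALSE])
  }
  out
}

classify_ftype <- function(key, gene) {
  if (key == "CDS") {
    if (grepl("^orf[0-9]*$", gene, ignore.case = TRUE)) "orf" else "CDS"
  } else if (key == "tRNA") "tRNA"
  else if (key == "rRNA") "rRNA"
  else if (gene == "rnpB") "rnpB"
  else NA_character_
}

#' Read annotated genomes from a GenBank flat file
#'
#' One `MitoGenome` per record. `join()` locations become multi-exon
#' features, `complement()` sets the minus strand, and a join split at
#' the origin of a circular record is normalized to a single wrapped
#' exon. Topology is read from the LOCUS line.
#'
#' @param path GenBank flat file (one or more records)
#' @param name_map named character vector of gene-name normalizations
#'   applied at parse time
#' @return list of `MitoGenome`
#' @export
read_genbank <- function(path, name_map = DEFAULT_NAME_MAP) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("no LOCUS line found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i)
    parse_genbank_record(lines[starts[i]:ends[i]], name_map))
}

parse_genbank_record <- function(lines, name_map) {
  locus <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  id <- locus[2L]
  len <- suppressWarnings(as.integer(locus[which(locus == "bp") - 1L]))
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) == 0L) stop("record ", id, " has no ORIGIN block")
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(len) && nchar(sequence) != len)
    stop("record ", id, ": LOCUS length ", len,
         " does not match ORIGIN sequence length ", nchar(sequence))

  features <- list()
  if (length(fstart) > 0L && ostart[1L] > fstart[1L] + 1L) {
    flines <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    features <- parse_feature_block(flines, id, nchar(sequence),
                                    topology == "circular", name_map)
  }
  mito_genome(id, sequence, topology, features)
}

parse_feature_block <- function(flines, id, genome_length, circular,
                                name_map) {
  is_new <- grepl("^ {5}\\S", flines)
  idx <- cumsum(is_new)
  features <- list()
  for (k in unique(idx[idx > 0L])) {
    chunk <- flines[idx == k]
    head_line <- trimws(chunk[1L])
    key <- sub("[[:space:]].*$", "", head_line)
    if (key %in% c("source", "gene", "misc_feature", "intron", "exon"))
      next
    rest <- trimws(sub("^\\S+[[:space:]]*", "", head_line))
    body <- if (length(chunk) > 1L) trimws(chunk[-1L]) else character(0)
    # location may continue over lines until the first qualifier
    qual_at <- grep("^/", body)
    loc_extra <- if (length(qual_at)) head(body, qual_at[1L] - 1L) else body
    loc <- paste(c(rest, loc_extra), collapse = "")
    quals <- if (length(qual_at)) body[qual_at[1L]:length(body)] else character(0)
    gene <- qualifier_value(quals, "gene")
    if (is.na(gene)) gene <- qualifier_value(quals, "label")
    product <- qualifier_value(quals, "product")
    if (is.na(product)) product <- ""
    if (is.na(gene)) gene <- key
    gene <- normalize_gene_name(gene, name_map)
    ftype <- classify_ftype(key, gene)
    if (is.na(ftype)) next  # unrecognized feature kinds are skipped
    pl <- tryCatch(parse_location(loc, key), error = function(e)
      stop("genome ", id, ", feature '", gene, "': ",
           conditionMessage(e), call. = FALSE))
    ex <- merge_origin_split(pl$exons, genome_length, circular)
    features[[length(features) + 1L]] <-
      gene_feature(gene, ftype, pl$strand, ex, product)
  }
  features
}

qualifier_value <- function(quals, name) {
  pat <- paste0("^/", name, "=")
  hit <- grep(pat, quals)
  if (length(hit) == 0L) return(NA_character_)
  v <- sub(pat, "", quals[hit[1L]])
  gsub("\"", "", v)
}

format_location <- function(f) {
  ex <- f$exons
  segs <- character(0)
  for (i in seq_len(nrow(ex))) {
    s <- ex[i, "start"]; e <- ex[i, "end"]
    if (s > e) {  # wrapped exon re-split at the origin for the flat file
      segs <- c(segs, paste0(s, "..", attr(f, "genome_length")),
                paste0(1L, "..", e))
    } else segs <- c(segs, paste0(s, "..", e))
  }
  loc <- if (length(segs) > 1L)
    paste0("join(", paste(segs, collapse = ","), ")") else segs
  if (f$strand == "-") paste0("complement(", loc, ")") else loc
}

#' Write genomes as a GenBank flat file
#'
#' Round-trips through [read_genbank()]: coordinates, strands, names
#' and topology are preserved exactly.
#'
#' @param genomes a `MitoGenome` or list of them
#' @param path output file
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "MitoGenome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(sprintf("LOCUS       %s  %d bp    DNA     %s  UNA 01-JAN-2000",
                       g$id, g$length, g$topology), con)
    writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                       g$id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", g$length), con)
    for (f in g$features) {
      attr(f, "genome_length") <- g$length
      key <- switch(f$ftype, CDS = "CDS", orf = "CDS", tRNA = "tRNA",
                    rRNA = "rRNA", rnpB = "ncRNA")
      writeLines(sprintf("     %-16s%s", key, format_location(f)), con)
      writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
      if (nchar(f$product) > 0L)
        writeLines(sprintf("                     /product=\"%s\"",
                           f$product), con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(g$sequence)
    pos <- seq(1L, nchar(s), 60L)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59L, nchar(s)))
      groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                          pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write named sequences as FASTA (60-column wrapped)
#'
#' @param seqs named character vector or named list of DNA/AA strings;
#'   names must be non-empty and unique
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  seqs <- unlist(seqs)
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm))) stop("all sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file
#' @return named character vector (uppercase)
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
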