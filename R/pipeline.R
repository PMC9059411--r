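# Pipeline orchestration: run every comparative stage over a genome
# panel and emit table analogs plus a machine-readable summary.

PIPELINE_STAGES <- c("composition", "annotation", "codons", "startstop",
                     "repeats", "rates", "pcl", "order", "supermatrix")

#' Validate a pipeline run configuration
#'
#' @param input GenBank file path(s), or a pre-parsed list of
#'   `MitoGenome` objects
#' @param out_dir output directory
#' @param reference_cds optional `CodingSequence` used as the Pcl
#'   reference (required only by the `pcl` stage)
#' @param pcl_gene host gene for intron position classes
#' @param core_genes gene set for rates/codons/supermatrix
#' @param order_genes gene set for gene-order comparison
#' @param repeat_min_len,repeat_min_identity interspersed-repeat
#'   thresholds
#' @param pcl_tolerance Pcl merge radius (nt)
#' @param seed RNG seed recorded in output headers
#' @return validated `RunConfig` object
#' @export
run_config <- function(input, out_dir, reference_cds = NULL,
                       pcl_gene = "cox1", core_genes = CORE_PCGS,
                       order_genes = ORDER_GENE_SET,
                       repeat_min_len = 40L, repeat_min_identity = 70,
                       pcl_tolerance = 0L, seed = 1L) {
  if (is.character(input)) {
    missing <- input[!file.exists(input)]
    if (length(missing) > 0L)
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  } else if (!is.list(input) ||
             !all(vapply(input, inherits, TRUE, "MitoGenome"))) {
    stop("input must be file paths or a list of MitoGenome objects")
  }
  stopifnot(repeat_min_len >= 10L, repeat_min_identity > 0,
            repeat_min_identity <= 100, pcl_tolerance >= 0L)
  if (!is.null(reference_cds) &&
      !inherits(reference_cds, "CodingSequence"))
    stop("reference_cds must be a CodingSequence")
  structure(list(input = input, out_dir = out_dir,
                 reference_cds = reference_cds, pcl_gene = pcl_gene,
                 core_genes = core_genes, order_genes = order_genes,
                 repeat_min_len = as.integer(repeat_min_len),
                 repeat_min_identity = repeat_min_identity,
                 pcl_tolerance = as.integer(pcl_tolerance),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

load_config_genomes <- function(config) {
  if (!is.character(config$input)) return(config$input)
  genomes <- list()
  for (p in config$input)
    genomes <- c(genomes, read_genbank(p))
  genomes
}

config_header <- function(config) {
  ver <- as.character(utils::packageVersion("mitocomp"))
  tf <- tempfile()
  on.exit(unlink(tf))
  keys <- config[c("pcl_gene", "repeat_min_len", "repeat_min_identity",
                   "pcl_tolerance", "seed")]
  writeLines(jsonlite::toJSON(keys, auto_unbox = TRUE), tf)
  hash <- unname(tools::md5sum(tf))
  sprintf(paste0("# mitocomp %s | config %s | repeat_min_len=%d ",
                 "repeat_min_identity=%g pcl_tolerance=%d seed=%d"),
          ver, hash, config$repeat_min_len, config$repeat_min_identity,
          config$pcl_tolerance, config$seed)
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Run a single pipeline stage
#'
#' Stage outputs are identical to the corresponding slice of
#' [run_all()] on the same configuration.
#'
#' @param stage_name one of `composition`, `annotation`, `codons`,
#'   `startstop`, `repeats`, `rates`, `pcl`, `order`, `supermatrix`
#' @param config a `RunConfig`
#' @return invisibly, the file(s) written
#' @export
run_stage <- function(stage_name, config) {
  if (!stage_name %in% PIPELINE_STAGES)
    stop("unknown stage '", stage_name, "'; valid stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  genomes <- load_config_genomes(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_header(config)
  out <- function(f) file.path(config$out_dir, f)
  few <- length(genomes) < 2L

  written <- switch(
    stage_name,
    composition = write_stage_tsv(composition_table(genomes),
                                  out("composition.tsv"), hdr),
    annotation = write_stage_tsv(features_table(genomes),
                                 out("annotation.tsv"), hdr),
    codons = {
      rows <- lapply(genomes, function(g) {
        cds <- lapply(intersect(config$core_genes,
                                vapply(g$features, `[[`, "", "name")),
                      function(gn) suppressWarnings(extract_cds(g, gn)))
        cu <- codon_counts(cds)
        cbind(genome_id = g$id, cu$table)
      })
      write_stage_tsv(do.call(rbind, rows), out("codon_usage.tsv"), hdr)
    },
    startstop = write_stage_tsv(
      start_stop_table(genomes, config$core_genes),
      out("start_stop.tsv"), hdr),
    repeats = {
      tag <- function(df, id) {
        if (nrow(df) == 0L)
          cbind(data.frame(genome_id = character(0)), df)
        else cbind(genome_id = id, df)
      }
      rep_rows <- lapply(genomes, function(g)
        tag(find_interspersed_repeats(g, config$repeat_min_len,
                                      config$repeat_min_identity), g$id))
      tan_rows <- lapply(genomes, function(g)
        tag(find_tandem_repeats(g), g$id))
      p1 <- write_stage_tsv(do.call(rbind, rep_rows),
                            out("repeats_interspersed.tsv"), hdr)
      p2 <- write_stage_tsv(do.call(rbind, tan_rows),
                            out("repeats_tandem.tsv"), hdr)
      c(p1, p2)
    },
    rates = {
      df <- if (few) insufficient_note("rates")
      else rates_table(genomes, config$core_genes)
      write_stage_tsv(df, out("rates.tsv"), hdr)
    },
    pcl = {
      if (is.null(config$reference_cds))
        stop("the pcl stage needs a reference CDS; set reference_cds ",
             "in run_config()")
      asg <- assign_pcls(genomes, config$pcl_gene, config$reference_cds,
                         config$pcl_tolerance)
      p1 <- write_stage_tsv(asg, out("pcl_assignments.tsv"), hdr)
      p2 <- if (nrow(asg) > 0L) {
        m <- classify_common_rare(asg, n_species = length(genomes))
        write_pcl_tsv(m, out("pcl_matrix.tsv"))
      } else {
        write_stage_tsv(data.frame(note = "no introns found"),
                        out("pcl_matrix.tsv"), hdr)
      }
      c(p1, p2)
    },
    order = {
      if (few) {
        write_stage_tsv(insufficient_note("gene order"),
                        out("gene_order.tsv"), hdr)
      } else {
        orders <- lapply(genomes, extract_gene_order, config$order_genes)
        bp <- gene_order_matrix(orders, "breakpoints")
        pc <- gene_order_matrix(orders, "positional")
        groups <- identical_arrangement_groups(orders)
        p1 <- write_stage_tsv(as.data.frame(bp),
                              out("order_breakpoints.tsv"), hdr)
        p2 <- write_stage_tsv(as.data.frame(pc),
                              out("order_positional.tsv"), hdr)
        p3 <- write_stage_tsv(
          data.frame(group = rep(seq_along(groups), lengths(groups)),
                     genome_id = unlist(groups)),
          out("order_groups.tsv"), hdr)
        c(p1, p2, p3)
      }
    },
    supermatrix = {
      if (length(genomes) < 3L) {
        write_stage_tsv(insufficient_note("supermatrix"),
                        out("supermatrix_note.tsv"), hdr)
      } else {
        res <- supermatrix_nj(genomes, config$core_genes)
        write_phylip(res$supermatrix, out("supermatrix.phy"),
                     out("supermatrix_partitions.txt"))
        write_fasta(res$supermatrix$matrix, out("supermatrix.fasta"))
        ape::write.tree(res$tree, out("tree.nwk"))
        out(c("supermatrix.phy", "supermatrix_partitions.txt",
              "supermatrix.fasta", "tree.nwk"))
      }
    })
  invisible(written)
}

insufficient_note <- function(what) {
  data.frame(note = paste0("insufficient genomes for ", what,
                           " (need >= 2)"))
}

#' Run the full comparative pipeline
#'
#' Executes every stage over the configured panel and writes the table
#' analogs (composition, annotation, codon usage, start/stop codons,
#' repeats, per-gene rates, Pcl matrix, gene-order matrices,
#' supermatrix + NJ tree) plus a JSON summary. Per-genome stage
#' failures are caught and logged in the summary; the run continues
#' with the remaining stages.
#'
#' @param config a `RunConfig`
#' @return invisibly, a list with per-stage outputs and errors
#' @export
run_all <- function(config) {
  genomes <- load_config_genomes(config)
  if (length(genomes) < 1L) stop("no parseable genomes in input")
  results <- list()
  errors <- list()
  stages <- PIPELINE_STAGES
  if (is.null(config$reference_cds))
    stages <- setdiff(stages, "pcl")
  for (s in stages) {
    r <- tryCatch(run_stage(s, config), error = function(e)
      structure(conditionMessage(e), class = "stage_error"))
    if (inherits(r, "stage_error")) errors[[s]] <- unclass(r)
    else results[[s]] <- r
  }
  summary <- list(
    n_genomes = length(genomes),
    genome_ids = vapply(genomes, `[[`, "", "id"),
    stages_run = names(results),
    stages_failed = errors,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, errors = errors, summary = summary))
}
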