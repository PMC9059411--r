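# Pairwise K2P distances and NG86 Ka/Ks under the mold mitochondrial
# genetic code, with per-gene panel summaries.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

is_transition <- function(x, y) {
  (x %in% PURINES & y %in% PURINES) |
    (x %in% PYRIMIDINES & y %in% PYRIMIDINES)
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' Complete deletion: columns containing a gap or N are excluded. Over
#' the remaining columns the transition proportion P and transversion
#' proportion Q give Kimura's distance
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). A non-positive log
#' argument marks the pair saturated and reports an infinite distance.
#'
#' @param aln an `Alignment` (or list with `a_row`, `b_row`)
#' @return object of class `PairwiseRates` (partial): `P`, `Q`, `k2p`,
#'   `n_sites`, `saturated`
#' @export
k2p_distance <- function(aln) {
  av <- .chars(aln$a_row); bv <- .chars(aln$b_row)
  ok <- av %in% DNA_BASES & bv %in% DNA_BASES
  n <- sum(ok)
  if (n < 1L) stop("no comparable (gap- and N-free) columns")
  a <- av[ok]; b <- bv[ok]
  diff <- a != b
  P <- sum(diff & is_transition(a, b)) / n
  Q <- sum(diff & !is_transition(a, b)) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  d <- if (saturated) Inf else -0.5 * log(arg1) - 0.25 * log(arg2)
  structure(list(P = P, Q = Q, k2p = d, n_sites = n,
                 saturated = saturated),
            class = "PairwiseRates")
}

#' @export
print.PairwiseRates <- function(x, ...) {
  cat("PairwiseRates:")
  for (f in c("P", "Q", "k2p", "ka", "ks", "ka_ks"))
    if (!is.null(x[[f]]))
      cat(sprintf(" %s=%s", f, format(x[[f]], digits = 4)))
  cat("\n")
  invisible(x)
}

# --- NG86 machinery (genetic code 4 by default) ------------------------

SENSE <- NULL  # codon environment caches, built per genetic code
ng86_env <- local({
  cache <- list()
  function(genetic_code = CODE4) {
    key <- paste(genetic_code, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    codons <- names(genetic_code)
    stops <- codons[genetic_code == "*"]
    syn_sites <- setNames(numeric(length(codons)), codons)
    for (cod in codons) {
      if (cod %in% stops) next
      s <- 0
      for (p in 1:3) {
        alts <- setdiff(DNA_BASES, substr(cod, p, p))
        muts <- vapply(alts, function(b) {
          m <- cod; substr(m, p, p) <- b; m
        }, "")
        valid <- muts[!(muts %in% stops)]
        # mutations to stop codons are excluded from the denominator
        if (length(valid) > 0L)
          s <- s + sum(genetic_code[valid] == genetic_code[[cod]]) /
            length(valid)
      }
      syn_sites[[cod]] <- s
    }
    e <- list(codons = codons, stops = stops, syn_sites = syn_sites,
              code = genetic_code)
    cache[[key]] <<- e
    e
  }
})

# average synonymous/nonsynonymous differences between two codons over
# all minimal mutational pathways; paths through stop codons excluded
# (falling back to all paths if every path crosses a stop)
codon_pair_diffs <- function(c1, c2, env) {
  pos <- which(.chars(c1) != .chars(c2))
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- if (nd == 1L) list(pos)
  else if (nd == 2L) list(pos, rev(pos))
  else list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
            pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  walk <- function(order) {
    cur <- c1; sd <- 0; ndf <- 0; valid <- TRUE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% env$stops) valid <- FALSE
      if (env$code[[cur]] == env$code[[nxt]] &&
          !(nxt %in% env$stops) && !(cur %in% env$stops))
        sd <- sd + 1 else ndf <- ndf + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndf, valid = as.numeric(valid))
  }
  res <- vapply(perms, walk, numeric(3))
  use <- res["valid", ] == 1
  if (!any(use)) use <- rep(TRUE, ncol(res))  # all paths cross a stop
  c(sd = mean(res["sd", use]), nd = mean(res["nd", use]))
}

#' NG86 Ka/Ks from a codon-aware alignment
#'
#' Nei-Gojobori counting: each codon position contributes its fraction
#' of synonymous one-step changes to the synonymous site count
#' (mutations to stop codons excluded from the denominator, so
#' synonymous + nonsynonymous sites = 3 per codon); differences are
#' averaged over all minimal mutational pathways between the two
#' codons, excluding paths through stops. pS and pN receive the
#' Jukes-Cantor correction K = -3/4 ln(1 - 4/3 p); p >= 3/4 marks the
#' estimate saturated. `ka_ks` is `NA` when Ks = 0.
#'
#' @param aln codon-aware `Alignment` (columns in frame, e.g. from
#'   [codon_aware_align()])
#' @param genetic_code codon map, default table 4
#' @return `PairwiseRates`: `ka`, `ks`, `ka_ks`, site and difference
#'   counts, `saturated`
#' @export
ng86_ka_ks <- function(aln, genetic_code = CODE4) {
  stopifnot(nchar(aln$a_row) %% 3L == 0L)
  env <- ng86_env(genetic_code)
  ca <- .codons(aln$a_row); cb <- .codons(aln$b_row)
  keep <- !grepl("[-N]", paste0(ca, cb)) &
    !(ca %in% env$stops) & !(cb %in% env$stops)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no comparable codon columns")
  Sa <- sum(env$syn_sites[ca]); Sb <- sum(env$syn_sites[cb])
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i)
    codon_pair_diffs(ca[i], cb[i], env), numeric(2))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  }
  saturated <- pS >= 0.75 || pN >= 0.75
  ks <- jc(pS); ka <- jc(pN)
  structure(list(ka = ka, ks = ks,
                 ka_ks = if (is.finite(ks) && ks > 0 && is.finite(ka))
                   ka / ks else NA_real_,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = Sd, nonsyn_diffs = Nd,
                 n_codons = length(ca), saturated = saturated),
            class = "PairwiseRates")
}

#' Per-gene evolutionary-rate summary over a genome panel
#'
#' Every unordered genome pair carrying the gene is aligned codon-aware
#' and the K2P distance and NG86 Ka/Ks computed; saturated pairs (and
#' undefined Ka/Ks ratios) are excluded from the means and reported.
#'
#' @param genomes list of `MitoGenome`
#' @param gene gene name, present in at least two genomes
#' @return list: `gene`, `pairs` (per-pair data.frame), `mean_k2p`,
#'   `mean_ka`, `mean_ks`, `mean_ka_ks`, `n_pairs`, `n_saturated`
#' @export
panel_rate_summary <- function(genomes, gene) {
  cds <- list()
  for (g in genomes) {
    x <- tryCatch(suppressWarnings(extract_cds(g, gene)),
                  error = function(e) NULL)
    if (!is.null(x)) cds[[g$id]] <- x
  }
  if (length(cds) < 2L)
    stop("gene '", gene, "' present in fewer than 2 genomes")
  ids <- names(cds)
  pairs <- combn(ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    aln <- codon_aware_align(cds[[i1]], cds[[i2]])
    kd <- k2p_distance(aln)
    kk <- ng86_ka_ks(aln)
    data.frame(gene = gene, genome_a = i1, genome_b = i2,
               P = kd$P, Q = kd$Q, k2p = kd$k2p,
               ka = kk$ka, ks = kk$ks, ka_ks = kk$ka_ks,
               saturated = kd$saturated || kk$saturated,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$saturated
  mean_or_na <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)])
                            else NA_real_
  list(gene = gene, pairs = tab,
       mean_k2p = mean_or_na(tab$k2p[ok]),
       mean_ka = mean_or_na(tab$ka[ok]),
       mean_ks = mean_or_na(tab$ks[ok]),
       mean_ka_ks = mean_or_na(tab$ka_ks[ok]),
       n_pairs = nrow(tab), n_saturated = sum(tab$saturated))
}

#' Rate summary table over several genes
#'
#' @param genomes list of `MitoGenome`
#' @param genes gene names (default the 15 core PCGs)
#' @return data.frame: gene, mean_k2p, mean_ka, mean_ks, mean_ka_ks,
#'   n_pairs, n_saturated
#' @export
rates_table <- function(genomes, genes = CORE_PCGS) {
  rows <- lapply(genes, function(gene) {
    s <- tryCatch(panel_rate_summary(genomes, gene),
                  error = function(e) NULL)
    if (is.null(s))
      return(data.frame(gene = gene, mean_k2p = NA_real_,
                        mean_ka = NA_real_, mean_ks = NA_real_,
                        mean_ka_ks = NA_real_, n_pairs = 0L,
                        n_saturated = 0L, stringsAsFactors = FALSE))
    data.frame(gene = gene, mean_k2p = s$mean_k2p, mean_ka = s$mean_ka,
               mean_ks = s$mean_ks, mean_ka_ks = s$mean_ka_ks,
               n_pairs = s$n_pairs, n_saturated = s$n_saturated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
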