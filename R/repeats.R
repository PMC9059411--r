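# Intra-genomic interspersed repeats (seed-and-extend self-comparison)
# and tandem repeats.

# positions of every k-mer in a sequence string; k-mers with more than
# max_occ occurrences (low-complexity) are dropped
kmer_index <- function(seqstr, k, max_occ = 60L) {
  n <- nchar(seqstr)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seqstr, starts, starts + k - 1L)
  idx <- split(starts, kmers)
  idx[lengths(idx) <= max_occ & !grepl("N", names(idx), fixed = TRUE)]
}

# is position i inside any of the (start, end) pairs flattened in v?
in_spans <- function(i, v) {
  if (length(v) == 0L) return(FALSE)
  any(i >= v[c(TRUE, FALSE)] & i <= v[c(FALSE, TRUE)])
}

# greedy ungapped X-drop extension of a seed match between positions
# i..(i+len-1) and j..(j+len-1) of chars x and y (same direction)
extend_seed <- function(x, y, i, j, len, xdrop = 12L,
                        match = 1L, mismatch = -2L) {
  nx <- length(x); ny <- length(y)
  # right
  ri <- i + len - 1L; rj <- j + len - 1L
  best <- 0L; cur <- 0L; bi <- ri; bj <- rj
  while (ri < nx && rj < ny) {
    ri <- ri + 1L; rj <- rj + 1L
    cur <- cur + if (x[ri] == y[rj]) match else mismatch
    if (cur > best) { best <- cur; bi <- ri; bj <- rj }
    if (best - cur > xdrop) break
  }
  ri <- bi; rj <- bj
  # left
  li <- i; lj <- j
  best <- 0L; cur <- 0L; bi <- li; bj <- lj
  while (li > 1L && lj > 1L) {
    li <- li - 1L; lj <- lj - 1L
    cur <- cur + if (x[li] == y[lj]) match else mismatch
    if (cur > best) { best <- cur; bi <- li; bj <- lj }
    if (best - cur > xdrop) break
  }
  li <- bi; lj <- bj
  span <- li:ri
  ident <- 100 * sum(x[span] == y[lj:rj]) / length(span)
  list(i1 = li, i2 = ri, j1 = lj, j2 = rj, length = length(span),
       identity = ident)
}

#' Find interspersed repeats within a genome
#'
#' Self-comparison by exact k-mer seeding on both strands followed by
#' ungapped X-drop extension; hits on the same diagonal are merged, the
#' trivial self-diagonal is excluded, and on circular genomes the scan
#' runs over the doubled sequence with hits deduplicated modulo the
#' genome length.
#'
#' @param genome a `MitoGenome` (or DNA string)
#' @param min_len minimum repeat length (bp)
#' @param min_identity minimum percent identity of a reported pair
#' @param seed_k seed k-mer size
#' @return data.frame of `RepeatPair` rows: start1, end1, start2, end2,
#'   strandedness (`direct`/`inverted`), length, identity. Coordinates
#'   are 1-based on the plus strand; a span may exceed the genome
#'   length when it wraps the origin (interpret modulo length).
#' @export
find_interspersed_repeats <- function(genome, min_len = 40L,
                                      min_identity = 70, seed_k = 11L) {
  seq <- if (inherits(genome, "MitoGenome")) genome$sequence else genome
  L <- nchar(seq)
  circular <- inherits(genome, "MitoGenome") &&
    genome$topology == "circular"
  if (L < min_len) return(empty_repeat_df())
  scan_seq <- if (circular) paste0(seq, substr(seq, 1L, min(L, 2000L)))
              else seq
  x <- .chars(scan_seq)
  idx <- kmer_index(scan_seq, seed_k)

  hits <- list()
  add_hit <- function(h, strandedness) {
    hits[[length(hits) + 1L]] <<- c(h, list(strandedness = strandedness))
  }

  # direct repeats: pair up occurrences of each repeated k-mer,
  # grouped by diagonal so each diagonal is extended once
  seen_diag <- new.env(hash = TRUE)
  for (pos in idx[lengths(idx) >= 2L]) {
    for (a in seq_len(length(pos) - 1L)) for (b in (a + 1L):length(pos)) {
      i <- pos[a]; j <- pos[b]
      if (i == j) next
      dg <- paste0("d", j - i)
      done <- get0(dg, envir = seen_diag, ifnotfound = integer(0))
      if (in_spans(i, done)) next
      h <- extend_seed(x, x, i, j, seed_k)
      if (h$i2 >= h$j1) next  # overlapping copies: tandem, not interspersed
      assign(dg, c(done, h$i1, h$i2), envir = seen_diag)
      if (h$length >= min_len && h$identity >= min_identity)
        add_hit(h, "direct")
    }
  }

  # inverted repeats: seeds shared between the sequence and its
  # reverse complement
  rc_str <- revcomp(scan_seq)
  rc <- .chars(rc_str)
  n <- length(x)
  idx_rc <- kmer_index(rc_str, seed_k)
  shared <- intersect(names(idx), names(idx_rc))
  seen_anti <- new.env(hash = TRUE)
  for (km in shared) {
    for (i in idx[[km]]) for (jr in idx_rc[[km]]) {
      # map revcomp coordinate back to forward coordinates
      j_end <- n - jr + 1L          # forward end of the rc seed
      j_start <- j_end - seed_k + 1L
      if (j_start <= i + seed_k - 1L) next  # keep ordered, non-identical
      ag <- paste0("a", i + jr)     # anti-diagonal key
      done <- get0(ag, envir = seen_anti, ifnotfound = integer(0))
      if (in_spans(i, done)) next
      h <- extend_seed(x, rc, i, jr, seed_k)
      assign(ag, c(done, h$i1, h$i2), envir = seen_anti)
      if (h$length >= min_len && h$identity >= min_identity) {
        f2 <- n - h$j1 + 1L; f1 <- n - h$j2 + 1L
        if (f1 > h$i2)
          add_hit(list(i1 = h$i1, i2 = h$i2, j1 = f1, j2 = f2,
                       length = h$length, identity = h$identity),
                  "inverted")
      }
    }
  }

  if (length(hits) == 0L) return(empty_repeat_df())
  df <- do.call(rbind, lapply(hits, function(h)
    data.frame(start1 = h$i1, end1 = h$i2, start2 = h$j1, end2 = h$j2,
               strandedness = h$strandedness, length = h$length,
               identity = h$identity, stringsAsFactors = FALSE)))
  if (circular) {
    # drop hits living entirely in the doubled tail, fold the rest,
    # and discard pairs that fold onto themselves (sequence vs its
    # own image in the tail)
    df <- df[df$start1 <= L, , drop = FALSE]
    shift <- df$start2 > L & df$end2 > L
    df$start2[shift] <- df$start2[shift] - L
    df$end2[shift] <- df$end2[shift] - L
    df <- df[!(df$start1 == df$start2 & df$end1 == df$end2), ,
             drop = FALSE]
  }
  df <- dedupe_repeats(df)
  df[order(-df$length, df$start1), , drop = FALSE]
}

empty_repeat_df <- function() {
  data.frame(start1 = integer(0), end1 = integer(0), start2 = integer(0),
             end2 = integer(0), strandedness = character(0),
             length = integer(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

# collapse hits whose both intervals are contained in an already-kept
# longer hit, and symmetric duplicates
dedupe_repeats <- function(df) {
  if (nrow(df) <= 1L) return(df)
  # canonical order: first interval before second
  swap <- df$start2 < df$start1
  tmp <- df[swap, c("start2", "end2")]
  df[swap, c("start2", "end2")] <- df[swap, c("start1", "end1")]
  df[swap, c("start1", "end1")] <- tmp
  df <- df[order(-df$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$strandedness[i] == df$strandedness[j] &&
          df$start1[i] >= df$start1[j] - 5L && df$end1[i] <= df$end1[j] + 5L &&
          df$start2[i] >= df$start2[j] - 5L && df$end2[i] <= df$end2[j] + 5L) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' Find tandem repeat arrays
#'
#' For each candidate period p the sequence is compared against itself
#' shifted by p; maximal runs of agreement (runs separated by a single
#' mismatch are merged when overall identity stays >= 90%) of total
#' length >= min_total with >= 2 copies are reported. The repeat unit is
#' canonicalized to its lexicographically smallest rotation, and arrays
#' explained by a shorter period are suppressed.
#'
#' @param genome a `MitoGenome` or DNA string
#' @param min_total minimum total array length in bp (the default keeps
#'   arrays longer than 10 bp)
#' @param min_unit,max_unit period range searched
#' @return data.frame of `TandemArray` rows: start, end, unit,
#'   unit_len, copies, total_len, identity
#' @export
find_tandem_repeats <- function(genome, min_total = 11L, min_unit = 1L,
                                max_unit = 200L) {
  seq <- if (inherits(genome, "MitoGenome")) genome$sequence else genome
  x <- .chars(seq)
  n <- length(x)
  out <- list()
  for (p in min_unit:min(max_unit, n %/% 2L)) {
    eq <- x[seq_len(n - p)] == x[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # candidate start runs: long enough that, after single-mismatch
    # merging, a >= 2-copy array could result
    cand <- which(r$values & r$lengths >= max(3L, p %/% 2L, min_unit))
    merged <- list()
    for (ri in cand) {
      s <- starts[ri]; e <- ends[ri]; mism <- 0L
      k <- ri
      while (k + 2L <= length(r$values) && !r$values[k + 1L] &&
             r$lengths[k + 1L] == 1L && r$values[k + 2L]) {
        mism <- mism + 1L
        k <- k + 2L
        e <- ends[k]
      }
      len <- e - s + 1L
      if (len >= p && (len - mism) / len >= 0.9) {
        total <- len + p
        if (total >= min_total && total / p >= 2) {
          merged[[length(merged) + 1L]] <-
            c(start = s, end = e + p, period = p, mism = mism)
        }
      }
    }
    for (m in merged) {
      unit <- paste(x[m[["start"]]:(m[["start"]] + p - 1L)], collapse = "")
      total <- m[["end"]] - m[["start"]] + 1L
      out[[length(out) + 1L]] <- data.frame(
        start = m[["start"]], end = m[["end"]],
        unit = canonical_rotation(unit), unit_len = p,
        copies = total / p, total_len = total,
        identity = 100 * (total - m[["mism"]]) / total,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      copies = numeric(0), total_len = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- unique(df)
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  # suppress arrays explained by a smaller period or contained in a
  # longer array of the same period
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    contains <- df$start <= df$start[i] & df$end >= df$end[i] & keep
    contains[i] <- FALSE
    cover <- contains & (df$unit_len < df$unit_len[i] |
      (df$unit_len == df$unit_len[i] & df$total_len > df$total_len[i]))
    if (any(cover)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

canonical_rotation <- function(unit) {
  n <- nchar(unit)
  if (n <= 1L) return(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L)), "")
  sort(rots)[1L]
}

#' Fraction of a genome covered by repeats
#'
#' Union of all repeat-covered positions (both copies of every pair, or
#' tandem spans) over the genome length, as a percentage. Positions are
#' counted once however many repeats cover them.
#'
#' @param repeats data.frame from [find_interspersed_repeats()] (with
#'   start1/end1/start2/end2) or [find_tandem_repeats()] (start/end)
#' @param genome_length genome length in bp
#' @return percentage in `[0, 100]`
#' @export
repeat_fraction <- function(repeats, genome_length) {
  covered <- rep(FALSE, genome_length)
  mark <- function(s, e) {
    if (is.na(s) || is.na(e)) return()
    p <- if (s <= e) s:e else c(s:genome_length, 1:e)
    p <- ((p - 1L) %% genome_length) + 1L
    covered[p] <<- TRUE
  }
  if (nrow(repeats) > 0L) {
    if (all(c("start1", "end1") %in% names(repeats))) {
      for (i in seq_len(nrow(repeats))) {
        mark(repeats$start1[i], repeats$end1[i])
        mark(repeats$start2[i], repeats$end2[i])
      }
    } else {
      for (i in seq_len(nrow(repeats))) mark(repeats$start[i], repeats$end[i])
    }
  }
  100 * sum(covered) / genome_length
}
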