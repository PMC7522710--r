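#' Find ungapped local similarities (HSPs) between a host contig and a virus
#'
#' Exact k-mer seeds between the contig and both strands of the virus are
#' extended ungapped in both directions under an X-drop rule (match +1,
#' mismatch -2, extension abandoned once the running score falls more than
#' `xdrop` below its maximum; the reported end is the maximum-scoring
#' column). Seeds falling inside an HSP already extended on the same
#' diagonal and orientation are skipped, and HSPs scoring below `min_score`
#' are discarded.
#'
#' Coordinates are 1-based inclusive. For orientation `-` the contig
#' interval aligns to the reverse complement of the virus interval (the
#' virus interval itself stays in + strand coordinates, with `contig_start`
#' pairing with `virus_end`).
#'
#' @param contig,virus named character vectors of length 1.
#' @param k exact seed length.
#' @param xdrop X-drop termination threshold (score units).
#' @param min_score minimum HSP score (matches - 2*mismatches).
#' @return data.frame of HSPs: contig_start, contig_end, virus_start,
#'   virus_end, orientation, matches, aligned_columns, score. Empty when
#'   nothing scores above `min_score`.
#' @export
find_hsps <- function(contig, virus, k = 11L, xdrop = 20L, min_score = 30L) {
  cr <- as_refseq(contig)
  vr <- as_refseq(virus)
  if (!nzchar(cr$seq) || !nzchar(vr$seq)) stop("both sequences must be non-empty")
  k <- as.integer(k)
  Lv <- nchar(vr$seq)
  out <- list()
  for (orient in c("+", "-")) {
    tseq <- if (orient == "+") vr$seq else dna_revcomp(vr$seq)
    h <- .scan_orientation(cr$seq, tseq, k, xdrop, min_score)
    if (nrow(h) == 0L) next
    if (orient == "+") {
      h$virus_start <- h$t_start
      h$virus_end <- h$t_end
    } else {
      h$virus_start <- Lv - h$t_end + 1L
      h$virus_end <- Lv - h$t_start + 1L
    }
    h$orientation <- orient
    out[[orient]] <- h[, c("contig_start", "contig_end", "virus_start",
                           "virus_end", "orientation", "matches",
                           "aligned_columns", "score")]
  }
  if (length(out) == 0L) {
    return(data.frame(contig_start = integer(0), contig_end = integer(0),
                      virus_start = integer(0), virus_end = integer(0),
                      orientation = character(0), matches = integer(0),
                      aligned_columns = integer(0), score = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$contig_start, res$contig_end, res$orientation), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# X-drop extension along +1 direction: eq is the logical match vector ahead
# of the seed; returns list(ext = columns extended, score, matches)
.xdrop_extend <- function(eq, xdrop) {
  n <- length(eq)
  if (n == 0L) return(list(ext = 0L, score = 0L, matches = 0L))
  sc <- cumsum(ifelse(eq, 1L, -2L))
  runmax <- cummax(c(0L, sc))[-1L]
  viol <- which(runmax - sc > xdrop)
  lim <- if (length(viol)) viol[1L] - 1L else n
  if (lim == 0L) return(list(ext = 0L, score = 0L, matches = 0L))
  ext <- which.max(sc[seq_len(lim)])
  if (sc[ext] <= 0L) return(list(ext = 0L, score = 0L, matches = 0L))
  list(ext = ext, score = sc[ext], matches = sum(eq[seq_len(ext)]))
}

.scan_orientation <- function(cseq, tseq, k, xdrop, min_score) {
  craw <- charToRaw(cseq)
  traw <- charToRaw(tseq)
  Lc <- length(craw); Lt <- length(traw)
  empty <- data.frame(contig_start = integer(0), contig_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      matches = integer(0), aligned_columns = integer(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (Lc < k || Lt < k) return(empty)

  tstarts <- seq_len(Lt - k + 1L)
  tkmers <- substring(tseq, tstarts, tstarts + k - 1L)
  keep <- !grepl("N", tkmers, fixed = TRUE)
  env <- list2env(split(tstarts[keep], tkmers[keep]), hash = TRUE)

  cstarts <- seq_len(Lc - k + 1L)
  ckmers <- substring(cseq, cstarts, cstarts + k - 1L)
  hitlist <- lapply(ckmers, function(km) get0(km, envir = env, ifnotfound = NULL))
  nh <- lengths(hitlist)
  if (sum(nh) == 0L) return(empty)
  cpos <- rep.int(cstarts, nh)
  tpos <- unlist(hitlist, use.names = FALSE)

  diag <- cpos - tpos
  o <- order(diag, cpos)
  cpos <- cpos[o]; tpos <- tpos[o]; diag <- diag[o]

  res <- list(); nres <- 0L
  last_diag <- NA_integer_; last_end <- -1L
  for (h in seq_along(cpos)) {
    if (is.na(last_diag) || diag[h] != last_diag) {
      last_diag <- diag[h]; last_end <- -1L
    }
    if (cpos[h] <= last_end) next
    cs <- cpos[h]; ts <- tpos[h]
    ce <- cs + k - 1L; te <- ts + k - 1L
    # right extension
    nr <- min(Lc - ce, Lt - te)
    right <- .xdrop_extend(
      if (nr > 0L) craw[(ce + 1L):(ce + nr)] == traw[(te + 1L):(te + nr)] else logical(0),
      xdrop)
    # left extension
    nl <- min(cs - 1L, ts - 1L)
    left <- .xdrop_extend(
      if (nl > 0L) rev(craw[(cs - nl):(cs - 1L)] == traw[(ts - nl):(ts - 1L)]) else logical(0),
      xdrop)
    score <- k + right$score + left$score
    contig_start <- cs - left$ext
    contig_end <- ce + right$ext
    last_end <- contig_end
    if (score < min_score) next
    nres <- nres + 1L
    res[[nres]] <- c(contig_start, contig_end, ts - left$ext, te + right$ext,
                     k + left$matches + right$matches,
                     contig_end - contig_start + 1L, score)
  }
  if (nres == 0L) return(empty)
  m <- do.call(rbind, res)
  data.frame(contig_start = m[, 1], contig_end = m[, 2], t_start = m[, 3],
             t_end = m[, 4], matches = m[, 5], aligned_columns = m[, 6],
             score = m[, 7], stringsAsFactors = FALSE)
}

#' Chain collinear HSPs into EVE fragments
#'
#' Greedy chaining in contig order: two HSPs are merged when they share an
#' orientation, their contig and virus gaps are both at most `max_gap`, and
#' they lie on the same alignment diagonal (equal gaps, as the model is
#' ungapped). Gap columns between members are counted as aligned columns;
#' when the contig and virus sequences are supplied the fragment identity is
#' recomputed exactly over the merged intervals, otherwise gap columns are
#' scored as mismatches against the pooled member matches.
#'
#' @param hsps data.frame from [find_hsps()].
#' @param max_gap maximum contig/virus gap (nt) bridged by chaining.
#' @param contig,virus optional sequences for exact identity recomputation.
#' @return data.frame of fragments sorted by contig coordinate:
#'   contig_start, contig_end, virus_start, virus_end, orientation,
#'   percent_identity, n_hsps, length.
#' @export
chain_into_fragments <- function(hsps, max_gap = 50L, contig = NULL,
                                 virus = NULL) {
  frag0 <- data.frame(contig_start = integer(0), contig_end = integer(0),
                      virus_start = integer(0), virus_end = integer(0),
                      orientation = character(0), percent_identity = numeric(0),
                      n_hsps = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hsps) || nrow(hsps) == 0L) return(frag0)
  h <- hsps[order(hsps$contig_start, hsps$contig_end), , drop = FALSE]
  chains <- list()
  cur <- h[1, , drop = FALSE]
  cur_n <- 1L
  flush <- function(cur, cur_n) {
    data.frame(contig_start = min(cur$contig_start),
               contig_end = max(cur$contig_end),
               virus_start = min(cur$virus_start),
               virus_end = max(cur$virus_end),
               orientation = cur$orientation[1],
               matches = sum(cur$matches),
               member_columns = sum(cur$aligned_columns),
               n_hsps = cur_n, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(h))[-1]) {
    x <- h[i, ]
    prev <- cur[nrow(cur), ]
    cgap <- x$contig_start - max(cur$contig_end) - 1L
    vgap <- if (x$orientation == "+") {
      x$virus_start - max(cur$virus_end) - 1L
    } else {
      min(cur$virus_start) - x$virus_end - 1L
    }
    same <- x$orientation == prev$orientation &&
      cgap <= max_gap && vgap <= max_gap && cgap == vgap
    if (same) {
      cur <- rbind(cur, x)
      cur_n <- cur_n + 1L
    } else {
      chains[[length(chains) + 1L]] <- flush(cur, cur_n)
      cur <- h[i, , drop = FALSE]
      cur_n <- 1L
    }
  }
  chains[[length(chains) + 1L]] <- flush(cur, cur_n)
  fr <- do.call(rbind, chains)
  fr$length <- fr$contig_end - fr$contig_start + 1L
  if (!is.null(contig) && !is.null(virus)) {
    fr$percent_identity <- vapply(seq_len(nrow(fr)), function(i)
      fragment_identity(fr[i, ], contig, virus), numeric(1))
  } else {
    # gap columns between members are mismatches
    total_cols <- fr$length
    fr$percent_identity <- 100 * fr$matches / total_cols
  }
  fr <- fr[order(fr$contig_start), c("contig_start", "contig_end",
                                     "virus_start", "virus_end",
                                     "orientation", "percent_identity",
                                     "n_hsps", "length")]
  rownames(fr) <- NULL
  fr
}

#' Percent identity of one fragment, recomputed from the sequences
#'
#' Compares the contig substring with the (orientation-aware) virus
#' substring over the fragment's reported intervals, column by column.
#'
#' @param fragment one fragment row (contig/virus intervals, orientation).
#' @param contig,virus named character vectors of length 1.
#' @return percent identity (0--100].
#' @export
fragment_identity <- function(fragment, contig, virus) {
  cr <- as_refseq(contig); vr <- as_refseq(virus)
  cs <- substr(cr$seq, fragment$contig_start, fragment$contig_end)
  vs <- substr(vr$seq, fragment$virus_start, fragment$virus_end)
  if (fragment$orientation == "-") vs <- dna_revcomp(vs)
  if (nchar(cs) != nchar(vs))
    stop("fragment intervals have unequal lengths; not an ungapped fragment")
  100 * sum(charToRaw(cs) == charToRaw(vs)) / nchar(cs)
}

#' Per-fragment and overall identity report
#'
#' Recomputes each fragment's percent identity directly from the sequences
#' and adds the length-weighted overall identity. Optionally writes a TSV
#' and a BED (0-based half-open) of the contig intervals.
#'
#' @param fragments data.frame from [chain_into_fragments()].
#' @param contig,virus named character vectors of length 1.
#' @param tsv,bed optional output paths.
#' @return list with `fragments` (identity-annotated table) and
#'   `overall_identity` (length-weighted percent identity).
#' @export
fragment_identity_report <- function(fragments, contig, virus,
                                     tsv = NULL, bed = NULL) {
  if (is.null(fragments) || nrow(fragments) == 0L)
    stop("no fragments to report")
  fr <- fragments
  fr$percent_identity <- vapply(seq_len(nrow(fr)), function(i)
    fragment_identity(fr[i, ], contig, virus), numeric(1))
  fr$length <- fr$contig_end - fr$contig_start + 1L
  overall <- sum(fr$percent_identity * fr$length) / sum(fr$length)
  if (!is.null(tsv)) write_tsv_header(fr, tsv)
  if (!is.null(bed)) {
    cid <- as_refseq(contig)$id
    bed_df <- data.frame(chrom = cid, start = fr$contig_start - 1L,
                         end = fr$contig_end,
                         name = sprintf("fragment_%d", seq_len(nrow(fr))),
                         score = round(fr$percent_identity),
                         strand = fr$orientation)
    write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  list(fragments = fr, overall_identity = overall)
}

#' Discover EVE fragments in a host contig
#'
#' One-call wrapper: [find_hsps()] then [chain_into_fragments()] with exact
#' identity recomputation.
#'
#' @inheritParams find_hsps
#' @param max_gap chaining gap tolerance (nt).
#' @return fragment data.frame (see [chain_into_fragments()]).
#' @export
discover_eve <- function(contig, virus, k = 11L, xdrop = 20L,
                         min_score = 30L, max_gap = 50L) {
  hsps <- find_hsps(contig, virus, k = k, xdrop = xdrop, min_score = min_score)
  chain_into_fragments(hsps, max_gap = max_gap, contig = contig, virus = virus)
}
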