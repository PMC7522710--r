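#' Positional nucleotide profile (sequence-logo matrix) of selected reads
#'
#' Selects alignments in a size class and orientation whose 5' end lies in
#' `region`, takes the read sequences as sequenced (5' to 3'), truncates
#' them at the 3' end to `truncate_to` nt, and tabulates weighted base
#' frequencies and per-position information content
#' \eqn{I(p) = 2 + \sum_b f_b \log_2 f_b} (0 log 0 = 0; no small-sample
#' correction). Frequencies are reported over RNA letters (T read as U).
#'
#' @param alignments alignment data.frame (one reference).
#' @param reads data.frame with `read_id`, `seq` supplying the sequences.
#' @param size_class inclusive read-length window (nt).
#' @param orientation "sense" (+ strand alignments) or "antisense" (-),
#'   relative to the reference + strand.
#' @param region optional c(start, end) restriction on the 5'-end position.
#' @param truncate_to 3' truncation length for the logo matrix.
#' @return object of class `nucleotide_profile`: list with `freq`
#'   (`truncate_to` x 4 matrix over A/C/G/U), `information` (bits per
#'   position), `n_reads` (total selected weight), `orientation`. With zero
#'   selected reads `freq`/`information` are NA and `n_reads` is 0.
#' @export
nucleotide_profile <- function(alignments, reads, size_class = c(26L, 30L),
                               orientation = c("sense", "antisense"),
                               region = NULL, truncate_to = 20L) {
  orientation <- match.arg(orientation)
  strand <- if (orientation == "sense") "+" else "-"
  sel <- alignments$strand == strand &
    alignments$read_len >= size_class[1] &
    alignments$read_len <= size_class[2]
  if (!is.null(region)) {
    sel <- sel & alignments$five_prime >= region[1] &
      alignments$five_prime <= region[2]
  }
  a <- alignments[sel, , drop = FALSE]
  bases <- c("A", "C", "G", "U")
  if (nrow(a) == 0L) {
    return(structure(list(freq = matrix(NA_real_, truncate_to, 4,
                                        dimnames = list(NULL, bases)),
                          information = rep(NA_real_, truncate_to),
                          n_reads = 0, orientation = orientation),
                     class = "nucleotide_profile"))
  }
  seqs <- reads$seq[match(a$read_id, reads$read_id)]
  if (anyNA(seqs)) stop("alignments reference reads absent from `reads`")
  seqs <- substr(chartr("T", "U", toupper(seqs)), 1L, truncate_to)
  counts <- matrix(0, truncate_to, 4, dimnames = list(NULL, bases))
  mat <- matrix("", nrow(a), truncate_to)
  ch <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(ch)) mat[i, seq_along(ch[[i]])] <- ch[[i]]
  for (b in bases) {
    counts[, b] <- colSums((mat == b) * a$weight)
  }
  totals <- rowSums(counts)
  freq <- counts / ifelse(totals > 0, totals, NA_real_)
  info <- apply(freq, 1, function(f) {
    if (anyNA(f)) return(NA_real_)
    2 + sum(ifelse(f > 0, f * log2(f), 0))
  })
  structure(list(freq = freq, information = info, n_reads = sum(a$weight),
                 orientation = orientation),
            class = "nucleotide_profile")
}

#' 1U and 10A bias fractions of a nucleotide profile
#'
#' @param profile a [nucleotide_profile()].
#' @return list with `u1` (U frequency at position 1) and `a10` (A
#'   frequency at position 10).
#' @export
bias_fractions <- function(profile) {
  if (profile$n_reads == 0)
    stop("bias fractions are undefined for an empty profile (n_reads = 0)")
  list(u1 = unname(profile$freq[1L, "U"]),
       a10 = unname(profile$freq[10L, "A"]))
}

#' 5'-overlap spectrum and ping-pong z-score
#'
#' With S(i) the weighted + strand 5'-end counts at reference position i
#' (restricted to `region` when given: a pair is attributed to a region by
#' the + read's 5' position) and A(j) the weighted - strand 5'-end counts,
#' the pair count at overlap distance d is
#' \eqn{c(d) = \sum_i S(i) A(i + d - 1)} for d = 1..Dmax. Probabilities are
#' p(d) = c(d)/sum(c); z-scores use the mean and population SD over the
#' d = 1..Dmax background window (each bin, including d = 10, belongs to
#' its own background). The ping-pong statistic is z(10). When the spectrum
#' is constant (sd = 0, e.g. all zeros) z is undefined and reported as NA.
#'
#' @param alignments alignment data.frame (one reference).
#' @param size_class inclusive read-length window (nt).
#' @param region optional c(start, end) restriction (on + read 5' ends).
#' @param Dmax largest overlap distance considered.
#' @return object of class `overlap_spectrum`: data.frame with `d`,
#'   `count`, `prob`, `z`; attributes `ping_pong_z` (z at d = 10) and
#'   `total_pairs`.
#' @export
overlap_spectrum <- function(alignments, size_class = c(26L, 30L),
                             region = NULL, Dmax = 30L) {
  a <- alignments[alignments$read_len >= size_class[1] &
                    alignments$read_len <= size_class[2], , drop = FALSE]
  L <- max(c(a$five_prime, 1L))
  S <- numeric(L + Dmax)
  A <- numeric(L + Dmax)
  plus <- a$strand == "+"
  if (!is.null(region)) {
    plus <- plus & a$five_prime >= region[1] & a$five_prime <= region[2]
  }
  minus <- a$strand == "-"
  if (any(plus)) {
    t <- tapply(a$weight[plus], a$five_prime[plus], sum)
    S[as.integer(names(t))] <- t
  }
  if (any(minus)) {
    t <- tapply(a$weight[minus], a$five_prime[minus], sum)
    A[as.integer(names(t))] <- t
  }
  cd <- vapply(seq_len(Dmax), function(d)
    sum(S[seq_len(L)] * A[seq_len(L) + d - 1L]), numeric(1))
  total <- sum(cd)
  prob <- if (total > 0) cd / total else rep(0, Dmax)
  mu <- mean(cd)
  sdp <- sqrt(mean((cd - mu)^2))  # population SD
  z <- if (sdp > 0) (cd - mu) / sdp else rep(NA_real_, Dmax)
  out <- data.frame(d = seq_len(Dmax), count = cd, prob = prob, z = z)
  class(out) <- c("overlap_spectrum", class(out))
  attr(out, "ping_pong_z") <- z[10L]
  attr(out, "total_pairs") <- total
  out
}

#' Ping-pong z-score of an alignment set
#'
#' Convenience accessor: z(10) of [overlap_spectrum()]. NA when the
#' spectrum is degenerate (no opposite-strand pairs).
#'
#' @inheritParams overlap_spectrum
#' @return numeric scalar (possibly NA).
#' @export
ping_pong_z <- function(alignments, size_class = c(26L, 30L), region = NULL,
                        Dmax = 30L) {
  attr(overlap_spectrum(alignments, size_class, region, Dmax), "ping_pong_z")
}

#' Re-express EVE-locus alignments in virus coordinates
#'
#' Maps each alignment on the EVE locus through the fragment containing its
#' footprint into virus coordinates, flipping the strand for fragments in
#' reverse orientation. Alignments not fully contained in any fragment are
#' dropped and counted.
#'
#' @param alignments alignment data.frame on the EVE-bearing contig (or
#'   locus; coordinates must match the fragment table's contig intervals).
#' @param fragments fragment table (contig/virus intervals, orientation).
#' @param virus_id reference id for the converted alignments.
#' @return alignment data.frame in virus coordinates, with attribute
#'   `n_dropped` (alignments outside all fragments).
#' @export
orient_relative_to_virus <- function(alignments, fragments, virus_id = "virus") {
  if (is.null(fragments) || nrow(fragments) == 0L)
    stop("fragment table is empty; cannot orient alignments")
  n <- nrow(alignments)
  pos <- alignments$pos
  end <- pos + alignments$read_len - 1L
  frag_idx <- rep(NA_integer_, n)
  for (f in seq_len(nrow(fragments))) {
    inside <- pos >= fragments$contig_start[f] & end <= fragments$contig_end[f]
    frag_idx[inside & is.na(frag_idx)] <- f
  }
  keep <- !is.na(frag_idx)
  a <- alignments[keep, , drop = FALSE]
  fi <- frag_idx[keep]
  fs <- fragments$contig_start[fi]
  vs <- fragments$virus_start[fi]
  ve <- fragments$virus_end[fi]
  flip <- fragments$orientation[fi] == "-"
  new_pos <- ifelse(flip,
                    ve - (a$pos + a$read_len - 1L - fs),
                    vs + (a$pos - fs))
  new_strand <- ifelse(flip,
                       ifelse(a$strand == "+", "-", "+"),
                       a$strand)
  a$pos <- as.integer(new_pos)
  a$strand <- new_strand
  a$ref_id <- virus_id
  a$five_prime <- as.integer(ifelse(new_strand == "+", a$pos,
                                    a$pos + a$read_len - 1L))
  rownames(a) <- NULL
  attr(a, "n_dropped") <- sum(!keep)
  a
}
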