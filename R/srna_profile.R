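#' Strand-resolved size spectrum of aligned small RNAs
#'
#' Sums alignment weights (1/n_best) by read length and strand over the
#' size window. Weighted counting is the default consequence of fractional
#' multi-mapper weighting; set `weighted = FALSE` for one-count-per-
#' alignment parity with single-hit aligners.
#'
#' @param alignments alignment data.frame (one reference).
#' @param window inclusive length window (nt).
#' @param weighted use alignment weights (default) or raw alignment counts.
#' @return data.frame with `length`, `strand`, `count` covering the full
#'   window grid (zeros included). Attributes: `library_total` (total
#'   weight in window), `n_dropped` (weight outside the window).
#' @export
size_spectrum <- function(alignments, window = c(19L, 33L), weighted = TRUE) {
  lens <- seq(window[1], window[2])
  grid <- expand.grid(length = lens, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  w <- if (weighted) alignments$weight else rep(1, nrow(alignments))
  inside <- alignments$read_len >= window[1] & alignments$read_len <= window[2]
  key <- paste(alignments$read_len[inside], alignments$strand[inside])
  agg <- tapply(w[inside], key, sum)
  gkey <- paste(grid$length, grid$strand)
  grid$count <- as.numeric(agg[gkey])
  grid$count[is.na(grid$count)] <- 0
  attr(grid, "library_total") <- sum(w[inside])
  attr(grid, "n_dropped") <- sum(w[!inside])
  grid
}

#' Per-position strand-resolved coverage of a reference
#'
#' For each reference position and strand, the weighted count of read 5'
#' ends and the weighted footprint depth, restricted to a read-length size
#' class. Positions with zero total depth are flagged uncovered.
#'
#' @param alignments alignment data.frame (one reference).
#' @param ref_len reference length (nt).
#' @param size_class inclusive read-length window (nt).
#' @param weighted use alignment weights (default) or raw counts.
#' @return data.frame with `pos`, `strand`, `five_prime_count`, `depth`,
#'   plus attribute `uncovered` (positions with zero depth on both strands)
#'   and `size_class`.
#' @export
coverage_track <- function(alignments, ref_len, size_class = c(19L, 33L),
                           weighted = TRUE) {
  a <- alignments[alignments$read_len >= size_class[1] &
                    alignments$read_len <= size_class[2], , drop = FALSE]
  w <- if (weighted) a$weight else rep(1, nrow(a))
  out <- list()
  for (s in c("+", "-")) {
    sel <- a$strand == s
    fp <- numeric(ref_len)
    dp_delta <- numeric(ref_len + 1L)
    if (any(sel)) {
      fp_tab <- tapply(w[sel], a$five_prime[sel], sum)
      fp[as.integer(names(fp_tab))] <- fp_tab
      st <- a$pos[sel]
      en <- a$pos[sel] + a$read_len[sel] - 1L
      for (i in seq_along(st)) {
        dp_delta[st[i]] <- dp_delta[st[i]] + w[sel][i]
        dp_delta[en[i] + 1L] <- dp_delta[en[i] + 1L] - w[sel][i]
      }
    }
    out[[s]] <- data.frame(pos = seq_len(ref_len), strand = s,
                           five_prime_count = fp,
                           depth = cumsum(dp_delta[seq_len(ref_len)]),
                           stringsAsFactors = FALSE)
  }
  track <- rbind(out[["+"]], out[["-"]])
  tot <- out[["+"]]$depth + out[["-"]]$depth
  attr(track, "uncovered") <- which(tot == 0)
  attr(track, "size_class") <- size_class
  track
}
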