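#' @importFrom stats runif rbinom prop.test setNames
#' @importFrom utils write.table read.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; delegates to Biostrings.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence at a given GC content
#'
#' @param n sequence length (nt).
#' @param gc_content expected fraction of G+C bases.
#' @return a single DNA string of length `n`.
#' @export
random_dna <- function(n, gc_content = 0.5) {
  stopifnot(n >= 0, gc_content >= 0, gc_content <= 1)
  if (n == 0L) return("")
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p[DNA_BASES]), collapse = "")
}

# substitute each base with prob `rate`, uniformly among the other 3 bases;
# returns list(seq = mutated string, n_sub = substitution count,
#              pos = substituted positions)
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(list(seq = seq, n_sub = 0L, pos = integer(0)))
  hit <- which(runif(n) < rate)
  if (length(hit) == 0L) return(list(seq = seq, n_sub = 0L, pos = integer(0)))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit), pos = hit)
}

# named length-1 character -> list(id, seq); accepts list(id=, seq=) too
as_refseq <- function(ref) {
  if (is.list(ref) && !is.null(ref$seq)) {
    return(list(id = as.character(ref$id), seq = toupper(as.character(ref$seq))))
  }
  stopifnot(is.character(ref), length(ref) == 1L)
  id <- names(ref)
  if (is.null(id) || !nzchar(id)) id <- "ref"
  list(id = id, seq = toupper(unname(ref)))
}

# Hamming distance helpers on raw vectors
count_mismatch_raw <- function(a, b) sum(a != b)

# write a TSV with '# key=value' comment header lines
write_tsv_header <- function(df, path, header = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_header <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}

#' An empty alignment table with the canonical columns
#'
#' @return zero-row data.frame with the alignment schema used throughout
#'   the package.
#' @export
empty_alignments <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             pos = integer(0), strand = character(0),
             mismatches = integer(0), n_best = integer(0),
             weight = numeric(0), read_len = integer(0),
             five_prime = integer(0), stringsAsFactors = FALSE)
}
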