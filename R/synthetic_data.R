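#' Simulation configuration for EVE / viral small-RNA read populations
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' describe the study system the pipeline is designed for: a ~10.7 kb
#' positive-strand RNA virus; an endogenous viral element (EVE) made of four
#' adjacent viral fragments, two of them inserted in reverse orientation,
#' diverged ~4\% from the circulating virus and embedded in host flanking
#' sequence; read populations of 21-nt siRNAs from both viral strands,
#' 26--30 nt primary piRNAs transcribed from the EVE locus with a 1U bias,
#' and secondary piRNAs cut from the viral genome whose 5' ends overlap a
#' primary 5' end by exactly 10 nt; 19--33 nt library size selection and a
#' small per-base sequencing error rate.
#'
#' @param seed integer RNG seed; mandatory. All generator operations derive
#'   their RNG state from it, so a fixed config reproduces byte-identical
#'   output.
#' @param virus_length viral genome length (nt).
#' @param n_fragments number of EVE fragments copied from the virus.
#' @param fragment_length_range length range (nt) of each fragment.
#' @param flipped_fragments indices (in EVE order) of fragments inserted in
#'   reverse-complement orientation relative to the virus.
#' @param divergence per-site substitution probability applied to each
#'   planted fragment (EVE-virus divergence).
#' @param host_flank_length host sequence length (nt) on each side of the EVE.
#' @param n_sirna,n_primary,n_secondary read counts per population.
#' @param sirna_length siRNA length (nt).
#' @param pirna_length_range piRNA length range (nt).
#' @param u1_enforcement probability that a primary piRNA start is drawn
#'   among template positions whose first transcribed base is U; the
#'   remainder are drawn among non-U starts, so this is exactly the expected
#'   1U fraction.
#' @param size_selection library size-selection window (nt); reads outside
#'   it are discarded, mirroring gel purification.
#' @param error_rate per-base sequencing substitution probability.
#' @param gc_content GC fraction of the random virus and host sequence.
#' @param degrade_quality if TRUE, write low-quality (Phred 2) 3' tails on
#'   the last 5 bases of each read (for quality-filter tests); otherwise all
#'   qualities are constant Phred 40.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed,
                              virus_length = 10700L,
                              n_fragments = 4L,
                              fragment_length_range = c(300L, 2000L),
                              flipped_fragments = NULL,
                              divergence = 0.04,
                              host_flank_length = 5000L,
                              n_sirna = 20000L,
                              n_primary = 20000L,
                              n_secondary = 20000L,
                              sirna_length = 21L,
                              pirna_length_range = c(26L, 30L),
                              u1_enforcement = 0.9,
                              size_selection = c(19L, 33L),
                              error_rate = 0.001,
                              gc_content = 0.5,
                              degrade_quality = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory")
  seed <- as.integer(seed)
  if (is.null(flipped_fragments)) {
    flipped_fragments <- intersect(c(2L, 3L), seq_len(n_fragments))
  }
  cfg <- list(seed = seed, virus_length = as.integer(virus_length),
              n_fragments = as.integer(n_fragments),
              fragment_length_range = as.integer(fragment_length_range),
              flipped_fragments = as.integer(flipped_fragments),
              divergence = divergence,
              host_flank_length = as.integer(host_flank_length),
              n_sirna = as.integer(n_sirna),
              n_primary = as.integer(n_primary),
              n_secondary = as.integer(n_secondary),
              sirna_length = as.integer(sirna_length),
              pirna_length_range = as.integer(pirna_length_range),
              u1_enforcement = u1_enforcement,
              size_selection = as.integer(size_selection),
              error_rate = error_rate, gc_content = gc_content,
              degrade_quality = isTRUE(degrade_quality))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$virus_length > 0L,
    cfg$n_fragments >= 0L,
    length(cfg$fragment_length_range) == 2L,
    all(cfg$fragment_length_range > 0L),
    cfg$fragment_length_range[1] <= cfg$fragment_length_range[2],
    all(cfg$flipped_fragments >= 1L),
    all(cfg$flipped_fragments <= cfg$n_fragments),
    cfg$divergence >= 0, cfg$divergence < 1,
    cfg$host_flank_length > 0L,
    cfg$n_sirna >= 0L, cfg$n_primary >= 0L, cfg$n_secondary >= 0L,
    cfg$sirna_length > 0L,
    length(cfg$pirna_length_range) == 2L,
    all(cfg$pirna_length_range > 0L),
    cfg$pirna_length_range[1] <= cfg$pirna_length_range[2],
    cfg$u1_enforcement >= 0, cfg$u1_enforcement <= 1,
    length(cfg$size_selection) == 2L,
    cfg$size_selection[1] <= cfg$size_selection[2],
    cfg$error_rate >= 0, cfg$error_rate < 1,
    cfg$gc_content >= 0, cfg$gc_content <= 1
  )
  invisible(cfg)
}

#' Generate a random viral genome
#'
#' I.i.d. bases at the configured GC content; a stand-in for a ~10.7 kb
#' insect-specific flavivirus genome. Deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return named character vector of length 1 (`virus`).
#' @export
make_virus_genome <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  v <- random_dna(config$virus_length, config$gc_content)
  c(virus = v)
}

#' Plant an EVE into a synthetic host contig
#'
#' Copies `n_fragments` non-overlapping segments of the virus,
#' reverse-complements those listed in `flipped_fragments`, applies i.i.d.
#' substitutions at rate `divergence`, concatenates the fragments adjacently
#' (no host spacers, mirroring the adjacency of natural EVE fragments) and
#' embeds the concatenation between random host flanks.
#'
#' @param virus named character vector (the viral genome).
#' @param config a [simulation_config()].
#' @return list with `host_contig` (named character), `fragments` (the true
#'   fragment table: contig/virus intervals, orientation, realized percent
#'   identity), `eve_start`/`eve_end` (EVE interval on the contig).
#' @export
plant_eve <- function(virus, config) {
  validate_simulation_config(config)
  vref <- as_refseq(virus)
  Lv <- nchar(vref$seq)
  set.seed(config$seed + 1L)

  n <- config$n_fragments
  # draw fragment lengths and non-overlapping virus intervals, bounded retries
  ok <- FALSE
  for (try in seq_len(200L)) {
    lens <- sample(seq(config$fragment_length_range[1],
                       config$fragment_length_range[2]), n, replace = TRUE)
    starts <- vapply(lens, function(l) {
      hi <- Lv - l + 1L
      if (hi < 1L) return(NA_integer_)
      sample.int(hi, 1L)
    }, integer(1))
    if (anyNA(starts)) next
    ends <- starts + lens - 1L
    o <- order(starts)
    if (n <= 1L || all(starts[o][-1] > ends[o][-n])) {
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("could not place ", n, " non-overlapping fragments on a ",
                Lv, " nt virus after bounded retries")

  eve_parts <- character(n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    seg <- substr(vref$seq, starts[i], starts[i] + lens[i] - 1L)
    if (i %in% config$flipped_fragments) seg <- dna_revcomp(seg)
    mut <- mutate_seq(seg, config$divergence)
    eve_parts[i] <- mut$seq
    identity[i] <- 100 * (lens[i] - mut$n_sub) / lens[i]
  }

  left <- random_dna(config$host_flank_length, config$gc_content)
  right <- random_dna(config$host_flank_length, config$gc_content)
  contig <- paste0(left, paste(eve_parts, collapse = ""), right)
  eve_start <- config$host_flank_length + 1L
  offs <- cumsum(c(0L, lens[-n]))
  fragments <- data.frame(
    fragment = seq_len(n),
    contig_start = eve_start + offs,
    contig_end = eve_start + offs + lens - 1L,
    virus_start = starts,
    virus_end = starts + lens - 1L,
    orientation = ifelse(seq_len(n) %in% config$flipped_fragments, "-", "+"),
    percent_identity = identity,
    length = lens,
    stringsAsFactors = FALSE
  )
  list(host_contig = c(host = contig), fragments = fragments,
       eve_start = eve_start,
       eve_end = eve_start + sum(lens) - 1L)
}

# map a contig 5'-position (contig + strand) through its fragment into virus
# coordinates; returns list(virus_5p, virus_strand) or NAs when the read is
# not fully inside one fragment
.contig_to_virus_5p <- function(p, readlen, fragments) {
  f <- fragments[p >= fragments$contig_start &
                   (p + readlen - 1L) <= fragments$contig_end, , drop = FALSE]
  if (nrow(f) != 1L) return(list(virus_5p = NA_integer_, virus_strand = NA_character_))
  if (f$orientation == "+") {
    list(virus_5p = f$virus_start + (p - f$contig_start), virus_strand = "+")
  } else {
    list(virus_5p = f$virus_end - (p - f$contig_start), virus_strand = "-")
  }
}

#' Simulate small-RNA read populations with ground-truth labels
#'
#' Emits three truth-labelled populations. siRNAs: fixed length, 5' ends
#' uniform over the virus, both strands equiprobable, sequence taken from
#' the virus. Primary piRNAs: lengths uniform in `pirna_length_range`,
#' transcribed from the EVE locus of the host contig in its + (transcript)
#' orientation, so fragments flipped relative to the virus yield reads
#' antisense to the virus; 5' starts are drawn among U-start template
#' positions with probability `u1_enforcement` (rejection sampling of start
#' positions, never mutation of the read). Secondary piRNAs: for a sampled
#' U-initiated primary whose 5' end maps to virus coordinate `j` on the
#' minus strand, a plus-strand read is cut from the *virus* with 5' end at
#' `i = j - 9` (exact 10-nt 5' overlap). Per-base sequencing errors are then
#' applied and reads outside the size-selection window discarded.
#'
#' @param truth output of [plant_eve()] plus the `virus` element (see
#'   [simulate_dataset()]).
#' @param config a [simulation_config()].
#' @return list with `reads` (data.frame: read_id, seq, qual),
#'   `labels` (per-read truth: class, template, template-space 5' position
#'   and strand, virus-space 5' position and strand, length, partner_id),
#'   and `n_rejected` (size-selection rejections).
#' @export
simulate_reads <- function(truth, config) {
  validate_simulation_config(config)
  vref <- as_refseq(truth$virus)
  cref <- as_refseq(truth$host_contig)
  Lv <- nchar(vref$seq)
  fragments <- truth$fragments
  set.seed(config$seed + 2L)

  ids <- character(0); seqs <- character(0)
  cls <- character(0); template <- character(0)
  t5p <- integer(0); tstrand <- character(0)
  v5p <- integer(0); vstrand <- character(0)
  partner <- character(0)

  # --- siRNAs: both viral strands, uniform 5' positions -------------------
  if (config$n_sirna > 0L) {
    l <- config$sirna_length
    if (l > Lv) stop("sirna_length exceeds virus length")
    strand <- sample(c("+", "-"), config$n_sirna, replace = TRUE)
    fs <- sample.int(Lv - l + 1L, config$n_sirna, replace = TRUE)  # footprint start
    sq <- substring(vref$seq, fs, fs + l - 1L)
    neg <- strand == "-"
    if (any(neg)) sq[neg] <- dna_revcomp(sq[neg])
    p5 <- ifelse(neg, fs + l - 1L, fs)
    ids <- c(ids, sprintf("sirna_%06d", seq_len(config$n_sirna)))
    seqs <- c(seqs, sq)
    cls <- c(cls, rep("sirna", config$n_sirna))
    template <- c(template, rep("virus", config$n_sirna))
    t5p <- c(t5p, as.integer(p5)); tstrand <- c(tstrand, strand)
    v5p <- c(v5p, as.integer(p5)); vstrand <- c(vstrand, strand)
    partner <- c(partner, rep(NA_character_, config$n_sirna))
  }

  # --- primary piRNAs: EVE transcript (+ strand of the contig) ------------
  prim_tab <- NULL
  if (config$n_primary > 0L) {
    if (is.null(fragments) || nrow(fragments) == 0L)
      stop("primary piRNAs requested but the truth has no planted EVE")
    lr <- config$pirna_length_range
    cch <- strsplit(cref$seq, "", fixed = TRUE)[[1]]
    lens <- sample(seq(lr[1], lr[2]), config$n_primary, replace = TRUE)
    starts <- integer(config$n_primary)
    enforce <- runif(config$n_primary) < config$u1_enforcement
    for (l in unique(lens)) {
      elig <- seq(truth$eve_start, truth$eve_end - l + 1L)
      isT <- cch[elig] == "T"
      posT <- elig[isT]; posN <- elig[!isT]
      sel <- which(lens == l)
      for (i in sel) {
        pool <- if (enforce[i] && length(posT)) posT
                else if (!enforce[i] && length(posN)) posN
                else elig
        starts[i] <- pool[sample.int(length(pool), 1L)]
      }
    }
    sq <- substring(cref$seq, starts, starts + lens - 1L)
    vmap <- lapply(seq_len(config$n_primary), function(i)
      .contig_to_virus_5p(starts[i], lens[i], fragments))
    pv5 <- vapply(vmap, `[[`, integer(1), "virus_5p")
    pvs <- vapply(vmap, `[[`, character(1), "virus_strand")
    pid <- sprintf("primary_%06d", seq_len(config$n_primary))
    ids <- c(ids, pid); seqs <- c(seqs, sq)
    cls <- c(cls, rep("primary_pirna", config$n_primary))
    template <- c(template, rep("eve", config$n_primary))
    t5p <- c(t5p, starts); tstrand <- c(tstrand, rep("+", config$n_primary))
    v5p <- c(v5p, pv5); vstrand <- c(vstrand, pvs)
    partner <- c(partner, rep(NA_character_, config$n_primary))
    prim_tab <- data.frame(read_id = pid, start = starts, len = lens,
                           first_base = substr(sq, 1L, 1L),
                           virus_5p = pv5, virus_strand = pvs,
                           stringsAsFactors = FALSE)
  }

  # --- secondary piRNAs: virus template, exact 10-nt 5' overlap -----------
  if (config$n_secondary > 0L) {
    lr <- config$pirna_length_range
    if (is.null(prim_tab))
      stop("secondary piRNAs requested but no primary piRNAs were simulated")
    elig <- prim_tab[!is.na(prim_tab$virus_strand) &
                       prim_tab$virus_strand == "-" &
                       prim_tab$first_base == "T", , drop = FALSE]
    if (nrow(elig) == 0L)
      stop("secondary piRNAs requested but no eligible (U-initiated, ",
           "virus-antisense) primary piRNAs exist")
    lens <- sample(seq(lr[1], lr[2]), config$n_secondary, replace = TRUE)
    i5 <- integer(config$n_secondary)
    pids <- character(config$n_secondary)
    for (r in seq_len(config$n_secondary)) {
      for (try in seq_len(100L)) {
        pk <- sample.int(nrow(elig), 1L)
        i <- elig$virus_5p[pk] - 9L
        if (i >= 1L && i + lens[r] - 1L <= Lv) {
          i5[r] <- i; pids[r] <- elig$read_id[pk]
          break
        }
      }
      if (i5[r] == 0L) stop("could not place a secondary piRNA inside the virus")
    }
    sq <- substring(vref$seq, i5, i5 + lens - 1L)
    ids <- c(ids, sprintf("secondary_%06d", seq_len(config$n_secondary)))
    seqs <- c(seqs, sq)
    cls <- c(cls, rep("secondary_pirna", config$n_secondary))
    template <- c(template, rep("virus", config$n_secondary))
    t5p <- c(t5p, i5); tstrand <- c(tstrand, rep("+", config$n_secondary))
    v5p <- c(v5p, i5); vstrand <- c(vstrand, rep("+", config$n_secondary))
    partner <- c(partner, pids)
  }

  # --- sequencing errors ---------------------------------------------------
  if (config$error_rate > 0 && length(seqs)) {
    for (r in seq_along(seqs)) {
      seqs[r] <- mutate_seq(seqs[r], config$error_rate)$seq
    }
  }

  # --- size selection ------------------------------------------------------
  lens_all <- nchar(seqs)
  keep <- lens_all >= config$size_selection[1] & lens_all <= config$size_selection[2]
  n_rejected <- sum(!keep)

  qual <- strrep("I", lens_all[keep])  # Phred 40
  if (config$degrade_quality) {
    qual <- vapply(lens_all[keep], function(l) {
      tail_n <- min(5L, l)
      paste0(strrep("I", l - tail_n), strrep("#", tail_n))  # Phred 2 tail
    }, character(1))
  }

  reads <- data.frame(read_id = ids[keep], seq = seqs[keep], qual = qual,
                      stringsAsFactors = FALSE)
  labels <- data.frame(read_id = ids[keep], class = cls[keep],
                       template = template[keep], true_5p = t5p[keep],
                       true_strand = tstrand[keep], virus_5p = v5p[keep],
                       virus_strand = vstrand[keep], length = lens_all[keep],
                       partner_id = partner[keep], stringsAsFactors = FALSE)
  list(reads = reads, labels = labels, n_rejected = n_rejected)
}

#' Run the whole generator: virus, EVE-bearing contig, labelled reads
#'
#' @param config a [simulation_config()].
#' @return list with `virus`, `host_contig`, `fragments`, `eve_start`,
#'   `eve_end`, `reads`, `labels`, `n_rejected`, `config`.
#' @export
simulate_dataset <- function(config) {
  virus <- make_virus_genome(config)
  planted <- if (config$n_fragments > 0L) {
    plant_eve(virus, config)
  } else {
    set.seed(config$seed + 1L)
    list(host_contig = c(host = random_dna(2L * config$host_flank_length,
                                           config$gc_content)),
         fragments = NULL, eve_start = NA_integer_, eve_end = NA_integer_)
  }
  truth <- c(list(virus = virus), planted)
  rd <- simulate_reads(truth, config)
  c(truth, rd, list(config = config))
}
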