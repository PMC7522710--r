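#' Prevalence point estimate with Wilson score confidence interval
#'
#' Point estimate is 100 * positive / tested; the confidence interval is
#' the Wilson score interval (via [stats::prop.test()] without continuity
#' correction), the package's declared choice for small-sample binomial
#' prevalence.
#'
#' @param positive number of positive individuals.
#' @param tested number tested; must be > 0 and >= `positive`.
#' @param conf confidence level.
#' @return list with `percent`, `ci_low`, `ci_high` (all on the percent
#'   scale).
#' @export
prevalence <- function(positive, tested, conf = 0.95) {
  if (tested <= 0) stop("`tested` must be > 0")
  if (positive < 0 || positive > tested)
    stop("`positive` must lie in [0, tested]")
  ci <- prop.test(positive, tested, conf.level = conf,
                  correct = FALSE)$conf.int
  list(percent = 100 * positive / tested,
       ci_low = 100 * ci[1], ci_high = 100 * ci[2])
}

pipeline_schema <- function() {
  list(
    seed = "integer",
    out_dir = "character",
    simulate = names(formals(simulation_config)),
    align = c("max_mismatch", "seed_k"),
    discover = c("k", "xdrop", "min_score", "max_gap"),
    signature = c("size_class", "Dmax", "region"),
    trim = c("adapter", "min_phred", "size_window", "require_adapter")
  )
}

validate_pipeline_config <- function(cfg) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key: '", unknown[1], "'")
  for (sect in intersect(names(cfg), c("simulate", "align", "discover",
                                       "signature", "trim"))) {
    bad <- setdiff(names(cfg[[sect]]), schema[[sect]])
    if (length(bad))
      stop("unknown config key: '", sect, ".", bad[1], "'")
  }
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  invisible(cfg)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL  # the hash covers analysis-relevant keys only
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg[order(names(cfg))], tf)
  unname(tools::md5sum(tf))
}

tsv_header <- function(cfg, hash) {
  c(paste0("evepirna ", as.character(packageVersion("evepirna"))),
    paste0("config_hash=", hash),
    paste0("seed=", cfg$seed))
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate -> align -> discover -> profile -> signature ->
#' disambiguate on a synthetic dataset and writes every stage's table under
#' `out_dir` as TSV (with tool version, config hash and seed in comment
#' headers), references as FASTA, reads as FASTQ, and alignments as SAM.
#' Given a fixed config the output files are byte-identical across runs.
#'
#' @param config path to a YAML config, or an equivalent named list.
#'   Recognised keys: `seed` (mandatory), `out_dir`, and the optional
#'   sections `simulate` (arguments of [simulation_config()]), `align`
#'   (`max_mismatch`, `seed_k`), `discover` (`k`, `xdrop`, `min_score`,
#'   `max_gap`), `signature` (`size_class`, `Dmax`, `region`). Unknown keys
#'   raise an error naming the key.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return (invisibly) a list with the run directory, the per-stage objects
#'   and the collated `report` data.frame.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_pipeline_config(cfg)
  dir <- out_dir %||% cfg$out_dir %||% stop("config must set 'out_dir'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  hdr <- tsv_header(cfg, hash)
  log_path <- file.path(dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- simulate -----------------------------------------------------------
  sim_args <- cfg$simulate %||% list()
  sim_args$seed <- cfg$seed
  scfg <- do.call(simulation_config, sim_args)
  sim <- simulate_dataset(scfg)
  write_fasta(c(sim$virus, sim$host_contig), file.path(dir, "references.fasta"))
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  write_tsv_header(sim$fragments, file.path(dir, "truth_fragments.tsv"), hdr)
  write_tsv_header(sim$labels, file.path(dir, "truth_read_labels.tsv"), hdr)
  say("simulate: ", nrow(sim$reads), " reads emitted, ",
      sim$n_rejected, " rejected by size selection")

  # --- align --------------------------------------------------------------
  mmx <- cfg$align$max_mismatch %||% 1L
  seed_k <- cfg$align$seed_k %||% 9L
  va <- align_reads(sim$reads, sim$virus, max_mismatch = mmx, k = seed_k)
  ca <- align_reads(sim$reads, sim$host_contig, max_mismatch = mmx, k = seed_k)
  write_sam(va, sim$reads, sim$virus, file.path(dir, "virus_alignments.sam"))
  write_sam(ca, sim$reads, sim$host_contig, file.path(dir, "contig_alignments.sam"))
  say("align: ", length(unique(va$read_id)), "/", nrow(sim$reads),
      " reads mapped to the virus, ", length(unique(ca$read_id)),
      " to the host contig (max_mismatch=", mmx, ")")

  # --- discover -----------------------------------------------------------
  dk <- cfg$discover$k %||% 11L
  fragments <- discover_eve(sim$host_contig, sim$virus, k = dk,
                            xdrop = cfg$discover$xdrop %||% 20L,
                            min_score = cfg$discover$min_score %||% 30L,
                            max_gap = cfg$discover$max_gap %||% 50L)
  idrep <- fragment_identity_report(fragments, sim$host_contig, sim$virus,
                                    tsv = file.path(dir, "eve_fragments.tsv"),
                                    bed = file.path(dir, "eve_fragments.bed"))
  say("discover: ", nrow(fragments), " EVE fragments, overall identity ",
      sprintf("%.2f", idrep$overall_identity), "%")

  # --- profile ------------------------------------------------------------
  spec <- size_spectrum(va)
  write_tsv_header(spec, file.path(dir, "size_spectrum.tsv"), hdr)
  cov <- coverage_track(va, nchar(sim$virus[[1]]), size_class = c(26L, 30L))
  write_tsv_header(cov, file.path(dir, "coverage_26_30.tsv"), hdr)

  # --- signature ----------------------------------------------------------
  size_class <- cfg$signature$size_class %||% c(26L, 30L)
  Dmax <- cfg$signature$Dmax %||% 30L
  region <- cfg$signature$region
  os <- overlap_spectrum(va, size_class = size_class, region = region,
                         Dmax = Dmax)
  write_tsv_header(as.data.frame(os), file.path(dir, "overlap_spectrum.tsv"), hdr)
  profs <- list()
  for (orient in c("sense", "antisense")) {
    pr <- nucleotide_profile(va, sim$reads, size_class = size_class,
                             orientation = orient, region = region)
    profs[[orient]] <- pr
    if (pr$n_reads > 0) {
      m <- as.data.frame(pr$freq)
      m$position <- seq_len(nrow(m))
      m$information <- pr$information
      write_tsv_header(m, file.path(dir, paste0("logo_", orient, ".tsv")), hdr)
    }
  }
  zpp <- attr(os, "ping_pong_z")
  say("signature: ping_pong_z = ",
      if (is.na(zpp)) "NA (no opposite-strand pairs)" else sprintf("%.2f", zpp))

  # --- disambiguate -------------------------------------------------------
  eve_locus <- c(eve = substr(sim$host_contig[[1]], sim$eve_start, sim$eve_end))
  frag_local <- sim$fragments
  frag_local$contig_start <- frag_local$contig_start - sim$eve_start + 1L
  frag_local$contig_end <- frag_local$contig_end - sim$eve_start + 1L
  cls <- classify_reads(sim$reads, sim$virus, eve_locus,
                        fragments = frag_local, k = seed_k)
  write_tsv_header(cls$summary, file.path(dir, "classification_summary.tsv"), hdr)
  write_tsv_header(cls$classification,
                   file.path(dir, "classification_reads.tsv"), hdr)
  say("disambiguate: ",
      paste(cls$summary$class, cls$summary$n, sep = "=", collapse = ", "))

  # --- report (collation only, no recomputation) --------------------------
  report <- data.frame(
    metric = c("reads_emitted", "reads_rejected_size", "reads_mapped_virus",
               "eve_fragments", "overall_identity_percent", "ping_pong_z"),
    value = c(nrow(sim$reads), sim$n_rejected, length(unique(va$read_id)),
              nrow(fragments), idrep$overall_identity, zpp))
  write_tsv_header(report, file.path(dir, "report.tsv"), hdr)
  writeLines(log_lines, log_path)

  invisible(list(dir = dir, sim = sim, virus_alignments = va,
                 contig_alignments = ca, fragments = fragments,
                 identity = idrep, size_spectrum = spec,
                 overlap_spectrum = os, profiles = profs,
                 classification = cls, report = report))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
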