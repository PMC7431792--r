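# End-to-end pipeline driver: ORF calling -> (optional terminator screen) ->
# stage-1 screen -> stage-2 competitive assignment -> genome mapping ->
# normalized abundance, with a machine-readable run manifest. This is the
# programmatic equivalent of running the whole recruitment analysis in one
# call; the numbered scripts under analysis/ are thin narrative drivers over
# it and the individual module functions.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML/JSON file parsed into one)
#' with entries: `genome` (path to a FASTA with the focal genome, or a
#' `genome_record`), `reads` (path to FASTA/FASTQ, or a read data.frame),
#' optional `orfs_gff3` (external ORF calls to combine with the built-in
#' caller), optional `decoys` (path to a protein FASTA with headers
#' `<subject_id> phage=<phage_id>`, or a decoy data.frame), `evalue`
#' (cutoff, default 1e-5), `normalizer` ("per_orf" or "per_length"),
#' `db_gb` (metagenome size in Gb; default: bases in `reads` / 1e9),
#' `circular` (default TRUE), `find_terminators` (default FALSE), `seed`
#' (default 1), `out_dir` (required), `mode` ("seeded"/"exhaustive").
#'
#' @param config named list or path to a YAML/JSON config file.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_fragrec(sprintf("config file not found: %s", config),
                   "fragrec_input_error")
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config)
    else yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop_fragrec("config must be a named list", "fragrec_config_error")
  defaults <- list(evalue = 1e-5, normalizer = "per_orf", circular = TRUE,
                   find_terminators = FALSE, seed = 1L, mode = "seeded",
                   db_gb = NULL, orfs_gff3 = NULL, decoys = NULL,
                   focal_phage_id = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  for (nm in c("genome", "reads", "out_dir"))
    if (is.null(config[[nm]]))
      stop_fragrec(sprintf("config is missing required entry '%s'", nm),
                   "fragrec_config_error")
  ev <- suppressWarnings(as.numeric(config$evalue))
  if (is.na(ev) || ev <= 0)
    stop_fragrec(sprintf("config entry 'evalue' is not a positive number: %s",
                         config$evalue), "fragrec_config_error")
  config$evalue <- ev
  if (!config$normalizer %in% c("per_orf", "per_length"))
    stop_fragrec("config entry 'normalizer' must be 'per_orf' or 'per_length'",
                 "fragrec_config_error")
  if (!config$mode %in% c("seeded", "exhaustive"))
    stop_fragrec("config entry 'mode' must be 'seeded' or 'exhaustive'",
                 "fragrec_config_error")
  for (nm in c("genome", "reads", "orfs_gff3")) {
    v <- config[[nm]]
    if (is.character(v) && length(v) == 1L && !file.exists(v))
      stop_fragrec(sprintf("input file for '%s' not found: %s", nm, v),
                   "fragrec_input_error")
  }
  config
}

read_decoy_fasta <- function(path) {
  fa <- read_fasta(path)
  phage <- gff3_attr(gsub(" ", ";", fa$desc), "phage")
  phage[is.na(phage)] <- "decoy"
  data.frame(subject_id = fa$id, phage_id = phage, peptide = fa$seq,
             stringsAsFactors = FALSE)
}

#' Run the full recruitment pipeline
#'
#' Executes ORF calling (optionally combined with imported external calls
#' via the longer-call consensus rule), an optional terminator screen, the
#' two-stage competitive recruitment, genome mapping, and abundance
#' normalization; writes all primary outputs plus a JSON run manifest under
#' `config$out_dir`. Outputs are deterministic given the config.
#'
#' @param config see [validate_config()].
#' @return invisibly, a list with `orfs`, `terminators`, `candidates`,
#'   `recruits`, `abundance`, `manifest`.
#' @export
run_recruitment_pipeline <- function(config) {
  t0 <- Sys.time()
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(t) as.numeric(difftime(Sys.time(), t, units = "secs"))

  t <- tic()
  genome <- config$genome
  if (is.character(genome)) {
    fa <- read_fasta(genome)
    if (!nrow(fa))
      stop_fragrec("genome FASTA contains no records", "fragrec_input_error")
    genome <- genome_record(fa$id[1], fa$seq[1], circular = config$circular,
                            desc = fa$desc[1])
  }
  reads <- config$reads
  if (is.character(reads)) reads <- read_reads(reads)
  decoys <- config$decoys
  if (is.character(decoys)) decoys <- read_decoy_fasta(decoys)
  focal_id <- if (is.null(config$focal_phage_id)) genome$id
  else config$focal_phage_id
  timings$load <- toc(t)

  t <- tic()
  orfs <- call_orfs(genome)
  if (!is.null(config$orfs_gff3)) {
    imported <- gff3_to_orfs(config$orfs_gff3, genome)
    orfs <- consensus_longer(orfs, imported)
  }
  orfs_to_gff3(orfs, file.path(config$out_dir, "orfs.gff3"))
  write_proteome(orfs, file.path(config$out_dir, "proteome.faa"))
  timings$orfcall <- toc(t)

  terms <- NULL
  if (isTRUE(config$find_terminators)) {
    t <- tic()
    terms <- find_terminators(genome, orfs)
    write_terminator_table(terms, file.path(config$out_dir, "terminators.tsv"))
    timings$terminators <- toc(t)
  }

  t <- tic()
  proteome <- orf_proteins(orfs)
  cand <- screen_reads(reads, proteome, cutoff = config$evalue,
                       mode = config$mode)
  timings$screen <- toc(t)

  t <- tic()
  db <- composite_db(focal_id, proteome, decoys = decoys)
  recruits <- competitive_assign(cand, db, orfs, cutoff = config$evalue,
                                 mode = config$mode)
  write_recruitment_table(recruits,
                          file.path(config$out_dir, "recruitment.tsv"))
  timings$recruit <- toc(t)

  t <- tic()
  db_gb <- if (is.null(config$db_gb)) sum(nchar(reads$seq)) / 1e9
  else as.numeric(config$db_gb)
  metas <- unique(reads$source_metagenome)
  ab <- do.call(rbind, lapply(metas, function(mg) abundance_row(
    phage_id = focal_id, metagenome_id = mg,
    n_hits = sum(recruits$source_metagenome == mg),
    n_orfs = nrow(orfs), genome_len_bp = genome_length(genome),
    db_gb = db_gb, normalizer = config$normalizer)))
  write_abundance_table(ab, file.path(config$out_dir, "abundance.tsv"))
  timings$abundance <- toc(t)

  counts <- list(reads_in = nrow(reads), candidates = nrow(cand),
                 recruited = nrow(recruits))
  if (!(counts$recruited <= counts$candidates &&
        counts$candidates <= counts$reads_in))
    stop_fragrec("stage counts violate recruited <= candidates <= reads",
                 "fragrec_internal_error")
  manifest <- list(
    package = "fragrec",
    version = as.character(utils::packageVersion("fragrec")),
    seed = config$seed,
    config = config[setdiff(names(config), c("genome", "reads", "decoys"))],
    focal_phage_id = focal_id, genome_length = genome_length(genome),
    n_orfs = nrow(orfs),
    n_terminators = if (is.null(terms)) NA_integer_ else nrow(terms),
    counts = counts, db_gb = db_gb,
    timings_sec = lapply(timings, round, 3),
    outputs = list(orfs = "orfs.gff3", proteome = "proteome.faa",
                   recruitment = "recruitment.tsv",
                   abundance = "abundance.tsv"),
    total_sec = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(orfs = orfs, terminators = terms, candidates = cand,
                 recruits = recruits, abundance = ab, manifest = manifest))
}
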