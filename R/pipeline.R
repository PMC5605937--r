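#' Assemble a pipeline configuration
#'
#' Every default equals the published assay value where one exists: the 45-nt
#' anchor, 7-nt overlap trim, 16/20-nt length thresholds, Phred 10/15
#' trimming, 0.95 identity cutoff, 29-base motif window, 8 replicates.
#'
#' @param simulate if TRUE, generate a synthetic library from `sim`
#' @param sim a `sim_config` (used when `simulate = TRUE`)
#' @param genome_fasta,gff,r1,r2,replicate_ids input paths for real-data runs
#'   (`r1`/`r2` are parallel vectors, one pair of FASTQs per replicate)
#' @param anchor,overlap_trim,min_read1_len,read2_prefix_len,qmin,qavg filter
#'   settings (see [filter_config()])
#' @param min_identity,seed_k,max_insert mapper settings
#' @param tolerance,min_reads,attB_position,attB_strand,attB_window,near_window
#'   caller settings (attB NULL = auto / from manifest when simulating)
#' @param offset_left,offset_right,pseudocount,top_k motif settings
#' @param guide_site integration-site position for sgRNA design (NULL = the
#'   highest-frequency secondary site), `guide_radius`, `guide_max_mm` as in
#'   the guide module; `design_guides` toggles the stage
#' @param seed global seed; stage streams derive from it
#' @param output_dir where `run_all` writes outputs (NULL = no files)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            genome_fasta = NULL, gff = NULL,
                            r1 = NULL, r2 = NULL, replicate_ids = NULL,
                            anchor = DEFAULT_ANCHOR, overlap_trim = 7L,
                            min_read1_len = 16L, read2_prefix_len = 20L,
                            qmin = 10L, qavg = 15L,
                            min_identity = 0.95, seed_k = 12L, max_insert = 1000L,
                            tolerance = 0L, min_reads = 1L,
                            attB_position = NULL, attB_strand = NULL,
                            attB_window = 10L, near_window = 500L,
                            offset_left = 14L, offset_right = 14L,
                            pseudocount = 1, top_k = 25L,
                            design_guides = TRUE, guide_site = NULL,
                            guide_radius = 30L, guide_max_mm = 2L,
                            seed = 1L, output_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Range-checks every field and reports all violations at once; semantically
#' odd but legal settings (e.g. `qavg < qmin`) produce warnings in the
#' returned object, not errors.
#'
#' @param cfg a `pipeline_config`
#' @return list with `ok` (logical), `errors`, `warnings` (character vectors)
#' @export
validate_config <- function(cfg) {
  errors <- character(0); warnings <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(nchar(cfg$anchor) > 0 && !grepl("[^ACGT]", toupper(cfg$anchor)),
      "anchor must be a non-empty ACGT string")
  chk(cfg$overlap_trim >= 0, "overlap_trim must be >= 0")
  chk(cfg$min_read1_len >= 1, "min_read1_len must be >= 1")
  chk(cfg$read2_prefix_len >= 1, "read2_prefix_len must be >= 1")
  chk(cfg$qmin >= 0, "qmin must be >= 0")
  chk(cfg$qavg >= 0, "qavg must be >= 0")
  chk(cfg$min_identity > 0 && cfg$min_identity <= 1,
      "min_identity must lie in (0, 1]")
  chk(cfg$seed_k >= 8, "seed_k must be >= 8")
  chk(cfg$max_insert >= 1, "max_insert must be >= 1")
  chk(cfg$tolerance >= 0, "tolerance must be >= 0")
  chk(cfg$min_reads >= 1, "min_reads must be >= 1")
  chk(cfg$attB_window >= 0, "attB_window must be >= 0")
  chk(cfg$near_window >= 0, "near_window must be >= 0")
  chk(cfg$offset_left >= 0 && cfg$offset_right >= 0, "offsets must be >= 0")
  chk(cfg$pseudocount >= 0, "pseudocount must be >= 0")
  chk(cfg$guide_radius >= 12, "guide_radius must be >= 12")
  chk(cfg$guide_max_mm >= 0, "guide_max_mm must be >= 0")
  if (!cfg$simulate) {
    chk(!is.null(cfg$genome_fasta), "genome_fasta required when simulate = FALSE")
    chk(!is.null(cfg$r1) && !is.null(cfg$r2) && length(cfg$r1) == length(cfg$r2),
        "r1/r2 must be parallel FASTQ path vectors")
  }
  if (cfg$qavg < cfg$qmin)
    warnings <- c(warnings, "qavg < qmin is unusual (mean rule never binds)")
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

#' Serialize / restore a pipeline configuration as JSON
#' @param cfg a `pipeline_config`
#' @param path JSON file
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (!is.null(x$sim)) x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$sim)) raw$sim <- do.call(simulation_config, raw$sim)
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' simulate (optional) -> filter -> map -> call -> motif -> guides, with a
#' machine-readable run summary.  Deterministic for a fixed config and seed.
#'
#' @param cfg a `pipeline_config`
#' @param quiet suppress stage messages
#' @return list of class `run_summary` — see the `summary` element for the
#'   per-stage counts; `catalog`, `matrix`, `scan`, `guides`, `manifest` hold
#'   the stage objects
#' @export
run_all <- function(cfg = pipeline_config(), quiet = FALSE) {
  v <- validate_config(cfg)
  if (!v$ok) stop("invalid configuration:\n  - ", paste(v$errors, collapse = "\n  - "))
  for (w in v$warnings) warning(w, call. = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outd <- cfg$output_dir
  if (!is.null(outd)) dir.create(outd, showWarnings = FALSE, recursive = TRUE)

  manifest <- NULL
  annotation <- NULL
  if (cfg$simulate) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    say("[simulate] genome %d bp, %d secondary sites, %d replicates x %d pairs",
        sim$genome_length, sim$n_secondary_sites, sim$n_replicates,
        sim$reads_per_replicate)
    g0 <- generate_genome(sim)
    planted <- plant_sites(g0, motif_generator(conservation = sim$conservation), sim)
    g <- planted$genome
    lib <- simulate_library(g, planted$manifest, sim,
                            out_dir = if (is.null(outd)) NULL else file.path(outd, "fastq"))
    manifest <- lib$manifest
    pairs <- do.call(rbind, lib$pairs)
    annotation <- synthesize_annotation(g, manifest)
    if (is.null(cfg$attB_position)) {
      cfg$attB_position <- manifest$attB_position
      cfg$attB_strand <- manifest$attB_strand
    }
    replicate_ids <- sprintf("rep%d", seq_len(sim$n_replicates))
  } else {
    g <- read_fasta(cfg$genome_fasta)
    if (!is.null(cfg$gff)) annotation <- read_gff(cfg$gff)
    replicate_ids <- cfg$replicate_ids %||% sprintf("rep%d", seq_along(cfg$r1))
    pairs <- do.call(rbind, lapply(seq_along(cfg$r1), function(i)
      read_fastq_pairs(cfg$r1[i], cfg$r2[i], replicate_id = replicate_ids[i])))
  }

  fcfg <- filter_config(cfg$anchor, cfg$overlap_trim, cfg$min_read1_len,
                        cfg$read2_prefix_len, cfg$qmin, cfg$qavg)
  filt <- filter_library(pairs, fcfg)
  say("[filter] %d pairs -> %d accepted (%d no_anchor, %d low_quality, %d too_short)",
      filt$report$total, filt$report$accepted, filt$report$no_anchor,
      filt$report$low_quality, filt$report$too_short)

  maps <- map_pairs(filt$accepted, g, cfg$min_identity, cfg$max_insert)
  st <- table(factor(maps$status, levels = c("unique", "ambiguous", "unmapped", "discordant")))
  say("[map] %d unique, %d ambiguous, %d unmapped, %d discordant",
      st["unique"], st["ambiguous"], st["unmapped"], st["discordant"])

  catalog <- call_sites(maps, g, overlap_trim = cfg$overlap_trim,
                        replicate_ids = replicate_ids,
                        tolerance = cfg$tolerance, min_reads = cfg$min_reads,
                        attB_position = cfg$attB_position,
                        attB_strand = cfg$attB_strand,
                        attB_window = cfg$attB_window)
  say("[call] %d sites (%d secondary); secondary:attB ratio %s",
      nrow(catalog$sites), sum(!catalog$sites$is_attB),
      format(catalog$ratio_secondary_to_attB, digits = 3))
  gene_summary <- NULL
  if (!is.null(annotation)) {
    gc_ <- categorize_by_gene(catalog, annotation, cfg$near_window)
    catalog <- gc_$catalog
    gene_summary <- gc_$summary
  }

  mat <- NULL; scan <- NULL; freq_table <- NULL
  sec <- catalog$sites[!catalog$sites$is_attB, , drop = FALSE]
  wins <- extract_windows(g, sec, cfg$offset_left, cfg$offset_right)
  if (sum(!wins$has_N) >= 2L) {
    mat <- build_matrix(wins, pseudocount = cfg$pseudocount,
                        background = g$base_frequencies)
    catalog <- relative_scores(mat, catalog, g, cfg$offset_left, cfg$offset_right)
    scan <- scan_genome(mat, g, top_k = cfg$top_k, exclude = catalog)
    freq_table <- score_by_detection_frequency(catalog)
    say("[motif] %d windows; genome-scan mean %.3f bits", mat$n_windows, scan$mean)
  } else {
    say("[motif] skipped: fewer than 2 usable windows")
  }

  guides <- NULL
  if (isTRUE(cfg$design_guides) && nrow(sec) > 0L) {
    gs <- cfg$guide_site
    if (is.null(gs)) {
      top <- sec[order(-sec$detection_frequency, -sec$total_reads), ][1, ]
      gs <- top$position
      gstrand <- top$strand
    } else {
      hit <- catalog$sites[catalog$sites$position == gs, , drop = FALSE]
      gstrand <- if (nrow(hit) > 0L) hit$strand[1] else "+"
    }
    cand <- enumerate_candidates(g, gs, gstrand, cfg$guide_radius)
    guides <- select_guides(cand, g, cfg$guide_max_mm)
    say("[guides] site %d(%s): %d candidates, %d accepted",
        gs, gstrand, nrow(guides), sum(guides$accepted))
  }

  summary <- list(
    seed = cfg$seed,
    n_pairs = filt$report$total,
    filter = unclass(filt$report),
    mapping = as.list(setNames(as.integer(st), names(st))),
    n_sites = nrow(catalog$sites),
    n_secondary = sum(!catalog$sites$is_attB),
    attB_reads_total = catalog$attB_reads_total,
    secondary_reads_total = catalog$secondary_reads_total,
    ratio_secondary_to_attB = catalog$ratio_secondary_to_attB,
    detection_frequency_histogram =
      as.list(table(catalog$sites$detection_frequency[!catalog$sites$is_attB])),
    gene_summary = if (!is.null(gene_summary)) list(
      within_gene_fraction = gene_summary$within_gene_fraction,
      strand_counts = as.list(gene_summary$strand_counts),
      category_counts = as.list(gene_summary$category_counts)) else NULL,
    motif = if (!is.null(mat)) list(
      n_windows = mat$n_windows, consensus = mat$consensus,
      scan_mean = scan$mean, scan_sd = scan$sd,
      score_by_class = if (!is.null(freq_table)) freq_table$by_class else NULL) else NULL,
    guides = if (!is.null(guides)) list(
      n_candidates = nrow(guides), n_accepted = sum(guides$accepted)) else NULL,
    version = as.character(utils::packageVersion("phagesite"))
  )
  if (!is.null(outd)) {
    write_site_outputs(catalog, file.path(outd, "sites.bed"), file.path(outd, "sites.tsv"))
    if (!is.null(mat)) write_meme(mat, file.path(outd, "matrix.meme"))
    jsonlite::write_json(summary, file.path(outd, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    jsonlite::write_json(unclass(filt$report), file.path(outd, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(manifest)) write_manifest(manifest, file.path(outd, "manifest.json"))
  }
  structure(list(summary = summary, catalog = catalog, matrix = mat, scan = scan,
                 freq_table = freq_table, guides = guides, manifest = manifest,
                 annotation = annotation, genome = g, mappings = maps,
                 filter_report = filt$report, gene_summary = gene_summary),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<run_summary> %d pairs; %d sites (%d secondary); ",
                     "ratio %s; seed %d\n"),
              s$n_pairs, s$n_sites, s$n_secondary,
              format(s$ratio_secondary_to_attB, digits = 3), s$seed))
  invisible(x)
}
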