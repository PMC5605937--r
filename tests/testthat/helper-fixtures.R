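# Shared fixtures and independent oracles.  Oracles here are deliberately
# naive (full scans, literal loops) and never reuse the package's fast paths.

random_genome <- function(n, seed = 1L, circular = TRUE, gc = 0.5) {
  set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  genome(paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = ""),
         name = "fix", circular = circular)
}

write_temp_fasta <- function(records) {
  # records: named character vector
  tf <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(n) c(paste0(">", n), records[[n]]))), tf)
  tf
}

write_temp_fastq <- function(ids, seqs, quals) {
  tf <- tempfile(fileext = ".fastq")
  if (length(ids) == 0L) {
    file.create(tf)
  } else {
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), tf)
  }
  tf
}

# literal restatement of the iterative 3' trimming rule
oracle_quality_trim <- function(quals, qmin, qavg) {
  while (length(quals) > 0 &&
         (quals[length(quals)] < qmin || mean(quals) < qavg)) {
    quals <- quals[-length(quals)]
  }
  length(quals)
}

# brute-force full-scan mapper: every position, both strands, no seeds
oracle_map <- function(query, g, min_identity = 0.95) {
  L <- nchar(query)
  n <- g$length
  ext <- if (g$circular) paste0(g$seq, substr(g$seq, 1L, L)) else g$seq
  nw <- if (g$circular) n else n - L + 1L
  code <- match(strsplit(ext, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  count_mm <- function(q) {
    qc <- match(strsplit(q, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    mm <- integer(nw)
    for (j in seq_len(L)) {
      cj <- code[seq_len(nw) + j - 1L]
      mm <- mm + as.integer(is.na(cj) | is.na(qc[j]) | cj != qc[j])
    }
    mm
  }
  maxmm <- floor(L * (1 - min_identity) + 1e-9)
  mmf <- count_mm(query)
  mmr <- count_mm(revcomp(query))
  hf <- which(mmf <= maxmm)
  hr <- which(mmr <= maxmm)
  out <- data.frame(
    ref_start = c(hf, ((hr + L - 2L) %% n) + 1L),
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    n_mismatches = c(mmf[hf], mmr[hr]))
  out[order(out$strand, out$ref_start), , drop = FALSE]
}

normalize_hits <- function(h) {
  h <- data.frame(ref_start = as.integer(h$ref_start),
                  strand = as.character(h$strand),
                  n_mismatches = as.integer(h$n_mismatches),
                  stringsAsFactors = FALSE)
  h <- h[order(h$strand, h$ref_start), ]
  rownames(h) <- NULL
  h
}

# naive substring-based off-target counter (both strands, NGG PAM)
oracle_offtargets <- function(protospacer, g, max_mm = 2L) {
  L <- nchar(protospacer)
  n <- g$length
  ext <- paste0(g$seq, substr(g$seq, 1L, L + 3L))
  counts <- integer(max_mm + 1L)
  pc <- strsplit(protospacer, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(protospacer), "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    w <- strsplit(substr(ext, i, i + L - 1L), "", fixed = TRUE)[[1]]
    # + orientation: NGG at i+L .. i+L+2
    if (substr(ext, i + L + 1L, i + L + 2L) == "GG") {
      mm <- sum(w != pc | w == "N")
      if (mm <= max_mm) counts[mm + 1L] <- counts[mm + 1L] + 1L
    }
    # - orientation: CCN at i-3 .. i-1 (wrapped)
    j <- ((i - 4L) %% n) + 1L  # coord of the first C
    two <- paste0(substr(g$seq, j, j), substr(g$seq, ((j %% n) + 1L), ((j %% n) + 1L)))
    if (two == "CC") {
      mm <- sum(w != rc | w == "N")
      if (mm <= max_mm) counts[mm + 1L] <- counts[mm + 1L] + 1L
    }
  }
  setNames(counts, as.character(0:max_mm))
}

# small error-free simulation used by several modules
tiny_simulation <- function(seed = 11L, n_sites = 8L, genome_length = 20000L,
                            reads = 2000L, reps = 4L, ...) {
  sim <- simulation_config(genome_length = genome_length,
                           n_secondary_sites = n_sites,
                           reads_per_replicate = reads, n_replicates = reps,
                           substitution_error_rate = 0,
                           background_read_fraction = 0,
                           anchor_mutation_fraction = 0, seed = seed, ...)
  g0 <- generate_genome(sim)
  pl <- plant_sites(g0, motif_generator(), sim)
  lib <- simulate_library(pl$genome, pl$manifest, sim)
  list(sim = sim, genome = pl$genome, manifest = lib$manifest, pairs = lib$pairs)
}

run_tiny_pipeline <- function(fix, min_reads = 1L, tolerance = 0L) {
  pairs <- do.call(rbind, fix$pairs)
  filt <- filter_library(pairs, filter_config(anchor = fix$sim$anchor))
  maps <- map_pairs(filt$accepted, fix$genome)
  call_sites(maps, fix$genome,
             replicate_ids = sprintf("rep%d", seq_len(fix$sim$n_replicates)),
             min_reads = min_reads, tolerance = tolerance,
             attB_position = fix$manifest$attB_position,
             attB_strand = fix$manifest$attB_strand)
}
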