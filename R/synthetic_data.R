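#' Default phage anchor: the 45-nt constant attL-side sequence expected at the
#' 5' end of read 1 of every true junction pair.
#' @export
DEFAULT_ANCHOR <- "GTTGCAACAAATTGATAAGCAATGCTTTTTTATAATGCCAACTTA"

#' Simulation configuration
#'
#' Defaults describe the world the pipeline targets: a ~100-kb bacterial
#' chromosome segment at E. coli GC content, one dominant attB site plus many
#' low-frequency secondary sites, 8 replicate libraries of 2x75-bp pairs, a
#' secondary:attB read ratio of 0.51%, MiSeq-range Phred qualities decaying
#' toward the 3' end, and a small background of non-junction pairs.
#'
#' @param genome_length chromosome length (nt)
#' @param gc_content G+C fraction (E. coli ~0.508)
#' @param n_secondary_sites number of planted secondary integration sites
#' @param secondary_read_fraction target secondary:attB junction-read ratio
#' @param n_replicates number of replicate libraries
#' @param reads_per_replicate read pairs per replicate
#' @param read_length read length (nt)
#' @param insert_size_mean,insert_size_sd fragment size distribution (nt,
#'   measured from the anchor 5' end to the distal tagmentation end)
#' @param substitution_error_rate per-base substitution rate on host-derived
#'   bases (the anchor itself is error-free outside `anchor_mutation_fraction`)
#' @param quality_start,quality_end,quality_sd per-cycle mean Phred at cycle 1
#'   and at the last cycle (linear decay), and per-base Gaussian spread
#' @param background_read_fraction fraction of pairs with no phage anchor
#' @param anchor_mutation_fraction fraction of junction pairs given >= 1
#'   substitution inside the anchor (these must fail the exact-anchor filter)
#' @param anchor phage anchor sequence (read-1 5' constant)
#' @param conservation probability mass on the conserved base at each
#'   constrained motif position of the generating matrix
#' @param seed integer seed; all stages derive their streams from it
#' @return object of class `sim_config`
#' @export
simulation_config <- function(genome_length = 100000L,
                              gc_content = 0.508,
                              n_secondary_sites = 50L,
                              secondary_read_fraction = 0.0051,
                              n_replicates = 8L,
                              reads_per_replicate = 20000L,
                              read_length = 75L,
                              insert_size_mean = 300,
                              insert_size_sd = 50,
                              substitution_error_rate = 0.001,
                              quality_start = 38,
                              quality_end = 28,
                              quality_sd = 3,
                              background_read_fraction = 0.05,
                              anchor_mutation_fraction = 0.01,
                              anchor = DEFAULT_ANCHOR,
                              conservation = 0.9,
                              seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length), gc_content = gc_content,
              n_secondary_sites = as.integer(n_secondary_sites),
              secondary_read_fraction = secondary_read_fraction,
              n_replicates = as.integer(n_replicates),
              reads_per_replicate = as.integer(reads_per_replicate),
              read_length = as.integer(read_length),
              insert_size_mean = insert_size_mean, insert_size_sd = insert_size_sd,
              substitution_error_rate = substitution_error_rate,
              quality_start = quality_start, quality_end = quality_end,
              quality_sd = quality_sd,
              background_read_fraction = background_read_fraction,
              anchor_mutation_fraction = anchor_mutation_fraction,
              anchor = toupper(anchor), conservation = conservation,
              seed = as.integer(seed))
  fr <- c("gc_content", "secondary_read_fraction", "substitution_error_rate",
          "background_read_fraction", "anchor_mutation_fraction")
  for (f in fr) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("parameter error: %s = %s not in [0, 1]", f, format(cfg[[f]])))
  }
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    stop("parameter error: gc_content must lie strictly inside (0, 1)")
  if (cfg$genome_length < 10L * cfg$read_length)
    stop("parameter error: genome_length must be >= 10 x read_length")
  if (grepl("[^ACGT]", cfg$anchor) || nchar(cfg$anchor) == 0L)
    stop("parameter error: anchor must be a non-empty ACGT string")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome at a requested GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2.  Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a `sim_config`
#' @return a circular `genome`
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
         G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  seq <- paste(sample(DNA_BASES, config$genome_length, replace = TRUE, prob = p),
               collapse = "")
  genome(seq, name = "sim_genome", circular = TRUE)
}

#' Generating probability matrix for the integration-site motif
#'
#' Builds a width x 4 column-stochastic matrix (rows = positions labelled
#' relative to the first base of the 7-nt strand-exchange region at label 0;
#' columns A,C,G,T).  Constrained positions put `conservation` mass on the
#' stated base and spread the rest uniformly; unconstrained rows follow the
#' background.  Default constraints reproduce the field's att-core signature:
#' T at -1,-2,-3,-5,-6; C at -7,-10; A at +5,+6.
#'
#' @param width motif width (odd; default 29 giving labels -14..+14)
#' @param conserved named character vector, names = position labels
#' @param conservation probability on the conserved base
#' @param background length-4 base probabilities for free positions
#' @return matrix of class `motif_probs` with rownames = labels
#' @export
motif_generator <- function(width = 29L,
                            conserved = c("-10" = "C", "-7" = "C", "-6" = "T",
                                          "-5" = "T", "-3" = "T", "-2" = "T",
                                          "-1" = "T", "5" = "A", "6" = "A"),
                            conservation = 0.9,
                            background = rep(0.25, 4)) {
  stopifnot(width %% 2L == 1L, conservation > 0.25, conservation <= 1)
  half <- (width - 1L) %/% 2L
  labels <- as.character(seq(-half, half))
  m <- matrix(rep(background, each = width), nrow = width,
              dimnames = list(labels, DNA_BASES))
  for (lab in names(conserved)) {
    if (!lab %in% labels) stop("conserved position ", lab, " outside motif width")
    row <- rep((1 - conservation) / 3, 4)
    row[match(conserved[[lab]], DNA_BASES)] <- conservation
    m[lab, ] <- row
  }
  class(m) <- c("motif_probs", "matrix")
  m
}

#' Consensus sequence of a probability (or frequency) matrix
#' @param probs width x 4 matrix, columns A,C,G,T
#' @return character scalar
#' @export
motif_consensus <- function(probs) {
  paste(DNA_BASES[apply(unclass(probs), 1L, which.max)], collapse = "")
}

#' Sample motif windows column-wise from a probability matrix
#' @param probs width x 4 probability matrix
#' @param n number of windows
#' @return character vector of n sequences
#' @export
sample_windows <- function(probs, n) {
  w <- nrow(probs)
  cols <- vapply(seq_len(w), function(i)
    sample(DNA_BASES, n, replace = TRUE, prob = probs[i, ]), character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1L, paste, collapse = "")
}

# Segment of the integration strand: offset 0 starts at `pos` (the first base
# of the strand-exchange region) and advances 5'->3' on that strand.  On "+"
# this is the forward genome; on "-" it walks leftward on the forward strand
# and is reverse-complemented.  Vectorised over pos/strand; circular.
strand_segment <- function(g, pos, len, strand, offset = 0L) {
  stopifnot(g$circular || all(strand == "+"))
  n <- g$length
  fwd_start <- ifelse(strand == "+", pos + offset, pos - offset - len + 1L)
  fwd_start <- ((fwd_start - 1L) %% n) + 1L
  ext <- if (max(fwd_start) + len - 1L > n) paste0(g$seq, substr(g$seq, 1L, len)) else g$seq
  s <- substring(ext, fwd_start, fwd_start + len - 1L)
  neg <- strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

# Overwrite genome characters on the forward strand (circular-aware).
genome_overwrite <- function(g, start, replacement) {
  n <- g$length
  chars <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  idx <- (((start:(start + nchar(replacement) - 1L)) - 1L) %% n) + 1L
  chars[idx] <- strsplit(replacement, "", fixed = TRUE)[[1]]
  genome(paste(chars, collapse = ""), name = g$name, circular = g$circular)
}

#' Plant the attB site and secondary sites into a genome
#'
#' Each site's 29-base window (labels -14..+14 around the first base of the
#' strand-exchange region) is overwritten with a sequence sampled column-wise
#' from the generating matrix; attB receives the matrix consensus.  Sites are
#' placed with both strands equiprobable, uniformly over the configurations
#' whose windows do not overlap (minimum pairwise circular distance 40 nt),
#' via spaced order-statistics sampling; an infeasibly dense request errors.
#'
#' @param g a circular `genome`
#' @param probs generating matrix from [motif_generator()] (or a consensus
#'   string, used for every site)
#' @param config a `sim_config`
#' @param site_weights optional positive weights (length `n_secondary_sites`)
#'   governing the expected share of secondary junction reads per site;
#'   default uniform
#' @return list with elements `genome` (sites planted) and `manifest`
#'   (a `truth_manifest`)
#' @export
plant_sites <- function(g, probs, config, site_weights = NULL) {
  set.seed(config$seed + 1L)
  width <- if (is.character(probs)) nchar(probs) else nrow(probs)
  half <- (width - 1L) %/% 2L
  n_sites <- config$n_secondary_sites + 1L  # + attB
  min_gap <- max(40L, width + 5L)
  # uniform draw over spaced configurations (all circular gaps >= min_gap):
  # sort a plain uniform sample over the shrunk interval, then re-inflate
  slack <- g$length - n_sites * min_gap
  if (slack < n_sites)
    stop("failed to place ", n_sites, " non-overlapping sites in a ",
         g$length, "-nt genome (windows would overlap)")
  pos <- sort(sample.int(slack, n_sites)) + (seq_len(n_sites) - 1L) * min_gap
  pos <- pos[sample.int(n_sites)]  # random order: first entry becomes attB
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  windows <- if (is.character(probs)) rep(probs, n_sites) else sample_windows(probs, n_sites)
  if (!is.character(probs)) windows[1] <- motif_consensus(probs)
  for (i in seq_len(n_sites)) {
    w <- if (strand[i] == "+") windows[i] else revcomp(windows[i])
    g <- genome_overwrite(g, pos[i] - half, w)
  }
  if (is.null(site_weights)) site_weights <- rep(1, config$n_secondary_sites)
  stopifnot(length(site_weights) == config$n_secondary_sites, all(site_weights > 0))
  manifest <- structure(list(
    attB_position = pos[1], attB_strand = strand[1],
    secondary_sites = data.frame(
      position = pos[-1], strand = strand[-1], window = windows[-1],
      weight = site_weights / sum(site_weights), stringsAsFactors = FALSE),
    anchor_sequence = config$anchor,
    overlap_sequences = substr(windows, half + 1L, half + 7L),
    motif_width = width,
    counts = NULL,  # filled by simulate_library
    config = unclass(config)
  ), class = "truth_manifest")
  list(genome = g, manifest = manifest)
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat(sprintf("<truth_manifest> attB at %d(%s), %d secondary sites%s\n",
              x$attB_position, x$attB_strand, nrow(x$secondary_sites),
              if (is.null(x$counts)) "" else sprintf(", %d junction reads realized",
                                                     sum(x$counts))))
  invisible(x)
}

# introduce `k[i]` random substitutions into seqs[i] restricted to positions
# [from, to]; k entries of 0 are skipped
mutate_positions <- function(seqs, k, from, to) {
  hit <- which(k > 0L)
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    at <- sample(from:to, min(k[i], to - from + 1L))
    for (p in at) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# Phred strings for n reads of length L: per-cycle means mu (length L), sd
quality_strings <- function(n, mu, sd) {
  if (n == 0L) return(character(0))
  L <- length(mu)
  q <- round(rnorm(n * L, mean = rep(mu, times = n), sd = sd))
  q <- pmin(pmax(q, 2L), 41L)
  big <- intToUtf8(as.integer(q) + 33L)
  substring(big, seq(1L, n * L, by = L), seq(L, n * L, by = L))
}

#' Simulate junction-enriched paired-end libraries
#'
#' For each replicate, emits `reads_per_replicate` pairs: a
#' `background_read_fraction` share of anchor-free pairs from random genome
#' positions, the rest junction pairs whose site is attB with probability
#' `1/(1+f)` and a secondary site otherwise (`f` = `secondary_read_fraction`,
#' so the expected secondary:attB read-count ratio equals `f`).  Read 1 is
#' anchor + 7-nt strand-exchange overlap + host flank on the integration
#' strand; read 2 is the reverse complement of the fragment's distal end.
#' Substitution errors hit host-derived bases only; an
#' `anchor_mutation_fraction` share of junction pairs receives one anchor
#' substitution (and must later fail the exact-anchor filter).
#'
#' @param g planted `genome` from [plant_sites()]
#' @param manifest matching `truth_manifest`
#' @param config the `sim_config` used for planting
#' @param out_dir if non-NULL, write `repN_R1.fastq` / `repN_R2.fastq` there
#' @return list: `pairs` (list of `read_pairs`, one per replicate),
#'   `manifest` (with realized per-site x replicate junction counts in
#'   `$counts`; row 1 = attB), `files` (data.frame of paths or NULL)
#' @export
simulate_library <- function(g, manifest, config, out_dir = NULL) {
  set.seed(config$seed + 2L)
  rl <- config$read_length
  anchor <- config$anchor
  alen <- nchar(anchor)
  stopifnot(rl > alen + 7L)
  host1_len <- rl - alen
  n_sites <- nrow(manifest$secondary_sites)
  site_pos <- c(manifest$attB_position, manifest$secondary_sites$position)
  site_strand <- c(manifest$attB_strand, manifest$secondary_sites$strand)
  # per-site read-1 host templates (error-free), shared by all reads at a site
  host1_tpl <- strand_segment(g, site_pos, host1_len, site_strand)
  mu <- seq(config$quality_start, config$quality_end, length.out = rl)
  p_sec <- config$secondary_read_fraction / (1 + config$secondary_read_fraction)
  sec_w <- manifest$secondary_sites$weight
  counts <- matrix(0L, nrow = n_sites + 1L, ncol = config$n_replicates,
                   dimnames = list(c("attB", sprintf("site%03d", seq_len(n_sites))),
                                   sprintf("rep%d", seq_len(config$n_replicates))))
  pairs_by_rep <- vector("list", config$n_replicates)
  files <- NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  for (r in seq_len(config$n_replicates)) {
    N <- config$reads_per_replicate
    if (N == 0L) {
      pp <- read_pairs(character(0), character(0), character(0),
                       character(0), character(0), character(0))
      pairs_by_rep[[r]] <- pp
      if (!is.null(out_dir)) {
        f1 <- file.path(out_dir, sprintf("rep%d_R1.fastq", r))
        f2 <- file.path(out_dir, sprintf("rep%d_R2.fastq", r))
        write_fastq_pairs(pp, f1, f2)
        files <- rbind(files, data.frame(replicate = sprintf("rep%d", r),
                                         r1 = f1, r2 = f2, stringsAsFactors = FALSE))
      }
      next
    }
    is_bg <- runif(N) < config$background_read_fraction
    n_jx <- sum(!is_bg)
    # site assignment for junction reads (index 1 = attB)
    site_of <- integer(N)
    jx_sec <- runif(n_jx) < p_sec
    sec_idx <- if (n_sites > 0L) sample.int(n_sites, n_jx, replace = TRUE, prob = sec_w) else integer(n_jx)
    site_of[!is_bg] <- ifelse(jx_sec & n_sites > 0L, 1L + sec_idx, 1L)
    tab <- tabulate(site_of[!is_bg], nbins = n_sites + 1L)
    counts[, r] <- as.integer(tab)
    # fragment geometry (insert measured anchor 5' -> distal end)
    min_insert <- alen + rl
    insert <- round(rnorm(N, config$insert_size_mean, config$insert_size_sd))
    insert <- pmin(pmax(insert, min_insert), config$insert_size_mean + 4 * config$insert_size_sd)
    frag_host <- insert - alen
    off2 <- frag_host - rl

    pos_r <- integer(N); strand_r <- character(N)
    jx <- site_of > 0L
    pos_r[jx] <- site_pos[site_of[jx]]
    strand_r[jx] <- site_strand[site_of[jx]]
    pos_r[is_bg] <- sample.int(g$length, sum(is_bg), replace = TRUE)
    strand_r[is_bg] <- sample(c("+", "-"), sum(is_bg), replace = TRUE)

    r1 <- character(N)
    r1[jx] <- paste0(anchor, host1_tpl[site_of[jx]])
    if (any(is_bg)) r1[is_bg] <- strand_segment(g, pos_r[is_bg], rl, strand_r[is_bg])
    r2 <- revcomp(strand_segment(g, pos_r, rl, strand_r, offset = off2))

    # substitution errors on host-derived bases
    err <- config$substitution_error_rate
    if (err > 0) {
      k1j <- rbinom(N, host1_len, err); k1j[is_bg] <- 0L
      r1 <- mutate_positions(r1, k1j, alen + 1L, rl)
      k1b <- rbinom(N, rl, err); k1b[!is_bg] <- 0L
      r1 <- mutate_positions(r1, k1b, 1L, rl)
      r2 <- mutate_positions(r2, rbinom(N, rl, err), 1L, rl)
    }
    # anchor mutations in a dedicated junction-read subset
    if (config$anchor_mutation_fraction > 0 && any(jx)) {
      amut <- jx & runif(N) < config$anchor_mutation_fraction
      r1 <- mutate_positions(r1, as.integer(amut), 1L, alen)
    }
    q1 <- quality_strings(N, mu, config$quality_sd)
    q2 <- quality_strings(N, mu, config$quality_sd)
    ids <- sprintf("rep%d:pair%06d", r, seq_len(N))
    pp <- read_pairs(ids, r1, q1, r2, q2, replicate_id = sprintf("rep%d", r))
    pairs_by_rep[[r]] <- pp
    if (!is.null(out_dir)) {
      f1 <- file.path(out_dir, sprintf("rep%d_R1.fastq", r))
      f2 <- file.path(out_dir, sprintf("rep%d_R2.fastq", r))
      write_fastq_pairs(pp, f1, f2)
      files <- rbind(files, data.frame(replicate = sprintf("rep%d", r),
                                       r1 = f1, r2 = f2, stringsAsFactors = FALSE))
    }
  }
  manifest$counts <- counts
  list(pairs = pairs_by_rep, manifest = manifest, files = files)
}

#' Write a truth manifest as JSON
#' @param manifest `truth_manifest`
#' @param path output JSON path
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  if (!is.null(x$counts)) {
    x$counts <- list(rows = rownames(x$counts), cols = colnames(x$counts),
                     values = unname(apply(x$counts, 1L, as.integer, simplify = FALSE)))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Build a synthetic gene annotation around planted sites
#'
#' Lays genes so that a chosen fraction of the planted secondary sites fall
#' inside CDS spans (the rest between genes), which turns the within-gene
#' fraction of the called catalog into a construction echo.  Gene strands are
#' random; gene bodies extend around the covered sites.
#'
#' @param g planted `genome`
#' @param manifest `truth_manifest`
#' @param within_fraction fraction of secondary sites to cover with a CDS
#' @param gene_halfwidth half-length of each synthetic gene body
#' @return `gene_annotation`
#' @export
synthesize_annotation <- function(g, manifest, within_fraction = 0.776,
                                  gene_halfwidth = 150L) {
  set.seed(manifest$config$seed + 3L)
  sp <- manifest$secondary_sites$position
  n <- length(sp)
  k <- round(within_fraction * n)
  covered <- sort(sample.int(n, k))
  allpos <- sort(c(manifest$attB_position, sp))
  rows <- lapply(seq_along(covered), function(i) {
    p <- sp[covered[i]]
    below <- suppressWarnings(max(allpos[allpos < p]))
    above <- suppressWarnings(min(allpos[allpos > p]))
    # keep every neighbouring planted site (covered or not) strictly outside
    start <- max(1L, p - gene_halfwidth, if (is.finite(below)) below + 8L else 1L)
    end <- min(g$length, p + gene_halfwidth,
               if (is.finite(above)) above - 8L else g$length)
    data.frame(gene = sprintf("gene%03d", i), start = start, end = end,
               strand = sample(c("+", "-"), 1L), kind = "CDS",
               stringsAsFactors = FALSE)
  })
  gene_annotation(do.call(rbind, rows))
}
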