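#' Construct a site catalog
#'
#' Internal-ish constructor shared by the caller and the TSV reader.  `sites`
#' must carry one row per unique (position, strand) with a
#' `reads_per_replicate` list column.
#'
#' @param sites sites data.frame
#' @param n_replicates replicate count
#' @param replicate_ids replicate labels (column order of the count vectors)
#' @param genome_name sequence name used in BED output
#' @return object of class `site_catalog`
#' @export
new_site_catalog <- function(sites, n_replicates = NA_integer_,
                             replicate_ids = NULL, genome_name = "genome") {
  need <- c("site_id", "position", "strand", "total_reads", "detection_frequency")
  stopifnot(all(need %in% names(sites)))
  if (anyDuplicated(paste(sites$position, sites$strand)))
    stop("duplicate (position, strand) keys in site catalog")
  for (col in c("nearest_gene", "category")) {
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_character_, nrow(sites))
  }
  for (col in c("motif_score", "relative_score")) {
    if (is.null(sites[[col]])) sites[[col]] <- rep(NA_real_, nrow(sites))
  }
  if (is.null(sites$is_attB)) sites$is_attB <- rep(FALSE, nrow(sites))
  structure(list(sites = sites, n_replicates = n_replicates,
                 replicate_ids = replicate_ids,
                 attB_reads_total = NA_integer_, secondary_reads_total = NA_integer_,
                 ratio_secondary_to_attB = NA_real_,
                 genome_name = genome_name),
            class = "site_catalog")
}

#' @export
print.site_catalog <- function(x, ...) {
  cat(sprintf("<site_catalog> %d sites over %s replicates", nrow(x$sites),
              ifelse(is.na(x$n_replicates), "?", x$n_replicates)))
  if (!is.na(x$ratio_secondary_to_attB))
    cat(sprintf("; secondary:attB read ratio %.4f%%", 100 * x$ratio_secondary_to_attB))
  cat("\n")
  invisible(x)
}

#' Infer integration sites from unique junction mappings
#'
#' The mapped read-1 remnant begins immediately 3' of the 7-nt
#' strand-exchange region on the integration strand, so the site coordinate
#' (first base of that region) is `ref_start - overlap_trim` on the plus
#' strand and `ref_start + overlap_trim` on the minus strand, wrapped on
#' circular genomes.
#'
#' @param mappings junction-mapping data.frame from [map_pairs()]
#' @param g the `genome` (for length / wrap-around)
#' @param overlap_trim strand-exchange width used during filtering
#' @return data.frame `position`, `strand`, `replicate_id`, one row per
#'   unique mapping
#' @export
infer_junction <- function(mappings, g, overlap_trim = 7L) {
  u <- mappings[mappings$status == "unique", , drop = FALSE]
  pos <- ifelse(u$r1_strand == "+", u$r1_ref_start - overlap_trim,
                u$r1_ref_start + overlap_trim)
  if (g$circular) pos <- ((pos - 1L) %% g$length) + 1L
  else if (any(pos < 1L | pos > g$length))
    stop("inferred junction outside linear genome")
  data.frame(position = as.integer(pos), strand = u$r1_strand,
             replicate_id = u$replicate_id, stringsAsFactors = FALSE)
}

#' Collapse junctions into a site catalog
#'
#' Junctions sharing (position, strand) — within `tolerance` nt on the same
#' strand — merge into one site; per-replicate read counts are kept and the
#' detection frequency is the number of replicates contributing at least
#' `min_reads` reads.
#'
#' @param junctions data.frame from [infer_junction()] (rows = reads)
#' @param replicate_ids full replicate universe (defaults to the observed set)
#' @param tolerance merge radius in nt (default 0: exact coordinate)
#' @param min_reads per-replicate depth needed to count as detected
#' @param genome_name sequence name for outputs
#' @return a `site_catalog`
#' @export
collapse_and_merge <- function(junctions, replicate_ids = NULL, tolerance = 0L,
                               min_reads = 1L, genome_name = "genome") {
  if (tolerance < 0L) stop("parameter error: tolerance must be >= 0")
  if (is.null(replicate_ids)) replicate_ids <- sort(unique(junctions$replicate_id))
  nrep <- length(replicate_ids)
  if (nrow(junctions) == 0L) {
    sites <- data.frame(site_id = character(0), position = integer(0),
                        strand = character(0), total_reads = integer(0),
                        detection_frequency = integer(0), stringsAsFactors = FALSE)
    sites$reads_per_replicate <- list()
    return(new_site_catalog(sites, nrep, replicate_ids, genome_name))
  }
  dt <- data.table::as.data.table(junctions)
  agg <- dt[, .N, by = .(position, strand, replicate_id)]
  key <- agg[, .(total = sum(N)), by = .(position, strand)]
  data.table::setorder(key, strand, position)
  # merge within tolerance: greedy chain per strand, representative = member
  # with the most reads (ties: leftmost)
  key[, cluster := {
    cl <- integer(.N); cur <- 0L
    for (i in seq_len(.N)) {
      if (i == 1L || strand[i] != strand[i - 1L] ||
          position[i] - position[i - 1L] > tolerance) cur <- cur + 1L
      cl[i] <- cur
    }
    cl
  }]
  key[, rep_pos := position[which.max(total)], by = cluster]
  agg <- merge(agg, key[, .(position, strand, cluster, rep_pos)],
               by = c("position", "strand"))
  per_site <- agg[, .(N = sum(N)), by = .(cluster, rep_pos, strand, replicate_id)]
  clusters <- unique(per_site[, .(cluster, rep_pos, strand)])
  data.table::setorder(clusters, rep_pos, strand)
  counts <- lapply(seq_len(nrow(clusters)), function(i) {
    sub <- per_site[cluster == clusters$cluster[i]]
    v <- setNames(integer(nrep), replicate_ids)
    v[sub$replicate_id] <- sub$N
    v
  })
  sites <- data.frame(
    site_id = sprintf("IS%04d", seq_len(nrow(clusters))),
    position = clusters$rep_pos, strand = clusters$strand,
    total_reads = vapply(counts, sum, 0L),
    detection_frequency = vapply(counts, function(v) sum(v >= min_reads), 0L),
    stringsAsFactors = FALSE)
  sites$reads_per_replicate <- counts
  new_site_catalog(sites, nrep, replicate_ids, genome_name)
}

# circular distance between coordinates
circ_dist <- function(a, b, n, circular = TRUE) {
  d <- abs(a - b)
  if (circular) pmin(d, n - d) else d
}

#' Flag the attB site and compute the secondary:attB read ratio
#'
#' @param catalog a `site_catalog`
#' @param g the `genome` (for circular distances)
#' @param attB_position,attB_strand known attB coordinates, or NULL for auto
#'   mode (the single site with the most reads)
#' @param window sites within this distance of attB are flagged attB
#' @return catalog with `is_attB` set and read totals / ratio filled;
#'   ratio is `NA` if no attB site is found
#' @export
classify_attB <- function(catalog, g, attB_position = NULL, attB_strand = NULL,
                          window = 10L) {
  s <- catalog$sites
  if (nrow(s) == 0L) {
    warning("empty catalog: ratio undefined")
    return(catalog)
  }
  if (is.null(attB_position)) {
    top <- which.max(s$total_reads)
    attB_position <- s$position[top]
    attB_strand <- s$strand[top]
  }
  near <- circ_dist(s$position, attB_position, g$length, g$circular) <= window
  if (!is.null(attB_strand)) near <- near & s$strand == attB_strand
  s$is_attB <- near
  catalog$sites <- s
  catalog$attB_reads_total <- sum(s$total_reads[s$is_attB])
  catalog$secondary_reads_total <- sum(s$total_reads[!s$is_attB])
  if (catalog$attB_reads_total > 0L) {
    catalog$ratio_secondary_to_attB <-
      catalog$secondary_reads_total / catalog$attB_reads_total
  } else {
    warning("no attB reads found; ratio undefined")
    catalog$ratio_secondary_to_attB <- NA_real_
  }
  catalog
}

#' Categorize sites by position relative to host genes
#'
#' A site inside any CDS span is `within_gene`.  Otherwise the nearest gene
#' (by distance to its closer boundary) decides: within `near_window` nt the
#' site is `upstream` when it lies 5' of the gene start in the gene's own
#' orientation and `downstream` when 3' of its end; farther sites are
#' `intergenic_far`.
#'
#' @param catalog a `site_catalog`
#' @param annotation a `gene_annotation`
#' @param near_window distance cap for upstream/downstream (default 500 nt)
#' @return list: `catalog` (with `nearest_gene`, `category`) and `summary`
#'   (within-gene fraction over secondary sites, strand counts, category
#'   table)
#' @export
categorize_by_gene <- function(catalog, annotation, near_window = 500L) {
  s <- catalog$sites
  if (nrow(annotation) == 0L) {
    warning("empty annotation: all sites categorized intergenic_far")
    s$category <- rep("intergenic_far", nrow(s))
    s$nearest_gene <- NA_character_
  } else if (nrow(s) > 0L) {
    cds <- annotation[annotation$kind == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      p <- s$position[i]
      inside <- which(annotation$start <= p & p <= annotation$end & annotation$kind == "CDS")
      if (length(inside) > 0L) {
        s$category[i] <- "within_gene"
        s$nearest_gene[i] <- annotation$gene[inside[1]]
        next
      }
      d <- pmin(abs(annotation$start - p), abs(annotation$end - p))
      j <- which.min(d)
      s$nearest_gene[i] <- annotation$gene[j]
      if (d[j] > near_window) {
        s$category[i] <- "intergenic_far"
      } else {
        gplus <- annotation$strand[j] == "+"
        before <- p < annotation$start[j]
        after <- p > annotation$end[j]
        s$category[i] <- if ((gplus && before) || (!gplus && after)) "upstream"
                         else if ((gplus && after) || (!gplus && before)) "downstream"
                         else "within_gene"  # inside a non-CDS feature span
      }
    }
  }
  catalog$sites <- s
  sec <- s[!s$is_attB, , drop = FALSE]
  summary <- list(
    n_secondary = nrow(sec),
    within_gene_fraction = if (nrow(sec)) mean(sec$category == "within_gene") else NA_real_,
    strand_counts = c(plus = sum(sec$strand == "+"), minus = sum(sec$strand == "-")),
    category_counts = table(factor(sec$category,
      levels = c("within_gene", "upstream", "downstream", "intergenic_far")))
  )
  list(catalog = catalog, summary = summary)
}

#' Call sites from junction mappings (convenience wrapper)
#'
#' Runs [infer_junction()], [collapse_and_merge()] and [classify_attB()].
#'
#' @param mappings data.frame from [map_pairs()]
#' @param g the `genome`
#' @param overlap_trim strand-exchange width (must match the filter config)
#' @param replicate_ids replicate universe
#' @param tolerance,min_reads see [collapse_and_merge()]
#' @param attB_position,attB_strand,attB_window see [classify_attB()]
#' @return a `site_catalog`
#' @export
call_sites <- function(mappings, g, overlap_trim = 7L, replicate_ids = NULL,
                       tolerance = 0L, min_reads = 1L,
                       attB_position = NULL, attB_strand = NULL, attB_window = 10L) {
  jx <- infer_junction(mappings, g, overlap_trim)
  cat_ <- collapse_and_merge(jx, replicate_ids = replicate_ids,
                             tolerance = tolerance, min_reads = min_reads,
                             genome_name = g$name)
  classify_attB(cat_, g, attB_position, attB_strand, attB_window)
}
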