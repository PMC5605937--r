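#' Build a k-mer genome index
#'
#' Exposes the seed-table contract used for lookups and diagnostics: every
#' genome k-mer free of N maps to its sorted 1-based start positions (on
#' circular genomes, starts wrap across the origin).  The batch mappers carry
#' their own internal seed structures; this index mainly serves the lookup
#' API and keeps a handle on the genome.
#'
#' @param g a `genome`
#' @param k seed length (default 12; < 8 is rejected as unspecific)
#' @return object of class `genome_index`
#' @export
build_index <- function(g, k = 12L) {
  if (k < 8L) stop("parameter error: seed length k = ", k, " too unspecific (< 8)")
  n <- g$length
  last <- if (g$circular) n else n - k + 1L
  if (last < 1L) stop("genome shorter than seed length")
  ext <- if (g$circular) paste0(g$seq, substr(g$seq, 1L, k)) else g$seq
  starts <- seq_len(last)
  kmers <- substring(ext, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  table <- split(starts[keep], kmers[keep])
  table <- lapply(table, sort)
  structure(list(k = as.integer(k), table = table, genome = g),
            class = "genome_index")
}

#' Look up a k-mer in a genome index
#' @param index a `genome_index`
#' @param kmer sequence of length `index$k`
#' @return sorted integer positions (1-based; empty if absent)
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(nchar(kmer) == index$k)
  index$table[[toupper(kmer)]] %||% integer(0)
}

#' Map a single query to the genome
#'
#' Seed-and-extend, ungapped, both strands.  A hit is reported when identity
#' = (|query| - mismatches) / |query| is at least `min_identity`; N in the
#' genome counts as a mismatch.  `ref_start` is the forward-genome coordinate
#' (1-based) of the query's 5'-most aligned base, so it sits at the right end
#' of the aligned interval for minus-strand hits.
#'
#' @param query DNA string (>= 16 nt recommended; >= 8 required)
#' @param index a `genome_index` (or a `genome`)
#' @param min_identity identity cutoff (default 0.95)
#' @return data.frame of hits, best identity first: `ref_start`, `strand`,
#'   `n_mismatches`, `identity`
#' @export
map_read <- function(query, index, min_identity = 0.95) {
  hits <- map_reads(query, index, min_identity)
  hits[hits$query == 1L, c("ref_start", "strand", "n_mismatches", "identity")]
}

#' Map many queries to the genome
#' @param queries character vector of DNA queries
#' @param index a `genome_index` (or a `genome`)
#' @param min_identity identity cutoff
#' @return data.frame: `query` (index into `queries`), `ref_start`, `strand`,
#'   `n_mismatches`, `identity`; hits for each query are best-identity first
#' @export
map_reads <- function(queries, index, min_identity = 0.95) {
  g <- if (inherits(index, "genome_index")) index$genome else index
  df <- .cpp_map_reads(as.character(queries), g$seq, min_identity, g$circular)
  L <- nchar(queries)[df$query]
  data.frame(query = df$query, ref_start = df$ref_start,
             strand = c("+", "-")[(df$strand < 0L) + 1L],
             n_mismatches = df$mismatches,
             identity = (L - df$mismatches) / L,
             stringsAsFactors = FALSE)
}

#' Map trimmed junction pairs
#'
#' Maps every accepted `host_seq1`/`host_seq2` pair; a concordant pairing
#' requires opposite strands in forward-reverse orientation with fragment
#' span at most `max_insert` (circular-aware).  `status` is `unique` when
#' exactly one concordant pairing maximises summed identity, `ambiguous` on a
#' tie, `unmapped` when read 1 has no hit, `discordant` otherwise.
#'
#' @param accepted data.frame from [filter_library()] (`pair_id`,
#'   `replicate_id`, `host_seq1`, `host_seq2`)
#' @param index a `genome_index` (or a `genome`)
#' @param min_identity identity cutoff (default 0.95)
#' @param max_insert maximum fragment span (default 1000 nt)
#' @return data.frame of junction mappings: per pair `status`, read-1/2
#'   `ref_start` (5'-most base, forward coords), `strand`, `mismatches`,
#'   `span`
#' @export
map_pairs <- function(accepted, index, min_identity = 0.95, max_insert = 1000L) {
  g <- if (inherits(index, "genome_index")) index$genome else index
  df <- .cpp_map_pairs(accepted$host_seq1, accepted$host_seq2, g$seq,
                       min_identity, as.integer(max_insert), g$circular)
  out <- cbind(data.frame(pair_id = accepted$pair_id,
                          replicate_id = accepted$replicate_id,
                          stringsAsFactors = FALSE),
               as.data.frame(df, stringsAsFactors = FALSE))
  out
}

#' Map one trimmed junction
#' @param junction a `trimmed_junction` from [process_pair()]
#' @param index a `genome_index` (or `genome`)
#' @param min_identity,max_insert see [map_pairs()]
#' @return one-row junction-mapping data.frame
#' @export
map_pair <- function(junction, index, min_identity = 0.95, max_insert = 1000L) {
  stopifnot(junction$rejection_reason == "none")
  acc <- data.frame(pair_id = junction$pair_id, replicate_id = junction$replicate_id,
                    host_seq1 = junction$host_seq1, host_seq2 = junction$host_seq2,
                    stringsAsFactors = FALSE)
  map_pairs(acc, index, min_identity, max_insert)
}
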