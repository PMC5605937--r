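#' Filter configuration
#'
#' All defaults are the published thresholds of the junction assay: exact
#' 45-nt anchor match, 7-nt strand-exchange trim, minimum 16-nt read-1 host
#' remnant, 20-nt read-2 prefix, 3' quality trimming at minimum Phred 10 and
#' mean Phred 15.
#'
#' @param anchor constant phage sequence expected in read 1 (uppercase ACGT)
#' @param overlap_trim strand-exchange bases removed from the remnant 5' end
#' @param min_read1_len minimum accepted host-remnant length
#' @param read2_prefix_len read-2 5' prefix taken for mapping
#' @param qmin minimum terminal Phred during 3' trimming
#' @param qavg minimum mean Phred during 3' trimming
#' @return object of class `filter_config`
#' @export
filter_config <- function(anchor = DEFAULT_ANCHOR, overlap_trim = 7L,
                          min_read1_len = 16L, read2_prefix_len = 20L,
                          qmin = 10L, qavg = 15L) {
  anchor <- toupper(anchor)
  if (nchar(anchor) == 0L || grepl("[^ACGT]", anchor))
    stop("anchor must be a non-empty uppercase ACGT string")
  if (overlap_trim < 0L) stop("overlap_trim must be >= 0")
  if (min_read1_len < 1L) stop("min_read1_len must be >= 1")
  structure(list(anchor = anchor, overlap_trim = as.integer(overlap_trim),
                 min_read1_len = as.integer(min_read1_len),
                 read2_prefix_len = as.integer(read2_prefix_len),
                 qmin = as.integer(qmin), qavg = as.numeric(qavg)),
            class = "filter_config")
}

#' Locate the exact phage anchor in read 1
#'
#' First exact occurrence, no mismatches tolerated (a single substitution
#' anywhere in the anchor disqualifies the read).
#'
#' @param read1_seq character vector of read-1 sequences
#' @param anchor anchor sequence
#' @return integer vector of 0-based offsets; `NA` where absent
#' @export
find_anchor <- function(read1_seq, anchor) {
  off <- regexpr(anchor, read1_seq, fixed = TRUE)
  ifelse(off > 0L, off - 1L, NA_integer_)
}

#' 3'-end quality trimming
#'
#' Iteratively removes the 3'-terminal base while the terminal Phred score is
#' below `qmin` or the mean Phred of the current read is below `qavg`.  On
#' exit (possibly empty) the terminal base has Phred at least `qmin` and the
#' mean is at least `qavg`.
#'
#' @param seq sequence string
#' @param quals integer Phred scores, one per base
#' @param qmin,qavg thresholds
#' @return list(seq=, quals=) of the retained prefix
#' @export
quality_trim_3prime <- function(seq, quals, qmin = 10L, qavg = 15) {
  stopifnot(nchar(seq) == length(quals))
  k <- quality_trim_len(quals, qmin, qavg)
  list(seq = substr(seq, 1L, k), quals = quals[seq_len(k)])
}

# retained prefix length under the iterative 3' trimming rule; the loop stops
# at the largest k with quals[k] >= qmin and mean(quals[1:k]) >= qavg
quality_trim_len <- function(quals, qmin, qavg) {
  n <- length(quals)
  if (n == 0L) return(0L)
  ok <- quals >= qmin & cumsum(quals) / seq_len(n) >= qavg
  if (!any(ok)) 0L else max(which(ok))
}

#' Process one read pair through the trimming cascade
#'
#' Order of operations: exact anchor search; discard bases up to and including
#' the anchor; 3' quality trim of the remnant; removal of the first
#' `overlap_trim` (strand-exchange) bases; length checks on the remnant and on
#' read 2.  Rejections are recorded as data (`rejection_reason`), not errors.
#'
#' @param pair one-row `read_pairs` (or list with the same fields)
#' @param config a `filter_config`
#' @return list of class `trimmed_junction`: `host_seq1`, `host_seq2`,
#'   `pair_id`, `replicate_id`, `rejection_reason` in
#'   none/no_anchor/low_quality/too_short
#' @export
process_pair <- function(pair, config = filter_config()) {
  res <- filter_pairs_core(pair$read1_seq[1], pair$read1_qual[1],
                           pair$read2_seq[1], config)
  structure(list(host_seq1 = res$host_seq1, host_seq2 = res$host_seq2,
                 pair_id = pair$pair_id[1], replicate_id = pair$replicate_id[1],
                 rejection_reason = res$reason), class = "trimmed_junction")
}

# vectorised cascade shared by process_pair and filter_library
filter_pairs_core <- function(r1seq, r1qual, r2seq, config) {
  n <- length(r1seq)
  reason <- rep("none", n)
  host1 <- character(n); host2 <- character(n)
  off <- find_anchor(r1seq, config$anchor)
  reason[is.na(off)] <- "no_anchor"
  ok <- !is.na(off)
  if (any(ok)) {
    cut <- off[ok] + nchar(config$anchor)  # bases consumed from read-1 5' end
    rem_seq <- substr(r1seq[ok], cut + 1L, nchar(r1seq[ok]))
    rem_qual <- substr(r1qual[ok], cut + 1L, nchar(r1qual[ok]))
    qlists <- phred_from_string(rem_qual)
    klen <- vapply(qlists, quality_trim_len, 0L, qmin = config$qmin, qavg = config$qavg)
    idx <- which(ok)
    emptied <- klen == 0L
    reason[idx[emptied]] <- "low_quality"
    trimmed <- substr(rem_seq, config$overlap_trim + 1L, klen)
    short1 <- !emptied & nchar(trimmed) < config$min_read1_len
    reason[idx[short1]] <- "too_short"
    short2 <- !emptied & !short1 & nchar(r2seq[ok]) < config$read2_prefix_len
    reason[idx[short2]] <- "too_short"
    acc <- !emptied & !short1 & !short2
    host1[idx[acc]] <- trimmed[acc]
    host2[idx[acc]] <- substr(r2seq[ok][acc], 1L, config$read2_prefix_len)
  }
  list(host_seq1 = host1, host_seq2 = host2, reason = reason)
}

#' Filter a whole library
#'
#' @param pairs a `read_pairs` data.frame
#' @param config a `filter_config`
#' @return list: `accepted` (data.frame pair_id, replicate_id, host_seq1,
#'   host_seq2) and `report` (`filter_report`: total plus per-reason counts)
#' @export
filter_library <- function(pairs, config = filter_config()) {
  res <- filter_pairs_core(pairs$read1_seq, pairs$read1_qual, pairs$read2_seq, config)
  keep <- res$reason == "none"
  accepted <- data.frame(pair_id = pairs$pair_id[keep],
                         replicate_id = pairs$replicate_id[keep],
                         host_seq1 = res$host_seq1[keep],
                         host_seq2 = res$host_seq2[keep],
                         stringsAsFactors = FALSE)
  report <- structure(list(
    total = nrow(pairs),
    accepted = sum(keep),
    no_anchor = sum(res$reason == "no_anchor"),
    low_quality = sum(res$reason == "low_quality"),
    too_short = sum(res$reason == "too_short")
  ), class = "filter_report")
  list(accepted = accepted, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d pairs: %d accepted; ",
                     "%d no_anchor, %d low_quality, %d too_short\n"),
              x$total, x$accepted, x$no_anchor, x$low_quality, x$too_short))
  invisible(x)
}
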