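#' Enumerate Cas9 sgRNA candidates around an integration site
#'
#' All 20-nt protospacers with an NGG PAM immediately 3', on either genome
#' strand, whose protospacer+PAM interval lies within `search_radius` of the
#' site.  A candidate `spans_junction` when its interval has at least one
#' base on each side of the 7-nt strand-exchange (overlap) region: phage
#' integration splits the host there (both resulting junctions retain the
#' overlap itself), so only spanning protospacers are disrupted in lysogens.
#'
#' @param g a `genome`
#' @param site_position 1-based coordinate of the first overlap base on the
#'   integration strand
#' @param site_strand `+` or `-` (fixes which side of `site_position` the
#'   overlap occupies on the forward strand)
#' @param search_radius maximum distance of the interval from the site
#' @param overlap_width strand-exchange width (default 7)
#' @return data.frame of candidates: `protospacer`, `pam`, `strand`,
#'   `protospacer_start` (forward coord of the interval's leftmost
#'   protospacer base), `cut_position`, `cut_distance`, `spans_junction`
#' @export
enumerate_candidates <- function(g, site_position, site_strand = "+",
                                 search_radius = 30L, overlap_width = 7L) {
  n <- g$length
  left_ov <- if (site_strand == "+") site_position else site_position - overlap_width + 1L
  right_ov <- left_ov + overlap_width - 1L
  lo <- site_position - search_radius
  hi <- site_position + search_radius
  # local sequence, re-based so local index 1 = genome coord `lo`
  local <- genome_subseq(g, lo, hi - lo + 1L)
  chars <- strsplit(local, "", fixed = TRUE)[[1]]
  width <- length(chars)
  res <- list()
  wrap <- function(p) if (g$circular) ((p - 1L) %% n) + 1L else p
  mid_ov <- (left_ov + right_ov) / 2
  for (s in seq_len(width - 22L)) {         # interval [s, s+22] local
    glo <- lo + s - 1L                       # genome coord of interval start
    # + orientation: protospacer [s, s+19], PAM [s+20, s+22] must be NGG
    if (chars[s + 21L] == "G" && chars[s + 22L] == "G") {
      proto <- substr(local, s, s + 19L)
      if (!grepl("N", proto, fixed = TRUE)) {
        cut_pos <- glo + 16.5  # between protospacer bases 17 and 18
        res[[length(res) + 1L]] <- data.frame(
          protospacer = proto, pam = substr(local, s + 20L, s + 22L),
          strand = "+", protospacer_start = wrap(glo),
          cut_position = cut_pos, cut_distance = abs(cut_pos - mid_ov),
          spans_junction = glo < left_ov && (glo + 22L) > right_ov,
          stringsAsFactors = FALSE)
      }
    }
    # - orientation: PAM occupies local [s, s+2] as CCN on the forward strand
    if (chars[s] == "C" && chars[s + 1L] == "C") {
      proto_fwd <- substr(local, s + 3L, s + 22L)
      if (!grepl("N", proto_fwd, fixed = TRUE)) {
        cut_pos <- glo + 5.5   # 3 bp 5' of PAM on the minus strand
        res[[length(res) + 1L]] <- data.frame(
          protospacer = revcomp(proto_fwd),
          pam = revcomp(substr(local, s, s + 2L)),
          strand = "-", protospacer_start = wrap(glo + 3L),
          cut_position = cut_pos, cut_distance = abs(cut_pos - mid_ov),
          spans_junction = glo < left_ov && (glo + 22L) > right_ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    warning("no PAM available within ", search_radius, " nt of site ", site_position)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), protospacer_start = integer(0),
                      cut_position = numeric(0), cut_distance = numeric(0),
                      spans_junction = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Count genome-wide off-targets of a protospacer
#'
#' Exhaustive both-strand scan: every position where the 20-mer matches with
#' at most `max_mm` substitutions AND an NGG PAM lies immediately 3' is
#' counted (the on-target site itself included).  N never matches.
#'
#' @param protospacer 20-nt sequence (as read on its own strand, PAM-proximal
#'   end last)
#' @param g a `genome`
#' @param max_mm maximum substitutions surveyed (default 2)
#' @return named integer vector: exact occurrence count per mismatch level
#'   `0..max_mm`
#' @export
count_offtargets <- function(protospacer, g, max_mm = 2L) {
  protospacer <- toupper(protospacer)
  L <- nchar(protospacer)
  n <- g$length
  pad <- L + 3L
  ext <- if (g$circular) paste0(g$seq, substr(g$seq, 1L, pad)) else g$seq
  code <- match(strsplit(ext, "", fixed = TRUE)[[1]], DNA_BASES)
  nw <- if (g$circular) n else n - L + 1L
  counts <- integer(max_mm + 1L)
  tally <- function(qcode, pam_ok) {
    mm <- integer(nw)
    for (j in seq_len(L)) {
      cj <- code[seq_len(nw) + j - 1L]
      mm <- mm + as.integer(is.na(cj) | cj != qcode[j])
    }
    ok <- pam_ok & mm <= max_mm
    tabulate(mm[ok] + 1L, nbins = max_mm + 1L)
  }
  qf <- match(strsplit(protospacer, "", fixed = TRUE)[[1]], DNA_BASES)
  # + orientation: protospacer at [i, i+L-1], PAM N-G-G at [i+L, i+L+2]
  gpos <- function(off) {
    v <- code[seq_len(nw) + off]
    !is.na(v) & v == 3L  # G (A=1,C=2,G=3,T=4)
  }
  pam_plus <- gpos(L + 1L) & gpos(L + 2L)
  counts <- counts + tally(qf, pam_plus)
  # - orientation: protospacer revcomp on forward, PAM as CC at [i-3, i-2].
  # scan windows [i, i+L-1] holding revcomp(protospacer); shift indices so
  # the CC sits inside the scanned frame: window' = [i-3, i+L-1]
  qr <- match(strsplit(revcomp(protospacer), "", fixed = TRUE)[[1]], DNA_BASES)
  cpos <- function(off) {
    i <- seq_len(nw) + off
    i <- if (g$circular) ((i - 1L) %% n) + 1L else i
    valid <- i >= 1L & i <= length(code)
    v <- rep(NA_integer_, nw)
    v[valid] <- code[i[valid]]
    !is.na(v) & v == 2L
  }
  pam_minus <- cpos(-3L) & cpos(-2L)
  counts <- counts + tally(qr, pam_minus)
  setNames(counts, as.character(0:max_mm))
}

#' Vet and rank sgRNA candidates
#'
#' Accepts junction-spanning candidates whose total occurrence count at up to
#' `max_mm` mismatches is exactly 1 (the on-target locus), ranked by the
#' distance of the predicted cut (between protospacer bases 17 and 18) to the
#' overlap midpoint.
#'
#' @param candidates data.frame from [enumerate_candidates()]
#' @param g a `genome`
#' @param max_mm mismatch depth of the uniqueness screen (default 2)
#' @return data.frame of all candidates with `offtarget_total`, `accepted`,
#'   `reason` columns, accepted-and-nearest first
#' @export
select_guides <- function(candidates, g, max_mm = 2L) {
  if (nrow(candidates) == 0L) {
    message("no candidates to vet (no PAM available near the site)")
    candidates$offtarget_total <- integer(0)
    candidates$accepted <- logical(0)
    candidates$reason <- character(0)
    return(candidates)
  }
  ot <- vapply(candidates$protospacer, function(p)
    sum(count_offtargets(p, g, max_mm)), integer(1), USE.NAMES = FALSE)
  candidates$offtarget_total <- ot
  candidates$accepted <- candidates$spans_junction & ot == 1L
  candidates$reason <- ifelse(candidates$accepted, "ok",
    ifelse(!candidates$spans_junction, "does_not_span_junction", "not_unique"))
  ord <- order(!candidates$accepted, candidates$cut_distance)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  if (!any(candidates$accepted))
    message("no junction-spanning unique sgRNA candidate at this site; ",
            "widen the radius or relax max_mm")
  candidates
}
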