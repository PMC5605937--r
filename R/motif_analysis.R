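#' Extract motif windows around catalog sites
#'
#' Windows are read on the integration strand with position labels
#' `-offset_left .. +offset_right`, label 0 being the first base of the 7-nt
#' strand-exchange region.  Plus-strand sites take the forward interval
#' `[pos - offset_left, pos + offset_right]`; minus-strand sites take the
#' reverse complement of the mirrored interval.  Windows containing N are
#' flagged and excluded from matrix building.
#'
#' @param g a `genome`
#' @param catalog a `site_catalog` (or data.frame with `position`, `strand`)
#' @param offset_left,offset_right label range (defaults give 29-mers)
#' @return data.frame: `site_id`, `position`, `strand`, `sequence`, `has_N`
#' @export
extract_windows <- function(g, catalog, offset_left = 14L, offset_right = 14L) {
  s <- if (inherits(catalog, "site_catalog")) catalog$sites else catalog
  width <- offset_left + offset_right + 1L
  if (nrow(s) == 0L) {
    return(data.frame(site_id = character(0), position = integer(0),
                      strand = character(0), sequence = character(0),
                      has_N = logical(0), stringsAsFactors = FALSE))
  }
  if (!g$circular) {
    lo <- ifelse(s$strand == "+", s$position - offset_left, s$position - offset_right)
    hi <- lo + width - 1L
    off_end <- lo < 1L | hi > g$length
    if (any(off_end)) {
      warning(sum(off_end), " window(s) fall off the linear genome ends; skipped")
      s <- s[!off_end, , drop = FALSE]
    }
    if (nrow(s) == 0L) {
      return(data.frame(site_id = character(0), position = integer(0),
                        strand = character(0), sequence = character(0),
                        has_N = logical(0), stringsAsFactors = FALSE))
    }
  }
  seqs <- strand_segment(g, s$position, width, s$strand, offset = -offset_left)
  data.frame(site_id = s$site_id %||% sprintf("w%d", seq_len(nrow(s))),
             position = s$position, strand = s$strand, sequence = seqs,
             has_N = grepl("N", seqs, fixed = TRUE), stringsAsFactors = FALSE)
}

#' Build a position-specific scoring matrix from motif windows
#'
#' Counts per position/base, pseudocounted frequencies
#' `(count + pc) / (n + 4 pc)`, log2-odds against the background, and
#' per-position information content `2 + sum f log2 f` (bits).
#'
#' @param windows character vector of equal-length windows (N-free), or the
#'   data.frame from [extract_windows()] (N-containing rows are dropped)
#' @param pseudocount per-base pseudocount (default 1)
#' @param background length-4 base probabilities (e.g. genome composition);
#'   default uniform
#' @return object of class `pssm`: list with `counts`, `frequencies`,
#'   `log_odds` (width x 4 matrices, rows labelled by position),
#'   `information_content`, `background`, `pseudocount`, `n_windows`,
#'   `consensus`, `max_score`
#' @export
build_matrix <- function(windows, pseudocount = 1, background = rep(0.25, 4)) {
  if (is.data.frame(windows)) windows <- windows$sequence[!windows$has_N]
  windows <- toupper(windows)
  if (length(windows) < 2L)
    stop("insufficient data: need >= 2 N-free windows, got ", length(windows))
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("windows have unequal lengths")
  if (any(grepl("[^ACGT]", windows))) stop("windows must be N-free ACGT strings")
  background <- background / sum(background)
  half <- (w - 1L) %/% 2L
  labels <- if (w %% 2L == 1L) as.character(seq(-half, half)) else as.character(seq_len(w))
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE)), nrow = w)
  counts <- t(apply(m, 1L, function(row) tabulate(match(row, DNA_BASES), 4L)))
  dimnames(counts) <- list(labels, DNA_BASES)
  n <- length(windows)
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  lo <- log2(sweep(freq, 2L, background, "/"))
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  ic <- 2 + rowSums(plogp)
  structure(list(counts = counts, frequencies = freq, log_odds = lo,
                 information_content = setNames(ic, labels),
                 background = setNames(background, DNA_BASES),
                 pseudocount = pseudocount, n_windows = n,
                 consensus = motif_consensus(freq),
                 max_score = sum(apply(lo, 1L, max))),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> width %d from %d windows; consensus %s; max score %.2f bits\n",
              nrow(x$counts), x$n_windows, x$consensus, x$max_score))
  invisible(x)
}

#' Score a window against a PSSM
#'
#' Sum of per-position log2-odds.  Windows containing N get `NA` (undefined
#' score).
#'
#' @param matrix a `pssm`
#' @param window sequence(s) of the matrix width (vectorised)
#' @return numeric score(s) in bits
#' @export
score_sequence <- function(matrix, window) {
  w <- nrow(matrix$log_odds)
  stopifnot(all(nchar(window) == w))
  vapply(toupper(window), function(s) {
    idx <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
    if (anyNA(idx)) return(NA_real_)
    sum(matrix$log_odds[cbind(seq_len(w), idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan the whole genome with a PSSM
#'
#' Scores every window start on both strands (circular-aware: exactly
#' `2 * length` windows on a circular genome).  Windows containing N score
#' `NA` and are excluded from the summary statistics.
#'
#' @param matrix a `pssm`
#' @param g a `genome`
#' @param top_k how many top-scoring windows to report
#' @param exclude data.frame of (`position`, `strand`) — typically the
#'   detected catalog — removed from the top-k report so it lists
#'   high-scoring but undetected windows
#' @return list of class `scan_summary`: `mean`, `sd`, `n_windows`,
#'   `histogram` (hist object data), `top_undetected` (data.frame `position`,
#'   `strand`, `score`), plus the raw per-strand score vectors in `scores`
#' @export
scan_genome <- function(matrix, g, top_k = 25L, exclude = NULL) {
  w <- nrow(matrix$log_odds)
  n <- g$length
  nw <- if (g$circular) n else n - w + 1L
  if (nw < 1L) stop("genome shorter than matrix width")
  ext <- if (g$circular) paste0(g$seq, substr(g$seq, 1L, w)) else g$seq
  code <- match(strsplit(ext, "", fixed = TRUE)[[1]], DNA_BASES)  # NA for N
  lo <- matrix$log_odds
  # minus-strand windows scored via the reverse-complemented matrix so a
  # single forward pass covers both strands
  lo_rc <- lo[rev(seq_len(w)), rev(seq_len(4L)), drop = FALSE]
  sc_f <- numeric(nw); sc_r <- numeric(nw)
  for (j in seq_len(w)) {
    cj <- code[seq_len(nw) + j - 1L]
    sc_f <- sc_f + lo[j, ][cj]
    sc_r <- sc_r + lo_rc[j, ][cj]
  }
  fwd <- sc_f; rev_ <- sc_r
  # minus-strand "site position" label: the window whose forward interval is
  # [i, i+w-1] corresponds, on the minus strand, to label 0 at the mirrored
  # offset (offset_right from the left end)
  half_l <- (w - 1L) %/% 2L
  pos_fwd <- (((seq_len(nw) - 1L) + half_l) %% n) + 1L          # label-0 coord, + strand
  pos_rev <- (((seq_len(nw) - 1L) + (w - 1L - half_l)) %% n) + 1L  # label-0 coord, - strand
  all_scores <- c(fwd, rev_)
  all_pos <- c(pos_fwd, pos_rev)
  all_strand <- rep(c("+", "-"), each = nw)
  okv <- !is.na(all_scores)
  h <- graphics::hist(all_scores[okv], breaks = 50, plot = FALSE)
  keep <- okv
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "site_catalog")) exclude$sites else exclude
    keep <- keep & !(paste(all_pos, all_strand) %in% paste(ex$position, ex$strand))
  }
  ord <- order(all_scores[keep], decreasing = TRUE)[seq_len(min(top_k, sum(keep)))]
  idx <- which(keep)[ord]
  structure(list(
    mean = mean(all_scores[okv]), sd = stats::sd(all_scores[okv]),
    n_windows = sum(okv),
    histogram = list(breaks = h$breaks, counts = h$counts),
    top_undetected = data.frame(position = all_pos[idx], strand = all_strand[idx],
                                score = all_scores[idx], stringsAsFactors = FALSE),
    scores = list(fwd = fwd, rev = rev_)
  ), class = "scan_summary")
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("<scan_summary> %d windows scored; mean %.3f, sd %.3f bits\n",
              x$n_windows, x$mean, x$sd))
  invisible(x)
}

#' Score catalog sites and centre them on the catalog mean
#'
#' `motif_score` is the PSSM score of each site's window; `relative_score`
#' subtracts the mean over all scored sites (so the catalog mean is 0 and
#' ranking is unchanged).
#'
#' @param matrix a `pssm`
#' @param catalog a `site_catalog`
#' @param g the `genome` the catalog refers to
#' @param offset_left,offset_right window registration (must match the matrix)
#' @return catalog with `motif_score` and `relative_score` filled
#' @export
relative_scores <- function(matrix, catalog, g,
                            offset_left = 14L, offset_right = 14L) {
  wins <- extract_windows(g, catalog, offset_left, offset_right)
  sc <- rep(NA_real_, nrow(catalog$sites))
  ok <- !wins$has_N
  sc[match(wins$site_id[ok], catalog$sites$site_id)] <-
    score_sequence(matrix, wins$sequence[ok])
  catalog$sites$motif_score <- sc
  catalog$sites$relative_score <- sc - mean(sc, na.rm = TRUE)
  catalog
}

#' Mean motif score by detection frequency
#'
#' One row per observed detection frequency plus the coarse reporting classes
#' (1 / 2-4 / >4 replicates).
#'
#' @param catalog a scored `site_catalog`
#' @param include_attB include the attB site itself (default FALSE)
#' @return list: `by_frequency` (data.frame `detection_frequency`,
#'   `mean_score`, `n`) and `by_class` (data.frame `class`, `mean_score`, `n`)
#' @export
score_by_detection_frequency <- function(catalog, include_attB = FALSE) {
  s <- catalog$sites
  if (!include_attB) s <- s[!s$is_attB, , drop = FALSE]
  s <- s[!is.na(s$motif_score), , drop = FALSE]
  if (nrow(s) == 0L) {
    empty <- data.frame(mean_score = numeric(0), n = integer(0))
    return(list(by_frequency = cbind(data.frame(detection_frequency = integer(0)), empty),
                by_class = cbind(data.frame(class = character(0)), empty)))
  }
  byf <- aggregate(s$motif_score, by = list(detection_frequency = s$detection_frequency),
                   FUN = mean)
  names(byf)[2] <- "mean_score"
  byf$n <- as.integer(table(s$detection_frequency)[as.character(byf$detection_frequency)])
  cls <- cut(s$detection_frequency, breaks = c(0, 1, 4, Inf),
             labels = c("1", "2-4", ">4"))
  byc <- aggregate(s$motif_score, by = list(class = cls), FUN = mean, drop = TRUE)
  names(byc)[2] <- "mean_score"
  byc$n <- as.integer(table(cls[!is.na(cls)])[as.character(byc$class)])
  list(by_frequency = byf, by_class = byc)
}

#' Export a PSSM in MEME minimal motif format
#' @param matrix a `pssm`
#' @param path output file
#' @param name motif name
#' @export
write_meme <- function(matrix, path, name = "integration_site") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, matrix$background), collapse = " "),
               "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(matrix$frequencies), matrix$n_windows)), con)
  writeLines(apply(matrix$frequencies, 1L, function(r)
    paste(sprintf("%.6f", r), collapse = "  ")), con)
  invisible(path)
}
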