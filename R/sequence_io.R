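#' Genome object
#'
#' Lightweight container for a (by default circular) bacterial chromosome.
#' Base frequencies are computed over A/C/G/T only; N bases are tolerated in
#' the sequence but excluded from composition and from motif statistics.
#'
#' @param sequence DNA string (A/C/G/T/N, any case)
#' @param name sequence identifier
#' @param circular treat coordinates modulo length (default TRUE)
#' @return object of class `genome`: list with `name`, `seq`, `length`,
#'   `circular`, `base_frequencies`
#' @export
genome <- function(sequence, name = "genome", circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("genome sequence is empty")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d in genome sequence",
                 substr(sequence, bad, bad), bad))
  }
  counts <- vapply(DNA_BASES, function(b)
    lengths(regmatches(sequence, gregexpr(b, sequence, fixed = TRUE))), numeric(1))
  tot <- sum(counts)
  structure(list(
    name = name,
    seq = sequence,
    length = nchar(sequence),
    circular = circular,
    base_frequencies = if (tot > 0) counts / tot else setNames(rep(NA_real_, 4), DNA_BASES)
  ), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %s; GC %.1f%%\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              100 * sum(x$base_frequencies[c("C", "G")])))
  invisible(x)
}

#' @export
length.genome <- function(x) x$length

#' Read the first record of a FASTA file as a genome
#'
#' Multi-record files trigger a warning and only the first record is kept
#' (single-chromosome bacterial assemblies are the intended input).
#'
#' @param path FASTA file
#' @param circular passed to [genome()]
#' @return a `genome`
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA file '", path, "' contains no records")
  if (length(ss) > 1L) {
    warning(sprintf("FASTA '%s' has %d records; using the first ('%s')",
                    path, length(ss), names(ss)[1]))
  }
  nm <- sub("\\s.*$", "", names(ss)[1])
  genome(as.character(ss[[1]]), name = nm, circular = circular)
}

#' Write a genome to FASTA
#' @param g a `genome`
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(g, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(g$seq)
  names(ss) <- g$name
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Extract a subsequence with circular wrap-around
#'
#' For circular genomes any integer `start` is valid (taken modulo length) and
#' the result always has exactly `len` characters.  For linear genomes,
#' requests off either end raise an error.
#'
#' @param g a `genome`
#' @param start 1-based start coordinate
#' @param len subsequence length
#' @return character scalar of length `len`
#' @export
genome_subseq <- function(g, start, len) {
  stopifnot(len >= 0)
  if (len == 0L) return("")
  n <- g$length
  if (!g$circular) {
    if (start < 1L || start + len - 1L > n)
      stop(sprintf("subsequence [%d, %d] outside linear genome of length %d",
                   start, start + len - 1L, n))
    return(substr(g$seq, start, start + len - 1L))
  }
  start <- ((start - 1L) %% n) + 1L
  if (start + len - 1L <= n) return(substr(g$seq, start, start + len - 1L))
  # wrap: may need multiple copies if len > n
  reps <- ceiling((start + len - 1L) / n)
  substr(strrep(g$seq, reps), start, start + len - 1L)
}

#' Paired reads container
#'
#' A data.frame subclass with one row per read pair: `pair_id`, `read1_seq`,
#' `read1_qual`, `read2_seq`, `read2_qual`, `replicate_id`.
#'
#' @param pair_id,read1_seq,read1_qual,read2_seq,read2_qual,replicate_id
#'   per-pair character vectors (qualities Phred+33 encoded)
#' @return `read_pairs` data.frame
#' @export
read_pairs <- function(pair_id, read1_seq, read1_qual, read2_seq, read2_qual,
                       replicate_id = "rep1") {
  stopifnot(all(nchar(read1_seq) == nchar(read1_qual)),
            all(nchar(read2_seq) == nchar(read2_qual)))
  df <- data.frame(pair_id = as.character(pair_id),
                   read1_seq = toupper(read1_seq), read1_qual = read1_qual,
                   read2_seq = toupper(read2_seq), read2_qual = read2_qual,
                   replicate_id = as.character(replicate_id),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_pairs", "data.frame")
  df
}

#' Read a FASTQ pair of files (Phred+33)
#'
#' Records are paired by file order; IDs are taken from the read-1 headers.
#' A record-count mismatch between the two files is an error.
#'
#' @param path_r1,path_r2 FASTQ files for mates 1 and 2
#' @param replicate_id replicate label attached to every pair
#' @return `read_pairs` data.frame
#' @export
read_fastq_pairs <- function(path_r1, path_r2, replicate_id = "rep1") {
  rd <- function(p) {
    x <- tryCatch(Biostrings::readDNAStringSet(p, format = "fastq", with.qualities = TRUE),
                  error = function(e) stop("malformed FASTQ '", p, "': ", conditionMessage(e)))
    list(seq = as.character(x),
         qual = as.character(S4Vectors::mcols(x)$qualities),
         id = sub("\\s.*$", "", names(x)))
  }
  r1 <- rd(path_r1); r2 <- rd(path_r2)
  if (length(r1$seq) != length(r2$seq))
    stop(sprintf("read pairing error: %d records in '%s' but %d in '%s'",
                 length(r1$seq), path_r1, length(r2$seq), path_r2))
  if (length(r1$seq) == 0L)
    return(read_pairs(character(0), character(0), character(0),
                      character(0), character(0), character(0)))
  read_pairs(r1$id, r1$seq, r1$qual, r2$seq, r2$qual, replicate_id)
}

#' Write paired reads as two FASTQ files
#' @param pairs a `read_pairs` data.frame
#' @param path_r1,path_r2 output FASTQ paths
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  wr <- function(seqs, quals, ids, path) {
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- ids
    Biostrings::writeXStringSet(ss, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$read1_seq, pairs$read1_qual, pairs$pair_id, path_r1)
  wr(pairs$read2_seq, pairs$read2_qual, pairs$pair_id, path_r2)
  invisible(c(path_r1, path_r2))
}

#' Read a GFF3 gene annotation
#'
#' CDS and rRNA features are retained with their kind; all other feature types
#' are kept as `other`.  Gene names fall back through the `gene`, `Name`,
#' `locus_tag` attributes.  Lines that do not have 9 tab-separated fields are
#' skipped with a warning rather than failing the whole load.
#'
#' @param path GFF3 file
#' @return `gene_annotation` data.frame with columns `gene`, `start`, `end`,
#'   `strand`, `kind`, sorted by `start`
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- body & nf != 9L
  if (any(bad)) {
    warning(sprintf("skipping %d unparseable GFF line(s) (first at line %d)",
                    sum(bad), which(bad)[1]))
  }
  keep <- lines[!bad]
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(keep, tf)
  gr <- tryCatch(rtracklayer::import(tf, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ", conditionMessage(e)))
  if (length(gr) == 0L) {
    warning("annotation '", path, "' has no usable features; sites will be uncategorized")
    return(gene_annotation(data.frame(gene = character(0), start = integer(0),
                                      end = integer(0), strand = character(0),
                                      kind = character(0))))
  }
  md <- S4Vectors::mcols(gr)
  pick <- function(field) if (field %in% colnames(md)) as.character(md[[field]]) else rep(NA_character_, length(gr))
  nm <- pick("gene")
  nm <- ifelse(is.na(nm) | nm == "", pick("Name"), nm)
  nm <- ifelse(is.na(nm) | nm == "", pick("locus_tag"), nm)
  nm[is.na(nm) | nm == ""] <- sprintf("feature_%d", which(is.na(nm) | nm == ""))
  type <- as.character(md$type)
  kind <- ifelse(type == "CDS", "CDS", ifelse(type == "rRNA", "rRNA", "other"))
  df <- data.frame(gene = nm,
                   start = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)),
                   kind = kind, stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  gene_annotation(df)
}

#' Construct a gene annotation table
#' @param df data.frame with `gene`, `start`, `end`, `strand`, `kind`
#' @return `gene_annotation` data.frame sorted by start
#' @export
gene_annotation <- function(df) {
  stopifnot(all(c("gene", "start", "end", "strand", "kind") %in% names(df)))
  if (nrow(df) > 0L) {
    stopifnot(all(df$start <= df$end), all(df$strand %in% c("+", "-")))
    df <- df[order(df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Write a gene annotation as GFF3
#' @param ann `gene_annotation`
#' @param path output file
#' @param seqname sequence name for column 1
#' @export
write_gff <- function(ann, path, seqname = "genome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ann) > 0L) {
    writeLines(sprintf("%s\tphagesite\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s",
                       seqname, ifelse(ann$kind == "other", "gene", ann$kind),
                       ann$start, ann$end, ann$strand,
                       make.unique(ann$gene), ann$gene), con)
  }
  invisible(path)
}

#' Write the site catalog as BED6 + TSV
#'
#' The BED file is 0-based half-open; its score column holds the relative
#' motif score times 100 (rounded), or 0 for unscored sites.  The TSV is
#' 1-based and holds one row per site with per-replicate read counts packed
#' as a comma-separated string.
#'
#' @param catalog a `site_catalog`
#' @param bed_path,tsv_path output paths (either may be NULL to skip)
#' @return invisible vector of paths written
#' @export
write_site_outputs <- function(catalog, bed_path = NULL, tsv_path = NULL) {
  s <- catalog$sites
  written <- character(0)
  if (!is.null(tsv_path)) {
    out <- data.frame(
      site_id = s$site_id, position_1based = s$position, strand = s$strand,
      total_reads = s$total_reads,
      reads_per_replicate = vapply(s$reads_per_replicate, paste, "", collapse = ","),
      detection_frequency = s$detection_frequency,
      is_attB = s$is_attB, nearest_gene = s$nearest_gene, category = s$category,
      motif_score = s$motif_score, relative_score = s$relative_score,
      stringsAsFactors = FALSE)
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  if (!is.null(bed_path)) {
    score <- ifelse(is.na(s$relative_score), 0, round(s$relative_score * 100))
    bed <- data.frame(chrom = rep(catalog$genome_name %||% "genome", nrow(s)),
                      start = s$position - 1L, end = s$position,
                      name = s$site_id, score = score, strand = s$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  invisible(written)
}

#' Re-read a site TSV written by [write_site_outputs()]
#' @param tsv_path file written by `write_site_outputs`
#' @param n_replicates replicate count for the catalog header
#' @return a `site_catalog`
#' @export
read_site_tsv <- function(tsv_path, n_replicates = NA_integer_) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  rpr <- lapply(strsplit(as.character(df$reads_per_replicate), ","),
                function(x) as.integer(x))
  if (nrow(df) == 0L) rpr <- list()
  sites <- data.frame(site_id = as.character(df$site_id), position = df$position_1based,
                      strand = df$strand, total_reads = df$total_reads,
                      detection_frequency = df$detection_frequency,
                      is_attB = df$is_attB, nearest_gene = as.character(df$nearest_gene),
                      category = as.character(df$category),
                      motif_score = df$motif_score, relative_score = df$relative_score,
                      stringsAsFactors = FALSE)
  sites$reads_per_replicate <- rpr
  new_site_catalog(sites, n_replicates = n_replicates)
}
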