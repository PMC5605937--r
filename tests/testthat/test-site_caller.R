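test_that("infer_junction recovers planted sites on both strands", {
  fix <- tiny_simulation(seed = 31L, n_sites = 8L, reads = 1200L, reps = 2L)
  filt <- filter_library(do.call(rbind, fix$pairs), filter_config())
  maps <- map_pairs(filt$accepted, fix$genome)
  jx <- infer_junction(maps, fix$genome)
  called <- unique(paste(jx$position, jx$strand))
  m <- fix$manifest
  realized <- rowSums(m$counts) > 0
  planted <- paste(c(m$attB_position, m$secondary_sites$position),
                   c(m$attB_strand, m$secondary_sites$strand))[realized]
  expect_setequal(called, planted)
  # read conservation: one junction row per unique mapping
  expect_equal(nrow(jx), sum(maps$status == "unique"))
})

test_that("infer_junction wraps across the circular origin", {
  # hand-built fixture: site near the origin so read-1 remnants wrap
  g <- random_genome(5000L, seed = 32L)
  for (strand in c("+", "-")) {
    pos <- if (strand == "+") 4995L else 6L
    # construct an error-free junction pair exactly as the library would
    host1 <- phagesite:::strand_segment(g, pos, 30L, strand)
    r1 <- paste0(DEFAULT_ANCHOR, host1)
    r2 <- revcomp(phagesite:::strand_segment(g, pos, 75L, strand, offset = 180L))
    pr <- read_pairs("w", r1, string_from_phred(rep(40L, 75)),
                     r2, string_from_phred(rep(40L, 75)))
    tj <- process_pair(pr, filter_config())
    expect_identical(tj$rejection_reason, "none")
    mp <- map_pair(tj, g)
    expect_identical(mp$status, "unique")
    jx <- infer_junction(mp, g)
    expect_equal(jx$position, pos)
    expect_identical(jx$strand, strand)
  }
})

test_that("collapse_and_merge: keys, detection frequency, tolerance", {
  jx <- data.frame(
    position = c(rep(100L, 7), 100L, 250L),
    strand = c(rep("+", 7), "-", "+"),
    replicate_id = c("rep1", "rep1", "rep2", "rep3", "rep4", "rep5", "rep5",
                     "rep1", "rep2"),
    stringsAsFactors = FALSE)
  cat_ <- collapse_and_merge(jx, replicate_ids = sprintf("rep%d", 1:8))
  s <- cat_$sites
  expect_equal(nrow(s), 3L)  # (100,+), (100,-), (250,+): strand in the key
  plus100 <- s[s$position == 100 & s$strand == "+", ]
  expect_equal(plus100$detection_frequency, 5L)  # seen in 5 of 8 replicates
  expect_equal(plus100$total_reads, 7L)
  expect_equal(unname(plus100$reads_per_replicate[[1]]),
               c(2L, 1L, 1L, 1L, 2L, 0L, 0L, 0L))
  # min_reads raises the bar
  cat2 <- collapse_and_merge(jx, replicate_ids = sprintf("rep%d", 1:8), min_reads = 2L)
  expect_equal(cat2$sites$detection_frequency[cat2$sites$position == 100 &
                                              cat2$sites$strand == "+"], 2L)
  # tolerance: P and P+1 merge at 2, stay apart at 0
  jx2 <- data.frame(position = c(500L, 501L, 501L), strand = "+",
                    replicate_id = c("rep1", "rep1", "rep2"), stringsAsFactors = FALSE)
  c0 <- collapse_and_merge(jx2, tolerance = 0L)
  expect_equal(nrow(c0$sites), 2L)
  c2 <- collapse_and_merge(jx2, tolerance = 2L)
  expect_equal(nrow(c2$sites), 1L)
  expect_equal(c2$sites$position, 501L)  # representative = most reads
  expect_equal(c2$sites$total_reads, 3L)
  expect_error(collapse_and_merge(jx2, tolerance = -1L), "tolerance")
  # empty input
  e <- collapse_and_merge(jx2[0, ], replicate_ids = "rep1")
  expect_equal(nrow(e$sites), 0L)
})

test_that("classify_attB: flags, ratio, auto mode", {
  sites <- data.frame(site_id = sprintf("IS%d", 1:3),
                      position = c(1000L, 1004L, 5000L), strand = c("+", "+", "-"),
                      total_reads = c(980L, 3L, 17L),
                      detection_frequency = c(8L, 2L, 5L), stringsAsFactors = FALSE)
  sites$reads_per_replicate <- list(c(a = 980L), c(a = 3L), c(a = 17L))
  g <- random_genome(10000L, seed = 1L)
  cat_ <- new_site_catalog(sites, 8L)
  out <- classify_attB(cat_, g, attB_position = 1000L, attB_strand = "+", window = 10L)
  expect_identical(out$sites$is_attB, c(TRUE, TRUE, FALSE))  # 1004 within +/-10
  expect_equal(out$attB_reads_total, 983L)
  expect_equal(out$secondary_reads_total, 17L)
  expect_equal(out$ratio_secondary_to_attB, 17 / 983)
  # auto mode picks the max-read site
  auto <- classify_attB(cat_, g)
  expect_true(auto$sites$is_attB[1])
  # catalog with only attB: ratio 0
  only <- new_site_catalog(sites[1, ], 8L)
  o <- classify_attB(only, g, attB_position = 1000L, attB_strand = "+")
  expect_equal(o$secondary_reads_total, 0L)
  expect_equal(o$ratio_secondary_to_attB, 0)
  # no attB reads: NA with warning
  none <- new_site_catalog(sites[3, ], 8L)
  expect_warning(nr <- classify_attB(none, g, attB_position = 1000L,
                                     attB_strand = "+"), "ratio undefined")
  expect_true(is.na(nr$ratio_secondary_to_attB))
})

test_that("auto attB agrees with the manifest on simulated data", {
  fix <- tiny_simulation(seed = 33L, n_sites = 6L, reads = 3000L, reps = 2L)
  cat_ <- run_tiny_pipeline(fix)
  auto <- classify_attB(collapse_and_merge(
    infer_junction(map_pairs(filter_library(do.call(rbind, fix$pairs),
                                            filter_config())$accepted, fix$genome),
    fix$genome), replicate_ids = c("rep1", "rep2")), fix$genome)
  top <- auto$sites[auto$sites$is_attB, ]
  expect_equal(top$position, fix$manifest$attB_position)
  expect_identical(top$strand, fix$manifest$attB_strand)
})

test_that("categorize_by_gene: orientation arithmetic and summaries", {
  g <- random_genome(3000L, seed = 2L)
  ann <- gene_annotation(data.frame(
    gene = c("gplus", "gminus"), start = c(100L, 100L), end = c(200L, 200L),
    strand = c("+", "-"), kind = c("CDS", "CDS"), stringsAsFactors = FALSE))
  mk <- function(pos) {
    s <- data.frame(site_id = "s", position = pos, strand = "+",
                    total_reads = 5L, detection_frequency = 1L,
                    stringsAsFactors = FALSE)
    s$reads_per_replicate <- list(c(rep1 = 5L))
    new_site_catalog(s, 1L)
  }
  # inside a CDS
  r <- categorize_by_gene(mk(150L), ann[1, ])
  expect_identical(r$catalog$sites$category, "within_gene")
  expect_identical(r$catalog$sites$nearest_gene, "gplus")
  # site at 95 near a + gene 100..200: upstream
  r <- categorize_by_gene(mk(95L), ann[1, ])
  expect_identical(r$catalog$sites$category, "upstream")
  # same coordinate near a - gene 100..200 (gene start at 200): downstream
  r <- categorize_by_gene(mk(95L), ann[2, ])
  expect_identical(r$catalog$sites$category, "downstream")
  # and mirrored on the other flank
  r <- categorize_by_gene(mk(205L), ann[2, ])
  expect_identical(r$catalog$sites$category, "upstream")
  # beyond near_window: intergenic_far
  r <- categorize_by_gene(mk(900L), ann[1, ], near_window = 500L)
  expect_identical(r$catalog$sites$category, "intergenic_far")
  # empty annotation: warning, intergenic_far
  expect_warning(r <- categorize_by_gene(mk(150L), gene_annotation(
    data.frame(gene = character(0), start = integer(0), end = integer(0),
               strand = character(0), kind = character(0)))), "empty annotation")
  expect_identical(r$catalog$sites$category, "intergenic_far")
})

test_that("within-gene fraction echoes the synthetic annotation construction", {
  fix <- tiny_simulation(seed = 35L, n_sites = 50L, genome_length = 60000L,
                         reads = 6000L, reps = 4L,
                         secondary_read_fraction = 0.2)
  cat_ <- run_tiny_pipeline(fix)
  ann <- synthesize_annotation(fix$genome, fix$manifest, within_fraction = 0.776)
  res <- categorize_by_gene(cat_, ann)
  n <- res$summary$n_secondary
  expect_gt(n, 40)  # high secondary fraction: nearly all 50 sites seen
  expect_lt(abs(res$summary$within_gene_fraction - 0.776), 1 / n + 0.03)
  # strand counts partition the secondary sites
  expect_equal(sum(res$summary$strand_counts), n)
  expect_equal(sum(res$summary$category_counts), n)
})

test_that("exact recovery and read conservation on an error-free library", {
  fix <- tiny_simulation(seed = 36L, n_sites = 10L, reads = 4000L, reps = 4L,
                         secondary_read_fraction = 0.05)
  pairs <- do.call(rbind, fix$pairs)
  filt <- filter_library(pairs, filter_config())
  maps <- map_pairs(filt$accepted, fix$genome)
  cat_ <- call_sites(maps, fix$genome, replicate_ids = sprintf("rep%d", 1:4),
                     attB_position = fix$manifest$attB_position,
                     attB_strand = fix$manifest$attB_strand)
  m <- fix$manifest
  realized <- m$counts[rowSums(m$counts) > 0, , drop = FALSE]
  planted_keys <- paste(c(m$attB_position, m$secondary_sites$position),
                        c(m$attB_strand, m$secondary_sites$strand))[rowSums(m$counts) > 0]
  expect_setequal(paste(cat_$sites$position, cat_$sites$strand), planted_keys)
  # per-replicate counts match the realized manifest allocation
  ord <- match(paste(cat_$sites$position, cat_$sites$strand), planted_keys)
  for (i in seq_len(nrow(cat_$sites))) {
    expect_equal(unname(cat_$sites$reads_per_replicate[[i]]),
                 unname(realized[ord[i], ]))
  }
  # conservation: site reads == unique mappings == accepted pairs (no losses)
  expect_equal(sum(cat_$sites$total_reads), sum(maps$status == "unique"))
  expect_equal(sum(cat_$sites$total_reads), filt$report$accepted)
})

test_that("ratio estimator is unbiased across 20 seeds (scaled down)", {
  ratios <- vapply(1:20, function(s) {
    fix <- tiny_simulation(seed = 100L + s, n_sites = 10L, reads = 2500L,
                           reps = 8L)
    cat_ <- run_tiny_pipeline(fix)
    cat_$ratio_secondary_to_attB
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.0051), 0.1 * 0.0051)
})

test_that("called strands are balanced on strand-symmetric simulations", {
  fix <- tiny_simulation(seed = 37L, n_sites = 60L, genome_length = 80000L,
                         reads = 8000L, reps = 2L, secondary_read_fraction = 0.3)
  cat_ <- run_tiny_pipeline(fix)
  sec <- cat_$sites[!cat_$sites$is_attB, ]
  n <- nrow(sec)
  expect_lt(abs(sum(sec$strand == "+") - n / 2), 3 * sqrt(n * 0.25))
})
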