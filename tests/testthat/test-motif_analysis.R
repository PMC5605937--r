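test_that("extract_windows: width, registration, strand mirroring", {
  fix <- tiny_simulation(seed = 41L, n_sites = 10L, reads = 200L, reps = 1L)
  m <- fix$manifest
  df <- data.frame(site_id = sprintf("s%d", seq_len(nrow(m$secondary_sites))),
                   position = m$secondary_sites$position,
                   strand = m$secondary_sites$strand, stringsAsFactors = FALSE)
  w <- extract_windows(fix$genome, df)
  expect_true(all(nchar(w$sequence) == 29L))
  # windows read on the integration strand reproduce the planted 29-mers for
  # both + and - sites
  expect_identical(w$sequence, m$secondary_sites$window)
  expect_true(any(m$secondary_sites$strand == "-"))
  # asymmetric offsets still give the right width and register
  w2 <- extract_windows(fix$genome, df, offset_left = 10L, offset_right = 18L)
  expect_true(all(nchar(w2$sequence) == 29L))
  # label 0..+14 bases agree between the two registrations (labels -10..+14)
  expect_identical(substr(w2$sequence, 11, 25), substr(w$sequence, 15, 29))
  # off-end windows on a linear genome are skipped with a warning
  gl <- genome(substr(fix$genome$seq, 1, 2000), circular = FALSE)
  near_end <- data.frame(site_id = "e", position = 5L, strand = "+",
                         stringsAsFactors = FALSE)
  expect_warning(we <- extract_windows(gl, near_end), "off the linear")
  expect_equal(nrow(we), 0L)
})

test_that("build_matrix matches the hand-computed toy oracle", {
  # toy width-4 windows; all numbers below derived by hand:
  # counts: pos1 A=2,T=1; pos2 C=3; pos3 G=3; pos4 T=1,A=2
  wins <- c("ACGT", "ACGA", "TCGA")
  m <- build_matrix(wins, pseudocount = 1, background = rep(0.25, 4))
  expect_equal(unname(m$counts[1, ]), c(2, 0, 0, 1))
  # frequencies: (count + 1) / (3 + 4)
  expect_equal(unname(m$frequencies[1, ]), c(3, 1, 1, 2) / 7)
  expect_equal(unname(m$frequencies[2, ]), c(1, 4, 1, 1) / 7)
  expect_equal(unname(rowSums(m$frequencies)), rep(1, 4), tolerance = 1e-9)
  # log odds = log2(freq / 0.25)
  expect_equal(m$log_odds[1, "A"], log2((3 / 7) / 0.25))
  expect_equal(m$log_odds[2, "C"], log2((4 / 7) / 0.25))
  # score of "ACGT" = hand-summed log odds
  hand <- log2((3 / 7) / 0.25) + log2((4 / 7) / 0.25) +
          log2((4 / 7) / 0.25) + log2((2 / 7) / 0.25)
  expect_equal(score_sequence(m, "ACGT"), hand)
  expect_error(build_matrix(wins[1]), "insufficient")
})

test_that("information content spans [0, 2] with the right extremes", {
  # identical windows, no pseudocount: IC exactly 2 everywhere
  m <- build_matrix(rep("ACGT", 4), pseudocount = 0)
  expect_equal(unname(m$information_content), rep(2, 4))
  # uniform base usage at a position: IC 0
  m2 <- build_matrix(c("AAAA", "CAAA", "GAAA", "TAAA"), pseudocount = 0)
  expect_equal(unname(m2$information_content[1]), 0)
  expect_true(all(m2$information_content >= 0 & m2$information_content <= 2 + 1e-12))
})

test_that("score_sequence: consensus maximal, uniform zero, N undefined", {
  set.seed(42)
  wins <- sample_windows(motif_generator(width = 9L, conserved = c("0" = "T"),
                                         conservation = 0.95), 50)
  m <- build_matrix(wins)
  cons_score <- score_sequence(m, m$consensus)
  expect_equal(cons_score, m$max_score)
  for (i in 1:20) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    expect_lte(score_sequence(m, rnd), cons_score)
  }
  # uniform matrix against uniform background scores 0 everywhere
  mu <- build_matrix(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  expect_equal(score_sequence(mu, "ACGT"), 0)
  expect_true(is.na(score_sequence(m, "ACGTNACGT")))
  # background shift leaves score differences unchanged
  m_bg <- build_matrix(wins, background = c(0.3, 0.2, 0.2, 0.3))
  a <- paste(rep("A", 9), collapse = ""); t <- paste(rep("T", 9), collapse = "")
  d1 <- score_sequence(m, a) - score_sequence(m, t)
  d2 <- score_sequence(m_bg, a) - score_sequence(m_bg, t)
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("scan_genome: counts, uniform-zero, planted sites above baseline", {
  g <- random_genome(4000L, seed = 44L)
  mu <- build_matrix(c("AAAA", "CCCC", "GGGG", "TTTT"), pseudocount = 0)
  sc <- scan_genome(mu, g)
  expect_equal(sc$n_windows, 2L * 4000L)  # both strands, circular
  expect_equal(sc$mean, 0)
  expect_equal(sc$sd, 0)
  # linear genome scores n - w + 1 windows per strand
  gl <- genome(g$seq, circular = FALSE)
  expect_equal(scan_genome(mu, gl)$n_windows, 2L * (4000L - 4L + 1L))
  # planted-motif simulation: detected sites outscore the genome baseline
  fix <- tiny_simulation(seed = 45L, n_sites = 20L, genome_length = 30000L,
                         reads = 3000L, reps = 2L, secondary_read_fraction = 0.2)
  cat_ <- run_tiny_pipeline(fix)
  wins <- extract_windows(fix$genome, cat_$sites[!cat_$sites$is_attB, ])
  m <- build_matrix(wins, background = fix$genome$base_frequencies)
  cat_ <- relative_scores(m, cat_, fix$genome)
  scan <- scan_genome(m, fix$genome, exclude = cat_)
  detected_mean <- mean(cat_$sites$motif_score, na.rm = TRUE)
  expect_gt(detected_mean, scan$mean)
  # the top-undetected report never contains a catalog site
  expect_false(any(paste(scan$top_undetected$position, scan$top_undetected$strand)
                   %in% paste(cat_$sites$position, cat_$sites$strand)))
})

test_that("relative_scores: centering identity and order preservation", {
  fix <- tiny_simulation(seed = 46L, n_sites = 12L, reads = 1500L, reps = 2L,
                         secondary_read_fraction = 0.2)
  cat_ <- run_tiny_pipeline(fix)
  wins <- extract_windows(fix$genome, cat_$sites)
  m <- build_matrix(wins)
  cat_ <- relative_scores(m, cat_, fix$genome)
  s <- cat_$sites
  expect_equal(sum(s$relative_score, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_identical(order(s$relative_score), order(s$motif_score))
  # single-site catalog: relative score 0
  one <- new_site_catalog(s[1, c("site_id", "position", "strand", "total_reads",
                                 "detection_frequency", "is_attB")], 2L)
  one <- relative_scores(m, one, fix$genome)
  expect_equal(one$sites$relative_score, 0)
})

test_that("score_by_detection_frequency: partition and grouping", {
  s <- data.frame(site_id = sprintf("s%d", 1:6), position = c(10, 50, 90, 130, 170, 210) * 10L,
                  strand = "+", total_reads = 5L,
                  detection_frequency = c(1L, 1L, 2L, 4L, 5L, 8L),
                  is_attB = FALSE, motif_score = c(1, 2, 3, 4, 5, 6),
                  relative_score = NA_real_, stringsAsFactors = FALSE)
  s$reads_per_replicate <- rep(list(c(rep1 = 5L)), 6)
  cat_ <- new_site_catalog(s, 8L)
  tab <- score_by_detection_frequency(cat_)
  expect_equal(sum(tab$by_frequency$n), 6L)
  expect_equal(sum(tab$by_class$n), 6L)
  expect_equal(tab$by_frequency$mean_score[tab$by_frequency$detection_frequency == 1], 1.5)
  expect_identical(as.character(tab$by_class$class), c("1", "2-4", ">4"))
  expect_equal(tab$by_class$mean_score, c(1.5, 3.5, 5.5))
  # all sites frequency 1: a single row
  s1 <- s; s1$detection_frequency <- 1L
  t1 <- score_by_detection_frequency(new_site_catalog(s1, 8L))
  expect_equal(nrow(t1$by_frequency), 1L)
})

test_that("matrix recovery: 300 sampled windows reproduce the generator", {
  set.seed(47)
  probs <- motif_generator()
  wins <- sample_windows(probs, 300)
  m <- build_matrix(wins, pseudocount = 1)
  dev <- max(abs(m$frequencies - unclass(probs)))
  expect_lte(dev, 0.08)
  # the nine constrained positions carry the highest information content
  ic <- m$information_content
  constrained <- c("-10", "-7", "-6", "-5", "-3", "-2", "-1", "5", "6")
  expect_setequal(names(sort(ic, decreasing = TRUE))[1:9], constrained)
})

test_that("write_meme emits a parseable minimal motif file", {
  m <- build_matrix(c("ACGT", "ACGA", "TCGA"))
  tf <- tempfile(fileext = ".meme")
  write_meme(m, tf)
  lines <- readLines(tf)
  expect_identical(lines[1], "MEME version 4")
  expect_true(any(grepl("^MOTIF ", lines)))
  probrows <- lines[(which(grepl("^letter-probability", lines)) + 1):length(lines)]
  vals <- do.call(rbind, lapply(strsplit(trimws(probrows), "\\s+"), as.numeric))
  expect_equal(rowSums(vals), rep(1, 4), tolerance = 1e-4)
  expect_equal(vals, unname(unclass(m$frequencies)), tolerance = 1e-5)
})
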