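test_that("score_cigar sums matching, indel and clipped components", {
  s <- score_cigar(c("100M", "48=1X2I47=3S", "*", "10M2D5M3H"))
  expect_equal(s$matching, c(100L, 95L, NA, 15L))
  expect_equal(s$indels, c(0L, 1L, NA, 1L))
  expect_equal(s$clipped, c(0L, 3L, NA, 3L))
  # X never counts as matching; N and P contribute nothing
  expect_equal(score_cigar("10=5X10=100N3P")$matching, 20L)
  # indel bases metric counts lengths instead of events
  expect_equal(score_cigar("10M3I2D10M", indel_metric = "bases")$indels, 5L)
  expect_equal(score_cigar("10M3I2D10M")$indels, 2L)
})

test_that("score_cigar rejects malformed strings naming the token", {
  expect_error(score_cigar("10M5Q3S"), "5Q")
  expect_error(score_cigar("MM"), "malformed")
})

test_that("compare_scores is a strict three-level hierarchy", {
  sc <- function(m, i, c) data.frame(matching = m, indels = i, clipped = c)
  r <- compare_scores(sc(100, 0, 0), sc(98, 0, 0))
  expect_equal(r$winner, "A"); expect_equal(r$tiebreak_level, "matches")
  r <- compare_scores(sc(95, 1, 0), sc(95, 2, 0))
  expect_equal(r$winner, "A"); expect_equal(r$tiebreak_level, "indels")
  r <- compare_scores(sc(95, 1, 3), sc(95, 1, 0))
  expect_equal(r$winner, "B"); expect_equal(r$tiebreak_level, "clips")
  r <- compare_scores(sc(95, 1, 3), sc(95, 1, 3))
  expect_equal(r$winner, "tie"); expect_equal(r$tiebreak_level, "full_tie")
})

test_that("compare_scores agrees with a brute-force lexicographic oracle", {
  set.seed(101)
  n <- 2000
  a <- data.frame(matching = sample(90:100, n, TRUE),
                  indels = sample(0:3, n, TRUE),
                  clipped = sample(0:4, n, TRUE))
  b <- data.frame(matching = sample(90:100, n, TRUE),
                  indels = sample(0:3, n, TRUE),
                  clipped = sample(0:4, n, TRUE))
  got <- compare_scores(a, b)$winner
  want <- vapply(seq_len(n), function(i)
    oracle_compare(a[i, ], b[i, ]), character(1))
  expect_identical(got, want)
  # antisymmetry: swapping arguments swaps A and B verdicts
  swapped <- compare_scores(b, a)$winner
  expect_identical(swapped[got == "A"], rep("B", sum(got == "A")))
  expect_identical(swapped[got == "tie"], rep("tie", sum(got == "tie")))
})

test_that("pair_records joins by read name and conserves the read set", {
  recs <- function(qn, flag, cigar)
    data.frame(qname = qn, flag = flag, rname = "chr1", pos = 1L,
               mapq = 60L, cigar = cigar, seq = "ACGT",
               stringsAsFactors = FALSE)
  a <- recs(c("r1", "r2", "r3"), c(0L, 0L, 4L), c("4M", "4M", "*"))
  b <- recs(c("r1", "r2", "r3"), c(0L, 4L, 4L), c("4M", "*", "*"))
  p <- pair_records(a, b)
  expect_equal(nrow(p), 3L)
  expect_equal(p$mapped_b[p$read_id == "r2"], FALSE)
  expect_equal(p$mapped_a[p$read_id == "r3"], FALSE)
  expect_equal(p$mapped_b[p$read_id == "r3"], FALSE)
  # duplicate primary record is an error naming the read
  expect_error(pair_records(rbind(a, a[1, ]), b), "r1")
  # secondary/supplementary records are skipped, not treated as duplicates
  sec <- a[1, ]; sec$flag <- 256L
  p2 <- pair_records(rbind(a, sec), b)
  expect_equal(nrow(p2), 3L)
  expect_equal(attr(p2, "n_secondary_skipped"), 1L)
  # one-sided read set triggers a warning, read kept as absent
  expect_warning(p3 <- pair_records(a[1:2, ], b), "one side only")
  expect_equal(nrow(p3), 3L)
})

test_that("pair_records reads SAM files written by write_sam", {
  cfg <- tiny_cfg(n_reads = 60L)
  g <- generate_parental_genomes(cfg)
  tx <- simulate_transcripts(cfg, g)
  rd <- simulate_hybrid_reads(cfg, g, tx)
  aln <- write_synthetic_alignments(rd, g)
  fa <- tempfile(fileext = ".sam"); fb <- tempfile(fileext = ".sam")
  sl_a <- setNames(Biostrings::width(g$genome_a), names(g$genome_a))
  sl_b <- setNames(Biostrings::width(g$genome_b), names(g$genome_b))
  write_sam(aln$sam_a, sl_a, fa)
  write_sam(aln$sam_b, sl_b, fb)
  p_file <- pair_records(fa, fb)
  p_mem <- pair_records(aln$sam_a, aln$sam_b)
  p_file <- p_file[order(p_file$read_id), ]
  p_mem <- p_mem[order(p_mem$read_id), ]
  expect_equal(p_file$cigar_a, p_mem$cigar_a)
  expect_equal(p_file$cigar_b, p_mem$cigar_b)
})

test_that("assign_reads partitions reads and the counts always sum", {
  pairs <- data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    mapped_a = c(TRUE, TRUE, FALSE, FALSE),
    cigar_a = c("100M", "50M", "*", "*"),
    mapped_b = c(TRUE, FALSE, TRUE, FALSE),
    cigar_b = c("98M2S", "*", "70M", "*"),
    stringsAsFactors = FALSE)
  asn <- assign_reads(pairs)
  cat_of <- setNames(asn$assignments$category, asn$assignments$read_id)
  expect_equal(unname(cat_of["r1"]), "unique_a")  # (100,0,0) beats (98,0,2)
  expect_equal(unname(cat_of["r2"]), "unique_a")  # mapped one side only
  expect_equal(unname(cat_of["r3"]), "unique_b")
  expect_equal(unname(cat_of["r4"]), "unmapped_both")
  expect_equal(sum(asn$summary[1:4]), asn$summary[["total"]])
  lev <- setNames(asn$assignments$tiebreak_level, asn$assignments$read_id)
  expect_equal(unname(lev["r2"]), "mapped_vs_unmapped")
  # identical CIGARs on both sides are discarded as ties
  tie <- data.frame(read_id = "t", mapped_a = TRUE, cigar_a = "50M",
                    mapped_b = TRUE, cigar_b = "50M")
  expect_equal(assign_reads(tie)$summary[["discarded_tie"]], 1L)
  # empty input gives all-zero counts
  expect_equal(assign_reads(pairs[0, ])$summary[["total"]], 0L)
})

test_that("swapping the A and B inputs swaps the unique counts exactly", {
  n <- 5000
  pairs <- data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    mapped_a = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
    cigar_a = random_cigars(n, seed = 7),
    mapped_b = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.9, 0.1)),
    cigar_b = random_cigars(n, seed = 8),
    stringsAsFactors = FALSE)
  fwd <- assign_reads(pairs)$summary
  swapped <- pairs
  names(swapped) <- c("read_id", "mapped_b", "cigar_b", "mapped_a",
                      "cigar_a")
  rev <- assign_reads(swapped)$summary
  expect_equal(fwd[["unique_a"]], rev[["unique_b"]])
  expect_equal(fwd[["unique_b"]], rev[["unique_a"]])
  expect_equal(fwd[["discarded_tie"]], rev[["discarded_tie"]])
  expect_equal(fwd[["unmapped_both"]], rev[["unmapped_both"]])
})

test_that("summarize_assignment reports half-up one-decimal percentages", {
  # degenerate all-tie input: 0/0/0/100 percent
  s <- c(unique_a = 0L, unique_b = 0L, unmapped_both = 0L,
         discarded_tie = 10L, total = 10L)
  out <- summarize_assignment(s)
  expect_equal(out$percent, c(0, 0, 0, 100))
  expect_error(summarize_assignment(
    c(unique_a = 0L, unique_b = 0L, unmapped_both = 0L,
      discarded_tie = 0L, total = 0L)), "total")
})

test_that("partition_sam extracts exactly the uniquely assigned reads", {
  cfg <- tiny_cfg(seed = 9L, n_reads = 80L)
  sim <- simulate_dataset(cfg, tempfile())
  asn <- assign_reads(pair_records(sim$alignments$sam_a,
                                   sim$alignments$sam_b))
  out <- tempfile(fileext = ".sam")
  partition_sam(sim$paths$sam_a, asn, "unique_a", out)
  got <- read.delim(text = grep("^@", readLines(out), value = TRUE,
                                invert = TRUE), header = FALSE)
  want <- asn$assignments$read_id[asn$assignments$category == "unique_a"]
  expect_setequal(got$V1, want)
})
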