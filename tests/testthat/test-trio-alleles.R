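mk_sites <- function(gt_sire, gt_dam, gt_hybrid = "0/1",
                     ad_ref = 5L, ad_alt = 5L, reference_species = "A",
                     impact = NA_character_, chrom = "chr1",
                     pos = seq_along(gt_sire)) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             gt_sire = gt_sire, gt_dam = gt_dam, gt_hybrid = gt_hybrid,
             ad_hybrid_ref = ad_ref, ad_hybrid_alt = ad_alt,
             impact = impact, reference_species = reference_species,
             stringsAsFactors = FALSE)
}

test_that("alternative-monoallelic selection keeps opposite homozygotes", {
  s <- mk_sites(gt_sire = c("0/0", "1/1", "0/1", "1/1", NA),
                gt_dam = c("1/1", "0/0", "1/1", "1/1", "0/0"))
  sel <- select_alt_monoallelic(s)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$alt_parent, c("dam", "sire"))
  expect_equal(attr(sel, "n_missing_parent_gt"), 1L)
  expect_equal(attr(sel, "n_not_alternative"), 2L)
})

test_that("planted alternatively homozygous sites are recovered", {
  cfg <- tiny_cfg(seed = 14L, chrom_length = 60000L,
                  frac_monoallelic_sites = 0.3, mean_depth = 60)
  g <- generate_parental_genomes(cfg)
  trio <- simulate_trio_vcf(cfg, g)
  n_sub <- sum(g$sites$type == "sub")
  n_planted <- sum(trio$truth$class == "alt_mono")
  expect_true(abs(n_planted - 0.3 * n_sub) <
              3 * sqrt(n_sub * 0.3 * 0.7))
  sel <- select_alt_monoallelic(trio$table_a)
  # everything selected was planted; losses are only missing-GT sites
  planted <- trio$truth$site_id[trio$truth$class == "alt_mono"]
  expect_true(all(sel$site_id %in% planted))
  missing <- trio$truth$site_id[!is.na(trio$truth$missing_parent)]
  expect_setequal(setdiff(planted, sel$site_id),
                  intersect(planted,
                            union(missing,
                                  setdiff(trio$truth$site_id,
                                          trio$table_a$site_id))))
})

test_that("hybrid zygosity follows the genotype call", {
  s <- mk_sites(gt_sire = rep("0/0", 3), gt_dam = rep("1/1", 3),
                gt_hybrid = c("0/1", "1/1", NA))
  z <- classify_hybrid_zygosity(s)
  expect_equal(z$zygosity, c("biallelic", "monoallelic"))
  expect_equal(attr(z, "n_missing_hybrid_gt"), 1L)
})

test_that("allelic depth ratio matches its anchor points and bounds", {
  expect_equal(allelic_depth_ratio(10, 0), 1)
  expect_equal(allelic_depth_ratio(0, 7), 1)
  expect_equal(allelic_depth_ratio(5, 5), 0)
  expect_equal(allelic_depth_ratio(7, 3), 0.4)
  expect_error(allelic_depth_ratio(0, 0), "zero total depth")
  expect_error(allelic_depth_ratio(-1, 2), "non-negative")
  set.seed(6)
  r <- stats::rpois(500, 20); a <- stats::rpois(500, 20)
  ok <- r + a > 0
  ratio <- allelic_depth_ratio(r[ok], a[ok])
  expect_true(all(ratio >= 0 & ratio <= 1))
  expect_identical(ratio == 1, (r[ok] == 0) | (a[ok] == 0))
  expect_identical(ratio == 0, r[ok] == a[ok])
})

test_that("signed bins ceil to 0.1 grid with a floor bin of 0.1", {
  expect_equal(signed_bin(0, "dam"), 0.1)
  expect_equal(signed_bin(1, "dam"), 1.0)
  expect_equal(signed_bin(0.25, "dam"), 0.3)
  expect_equal(signed_bin(0.2, "dam"), 0.2)  # exact edge stays low
  expect_equal(signed_bin(1, "sire"), -1.0)
  # figure convention flips which parent is positive
  expect_equal(signed_bin(1, "sire", convention = "figure"), 1.0)
  # a ratio from integer depths lands on its exact edge bin
  expect_equal(signed_bin(allelic_depth_ratio(6, 4), "dam"), 0.2)
})

test_that("swapping the parents mirrors the signed-bin histogram", {
  set.seed(9)
  n <- 400
  s <- mk_sites(gt_sire = sample(c("0/0", "1/1"), n, TRUE),
                gt_dam = NA, ad_ref = stats::rpois(n, 25) + 1L,
                ad_alt = stats::rpois(n, 25))
  s$gt_dam <- ifelse(s$gt_sire == "0/0", "1/1", "0/0")
  run <- function(x) {
    sel <- select_alt_monoallelic(x)
    bin_histogram(signed_bin(
      allelic_depth_ratio(sel$ad_hybrid_ref, sel$ad_hybrid_alt),
      sel$alt_parent))
  }
  h1 <- run(s)
  sw <- s; sw$gt_sire <- s$gt_dam; sw$gt_dam <- s$gt_sire
  h2 <- run(sw)
  expect_equal(h1$count, rev(h2$count))
  expect_equal(sum(h1$count), nrow(s))
})

test_that("origin calls follow the reference-matching rule", {
  s <- mk_sites(gt_sire = c("1/1", "1/1", "1/1"),
                gt_dam = c("0/0", "0/0", "0/0"),
                gt_hybrid = c("0/0", "1/1", "0/1"))
  calls <- origin_from_variant(s)
  expect_equal(calls$origin, c("dam", "sire"))
  expect_equal(attr(calls, "n_heterozygous_excluded"), 1L)
  # against the other reference the rule inverts
  sB <- mk_sites(gt_sire = "0/0", gt_dam = "1/1", gt_hybrid = "0/0",
                 reference_species = "B")
  expect_equal(origin_from_variant(sB)$origin, "sire")
})

test_that("blocks are maximal runs conserving every call", {
  calls <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
    origin = c("dam", "dam", "sire", "sire", "sire"))
  b <- build_blocks(calls)
  expect_equal(nrow(b), 2L)
  expect_equal(b$origin, c("dam", "sire"))
  expect_equal(b$n_variants, c(2L, 3L))
  expect_equal(b$start, c(9L, 29L))
  expect_equal(b$end, c(20L, 50L))
  # single call spans one bp
  one <- build_blocks(data.frame(chrom = "chr1", pos = 7L, origin = "dam"))
  expect_equal(one$end - one$start, 1L)
  # alternating origins never merge
  alt <- build_blocks(data.frame(chrom = "chr1", pos = 1:4 * 10L,
                                 origin = rep(c("dam", "sire"), 2)))
  expect_equal(nrow(alt), 4L)
  expect_error(build_blocks(data.frame(chrom = "chr1", pos = c(5L, 1L),
                                       origin = "dam")), "sorted")
})

test_that("random block structures conserve calls and stay maximal", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    calls <- data.frame(
      chrom = sort(sample(c("chr1", "chr2"), n, TRUE)),
      origin = sample(c("dam", "sire"), n, TRUE))
    calls$pos <- stats::ave(seq_len(n), calls$chrom,
                            FUN = function(i) sort(sample(1e5, length(i))))
    b <- build_blocks(calls)
    expect_equal(sum(b$n_variants), n)
    # every call falls inside exactly one block of its origin
    hits <- mapply(function(ch, p, o) sum(
      b$chrom == ch & b$start < p & b$end >= p & b$origin == o),
      calls$chrom, calls$pos, calls$origin)
    expect_true(all(hits == 1L))
    # maximality: adjacent blocks on a chromosome differ in origin
    for (ch in unique(b$chrom)) {
      o <- b$origin[b$chrom == ch]
      if (length(o) > 1) expect_true(all(o[-1] != o[-length(o)]))
    }
  }
})

test_that("planted origin blocks are reconstructed exactly", {
  # noise-free genotypes: plant block structure, derive calls, rebuild
  plant <- data.frame(
    chrom = rep(c("chr1", "chr2"), c(6, 4)),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L,
            150L, 250L, 350L, 450L),
    origin = c("dam", "dam", "sire", "sire", "dam", "dam",
               "sire", "sire", "sire", "dam"))
  # encode as trio sites against reference A (dam genome): origin dam
  # means hybrid expresses the reference allele (0/0)
  s <- mk_sites(gt_sire = rep("1/1", 10), gt_dam = rep("0/0", 10),
                gt_hybrid = ifelse(plant$origin == "dam", "0/0", "1/1"),
                chrom = plant$chrom, pos = plant$pos)
  b <- build_blocks(origin_from_variant(s))
  expect_equal(b$origin, c("dam", "sire", "dam", "sire", "dam"))
  expect_equal(b$n_variants, c(2L, 2L, 2L, 3L, 1L))
})

test_that("impact fractions are tabulated per zygosity partition", {
  s <- mk_sites(gt_sire = rep("1/1", 8), gt_dam = rep("0/0", 8),
                gt_hybrid = c(rep("0/1", 4), rep("1/1", 4)),
                impact = c("HIGH", "MODERATE", "LOW", "MODIFIER",
                           "MODERATE", "MODERATE", "LOW", NA))
  z <- classify_hybrid_zygosity(s)
  f <- impact_fractions(z)
  bi <- f[f$zygosity == "biallelic", ]
  expect_equal(bi$percent[match(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                                bi$impact)], c(25, 25, 25, 25))
  mono <- f[f$zygosity == "monoallelic", ]
  expect_equal(mono$n[match(c("MODERATE", "LOW"), mono$impact)],
               c(2L, 1L))
  expect_equal(sum(mono$percent), 100)
  expect_equal(attr(f, "n_missing_impact"), 1L)
})

test_that("trio VCFs round-trip through the reader", {
  cfg <- tiny_cfg(seed = 25L, chrom_length = 20000L)
  sim <- simulate_dataset(cfg, tempfile())
  for (k in c("a", "b")) {
    tab <- sim$trio[[paste0("table_", k)]]
    v <- read_trio_vcf(sim$paths[[paste0("vcf_", k)]],
                       reference_species = toupper(k))
    expect_equal(nrow(v), nrow(tab))
    expect_equal(v$pos, tab$pos)
    expect_equal(v$ad_hybrid_ref, tab$ad_hybrid_ref)
    expect_equal(v$ad_hybrid_alt, tab$ad_hybrid_alt)
    expect_equal(v$impact, tab$impact)
    expect_identical(is.na(v$gt_sire), tab$gt_sire == "./.")
    same <- tab$gt_sire != "./."
    expect_equal(v$gt_sire[same], tab$gt_sire[same])
    expect_equal(v$gt_hybrid, tab$gt_hybrid)
  }
})

test_that("threshold genotyping calls extremes homozygous", {
  # planted fraction 1 with deep coverage: zero reads on one allele and a
  # homozygous call; planted 0.5: heterozygous call
  cfg <- tiny_cfg(seed = 18L, chrom_length = 10000L, mean_depth = 1000,
                  frac_monoallelic_sites = 1, frac_hybrid_biallelic = 0)
  g <- generate_parental_genomes(cfg)
  trio <- simulate_trio_vcf(cfg, g)
  t_a <- trio$table_a
  truth <- trio$truth[match(t_a$site_id, trio$truth$site_id), ]
  mono <- truth$hybrid_state %in% c("mono_sire", "mono_dam")
  expect_true(all(t_a$gt_hybrid[mono] %in% c("0/0", "1/1")))
  expect_true(all(pmin(t_a$ad_hybrid_ref, t_a$ad_hybrid_alt)[mono] == 0L))
  cfg2 <- tiny_cfg(seed = 18L, chrom_length = 10000L, mean_depth = 1000,
                   frac_monoallelic_sites = 1, frac_hybrid_biallelic = 1)
  trio2 <- simulate_trio_vcf(cfg2, generate_parental_genomes(cfg2))
  expect_true(all(trio2$table_a$gt_hybrid == "0/1"))
  # no site ever survives with zero total depth
  expect_true(all(trio2$table_a$ad_hybrid_ref +
                  trio2$table_a$ad_hybrid_alt > 0))
})
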