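# Trio variant-call simulation. Each diagnostic substitution site between
# the two parental genomes yields one candidate VCF record per reference.
# Parental genotypes are planted at the allele level (A-genome allele vs
# B-genome allele) so the two per-reference VCFs are automatically
# consistent; hybrid allelic depths are drawn binomially around a planted
# allele fraction, and the hybrid genotype is then re-derived from the
# depths with a simple minor-fraction threshold, mimicking a depth-driven
# variant caller.

#' @noRd
IMPACT_CLASSES <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# planted impact-class mixtures: moderate/low enriched when the hybrid is
# biallelic, mirroring the expression-compensation signal the pipeline is
# meant to detect
#' @noRd
impact_probs <- function(state) {
  switch(state,
         biallelic = c(0.06, 0.22, 0.22, 0.50),
         mono_dam = ,
         mono_sire = c(0.06, 0.12, 0.12, 0.70),
         c(0.08, 0.16, 0.16, 0.60))
}

#' Simulate trio variant calls against both references
#'
#' For a configurable fraction of diagnostic substitution sites the two
#' parents are planted alternatively homozygous (one 0/0, the other 1/1);
#' remaining sites receive non-informative genotype patterns. The hybrid's
#' allelic depth at each site is binomial around a planted allele fraction
#' (0.5 for biallelic sites, 0 or 1 for monoallelic ones) with total depth
#' Poisson(`mean_depth`); its genotype is derived from the depths (minor
#' allele fraction < 0.1 is called homozygous). Sites drawing zero hybrid
#' depth are omitted from that VCF. Each record carries a planted snpEff-style
#' `IMPACT` annotation.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [generate_parental_genomes()].
#' @return list of class `trio_sim`: `table_a`, `table_b` (per-reference
#'   site tables in the layout returned by [read_trio_vcf()]) and `truth`
#'   (planted class, parental allele pairs, hybrid allele fraction and
#'   expression state per site).
#' @export
simulate_trio_vcf <- function(cfg, genomes) {
  stopifnot(inherits(cfg, "sim_config"))
  force(genomes)  # evaluate before seeding: arguments may consume the RNG
  set.seed(seed_for(cfg, "vcf"))
  sites <- genomes$sites[genomes$sites$type == "sub", , drop = FALSE]
  ns <- nrow(sites)
  if (ns == 0L) stop("no diagnostic substitution sites to simulate from")

  is_mono <- stats::runif(ns) < cfg$frac_monoallelic_sites
  # parental allele pairs over {A-genome allele, B-genome allele}
  dam_g <- ifelse(is_mono, "AA", NA)
  sire_g <- ifelse(is_mono, "BB", NA)
  other_scen <- sample(c("sire_het", "both_ref", "dam_het"), ns,
                       replace = TRUE)
  dam_g[!is_mono] <- c(sire_het = "AA", both_ref = "AA",
                       dam_het = "AB")[other_scen[!is_mono]]
  sire_g[!is_mono] <- c(sire_het = "AB", both_ref = "AA",
                        dam_het = "BB")[other_scen[!is_mono]]
  missing_parent <- ifelse(stats::runif(ns) < 0.02,
                           sample(c("sire", "dam"), ns, replace = TRUE),
                           NA)

  # hybrid planted state and fraction of the B (sire-genome) allele
  state <- character(ns)
  bial <- stats::runif(ns) < cfg$frac_hybrid_biallelic
  from_sire <- stats::runif(ns) < 0.5
  state[is_mono] <- ifelse(bial[is_mono], "biallelic",
                           ifelse(from_sire[is_mono], "mono_sire",
                                  "mono_dam"))
  state[!is_mono] <- "other"
  dose_b <- function(g) (g == "AB") + 2 * (g == "BB")
  frac_b <- ifelse(is_mono,
                   ifelse(state == "biallelic", 0.5,
                          ifelse(state == "mono_sire", 1, 0)),
                   (dose_b(sire_g) + dose_b(dam_g)) / 4)

  impact <- vapply(state, function(s)
    sample(IMPACT_CLASSES, 1L, prob = impact_probs(s)), character(1))

  make_table <- function(ref_species) {
    # in the A-reference VCF the A-genome allele is REF; swapped for B
    enc <- function(g, a_is_ref) {
      out <- c(AA = if (a_is_ref) "0/0" else "1/1",
               AB = "0/1",
               BB = if (a_is_ref) "1/1" else "0/0")[g]
      unname(out)
    }
    a_is_ref <- ref_species == "A"
    pos <- if (a_is_ref) sites$pos_a else sites$pos_b
    ref <- if (a_is_ref) sites$ref_a else sites$ref_b
    alt <- if (a_is_ref) sites$ref_b else sites$ref_a
    alt_frac <- if (a_is_ref) frac_b else 1 - frac_b
    depth_h <- stats::rpois(ns, cfg$mean_depth)
    ad_alt <- stats::rbinom(ns, depth_h, alt_frac)
    ad_ref <- depth_h - ad_alt
    minor <- pmin(ad_ref, ad_alt) / pmax(depth_h, 1L)
    gt_h <- ifelse(minor < 0.1,
                   ifelse(ad_alt >= ad_ref, "1/1", "0/0"),
                   "0/1")
    gt_s <- enc(sire_g, a_is_ref)
    gt_d <- enc(dam_g, a_is_ref)
    ad_parent <- function(gt) {
      d <- stats::rpois(ns, cfg$mean_depth)
      a <- ifelse(gt == "1/1", d,
                  ifelse(gt == "0/1", stats::rbinom(ns, d, 0.5), 0L))
      cbind(ref = d - a, alt = a)
    }
    ad_s <- ad_parent(gt_s)
    ad_d <- ad_parent(gt_d)
    gt_s[!is.na(missing_parent) & missing_parent == "sire"] <- "./."
    gt_d[!is.na(missing_parent) & missing_parent == "dam"] <- "./."
    tab <- data.frame(
      chrom = sites$chrom, pos = pos, ref = ref, alt = alt,
      gt_sire = gt_s, gt_dam = gt_d, gt_hybrid = gt_h,
      ad_sire_ref = ad_s[, "ref"], ad_sire_alt = ad_s[, "alt"],
      ad_dam_ref = ad_d[, "ref"], ad_dam_alt = ad_d[, "alt"],
      ad_hybrid_ref = ad_ref, ad_hybrid_alt = ad_alt,
      impact = impact, reference_species = ref_species,
      site_id = paste0(sites$chrom, ":", sites$pos_a),
      stringsAsFactors = FALSE)
    tab <- tab[depth_h > 0L, , drop = FALSE]
    tab[order(tab$chrom, tab$pos), , drop = FALSE]
  }

  truth <- data.frame(
    site_id = paste0(sites$chrom, ":", sites$pos_a),
    chrom = sites$chrom, pos_a = sites$pos_a, pos_b = sites$pos_b,
    class = ifelse(is_mono, "alt_mono", "other"),
    dam_alleles = dam_g, sire_alleles = sire_g,
    missing_parent = missing_parent,
    hybrid_state = state, frac_b = frac_b, impact = impact,
    stringsAsFactors = FALSE)
  structure(list(table_a = make_table("A"), table_b = make_table("B"),
                 truth = truth),
            class = "trio_sim")
}

#' Write a trio site table as a three-sample VCF v4.2
#'
#' Emits `GT:AD` FORMAT fields for sire, dam and hybrid and the planted
#' `IMPACT` INFO annotation.
#'
#' @param table a site table from [simulate_trio_vcf()] (`table_a` or
#'   `table_b`).
#' @param seqlengths named vector of contig lengths for the header.
#' @param path output file.
#' @param samples sample column names, in order (sire, dam, hybrid).
#' @return invisibly, `path`.
#' @export
write_trio_vcf <- function(table, seqlengths, path,
                           samples = c("sire", "dam", "geep")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(seqlengths),
            as.integer(seqlengths)),
    paste0("##INFO=<ID=IMPACT,Number=1,Type=String,",
           "Description=\"Predicted variant impact class\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt <- function(gt, r, a) sprintf("%s:%d,%d", gt, r, a)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tIMPACT=%s\tGT:AD\t%s\t%s\t%s",
                  table$chrom, table$pos, table$site_id, table$ref,
                  table$alt, table$impact,
                  fmt(table$gt_sire, table$ad_sire_ref, table$ad_sire_alt),
                  fmt(table$gt_dam, table$ad_dam_ref, table$ad_dam_alt),
                  fmt(table$gt_hybrid, table$ad_hybrid_ref,
                      table$ad_hybrid_alt))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run the full simulator and write every input file
#'
#' Convenience wrapper: generates genomes, transcripts, reads, dual SAM
#' alignments and the two trio VCFs from one configuration and writes them
#' (plus truth tables) under `dir`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param dialect CIGAR dialect for the synthetic alignments.
#' @return a list with the in-memory simulation objects (`genomes`,
#'   `transcripts`, `reads`, `alignments`, `trio`) and `paths` to every
#'   file written.
#' @export
simulate_dataset <- function(cfg, dir, dialect = c("extended", "legacy")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- generate_parental_genomes(cfg)
  transcripts <- simulate_transcripts(cfg, genomes)
  reads <- simulate_hybrid_reads(cfg, genomes, transcripts)
  paths <- write_simulated_inputs(genomes, transcripts, reads, dir)
  aln <- write_synthetic_alignments(reads, genomes, dialect = dialect)
  paths$sam_a <- file.path(dir, "aln_A.sam")
  paths$sam_b <- file.path(dir, "aln_B.sam")
  write_sam(aln$sam_a, Biostrings::width(genomes$genome_a) |>
              stats::setNames(names(genomes$genome_a)), paths$sam_a)
  write_sam(aln$sam_b, Biostrings::width(genomes$genome_b) |>
              stats::setNames(names(genomes$genome_b)), paths$sam_b)
  trio <- simulate_trio_vcf(cfg, genomes)
  paths$vcf_a <- file.path(dir, "trio_A.vcf")
  paths$vcf_b <- file.path(dir, "trio_B.vcf")
  write_trio_vcf(trio$table_a,
                 stats::setNames(Biostrings::width(genomes$genome_a),
                                 names(genomes$genome_a)), paths$vcf_a)
  write_trio_vcf(trio$table_b,
                 stats::setNames(Biostrings::width(genomes$genome_b),
                                 names(genomes$genome_b)), paths$vcf_b)
  paths$truth_sites <- file.path(dir, "truth_sites.tsv")
  utils::write.table(trio$truth, paths$truth_sites, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(genomes = genomes, transcripts = transcripts, reads = reads,
       alignments = aln, trio = trio, paths = paths)
}
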