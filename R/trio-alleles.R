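# Trio-variant analyses: selection of sites where the parents are
# alternatively homozygous, hybrid zygosity classification, signed
# allelic-depth-ratio binning, parental-origin calls with block
# summarization along the genome, and impact-class tabulation.

#' Read a three-sample trio VCF into a site table
#'
#' Loads a VCF with `GT` and `AD` FORMAT fields for the sire, dam and
#' hybrid samples. Only biallelic SNV records are retained (multiallelic
#' records are dropped and counted); genotypes are normalized to unphased
#' `0/0`, `0/1`, `1/1` (phase separators removed, `1/0` folded to `0/1`).
#' An `IMPACT` INFO annotation is carried along when present, or can be
#' supplied as a sidecar data.frame.
#'
#' @param path VCF file (three samples).
#' @param samples named character vector mapping roles to VCF sample
#'   names: `c(sire = ..., dam = ..., hybrid = ...)`.
#' @param reference_species `"A"` or `"B"`: which parental genome this VCF
#'   was called against.
#' @param impact optional data.frame `site_id`, `impact` overriding the
#'   VCF annotation (`site_id` as `chrom:pos`).
#' @return data.frame of class `trio_sites`: `chrom`, `pos`, `ref`, `alt`,
#'   `gt_sire`, `gt_dam`, `gt_hybrid`, `ad_hybrid_ref`, `ad_hybrid_alt`,
#'   `impact`, `reference_species`; attribute `n_multiallelic_dropped`.
#' @export
read_trio_vcf <- function(path,
                          samples = c(sire = "sire", dam = "dam",
                                      hybrid = "geep"),
                          reference_species = c("A", "B"),
                          impact = NULL) {
  reference_species <- match.arg(reference_species)
  stopifnot(all(c("sire", "dam", "hybrid") %in% names(samples)))
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  alt_list <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt_list) != 1L
  n_multi <- sum(multi)
  vcf <- vcf[!multi]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  norm_gt <- function(g) {
    g <- gsub("\\|", "/", g)
    g[g == "1/0"] <- "0/1"
    g[g %in% c(".", "./.", ".|.")] <- NA_character_
    g
  }
  ad_h <- ad[, samples[["hybrid"]]]
  ad_ref <- vapply(ad_h, function(x) as.integer(x[1L]), integer(1))
  ad_alt <- vapply(ad_h, function(x) as.integer(x[2L]), integer(1))
  info <- VariantAnnotation::info(vcf)
  imp <- if ("IMPACT" %in% names(info)) as.character(info$IMPACT)
         else rep(NA_character_, length(vcf))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_list)),
    gt_sire = norm_gt(gt[, samples[["sire"]]]),
    gt_dam = norm_gt(gt[, samples[["dam"]]]),
    gt_hybrid = norm_gt(gt[, samples[["hybrid"]]]),
    ad_hybrid_ref = ad_ref, ad_hybrid_alt = ad_alt,
    impact = imp, reference_species = reference_species,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(impact)) {
    key <- paste0(out$chrom, ":", out$pos)
    out$impact <- impact$impact[match(key, impact$site_id)]
  }
  attr(out, "n_multiallelic_dropped") <- n_multi
  class(out) <- c("trio_sites", "data.frame")
  out
}

#' Retain sites where the parents are alternatively homozygous
#'
#' Keeps sites at which one parent is `0/0` and the other `1/1` (either
#' orientation) -- the configuration under which every hybrid read is
#' diagnostic for its parent of origin. Sites with a missing parental
#' genotype are dropped and counted.
#'
#' @param sites a `trio_sites` data.frame.
#' @return the filtered `trio_sites` with an added `alt_parent` column
#'   (`"sire"` or `"dam"`: the parent homozygous for the alternate
#'   allele); attributes `n_missing_parent_gt`, `n_not_alternative`.
#' @export
select_alt_monoallelic <- function(sites) {
  missing <- is.na(sites$gt_sire) | is.na(sites$gt_dam)
  alt_sd <- sites$gt_sire == "1/1" & sites$gt_dam == "0/0"
  alt_ds <- sites$gt_sire == "0/0" & sites$gt_dam == "1/1"
  keep <- !missing & (alt_sd | alt_ds)
  out <- sites[keep, , drop = FALSE]
  out$alt_parent <- ifelse(alt_sd[keep], "sire", "dam")
  attr(out, "n_missing_parent_gt") <- sum(missing)
  attr(out, "n_not_alternative") <- sum(!missing & !keep)
  class(out) <- c("trio_sites", "data.frame")
  out
}

#' Classify hybrid zygosity at each site
#'
#' A site is `biallelic` when the hybrid genotype is heterozygous and
#' `monoallelic` when it is homozygous for either allele. Sites with a
#' missing hybrid genotype are excluded and counted.
#'
#' @param sites a `trio_sites` data.frame.
#' @return the sites with an added `zygosity` column; attribute
#'   `n_missing_hybrid_gt`.
#' @export
classify_hybrid_zygosity <- function(sites) {
  missing <- is.na(sites$gt_hybrid)
  out <- sites[!missing, , drop = FALSE]
  out$zygosity <- ifelse(out$gt_hybrid == "0/1", "biallelic", "monoallelic")
  attr(out, "n_missing_hybrid_gt") <- sum(missing)
  class(out) <- class(sites)
  out
}

#' Allelic depth ratio
#'
#' Normalized imbalance between the two allele depths,
#' `|ref - alt| / (ref + alt)`: 1 when all reads support a single allele
#' (monoallelic expression), 0 when both alleles are supported equally
#' (unbiased biallelic expression).
#'
#' @param ref_depth,alt_depth non-negative integer vectors of per-allele
#'   read depths; each pair must have positive total depth.
#' @return numeric vector of ratios in `[0, 1]`.
#' @export
#' @examples
#' allelic_depth_ratio(10, 0)  # 1
#' allelic_depth_ratio(5, 5)   # 0
#' allelic_depth_ratio(7, 3)   # 0.4
allelic_depth_ratio <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0))
    stop("allelic_depth_ratio: depths must be non-negative", call. = FALSE)
  tot <- ref_depth + alt_depth
  if (any(tot == 0))
    stop("allelic_depth_ratio: zero total depth; filter such sites first",
         call. = FALSE)
  abs(ref_depth - alt_depth) / tot
}

#' Signed allelic-depth-ratio bin
#'
#' Bins a ratio into magnitudes 0.1, 0.2, ..., 1.0 (bin edges at multiples
#' of 0.1; a ratio falls into the bin whose upper edge it does not exceed,
#' and ratio 0 lands in the lowest bin 0.1, which therefore contains only
#' heterozygous-balanced sites). The algebraic sign encodes which parent
#' is homozygous for the alternate allele. Under the default `"results"`
#' convention sites where the dam (the maternal, A-genome parent) carries
#' `1/1` are positive; the `"figure"` convention flips the sign so that
#' sire-alternate sites are positive.
#'
#' @param ratio numeric vector in `[0, 1]` from [allelic_depth_ratio()].
#' @param alt_parent `"sire"`/`"dam"` per site (from
#'   [select_alt_monoallelic()]).
#' @param convention `"results"` (dam-alternate positive, default) or
#'   `"figure"` (sire-alternate positive).
#' @return numeric vector of signed bins in `{-1, ..., -0.1, 0.1, ..., 1}`.
#' @export
#' @examples
#' signed_bin(0.25, "dam")   #  0.3
#' signed_bin(1.0, "sire")   # -1.0
signed_bin <- function(ratio, alt_parent,
                       convention = c("results", "figure")) {
  convention <- match.arg(convention)
  if (any(ratio < 0 | ratio > 1))
    stop("signed_bin: ratio must lie in [0, 1]", call. = FALSE)
  mag <- pmax(0.1, ceiling(round(ratio * 10, 9)) / 10)
  pos_parent <- if (convention == "results") "dam" else "sire"
  sgn <- ifelse(alt_parent == pos_parent, 1, -1)
  sgn * mag
}

#' Histogram of signed allelic-depth bins
#'
#' @param bins numeric vector from [signed_bin()].
#' @return data.frame `bin`, `count` over all 20 signed bins (-1.0 to
#'   -0.1 and 0.1 to 1.0), zero-filled.
#' @export
bin_histogram <- function(bins) {
  levels <- round(c(-(10:1), 1:10) / 10, 1)
  tab <- table(factor(round(bins, 1), levels = levels))
  data.frame(bin = levels, count = as.integer(tab), row.names = NULL)
}

#' Parental origin of a homozygous hybrid variant
#'
#' Applicable at sites where the parents are alternatively homozygous and
#' the hybrid is homozygous too: a homozygous-reference hybrid call means
#' the expressed transcript carries the allele of the parent whose genome
#' matches the reference the VCF was called against, and a
#' homozygous-alternate call points to the opposite parent. Heterozygous
#' hybrid sites are excluded (and counted).
#'
#' @param sites a `trio_sites` data.frame (after
#'   [select_alt_monoallelic()]).
#' @param parent_of_reference named map from reference species to the
#'   parent whose genome it is; the default matches a buck x ewe cross
#'   with genome A the maternal (sheep) reference.
#' @return data.frame `chrom`, `pos`, `origin` (`"sire"`/`"dam"`), one row
#'   per applicable site, ordered by chromosome and position; attribute
#'   `n_heterozygous_excluded`.
#' @export
origin_from_variant <- function(sites,
                                parent_of_reference = c(A = "dam",
                                                        B = "sire")) {
  applicable <- !is.na(sites$gt_hybrid) & sites$gt_hybrid != "0/1"
  s <- sites[applicable, , drop = FALSE]
  ref_parent <- unname(parent_of_reference[s$reference_species])
  other <- ifelse(ref_parent == "dam", "sire", "dam")
  origin <- ifelse(s$gt_hybrid == "0/0", ref_parent, other)
  out <- data.frame(chrom = s$chrom, pos = s$pos, origin = origin,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_heterozygous_excluded") <- sum(!applicable)
  out
}

#' Merge consecutive same-origin calls into blocks
#'
#' Maximal runs of consecutive variant calls with the same parental origin
#' on one chromosome are merged into blocks; a block spans from its first
#' to its last call (reported 0-based half-open, so an isolated call spans
#' 1 bp). Blocks with fewer than `min_variants` calls are dropped after
#' merging (adjacent survivors are deliberately not re-merged).
#'
#' @param calls data.frame `chrom`, `pos` (1-based), `origin`, sorted by
#'   chromosome then position.
#' @param min_variants minimum calls per reported block.
#' @return data.frame of class `origin_blocks`: `chrom`, `start`, `end`
#'   (0-based half-open), `origin`, `n_variants`.
#' @export
build_blocks <- function(calls, min_variants = 1L) {
  if (nrow(calls) == 0L)
    return(structure(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), origin = character(0),
                                n_variants = integer(0)),
                     class = c("origin_blocks", "data.frame")))
  runs <- rle(calls$chrom)
  per_chrom_sorted <- !vapply(split(calls$pos, factor(calls$chrom)),
                              is.unsorted, logical(1))
  if (any(duplicated(runs$values)) || !all(per_chrom_sorted))
    stop("build_blocks: calls must be sorted by chromosome and position",
         call. = FALSE)
  new_block <- c(TRUE, calls$origin[-1L] != calls$origin[-nrow(calls)] |
                        calls$chrom[-1L] != calls$chrom[-nrow(calls)])
  grp <- cumsum(new_block)
  grp <- factor(grp, levels = unique(grp))
  out <- data.frame(
    chrom = tapply(calls$chrom, grp, `[`, 1L),
    start = as.integer(tapply(calls$pos, grp, min)) - 1L,
    end = as.integer(tapply(calls$pos, grp, max)),
    origin = tapply(calls$origin, grp, `[`, 1L),
    n_variants = as.integer(tapply(calls$pos, grp, length)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n_variants >= min_variants, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("origin_blocks", "data.frame"))
}

#' Per-chromosome bp totals of origin blocks
#'
#' @param blocks an `origin_blocks` data.frame.
#' @return data.frame `chrom`, `origin`, `bp` (summed block spans).
#' @export
block_bp_totals <- function(blocks) {
  if (nrow(blocks) == 0L)
    return(data.frame(chrom = character(0), origin = character(0),
                      bp = integer(0)))
  agg <- stats::aggregate(bp ~ chrom + origin,
                          data = data.frame(chrom = blocks$chrom,
                                            origin = blocks$origin,
                                            bp = blocks$end - blocks$start),
                          FUN = sum)
  agg[order(agg$chrom, agg$origin), , drop = FALSE]
}

#' Write origin blocks as a BED file
#'
#' BED columns: chrom, start, end (0-based half-open), name = origin,
#' score = number of supporting variants.
#'
#' @param blocks an `origin_blocks` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_blocks_bed <- function(blocks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", blocks$chrom, blocks$start,
                     blocks$end, blocks$origin, blocks$n_variants), path)
  invisible(path)
}

#' Impact-class percentages by hybrid zygosity
#'
#' Tabulates the predicted variant impact classes (HIGH, MODERATE, LOW,
#' MODIFIER) separately for monoallelically and biallelically expressed
#' hybrid sites. Sites lacking an impact annotation are counted
#' separately, not tabulated.
#'
#' @param sites a `trio_sites` data.frame with `zygosity` (from
#'   [classify_hybrid_zygosity()]) and `impact` columns.
#' @return data.frame `zygosity`, `impact`, `n`, `percent` (per-partition
#'   percentages, one decimal, half-up); attribute `n_missing_impact`.
#' @export
impact_fractions <- function(sites) {
  stopifnot(all(c("zygosity", "impact") %in% names(sites)))
  missing <- is.na(sites$impact)
  s <- sites[!missing, , drop = FALSE]
  out <- expand.grid(zygosity = c("monoallelic", "biallelic"),
                     impact = IMPACT_CLASSES, stringsAsFactors = FALSE)
  out <- out[order(out$zygosity, out$impact), , drop = FALSE]
  tab <- table(factor(s$zygosity, c("monoallelic", "biallelic")),
               factor(s$impact, IMPACT_CLASSES))
  out$n <- mapply(function(z, i) tab[z, i], out$zygosity, out$impact)
  tot <- stats::setNames(rowSums(tab), rownames(tab))
  out$percent <- ifelse(tot[out$zygosity] > 0,
                        round_half_up(100 * out$n / tot[out$zygosity], 1),
                        NA_real_)
  rownames(out) <- NULL
  attr(out, "n_missing_impact") <- sum(missing)
  out
}
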