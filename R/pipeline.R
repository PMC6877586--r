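# End-to-end orchestration: simulate inputs, arbitrate the dual
# alignments, quantify and compare expression, run the trio-allele
# analyses and the imprinting cross-reference, and bundle every summary
# into one reproducible JSON + Markdown report.

#' Pipeline run configuration
#'
#' Combines the simulator configuration with the analysis thresholds of
#' every stage. Configurations serialize losslessly to YAML with
#' [save_run_config()] / [load_run_config()].
#'
#' @param sim a [sim_config()].
#' @param stages subset of
#'   `c("simulate", "assign", "quantify", "compare", "alleles",
#'   "imprint")` to execute, in pipeline order.
#' @param fpkm_threshold expression filter threshold.
#' @param strict_greater drop genes exactly at the FPKM threshold.
#' @param min_variants minimum calls per reported origin block.
#' @param sign_convention `"results"` or `"figure"` (see [signed_bin()]).
#' @param indel_metric `"events"` or `"bases"` (see [score_cigar()]).
#' @param dialect CIGAR dialect for the simulated alignments.
#' @param top_n size of the top-expressed overlap comparison.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "assign", "quantify",
                                  "compare", "alleles", "imprint"),
                       fpkm_threshold = 1,
                       strict_greater = FALSE,
                       min_variants = 1L,
                       sign_convention = "results",
                       indel_metric = "events",
                       dialect = "extended",
                       top_n = 20L) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(inherits(sim, "sim_config"),
            sign_convention %in% c("results", "figure"),
            indel_metric %in% c("events", "bases"),
            dialect %in% c("extended", "legacy"))
  structure(list(sim = sim, stages = stages,
                 fpkm_threshold = fpkm_threshold,
                 strict_greater = strict_greater,
                 min_variants = as.integer(min_variants),
                 sign_convention = sign_convention,
                 indel_metric = indel_metric, dialect = dialect,
                 top_n = as.integer(top_n)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file.
#' @export
save_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- unclass(cfg$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(run_config, c(list(sim = sim), x))
}

#' @noRd
stage_log <- function(verbose, stage, ...) {
  if (verbose) message("[", stage, "] ", ...)
}

#' Run the full synthetic-data pipeline
#'
#' Executes the configured stages in order -- simulate inputs, assign
#' reads to parental genomes, quantify expression per partition, compare
#' transcriptome sets, run the trio-allele analyses on both per-reference
#' VCFs, and cross-reference parental origins against the imprinting
#' database -- and writes `report.json` and `report.md` under `outdir`.
#' Identical configurations (same seed) produce identical reports.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory.
#' @param verbose log per-stage record counts.
#' @return the report, a nested list mirroring `report.json`.
#' @export
run_pipeline <- function(cfg, outdir, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = list(seed = cfg$sim$seed,
                               stages = cfg$stages,
                               dialect = cfg$dialect,
                               sign_convention = cfg$sign_convention))
  sim <- NULL
  if ("simulate" %in% cfg$stages) {
    sim <- simulate_dataset(cfg$sim, file.path(outdir, "inputs"),
                            dialect = cfg$dialect)
    stage_log(verbose, "simulate", length(sim$reads$reads), " reads, ",
              nrow(sim$genomes$sites), " diagnostic sites, ",
              nrow(sim$trio$table_a), "/", nrow(sim$trio$table_b),
              " VCF records")
    report$simulate <- list(
      n_reads = length(sim$reads$reads),
      n_diagnostic_sites = nrow(sim$genomes$sites),
      n_transcripts = nrow(sim$transcripts))
  } else {
    stop("run_pipeline currently requires the 'simulate' stage as input ",
         "source", call. = FALSE)
  }

  assignment <- NULL
  if ("assign" %in% cfg$stages) {
    pairs <- pair_records(sim$alignments$sam_a, sim$alignments$sam_b)
    assignment <- assign_reads(pairs, indel_metric = cfg$indel_metric)
    summ <- summarize_assignment(assignment)
    stage_log(verbose, "assign", paste(summ$category, summ$count,
                                       collapse = ", "))
    report$assign <- list(counts = as.list(assignment$summary),
                          percent = stats::setNames(as.list(summ$percent),
                                                    summ$category))
  }

  if ("quantify" %in% cfg$stages && !is.null(assignment)) {
    part_a <- file.path(outdir, "unique_A.sam")
    part_b <- file.path(outdir, "unique_B.sam")
    partition_sam(sim$paths$sam_a, assignment, "unique_a", part_a)
    partition_sam(sim$paths$sam_b, assignment, "unique_b", part_b)
    expr <- lapply(c(a = part_a, b = part_b), function(p) {
      cnt <- count_reads_per_transcript(p, sim$paths$gff)
      compute_fpkm(cnt, total_mapped = max(sum(cnt$count), 1))
    })
    report$quantify <- list(
      n_expressed_a = length(filter_expressed(expr$a, cfg$fpkm_threshold,
                                              cfg$strict_greater)),
      n_expressed_b = length(filter_expressed(expr$b, cfg$fpkm_threshold,
                                              cfg$strict_greater)))
    stage_log(verbose, "quantify", report$quantify$n_expressed_a,
              " A-expressed, ", report$quantify$n_expressed_b,
              " B-expressed genes")

    if ("compare" %in% cfg$stages) {
      set_a <- drop_uncharacterized(
        filter_expressed(expr$a, cfg$fpkm_threshold, cfg$strict_greater))
      set_b <- drop_uncharacterized(
        filter_expressed(expr$b, cfg$fpkm_threshold, cfg$strict_greater))
      truth_tx <- sim$transcripts
      parent_a <- drop_uncharacterized(
        toupper(truth_tx$gene[truth_tx$frac_a > 0]))
      parent_b <- drop_uncharacterized(
        toupper(truth_tx$gene[truth_tx$frac_a < 1]))
      venn <- venn4(list(hybrid_vs_A = set_a, hybrid_vs_B = set_b,
                         parent_A = parent_a, parent_B = parent_b))
      report$compare <- list(
        top_n = cfg$top_n,
        top_n_overlap = top_n_overlap(expr$a, expr$b, n = cfg$top_n),
        venn = stats::setNames(as.list(venn$count), venn$region))
      stage_log(verbose, "compare", "venn over ", sum(venn$count),
                " genes")
    }
  }

  if ("alleles" %in% cfg$stages) {
    alle <- lapply(c(A = "vcf_a", B = "vcf_b"), function(k) {
      sites <- read_trio_vcf(sim$paths[[k]],
                             reference_species = if (k == "vcf_a") "A"
                                                 else "B")
      sel <- select_alt_monoallelic(sites)
      zyg <- classify_hybrid_zygosity(sel)
      ratio <- allelic_depth_ratio(zyg$ad_hybrid_ref, zyg$ad_hybrid_alt)
      bins <- signed_bin(ratio, zyg$alt_parent,
                         convention = cfg$sign_convention)
      calls <- origin_from_variant(zyg)
      blocks <- build_blocks(calls, min_variants = cfg$min_variants)
      list(n_sites = nrow(sites), n_alt_mono = nrow(sel),
           biallelic_fraction = mean(zyg$zygosity == "biallelic"),
           histogram = bin_histogram(bins),
           n_origin_calls = nrow(calls), blocks = blocks,
           bp_totals = block_bp_totals(blocks),
           impact = impact_fractions(zyg))
    })
    report$alleles <- lapply(alle, function(x) list(
      n_sites = x$n_sites, n_alt_mono = x$n_alt_mono,
      biallelic_fraction = x$biallelic_fraction,
      histogram = stats::setNames(as.list(x$histogram$count),
                                  format(x$histogram$bin)),
      n_origin_calls = x$n_origin_calls,
      n_blocks = nrow(x$blocks),
      bp_totals = x$bp_totals,
      impact = x$impact))
    for (k in c("A", "B"))
      write_blocks_bed(alle[[k]]$blocks,
                       file.path(outdir, paste0("blocks_", k, ".bed")))
    stage_log(verbose, "alleles",
              "alt-monoallelic sites: A=", alle$A$n_alt_mono,
              ", B=", alle$B$n_alt_mono)
  }

  if ("imprint" %in% cfg$stages) {
    cr <- crossref_imprint(imprint_fixture_origins(), read_imprint_db())
    report$imprint <- list(n_matched = cr$n_matched,
                           n_concordant = cr$n_concordant,
                           n_discordant = cr$n_discordant,
                           n_unresolvable = cr$n_unresolvable)
    stage_log(verbose, "imprint", cr$n_matched, " matched, ",
              cr$n_discordant, " discordant")
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report_md(report), file.path(outdir, "report.md"))
  invisible(report)
}

#' @noRd
render_report_md <- function(report) {
  out <- c("# Hybrid transcriptome pipeline report", "")
  if (!is.null(report$assign)) {
    out <- c(out, "## Read assignment", "",
             sprintf("- %s: %d (%.1f%%)",
                     names(report$assign$percent),
                     unlist(report$assign$counts[
                       names(report$assign$percent)]),
                     unlist(report$assign$percent)), "")
  }
  if (!is.null(report$compare)) {
    out <- c(out, "## Transcriptome comparison", "",
             sprintf("- top-%d overlap: %d", report$compare$top_n,
                     report$compare$top_n_overlap),
             sprintf("- %s: %d", names(report$compare$venn),
                     unlist(report$compare$venn)), "")
  }
  if (!is.null(report$alleles)) {
    for (k in names(report$alleles)) {
      a <- report$alleles[[k]]
      out <- c(out, paste0("## Trio alleles (reference ", k, ")"), "",
               sprintf("- alternatively monoallelic sites: %d of %d",
                       a$n_alt_mono, a$n_sites),
               sprintf("- hybrid biallelic fraction: %.3f",
                       a$biallelic_fraction),
               sprintf("- origin calls: %d in %d blocks", a$n_origin_calls,
                       a$n_blocks), "")
    }
  }
  if (!is.null(report$imprint)) {
    out <- c(out, "## Imprinting cross-reference", "",
             sprintf("- matched: %d", report$imprint$n_matched),
             sprintf("- concordant: %d", report$imprint$n_concordant),
             sprintf("- discordant: %d", report$imprint$n_discordant),
             sprintf("- unresolvable: %d", report$imprint$n_unresolvable),
             "")
  }
  out
}
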