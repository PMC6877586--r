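# Analytic construction of the dual-reference alignments consumed by the
# arbitration stage. Against its true genome a read's CIGAR is the recorded
# sequencing-error edit script; against the other genome the read is aligned
# (Needleman-Wunsch, read-global) to the truth-mapped target window, so the
# CIGAR additionally reflects the diagnostic differences between the two
# parental genomes. No external aligner is involved and placement is always
# anchored at the known source locus.

#' @noRd
.align_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                       mismatch = -3)
    mat
  }
})

# align reads to genomic windows (element-wise); returns per-read window
# offsets (1-based) and extended-dialect CIGARs
#' @noRd
align_to_windows <- function(reads, windows) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAStringSet(windows),
    type = "global-local", substitutionMatrix = .align_submat(),
    gapOpening = 5, gapExtension = 2)
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  list(offset = Biostrings::start(Biostrings::subject(aln)),
       cigar = mapply(cigar_from_aligned, pat, sub, USE.NAMES = FALSE))
}

#' Construct SAM alignments of the simulated reads against both genomes
#'
#' Alignments are derived from simulation truth: the CIGAR against a read's
#' genome of origin encodes exactly the sequencing errors applied to it,
#' while the CIGAR against the other genome is obtained by aligning the
#' read to the truth-mapped window of that genome and therefore also
#' reflects every diagnostic site the read spans. Two CIGAR dialects are
#' supported: `"extended"` distinguishes `=`/`X`, `"legacy"` writes all
#' aligned bases as `M` and soft-clips mismatch-dense read ends (a run
#' triggers when >= `clip_min` mismatches chain within `clip_gap` bp of a
#' read end). Reads whose mapped window on a genome collapses below 60% of
#' the read length are emitted as unmapped on that side.
#'
#' @param reads output of [simulate_hybrid_reads()].
#' @param genomes output of [generate_parental_genomes()].
#' @param dialect `"extended"` or `"legacy"`.
#' @param pad bp of genomic context added on each side of the mapped
#'   window before alignment.
#' @param clip_gap,clip_min legacy-dialect end-clipping parameters.
#' @return list of class `dual_sam` with data.frames `sam_a`, `sam_b`
#'   (columns `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`),
#'   one row per read in each.
#' @export
write_synthetic_alignments <- function(reads, genomes,
                                       dialect = c("extended", "legacy"),
                                       pad = 12L, clip_gap = 10L,
                                       clip_min = 2L) {
  dialect <- match.arg(dialect)
  truth <- reads$truth
  n <- nrow(truth)
  chr_a <- as.character(genomes$genome_a)
  chr_b <- as.character(genomes$genome_b)
  len_a <- stats::setNames(nchar(chr_a), names(chr_a))
  len_b <- stats::setNames(nchar(chr_b), names(chr_b))
  read_seq <- unname(reads$reads[truth$read_id])
  side_tab <- function(side) {
    glen <- if (side == "A") len_a else len_b
    is_true <- truth$origin == side
    s <- if (side == "A") truth$start_a else truth$start_b
    e <- if (side == "A") truth$end_a else truth$end_b
    ws <- pmax(1L, s - pad)
    we <- pmin(unname(glen[truth$chrom]), e + pad)
    mapped <- is_true | (we - ws + 1L >= 0.6 * nchar(read_seq))
    pos <- ifelse(is_true, s, 0L)
    cig <- ifelse(is_true, truth$err_cigar, "*")
    todo <- which(!is_true & mapped)
    if (length(todo)) {
      gseq <- if (side == "A") chr_a else chr_b
      windows <- substr(gseq[truth$chrom[todo]], ws[todo], we[todo])
      aln <- align_to_windows(read_seq[todo], windows)
      pos[todo] <- ws[todo] + aln$offset - 1L
      cig[todo] <- aln$cigar
    }
    if (dialect == "legacy") {
      for (i in which(mapped)) {
        leg <- extended_to_legacy(cig[i], clip_gap, clip_min)
        cig[i] <- leg$cigar
        pos[i] <- pos[i] + leg$pos_shift
      }
    }
    data.frame(qname = truth$read_id,
               flag = ifelse(mapped, 0L, 4L),
               rname = ifelse(mapped, truth$chrom, "*"),
               pos = as.integer(ifelse(mapped, pos, 0L)),
               mapq = ifelse(mapped, 60L, 0L),
               cigar = cig, seq = read_seq, stringsAsFactors = FALSE)
  }
  structure(list(sam_a = side_tab("A"), sam_b = side_tab("B")),
            class = "dual_sam")
}

#' Write alignment records as a SAM v1.6 file
#'
#' @param records data.frame as produced in [write_synthetic_alignments()]
#'   (`qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`).
#' @param seqlengths named vector of reference sequence lengths for the
#'   `@SQ` header lines.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(records, seqlengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)),
           "@PG\tID:hybridscope\tPN:hybridscope")
  qual <- ifelse(records$cigar == "*", strrep("I", nchar(records$seq)),
                 strrep("I", nchar(records$seq)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
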