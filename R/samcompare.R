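# Read-by-read arbitration between alignments of one read set against two
# reference genomes. The score of an alignment is read from its CIGAR
# string alone, as a three-component hierarchy: matching bases first, then
# the number of indels, then clipped bases. Reads mapped on one side only
# are unique to that side without scoring; reads whose final scores are
# identical are discarded as ties.

#' Score a CIGAR string
#'
#' Computes the hierarchical alignment score used for dual-reference
#' arbitration: `matching` is the summed length of `M` and `=` operations
#' (`X` is a mismatch and never counts as matching); `indels` counts `I`
#' and `D` operations, either as events (default) or as bases; `clipped`
#' is the summed length of `S` and `H` operations. `N` and `P` contribute
#' nothing. The `"*"` placeholder of an unmapped record scores `NA`.
#'
#' @param cigar character vector of CIGAR strings.
#' @param indel_metric `"events"` (count of I/D operations) or `"bases"`
#'   (summed I/D lengths).
#' @return data.frame of class `cigar_score` with integer columns
#'   `matching`, `indels`, `clipped`, one row per input CIGAR; `NA` rows
#'   for unmapped placeholders.
#' @export
#' @examples
#' score_cigar(c("100M", "48=1X2I47=3S", "*"))
score_cigar <- function(cigar, indel_metric = c("events", "bases")) {
  indel_metric <- match.arg(indel_metric)
  n <- length(cigar)
  out <- data.frame(matching = rep(NA_integer_, n),
                    indels = rep(NA_integer_, n),
                    clipped = rep(NA_integer_, n))
  mapped <- !is.na(cigar) & cigar != "*"
  if (any(mapped)) {
    bad <- mapped & !grepl(CIGAR_RE, cigar)
    if (any(bad)) cigar_runs(cigar[which(bad)[1L]])  # raises parse error
    ops <- GenomicAlignments::explodeCigarOps(cigar[mapped])
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar[mapped])
    out$matching[mapped] <- mapply(function(o, l)
      sum(l[o %in% c("M", "=")]), ops, lens)
    out$indels[mapped] <- if (indel_metric == "events")
      mapply(function(o, l) sum(o %in% c("I", "D")), ops, lens)
    else
      mapply(function(o, l) sum(l[o %in% c("I", "D")]), ops, lens)
    out$clipped[mapped] <- mapply(function(o, l)
      sum(l[o %in% c("S", "H")]), ops, lens)
  }
  class(out) <- c("cigar_score", "data.frame")
  out
}

#' Compare two alignment scores hierarchically
#'
#' Lexicographic comparison of [score_cigar()] scores: more matching bases
#' wins; on a tie, fewer indels wins; on a further tie, fewer clipped
#' bases wins; if all three components are equal the comparison is a tie.
#'
#' @param a,b `cigar_score` data.frames of equal row count (recycled if
#'   one has a single row).
#' @return data.frame with `winner` (`"A"`, `"B"` or `"tie"`) and
#'   `tiebreak_level` (`"matches"`, `"indels"`, `"clips"` or
#'   `"full_tie"`), one row per score pair.
#' @export
compare_scores <- function(a, b) {
  stopifnot(all(c("matching", "indels", "clipped") %in% names(a)),
            all(c("matching", "indels", "clipped") %in% names(b)))
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L) a <- a[rep(1L, n), ]
  if (nrow(b) == 1L) b <- b[rep(1L, n), ]
  winner <- rep("tie", n)
  level <- rep("full_tie", n)
  m <- sign(a$matching - b$matching)
  i <- sign(b$indels - a$indels)    # fewer indels wins
  cl <- sign(b$clipped - a$clipped) # fewer clipped bases wins
  at_m <- m != 0
  at_i <- !at_m & i != 0
  at_c <- !at_m & !at_i & cl != 0
  winner[at_m] <- ifelse(m[at_m] > 0, "A", "B")
  winner[at_i] <- ifelse(i[at_i] > 0, "A", "B")
  winner[at_c] <- ifelse(cl[at_c] > 0, "A", "B")
  level[at_m] <- "matches"; level[at_i] <- "indels"; level[at_c] <- "clips"
  data.frame(winner = winner, tiebreak_level = level)
}

# read a SAM (or BAM) file into a minimal record table via Rsamtools
#' @noRd
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(qname = x$qname, flag = x$flag,
             rname = as.character(x$rname), pos = x$pos,
             cigar = ifelse(is.na(x$cigar), "*", x$cigar),
             stringsAsFactors = FALSE)
}

#' Pair name-matched alignment records from two references
#'
#' Joins the primary alignment records of the same read set aligned
#' against reference A and reference B by read name. Secondary and
#' supplementary records are skipped (and counted); a read unmapped on a
#' side, or absent from it, is recorded as absent there. A duplicate
#' primary record for a read name is an error.
#'
#' @param sam_a,sam_b paths to SAM/BAM files, or record data.frames with
#'   columns `qname`, `flag`, `cigar` (as from
#'   [write_synthetic_alignments()]).
#' @return data.frame of class `dual_alignments`: `read_id`, `mapped_a`,
#'   `cigar_a`, `mapped_b`, `cigar_b`; attribute `n_secondary_skipped`.
#' @export
pair_records <- function(sam_a, sam_b) {
  load_side <- function(x, side) {
    rec <- if (is.character(x)) read_sam(x) else x
    sec <- bitwAnd(rec$flag, 0x900L) != 0L
    n_sec <- sum(sec)
    rec <- rec[!sec, , drop = FALSE]
    dup <- duplicated(rec$qname)
    if (any(dup))
      stop("duplicate primary record for read '", rec$qname[dup][1L],
           "' in SAM ", side, call. = FALSE)
    rec$mapped <- bitwAnd(rec$flag, 0x4L) == 0L & rec$cigar != "*"
    attr(rec, "n_secondary") <- n_sec
    rec
  }
  a <- load_side(sam_a, "A")
  b <- load_side(sam_b, "B")
  ids <- union(a$qname, b$qname)
  only_a <- setdiff(a$qname, b$qname)
  only_b <- setdiff(b$qname, a$qname)
  if (length(only_a) || length(only_b))
    warning(length(only_a) + length(only_b),
            " read(s) present on one side only; treated as absent on the ",
            "missing side")
  ia <- match(ids, a$qname)
  ib <- match(ids, b$qname)
  out <- data.frame(
    read_id = ids,
    mapped_a = !is.na(ia) & a$mapped[ia],
    cigar_a = ifelse(is.na(ia), "*", a$cigar[ia]),
    mapped_b = !is.na(ib) & b$mapped[ib],
    cigar_b = ifelse(is.na(ib), "*", b$cigar[ib]),
    stringsAsFactors = FALSE)
  out$cigar_a[!out$mapped_a] <- "*"
  out$cigar_b[!out$mapped_b] <- "*"
  attr(out, "n_secondary_skipped") <-
    attr(a, "n_secondary") + attr(b, "n_secondary")
  class(out) <- c("dual_alignments", "data.frame")
  out
}

#' Assign each read to a reference genome, or discard it
#'
#' Reads mapped on exactly one side are unique to that side
#' (`tiebreak_level = "mapped_vs_unmapped"`); reads mapped on both sides
#' are arbitrated with [compare_scores()]; full ties are discarded; reads
#' unmapped on both sides are counted as such. The four categories
#' partition the input.
#'
#' @param pairs output of [pair_records()].
#' @param indel_metric passed to [score_cigar()].
#' @return list of class `assignment`: `assignments` (per-read data.frame
#'   with `read_id`, `category`, `tiebreak_level`) and `summary` (named
#'   counts `unique_a`, `unique_b`, `unmapped_both`, `discarded_tie`,
#'   `total`).
#' @export
assign_reads <- function(pairs, indel_metric = c("events", "bases")) {
  indel_metric <- match.arg(indel_metric)
  n <- nrow(pairs)
  category <- rep("unmapped_both", n)
  level <- rep(NA_character_, n)
  one_a <- pairs$mapped_a & !pairs$mapped_b
  one_b <- pairs$mapped_b & !pairs$mapped_a
  both <- pairs$mapped_a & pairs$mapped_b
  category[one_a] <- "unique_a"
  category[one_b] <- "unique_b"
  level[one_a | one_b] <- "mapped_vs_unmapped"
  if (any(both)) {
    sa <- score_cigar(pairs$cigar_a[both], indel_metric)
    sb <- score_cigar(pairs$cigar_b[both], indel_metric)
    cmp <- compare_scores(sa, sb)
    category[both] <- c(A = "unique_a", B = "unique_b",
                        tie = "discarded_tie")[cmp$winner]
    level[both] <- cmp$tiebreak_level
  }
  summary <- c(unique_a = sum(category == "unique_a"),
               unique_b = sum(category == "unique_b"),
               unmapped_both = sum(category == "unmapped_both"),
               discarded_tie = sum(category == "discarded_tie"),
               total = n)
  structure(list(
    assignments = data.frame(read_id = pairs$read_id, category = category,
                             tiebreak_level = level,
                             stringsAsFactors = FALSE),
    summary = summary), class = "assignment")
}

#' Report assignment counts with percentages
#'
#' @param assignment output of [assign_reads()], or a named count vector
#'   with elements `unique_a`, `unique_b`, `unmapped_both`,
#'   `discarded_tie` and `total`.
#' @return data.frame with `category`, `count` and `percent` (100 x
#'   count/total, rounded half-up to one decimal).
#' @export
#' @examples
#' summarize_assignment(c(unique_a = 14011831, unique_b = 15371814,
#'                        unmapped_both = 12698235,
#'                        discarded_tie = 48619799, total = 90701679))
summarize_assignment <- function(assignment) {
  s <- if (inherits(assignment, "assignment")) assignment$summary
       else assignment
  if (is.na(s[["total"]]) || s[["total"]] <= 0)
    stop("summarize_assignment: total must be > 0", call. = FALSE)
  cats <- c("unique_a", "unique_b", "unmapped_both", "discarded_tie")
  data.frame(category = cats,
             count = as.numeric(s[cats]),
             percent = round_half_up(100 * as.numeric(s[cats]) /
                                     s[["total"]], 1),
             row.names = NULL)
}

#' Split SAM records into the two unique-read partitions
#'
#' Filters a SAM file (header preserved) down to the reads assigned
#' uniquely to one reference, yielding the per-parent read sets used for
#' expression quantification.
#'
#' @param sam_path SAM file the partition is drawn from.
#' @param assignment output of [assign_reads()].
#' @param category `"unique_a"` or `"unique_b"`.
#' @param out_path output SAM path.
#' @return invisibly, `out_path`.
#' @export
partition_sam <- function(sam_path, assignment, category, out_path) {
  stopifnot(category %in% c("unique_a", "unique_b"))
  keep_ids <- assignment$assignments$read_id[
    assignment$assignments$category == category]
  lines <- readLines(sam_path)
  hdr <- grepl("^@", lines)
  qname <- sub("\t.*", "", lines)
  writeLines(c(lines[hdr], lines[!hdr & qname %in% keep_ids]), out_path)
  invisible(out_path)
}
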