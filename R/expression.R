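# Transcript quantification (simple FPKM over an annotation) and the
# transcriptome set comparisons: expression filtering, removal of
# uncharacterized gene symbols, top-N overlaps, four-set intersection
# counts, reference-set cross-references and pathway-frequency tables.
# All gene-symbol handling is case-insensitive; symbols are stored
# upper-case.

#' Count reads per transcript from an alignment file
#'
#' Overlap-counts primary aligned reads against transcript features of a
#' GFF3 annotation (features of type `transcript` carrying a `gene`
#' attribute). A read is counted for every transcript its aligned span
#' overlaps.
#'
#' @param sam_path SAM/BAM file of reads (e.g. a partition from
#'   [partition_sam()]).
#' @param gff_path GFF3 annotation with transcript features.
#' @return data.frame `transcript_id`, `gene`, `length`, `count`.
#' @export
count_reads_per_transcript <- function(sam_path, gff_path) {
  gff <- rtracklayer::import(gff_path, format = "gff3")
  tx <- gff[gff$type == "transcript"]
  rec <- read_sam(sam_path)
  rec <- rec[bitwAnd(rec$flag, 0x904L) == 0L & rec$cigar != "*", ,
             drop = FALSE]
  if (nrow(rec) > 0) {
    w <- GenomicAlignments::cigarWidthAlongReferenceSpace(rec$cigar)
    reads <- GenomicRanges::GRanges(rec$rname,
                                    IRanges::IRanges(rec$pos, width = w))
    cnt <- GenomicRanges::countOverlaps(tx, reads)
  } else {
    cnt <- rep(0L, length(tx))
  }
  data.frame(transcript_id = as.character(tx$ID),
             gene = toupper(as.character(tx$gene)),
             length = BiocGenerics::width(tx),
             count = cnt, stringsAsFactors = FALSE)
}

#' Compute FPKM expression records
#'
#' FPKM = count x 10^9 / (length x total_mapped): fragments per kilobase
#' of transcript per million mapped reads. `total_mapped` defaults to the
#' sum of the supplied counts (library-internal normalization).
#'
#' @param counts data.frame with `gene`, `length`, `count` (as from
#'   [count_reads_per_transcript()]).
#' @param total_mapped total mapped reads used as the library size.
#' @return data.frame of class `expression_records`: `gene_symbol`,
#'   `transcript_length`, `read_count`, `fpkm`.
#' @export
#' @examples
#' compute_fpkm(data.frame(gene = "B2M", length = 1000, count = 100),
#'              total_mapped = 1e6)  # fpkm 100
compute_fpkm <- function(counts, total_mapped = sum(counts$count)) {
  stopifnot(all(c("gene", "length", "count") %in% names(counts)))
  if (is.na(total_mapped) || total_mapped <= 0)
    stop("compute_fpkm: total_mapped must be > 0", call. = FALSE)
  if (any(counts$length <= 0))
    stop("compute_fpkm: transcript lengths must be > 0", call. = FALSE)
  out <- data.frame(
    gene_symbol = toupper(counts$gene),
    transcript_length = counts$length,
    read_count = counts$count,
    fpkm = counts$count * 1e9 / (counts$length * total_mapped),
    stringsAsFactors = FALSE)
  class(out) <- c("expression_records", "data.frame")
  out
}

#' Filter to expressed genes by FPKM threshold
#'
#' Retains records at or above the threshold: the boundary value
#' `fpkm == threshold` is kept by default (genes strictly below the
#' threshold are neglected); set `strict_greater = TRUE` to require
#' `fpkm > threshold`.
#'
#' @param records an `expression_records` data.frame.
#' @param threshold FPKM cutoff (default 1).
#' @param strict_greater drop the boundary value as well.
#' @return character vector of unique upper-case gene symbols.
#' @export
filter_expressed <- function(records, threshold = 1,
                             strict_greater = FALSE) {
  keep <- if (strict_greater) records$fpkm > threshold
          else records$fpkm >= threshold
  normalize_symbols(records$gene_symbol[keep])
}

#' Drop uncharacterized gene symbols
#'
#' Removes symbols matching the uncharacterized-gene pattern (by default
#' LOC-numbered loci and anything containing "uncharacterized",
#' case-insensitive); such genes carry no information for interspecies
#' comparison.
#'
#' @param symbols character vector of gene symbols.
#' @param pattern regular expression identifying uncharacterized symbols.
#' @return the filtered symbol vector (upper-case, unique).
#' @export
#' @examples
#' drop_uncharacterized(c("LOC101112", "GRB10"))  # "GRB10"
drop_uncharacterized <- function(symbols,
                                 pattern = "^LOC[0-9]+$|UNCHARACTERIZED") {
  s <- normalize_symbols(symbols)
  s[!grepl(pattern, s, ignore.case = TRUE)]
}

#' Overlap of the N highest expressed genes of two datasets
#'
#' Ranks each dataset by FPKM (descending) after removing uncharacterized
#' symbols, takes the top `n`, and counts the common symbols. Rank ties at
#' the boundary are broken by lexicographic symbol order so the result is
#' deterministic.
#'
#' @param a,b `expression_records` data.frames.
#' @param n number of top genes per dataset (default 100).
#' @return integer: the number of shared symbols.
#' @export
top_n_overlap <- function(a, b, n = 100) {
  top <- function(r) {
    r <- r[!grepl("^LOC[0-9]+$|UNCHARACTERIZED", toupper(r$gene_symbol),
                  ignore.case = TRUE), , drop = FALSE]
    r$gene_symbol <- toupper(r$gene_symbol)
    r <- r[!duplicated(r$gene_symbol), , drop = FALSE]
    if (nrow(r) < n)
      warning("fewer than ", n, " records; using all ", nrow(r))
    r <- r[order(-r$fpkm, r$gene_symbol), , drop = FALSE]
    utils::head(r$gene_symbol, n)
  }
  length(intersect(top(a), top(b)))
}

#' Four-set intersection region counts
#'
#' Computes the 15 disjoint regions of a four-set Venn diagram. Region
#' names are the `&`-joined labels of the sets a gene belongs to; the
#' region counts are disjoint and sum to the size of the union.
#'
#' @param sets named list of exactly four character vectors of gene
#'   symbols (case-insensitive).
#' @return data.frame `region`, `count` covering all 15 regions.
#' @export
venn4 <- function(sets) {
  if (length(sets) != 4L || is.null(names(sets)) || any(names(sets) == ""))
    stop("venn4 requires exactly four named sets", call. = FALSE)
  sets <- lapply(sets, normalize_symbols)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(names(sets), k, paste, collapse = "&", simplify = FALSE)))
  counts <- table(factor(key, levels = combos))
  data.frame(region = combos, count = as.integer(counts[combos]),
             row.names = NULL)
}

#' Cross-reference a gene set against a reference set
#'
#' Counts the query genes present in the reference set and reports the
#' percentage of the query, rounded half-up to one decimal.
#'
#' @param query,reference character vectors of gene symbols
#'   (case-insensitive).
#' @return list with `n_in` and `percent`.
#' @export
#' @examples
#' # 88 of 219 hybrid-unique genes found age-dependently expressed
#' crossref_membership(paste0("G", 1:219), paste0("G", 1:88))
crossref_membership <- function(query, reference) {
  q <- normalize_symbols(query)
  if (length(q) == 0L)
    stop("crossref_membership: empty query set", call. = FALSE)
  r <- normalize_symbols(reference)
  n_in <- length(intersect(q, r))
  list(n_in = n_in,
       percent = round_half_up(100 * n_in / length(q), 1))
}

#' Per-pathway gene counts as percentages of a gene universe
#'
#' @param assignments data.frame with columns `gene` and `pathway` (a gene
#'   may map to several pathways).
#' @param universe_size size of the gene universe the percentages refer
#'   to.
#' @return data.frame `pathway`, `n_genes`, `percent` (two decimals,
#'   half-up), ordered by decreasing count.
#' @export
pathway_percentages <- function(assignments, universe_size) {
  if (is.na(universe_size) || universe_size <= 0)
    stop("pathway_percentages: universe_size must be > 0", call. = FALSE)
  stopifnot(all(c("gene", "pathway") %in% names(assignments)))
  u <- unique(data.frame(gene = toupper(assignments$gene),
                         pathway = assignments$pathway))
  tab <- table(u$pathway)
  out <- data.frame(pathway = names(tab), n_genes = as.integer(tab),
                    row.names = NULL)
  out$percent <- round_half_up(100 * out$n_genes / universe_size, 2)
  out[order(-out$n_genes, out$pathway), , drop = FALSE]
}
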