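# CIGAR manipulation shared by the simulator and the arbitration module.
# Parsing of well-formed strings is delegated to GenomicAlignments; the
# helpers here build CIGARs from alignments and translate between the
# extended (=/X) and legacy (all-M, mismatch-clipped) dialects.

#' @noRd
CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

# explode one CIGAR into per-run ops/lengths, with a friendly parse error
#' @noRd
cigar_runs <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(NULL)
  if (!grepl(CIGAR_RE, cigar)) {
    bad <- regmatches(cigar, regexpr("[0-9]*[^0-9MIDNSHP=X]|[MIDNSHP=X]{2,}",
                                     cigar))
    stop("malformed CIGAR '", cigar, "' at token '",
         if (length(bad)) bad else cigar, "'", call. = FALSE)
  }
  list(ops = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
       lens = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]])
}

# run-length encode per-column ops into a CIGAR string
#' @noRd
cols_to_cigar <- function(cols) {
  if (length(cols) == 0L) return("*")
  r <- rle(cols)
  paste0(r$lengths, r$values, collapse = "")
}

# per-column ops from gapped aligned pattern/subject strings
#' @noRd
cigar_from_aligned <- function(pat, sub) {
  p <- strsplit(pat, "")[[1L]]
  s <- strsplit(sub, "")[[1L]]
  cols <- ifelse(p == "-", "D", ifelse(s == "-", "I",
                 ifelse(p == s, "=", "X")))
  cols_to_cigar(cols)
}

# Translate an extended-dialect CIGAR to the legacy dialect: aligned
# columns become M, and a mismatch-dense run at either read end is
# soft-clipped. A run triggers when the outermost mismatch lies within
# `clip_gap` bp of the read end and at least `clip_min` mismatches are
# chained with inter-mismatch gaps <= `clip_gap`; the clip extends from the
# read end through the innermost mismatch of the chain. Returns the legacy
# CIGAR and the shift of the leftmost aligned reference position.
#' @noRd
extended_to_legacy <- function(cigar, clip_gap = 10L, clip_min = 2L) {
  runs <- cigar_runs(cigar)
  if (is.null(runs)) return(list(cigar = "*", pos_shift = 0L))
  cols <- rep(runs$ops, runs$lens)
  consumes_read <- cols %in% c("M", "I", "S", "=", "X")
  readpos <- cumsum(consumes_read)
  n <- sum(consumes_read)
  xs <- readpos[cols == "X"]
  chain_cut <- function(x_sorted_out_to_in, end_dist) {
    # x positions ordered from the read end inward; end_dist(x) = distance
    # from the read end
    if (length(x_sorted_out_to_in) == 0L) return(NA_integer_)
    if (end_dist(x_sorted_out_to_in[1L]) > clip_gap) return(NA_integer_)
    chain <- x_sorted_out_to_in[1L]
    for (x in x_sorted_out_to_in[-1L]) {
      if (abs(x - chain[length(chain)]) <= clip_gap) chain <- c(chain, x)
      else break
    }
    if (length(chain) >= clip_min) chain[length(chain)] else NA_integer_
  }
  right_cut <- chain_cut(sort(xs, decreasing = TRUE), function(x) n - x)
  left_cut <- chain_cut(sort(xs), function(x) x - 1L)
  clip <- rep(FALSE, length(cols))
  if (!is.na(right_cut)) clip[consumes_read & readpos >= right_cut] <- TRUE
  if (!is.na(left_cut)) clip[consumes_read & readpos <= left_cut] <- TRUE
  # reference-consuming columns dropped with a clipped end shift POS
  ref_cols <- cols %in% c("M", "D", "N", "=", "X")
  if (!is.na(left_cut)) {
    left_region <- readpos <= left_cut
    pos_shift <- sum(ref_cols & left_region)
  } else pos_shift <- 0L
  drop <- logical(length(cols))
  if (!is.na(right_cut)) drop[cols == "D" & readpos >= right_cut] <- TRUE
  if (!is.na(left_cut)) drop[cols == "D" & readpos <= left_cut] <- TRUE
  out <- cols
  out[out %in% c("=", "X")] <- "M"
  out[clip] <- "S"
  out <- out[!drop]
  list(cigar = cols_to_cigar(out), pos_shift = pos_shift)
}

# width of the read implied by a CIGAR (SEQ length)
#' @noRd
cigar_read_width <- function(cigar) {
  runs <- cigar_runs(cigar)
  if (is.null(runs)) return(NA_integer_)
  sum(runs$lens[runs$ops %in% c("M", "I", "S", "=", "X")])
}
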