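#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' parental divergence, transcript layout, read sampling, the indel-prone
#' sequencing error model, and the trio-variant planting scheme. All
#' randomness downstream flows from `seed`; identical configurations
#' reproduce byte-identical output files.
#'
#' @param seed integer seed for all random draws.
#' @param n_chromosomes number of chromosomes per genome.
#' @param chrom_length chromosome length in bp.
#' @param divergence per-base substitution rate between the two parental
#'   genomes (0--0.2; higher values make coordinate mapping between the two
#'   genomes ambiguous and are rejected).
#' @param indel_divergence per-base rate of 1--3 bp indels between the
#'   parental genomes.
#' @param n_transcripts number of transcripts laid out on the genome.
#' @param transcript_length_range length-2 vector, min/max transcript bp.
#' @param read_length read length in bp (reads from shorter transcripts are
#'   truncated to the transcript).
#' @param n_reads number of hybrid reads to simulate.
#' @param seq_error_sub per-base substitution sequencing-error rate.
#' @param seq_error_indel per-base 1--3 bp indel sequencing-error rate.
#' @param frac_monoallelic_sites proportion of diagnostic sites planted as
#'   alternatively homozygous in the parents.
#' @param mean_depth mean (Poisson) read depth per variant site and sample.
#' @param frac_mono_transcripts proportion of transcripts expressed
#'   monoallelically in the hybrid (the rest are biallelic 50/50 mixtures).
#' @param frac_hybrid_biallelic proportion of planted alternatively
#'   homozygous sites at which the hybrid is planted as biallelic
#'   (allele fraction 0.5); the remainder are planted monoallelic for one
#'   parent's allele.
#' @param frac_uncharacterized proportion of transcripts given LOC-style
#'   uncharacterized gene symbols.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 100000L,
                       divergence = 0.02,
                       indel_divergence = 0.002,
                       n_transcripts = 40L,
                       transcript_length_range = c(500L, 2000L),
                       read_length = 100L,
                       n_reads = 2000L,
                       seq_error_sub = 0.005,
                       seq_error_indel = 0.001,
                       frac_monoallelic_sites = 0.3,
                       mean_depth = 50,
                       frac_mono_transcripts = 0.5,
                       frac_hybrid_biallelic = 0.74,
                       frac_uncharacterized = 0.1) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    divergence = divergence,
    indel_divergence = indel_divergence,
    n_transcripts = as.integer(n_transcripts),
    transcript_length_range = as.integer(transcript_length_range),
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    seq_error_sub = seq_error_sub,
    seq_error_indel = seq_error_indel,
    frac_monoallelic_sites = frac_monoallelic_sites,
    mean_depth = mean_depth,
    frac_mono_transcripts = frac_mono_transcripts,
    frac_hybrid_biallelic = frac_hybrid_biallelic,
    frac_uncharacterized = frac_uncharacterized
  )
  rates <- c("divergence", "indel_divergence", "seq_error_sub",
             "seq_error_indel", "frac_monoallelic_sites",
             "frac_mono_transcripts", "frac_hybrid_biallelic",
             "frac_uncharacterized")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: `", r, "` must be a single rate in [0, 1]",
           call. = FALSE)
  }
  if (cfg$divergence > 0.2)
    stop("sim_config: divergence > 0.2 makes A/B coordinate mapping ",
         "ambiguous; rejected", call. = FALSE)
  counts <- c("n_chromosomes", "chrom_length", "n_transcripts",
              "read_length", "n_reads")
  for (k in counts) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 0 ||
        (cfg[[k]] == 0 && !k %in% c("n_reads", "n_transcripts")))
      stop("sim_config: `", k, "` must be a positive count", call. = FALSE)
  }
  if (length(cfg$transcript_length_range) != 2L ||
      any(cfg$transcript_length_range <= 0) ||
      diff(cfg$transcript_length_range) < 0)
    stop("sim_config: transcript_length_range must be an increasing ",
         "positive pair", call. = FALSE)
  if (cfg$mean_depth <= 0)
    stop("sim_config: mean_depth must be positive", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# per-stage seeds derived from the one configured seed, so each generator
# stage is reproducible on its own and in any call order
#' @noRd
seed_for <- function(cfg, stage) {
  off <- c(genomes = 0L, transcripts = 101L, reads = 202L, vcf = 303L)[stage]
  as.integer((as.numeric(cfg$seed) + off) %% 2147483647)
}

DNA_BASES4 <- c("A", "C", "G", "T")

# Sample substitution / 1-3 bp indel events along a sequence of length L.
# Events never overlap (later colliding events are dropped).
#' @noRd
mutate_events <- function(L, sub_rate, indel_rate, max_indel = 3L) {
  pos <- integer(0); type <- character(0); len <- integer(0)
  if (sub_rate > 0) {
    sp <- which(stats::runif(L) < sub_rate)
    pos <- c(pos, sp); type <- c(type, rep("sub", length(sp)))
    len <- c(len, rep(1L, length(sp)))
  }
  if (indel_rate > 0) {
    ip <- which(stats::runif(L) < indel_rate)
    it <- sample(c("ins", "del"), length(ip), replace = TRUE)
    il <- sample.int(max_indel, length(ip), replace = TRUE)
    pos <- c(pos, ip); type <- c(type, it); len <- c(len, il)
  }
  if (length(pos) == 0L)
    return(data.frame(pos = integer(0), type = character(0),
                      len = integer(0)))
  o <- order(pos, type)
  ev <- data.frame(pos = pos[o], type = type[o], len = len[o])
  # clip deletions at the chromosome end
  over <- ev$type == "del" & ev$pos + ev$len - 1L > L
  ev$len[over] <- L - ev$pos[over] + 1L
  # drop events that collide with the span of an earlier one
  keep <- logical(nrow(ev)); last_end <- 0L
  for (i in seq_len(nrow(ev))) {
    if (ev$pos[i] > last_end) {
      keep[i] <- TRUE
      span <- if (ev$type[i] == "del") ev$pos[i] + ev$len[i] - 1L else ev$pos[i]
      last_end <- span
    }
  }
  ev[keep, , drop = FALSE]
}

# Apply mutation events to a sequence. Returns the mutated sequence, the
# extended CIGAR of mutant-vs-original (ops =, X, I, D), per-event alleles
# and mutant-space coordinates, and the piecewise original->mutant
# coordinate shift map.
#' @noRd
apply_events <- function(seq, events) {
  L <- nchar(seq)
  ops <- character(0); lens <- integer(0)
  pieces <- character(0)
  ref <- character(0); alt <- character(0); pos_b <- integer(0)
  map_start <- 1L; map_shift <- 0L
  cursor <- 1L; shift <- 0L
  add_op <- function(op, l) {
    if (l > 0L) { ops <<- c(ops, op); lens <<- c(lens, l) }
  }
  n <- if (is.null(events)) 0L else nrow(events)
  for (i in seq_len(n)) {
    p <- events$pos[i]; ty <- events$type[i]; l <- events$len[i]
    if (ty == "sub") {
      add_op("=", p - cursor)
      if (p > cursor) pieces <- c(pieces, substr(seq, cursor, p - 1L))
      old <- substr(seq, p, p)
      new <- sample(setdiff(DNA_BASES4, old), 1L)
      pieces <- c(pieces, new)
      add_op("X", 1L)
      ref <- c(ref, old); alt <- c(alt, new); pos_b <- c(pos_b, p + shift)
      cursor <- p + 1L
    } else if (ty == "del") {
      add_op("=", p - cursor)
      if (p > cursor) pieces <- c(pieces, substr(seq, cursor, p - 1L))
      add_op("D", l)
      ref <- c(ref, substr(seq, p, p + l - 1L)); alt <- c(alt, "-")
      pos_b <- c(pos_b, p + shift)
      cursor <- p + l
      shift <- shift - l
      map_start <- c(map_start, p + l); map_shift <- c(map_shift, shift)
    } else { # insertion after position p
      add_op("=", p - cursor + 1L)
      pieces <- c(pieces, substr(seq, cursor, p))
      ins <- paste(sample(DNA_BASES4, l, replace = TRUE), collapse = "")
      pieces <- c(pieces, ins)
      add_op("I", l)
      ref <- c(ref, "-"); alt <- c(alt, ins); pos_b <- c(pos_b, p + shift + 1L)
      cursor <- p + 1L
      shift <- shift + l
      map_start <- c(map_start, p + 1L); map_shift <- c(map_shift, shift)
    }
  }
  add_op("=", L - cursor + 1L)
  if (cursor <= L) pieces <- c(pieces, substr(seq, cursor, L))
  # merge adjacent identical ops (can arise after zero-length drops)
  if (length(ops) > 1L) {
    grp <- cumsum(c(TRUE, ops[-1L] != ops[-length(ops)]))
    lens <- as.integer(tapply(lens, grp, sum))
    ops <- ops[!duplicated(grp)]
  }
  list(seq = paste(pieces, collapse = ""),
       cigar = paste0(lens, ops, collapse = ""),
       detail = if (n > 0L)
         data.frame(pos = events$pos, type = events$type, len = events$len,
                    ref = ref, alt = alt, pos_b = pos_b)
       else
         data.frame(pos = integer(0), type = character(0), len = integer(0),
                    ref = character(0), alt = character(0),
                    pos_b = integer(0)),
       map = data.frame(start = map_start, shift = map_shift))
}

# piecewise-constant coordinate shift lookup (both directions share shape)
#' @noRd
map_pos <- function(map, pos) {
  pos + map$shift[findInterval(pos, map$start)]
}

# invert an original->mutant shift map into mutant->original
#' @noRd
invert_map <- function(map) {
  data.frame(start = map$start + map$shift, shift = -map$shift)
}

#' Generate two diverged parental genomes
#'
#' Genome A is random sequence; genome B is genome A mutated at the
#' configured substitution and 1--3 bp indel rates. Every difference is
#' recorded as a diagnostic site with coordinates in both genome spaces,
#' and piecewise coordinate-shift maps between A-space and B-space are
#' returned so intervals can be lifted across.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `parental_genomes` with elements `genome_a`,
#'   `genome_b` ([Biostrings::DNAStringSet]), `sites` (data.frame: `chrom`,
#'   `pos_a`, `pos_b`, `type` in sub/ins/del, `len`, `ref_a`, `ref_b`), and
#'   per-chromosome coordinate maps `map_a2b`, `map_b2a`.
#' @export
generate_parental_genomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed_for(cfg, "genomes"))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  seq_a <- character(cfg$n_chromosomes)
  seq_b <- character(cfg$n_chromosomes)
  map_a2b <- list(); map_b2a <- list()
  sites <- vector("list", cfg$n_chromosomes)
  for (i in seq_len(cfg$n_chromosomes)) {
    a <- paste(sample(DNA_BASES4, cfg$chrom_length, replace = TRUE),
               collapse = "")
    ev <- mutate_events(cfg$chrom_length, cfg$divergence,
                        cfg$indel_divergence)
    mut <- apply_events(a, ev)
    seq_a[i] <- a
    seq_b[i] <- mut$seq
    map_a2b[[chroms[i]]] <- mut$map
    map_b2a[[chroms[i]]] <- invert_map(mut$map)
    d <- mut$detail
    sites[[i]] <- data.frame(
      chrom = rep(chroms[i], nrow(d)),
      pos_a = d$pos, pos_b = d$pos_b, type = d$type, len = d$len,
      ref_a = d$ref, ref_b = d$alt, stringsAsFactors = FALSE)
  }
  ga <- Biostrings::DNAStringSet(seq_a); names(ga) <- chroms
  gb <- Biostrings::DNAStringSet(seq_b); names(gb) <- chroms
  structure(list(genome_a = ga, genome_b = gb,
                 sites = do.call(rbind, sites),
                 map_a2b = map_a2b, map_b2a = map_b2a),
            class = "parental_genomes")
}

#' Lay out transcripts with expression levels and parental origin
#'
#' Places non-overlapping transcripts on the shared coordinate space
#' (A-space), assigns each a gene symbol (a configurable fraction get
#' LOC-style uncharacterized symbols), a log-normal expression level, and a
#' hybrid parent-of-origin mixture: monoallelic transcripts are expressed
#' entirely from one parental genome, biallelic ones 50/50.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [generate_parental_genomes()].
#' @return data.frame with columns `transcript_id`, `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive, A-space), `length`, `level`
#'   (FPKM-like), `frac_a` (proportion of hybrid reads drawn from genome A),
#'   `origin_class` (`mono_A`, `mono_B`, `biallelic`).
#' @export
simulate_transcripts <- function(cfg, genomes) {
  stopifnot(inherits(cfg, "sim_config"))
  force(genomes)  # evaluate before seeding: arguments may consume the RNG
  set.seed(seed_for(cfg, "transcripts"))
  chroms <- names(genomes$genome_a)
  out <- list(); placed <- 0L; ci <- 0L
  cursor <- stats::setNames(rep(1L, length(chroms)), chroms)
  exhausted <- stats::setNames(rep(FALSE, length(chroms)), chroms)
  while (placed < cfg$n_transcripts && !all(exhausted)) {
    ci <- ci %% length(chroms) + 1L
    ch <- chroms[ci]
    if (exhausted[ch]) next
    gap <- sample(200:800, 1L)
    len <- sample(cfg$transcript_length_range[1]:cfg$transcript_length_range[2], 1L)
    start <- cursor[ch] + gap
    end <- start + len - 1L
    if (end > cfg$chrom_length - 200L) { exhausted[ch] <- TRUE; next }
    cursor[ch] <- end + 1L
    placed <- placed + 1L
    out[[placed]] <- data.frame(chrom = ch, start = start, end = end,
                                length = len)
  }
  if (placed < cfg$n_transcripts)
    warning("only ", placed, " of ", cfg$n_transcripts,
            " transcripts fitted on the genome")
  tx <- do.call(rbind, out)
  n <- nrow(tx)
  tx$transcript_id <- sprintf("TX%04d", seq_len(n))
  n_loc <- round(cfg$frac_uncharacterized * n)
  sym <- sprintf("GENE%04d", seq_len(n))
  if (n_loc > 0)
    sym[sample.int(n, n_loc)] <- sprintf("LOC%06d", sample.int(899999, n_loc) + 100000L)
  tx$gene <- sym
  tx$level <- stats::rlnorm(n, meanlog = 2, sdlog = 1.2)
  mono <- stats::runif(n) < cfg$frac_mono_transcripts
  from_a <- stats::runif(n) < 0.5
  tx$origin_class <- ifelse(mono, ifelse(from_a, "mono_A", "mono_B"),
                            "biallelic")
  tx$frac_a <- ifelse(mono, ifelse(from_a, 1, 0), 0.5)
  tx[, c("transcript_id", "gene", "chrom", "start", "end", "length",
         "level", "frac_a", "origin_class")]
}

#' Simulate hybrid reads of mixed parental origin
#'
#' Draws reads from transcripts with probability proportional to
#' expression level times length; each read's parental genome is chosen
#' from its transcript's origin mixture, the sequence is taken from that
#' genome (transcript coordinates lifted to B-space for B-origin reads),
#' and indel-prone sequencing errors are applied at the configured rates.
#' Reads longer than their transcript are truncated to the transcript.
#'
#' @param cfg a [sim_config()].
#' @param genomes output of [generate_parental_genomes()].
#' @param transcripts output of [simulate_transcripts()].
#' @return a list of class `hybrid_reads`: `reads` (named character vector
#'   of read sequences) and `truth` (data.frame: `read_id`, `origin` A|B,
#'   `transcript_id`, `chrom`, `start`, `end` -- 0-based half-open on the
#'   source genome -- plus 1-based source intervals in both coordinate
#'   spaces `start_a`, `end_a`, `start_b`, `end_b`, the extended
#'   read-vs-source CIGAR `err_cigar`, and error counts).
#' @export
simulate_hybrid_reads <- function(cfg, genomes, transcripts) {
  stopifnot(inherits(cfg, "sim_config"))
  force(genomes); force(transcripts)  # lazy args must not consume the RNG
  set.seed(seed_for(cfg, "reads"))
  n <- cfg$n_reads
  truth <- data.frame(read_id = character(0), origin = character(0),
                      transcript_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      err_cigar = character(0), n_sub_err = integer(0),
                      n_indel_err = integer(0))
  if (n == 0L)
    return(structure(list(reads = character(0), truth = truth),
                     class = "hybrid_reads"))
  tx <- transcripts
  pick <- sample.int(nrow(tx), n, replace = TRUE, prob = tx$level * tx$length)
  origin <- ifelse(stats::runif(n) < tx$frac_a[pick], "A", "B")
  reads <- character(n)
  rows <- vector("list", n)
  chr_a <- as.character(genomes$genome_a)
  chr_b <- as.character(genomes$genome_b)
  for (i in seq_len(n)) {
    t <- tx[pick[i], ]
    ch <- t$chrom
    if (origin[i] == "A") {
      ts <- t$start; te <- t$end
    } else {
      ts <- map_pos(genomes$map_a2b[[ch]], t$start)
      te <- map_pos(genomes$map_a2b[[ch]], t$end)
      te <- min(te, nchar(chr_b[[ch]]))
    }
    tl <- te - ts + 1L
    rl <- min(cfg$read_length, tl)
    s <- ts + sample.int(tl - rl + 1L, 1L) - 1L
    e <- s + rl - 1L
    src <- if (origin[i] == "A") substr(chr_a[[ch]], s, e)
           else substr(chr_b[[ch]], s, e)
    ev <- mutate_events(rl, cfg$seq_error_sub, cfg$seq_error_indel)
    mut <- apply_events(src, ev)
    reads[i] <- mut$seq
    if (origin[i] == "A") {
      sa <- s; ea <- e
      sb <- map_pos(genomes$map_a2b[[ch]], s)
      eb <- map_pos(genomes$map_a2b[[ch]], e)
    } else {
      sb <- s; eb <- e
      sa <- map_pos(genomes$map_b2a[[ch]], s)
      ea <- map_pos(genomes$map_b2a[[ch]], e)
    }
    rows[[i]] <- data.frame(
      read_id = sprintf("read%06d", i), origin = origin[i],
      transcript_id = t$transcript_id, chrom = ch,
      start = s - 1L, end = e,
      start_a = sa, end_a = ea, start_b = sb, end_b = eb,
      err_cigar = mut$cigar,
      n_sub_err = sum(ev$type == "sub"),
      n_indel_err = sum(ev$type != "sub"))
  }
  truth <- do.call(rbind, rows)
  names(reads) <- truth$read_id
  structure(list(reads = reads, truth = truth), class = "hybrid_reads")
}

#' Write genomes, transcripts, reads and truth tables to disk
#'
#' FASTA is 60-column wrapped; FASTQ uses a constant Phred+33 quality;
#' transcripts are written as GFF3 `transcript` features with `gene=`
#' attributes; the read truth table is a TSV with 0-based half-open
#' coordinates.
#'
#' @param genomes,transcripts,reads simulator outputs.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulated_inputs <- function(genomes, transcripts, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome_a = file.path(dir, "genome_A.fa"),
    genome_b = file.path(dir, "genome_B.fa"),
    gff = file.path(dir, "transcripts.gff3"),
    fastq = file.path(dir, "reads.fastq"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    truth_transcripts = file.path(dir, "truth_transcripts.tsv"))
  Biostrings::writeXStringSet(genomes$genome_a, paths$genome_a, width = 60L)
  Biostrings::writeXStringSet(genomes$genome_b, paths$genome_b, width = 60L)
  gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(transcripts$start, transcripts$end),
    strand = "+", type = "transcript",
    ID = transcripts$transcript_id, gene = transcripts$gene)
  rtracklayer::export(gr, paths$gff, format = "gff3")
  if (length(reads$reads) > 0) {
    dss <- Biostrings::DNAStringSet(reads$reads)
    quals <- Biostrings::BStringSet(strrep("I", nchar(reads$reads)))
    Biostrings::writeXStringSet(dss, paths$fastq, format = "fastq",
                                qualities = quals)
  } else {
    file.create(paths$fastq)
  }
  utils::write.table(
    reads$truth[, c("read_id", "origin", "chrom", "start", "end")],
    paths$truth_reads, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(transcripts, paths$truth_transcripts, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
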