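# small simulation configurations shared across test files

tiny_cfg <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L, chrom_length = 30000L,
                   n_transcripts = 12L, n_reads = 300L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# independent three-key lexicographic comparison used as the comparator
# oracle: more matching wins, then fewer indels, then fewer clips
oracle_compare <- function(a, b) {
  ka <- c(-a$matching, a$indels, a$clipped)
  kb <- c(-b$matching, b$indels, b$clipped)
  for (j in 1:3) {
    if (ka[j] < kb[j]) return("A")
    if (ka[j] > kb[j]) return("B")
  }
  "tie"
}

# random plausible CIGAR strings with controllable score components
random_cigars <- function(n, seed = 1) {
  set.seed(seed)
  m <- sample(80:100, n, replace = TRUE)
  i <- sample(0:2, n, replace = TRUE)
  s <- sample(0:4, n, replace = TRUE)
  paste0(pmax(m - 10, 1), "M",
         ifelse(i > 0, paste0(i, "I"), ""),
         "10M",
         ifelse(s > 0, paste0(s, "S"), ""))
}
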