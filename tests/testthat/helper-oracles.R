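# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (plain R loops over all windows / all read pairs) so
# they stay independent of the implementation paths they check.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# exhaustive double-strand Hamming scan over all windows of all regions
naive_map <- function(seq, refs, max_mm) {
  n <- nchar(seq)
  rows <- list()
  for (rn in region_names(refs)) {
    ref <- region_seq(refs, rn)
    L <- nchar(ref)
    if (n > L) next
    rc <- revcomp_chr(seq)
    for (s in 0:(L - n)) {
      win <- strsplit(substr(ref, s + 1L, s + n), "")[[1L]]
      for (strand in c("+", "-")) {
        pat <- strsplit(if (strand == "+") seq else rc, "")[[1L]]
        mm <- sum(win != pat)
        if (mm <= max_mm)
          rows[[length(rows) + 1L]] <- data.frame(
            region = rn, start = s, end = s + n, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(region = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$region, region_names(refs)), out$start,
                   match(out$strand, c("+", "-"))), ]
  rownames(out) <- NULL
  out
}

# exhaustive pairwise 5'-overlap enumeration over retained hits of a region
naive_pair_counts <- function(map, nf, region, window, K) {
  h <- map$hits[map$hits$retained & map$hits$region == region &
                  map$hits$length >= window[1] &
                  map$hits$length <= window[2], ]
  s <- h[h$strand == "+", ]
  a <- h[h$strand == "-", ]
  pc <- numeric(K)
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(a))) {
      k <- (a$end[j] - 1L) - s$start[i] + 1L
      if (k >= 1L && k <= K)
        pc[k] <- pc[k] + (s$mult[i] * nf) * (a$mult[j] * nf)
    }
  }
  pc
}

# small reference set with one analysis region plus category regions
tiny_refs <- function(seed = 42L, analysis_len = 400L) {
  set.seed(seed)
  reference_set(
    c(locus = rand_seq(analysis_len), gen = rand_seq(300),
      misc = rand_seq(120), trn = rand_seq(100), mir = rand_seq(110)),
    roles = c(locus = "analysis", gen = "normalization_genome",
              misc = "miscRNA", trn = "tRNA", mir = "miRNA"))
}

# a coverage_profile built directly from 5'-end count vectors
fake_profile <- function(sense, antisense, region = "locus",
                         window = c(23L, 29L)) {
  structure(list(region = region, window = as.integer(window),
                 sense = sense, antisense = antisense, norm_factor = 1),
            class = "coverage_profile")
}

# small simulation config: single 2-kb locus, no background (norm factor 1)
bare_config <- function(seed, d_max = 1000, strand_ratio = 0.5,
                        conversion = 0.45, one_u_bias = 0.75,
                        pingpong_fraction = 0.25, sirna_fraction = 0.2,
                        mismatch_fraction = 0, locus_len = 2000L) {
  simulation_config(
    seed = seed,
    references = list(locus = list(length = locus_len, role = "analysis")),
    regions = list(locus = list(d_max = d_max, strand_ratio = strand_ratio,
                                conversion = conversion)),
    pirna = list(lengths = 23:29,
                 length_probs = c(0.06, 0.12, 0.20, 0.26, 0.20, 0.10, 0.06),
                 one_u_bias = one_u_bias,
                 pingpong_fraction = pingpong_fraction),
    sirna = list(fraction_21nt = sirna_fraction),
    mismatch = list(read_fraction = mismatch_fraction, n_mismatches = 3L),
    background = list(genome = 0L, miscRNA = 0L, tRNA = 0L, miRNA = 0L))
}

# simulate -> trim -> map for a bare config
bare_map <- function(cfg, generation = 1L, lineage = "paternal",
                     max_mm = 0L) {
  refs <- make_references(cfg)
  sim <- simulate_library(cfg, generation, lineage, refs = refs)
  tl <- trim_library(sim$reads, cfg$adapter)
  list(map = map_library(tl$reads, refs, max_mm = max_mm), sim = sim,
       refs = refs)
}
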