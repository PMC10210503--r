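# Seeded generator of every input the pipeline consumes: reference
# sequences, small RNA libraries with a 23-29-nt piRNA mode, a 21-nt siRNA
# component, tunable 1U bias, strand ratio, ping-pong pairing and background
# normalization categories; egg-chamber count tables; qPCR plate tables.
# Conversion over generations follows a per-generation Bernoulli model:
# density(g) = D_max * (1 - (1 - c)^g) for paternal lineages, D_max for
# maternal ones.

.seed_offset <- function(seed, offset) {
  (as.integer(seed) %% 2097152L) * 1000L + as.integer(offset)
}

#' Simulation configuration
#'
#' Defaults mirror the experimental system under study: an 18-kb
#' multi-domain transgene (with 3.5-kb reporter, 1.8-kb plasmid backbone and
#' short terminal P-element domains), a 0.9-kb unique subtelomeric domain
#' with strongly asymmetric strand output, a 4.1-kb eye-color gene, a 20-kb
#' genome background containing embedded miscRNA/tRNA/miRNA category
#' regions, and a per-generation conversion probability of 0.45 which
#' approaches the plateau density in about four generations.
#'
#' @param seed Integer seed; every simulated artifact is reproducible from
#'   it.
#' @param ... Top-level overrides merged into the default list (via
#'   [utils::modifyList()]).
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    adapter = "TGGAATTCTCGGGTGCCAAG",
    trim = list(min_len = 18L, max_len = 30L),
    references = list(
      plarb = list(length = 18000L, role = "analysis",
                   subregions = list(P5 = c(0L, 580L),
                                     lacZ = c(580L, 4080L),
                                     rosy = c(4080L, 11280L),
                                     Adh = c(11280L, 15970L),
                                     plasmid = c(15970L, 17770L),
                                     P3 = c(17770L, 18000L))),
      T3 = list(length = 900L, role = "analysis"),
      white = list(length = 4100L, role = "analysis"),
      genome_bg = list(length = 20000L, role = "normalization_genome",
                       subregions = list(miscRNA_bg = c(2000L, 5000L),
                                         tRNA_bg = c(6000L, 7500L),
                                         miRNA_bg = c(8000L, 10000L))),
      flank = list(length = 2000L, role = "flanking")),
    category_regions = c(miscRNA_bg = "miscRNA", tRNA_bg = "tRNA",
                         miRNA_bg = "miRNA"),
    regions = list(
      plarb = list(d_max = 1500, strand_ratio = 0.5, conversion = 0.45),
      T3 = list(d_max = 2500, strand_ratio = 0.9, conversion = 1.0),
      white = list(d_max = 1600, strand_ratio = 0.5, conversion = 0.45)),
    pirna = list(lengths = 23:29,
                 length_probs = c(0.06, 0.12, 0.20, 0.26, 0.20, 0.10, 0.06),
                 one_u_bias = 0.75, pingpong_fraction = 0.25),
    sirna = list(fraction_21nt = 0.2),
    mismatch = list(read_fraction = 0.05, n_mismatches = 3L),
    background = list(genome = 13500L, miscRNA = 3000L, tRNA = 1500L,
                      miRNA = 2000L),
    egg = list(sublines = 4L, chambers = 150L, p_max = 0.95,
               conversion = 0.45),
    qpcr = list(input_fraction = 0.05, ct_noise_sd = 0.1, n_bio = 3L,
                n_tech = 3L,
                chip_enrichment = c("42AB" = 25, plarb_MI = 18,
                                    plarb_PI = 4, T3_MI = 20, T3_PI = 15),
                rt_ratio = c(plarb = 0.8, T3 = 0.5),
                reference_gene = "RpL32"))
  dots <- list(...)
  # reference and region layouts are replaced outright; everything else is
  # merged key-wise so partial overrides (e.g. pirna$one_u_bias) work
  whole <- intersect(names(dots), c("references", "regions"))
  cfg <- utils::modifyList(cfg, dots[setdiff(names(dots), whole)])
  cfg[whole] <- dots[whole]
  cfg
}

# expected normalization factor implied by the configured background.
# All background reads are drawn from the genome background region (the
# category regions are embedded in it), so genome = sum of all categories
# and the denominator subtracts miscRNA and tRNA. When every background
# count is zero the generator emits unnormalized libraries (factor 1) and
# density targets are interpreted as raw reads/kb.
.expected_nf <- function(cfg) {
  bg <- cfg$background
  tot <- bg$genome + bg$miscRNA + bg$tRNA + bg$miRNA
  if (tot == 0L) return(1)
  denom <- tot - bg$miscRNA - bg$tRNA
  if (denom <= 0) stop("configured background yields an empty denominator")
  1e6 / denom
}

#' Generate the reference set
#'
#' Random sequences at the configured lengths, reproducible from the seed.
#' Category regions (miscRNA/tRNA/miRNA) are slices of the genome
#' background, so their reads also count as genome-matching, as required by
#' the normalization denominator. Sub-region coordinates are returned as a
#' BED-style annotation (and written alongside the FASTA when `dir` is
#' given).
#'
#' @param cfg A [simulation_config()].
#' @param dir Optional output directory; writes `references.fasta` and
#'   `subregions.bed`.
#' @return A [reference_set()] with a `"subregions"` attribute (BED data
#'   frame) and a `"files"` attribute when written.
#' @export
make_references <- function(cfg, dir = NULL) {
  set.seed(.seed_offset(cfg$seed, 0L))
  chars <- list()
  roles <- character()
  bed <- list()
  for (rn in names(cfg$references)) {
    def <- cfg$references[[rn]]
    chars[[rn]] <- paste(sample(c("A", "C", "G", "T"), def$length,
                                replace = TRUE), collapse = "")
    roles[rn] <- def$role
    for (sn in names(def$subregions)) {
      co <- def$subregions[[sn]]
      if (co[1L] < 0L || co[2L] > def$length || co[1L] >= co[2L])
        stop("sub-region ", sn, " outside parent region ", rn)
      bed[[length(bed) + 1L]] <- data.frame(
        region = rn, start = co[1L], end = co[2L], name = sn,
        stringsAsFactors = FALSE)
    }
  }
  # category regions are substrings of the genome background
  gdef <- cfg$references$genome_bg
  for (cn in if (is.null(gdef)) character() else
       names(cfg$category_regions)) {
    co <- gdef$subregions[[cn]]
    if (is.null(co)) stop("category region not embedded in background: ", cn)
    chars[[cn]] <- substr(chars[["genome_bg"]], co[1L] + 1L, co[2L])
    roles[cn] <- unname(cfg$category_regions[cn])
  }
  refs <- reference_set(unlist(chars), roles)
  bed <- if (length(bed)) do.call(rbind, bed) else
    data.frame(region = character(), start = integer(), end = integer(),
               name = character(), stringsAsFactors = FALSE)
  attr(refs, "subregions") <- bed
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "references.fasta")
    desc <- stats::setNames(
      sprintf("seed=%d role=%s", cfg$seed, refs$info$role), refs$info$name)
    write_fasta(refs, fa, descriptions = desc)
    bedf <- file.path(dir, "subregions.bed")
    write_table(bed, bedf, comment = sprintf("seed=%d", cfg$seed))
    rolesf <- file.path(dir, "reference_roles.tsv")
    write_table(refs$info[, c("name", "role")], rolesf,
                comment = sprintf("seed=%d", cfg$seed))
    attr(refs, "files") <- c(fasta = fa, bed = bedf, roles = rolesf)
  }
  refs
}

# sample n 5'-end positions in [lo, hi] (0-based), preferring positions
# whose reference base equals `want` with probability `bias`
.biased_positions <- function(n, lo, hi, chars, want, bias) {
  if (n == 0L) return(integer())
  rng <- lo:hi
  is_want <- chars[rng + 1L] == want
  cand_y <- rng[is_want]
  cand_n <- rng[!is_want]
  forced <- stats::runif(n) < bias & length(cand_y) > 0L
  pos <- integer(n)
  if (any(forced))
    pos[forced] <- cand_y[sample.int(length(cand_y), sum(forced),
                                     replace = TRUE)]
  if (any(!forced)) {
    pool <- if (length(cand_n)) cand_n else rng
    pos[!forced] <- pool[sample.int(length(pool), sum(!forced),
                                    replace = TRUE)]
  }
  pos
}

# inject k random substitutions into a sequence
.mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(ch), min(k, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate one small RNA library
#'
#' Draws piRNA-window reads per analysis region at the generation-dependent
#' density target, with the configured length distribution, strand ratio,
#' 1U bias (the 5' base is uridine with exactly probability `one_u_bias`,
#' implemented by biased placement so every read remains a perfect reference
#' substring), and ping-pong structure (a `pingpong_fraction` of antisense
#' reads get their 5' end exactly 9 bp downstream of a sampled sense
#' partner's 5' end, the 10-nt overlap register). A 21-nt siRNA component is
#' emitted on both strands at a generation-independent density, a configured
#' fraction of piRNA reads receive random substitutions, background reads
#' are appended from the normalization category regions, and the 3' adapter
#' is appended to every read.
#'
#' @param cfg A [simulation_config()].
#' @param generation Generation number (>= 1).
#' @param lineage `"paternal"` (geometric approach to the plateau) or
#'   `"maternal"` (at plateau from G1).
#' @param refs Reference set from [make_references()] (regenerated from the
#'   config when omitted).
#' @param fastq,truth Optional output paths for the FASTQ and the truth
#'   table.
#' @return List: `reads` (data frame `id`, `seq`, `qual` with adapter
#'   appended), `truth` (one row per read with every generating parameter),
#'   `expected` (list with the expected normalization factor and the
#'   per-region density targets).
#' @export
simulate_library <- function(cfg, generation, lineage = c("paternal",
                                                          "maternal"),
                             refs = NULL, fastq = NULL, truth = NULL) {
  lineage <- match.arg(lineage)
  stopifnot(generation >= 1L)
  if (is.null(refs)) refs <- make_references(cfg)
  set.seed(.seed_offset(cfg$seed,
                        generation * 8L +
                          (lineage == "maternal") * 4L + 1L))
  nf <- .expected_nf(cfg)
  pir <- cfg$pirna
  rows <- list()
  targets <- numeric()

  for (rn in names(cfg$regions)) {
    par <- cfg$regions[[rn]]
    L <- region_length(refs, rn)
    chars <- strsplit(region_seq(refs, rn), "", fixed = TRUE)[[1L]]
    dens <- if (lineage == "maternal") par$d_max else
      par$d_max * (1 - (1 - par$conversion)^generation)
    targets[rn] <- dens
    n_pi <- stats::rpois(1L, dens * (L / 1000) / nf)
    if (n_pi > 0L) {
      lens <- sample(pir$lengths, n_pi, replace = TRUE,
                     prob = pir$length_probs)
      sense <- stats::runif(n_pi) < par$strand_ratio
      start <- integer(n_pi)
      pp <- logical(n_pi)
      # sense reads: 5' end at a T with probability one_u_bias
      for (len in unique(lens[sense])) {
        idx <- which(sense & lens == len)
        start[idx] <- .biased_positions(length(idx), 0L, L - len, chars,
                                        "T", pir$one_u_bias)
      }
      sense_p <- start[sense]
      anti_idx <- which(!sense)
      if (length(anti_idx)) {
        pp_flag <- stats::runif(length(anti_idx)) < pir$pingpong_fraction &
          length(sense_p) > 0L
        for (j in seq_along(anti_idx)) {
          i <- anti_idx[j]
          len <- lens[i]
          if (pp_flag[j]) {
            # partner sense 5' p, antisense 5' at q = p + 9
            cand <- sense_p[sense_p >= len - 10L & sense_p <= L - 10L]
            if (length(cand)) {
              cand_t <- cand[chars[cand + 10L] == "A"]
              p <- if (stats::runif(1L) < pir$one_u_bias &&
                       length(cand_t) > 0L)
                cand_t[sample.int(length(cand_t), 1L)] else
                  cand[sample.int(length(cand), 1L)]
              q <- p + 9L
              start[i] <- q - len + 1L
              pp[i] <- TRUE
              next
            }
          }
          q <- .biased_positions(1L, len - 1L, L - 1L, chars, "A",
                                 pir$one_u_bias)
          start[i] <- q - len + 1L
        }
      }
      seqs <- substr(rep(region_seq(refs, rn), n_pi), start + 1L,
                     start + lens)
      seqs[!sense] <- .revcomp(seqs[!sense])
      n_mm <- integer(n_pi)
      mut <- stats::runif(n_pi) < cfg$mismatch$read_fraction
      if (any(mut)) {
        seqs[mut] <- vapply(seqs[mut], .mutate_seq, character(1),
                            k = cfg$mismatch$n_mismatches)
        n_mm[mut] <- cfg$mismatch$n_mismatches
      }
      rows[[paste0(rn, "_pi")]] <- data.frame(
        category = "pirna", region = rn,
        strand = ifelse(sense, "+", "-"), start = start, length = lens,
        seq = seqs, pingpong = pp, n_mismatches = n_mm,
        stringsAsFactors = FALSE)
    }
    # generation-independent 21-nt siRNA component, both strands
    n_si <- stats::rpois(1L,
                         cfg$sirna$fraction_21nt * par$d_max *
                           (L / 1000) / nf)
    if (n_si > 0L && L >= 21L) {
      s_start <- sample.int(L - 21L + 1L, n_si, replace = TRUE) - 1L
      s_sense <- stats::runif(n_si) < 0.5
      s_seq <- substr(rep(region_seq(refs, rn), n_si), s_start + 1L,
                      s_start + 21L)
      s_seq[!s_sense] <- .revcomp(s_seq[!s_sense])
      rows[[paste0(rn, "_si")]] <- data.frame(
        category = "sirna", region = rn,
        strand = ifelse(s_sense, "+", "-"), start = s_start, length = 21L,
        seq = s_seq, pingpong = FALSE, n_mismatches = 0L,
        stringsAsFactors = FALSE)
    }
  }

  # background reads for the normalization categories; genome-only reads are
  # rejected out of the embedded category slices so each category count
  # stays interpretable
  bg <- cfg$background
  if (any(unlist(bg) > 0L)) {
  gdef <- cfg$references$genome_bg
  if (is.null(gdef))
    stop("background reads require a genome_bg reference region")
  g_seq <- region_seq(refs, "genome_bg")
  g_len <- nchar(g_seq)
  slices <- gdef$subregions[names(cfg$category_regions)]
  draw_bg <- function(n, category, src_region, lo_len = 18L,
                      hi_len = 30L) {
    if (n == 0L) return(NULL)
    src <- region_seq(refs, src_region)
    Ls <- nchar(src)
    lens <- sample(lo_len:hi_len, n, replace = TRUE)
    starts <- vapply(lens, function(l)
      sample.int(Ls - l + 1L, 1L) - 1L, integer(1))
    data.frame(category = category, region = src_region, strand = "+",
               start = starts, length = lens,
               seq = substr(rep(src, n), starts + 1L, starts + lens),
               pingpong = FALSE, n_mismatches = 0L,
               stringsAsFactors = FALSE)
  }
  n_gen <- if (bg$genome > 0L) stats::rpois(1L, bg$genome) else 0L
  if (n_gen > 0L) {
    lens <- sample(18:30, n_gen, replace = TRUE)
    starts <- integer(n_gen)
    for (j in seq_len(n_gen)) {
      repeat {
        s <- sample.int(g_len - lens[j] + 1L, 1L) - 1L
        inside <- vapply(slices, function(co)
          s >= co[1L] && s + lens[j] <= co[2L], logical(1))
        if (!any(inside)) break
      }
      starts[j] <- s
    }
    rows[["bg_genome"]] <- data.frame(
      category = "background_genome", region = "genome_bg", strand = "+",
      start = starts, length = lens,
      seq = substr(rep(g_seq, n_gen), starts + 1L, starts + lens),
      pingpong = FALSE, n_mismatches = 0L, stringsAsFactors = FALSE)
  }
  rows[["bg_misc"]] <- if (bg$miscRNA > 0L)
    draw_bg(stats::rpois(1L, bg$miscRNA), "background_miscRNA",
            "miscRNA_bg") else NULL
  rows[["bg_trna"]] <- if (bg$tRNA > 0L)
    draw_bg(stats::rpois(1L, bg$tRNA), "background_tRNA", "tRNA_bg") else
      NULL
  rows[["bg_mirna"]] <- if (bg$miRNA > 0L)
    draw_bg(stats::rpois(1L, bg$miRNA), "background_miRNA", "miRNA_bg",
            21L, 23L) else NULL
  }

  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), region = character(),
               strand = character(), start = integer(), length = integer(),
               seq = character(), pingpong = logical(),
               n_mismatches = integer(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  tab$id <- sprintf("sim_%s_g%d_%06d", substr(lineage, 1L, 3L), generation,
                    seq_len(nrow(tab)))
  tab$first_nt <- substr(tab$seq, 1L, 1L)
  reads <- data.frame(id = tab$id,
                      seq = paste0(tab$seq, cfg$adapter),
                      qual = strrep("I", nchar(tab$seq) +
                                      nchar(cfg$adapter)),
                      stringsAsFactors = FALSE)
  truth_tab <- tab[, c("id", "category", "region", "strand", "start",
                       "length", "first_nt", "pingpong", "n_mismatches")]
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth))
    write_table(truth_tab, truth,
                comment = sprintf("seed=%d generation=%d lineage=%s",
                                  cfg$seed, generation, lineage))
  list(reads = reads, truth = truth_tab,
       expected = list(norm_factor = nf, density_targets = targets,
                       generation = generation, lineage = lineage))
}

#' Simulate egg-chamber repression counts
#'
#' Each chamber is independently repressed with probability
#' `p_g = 1 - (1 - c)^g` for paternal lineages or `p_max` for maternal
#' ones; per-subline totals are Poisson around the configured chamber count
#' and repressed counts are binomial draws.
#'
#' @param cfg A [simulation_config()].
#' @param generations Integer vector of generations.
#' @param lineage `"paternal"` or `"maternal"`.
#' @return Data frame: `lineage`, `generation`, `subline`, `stage_window`,
#'   `n_total`, `n_repressed`, `p_true`.
#' @export
simulate_egg_chambers <- function(cfg, generations = 1:4,
                                  lineage = c("paternal", "maternal")) {
  lineage <- match.arg(lineage)
  set.seed(.seed_offset(cfg$seed, 300L + (lineage == "maternal")))
  egg <- cfg$egg
  rows <- expand.grid(subline = paste0("S", seq_len(egg$sublines)),
                      generation = generations, stringsAsFactors = FALSE)
  rows$lineage <- lineage
  rows$stage_window <- "8-10"
  rows$p_true <- if (lineage == "maternal") egg$p_max else
    1 - (1 - egg$conversion)^rows$generation
  rows$n_total <- stats::rpois(nrow(rows), egg$chambers)
  rows$n_total[rows$n_total == 0L] <- 1L
  rows$n_repressed <- stats::rbinom(nrow(rows), rows$n_total, rows$p_true)
  rows[, c("lineage", "generation", "subline", "stage_window", "n_total",
           "n_repressed", "p_true")]
}

#' Simulate qPCR plate tables
#'
#' Ct and Sq values are generated by inverting the analysis formulas, so
#' that with zero noise the pipeline returns the configured fold
#' enrichments and RT ratios exactly; Gaussian noise of SD `noise_sd` is
#' added to each technical replicate Ct (multiplicative `2^noise` on Sq).
#'
#' @param cfg A [simulation_config()].
#' @param noise_sd Ct noise SD; defaults to the configured value.
#' @return List: `chip` (data frame `sample_id`, `region`, `mean_ct_chip`,
#'   `mean_ct_input`, `mean_ct_ns`, `input_fraction`), `rt` (long data
#'   frame `sample_id`, `gene`, `sq`), `truth` (configured enrichments and
#'   ratios).
#' @export
simulate_qpcr <- function(cfg, noise_sd = cfg$qpcr$ct_noise_sd) {
  set.seed(.seed_offset(cfg$seed, 400L))
  q <- cfg$qpcr
  dil <- 1 / q$input_fraction
  chip <- list()
  for (rg in names(q$chip_enrichment)) {
    E <- q$chip_enrichment[[rg]]
    for (b in seq_len(q$n_bio)) {
      ct_input <- mean(20 + stats::rnorm(2L, 0, noise_sd))
      ct_ns <- mean(28 + stats::rnorm(2L, 0, noise_sd))
      ct_chip <- mean(28 - log2(E) + stats::rnorm(2L, 0, noise_sd))
      chip[[paste(rg, b)]] <- data.frame(
        sample_id = paste0(rg, "_rep", b), region = rg,
        mean_ct_chip = ct_chip, mean_ct_input = ct_input,
        mean_ct_ns = ct_ns, input_fraction = q$input_fraction,
        stringsAsFactors = FALSE)
    }
  }
  rt <- list()
  for (gn in names(q$rt_ratio)) {
    r <- q$rt_ratio[[gn]]
    for (b in seq_len(q$n_bio)) {
      sid <- paste0(gn, "_rep", b)
      rt[[paste(gn, b, "g")]] <- data.frame(
        sample_id = sid, gene = gn,
        sq = r * 4 * 2^stats::rnorm(q$n_tech, 0, noise_sd),
        stringsAsFactors = FALSE)
      rt[[paste(gn, b, "r")]] <- data.frame(
        sample_id = sid, gene = q$reference_gene,
        sq = 4 * 2^stats::rnorm(q$n_tech, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(chip = do.call(rbind, c(chip, list(make.row.names = FALSE))),
       rt = do.call(rbind, c(rt, list(make.row.names = FALSE))),
       truth = list(chip_enrichment = q$chip_enrichment,
                    rt_ratio = q$rt_ratio))
}
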