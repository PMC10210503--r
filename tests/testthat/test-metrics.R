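# helper: a map with hand-placed reads on the tiny locus
place_reads <- function(refs, layout, unique_only = TRUE, max_mm = 0L) {
  # layout: data.frame(start 0-based, len, strand, n copies)
  ref <- region_seq(refs, "locus")
  seqs <- mapply(function(s, l, st) {
    w <- substr(ref, s + 1, s + l)
    if (st == "-") revcomp_chr(w) else w
  }, layout$start, layout$len, layout$strand)
  map_library(data.frame(seq = rep(seqs, layout$n)), refs,
              unique_only = unique_only, max_mm = max_mm)
}

test_that("size distribution places normalized counts in the right cells", {
  refs <- tiny_refs(31)
  ann <- library_annotation(2e6, 1e6) # norm factor 1
  m <- place_reads(refs, data.frame(start = 40, len = 26, strand = "+",
                                    n = 10))
  sd1 <- size_distribution(m, ann, "locus")
  expect_equal(sd1$count[sd1$length == 26 & sd1$strand == "sense"], 10)
  expect_equal(sum(sd1$count), 10)

  # equal sense/antisense reads give a symmetric distribution
  m2 <- place_reads(refs, data.frame(start = c(40, 80), len = c(25, 25),
                                     strand = c("+", "-"), n = c(4, 4)))
  sd2 <- size_distribution(m2, ann, "locus")
  expect_equal(sd2$count[sd2$strand == "sense"],
               sd2$count[sd2$strand == "antisense"])
})

test_that("simulated libraries peak at the configured 26-nt mode", {
  # at the plateau the piRNA mode towers over the constant siRNA component
  res <- bare_map(bare_config(32, d_max = 1500), lineage = "maternal")
  sd1 <- size_distribution(res$map, NULL, "locus")
  tot <- tapply(sd1$count, sd1$length, sum)
  expect_identical(names(which.max(tot)), "26")
})

test_that("coverage profiles record normalized 5' ends per strand", {
  refs <- tiny_refs(33)
  ann <- library_annotation(2e6, 5e5) # norm factor 2
  m <- place_reads(refs, data.frame(start = c(100, 130),
                                    len = c(26, 24),
                                    strand = c("+", "-"), n = c(3, 2)))
  prof <- coverage_profile(m, ann, "locus")
  expect_length(prof$sense, region_length(refs, "locus"))
  expect_equal(prof$sense[101], 6) # 3 reads x factor 2 at start 100
  expect_equal(sum(prof$sense), 6)
  # antisense 5' end sits at end - 1 = 130 + 24 - 1
  expect_equal(prof$antisense[130 + 24], 4)
  expect_equal(sum(prof$antisense), 4)

  # 21-nt reads fall outside the 23-29 window
  m21 <- place_reads(refs, data.frame(start = 50, len = 21, strand = "+",
                                      n = 5))
  expect_equal(sum(coverage_profile(m21, ann, "locus")$sense), 0)
})

test_that("density per kb follows the unit convention and 1U accounting", {
  set.seed(34)
  refs <- reference_set(c(locus = rand_seq(4100)), roles = "analysis")
  # choose starts by the reference base to fix the first nucleotide
  ref <- region_seq(refs, "locus")
  ch <- strsplit(ref, "")[[1]]
  tpos <- which(ch == "T")[1:2] - 1
  gpos <- which(ch == "G")[1] - 1
  stopifnot(all(c(tpos, gpos) < 4000))
  m <- place_reads(refs, data.frame(start = c(tpos, gpos), len = 26,
                                    strand = "+", n = 1))
  ann <- library_annotation(2e6, 1e6)
  d <- density_per_kb(m, ann, "locus")
  expect_equal(d$density, 3 / 4.1)
  expect_equal(d$one_u_fraction, 2 / 3)

  # the printed-unit worked example: 2698 normalized reads on 4.1 kb
  expect_equal(round(2698 / 4.1, 2), 658.05)

  # no mapped reads: zero density, flagged 1U
  m0 <- map_library(data.frame(seq = strrep("AC", 13)), refs)
  d0 <- density_per_kb(m0, ann, "locus")
  expect_equal(d0$density, 0)
  expect_false(d0$one_u_defined)
  expect_true(is.na(d0$one_u_fraction))
})

test_that("density is invariant to read order and multiplicity encoding", {
  res <- bare_map(bare_config(35, d_max = 800))
  ann <- NULL
  d1 <- density_per_kb(res$map, ann, "locus")
  # re-map with expanded (per-copy) representation in shuffled order
  tl <- trim_library(res$sim$reads)
  set.seed(1)
  shuffled <- tl$reads[sample(nrow(tl$reads)), ]
  d2 <- density_per_kb(map_library(shuffled, res$refs), ann, "locus")
  expect_equal(d2$density, d1$density)
  expect_equal(d2$one_u_fraction, d1$one_u_fraction)
})

test_that("generation ratios reproduce printed and constructed values", {
  ser <- conversion_series(c(1, 4), c(658, 1480))
  expect_equal(generation_ratio(ser, 1, 4), 2.25)
  expect_equal(generation_ratio(conversion_series(1:2, c(5, 5)), 1, 2), 1)
  growth <- conversion_series(1:4, 100 * 1.5^(0:3))
  expect_equal(generation_ratio(growth, 1, 4, digits = NULL), 3.375)
  expect_error(generation_ratio(ser, 1, 7), "not present")
})

test_that("conversion-rate fitting inverts the saturation model", {
  g <- 1:6
  d <- 1400 * (1 - (1 - 0.45)^g)
  est <- estimate_conversion_rate(conversion_series(g, d))
  expect_equal(est$c, 0.45, tolerance = 1e-6)
  expect_equal(est$D_max, 1400, tolerance = 1e-4)
  # a plateau series has successive post-plateau ratios near 1
  plateau <- conversion_series(1:5, c(700, 1280, 1390, 1398, 1400))
  expect_equal(generation_ratio(plateau, 4, 5, digits = NULL), 1,
               tolerance = 0.01)
})

test_that("overlap signature concentrates at the constructed register", {
  refs <- tiny_refs(36)
  ann <- library_annotation(2e6, 1e6)
  # sense 5' at p, antisense 5' at p + 9: a pure 10-nt overlap library
  m <- place_reads(refs, data.frame(start = c(100, 200, 85),
                                    len = c(26, 26, 25),
                                    strand = c("+", "+", "-"),
                                    n = c(2, 1, 3)))
  # antisense 5' end at start + len - 1 = 85 + 25 - 1 = 109 = 100 + 9
  prof <- coverage_profile(m, ann, "locus")
  sig <- overlap_signature(prof)
  expect_identical(which.max(sig$pair_counts), 10L)
  expect_identical(which.max(sig$zscores), 10L)
  expect_gt(sig$zscores[10], 0)
  # exhaustive pairwise enumeration gives identical pair counts
  expect_equal(sig$pair_counts,
               naive_pair_counts(m, ann$norm_factor, "locus", c(23, 29), 25))
})

test_that("overlap signature equals pair enumeration on random libraries", {
  set.seed(37)
  refs <- tiny_refs(37)
  for (rep in 1:5) {
    layout <- data.frame(start = sample(0:350, 30, replace = TRUE),
                       len = sample(23:29, 30, replace = TRUE),
                       strand = sample(c("+", "-"), 30, replace = TRUE),
                       n = sample(1:4, 30, replace = TRUE))
    m <- place_reads(refs, layout, unique_only = FALSE)
    ann <- library_annotation(2e6, 1e6)
    prof <- coverage_profile(m, ann, "locus")
    if (sum(prof$sense) == 0 || sum(prof$antisense) == 0) next
    sig <- overlap_signature(prof)
    expect_equal(sig$pair_counts,
                 naive_pair_counts(m, 1, "locus", c(23, 29), 25))
  }
})

test_that("flat pair counts are flagged degenerate", {
  # one sense spike against uniform antisense coverage: every register sees
  # exactly one pair, so the background has zero variance
  flat <- fake_profile(c(1, rep(0, 39)), rep(1, 40))
  sigf <- overlap_signature(flat, K = 25)
  expect_true(all(sigf$pair_counts == sigf$pair_counts[1]))
  expect_true(sigf$degenerate)
  expect_true(all(is.na(sigf$zscores)))
})

test_that("strand asymmetry classes follow the minority thresholds", {
  expect_identical(strand_asymmetry(fake_profile(50, 50))$class,
                   "symmetric_dual")
  expect_identical(strand_asymmetry(fake_profile(90, 10))$class,
                   "asymmetric_dual")
  expect_identical(strand_asymmetry(fake_profile(999, 1))$class,
                   "uni_strand")
  expect_equal(strand_asymmetry(fake_profile(90, 10))$sense_fraction, 0.9)
  expect_error(strand_asymmetry(fake_profile(0, 0)), "zero coverage")
})

test_that("sense fraction recovers the simulated strand ratio within 3 sigma", {
  for (s in c(0.5, 0.9)) {
    res <- bare_map(bare_config(38 + round(10 * s), d_max = 1500,
                                strand_ratio = s))
    prof <- coverage_profile(res$map, NULL, "locus")
    n <- sum(prof$sense) + sum(prof$antisense)
    sf <- sum(prof$sense) / n
    expect_lt(abs(sf - s), 3 * sqrt(s * (1 - s) / n) + 1e-9)
  }
})

test_that("siRNA/piRNA partition ratio and its undefined flag", {
  refs <- tiny_refs(39)
  ann <- library_annotation(2e6, 1e6)
  m <- place_reads(refs, data.frame(start = c(60, 120), len = c(26, 21),
                                    strand = "+", n = c(100, 50)))
  r <- sirna_pirna_ratio(m, ann, "locus")
  expect_equal(r$ratio, 2)
  expect_true(r$defined)

  m_no21 <- place_reads(refs, data.frame(start = 60, len = 26,
                                         strand = "+", n = 10))
  r0 <- sirna_pirna_ratio(m_no21, ann, "locus")
  expect_false(r0$defined)
  expect_true(is.na(r0$ratio))
})

test_that("the 23-29/21-nt ratio grows along a paternal conversion series", {
  cfg <- bare_config(40, d_max = 2000, sirna_fraction = 0.3)
  refs <- make_references(cfg)
  ratios <- vapply(c(1L, 4L), function(g) {
    sim <- simulate_library(cfg, g, "paternal", refs = refs)
    m <- map_library(trim_library(sim$reads)$reads, refs)
    sirna_pirna_ratio(m, NULL, "locus")$ratio
  }, numeric(1))
  expect_gt(ratios[2], ratios[1])
})

test_that("dinucleotide content counts overlapping windows", {
  p <- dinucleotide_content("ATAT")
  expect_equal(unname(p["AT"]), 2 / 3)
  expect_equal(unname(p["TA"]), 1 / 3)
  expect_equal(sum(p), 1)
  expect_equal(unname(dinucleotide_content("AAAA")["AA"]), 1)
  # windows containing N are skipped with an adjusted denominator
  pn <- dinucleotide_content("AANTT")
  expect_equal(unname(pn["AA"]), 0.5)
  expect_equal(unname(pn["TT"]), 0.5)
  expect_error(dinucleotide_content("A"), "length >= 2")
})

test_that("uniform sequence dinucleotide frequencies sit near 1/16", {
  set.seed(41)
  p <- dinucleotide_content(rand_seq(10000))
  se <- sqrt((1 / 16) * (15 / 16) / 9999)
  expect_true(all(abs(p - 1 / 16) < 3.5 * se))
})

test_that("the density regression recovers planted coefficients", {
  set.seed(42)
  hits <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    len <- runif(50, 0.5, 20)
    dens <- 100 - 5 * len + rnorm(50, 0, 1)
    fit <- fit_density_model(data.frame(density = dens, length_kb = len),
                             "length_kb")
    co <- fit$coefficients[fit$coefficients$term == "length_kb", ]
    ci <- co$estimate + c(-1, 1) * qt(0.975, 48) * co$std_error
    if (ci[1] <= -5 && -5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("degenerate regressions behave and error as specified", {
  set.seed(43)
  const <- data.frame(density = rep(7, 20) + rnorm(20, 0, 1e-8),
                      length_kb = runif(20, 1, 10))
  fit <- fit_density_model(const, "length_kb")
  co <- fit$coefficients[fit$coefficients$term == "length_kb", ]
  expect_lt(abs(co$estimate), 1e-6)
  expect_gt(co$p_value, 0.3)

  expect_error(fit_density_model(data.frame(density = 1:2,
                                            length_kb = 1:2),
                                 "length_kb"), "at least 3")
  dup <- data.frame(density = rnorm(10), a = 1:10, b = 1:10)
  expect_error(fit_density_model(dup, c("a", "b")), "collinear")
})
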