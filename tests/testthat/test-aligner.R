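test_that("identity windows map to a single exact hit on either strand", {
  refs <- tiny_refs(7)
  r <- substr(region_seq(refs, "locus"), 11, 36)
  h <- map_read(r, refs, 0)
  expect_identical(nrow(h), 1L)
  expect_identical(h$region, "locus")
  expect_identical(h$start, 10L)
  expect_identical(h$end, 36L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)

  hr <- map_read(revcomp_chr(r), refs, 0)
  expect_identical(hr[, c("region", "start", "end")],
                   h[, c("region", "start", "end")])
  expect_identical(hr$strand, "-")
})

test_that("mismatched windows appear only when max_mm allows them", {
  refs <- tiny_refs(8)
  r <- substr(region_seq(refs, "locus"), 101, 126)
  ch <- strsplit(r, "")[[1]]
  for (p in c(3, 12, 20)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  r3 <- paste(ch, collapse = "")
  h0 <- map_read(r3, refs, 0)
  h3 <- map_read(r3, refs, 3)
  expect_false(any(h0$start == 100 & h0$region == "locus"))
  expect_true(any(h3$start == 100 & h3$region == "locus" &
                    h3$mismatches == 3))
  # brute-force scan agrees on the full hit set
  expect_equal(h3, naive_map(r3, refs, 3))
})

test_that("map_read equals the exhaustive Hamming scan on random inputs", {
  set.seed(11)
  refs <- reference_set(c(a = rand_seq(300), b = rand_seq(150)),
                        roles = "analysis")
  for (i in 1:60) {
    n <- sample(18:30, 1)
    mm <- sample(0:3, 1)
    r <- if (i %% 2 == 0) {
      s <- sample(0:(300 - n), 1)
      w <- substr(region_seq(refs, "a"), s + 1, s + n)
      ch <- strsplit(w, "")[[1]]
      for (p in sample(n, sample(0:3, 1)))
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    } else rand_seq(n)
    expect_equal(map_read(r, refs, mm), naive_map(r, refs, mm))
  }
})

test_that("hit sets are monotone in the mismatch allowance", {
  set.seed(12)
  refs <- reference_set(c(a = rand_seq(250)), roles = "analysis")
  key <- function(h) paste(h$region, h$start, h$strand)
  for (i in 1:10) {
    s <- sample(0:(250 - 24), 1)
    w <- substr(region_seq(refs, "a"), s + 1, s + 24)
    ch <- strsplit(w, "")[[1]]
    for (p in sample(24, 2)) ch[p] <- sample(setdiff(c("A","C","G","T"),
                                                     ch[p]), 1)
    r <- paste(ch, collapse = "")
    hits <- lapply(0:3, function(mm) map_read(r, refs, mm))
    for (k in 1:3)
      expect_true(all(key(hits[[k]]) %in% key(hits[[k + 1]])))
  }
})

test_that("reverse-complement symmetry mirrors hit coordinates", {
  set.seed(13)
  S <- rand_seq(200)
  refs_f <- reference_set(c(a = S), roles = "analysis")
  refs_r <- reference_set(c(a = revcomp_chr(S)), roles = "analysis")
  key <- function(start, strand) sort(paste(start, strand))
  for (i in 1:10) {
    n <- sample(18:30, 1)
    s <- sample(0:(200 - n), 1)
    r <- substr(S, s + 1, s + n)
    h_f <- map_read(r, refs_f, 1)
    # revcomp(read) on revcomp(reference): positions mirror, strand is kept
    h_rc <- map_read(revcomp_chr(r), refs_r, 1)
    expect_identical(key(200L - h_f$end, h_f$strand),
                     key(h_rc$start, h_rc$strand))
    # the read itself on revcomp(reference): positions mirror, strand flips
    h_fl <- map_read(r, refs_r, 1)
    expect_identical(key(200L - h_f$end,
                         ifelse(h_f$strand == "+", "-", "+")),
                     key(h_fl$start, h_fl$strand))
  }
})

test_that("reads with N and overlong reads are handled per contract", {
  refs <- tiny_refs(9)
  expect_error(map_read("ACGTNACGTACGTACGTACGTACGT", refs, 0), "N")
  long_read <- rand_seq(500)
  expect_identical(nrow(map_read(long_read, refs, 0)), 0L)
})

test_that("map_library collapses multiplicities and excludes multi-mappers", {
  set.seed(14)
  core <- rand_seq(400)
  dup <- substr(core, 51, 76)
  tandem <- paste0(core, "TTTTTTTTTT", dup) # dup occurs twice
  refs <- reference_set(c(locus = tandem), roles = "analysis")
  uniq <- substr(core, 201, 226)

  m <- map_library(data.frame(seq = c(rep(uniq, 100), dup)), refs,
                   unique_only = TRUE)
  h <- m$hits[m$hits$retained, ]
  expect_identical(nrow(h), 1L)
  expect_identical(h$mult, 100L)
  expect_identical(h$seq, uniq)
  expect_identical(unname(m$counts["multi"]), 1L)

  m2 <- map_library(data.frame(seq = dup), refs, unique_only = FALSE)
  expect_identical(sum(m2$hits$retained), 2L)
})

test_that("uniqueness is judged on analysis regions only", {
  set.seed(15)
  shared <- rand_seq(26)
  refs <- reference_set(
    c(locus = paste0(rand_seq(100), shared, rand_seq(100)),
      gen = paste0(rand_seq(50), shared, rand_seq(50))),
    roles = c(locus = "analysis", gen = "normalization_genome"))
  m <- map_library(data.frame(seq = shared), refs, unique_only = TRUE)
  # two hits overall, but only one on an analysis region: read stays unique
  expect_identical(nrow(m$hits), 2L)
  expect_identical(sum(m$hits$retained), 1L)
  expect_identical(m$hits$region[m$hits$retained], "locus")
})

test_that("library mapping agrees with per-read mapping at 3 mismatches", {
  set.seed(16)
  refs <- reference_set(c(a = rand_seq(500)), roles = "analysis")
  reads <- vapply(1:30, function(i) {
    n <- sample(18:30, 1)
    s <- sample(0:(500 - n), 1)
    w <- substr(region_seq(refs, "a"), s + 1, s + n)
    ch <- strsplit(w, "")[[1]]
    for (p in sample(n, sample(0:3, 1)))
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1))
  m <- map_library(data.frame(seq = reads), refs, max_mm = 3,
                   unique_only = FALSE)
  for (r in unique(reads)) {
    h_lib <- m$hits[m$hits$seq == r, c("region", "start", "strand",
                                       "mismatches")]
    rownames(h_lib) <- NULL
    h_one <- map_read(r, refs, 3)[, c("region", "start", "strand",
                                      "mismatches")]
    expect_equal(h_lib, h_one)
  }
})
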