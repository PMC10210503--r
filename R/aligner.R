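# Ungapped, strand-aware, mismatch-tolerant matching of short reads against
# a small reference set. Correctness is defined by brute-force semantics: a
# hit is every (region, start, strand) whose Hamming distance between the
# read (or its reverse complement on "-") and the reference window is at most
# max_mm. Biostrings provides the scan; no heuristics, no random choices.

# mismatch counts of `seq` placed at 1-based starts in character `subject`
.hamming_at <- function(seq, subject, starts) {
  n <- nchar(seq)
  if (!length(starts)) return(integer())
  rb <- charToRaw(seq)
  vapply(starts, function(s) {
    sum(charToRaw(substr(subject, s, s + n - 1L)) != rb)
  }, integer(1))
}

# all (start0, strand, mismatches) of one pattern on one region
.scan_region <- function(seq, subj_dna, subj_chr, max_mm) {
  n <- nchar(seq)
  L <- nchar(subj_chr)
  out <- list()
  if (n <= L) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else .revcomp(seq)
      m <- Biostrings::matchPattern(pat, subj_dna, max.mismatch = max_mm,
                                    with.indels = FALSE)
      s <- Biostrings::start(m)
      s <- s[s >= 1L & s + n - 1L <= L]
      if (length(s)) {
        mm <- .hamming_at(pat, subj_chr, s)
        keep <- mm <= max_mm
        if (any(keep))
          out[[strand]] <- data.frame(start = s[keep] - 1L,
                                      strand = strand,
                                      mismatches = mm[keep],
                                      stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, unname(out))
}

.sort_hits <- function(hits, region_order) {
  if (!nrow(hits)) return(hits)
  o <- order(match(hits$region, region_order), hits$start,
             match(hits$strand, c("+", "-")))
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Map one read against a reference set
#'
#' Reports every ungapped placement of the read, on either strand, with at
#' most `max_mm` mismatches (Hamming distance; no indels). A `"+"` hit means
#' the read is sense to the reference as written; on `"-"` the reverse
#' complement of the read matches the reference window. Coordinates are
#' 0-based half-open. Hits are sorted by (region, start, strand) with regions
#' in reference-set order.
#'
#' @param seq Read sequence, `{A,C,G,T}` only (reads containing `N` are a
#'   precondition error: mismatch counting with `N` is ill-defined).
#' @param refs A [reference_set()].
#' @param max_mm Maximum mismatches, 0..3.
#' @return Data frame with columns `region`, `start`, `end`, `strand`,
#'   `mismatches`. A read longer than every reference yields zero rows.
#' @export
map_read <- function(seq, refs, max_mm = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("N", seq, fixed = TRUE))
    stop("read contains N; mismatch counting with N is ill-defined")
  if (max_mm < 0L || max_mm > 3L)
    stop("max_mm must be between 0 and 3")
  n <- nchar(seq)
  res <- list()
  for (i in seq_len(nrow(refs$info))) {
    rn <- refs$info$name[i]
    h <- .scan_region(seq, refs$seqs[[rn]], as.character(refs$seqs[[rn]]),
                      max_mm)
    if (!is.null(h)) {
      h$region <- rn
      res[[rn]] <- h
    }
  }
  if (!length(res)) {
    return(data.frame(region = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, unname(res))
  hits$end <- hits$start + n
  hits <- hits[, c("region", "start", "end", "strand", "mismatches")]
  .sort_hits(hits, refs$info$name)
}

# fast exact-match path: per width group, PDict on both strands
.map_exact <- function(seqs, refs) {
  widths <- nchar(seqs)
  res <- list()
  k <- 0L
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    fwd <- Biostrings::DNAStringSet(seqs[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (i in seq_len(nrow(refs$info))) {
      rn <- refs$info$name[i]
      subj <- refs$seqs[[rn]]
      if (w > length(subj)) next
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subj)
        st <- Biostrings::startIndex(m)
        nh <- lengths(st)
        if (sum(nh) == 0L) next
        k <- k + 1L
        res[[k]] <- data.frame(
          seq_idx = rep(idx, nh),
          region = rn,
          start = unlist(st[nh > 0L]) - 1L,
          strand = strand,
          mismatches = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(seq_idx = integer(), region = character(),
                      start = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Map a read library
#'
#' Collapses identical read sequences (multiplicity preserved on hits), maps
#' each distinct sequence with [map_read()] semantics, and applies the
#' multi-mapper policy: with `unique_only = TRUE` (the default for all
#' headline metrics) reads with more than one hit across the analysis-role
#' regions are excluded from downstream counting but tallied as `"multi"`.
#' Uniqueness is evaluated within analysis-role regions only; a read also
#' matching a normalization-category region remains unique for the analysis.
#' Reads containing `N` are excluded from mapping and tallied.
#'
#' @param reads Data frame with columns `seq` and optionally `id`, `count`
#'   (pre-collapsed multiplicities), e.g. the `reads` element of
#'   [trim_library()]; or a character vector of sequences.
#' @param refs A [reference_set()].
#' @param max_mm Maximum mismatches, 0..3. `max_mm = 0` uses a fast
#'   dictionary scan; higher values scan each distinct sequence in turn.
#' @param unique_only Apply the unique-mapper policy above.
#' @return Object of class `"smrna_map"`: `hits` (data frame `seq`, `region`,
#'   `start`, `end`, `strand`, `mismatches`, `mult`, `length`, `first_nt`,
#'   `role`, `retained`), `reads` (per distinct sequence: `seq`, `mult`,
#'   `n_analysis_hits`), `counts` (total, mapped, multi, unmatched,
#'   excluded_n), plus the reference info.
#' @export
map_library <- function(reads, refs, max_mm = 0L, unique_only = TRUE) {
  if (is.character(reads))
    reads <- data.frame(seq = reads, stringsAsFactors = FALSE)
  if (max_mm < 0L || max_mm > 3L)
    stop("max_mm must be between 0 and 3")
  count <- if ("count" %in% names(reads)) reads$count else
    rep(1L, nrow(reads))
  seqs_all <- toupper(reads$seq)
  has_n <- grepl("N", seqs_all, fixed = TRUE)
  excluded_n <- sum(count[has_n])
  mult <- tapply(count[!has_n], seqs_all[!has_n], sum)
  useqs <- names(mult)
  mult <- as.integer(mult)

  if (length(useqs) == 0L) {
    hits <- data.frame(seq = character(), region = character(),
                       start = integer(), end = integer(),
                       strand = character(), mismatches = integer(),
                       mult = integer(), length = integer(),
                       first_nt = character(), role = character(),
                       retained = logical(), stringsAsFactors = FALSE)
  } else if (max_mm == 0L) {
    h <- .map_exact(useqs, refs)
    hits <- data.frame(seq = useqs[h$seq_idx], region = h$region,
                       start = h$start, strand = h$strand,
                       mismatches = h$mismatches, stringsAsFactors = FALSE)
  } else {
    acc <- vector("list", length(useqs))
    for (j in seq_along(useqs)) {
      h <- map_read(useqs[j], refs, max_mm)
      if (nrow(h)) {
        h$seq <- useqs[j]
        acc[[j]] <- h
      }
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    hits <- if (length(acc)) do.call(rbind, acc) else
      data.frame(seq = character(), region = character(), start = integer(),
                 end = integer(), strand = character(),
                 mismatches = integer(), stringsAsFactors = FALSE)
  }

  if (nrow(hits)) {
    i <- match(hits$seq, useqs)
    hits$mult <- mult[i]
    hits$length <- nchar(hits$seq)
    hits$end <- hits$start + hits$length
    hits$first_nt <- substr(hits$seq, 1L, 1L)
    hits$role <- refs$info$role[match(hits$region, refs$info$name)]
    na_hits <- table(factor(hits$seq[hits$role == "analysis"],
                            levels = useqs))
    n_analysis <- as.integer(na_hits)
    hits$retained <- hits$role == "analysis" &
      (if (unique_only) n_analysis[i] == 1L else TRUE)
    hits <- .sort_hits(hits[, c("seq", "region", "start", "end", "strand",
                                "mismatches", "mult", "length", "first_nt",
                                "role", "retained")],
                       refs$info$name)
  } else {
    n_analysis <- integer(length(useqs))
    hits$mult <- integer(); hits$length <- integer()
    hits$end <- integer(); hits$first_nt <- character()
    hits$role <- character(); hits$retained <- logical()
  }

  read_tab <- data.frame(seq = useqs, mult = mult,
                         n_analysis_hits = n_analysis,
                         stringsAsFactors = FALSE)
  mapped_any <- useqs %in% hits$seq
  counts <- c(total = sum(count),
              mapped = sum(mult[mapped_any]),
              multi = sum(mult[n_analysis > 1L]),
              unmatched = sum(mult[!mapped_any]),
              excluded_n = excluded_n)
  structure(list(hits = hits, reads = read_tab, counts = counts,
                 refs_info = refs$info, max_mm = max_mm,
                 unique_only = unique_only),
            class = "smrna_map")
}

#' @export
print.smrna_map <- function(x, ...) {
  cat("smrna_map:", nrow(x$hits), "hits from", nrow(x$reads),
      "distinct sequences (max_mm =", x$max_mm, ")\n")
  print(x$counts)
  invisible(x)
}

#' Export alignment hits as TSV
#'
#' @param map An [map_library()] result.
#' @param path Output path.
#' @param retained_only Write only hits retained for analysis.
#' @return `path`, invisibly.
#' @export
write_hits <- function(map, path, retained_only = FALSE) {
  h <- map$hits
  if (retained_only) h <- h[h$retained, , drop = FALSE]
  write_table(h, path)
}

# retained analysis hits for one region, optionally length-filtered
.region_hits <- function(map, region, window = NULL) {
  if (!region %in% map$refs_info$name)
    stop("unknown region: ", region)
  h <- map$hits[map$hits$retained & map$hits$region == region, , drop = FALSE]
  if (!is.null(window))
    h <- h[h$length >= window[1] & h$length <= window[2], , drop = FALSE]
  h
}
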