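#' Read a 4-line FASTQ file
#'
#' Minimal strict FASTQ reader for small RNA libraries. Qualities are kept as
#' text; they play no role in the analysis (Phred+33 is assumed but ignored).
#'
#' @param path FASTQ path (plain or gzip).
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  hd <- lines[seq(1L, n, 4L)]
  sq <- toupper(lines[seq(2L, n, 4L)])
  pl <- lines[seq(3L, n, 4L)]
  ql <- lines[seq(4L, n, 4L)]
  if (!all(startsWith(hd, "@")))
    stop("malformed FASTQ (missing '@' header) in: ", path)
  if (!all(startsWith(pl, "+")))
    stop("malformed FASTQ (missing '+' separator) in: ", path)
  bad <- nchar(sq) != nchar(ql)
  if (any(bad))
    stop("malformed FASTQ (sequence/quality length mismatch) at record ",
         which(bad)[1L], " in: ", path)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hd)),
             seq = sq, qual = ql, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Data frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to maximal quality).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  out <- rbind(paste0("@", reads$id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

# Leftmost adapter position (1-based) in each read, or NA.
# A match is either the full adapter anywhere, or a prefix of the adapter of
# length >= min_overlap at the read's 3' end.
.adapter_positions <- function(seqs, adapter, min_overlap = 8L) {
  alen <- nchar(adapter)
  n <- nchar(seqs)
  pos <- rep(NA_integer_, length(seqs))
  full <- regexpr(adapter, seqs, fixed = TRUE)
  hit <- full > 0L
  pos[hit] <- full[hit]
  if (alen > min_overlap) {
    for (k in seq(alen - 1L, min_overlap)) {
      pref <- substr(adapter, 1L, k)
      cand <- n - k + 1L
      ok <- cand >= 1L & substr(seqs, cand, n) == pref
      pos[ok] <- pmin(pos[ok], cand[ok], na.rm = TRUE)
    }
  }
  pos
}

#' Trim the 3' adapter from one read
#'
#' The insert is the prefix of the read before the leftmost adapter match.
#' Matching is exact (no mismatches): the full adapter anywhere in the read,
#' or at least `min_overlap` bases of the adapter prefix flush with the 3'
#' end. Reads without a match, or with an insert outside
#' `[min_len, max_len]`, are rejected with a coded reason.
#'
#' @param seq Read sequence (character scalar).
#' @param adapter Adapter sequence; the default is the 3' ligation adapter
#'   used in standard small RNA library preparation.
#' @param min_len,max_len Retained insert length window (nt).
#' @param min_overlap Minimum adapter prefix length accepted at the 3' end.
#' @return List with `status` (`"ok"`, `"empty"`, `"no_adapter"`,
#'   `"too_short"`, `"too_long"`) and, when `status == "ok"`, the trimmed
#'   `seq`, its `length` and `first_nt`.
#' @export
trim_adapter <- function(seq, adapter = "TGGAATTCTCGGGTGCCAAG",
                         min_len = 18L, max_len = 30L, min_overlap = 8L) {
  stopifnot(length(seq) == 1L, nzchar(adapter), min_len <= max_len)
  if (!nzchar(seq)) return(list(status = "empty"))
  pos <- .adapter_positions(toupper(seq), toupper(adapter), min_overlap)
  if (is.na(pos)) return(list(status = "no_adapter"))
  insert <- substr(seq, 1L, pos - 1L)
  len <- nchar(insert)
  if (len < min_len) return(list(status = "too_short"))
  if (len > max_len) return(list(status = "too_long"))
  list(status = "ok", seq = insert, length = len,
       first_nt = substr(insert, 1L, 1L))
}

#' Trim a whole read library
#'
#' Vectorized [trim_adapter()] over a library. Rejected reads are never
#' silently dropped: they are tallied per reason and returned.
#'
#' @param reads Data frame with columns `id`, `seq` (e.g. from
#'   [read_fastq()]), or a character vector of sequences.
#' @inheritParams trim_adapter
#' @return List of class `"trimmed_library"`: `reads` (data frame `id`,
#'   `seq`, `length`, `first_nt`), `rejected` (data frame `id`, `reason`) and
#'   `counts` (named integer vector over all statuses).
#' @export
trim_library <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAG",
                         min_len = 18L, max_len = 30L, min_overlap = 8L) {
  if (is.character(reads))
    reads <- data.frame(id = paste0("read_", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  stopifnot(nzchar(adapter), min_len <= max_len)
  seqs <- toupper(reads$seq)
  pos <- .adapter_positions(seqs, toupper(adapter), min_overlap)
  insert <- substr(seqs, 1L, ifelse(is.na(pos), 0L, pos - 1L))
  len <- nchar(insert)
  status <- rep("ok", length(seqs))
  status[is.na(pos)] <- "no_adapter"
  status[!nzchar(seqs)] <- "empty"
  sel <- status == "ok"
  status[sel & len < min_len] <- "too_short"
  status[sel & len > max_len] <- "too_long"
  keep <- status == "ok"
  counts <- table(factor(status,
                         levels = c("ok", "empty", "no_adapter",
                                    "too_short", "too_long")))
  structure(list(
    reads = data.frame(id = reads$id[keep], seq = insert[keep],
                       length = len[keep],
                       first_nt = substr(insert[keep], 1L, 1L),
                       stringsAsFactors = FALSE),
    rejected = data.frame(id = reads$id[!keep], reason = status[!keep],
                          stringsAsFactors = FALSE),
    counts = c(counts)), class = "trimmed_library")
}

#' @export
print.trimmed_library <- function(x, ...) {
  cat("trimmed_library:", nrow(x$reads), "retained reads\n")
  print(x$counts)
  invisible(x)
}

#' Write / read a TSV table
#'
#' Deterministic column order, tab-separated, no quoting. Non-finite numeric
#' values (NaN, Inf) are refused; `NA` is allowed and round-trips.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comment Optional character vector written as leading `#` lines
#'   (used to embed provenance such as the simulation seed).
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_table <- function(x, path, comment = NULL) {
  for (cn in names(x)) {
    v <- x[[cn]]
    if (is.numeric(v) && any(is.nan(v) | (!is.na(v) & !is.finite(v))))
      stop("non-finite value in column: ", cn)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a strand-resolved coverage profile as bedGraph
#'
#' Four columns (region, start, end, value), 0-based half-open, runs of equal
#' value merged, zero runs omitted. Antisense coverage is written with
#' negative sign, the usual convention for strand-split small RNA tracks.
#' A header comment records region, length and length window so the file can
#' be read back with [read_coverage()].
#'
#' @param profile A [coverage_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(profile, path) {
  stopifnot(inherits(profile, "coverage_profile"))
  if (any(!is.finite(profile$sense)) || any(!is.finite(profile$antisense)))
    stop("non-finite value in coverage profile")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region=%s length=%d window=%d-%d",
                     profile$region, length(profile$sense),
                     profile$window[1], profile$window[2]), con)
  .bg_lines <- function(v, sign) {
    r <- rle(v * sign)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(character())
    sprintf("%s\t%d\t%d\t%s", profile$region, starts[keep], ends[keep],
            format(r$values[keep], trim = TRUE, scientific = FALSE))
  }
  writeLines(c(.bg_lines(profile$sense, 1), .bg_lines(profile$antisense, -1)),
             con)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1L]
  m <- regmatches(hdr, regexec(
    "region=(\\S+) length=(\\d+) window=(\\d+)-(\\d+)", hdr))[[1L]]
  if (length(m) != 5L) stop("missing coverage header in: ", path)
  L <- as.integer(m[3L])
  sense <- numeric(L)
  antisense <- numeric(L)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    for (p in parts) {
      s <- as.integer(p[2L]); e <- as.integer(p[3L]); v <- as.numeric(p[4L])
      if (v >= 0) sense[(s + 1L):e] <- v else antisense[(s + 1L):e] <- -v
    }
  }
  structure(list(region = m[2L], window = as.integer(m[4:5]),
                 sense = sense, antisense = antisense,
                 norm_factor = NA_real_),
            class = "coverage_profile")
}
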