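#' Library annotation and normalization factor
#'
#' Categorizes reads by the role of the regions they match with 0 mismatches
#' (genome, miscRNA, tRNA, miRNA) and computes the per-million normalization
#' factor used for library comparisons: reads are scaled relative to the
#' number of reads aligning to the genome category but not to miscRNAs
#' (rRNA, snoRNA, ...) or tRNAs. Categories are not mutually exclusive: a
#' read matching both a miRNA and a genome region counts in both tallies;
#' the subtraction happens only in the denominator.
#'
#' @param map A [map_library()] result. Annotation is defined on 0-mismatch
#'   hits; if the map was built with `max_mm > 0`, only its 0-mismatch hits
#'   are used.
#' @return Object of class `"library_annotation"`; see
#'   [library_annotation()].
#' @export
annotate_library <- function(map) {
  stopifnot(inherits(map, "smrna_map"))
  h <- map$hits[map$hits$mismatches == 0L, , drop = FALSE]
  count_role <- function(role) {
    s <- unique(h$seq[h$role == role])
    sum(map$reads$mult[map$reads$seq %in% s])
  }
  matched <- unique(h$seq)
  unmatched <- sum(map$reads$mult[!map$reads$seq %in% matched]) +
    unname(map$counts["excluded_n"])
  library_annotation(
    total_reads = unname(map$counts["total"]),
    genome = count_role("normalization_genome"),
    miscRNA = count_role("miscRNA"),
    tRNA = count_role("tRNA"),
    miRNA = count_role("miRNA"),
    unmatched = unmatched)
}

#' Construct a library annotation
#'
#' Normally produced by [annotate_library()]; the constructor is exported so
#' that category counts from an external annotation run (or a worked
#' example) can be used directly. The normalization denominator is
#' `genome - miscRNA - tRNA` and the normalization factor `1e6 /
#' denominator`, i.e. normalized counts are per million genome-matching
#' reads after subtracting structural RNA.
#'
#' @param total_reads Total reads entering annotation.
#' @param genome,miscRNA,tRNA,miRNA,unmatched Category read counts.
#' @return List of class `"library_annotation"` with the counts,
#'   `norm_denominator` and `norm_factor`.
#' @export
library_annotation <- function(total_reads, genome, miscRNA = 0, tRNA = 0,
                               miRNA = 0, unmatched = 0) {
  counts <- c(genome = genome, miscRNA = miscRNA, tRNA = tRNA,
              miRNA = miRNA, unmatched = unmatched)
  if (any(counts < 0) || any(counts > total_reads))
    stop("category counts must lie in [0, total_reads]")
  denom <- genome - miscRNA - tRNA
  if (denom <= 0)
    stop("empty normalization denominator")
  structure(list(total_reads = total_reads, counts = counts,
                 norm_denominator = denom,
                 norm_factor = 1e6 / denom),
            class = "library_annotation")
}

#' @export
print.library_annotation <- function(x, ...) {
  cat("library_annotation: total =", x$total_reads, "\n")
  print(x$counts)
  cat("norm_denominator =", x$norm_denominator,
      "; norm_factor =", format(x$norm_factor), "\n")
  invisible(x)
}

#' Normalize a raw read count
#'
#' Three alternative per-million scalings; all preserve within-library count
#' ratios exactly, and libraries with identical per-category composition get
#' identical normalized values up to a library-constant factor, so
#' conclusions should be robust to the choice.
#'
#' @param count Raw read count(s).
#' @param ann A [library_annotation()].
#' @param mode `"genome_minus_misc"` (the default normalization factor),
#'   `"per_million_miRNA"` or `"per_million_genome"`.
#' @return `count * 1e6 / denominator(mode)`.
#' @export
normalize_count <- function(count, ann,
                            mode = c("genome_minus_misc",
                                     "per_million_miRNA",
                                     "per_million_genome")) {
  mode <- match.arg(mode)
  denom <- switch(mode,
    genome_minus_misc = ann$norm_denominator,
    per_million_miRNA = unname(ann$counts["miRNA"]),
    per_million_genome = unname(ann$counts["genome"]))
  if (is.na(denom) || denom <= 0)
    stop("zero normalization denominator for mode: ", mode)
  count * 1e6 / denom
}

#' Annotation summary table
#'
#' @param ann A [library_annotation()].
#' @return Data frame, one row per category plus the denominator and factor.
#' @export
annotation_table <- function(ann) {
  data.frame(category = c("total", names(ann$counts), "norm_denominator",
                          "norm_factor"),
             value = c(ann$total_reads, unname(ann$counts),
                       ann$norm_denominator, ann$norm_factor),
             stringsAsFactors = FALSE)
}

# normalization factor helper used by the metrics layer: ann may be NULL for
# unnormalized (factor 1) computations, e.g. scale-free signatures.
.nf <- function(ann) {
  if (is.null(ann)) return(1)
  stopifnot(inherits(ann, "library_annotation"))
  ann$norm_factor
}
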