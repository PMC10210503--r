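#' Region roles recognised by a reference set
#'
#' Each reference region carries a role that decides how it is used:
#' `"analysis"` regions are the loci whose small RNA production is being
#' quantified (transgene domains, reporter genes); `"normalization_genome"`,
#' `"miscRNA"`, `"tRNA"` and `"miRNA"` regions feed the library annotation
#' categories used for depth normalization; `"flanking"` regions are carried
#' along for spreading checks but enter no denominator.
#'
#' @export
REGION_ROLES <- c("analysis", "normalization_genome", "miscRNA", "tRNA",
                  "miRNA", "flanking")

#' Build a reference set
#'
#' Bundles named nucleotide sequences with per-region roles and lengths.
#' This is the mapping universe for [map_read()] and [map_library()]: a small
#' collection of regions (transgene constructs, repeat units, background
#' category sequences) rather than a whole genome assembly.
#'
#' @param seqs Named character vector or `DNAStringSet`. Names must be unique,
#'   sequences non-empty. Lowercase letters are uppercased.
#' @param roles Either a single role recycled to all regions or a character
#'   vector/named vector parallel to `seqs`. See [REGION_ROLES].
#' @return An object of class `"reference_set"` with elements `seqs`
#'   (a `DNAStringSet`) and `info` (data frame of name, role, length_bp,
#'   length_kb).
#' @export
reference_set <- function(seqs, roles = "analysis") {
  nm <- names(seqs)
  chars <- stats::setNames(toupper(as.character(seqs)), nm)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    stop("all reference sequences must be named")
  if (anyDuplicated(nm))
    stop("duplicate reference name: ", nm[duplicated(nm)][1L])
  empty <- !nzchar(chars)
  if (any(empty))
    stop("empty sequence for record: ", nm[empty][1L])
  bad <- grepl("[^ACGTNRYSWKMBDHV]", chars)
  if (any(bad))
    stop("non-IUPAC characters in record: ", nm[bad][1L])
  if (length(roles) == 1L) roles <- rep(roles, length(chars))
  if (!is.null(names(roles))) roles <- roles[nm]
  if (length(roles) != length(chars) || anyNA(roles))
    stop("a role must be assigned for every region")
  ok <- roles %in% REGION_ROLES
  if (!all(ok))
    stop("unknown region role: ", roles[!ok][1L])
  info <- data.frame(name = nm, role = unname(roles),
                     length_bp = nchar(chars),
                     stringsAsFactors = FALSE)
  info$length_kb <- info$length_bp / 1000
  structure(list(seqs = Biostrings::DNAStringSet(stats::setNames(chars, nm)),
                 info = info),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set with", nrow(x$info), "region(s)\n")
  print(x$info, row.names = FALSE)
  invisible(x)
}

#' Region accessors
#'
#' @param refs A [reference_set()].
#' @param region Region name.
#' @return `region_names()` the region names; `region_seq()` the sequence as a
#'   character scalar; `region_length()` its length in bp.
#' @export
region_names <- function(refs) refs$info$name

#' @rdname region_names
#' @export
region_seq <- function(refs, region) {
  .check_region(refs, region)
  as.character(refs$seqs[[region]])
}

#' @rdname region_names
#' @export
region_length <- function(refs, region) {
  .check_region(refs, region)
  refs$info$length_bp[match(region, refs$info$name)]
}

.check_region <- function(refs, region) {
  if (!region %in% refs$info$name)
    stop("unknown region: ", region)
  invisible(TRUE)
}

#' Read a FASTA file into a reference set
#'
#' Record names are the first whitespace-delimited word of each header;
#' sequences are uppercased. Duplicate names, empty sequences and non-IUPAC
#' characters raise an error naming the offending record.
#'
#' @param path FASTA file path (plain or gzip).
#' @param roles Role specification passed to [reference_set()]; a named vector
#'   keyed by record name, or a single role for all records.
#' @return A [reference_set()].
#' @export
read_fasta <- function(path, roles = "analysis") {
  x <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L])
  reference_set(stats::setNames(as.character(x), nm), roles)
}

#' Write a reference set as FASTA
#'
#' @param refs A [reference_set()].
#' @param path Output path.
#' @param descriptions Optional named character vector appended to headers
#'   after the record name (e.g. provenance such as the simulation seed).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path, descriptions = NULL) {
  x <- refs$seqs
  if (!is.null(descriptions)) {
    d <- descriptions[names(x)]
    hdr <- ifelse(is.na(d) | d == "", names(x), paste(names(x), d))
    names(x) <- hdr
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# reverse complement for plain character vectors (DNA alphabet + N)
.revcomp <- function(x) {
  rc <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(rc, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
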