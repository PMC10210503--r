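# Small RNA statistics on mapped libraries: size distributions, 5'-end
# coverage, densities per kb, ping-pong overlap signatures, strand asymmetry,
# siRNA/piRNA partition, dinucleotide content and the density ~ length
# regression. All counts are scaled by the library normalization factor; all
# coordinates are 0-based half-open internally.

#' Strand-split size distribution of mapped reads
#'
#' Normalized counts per read length and strand for one region, over the
#' retained (unique-mapper) hits.
#'
#' @param map A [map_library()] result.
#' @param ann A [library_annotation()], or `NULL` for unnormalized counts.
#' @param region Region name.
#' @param lo,hi Length window in nt.
#' @return Data frame of class `"size_distribution"` with columns `length`,
#'   `strand` (`"sense"`/`"antisense"`), `count` (normalized). The total over
#'   all cells equals the total normalized mapped count in the window.
#' @export
size_distribution <- function(map, ann, region, lo = 18L, hi = 30L) {
  h <- .region_hits(map, region, c(lo, hi))
  grid <- expand.grid(length = lo:hi, strand = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  key <- paste(h$length, ifelse(h$strand == "+", "sense", "antisense"))
  agg <- tapply(h$mult, key, sum)
  grid$count <- .nf(ann) *
    ifelse(is.na(agg[paste(grid$length, grid$strand)]), 0,
           agg[paste(grid$length, grid$strand)])
  attr(grid, "region") <- region
  class(grid) <- c("size_distribution", "data.frame")
  grid
}

#' Strand-resolved 5'-end coverage profile
#'
#' Per-position normalized counts of the 5' ends of length-selected reads on
#' one region. Position is the 5'-end coordinate, 0-based: a sense hit adds
#' its normalized multiplicity at `start`, an antisense hit at `end - 1`.
#'
#' @inheritParams size_distribution
#' @param window Length window (lo, hi) in nt; default the piRNA window.
#' @return List of class `"coverage_profile"`: `region`, `window`, numeric
#'   vectors `sense` and `antisense` of length equal to the region, and
#'   `norm_factor`.
#' @export
coverage_profile <- function(map, ann, region, window = c(23L, 29L)) {
  stopifnot(window[1] <= window[2])
  h <- .region_hits(map, region, window)
  L <- map$refs_info$length_bp[match(region, map$refs_info$name)]
  nf <- .nf(ann)
  fill <- function(pos0, w) {
    v <- numeric(L)
    if (length(pos0)) {
      agg <- rowsum(w, pos0)
      v[as.integer(rownames(agg)) + 1L] <- agg[, 1L] * nf
    }
    v
  }
  s <- h$strand == "+"
  structure(list(region = region, window = as.integer(window),
                 sense = fill(h$start[s], h$mult[s]),
                 antisense = fill(h$end[!s] - 1L, h$mult[!s]),
                 norm_factor = nf),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s [%d-%d nt]: sense %.1f, antisense %.1f\n",
              x$region, x$window[1], x$window[2], sum(x$sense),
              sum(x$antisense)))
  invisible(x)
}

#' Normalized read density per kb and 1U bias
#'
#' The headline conversion metric: normalized count of window-selected reads
#' divided by the region length in kb, together with the fraction of those
#' reads beginning with a 5' uridine (T in DNA space, evaluated on the
#' read's own strand).
#'
#' @inheritParams coverage_profile
#' @return List of class `"region_density"`: `region`, `length_kb`,
#'   `normalized_count`, `density` (reads/kb), `one_u_fraction` (`NA` and
#'   flagged `undefined` when no reads map), `n_reads` (raw).
#' @export
density_per_kb <- function(map, ann, region, window = c(23L, 29L)) {
  h <- .region_hits(map, region, window)
  L <- map$refs_info$length_bp[match(region, map$refs_info$name)]
  if (L == 0L) stop("zero-length region: ", region)
  n_raw <- sum(h$mult)
  norm <- n_raw * .nf(ann)
  one_u <- if (n_raw > 0) sum(h$mult[h$first_nt == "T"]) / n_raw else
    NA_real_
  structure(list(region = region, length_kb = L / 1000,
                 normalized_count = norm, density = norm / (L / 1000),
                 one_u_fraction = one_u, one_u_defined = n_raw > 0,
                 n_reads = n_raw),
            class = "region_density")
}

#' @export
print.region_density <- function(x, ...) {
  cat(sprintf("region_density %s: %.2f reads/kb (%.1f reads over %.2f kb), 1U = %s\n",
              x$region, x$density, x$normalized_count, x$length_kb,
              if (x$one_u_defined) sprintf("%.3f", x$one_u_fraction)
              else "undefined"))
  invisible(x)
}

#' Ping-pong overlap signature
#'
#' Counts weighted sense/antisense read pairs by the number of bases `k` by
#' which their 5' ends overlap: `pair_counts[k]` is the sum over positions
#' `p` of (normalized sense 5' count at `p`) x (normalized antisense 5'
#' count at `p + k - 1`). `k = 10` is the canonical ping-pong register. The
#' z-score of each register is taken against the mean and SD of registers
#' `1..K` (the background window includes `k = 10`, which is conservative:
#' a true signal shrinks its own z-score).
#'
#' @param profile A [coverage_profile()] (its vectors are 5'-end counts).
#' @param K Largest overlap register, at least 10.
#' @return List of class `"overlap_signature"`: `pair_counts`, `zscores`
#'   (all `NA` with `degenerate = TRUE` when the register counts have zero
#'   variance), `K`.
#' @export
overlap_signature <- function(profile, K = 25L) {
  stopifnot(inherits(profile, "coverage_profile"), K >= 10L)
  S <- profile$sense
  A <- profile$antisense
  if (sum(S) == 0 || sum(A) == 0)
    stop("overlap signature requires reads on both strands")
  L <- length(S)
  pc <- vapply(seq_len(K), function(k) {
    if (k > L) return(0)
    sum(S[seq_len(L - k + 1L)] * A[k:L])
  }, numeric(1))
  sdv <- stats::sd(pc)
  degenerate <- !is.finite(sdv) || sdv == 0
  z <- if (degenerate) rep(NA_real_, K) else (pc - mean(pc)) / sdv
  structure(list(pair_counts = pc, zscores = z, K = as.integer(K),
                 degenerate = degenerate),
            class = "overlap_signature")
}

#' @export
print.overlap_signature <- function(x, ...) {
  if (x$degenerate) {
    cat("overlap_signature: degenerate (zero variance across registers)\n")
  } else {
    cat(sprintf("overlap_signature: z(10) = %.2f, max register = %d\n",
                x$zscores[10], which.max(x$pair_counts)))
  }
  invisible(x)
}

#' Signature export table
#' @param sig An [overlap_signature()].
#' @return Data frame `k`, `pair_count`, `z`.
#' @export
signature_table <- function(sig) {
  data.frame(k = seq_len(sig$K), pair_count = sig$pair_counts,
             z = sig$zscores)
}

#' Strand asymmetry of a coverage profile
#'
#' Classifies a region as a symmetric dual-strand, asymmetric dual-strand or
#' uni-strand producer by the minority-strand fraction `m`:
#' `m >= symmetric_min` is symmetric dual-strand, `uni_max <= m <
#' symmetric_min` asymmetric dual-strand, `m < uni_max` uni-strand. The
#' thresholds operationalize what is usually a qualitative call; they are
#' exposed so users can tighten or relax them.
#'
#' @param profile A [coverage_profile()].
#' @param symmetric_min,uni_max Class thresholds on the minority fraction.
#' @return List: `sense_fraction`, `minority_fraction`, `class`.
#' @export
strand_asymmetry <- function(profile, symmetric_min = 0.25, uni_max = 0.02) {
  s <- sum(profile$sense)
  a <- sum(profile$antisense)
  if (s + a <= 0) stop("zero coverage: strand asymmetry undefined")
  sf <- s / (s + a)
  m <- min(sf, 1 - sf)
  cls <- if (m >= symmetric_min) "symmetric_dual" else
    if (m >= uni_max) "asymmetric_dual" else "uni_strand"
  list(sense_fraction = sf, minority_fraction = m, class = cls)
}

#' siRNA / piRNA partition ratio
#'
#' Ratio of normalized counts in the piRNA length window (23-29 nt) over the
#' 21-nt siRNA reads for one region. Undefined (flagged, `NA`) when the
#' library has no 21-nt reads on the region.
#'
#' @inheritParams coverage_profile
#' @param pirna_window piRNA length window.
#' @param sirna_length siRNA length.
#' @return List: `ratio`, `pirna_count`, `sirna_count` (normalized),
#'   `defined`.
#' @export
sirna_pirna_ratio <- function(map, ann, region, pirna_window = c(23L, 29L),
                              sirna_length = 21L) {
  nf <- .nf(ann)
  pir <- sum(.region_hits(map, region, pirna_window)$mult) * nf
  sir <- sum(.region_hits(map, region, rep(sirna_length, 2L))$mult) * nf
  if (sir == 0)
    return(list(ratio = NA_real_, pirna_count = pir, sirna_count = 0,
                defined = FALSE))
  list(ratio = pir / sir, pirna_count = pir, sirna_count = sir,
       defined = TRUE)
}

#' Dinucleotide content of a sequence
#'
#' Frequencies of the 16 dinucleotides over all overlapping windows.
#' Windows containing a base outside `{A,C,G,T}` are skipped and the
#' denominator adjusted accordingly.
#'
#' @param seq Character scalar, length >= 2.
#' @return Named numeric vector of class `"dinucleotide_profile"` over the
#'   16 dinucleotides; frequencies sum to 1.
#' @export
dinucleotide_content <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L) stop("sequence must have length >= 2")
  di <- paste0(substring(seq, 1:(n - 1L), 1:(n - 1L)),
               substring(seq, 2:n, 2:n))
  lev <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                         paste0))
  valid <- di %in% lev
  if (!any(valid)) stop("no valid dinucleotide window in sequence")
  counts <- table(factor(di[valid], levels = sort(lev)))
  structure(c(counts) / sum(valid), class = "dinucleotide_profile")
}

#' Linear model of piRNA density on sequence features
#'
#' Ordinary least squares with intercept regressing per-region piRNA density
#' on sequence length and composition features, with per-coefficient
#' two-sided p-values. Used to ask whether conversion efficiency tracks
#' simple sequence properties.
#'
#' @param data Data frame with the response and predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param response Response column name (default `"density"`).
#' @return List: `model` (the `lm` fit), `coefficients` (data frame `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`).
#' @export
fit_density_model <- function(data, predictors, response = "density") {
  if (nrow(data) < 3L)
    stop("need at least 3 rows to fit the density model")
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols))
    stop("missing column: ", missing_cols[1L])
  fit <- stats::lm(stats::reformulate(predictors, response), data = data)
  co <- stats::coef(fit)
  if (anyNA(co))
    stop("rank-deficient fit; collinear predictor: ",
         names(co)[is.na(co)][1L])
  s <- summary(fit)$coefficients
  list(model = fit,
       coefficients = data.frame(term = rownames(s),
                                 estimate = s[, 1L], std_error = s[, 2L],
                                 statistic = s[, 3L], p_value = s[, 4L],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE))
}

#' Per-generation conversion series
#'
#' Holds the normalized piRNA densities of one lineage over generations, the
#' substrate for conversion-kinetics ratios and rate fitting.
#'
#' @param generations Integer vector, strictly increasing.
#' @param densities Normalized densities (reads/kb), one per generation.
#' @param lineage `"paternal"` or `"maternal"`.
#' @param region Optional region name.
#' @param sirna_pirna Optional per-generation 23-29/21-nt ratio.
#' @param one_u Optional per-generation 1U fraction.
#' @return Data frame of class `"conversion_series"`.
#' @export
conversion_series <- function(generations, densities,
                              lineage = c("paternal", "maternal"),
                              region = NA_character_, sirna_pirna = NULL,
                              one_u = NULL) {
  lineage <- match.arg(lineage)
  generations <- as.integer(generations)
  if (any(diff(generations) <= 0L))
    stop("generations must be strictly increasing")
  if (length(densities) != length(generations))
    stop("one density per generation required")
  if (any(densities < 0)) stop("densities must be >= 0")
  out <- data.frame(generation = generations, density = densities)
  if (!is.null(sirna_pirna)) out$sirna_pirna <- sirna_pirna
  if (!is.null(one_u)) out$one_u <- one_u
  attr(out, "lineage") <- lineage
  attr(out, "region") <- region
  class(out) <- c("conversion_series", "data.frame")
  out
}

#' Density ratio between two generations
#'
#' @param series A [conversion_series()].
#' @param g_from,g_to Generations to compare; the ratio is
#'   `density(g_to) / density(g_from)`. Reported to 2 decimals in summaries.
#' @param digits Rounding applied to the returned ratio; `NULL` for the raw
#'   value.
#' @return The density ratio.
#' @export
generation_ratio <- function(series, g_from, g_to, digits = 2L) {
  i <- match(g_from, series$generation)
  j <- match(g_to, series$generation)
  if (is.na(i) || is.na(j))
    stop("generation not present in series")
  if (series$density[i] <= 0)
    stop("density at the reference generation must be > 0")
  r <- series$density[j] / series$density[i]
  if (is.null(digits)) r else round(r, digits)
}

#' Fit the conversion rate of a paternal series
#'
#' Fits the saturation model `density(g) = D_max * (1 - (1 - c)^g)`, a
#' per-generation Bernoulli conversion with probability `c` approaching the
#' plateau density `D_max` geometrically, to an observed series by nonlinear
#' least squares.
#'
#' @param series A [conversion_series()] (>= 3 generations recommended).
#' @return List: `c` (per-generation conversion probability), `D_max`,
#'   `fitted` densities, `model` (the `nls` fit).
#' @export
estimate_conversion_rate <- function(series) {
  if (nrow(series) < 2L) stop("need at least 2 generations")
  d <- series$density
  dmax0 <- max(d)
  c0 <- min(max(d[1L] / dmax0, 0.05), 0.95)
  fit <- stats::nls(density ~ Dmax * (1 - (1 - c)^generation),
                    data = as.data.frame(series),
                    start = list(Dmax = dmax0, c = c0),
                    algorithm = "port",
                    lower = c(Dmax = 1e-8, c = 1e-6),
                    upper = c(Dmax = Inf, c = 1))
  co <- stats::coef(fit)
  list(c = unname(co["c"]), D_max = unname(co["Dmax"]),
       fitted = stats::fitted(fit), model = fit)
}

#' Per-region metrics summary row
#'
#' Convenience wrapper collecting the headline per-region numbers into one
#' data frame row (density, 1U, strand class, z(10), siRNA/piRNA ratio).
#'
#' @inheritParams coverage_profile
#' @param K Overlap registers for the signature.
#' @return One-row data frame.
#' @export
region_metrics <- function(map, ann, region, window = c(23L, 29L), K = 25L) {
  dens <- density_per_kb(map, ann, region, window)
  prof <- coverage_profile(map, ann, region, window)
  asym <- tryCatch(strand_asymmetry(prof), error = function(e) NULL)
  z10 <- tryCatch({
    sig <- overlap_signature(prof, K)
    if (sig$degenerate) NA_real_ else sig$zscores[10L]
  }, error = function(e) NA_real_)
  sp <- sirna_pirna_ratio(map, ann, region, window)
  data.frame(region = region, length_kb = dens$length_kb,
             normalized_count = dens$normalized_count,
             density = dens$density,
             one_u_fraction = dens$one_u_fraction,
             sense_fraction = if (is.null(asym)) NA_real_ else
               asym$sense_fraction,
             strand_class = if (is.null(asym)) NA_character_ else asym$class,
             z10 = z10, sirna_pirna = sp$ratio,
             stringsAsFactors = FALSE)
}
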