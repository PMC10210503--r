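# Egg-chamber ON/OFF silencing summaries. Repression is scored per ovary as
# the percentage of egg chambers with no reporter expression in the
# germline; chambers are all-or-none, so the natural uncertainty model is
# binomial.

#' Percent repressed egg chambers with a Wilson interval
#'
#' `100 * n_repressed / n_total` with a Wilson score confidence interval.
#' Wilson (rather than Wald) is used because fully ON (0%) and fully OFF
#' (100%) ovaries both occur and the Wald interval collapses there.
#'
#' @param n_repressed,n_total Chamber counts, `0 <= n_repressed <= n_total`,
#'   `n_total > 0`. Counts entering this function are already filtered to
#'   the relevant stage window (e.g. stages 8-10 for RFP assays).
#' @param conf Confidence level.
#' @return List: `percent`, `ci_lower`, `ci_upper` (percent scale),
#'   `n_repressed`, `n_total`.
#' @export
repression_percentage <- function(n_repressed, n_total, conf = 0.95) {
  if (n_total <= 0) stop("n_total must be > 0")
  if (n_repressed < 0 || n_repressed > n_total)
    stop("n_repressed must lie in [0, n_total]")
  ci <- suppressWarnings(
    stats::prop.test(n_repressed, n_total, conf.level = conf,
                     correct = FALSE)$conf.int)
  list(percent = 100 * n_repressed / n_total,
       ci_lower = 100 * ci[1L], ci_upper = 100 * ci[2L],
       n_repressed = n_repressed, n_total = n_total)
}

#' Per-generation subline summary
#'
#' Unweighted mean and sample SD of per-subline repression percentages,
#' grouped by generation (and lineage when present). With a single subline
#' the mean is reported and the SD flagged undefined (`NA`).
#'
#' @param counts Data frame with columns `generation`, `subline`, `n_total`,
#'   `n_repressed`, and optionally `lineage`.
#' @return Data frame with one row per (lineage,) generation: `mean_percent`,
#'   `sd_percent`, `n_sublines`.
#' @export
subline_summary <- function(counts) {
  req <- c("generation", "subline", "n_total", "n_repressed")
  missing_cols <- setdiff(req, names(counts))
  if (length(missing_cols)) stop("missing column: ", missing_cols[1L])
  if (any(counts$n_total <= 0)) stop("n_total must be > 0")
  counts$percent <- 100 * counts$n_repressed / counts$n_total
  by_cols <- intersect(c("lineage", "generation"), names(counts))
  sp <- split(counts, counts[by_cols], drop = TRUE)
  rows <- lapply(sp, function(g) {
    out <- g[1L, by_cols, drop = FALSE]
    out$mean_percent <- mean(g$percent)
    out$sd_percent <- if (nrow(g) >= 2L) stats::sd(g$percent) else NA_real_
    out$n_sublines <- nrow(g)
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(if ("lineage" %in% by_cols) out$lineage else
    rep(1L, nrow(out)), out$generation), , drop = FALSE]
  rownames(out) <- NULL
  out
}
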