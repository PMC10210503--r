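# RT-qPCR and ChIP-qPCR normalization and group comparison statistics.

#' RT-qPCR sample
#'
#' A technical replicate set of standard-quantity (Sq) values for one gene in
#' one biological sample. Sq values come from a shared dilution series, so
#' the mean of the technical replicates (meanSq) is the per-sample quantity.
#'
#' @param sample_id Biological replicate label.
#' @param gene Gene name.
#' @param sq Numeric vector of technical replicate Sq values, all > 0.
#' @return List of class `"rt_qpcr_sample"` with `mean_sq`.
#' @export
rt_qpcr_sample <- function(sample_id, gene, sq) {
  if (any(sq <= 0)) stop("Sq values must be positive")
  structure(list(sample_id = sample_id, gene = gene, sq = sq,
                 mean_sq = mean(sq)),
            class = "rt_qpcr_sample")
}

#' Normalized transcript ratio of one sample
#'
#' `meanSq(gene) / meanSq(reference gene)`, computed within one biological
#' replicate; the reference is typically the ribosomal protein gene RpL32.
#'
#' @param sample_gene,sample_ref [rt_qpcr_sample()]s from the same biological
#'   replicate (mismatched labels are an error).
#' @return The meanSq ratio.
#' @export
rt_ratio <- function(sample_gene, sample_ref) {
  if (!identical(sample_gene$sample_id, sample_ref$sample_id))
    stop("gene and reference measurements come from different replicates: ",
         sample_gene$sample_id, " vs ", sample_ref$sample_id)
  if (sample_ref$mean_sq <= 0) stop("reference meanSq must be > 0")
  sample_gene$mean_sq / sample_ref$mean_sq
}

#' Per-sample RT ratios and group summary from a long table
#'
#' @param data Long data frame with columns `sample_id`, `gene`, `sq` (one
#'   row per technical replicate).
#' @param reference_gene Reference gene name (default `"RpL32"`).
#' @return List: `per_sample` (data frame `sample_id`, `gene`, `ratio`) and
#'   `summary` (per gene, mean of the per-sample ratios and SD).
#' @export
rt_ratio_table <- function(data, reference_gene = "RpL32") {
  mean_sq <- stats::aggregate(sq ~ sample_id + gene, data, mean)
  ref <- mean_sq[mean_sq$gene == reference_gene, c("sample_id", "sq")]
  if (!nrow(ref)) stop("reference gene absent: ", reference_gene)
  names(ref)[2L] <- "ref_sq"
  tgt <- mean_sq[mean_sq$gene != reference_gene, , drop = FALSE]
  m <- merge(tgt, ref, by = "sample_id")
  m$ratio <- m$sq / m$ref_sq
  per_sample <- m[order(m$gene, m$sample_id),
                  c("sample_id", "gene", "ratio")]
  rownames(per_sample) <- NULL
  sm <- stats::aggregate(ratio ~ gene, per_sample,
                         function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  summary <- data.frame(gene = sm$gene, mean_ratio = sm$ratio[, "mean"],
                        sd = sm$ratio[, "sd"], n = sm$ratio[, "n"],
                        stringsAsFactors = FALSE)
  list(per_sample = per_sample, summary = summary)
}

#' ChIP-qPCR sample
#'
#' Mean Ct values for one target region in one biological sample: specific
#' antibody pulldown, input, and nonspecific (IgG) control, plus the input
#' fraction. The input dilution factor is `1 / input_fraction` (e.g. a 5%
#' input gives a factor of 20).
#'
#' @param sample_id Biological replicate label.
#' @param target_region Amplicon/region name.
#' @param mean_ct_chip,mean_ct_input,mean_ct_ns Mean Ct of technical
#'   replicates for the specific ChIP, the input and the nonspecific
#'   control.
#' @param input_fraction Chromatin fraction set aside as input, in (0, 1].
#' @return List of class `"chip_sample"` with `dilution_factor`.
#' @export
chip_sample <- function(sample_id, target_region, mean_ct_chip,
                        mean_ct_input, mean_ct_ns,
                        input_fraction = 0.05) {
  if (input_fraction <= 0 || input_fraction > 1)
    stop("input_fraction must be in (0, 1]")
  structure(list(sample_id = sample_id, target_region = target_region,
                 mean_ct_chip = mean_ct_chip,
                 mean_ct_input = mean_ct_input,
                 mean_ct_ns = mean_ct_ns,
                 input_fraction = input_fraction,
                 dilution_factor = 1 / input_fraction),
            class = "chip_sample")
}

#' Input-normalized ChIP delta-Ct
#'
#' `deltaCt = meanCt[antibody] - (meanCt[input] - log2(dilution factor))`:
#' the pulldown Ct compared to the input Ct corrected for the fraction of
#' chromatin the input represents. Invariant to adding a constant to all Ct
#' values of the sample.
#'
#' @param s A [chip_sample()].
#' @param antibody `"target"` (specific antibody) or `"ns"` (nonspecific
#'   IgG control).
#' @return The normalized delta-Ct.
#' @export
chip_delta_ct <- function(s, antibody = c("target", "ns")) {
  antibody <- match.arg(antibody)
  ct <- switch(antibody, target = s$mean_ct_chip, ns = s$mean_ct_ns)
  ct - (s$mean_ct_input - log2(s$dilution_factor))
}

#' ChIP fold enrichment over the nonspecific control
#'
#' Computed as `2^(deltaCt[NS] - deltaCt[ChIP])`, the enrichment of the
#' specific antibody over the IgG control: 1 for no enrichment, > 1 for
#' specific signal. Note: this is the only algebraic reading of the usual
#' "2^-(deltaCt ChIP - deltaCt NS)"-style formula that has those two
#' properties; the sign conventions in the literature are frequently
#' garbled, so the implemented form is stated here explicitly.
#'
#' @param s A [chip_sample()].
#' @return Fold enrichment.
#' @export
fold_enrichment <- function(s) {
  2^(chip_delta_ct(s, "ns") - chip_delta_ct(s, "target"))
}

#' Rescale fold enrichments to a control region
#'
#' Each region's fold enrichment is divided by the control region's value
#' (by default the large germline cluster 42AB, constitutively high in
#' H3K9me3), so the control maps to 1.0.
#'
#' @param values Named numeric vector of fold enrichments.
#' @param control Control region name.
#' @return Named numeric vector of relative enrichments.
#' @export
normalize_to_region <- function(values, control = "42AB") {
  if (!control %in% names(values))
    stop("control region absent: ", control)
  if (values[[control]] <= 0)
    stop("control region value must be > 0")
  values / values[[control]]
}

#' Compare enrichment/expression groups
#'
#' Two designs: a bilateral (two-sided) Welch t-test for two groups, or a
#' one-way ANOVA followed by Tukey HSD pairwise comparisons for several.
#'
#' @param values_a For the t-test, the first group (numeric); for ANOVA, a
#'   named list of numeric groups.
#' @param values_b Second group for the t-test; ignored for ANOVA.
#' @param design `"t_test_bilateral"` or `"anova_tukey"`.
#' @return For the t-test: list `method`, `statistic`, `p_value`. For ANOVA:
#'   list `method`, `statistic` (F), `p_value` (overall), `tukey` (data
#'   frame of pairwise adjusted p-values).
#' @export
compare_groups <- function(values_a, values_b = NULL,
                           design = c("t_test_bilateral", "anova_tukey")) {
  design <- match.arg(design)
  if (design == "t_test_bilateral") {
    if (length(values_a) < 2L || length(values_b) < 2L)
      stop("each group needs n >= 2")
    tt <- stats::t.test(values_a, values_b, alternative = "two.sided",
                        var.equal = FALSE)
    return(list(method = "welch_t_test_bilateral",
                statistic = unname(tt$statistic),
                p_value = tt$p.value))
  }
  groups <- values_a
  if (!is.list(groups) || length(groups) < 2L)
    stop("ANOVA design needs a named list of >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  list(method = "anova_tukey",
       statistic = an[["F value"]][1L],
       p_value = an[["Pr(>F)"]][1L],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE))
}
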