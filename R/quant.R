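# Quantification stack: threshold CT calling, delta-CT / delta-delta-CT fold
# change (Livak 2^-ddCT; efficiency is reported but never used to correct the
# fold change), standard-curve amplification efficiency, digital-PCR Poisson
# quantification with pool fractions, JC-1 membrane-potential fold change,
# and two-sample group comparison.

#' Cycle threshold from an amplification curve
#'
#' Linear interpolation of the first crossing of a fixed fluorescence
#' threshold. A curve that never crosses is censored at the last cycle (not
#' an error).
#'
#' @param fluorescence Fluorescence values at integer cycles.
#' @param cycles Cycle numbers (defaults to 1..n).
#' @param threshold Fixed threshold in the linear range (default 0.15).
#' @return List with \code{ct} (NA when censored), \code{censored}, and
#'   \code{max_cycle}.
#' @export
ct_from_curve <- function(fluorescence, cycles = seq_along(fluorescence),
                          threshold = 0.15) {
  stopifnot(length(fluorescence) == length(cycles), length(cycles) >= 1L)
  above <- fluorescence >= threshold
  if (!any(above))
    return(list(ct = NA_real_, censored = TRUE,
                max_cycle = cycles[[length(cycles)]]))
  i <- which(above)[[1L]]
  ct <- if (i == 1L) cycles[[1L]] else {
    f0 <- fluorescence[[i - 1L]]; f1 <- fluorescence[[i]]
    cycles[[i - 1L]] + (threshold - f0) / (f1 - f0) *
      (cycles[[i]] - cycles[[i - 1L]])
  }
  list(ct = ct, censored = FALSE, max_cycle = cycles[[length(cycles)]])
}

#' Construct a CT measurement (replicate CTs for one sample/assay)
#'
#' @param sample Sample id.
#' @param assay Assay id.
#' @param cts Replicate CT values, each in (0, 40].
#' @param group Optional group label.
#' @return Object of class \code{ct_measurement}.
#' @export
ct_measurement <- function(sample, assay, cts, group = NULL) {
  cts <- as.numeric(cts)
  if (length(cts) < 1L || any(!is.finite(cts)) ||
      any(cts <= 0 | cts > 40))
    stop("ct_measurement: CTs must be finite and in (0, 40]")
  structure(list(sample = sample, assay = assay, cts = cts, group = group),
            class = "ct_measurement")
}

#' Normalized delta-CT for one sample
#'
#' \code{mean(target CTs) - mean(reference CTs)}; smaller values mean higher
#' transcription. Replicates are aggregated by the arithmetic mean with no
#' outlier rejection.
#'
#' @param target,reference [ct_measurement]s for the same sample.
#' @return List with \code{sample}, \code{target_assay},
#'   \code{reference_assay}, \code{delta_ct}.
#' @export
delta_ct <- function(target, reference) {
  if (!identical(target$sample, reference$sample))
    stop("delta_ct: sample mismatch ('", target$sample, "' vs '",
         reference$sample, "')")
  structure(list(sample = target$sample, target_assay = target$assay,
                 reference_assay = reference$assay,
                 delta_ct = mean(target$cts) - mean(reference$cts),
                 group = target$group),
            class = "delta_ct")
}

#' Fold change between two groups of delta-CT values
#'
#' \code{ddCT = mean(dCT a) - mean(dCT b)}; \code{FC(a vs b) = 2^-ddCT}
#' (uncorrected Livak form).
#'
#' @param dct_a,dct_b Numeric vectors of per-sample delta-CT values.
#' @return List with \code{ddct} and \code{fc}.
#' @export
fold_change <- function(dct_a, dct_b) {
  if (length(dct_a) == 0L || length(dct_b) == 0L)
    stop("fold_change: empty group")
  ddct <- mean(dct_a) - mean(dct_b)
  list(ddct = ddct, fc = 2^(-ddct))
}

#' Amplification efficiency from a dilution series
#'
#' Least-squares slope of CT on log10 relative input;
#' \code{E = 10^(-1/slope) - 1} (1 = perfect doubling).
#'
#' @param log10_input Log10 relative template input.
#' @param ct Mean CT at each dilution.
#' @return List with \code{slope}, \code{intercept}, \code{efficiency},
#'   \code{r_squared}, \code{n}.
#' @export
efficiency_from_dilution <- function(log10_input, ct) {
  if (length(log10_input) < 3L || length(ct) != length(log10_input))
    stop("efficiency_from_dilution: need >= 3 dilution points")
  if (stats::var(log10_input) == 0)
    stop("efficiency_from_dilution: zero variance in inputs")
  fit <- stats::lm(ct ~ log10_input)
  slope <- unname(stats::coef(fit)[[2L]])
  ss_tot <- sum((ct - mean(ct))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = slope, intercept = unname(stats::coef(fit)[[1L]]),
       efficiency = 10^(-1 / slope) - 1,
       r_squared = r2, n = length(ct))
}

#' Digital-PCR absolute quantification
#'
#' Poisson inversion of the positive-partition fraction:
#' \code{lambda = -ln(negatives/total)} copies per partition,
#' \code{copies/uL = lambda / partition volume}. The confidence interval is
#' Clopper-Pearson binomial on the positive count, propagated through the
#' same transform. A fully positive plate is reported as saturated.
#'
#' @param positives,total_partitions Partition counts.
#' @param partition_volume_ul Partition volume in microliters.
#' @param conf Confidence level.
#' @return Object of class \code{dpcr_result} with \code{lambda},
#'   \code{copies_per_ul}, \code{ci} (copies/uL), \code{saturated}.
#' @export
dpcr_quantify <- function(positives, total_partitions,
                          partition_volume_ul = 0.00091, conf = 0.95) {
  positives <- as.integer(positives); total <- as.integer(total_partitions)
  if (positives < 0L || positives > total)
    stop("dpcr_quantify: positives must be in [0, total]")
  if (partition_volume_ul <= 0) stop("dpcr_quantify: volume must be > 0")
  a <- 1 - conf
  saturated <- positives == total
  p_lo <- if (positives == 0L) 0 else stats::qbeta(a / 2, positives,
                                                   total - positives + 1L)
  p_hi <- if (saturated) 1 else stats::qbeta(1 - a / 2, positives + 1L,
                                             total - positives)
  lambda <- if (saturated) Inf else -log((total - positives) / total)
  to_copies <- function(p) -log(1 - p) / partition_volume_ul
  structure(list(positives = positives, total = total,
                 partition_volume_ul = partition_volume_ul,
                 lambda = lambda,
                 copies_per_ul = lambda / partition_volume_ul,
                 ci = c(lower = to_copies(p_lo), upper = to_copies(p_hi)),
                 conf = conf, saturated = saturated),
            class = "dpcr_result")
}

#' @export
print.dpcr_result <- function(x, ...) {
  cat(sprintf("<dpcr> %d/%d positive, lambda=%.4f, %.1f copies/uL [%.1f, %.1f]%s\n",
              x$positives, x$total, x$lambda, x$copies_per_ul,
              x$ci[["lower"]], x$ci[["upper"]],
              if (x$saturated) " SATURATED" else ""))
  invisible(x)
}

#' Fraction of a target RNA within a pool
#'
#' Ratio of target to pool absolute concentrations (copies/uL) from two
#' digital-PCR results.
#'
#' @param target,pool [dpcr_quantify()] results.
#' @return List with \code{fraction}, \code{target_copies_per_ul},
#'   \code{pool_copies_per_ul}.
#' @export
pool_fraction <- function(target, pool) {
  if (pool$copies_per_ul == 0) stop("pool_fraction: zero pool concentration")
  list(fraction = target$copies_per_ul / pool$copies_per_ul,
       target_copies_per_ul = target$copies_per_ul,
       pool_copies_per_ul = pool$copies_per_ul)
}

#' Membrane-potential fold change from JC-1 intensities
#'
#' \code{FC = (red_t/green_t) / (red_u/green_u)}: the treated-to-untreated
#' ratio of red (aggregate) to green (monomer) fluorescence.
#'
#' @param red_treated,green_treated,red_untreated,green_untreated Positive
#'   fluorescence intensities.
#' @return Fold change (numeric).
#' @export
mmp_fold_change <- function(red_treated, green_treated,
                            red_untreated, green_untreated) {
  v <- c(red_treated, green_treated, red_untreated, green_untreated)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("mmp_fold_change: intensities must be positive")
  (red_treated / green_treated) / (red_untreated / green_untreated)
}

#' Two-sample comparison of group values
#'
#' Two-sided independent-samples t-test; \code{student} assumes equal
#' variances, \code{welch} does not.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean_a},
#'   \code{mean_b}.
#' @export
compare_groups <- function(values_a, values_b,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("compare_groups: each group needs n >= 2")
  if (stats::var(c(values_a - mean(values_a), values_b - mean(values_b))) == 0)
    stop("compare_groups: zero pooled variance")
  tt <- stats::t.test(values_a, values_b,
                      var.equal = (variant == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}

# --- table-level pipeline helpers --------------------------------------------

#' Per-sample delta-CT values from a CT table
#'
#' The table holds one row per sample x assay with replicate columns
#' \code{rep1..repN} (as produced by [generate_ct_table()]). Censored
#' replicates (NA) are excluded from the mean; their count is reported.
#'
#' @param ct_table Data frame with columns \code{sample}, \code{assay},
#'   \code{rep*}, and optionally \code{group}.
#' @param target_assay,reference_assay Assay ids.
#' @return Data frame with \code{sample}, \code{group} (if present),
#'   \code{delta_ct}; attribute \code{censored} counts dropped replicates.
#' @export
ct_table_delta <- function(ct_table, target_assay, reference_assay) {
  repcols <- grep("^rep[0-9]+$", names(ct_table), value = TRUE)
  if (length(repcols) == 0L) stop("ct_table_delta: no rep* columns")
  mean_ct <- function(assay) {
    sub <- ct_table[ct_table$assay == assay, , drop = FALSE]
    m <- rowMeans(sub[, repcols, drop = FALSE], na.rm = TRUE)
    stats::setNames(m, sub$sample)
  }
  mt <- mean_ct(target_assay); mr <- mean_ct(reference_assay)
  samples <- intersect(names(mt), names(mr))
  if (length(samples) == 0L)
    stop("ct_table_delta: no samples shared by the two assays")
  out <- data.frame(sample = samples,
                    delta_ct = unname(mt[samples] - mr[samples]),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(ct_table)) {
    g <- ct_table$group[match(samples, ct_table$sample)]
    out$group <- g
  }
  ncens <- sum(is.na(ct_table[, repcols]))
  attr(out, "censored") <- ncens
  out
}

#' Relative quantification of two groups from a CT table
#'
#' Composition of [ct_table_delta()], [fold_change()] and [compare_groups()]:
#' the full delta-delta-CT pipeline from replicate CTs to fold change and
#' p-value.
#'
#' @param ct_table See [ct_table_delta()]; must carry a \code{group} column.
#' @param target_assay,reference_assay Assay ids.
#' @param group_a,group_b Group labels; fold change is a vs b.
#' @param variant t-test variant, see [compare_groups()].
#' @return List with \code{delta} (per-sample table), \code{ddct}, \code{fc},
#'   and \code{test}.
#' @export
relative_quantification <- function(ct_table, target_assay, reference_assay,
                                    group_a, group_b,
                                    variant = "student") {
  d <- ct_table_delta(ct_table, target_assay, reference_assay)
  if (!"group" %in% names(d))
    stop("relative_quantification: CT table has no group column")
  a <- d$delta_ct[d$group == group_a]
  b <- d$delta_ct[d$group == group_b]
  fcr <- fold_change(a, b)
  list(delta = d, ddct = fcr$ddct, fc = fcr$fc,
       test = compare_groups(a, b, variant = variant))
}

#' Fold changes from an oxidative-stress dataset
#'
#' Computes, per cell line, the treated-vs-untreated fold changes of the
#' dataset produced by [generate_h2o2_dataset()]: RNA (delta-delta-CT vs the
#' reference mRNA), mitochondrial DNA copy number (delta-delta-CT vs the
#' single-copy nuclear reference), and JC-1 membrane potential (ratio of
#' red/green ratios). The summary row reports the across-line means, the
#' form in which such ex vivo panels are usually read.
#'
#' @param dataset List with \code{rna}, \code{mtdna}, \code{mmp} data frames
#'   (see [generate_h2o2_dataset()]).
#' @return List with \code{per_line} data frame (cell line, rna_fc, mtdna_fc,
#'   mmp_fc) and \code{mean} named vector.
#' @export
h2o2_fold_changes <- function(dataset) {
  fc_from_ct <- function(df, target, reference) {
    lines <- unique(df$cell_line)
    vapply(lines, function(cl) {
      sub <- df[df$cell_line == cl, , drop = FALSE]
      sub$group <- sub$condition
      d <- ct_table_delta(sub, target, reference)
      fold_change(d$delta_ct[d$group == "treated"],
                  d$delta_ct[d$group == "untreated"])$fc
    }, 0)
  }
  rna <- fc_from_ct(dataset$rna, "IVS9", "ACTB")
  mtdna <- fc_from_ct(dataset$mtdna, "MT", "HGB")
  lines <- unique(dataset$mmp$cell_line)
  mmp <- vapply(lines, function(cl) {
    sub <- dataset$mmp[dataset$mmp$cell_line == cl, , drop = FALSE]
    tr <- sub[sub$condition == "treated", , drop = FALSE]
    un <- sub[sub$condition == "untreated", , drop = FALSE]
    mmp_fold_change(mean(tr$red), mean(tr$green),
                    mean(un$red), mean(un$green))
  }, 0)
  per_line <- data.frame(cell_line = names(rna), rna_fc = unname(rna),
                         mtdna_fc = unname(mtdna[names(rna)]),
                         mmp_fc = unname(mmp[names(rna)]),
                         stringsAsFactors = FALSE)
  list(per_line = per_line,
       mean = c(rna_fc = mean(per_line$rna_fc),
                mtdna_fc = mean(per_line$mtdna_fc),
                mmp_fc = mean(per_line$mmp_fc)))
}
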