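# Alpha diversity with iterated subsampling, qPCR standard-curve
# quantification with the non-nifH correction, and mock-community
# evaluation metrics.

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` with `p_i` the proportional abundance of OTU i.
#' Equals the OTU count for a perfectly even community and 1 for a
#' single-OTU community; permutation- and scale-invariant in the counts.
#'
#' @param counts non-negative numeric vector of per-OTU counts.
#' @return the inverse Simpson index (>= 1 for any non-degenerate input).
#' @export
inverse_simpson <- function(counts) {
  counts <- counts[counts > 0]
  tot <- sum(counts)
  if (!length(counts) || tot <= 0) stop("inverse_simpson: all counts zero")
  p <- counts / tot
  1 / sum(p^2)
}

#' Bootstrapped richness and diversity by iterated subsampling
#'
#' Samples whose read depth falls strictly below the nearest-rank 15th
#' percentile of depths are dropped; the remaining samples are repeatedly
#' subsampled without replacement to the minimum surviving depth, and
#' observed richness and inverse Simpson are averaged over iterations
#' (the reported `se` is the standard deviation of the statistic across
#' iterations).
#'
#' @param table an `otu_table` from [map_reads()], or a plain numeric
#'   matrix (rows = OTUs, columns = samples).
#' @param iterations subsampling iterations (default 1000).
#' @param drop_percentile percentile of depths below which samples are
#'   dropped (default 15, nearest-rank).
#' @param seed integer seed for reproducibility.
#' @return data.frame with one row per sample: richness mean/se, inverse
#'   Simpson mean/se, subsample depth, `dropped` flag.
#' @export
bootstrap_diversity <- function(table, iterations = 1000L,
                                drop_percentile = 15, seed = 1L) {
  counts <- if (inherits(table, "otu_table")) table$otus else as.matrix(table)
  depths <- colSums(counts)
  if (!length(depths)) stop("bootstrap_diversity: no samples")
  # nearest-rank percentile
  sorted <- sort(depths)
  rank <- max(1L, ceiling(drop_percentile / 100 * length(sorted)))
  threshold <- sorted[rank]
  dropped <- depths < threshold
  if (all(dropped)) stop("bootstrap_diversity: no samples survive the drop")
  depth <- min(depths[!dropped])
  set.seed(seed)
  out <- lapply(colnames(counts), function(s) {
    if (dropped[s])
      return(data.frame(sample_id = s, richness_mean = NA_real_,
                        richness_se = NA_real_, inv_simpson_mean = NA_real_,
                        inv_simpson_se = NA_real_, subsample_depth = depth,
                        iterations = iterations, dropped = TRUE))
    pool <- rep(seq_len(nrow(counts)), counts[, s])
    rich <- numeric(iterations); invs <- numeric(iterations)
    for (it in seq_len(iterations)) {
      sub <- if (length(pool) == depth) pool else sample(pool, depth)
      tab <- tabulate(sub, nbins = nrow(counts))
      rich[it] <- sum(tab > 0)
      invs[it] <- inverse_simpson(tab)
    }
    data.frame(sample_id = s, richness_mean = mean(rich),
               richness_se = sd(rich), inv_simpson_mean = mean(invs),
               inv_simpson_se = sd(invs), subsample_depth = depth,
               iterations = iterations, dropped = FALSE)
  })
  do.call(rbind, out)
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(copies) over a dilution
#' series; amplification efficiency is `10^(-1/slope) - 1` (1.0 = a
#' perfect doubling per cycle corresponds to a slope of -3.32).
#'
#' @param copies known copy numbers of the standards.
#' @param cq measured quantification cycles.
#' @return object of class `qpcr_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency`.
#' @export
fit_standard_curve <- function(copies, cq) {
  if (length(copies) != length(cq)) stop("fit_standard_curve: length mismatch")
  lg <- log10(copies)
  if (length(unique(lg)) < 3L)
    stop("fit_standard_curve: need >= 3 distinct concentrations")
  fit <- lm(cq ~ lg)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = 1 - ss_res / ss_tot,
                 efficiency = 10^(-1 / slope) - 1,
                 n = length(cq)),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat(sprintf(
    "<qpcr_curve> slope %.4f, intercept %.2f, r^2 %.4f, efficiency %.1f%%\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Invert a standard curve to copy numbers
#'
#' Replicate Cq values are averaged before inversion.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param cq numeric vector of replicate Cq values for one sample.
#' @return estimated copy number.
#' @export
quantify <- function(curve, cq) {
  10^((mean(cq) - curve$intercept) / curve$slope)
}

#' Correct qPCR copy numbers for non-target amplification
#'
#' Multiplies the estimated copies by the fraction of reads the pipeline
#' identified as genuine nifH, excluding co-amplified homologs from the
#' quantification.
#'
#' @param copies estimated copies.
#' @param nifh_read_fraction fraction of reads classified nifH, in
#'   \[0, 1\].
#' @return corrected copies.
#' @export
correct_nifh_copies <- function(copies, nifh_read_fraction) {
  if (any(nifh_read_fraction < 0 | nifh_read_fraction > 1))
    stop("correct_nifh_copies: fraction must be in [0, 1]")
  copies * nifh_read_fraction
}

#' Declare a mock community
#'
#' @param members member names.
#' @param proportions expected proportions; must sum to 1 (a vector of
#'   percentages summing to 100 is also accepted).
#' @return object of class `mock_spec`.
#' @export
mock_spec <- function(members, proportions) {
  if (length(members) != length(proportions)) stop("mock_spec: length mismatch")
  if (abs(sum(proportions) - 100) < 1e-6) proportions <- proportions / 100
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("mock_spec: proportions must sum to 1")
  structure(list(members = members,
                 proportions = setNames(proportions, members)),
            class = "mock_spec")
}

#' Compare an observed mock composition to its design
#'
#' Reports per-member observed percentages, bias ratios
#' (observed/expected), and the total variation distance between the
#' observed and declared compositions. Observed members missing from the
#' declaration are reported separately as contaminants.
#'
#' @param observed named numeric vector of per-member read counts.
#' @param spec a [mock_spec()].
#' @return object of class `mock_evaluation`: data.frame `members`
#'   (expected/observed percent, bias ratio, zero flag), `tvd`,
#'   `contaminants`.
#' @export
evaluate_mock <- function(observed, spec) {
  if (sum(observed) <= 0) stop("evaluate_mock: zero total reads")
  known <- names(observed) %in% spec$members
  contaminants <- observed[!known]
  obs <- setNames(numeric(length(spec$members)), spec$members)
  obs[names(observed)[known]] <- observed[known]
  obs_frac <- obs / sum(observed)
  exp_frac <- spec$proportions
  tvd <- 0.5 * sum(abs(obs_frac - exp_frac)) +
    0.5 * sum(contaminants) / sum(observed)
  members <- data.frame(
    member = spec$members,
    expected_percent = 100 * unname(exp_frac),
    observed_percent = 100 * unname(obs_frac),
    bias_ratio = unname(obs_frac / exp_frac),
    missing = unname(obs) == 0)
  structure(list(members = members, tvd = tvd,
                 contaminants = contaminants),
            class = "mock_evaluation")
}

#' @export
print.mock_evaluation <- function(x, ...) {
  cat("<mock_evaluation> TVD =", round(x$tvd, 4), "\n")
  print(x$members, row.names = FALSE)
  if (length(x$contaminants))
    cat("contaminants:", paste(names(x$contaminants), x$contaminants,
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}
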