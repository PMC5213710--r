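#' Quality-control filter on MRS records
#'
#' Excludes any record whose Cramer-Rao lower bound exceeds 20% for a
#' metabolite in use (the rule is strictly "exceeded": a CRLB of exactly
#' 20% is retained).
#'
#' @param records an `mrs_records` data frame.
#' @param crlb_max exclusion threshold in percent.
#' @param metabolites which CRLB fields to screen.
#' @return the retained records, with an `exclusions` attribute naming the
#'   excluded participant and metabolite(s).
#' @export
qc_filter <- function(records, crlb_max = 20,
                      metabolites = c("gaba", "glutamate")) {
  cols <- paste0("crlb_", metabolites)
  miss <- setdiff(cols, names(records))
  if (length(miss)) stopf("records lack CRLB field(s): %s",
                          paste(miss, collapse = ", "))
  bad <- records[, cols, drop = FALSE] > crlb_max
  drop <- rowSums(bad) > 0
  log <- do.call(rbind, lapply(which(drop), function(i) data.frame(
    participant_id = records$participant_id[i],
    metabolite = paste(metabolites[bad[i, ]], collapse = "+"),
    crlb = max(unlist(records[i, cols])))))
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- log %||% data.frame()
  out
}

#' Creatine normalisation and partial-volume correction
#'
#' Expresses glutamate and GABA as ratios to total creatine, with four
#' conventions for handling partial brain volume in the voxel:
#' \describe{
#' \item{A}{plain creatine ratios; the tissue composition is not divided
#'   out but exposed as covariates (`rel_grey`, `rel_white` = grey/white
#'   fraction of the voxel, and `total_tissue` = grey + white fraction)
#'   for use in partial correlations.}
#' \item{B}{`(metabolite/creatine) / grey_frac`.}
#' \item{C}{`(metabolite/creatine) / (grey_frac + white_frac)`.}
#' \item{D}{`(metabolite/grey_frac) / (creatine/(grey_frac + white_frac))`.}
#' }
#'
#' @param records QC-passed `mrs_records`.
#' @param variant `"A"`, `"B"`, `"C"` or `"D"`.
#' @return a data frame with `participant_id`, `group`, `glutamate`,
#'   `gaba`, `glu_minus_gaba`, the covariate columns (variant A) and a
#'   `correction_variant` attribute.
#' @examples
#' rec <- data.frame(participant_id = "p1", group = 0, glutamate_raw = 2,
#'                   gaba_raw = 0.5, creatine_raw = 1, grey_frac = 0.5,
#'                   white_frac = 0.3, csf_frac = 0.2)
#' correct_measures(rec, "C")$glutamate  # 2/0.8 = 2.5
#' @export
correct_measures <- function(records, variant = c("A", "B", "C", "D")) {
  variant <- match.arg(variant)
  r <- as.data.frame(records)
  if (any(r$creatine_raw <= 0))
    stopf("record(s) with non-positive creatine: %s",
          paste(r$participant_id[r$creatine_raw <= 0], collapse = ", "))
  if (any(r$grey_frac <= 0 | (r$grey_frac + r$white_frac) <= 0))
    stopf("record(s) with zero tissue fraction: %s",
          paste(r$participant_id[r$grey_frac <= 0], collapse = ", "))
  gcr <- r$glutamate_raw / r$creatine_raw
  bcr <- r$gaba_raw / r$creatine_raw
  tot <- r$grey_frac + r$white_frac
  vals <- switch(variant,
    A = list(glu = gcr, gaba = bcr),
    B = list(glu = gcr / r$grey_frac, gaba = bcr / r$grey_frac),
    C = list(glu = gcr / tot, gaba = bcr / tot),
    D = list(glu = (r$glutamate_raw / r$grey_frac) / (r$creatine_raw / tot),
             gaba = (r$gaba_raw / r$grey_frac) / (r$creatine_raw / tot)))
  out <- data.frame(participant_id = r$participant_id,
                    group = r$group %||% 0L,
                    glutamate = vals$glu, gaba = vals$gaba,
                    glu_minus_gaba = vals$glu - vals$gaba)
  if (variant == "A") {
    out$rel_grey <- r$grey_frac
    out$rel_white <- r$white_frac
    out$total_tissue <- tot
  }
  attr(out, "correction_variant") <- variant
  out
}

#' Nonparametric (Spearman) partial correlation
#'
#' Rank-transforms `x`, `y` and every covariate, residualises the ranks of
#' `x` and `y` on the covariate ranks (plus intercept) by least squares,
#' and correlates the residuals.  With no covariates this reduces exactly
#' to the ordinary Spearman rank correlation.  The two-sided p-value uses
#' the t approximation with `df = n - q - 2`, where `q` is the *rank* of
#' the covariate matrix, so perfectly collinear covariates are not
#' double-counted.  A seeded permutation p-value (permuting the
#' residualised ranks of `y`) is available for small samples.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data frame / matrix of covariates.
#' @param n_perm if > 0, number of permutations for a permutation p-value.
#' @param seed seed for the permutation draw.
#' @return a list: `rho`, `p`, `n`, `df`, `covariates` (names), `method`.
#' @export
partial_spearman <- function(x, y, covariates = NULL, n_perm = 0, seed = 1) {
  if (length(x) != length(y)) stopf("`x` and `y` differ in length")
  if (sd(x) < 1e-14 || sd(y) < 1e-14)
    stopf("`x` and `y` must not be constant")
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.data.frame(covariates)
    if (nrow(cv) != n) stopf("covariates have a different length")
    Z <- cbind(1, apply(as.matrix(cv), 2, rank))
    q <- qr(Z)$rank - 1
    if (n <= q + 2) stopf("need n > number of (independent) covariates + 2")
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
    cov_names <- colnames(cv)
  } else { q <- 0; cov_names <- character() }
  rho <- cor(rx, ry)
  df <- n - q - 2
  tstat <- rho * sqrt(df / max(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df)
  method <- "t"
  if (n_perm > 0) {
    obs <- abs(rho)
    exceed <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i)
      abs(cor(rx, sample(ry))) >= obs - 1e-12, logical(1))))
    p <- (exceed + 1) / (n_perm + 1)
    method <- "permutation"
  }
  list(rho = rho, p = p, n = n, df = df, covariates = cov_names,
       method = method)
}

#' Partial-correlation analysis linking neurochemistry to behavior
#'
#' Reproduces the full analysis battery relating dACC glutamate/GABA to
#' the learning-model parameters:
#' \enumerate{
#' \item Spearman partial correlation of the glutamate-minus-GABA contrast
#'   with the use-of-learnt-information parameter `gamma`, controlling for
#'   group assignment, inverse temperature `beta` and (variant A) the
#'   tissue-composition covariates.
#' \item The same for glutamate with `gamma` controlling additionally for
#'   GABA, and for GABA controlling additionally for glutamate.
#' \item A specificity screen of the contrast against every model
#'   parameter (`gamma`, `beta`, `alpha`, `lambda`), Bonferroni threshold
#'   0.0125 for the four tests.
#' \item The plain (Pearson) glutamate-GABA correlation.
#' }
#'
#' @param records `mrs_records` (QC is applied first).
#' @param fit a `fit_result` whose `estimates` carry the behavioral
#'   parameters, matched to `records` by `participant_id`.
#' @param variant partial-volume correction variant, see
#'   [correct_measures()].
#' @return a `neurochem_result` list: `correlations` (tidy data frame of
#'   every test: `analysis`, `x`, `y`, `rho`, `p`, `n`, `df`),
#'   `glu_gaba_r`, `bonferroni` (threshold 0.0125), `excluded`.
#' @export
neurochem_behavior_analysis <- function(records, fit,
                                        variant = c("A", "B", "C", "D")) {
  variant <- match.arg(variant)
  kept <- qc_filter(records)
  cm <- correct_measures(kept, variant)
  est <- fit$estimates
  est <- est[, setdiff(names(est), "group"), drop = FALSE]
  unmatched <- setdiff(cm$participant_id, est$participant_id)
  if (length(unmatched))
    stopf("participants without behavioral estimates: %s",
          paste(unmatched, collapse = ", "))
  d <- merge(cm, est, by = "participant_id")
  tissue <- if (variant == "A") c("rel_grey", "rel_white", "total_tissue")
            else character()
  base_cov <- function(extra = character(), drop = character()) {
    cols <- setdiff(unique(c("group", "beta", tissue, extra)), drop)
    d[, cols, drop = FALSE]
  }
  row_of <- function(analysis, x, y, ps) data.frame(
    analysis = analysis, x = x, y = y, rho = ps$rho, p = ps$p, n = ps$n,
    df = ps$df)
  out <- list()
  out[[1]] <- row_of("contrast_vs_gamma", "glu_minus_gaba", "gamma",
                     partial_spearman(d$glu_minus_gaba, d$gamma, base_cov()))
  out[[2]] <- row_of("glutamate_vs_gamma", "glutamate", "gamma",
                     partial_spearman(d$glutamate, d$gamma,
                                      cbind(base_cov(), gaba = d$gaba)))
  out[[3]] <- row_of("gaba_vs_gamma", "gaba", "gamma",
                     partial_spearman(d$gaba, d$gamma,
                                      cbind(base_cov(), glutamate = d$glutamate)))
  screen_pars <- intersect(c("gamma", "beta", "alpha", "lambda"), names(est))
  for (p in screen_pars) {
    ps <- partial_spearman(d$glu_minus_gaba, d[[p]],
                           base_cov(drop = if (p == "beta") "beta"))
    out[[length(out) + 1]] <- row_of(paste0("specificity_", p),
                                     "glu_minus_gaba", p, ps)
  }
  ct <- cor.test(d$glutamate, d$gaba)
  correlations <- do.call(rbind, out)
  structure(list(correlations = correlations,
                 glu_gaba_r = unname(ct$estimate), glu_gaba_p = ct$p.value,
                 bonferroni = 0.0125, variant = variant,
                 n = nrow(d),
                 excluded = attr(kept, "exclusions")),
            class = "neurochem_result")
}

#' @export
print.neurochem_result <- function(x, ...) {
  cat(sprintf("<neurochem_result variant %s, n = %d> r(glu, gaba) = %.2f (p = %.3g)\n",
              x$variant, x$n, x$glu_gaba_r, x$glu_gaba_p))
  print(x$correlations, row.names = FALSE, digits = 3)
  cat(sprintf("specificity screen Bonferroni threshold: p < %.4f\n",
              x$bonferroni))
  invisible(x)
}
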