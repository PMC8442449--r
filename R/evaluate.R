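#' Fit a linear mixed model of a similarity measure against model labels
#'
#' `measure ~ 0 + label + (1 | animal_id)`, fitted by restricted maximum
#' likelihood with lme4. The per-animal random intercept absorbs the
#' repeated-measures correlation of the 100 replicates per animal. On a
#' singular or failed fit the function falls back to per-label means with
#' animal-clustered standard errors, flagged in the `method` field.
#'
#' @param scores data frame from [score_batch()] (columns `animal_id`,
#'   `label`, and the measure column).
#' @param measure one of `"mean_distance"`, `"dtw"`, `"di"`.
#' @return an object of class `lmm_fit`: list with `measure`, `estimates`
#'   (data frame label/estimate/se), `random_intercept_sd`, `n_obs`,
#'   `method` (`"lmm"` or `"cluster_means"`).
#' @export
fit_strategy_lmm <- function(scores, measure = c("mean_distance", "dtw",
                                                 "di")) {
  measure <- match.arg(measure)
  d <- data.frame(y = scores[[measure]],
                  label = factor(scores$label),
                  animal_id = factor(scores$animal_id))
  fit <- NULL
  singular <- TRUE
  if (nlevels(d$animal_id) >= 2) {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(y ~ 0 + label + (1 | animal_id), data = d,
                                  REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) singular <- lme4::isSingular(fit, tol = 1e-5)
  }
  if (!is.null(fit) && !singular) {
    cf <- summary(fit)$coefficients
    est <- data.frame(label = sub("^label", "", rownames(cf)),
                      estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"],
                      stringsAsFactors = FALSE, row.names = NULL)
    sd_a <- sqrt(unname(lme4::VarCorr(fit)$animal_id[1]))
    method <- "lmm"
  } else {
    # cluster-robust fallback: label means, SE from between-animal spread
    est <- do.call(rbind, lapply(split(d, d$label), function(s) {
      am <- tapply(s$y, droplevels(s$animal_id), mean)
      data.frame(label = as.character(s$label[1]), estimate = mean(s$y),
                 se = if (length(am) > 1)
                   stats::sd(am) / sqrt(length(am)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(est) <- NULL
    sd_a <- NA_real_
    method <- "cluster_means"
  }
  structure(list(measure = measure, estimates = est,
                 random_intercept_sd = sd_a, n_obs = nrow(d),
                 method = method),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit %s (%s), %d obs, animal sd %.4g>\n", x$measure,
              x$method, x$n_obs, x$random_intercept_sd))
  print(x$estimates)
}

#' @keywords internal
strategy_of_label <- function(label) {
  pre <- sub("_.*$", "", label)
  c(no = "NO_BIAS", taxis = "TAXIS", ch = "CONSTANT_HEADING",
    bigrad = "BIGRADIENT", comb = "COMBINATION")[pre]
}

#' Choose the best cue variant of each strategy
#'
#' From fitted per-label estimates, selects for every strategy family the
#' cue variant with the most favourable estimate on the reference measure:
#' lowest for `mean_distance` and `dtw`, highest for `di`. The no-bias
#' control maps to itself. Exact ties resolve to the lexicographically
#' smallest label.
#'
#' @param fit an `lmm_fit` for the reference measure.
#' @return named character vector: strategy family -> selected label.
#' @export
select_best_variant <- function(fit) {
  est <- fit$estimates
  est$strategy <- strategy_of_label(est$label)
  lower_better <- fit$measure %in% c("mean_distance", "dtw")
  out <- vapply(split(est, est$strategy), function(s) {
    s <- s[order(s$label), ]   # lexicographic tie-break
    if (lower_better) s$label[which.min(s$estimate)]
    else s$label[which.max(s$estimate)]
  }, character(1))
  out
}

#' Top-decile strategy counts
#'
#' Ranks the pooled scores (one retained cue variant per strategy, equal
#' replicate counts) by the given measure - ascending for `mean_distance`
#' and `dtw`, descending for `di` - retains the best
#' `floor(fraction * N)` rows and tallies strategy membership. With five
#' strategies and no geomagnetic effect each strategy expects 20% of the
#' retained set. Ranking ties are broken by a stable sort on
#' (score, animal_id, replicate).
#'
#' @param scores pooled score table (columns `animal_id`, `label`,
#'   `replicate` and the measure).
#' @param measure one of `"mean_distance"`, `"dtw"`, `"di"`.
#' @param fraction retained fraction (default 0.10).
#' @return an object of class `strategy_counts`: data frame with `strategy`,
#'   `label`, `count`, `proportion`, plus attributes `measure`,
#'   `n_retained`.
#' @export
top_decile_counts <- function(scores, measure = c("mean_distance", "dtw",
                                                  "di"),
                              fraction = 0.10) {
  measure <- match.arg(measure)
  stopifnot(fraction > 0, fraction <= 1)
  tab <- table(scores$label)
  strat <- strategy_of_label(names(tab))
  if (anyDuplicated(strat))
    stop("pooled table must contain exactly one retained variant per ",
         "strategy; got labels ", paste(names(tab), collapse = ", "))
  if (length(unique(as.integer(tab))) != 1)
    stop("unequal per-strategy replicate counts: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  n_keep <- floor(fraction * nrow(scores))
  s <- scores[[measure]]
  if (measure == "di") s <- -s   # descending: high similarity first
  ord <- order(s, scores$animal_id, scores$replicate)
  top <- scores[ord[seq_len(n_keep)], ]
  counts <- table(factor(top$label, levels = sort(names(tab))))
  out <- data.frame(strategy = unname(strategy_of_label(names(counts))),
                    label = names(counts),
                    count = as.integer(counts),
                    proportion = as.integer(counts) / n_keep,
                    stringsAsFactors = FALSE)
  structure(out, measure = measure, n_retained = n_keep,
            class = c("strategy_counts", "data.frame"))
}

#' Run the full evaluation stage
#'
#' Fits the mixed model for each similarity measure over all simulated
#' model labels, selects the best cue variant per strategy on the reference
#' measure, pools the retained variants and computes top-decile counts per
#' measure.
#'
#' @param scores score table over all simulated models (from
#'   [score_batch()]).
#' @param reference_measure measure driving best-variant selection
#'   (default `"mean_distance"`).
#' @param fraction retained fraction for the counting stage.
#' @return list with `fits` (per-measure `lmm_fit`s), `retained` (selected
#'   labels), `counts` (per-measure `strategy_counts`).
#' @export
evaluate_strategies <- function(scores,
                                reference_measure = "mean_distance",
                                fraction = 0.10) {
  measures <- c("mean_distance", "dtw", "di")
  fits <- lapply(measures, function(m) fit_strategy_lmm(scores, m))
  names(fits) <- measures
  retained <- select_best_variant(fits[[reference_measure]])
  pooled <- scores[scores$label %in% retained, ]
  counts <- lapply(measures, function(m)
    top_decile_counts(pooled, m, fraction))
  names(counts) <- measures
  list(fits = fits, retained = retained, counts = counts)
}
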