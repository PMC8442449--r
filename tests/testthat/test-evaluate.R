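make_scores <- function(labels, n_animals, n_rep, effects, animal_sd = 0,
                        noise_sd = 1, seed = 1) {
  set.seed(seed)
  animals <- sprintf("a%02d", seq_len(n_animals))
  intercepts <- stats::rnorm(n_animals, 0, animal_sd)
  rows <- expand.grid(animal_id = animals, label = labels,
                      replicate = seq_len(n_rep),
                      stringsAsFactors = FALSE)
  rows$mean_distance <- 100 + effects[rows$label] +
    intercepts[match(rows$animal_id, animals)] +
    stats::rnorm(nrow(rows), 0, noise_sd)
  rows$dtw <- rows$mean_distance * 3
  rows$di <- -rows$mean_distance / 400
  rows
}

test_that("mixed model recovers label effects with animal intercepts", {
  eff <- c(no_bias = 0, taxis_F = -30)
  sc <- make_scores(names(eff), n_animals = 14, n_rep = 50, effects = eff,
                    animal_sd = 20, noise_sd = 10, seed = 42)
  fit <- fit_strategy_lmm(sc, "mean_distance")
  expect_equal(fit$method, "lmm")
  expect_equal(fit$n_obs, 1400)
  est <- fit$estimates
  diff_hat <- est$estimate[est$label == "taxis_F"] -
    est$estimate[est$label == "no_bias"]
  se <- sqrt(sum(est$se^2))
  expect_lt(abs(diff_hat - (-30)), 2 * se + 1)
  expect_gt(fit$random_intercept_sd, 5)   # injected at 20
})

test_that("degenerate designs collapse to per-label means", {
  # single label: intercept equals the grand mean
  sc <- make_scores("no_bias", 5, 10, c(no_bias = 7), animal_sd = 0,
                    noise_sd = 2, seed = 3)
  fit <- fit_strategy_lmm(sc, "mean_distance")
  expect_equal(fit$estimates$estimate, mean(sc$mean_distance),
               tolerance = 1e-6)
  # balanced data with zero animal variance: estimates equal label means
  eff <- c(no_bias = 0, taxis_F = -5)
  sc2 <- make_scores(names(eff), 6, 20, eff, animal_sd = 0, noise_sd = 1,
                     seed = 8)
  fit2 <- fit_strategy_lmm(sc2, "mean_distance")
  bylab <- tapply(sc2$mean_distance, sc2$label, mean)
  expect_equal(fit2$estimates$estimate[order(fit2$estimates$label)],
               as.numeric(bylab[order(names(bylab))]), tolerance = 1e-6)
})

test_that("best-variant selection honours measure direction and ties", {
  fit <- structure(list(
    measure = "mean_distance",
    estimates = data.frame(
      label = c("taxis_F", "taxis_H", "taxis_I", "no_bias"),
      estimate = c(210, 290, 240, 260), se = 1)),
    class = "lmm_fit")
  sel <- select_best_variant(fit)
  expect_equal(unname(sel["TAXIS"]), "taxis_F")
  expect_equal(unname(sel["NO_BIAS"]), "no_bias")
  # di: higher is better
  fit$measure <- "di"
  fit$estimates <- data.frame(label = c("taxis_F", "taxis_I"),
                              estimate = c(0.4, 0.6), se = 1)
  expect_equal(unname(select_best_variant(fit)["TAXIS"]), "taxis_I")
  # exact tie: lexicographically smallest label
  fit$estimates$estimate <- c(0.5, 0.5)
  expect_equal(unname(select_best_variant(fit)["TAXIS"]), "taxis_F")
})

test_that("top-decile counting matches a hand-ranked toy table", {
  labels <- c("no_bias", "taxis_F", "ch_minF", "bigrad_FI", "comb_FI")
  # 10 rows per label; scores arranged so the best 5 are taxis x3, ch x2
  sc <- data.frame(animal_id = "a1",
                   label = rep(labels, each = 10),
                   replicate = rep(1:10, times = 5))
  sc$mean_distance <- 100 + seq_len(50)
  sc$mean_distance[sc$label == "taxis_F"][1:3] <- c(1, 2, 3)
  sc$mean_distance[sc$label == "ch_minF"][1:2] <- c(4, 5)
  tc <- top_decile_counts(sc, "mean_distance", fraction = 0.10)
  expect_equal(attr(tc, "n_retained"), 5)
  expect_equal(tc$count[tc$label == "taxis_F"], 3L)
  expect_equal(tc$count[tc$label == "ch_minF"], 2L)
  expect_equal(sum(tc$count), 5L)
  expect_equal(sum(tc$proportion), 1)
  # invariant under strictly monotone transforms of the score
  sc2 <- sc; sc2$mean_distance <- sqrt(sc2$mean_distance)
  expect_equal(top_decile_counts(sc2, "mean_distance", 0.10)$count,
               tc$count)
  # di ranks descending
  sc$di <- -sc$mean_distance
  tcd <- top_decile_counts(sc, "di", 0.10)
  expect_equal(tcd$count, tc$count)
  # unequal per-strategy counts are rejected
  expect_error(top_decile_counts(sc[-1, ], "mean_distance"),
               "unequal per-strategy")
  # two variants of one strategy are rejected
  sc3 <- sc; sc3$label[sc3$label == "no_bias"] <- "taxis_H"
  expect_error(top_decile_counts(sc3, "mean_distance"),
               "one retained variant")
})

test_that("full evaluation wires fits, selection and counting together", {
  eff <- c(no_bias = 0, taxis_F = -20, taxis_H = -5, ch_minF = 10,
           bigrad_FI = 5, comb_FI = 2)
  sc <- make_scores(names(eff), 6, 25, eff, animal_sd = 5, noise_sd = 8,
                    seed = 11)
  ev <- evaluate_strategies(sc)
  expect_equal(unname(ev$retained["TAXIS"]), "taxis_F")
  expect_named(ev$counts, c("mean_distance", "dtw", "di"))
  tc <- ev$counts$mean_distance
  expect_equal(sum(tc$count), attr(tc, "n_retained"))
  expect_equal(attr(tc, "n_retained"), floor(0.10 * 6 * 25 * 5))
  # taxis has the strongest (lowest) scores, so it should dominate
  expect_equal(tc$strategy[which.max(tc$count)], "TAXIS")
})
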