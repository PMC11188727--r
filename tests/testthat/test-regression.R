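# hand-built cohort_table over pre-made 0/1 columns, bypassing the survey
# layer, for unit tests of the modelling stages
make_cohort <- function(data, frd_curies = character(), imputed = TRUE) {
  data <- as.data.frame(data, check.names = FALSE)
  stats <- data.frame(
    feature = names(data),
    mean_prevalence = vapply(data, function(x) mean(x, na.rm = TRUE), 0),
    sd_prevalence = vapply(data, function(x) sd(x, na.rm = TRUE), 0),
    missingness_rate = vapply(data, function(x) mean(is.na(x)), 0))
  structure(list(data = data, stats = stats,
                 respondent_id = sprintf("%05d", seq_len(nrow(data))),
                 frd_curies = frd_curies,
                 topics = setNames(names(data), names(data)),
                 imputed = imputed),
            class = "cohort_table")
}

test_that("cohort building filters rows and counts cells by hand", {
  keys <- data.frame(
    question_id = c("Q1", "Q2"), question_type = "binary",
    option_label = "", curie = c("HP:0000001", "MONDO:0000001"),
    predicate = c("has_phenotype", "has_disease"), survey = "health")
  tab <- data.frame(
    respondent_id = sprintf("%07d", 1:6),
    sex = c("female", "female", "female", "female", "male", "female"),
    completed_health = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    completed_internal = TRUE, completed_external = TRUE,
    Q1 = c("yes", "no", NA, "yes", "yes", "yes"),
    Q2 = c("no", "no", "yes", "no", "no", "no"))
  cohort <- build_cohort_table(tab, keys, list(),
                               c(x = "MONDO:0000001"))
  # rows: females 1-4 (5 is male, 6 incomplete)
  expect_equal(nrow(cohort$data), 4)
  # hand counts: Q1 = yes,no,NA,yes -> prevalence 2/3, missingness 1/4
  st <- cohort$stats[cohort$stats$feature == "HP:0000001", ]
  expect_equal(st$mean_prevalence, 2 / 3)
  expect_equal(st$missingness_rate, 1 / 4)
  # outcome column is excluded from the feature side
  xy <- exposomekg:::cohort_xy(cohort, "MONDO:0000001")
  expect_false("MONDO:0000001" %in% colnames(xy$x))
  # an all-male table gives an empty-cohort error
  tab$sex <- "male"
  expect_error(build_cohort_table(tab, keys, list(), character()),
               "empty cohort")
})

test_that("imputation recovers duplicated columns and is deterministic", {
  set.seed(12)
  n <- 400
  a <- rbinom(n, 1, 0.5)
  b <- a
  b[sample(n, 40)] <- NA
  noise1 <- rbinom(n, 1, 0.3)
  noise2 <- rbinom(n, 1, 0.6)
  cohort <- make_cohort(list(A = a, B = b, C = noise1, D = noise2),
                        imputed = FALSE)
  imp <- impute_rf_iterative(cohort, seed = 3)
  expect_false(any(is.na(imp$data)))
  idx <- which(is.na(b))
  expect_gte(mean(imp$data$B[idx] == a[idx]), 0.95)
  imp2 <- impute_rf_iterative(cohort, seed = 3)
  expect_identical(imp$data, imp2$data)
  # no missing cells: returned unchanged
  full <- make_cohort(list(A = a, C = noise1), imputed = FALSE)
  expect_identical(impute_rf_iterative(full, seed = 1)$data, full$data)
  # an all-missing column is a named error
  bad <- make_cohort(list(A = a, Z = rep(NA_integer_, n)), imputed = FALSE)
  expect_error(impute_rf_iterative(bad, seed = 1), "Z")
})

test_that("elastic net keeps signal, drops constants, may select nothing", {
  set.seed(21)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  copy <- y
  noise <- replicate(5, rbinom(n, 1, 0.4))
  colnames(noise) <- paste0("N", 1:5)
  cohort <- make_cohort(c(list(Y = y, COPY = copy, CONST = rep(1L, n)),
                          as.list(as.data.frame(noise))))
  expect_message(sel <- elastic_net_select(cohort, "Y", seed = 2),
                 "constant")
  expect_true("COPY" %in% sel)
  # pure-noise outcome: empty selection is a valid value and the pipeline
  # returns an explicit empty result
  cohort0 <- make_cohort(c(list(Y = rbinom(n, 1, 0.3)),
                           as.list(as.data.frame(noise))))
  res <- run_regression_frd(cohort0, "Y", seed = 5)
  expect_s3_class(res, "regression_result")
  expect_true(nrow(res) <= 5)
})

test_that("permutation importance ranks real signal above noise", {
  set.seed(31)
  n <- 600
  y <- rbinom(n, 1, 0.4)
  cohort <- make_cohort(list(Y = y, SIG = y,
                             N1 = rbinom(n, 1, 0.5),
                             N2 = rbinom(n, 1, 0.5)))
  imp <- rf_permutation_importance(cohort, "Y", c("SIG", "N1", "N2"),
                                   n_repeats = 5, seed = 4)
  expect_gt(imp$importance[imp$feature == "SIG"],
            max(imp$importance[imp$feature != "SIG"]) + 0.1)
  expect_true(imp$kept[imp$feature == "SIG"])
  imp2 <- rf_permutation_importance(cohort, "Y", c("SIG", "N1", "N2"),
                                    n_repeats = 5, seed = 4)
  expect_identical(imp, imp2)
  expect_error(
    rf_permutation_importance(cohort, "Y", "SIG", n_repeats = 1, seed = 1),
    "n_repeats")
})

test_that("single-predictor odds ratio equals the 2x2 cross-product", {
  # a=20 exposed cases, b=80 exposed controls, c=10, d=90
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  cohort <- make_cohort(list(Y = y, X = x))
  res <- fit_logistic_report(cohort, "Y", "X")
  expect_equal(res$odds_ratio, 2.25, tolerance = 1e-7)
  expect_equal(res$vif, 1)
})

test_that("logistic estimates match an independent IRLS fit to 6 figures", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(300:800, 1)
    k <- sample(2:5, 1)
    x <- matrix(rbinom(n * k, 1, runif(k, 0.2, 0.6)), n, k,
                dimnames = list(NULL, paste0("F", 1:k)))
    eta <- -1 + x %*% rnorm(k, 0, 0.7)
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    cohort <- make_cohort(c(list(Y = y), as.list(as.data.frame(x))))
    res <- fit_logistic_report(cohort, "Y", colnames(x))
    oracle <- oracle_logistic(x, y)
    expect_equal(log(res$odds_ratio), oracle$beta[-1], tolerance = 1e-6)
    expect_equal(res$se, oracle$se[-1], tolerance = 1e-6)
    # Wald z agrees to 6 figures; deep-tail p-values amplify the tiny SE
    # difference by z^2, hence the slightly wider tolerance on p itself
    expect_equal(log(res$odds_ratio) / res$se,
                 oracle$beta[-1] / oracle$se[-1], tolerance = 1e-6)
    expect_equal(res$p_raw, oracle$p[-1], tolerance = 1e-5)
    expect_true(all(res$ci_lower <= res$odds_ratio &
                      res$odds_ratio <= res$ci_upper))
  }
})

test_that("orthogonal predictors have unit VIF and separation is flagged", {
  x1 <- rep(c(0, 1), each = 200)
  x2 <- rep(c(0, 1, 0, 1), each = 100)  # orthogonal to x1
  set.seed(51)
  y <- rbinom(400, 1, plogis(-0.5 + 0.5 * x1))
  cohort <- make_cohort(list(Y = y, A = x1, B = x2))
  res <- fit_logistic_report(cohort, "Y", c("A", "B"))
  expect_equal(res$vif, c(1, 1), tolerance = 1e-12)
  # complete separation: flagged per feature, VIF omitted, no crash
  sep <- make_cohort(list(Y = x1, S = x1, B = x2))
  res2 <- fit_logistic_report(sep, "Y", c("S", "B"))
  expect_true(res2$flagged[res2$feature == "S"])
  expect_true(is.na(res2$vif[res2$feature == "S"]))
})

test_that("Bonferroni adjustment and tiers follow their definitions", {
  expect_equal(bonferroni_adjust(0.01, m = 1), 0.01)
  expect_equal(bonferroni_adjust(0.4, m = 3), 1)
  expect_equal(bonferroni_adjust(1e-4, m = 16), 1.6e-3)
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_equal(classify_tier(0.004), "significant")
  expect_equal(classify_tier(0.049), "suggestive")
  expect_equal(classify_tier(0.05), "none")  # strict inequality
  expect_equal(classify_tier(c(0.0049, 0.005)),
               c("significant", "suggestive"))
})

test_that("regression results round-trip to the reporting CSV", {
  x <- rep(c(0, 1), each = 100)
  set.seed(61)
  y <- rbinom(200, 1, plogis(-1 + x))
  cohort <- make_cohort(list(Y = y, X = x))
  res <- fit_logistic_report(cohort, "Y", "X")
  res$p_adj <- bonferroni_adjust(res$p_raw)
  res$tier <- classify_tier(res$p_adj)
  path <- tempfile(fileext = ".csv")
  write_regression_csv(res, path)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back$Odds, res$odds_ratio, tolerance = 1e-10)
  expect_equal(back$`Class ID`, "X")
  expect_equal(back$Tier, res$tier)
})
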