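#' Build the regression cohort table
#'
#' Applies the comparison-pipeline cohort restriction: female respondents
#' who completed all three surveys. Every ontology-aligned question becomes
#' a 0/1 feature keyed by CURIE: binary questions directly ("yes" = 1),
#' categorical questions as one indicator per option, and free-text
#' questions as one indicator per lexically mapped term. Missing cells stay
#' `NA` for downstream imputation; unmapped free-text answers are treated as
#' missing. Per-column prevalence mean/SD and missingness are computed
#' before imputation.
#'
#' @param table survey response table.
#' @param keys translation keys.
#' @param ontologies ontology list (for free-text mapping and topic labels).
#' @param frd_curies named character vector of outcome CURIEs.
#' @return Object of class `cohort_table`: `data` (numeric matrix-like data
#'   frame of 0/1/NA columns keyed by CURIE), `stats` (pre-imputation
#'   per-column mean, sd, missingness), `frd_curies`, `topics` and
#'   `imputed = FALSE`.
#' @export
build_cohort_table <- function(table, keys, ontologies, frd_curies) {
  rows <- table$sex == "female" & table$completed_health &
    table$completed_internal & table$completed_external
  if (sum(rows) == 0)
    stop_config("empty cohort: no female respondent completed all surveys")
  tab <- table[rows, , drop = FALSE]

  cols <- list()
  topics <- character(0)
  bin <- keys[keys$question_type == "binary", ]
  for (i in seq_len(nrow(bin))) {
    cell <- tab[[bin$question_id[i]]]
    cols[[bin$curie[i]]] <- ifelse(is.na(cell), NA_integer_,
                                   as.integer(cell == "yes"))
    topics[bin$curie[i]] <- bin$question_id[i]
  }
  cat_keys <- keys[keys$question_type == "categorical", ]
  for (i in seq_len(nrow(cat_keys))) {
    cell <- tab[[cat_keys$question_id[i]]]
    cols[[cat_keys$curie[i]]] <-
      ifelse(is.na(cell), NA_integer_,
             as.integer(cell == cat_keys$option_label[i]))
    topics[cat_keys$curie[i]] <- cat_keys$question_id[i]
  }
  ft <- keys[keys$question_type == "freetext", ]
  if (nrow(ft) > 0) {
    lex <- build_lexicon(ontologies)
    for (i in seq_len(nrow(ft))) {
      cell <- tab[[ft$question_id[i]]]
      mapped <- rep(NA_character_, length(cell))
      answered <- !is.na(cell) & nzchar(trimws(cell))
      uniq <- unique(cell[answered])
      lookup <- vapply(uniq, function(s) map_free_text(s, lex)$curie, "")
      mapped[answered] <- lookup[cell[answered]]
      mapped[mapped == "UNMAPPED"] <- NA_character_
      for (curie in sort(unique(mapped[!is.na(mapped)]))) {
        col <- ifelse(is.na(mapped), NA_integer_,
                      as.integer(mapped == curie))
        if (curie %in% names(cols)) {
          old <- cols[[curie]]
          cols[[curie]] <- pmax(old, col, na.rm = FALSE)
        } else {
          cols[[curie]] <- col
          topics[curie] <- ft$question_id[i]
        }
      }
    }
  }

  data <- as.data.frame(cols, check.names = FALSE)
  stats <- data.frame(
    feature = names(data),
    mean_prevalence = vapply(data, function(x) mean(x, na.rm = TRUE), 0),
    sd_prevalence = vapply(data, function(x) sd(x, na.rm = TRUE), 0),
    missingness_rate = vapply(data, function(x) mean(is.na(x)), 0))
  rownames(stats) <- NULL
  structure(list(data = data, stats = stats,
                 respondent_id = tab$respondent_id,
                 frd_curies = frd_curies, topics = topics,
                 imputed = FALSE),
            class = "cohort_table")
}

column_mode <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Iterative random-forest imputation (missForest scheme)
#'
#' Missing cells are initialised with the column mode, then columns are
#' visited in order of increasing missingness, each refit with a random
#' forest on all other columns and its missing entries re-predicted. The
#' loop stops the first time the difference criterion (proportion of imputed
#' cells that changed relative to the previous iteration) increases, and the
#' last pre-increase state is returned; `max_iter` caps the loop.
#'
#' @param cohort a `cohort_table`.
#' @param max_iter maximum sweeps over the columns.
#' @param num_trees trees per column forest.
#' @param seed integer seed.
#' @return The cohort with no missing cells and `imputed = TRUE`.
#' @export
impute_rf_iterative <- function(cohort, max_iter = 10, num_trees = 100,
                                seed = 1L) {
  data <- cohort$data
  all_missing <- names(data)[vapply(data, function(x) all(is.na(x)), TRUE)]
  if (length(all_missing) > 0)
    stop_config("cannot impute all-missing column(s): %s",
                paste(all_missing, collapse = ", "))
  na_idx <- lapply(data, function(x) which(is.na(x)))
  n_na <- sum(lengths(na_idx))
  if (n_na == 0) {
    cohort$imputed <- TRUE
    return(cohort)
  }
  miss_cols <- names(data)[lengths(na_idx) > 0]
  miss_cols <- miss_cols[order(lengths(na_idx)[miss_cols])]

  filled <- data
  for (col in miss_cols)
    filled[[col]][na_idx[[col]]] <- column_mode(data[[col]])

  prev <- filled
  prev_diff <- Inf
  for (iter in seq_len(max_iter)) {
    current <- prev
    for (ci in seq_along(miss_cols)) {
      col <- miss_cols[ci]
      obs <- which(!is.na(data[[col]]))
      x <- current[, setdiff(names(current), col), drop = FALSE]
      fit <- ranger::ranger(
        x = x[obs, , drop = FALSE],
        y = factor(data[[col]][obs], levels = c(0, 1)),
        num.trees = num_trees, num.threads = 1,
        seed = seed + iter * 1000L + ci)
      pred <- predict(fit, data = x[na_idx[[col]], , drop = FALSE],
                      num.threads = 1)$predictions
      current[[col]][na_idx[[col]]] <- as.integer(as.character(pred))
    }
    changed <- sum(vapply(miss_cols, function(col)
      sum(current[[col]][na_idx[[col]]] != prev[[col]][na_idx[[col]]]),
      0L))
    diff <- changed / n_na
    if (diff >= prev_diff) break
    prev <- current
    prev_diff <- diff
    if (diff == 0) break
  }
  cohort$data <- prev
  cohort$imputed <- TRUE
  cohort
}

cohort_xy <- function(cohort, outcome) {
  if (!outcome %in% names(cohort$data))
    stop_config("outcome %s not present in the cohort", outcome)
  x <- as.matrix(cohort$data[, setdiff(names(cohort$data), outcome),
                             drop = FALSE])
  list(x = x, y = cohort$data[[outcome]])
}

#' Elastic-net feature pre-selection
#'
#' Penalised logistic regression with mixing parameter `alpha_mix`, penalty
#' weight chosen by cross-validated deviance under the 1-SE rule; folds are
#' stratified by outcome so that rare-outcome folds are never empty. When
#' the 1-SE model is the null model the deviance-minimising penalty is used
#' instead, so a whole outcome is not silently dropped by an aggressive
#' penalty. Class imbalance is handled with inverse-prevalence observation
#' weights. Constant columns are dropped with a message, not an error. The
#' selected set (nonzero coefficients) may still be empty.
#'
#' @param cohort an imputed `cohort_table`.
#' @param outcome outcome CURIE.
#' @param alpha_mix elastic-net mixing parameter (default 0.5).
#' @param n_folds cross-validation folds.
#' @param seed integer seed (drives the fold assignment).
#' @return Character vector of selected feature CURIEs (possibly empty),
#'   with the chosen penalty as attribute `"lambda"`.
#' @export
elastic_net_select <- function(cohort, outcome, alpha_mix = 0.5,
                               n_folds = 10, seed = 1L) {
  stopifnot(isTRUE(cohort$imputed))
  xy <- cohort_xy(cohort, outcome)
  if (length(unique(xy$y)) < 2)
    stop_config("outcome has a single class")
  constant <- apply(xy$x, 2, function(v) var(v) == 0)
  if (any(constant)) {
    message("dropping constant feature(s): ",
            paste(colnames(xy$x)[constant], collapse = ", "))
    xy$x <- xy$x[, !constant, drop = FALSE]
  }
  prev <- mean(xy$y)
  w <- ifelse(xy$y == 1, 1 / (2 * prev), 1 / (2 * (1 - prev)))
  set.seed(seed)
  foldid <- integer(length(xy$y))
  for (cls in unique(xy$y)) {
    idx <- which(xy$y == cls)
    foldid[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  cv <- glmnet::cv.glmnet(xy$x, xy$y, family = "binomial",
                          alpha = alpha_mix, weights = w, foldid = foldid,
                          type.measure = "deviance")
  lambda <- cv$lambda.1se
  beta <- coef(cv, s = lambda)[-1, 1]
  if (all(beta == 0)) {
    lambda <- cv$lambda.min
    beta <- coef(cv, s = lambda)[-1, 1]
  }
  selected <- names(beta)[beta != 0]
  attr(selected, "lambda") <- lambda
  selected
}

#' Permutation importance from a random-forest classifier
#'
#' Fits a probability forest on the selected features using two thirds of
#' the rows and measures, on the held-out third, the mean decrease in AUROC
#' over `n_repeats` independent permutations of each feature column.
#' Features with mean importance > 0 are the ones worth carrying into the
#' logistic model.
#'
#' @param cohort an imputed `cohort_table`.
#' @param outcome outcome CURIE.
#' @param selected features entering the forest (non-empty).
#' @param n_repeats permutations per feature (>= 2).
#' @param num_trees forest size.
#' @param seed integer seed.
#' @return Data frame `feature`, `importance` (mean AUROC drop), `kept`.
#' @export
rf_permutation_importance <- function(cohort, outcome, selected,
                                      n_repeats = 5, num_trees = 200,
                                      seed = 1L) {
  if (n_repeats < 2) stop_config("n_repeats must be >= 2")
  if (length(selected) == 0) stop_config("selected feature set is empty")
  stopifnot(isTRUE(cohort$imputed))
  xy <- cohort_xy(cohort, outcome)
  x <- xy$x[, selected, drop = FALSE]
  set.seed(seed)
  n <- nrow(x)
  holdout <- sort(sample.int(n, round(n / 3)))
  train <- setdiff(seq_len(n), holdout)
  if (length(unique(xy$y[train])) < 2)
    stop_config("outcome has a single class in the training rows")
  fit <- ranger::ranger(x = as.data.frame(x[train, , drop = FALSE]),
                        y = factor(xy$y[train], levels = c(0, 1)),
                        probability = TRUE, num.trees = num_trees,
                        num.threads = 1, seed = seed)
  xh <- as.data.frame(x[holdout, , drop = FALSE])
  yh <- xy$y[holdout]
  base <- auroc(predict(fit, data = xh,
                        num.threads = 1)$predictions[, "1"], yh)
  imp <- vapply(seq_along(selected), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      xp <- xh
      set.seed(seed + j * 1000L + r)
      xp[[j]] <- sample(xp[[j]])
      base - auroc(predict(fit, data = xp,
                           num.threads = 1)$predictions[, "1"], yh)
    }, 0)
    mean(drops)
  }, 0)
  data.frame(feature = selected, importance = imp, kept = imp > 0)
}

#' Multivariable logistic regression report
#'
#' One maximum-likelihood logistic model of the outcome on all kept
#' features jointly (intercept included). Per coefficient: odds ratio
#' `exp(beta)`, Wald 95\% CI `exp(beta +/- 1.96 SE)`, two-sided Wald p, and
#' the variance inflation factor `1 / (1 - R^2)` from a linear regression of
#' that feature on the others. Features with unstable estimates (separation
#' or non-convergence, detected as Wald SE > 10 on the log-odds scale or a
#' non-converged fit) are flagged and their VIF omitted. Pre-imputation
#' prevalence and missingness statistics are attached per feature.
#'
#' @param cohort an imputed `cohort_table`.
#' @param outcome outcome CURIE.
#' @param kept_features features entering the model (non-empty).
#' @return Data frame of class `regression_result`: one row per feature with
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `se`, `p_raw`, `vif`, `flagged`
#'   and the per-feature prevalence statistics.
#' @export
fit_logistic_report <- function(cohort, outcome, kept_features) {
  if (length(kept_features) == 0) stop_config("kept_features is empty")
  stopifnot(isTRUE(cohort$imputed))
  xy <- cohort_xy(cohort, outcome)
  x <- xy$x[, kept_features, drop = FALSE]
  df <- data.frame(.y = xy$y, x, check.names = FALSE)
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = df,
        control = list(epsilon = 1e-13, maxit = 200)),
    warning = function(w) invokeRestart("muffleWarning"))
  sm <- summary(fit)$coefficients
  idx <- match(paste0("`", kept_features, "`"), rownames(sm))
  idx[is.na(idx)] <- match(kept_features, rownames(sm))[is.na(idx)]
  beta <- sm[idx, "Estimate"]
  se <- sm[idx, "Std. Error"]
  p <- sm[idx, "Pr(>|z|)"]
  flagged <- !fit$converged | se > 10
  vif <- vapply(seq_along(kept_features), function(j) {
    if (flagged[j] || length(kept_features) == 1) return(NA_real_)
    others <- x[, -j, drop = FALSE]
    if (all(apply(others, 2, var) == 0)) return(1)
    r2 <- summary(lm(x[, j] ~ others))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  vif[!flagged & length(kept_features) == 1] <- 1
  st <- cohort$stats[match(kept_features, cohort$stats$feature), ]
  out <- data.frame(
    feature = kept_features,
    topic = unname(cohort$topics[kept_features]),
    odds_ratio = exp(beta), ci_lower = exp(beta - 1.96 * se),
    ci_upper = exp(beta + 1.96 * se), se = se, p_raw = p, vif = vif,
    mean_prevalence = st$mean_prevalence,
    sd_prevalence = st$sd_prevalence,
    missingness_rate = st$missingness_rate,
    flagged = flagged)
  rownames(out) <- NULL
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the number of tests in the family
#' (default: the length of `p`).
#'
#' @param p_values raw p-values in [0, 1].
#' @param m family size.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_config("p-values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' Significance tier of an adjusted p-value
#'
#' Strictly below 0.005 is `"significant"`, strictly below 0.05 is
#' `"suggestive"`, anything else `"none"`.
#'
#' @param p_adj adjusted p-values in [0, 1].
#' @return Character vector of tiers.
#' @export
classify_tier <- function(p_adj) {
  if (any(p_adj < 0 | p_adj > 1, na.rm = TRUE))
    stop_config("p-values must lie in [0, 1]")
  ifelse(p_adj < 0.005, "significant",
         ifelse(p_adj < 0.05, "suggestive", "none"))
}

#' Run the full regression pipeline for one FRD
#'
#' Fixed stage order: elastic-net selection, random-forest permutation
#' importance, multivariable logistic regression, Bonferroni adjustment over
#' the features entering the logistic model, tier classification. An empty
#' selection at any stage returns an empty result rather than an error.
#'
#' @param cohort an imputed `cohort_table`.
#' @param outcome outcome CURIE.
#' @param seed integer seed.
#' @param n_repeats permutation repeats.
#' @return A `regression_result` with `p_adj` and `tier` columns (zero rows
#'   when nothing was selected).
#' @export
run_regression_frd <- function(cohort, outcome, seed = 1L, n_repeats = 5) {
  empty <- structure(
    data.frame(feature = character(), topic = character(),
               odds_ratio = numeric(), ci_lower = numeric(),
               ci_upper = numeric(), se = numeric(), p_raw = numeric(),
               vif = numeric(), mean_prevalence = numeric(),
               sd_prevalence = numeric(), missingness_rate = numeric(),
               flagged = logical(), p_adj = numeric(), tier = character()),
    class = c("regression_result", "data.frame"))
  selected <- suppressMessages(
    elastic_net_select(cohort, outcome, seed = seed))
  if (length(selected) == 0) return(empty)
  imp <- rf_permutation_importance(cohort, outcome, selected,
                                   n_repeats = n_repeats, seed = seed + 1L)
  kept <- imp$feature[imp$kept]
  if (length(kept) == 0) return(empty)
  res <- fit_logistic_report(cohort, outcome, kept)
  res$p_adj <- bonferroni_adjust(res$p_raw, m = nrow(res))
  res$tier <- classify_tier(res$p_adj)
  res
}

#' Write a regression result as CSV
#'
#' Column layout follows the reporting convention of the comparison
#' analysis: odds, CI limits, standard error, question topic, class id,
#' adjusted p-value, prevalence mean/SD, missingness, mean VIF, tier.
#'
#' @param result a `regression_result` with `p_adj`/`tier`.
#' @param path file path.
#' @export
write_regression_csv <- function(result, path) {
  out <- data.frame(
    Odds = result$odds_ratio,
    `CI lower limit` = result$ci_lower,
    `CI upper limit` = result$ci_upper,
    `Standard Error` = result$se,
    `Survey question topic` = result$topic,
    `Class ID` = result$feature,
    `p-value` = result$p_adj,
    `Mean prevalence` = result$mean_prevalence,
    `Sd prevalence` = result$sd_prevalence,
    `Missingness rate` = result$missingness_rate,
    `Mean VIF` = result$vif,
    Tier = result$tier, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
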