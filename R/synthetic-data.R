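#' Configuration for a synthetic survey study
#'
#' Bundles and validates every parameter of the synthetic cohort generator:
#' cohort size, the marginal prevalence targeted for each female reproductive
#' disorder (FRD), planted exposure-disorder effects on the odds-ratio scale,
#' exposure prevalences, missingness, the female fraction, and per-survey
#' completion rates. Defaults mirror a three-survey exposome study with
#' reported FRD prevalences of 7\% (endometriosis), 15\% (uterine fibroids)
#' and 13\% (ovarian cysts).
#'
#' @param n_respondents number of survey respondents (>= 1).
#' @param frd_prevalences named numeric vector of target marginal prevalences
#'   in (0,1), one per FRD, interpreted among female respondents.
#' @param frd_curies named character vector mapping each FRD name in
#'   `frd_prevalences` to its ontology CURIE.
#' @param planted_effects data frame with columns `exposure` (CURIE), `frd`
#'   (CURIE) and `odds_ratio` (> 0); may have zero rows.
#' @param exposure_prevalences named numeric vector, CURIE -> probability, for
#'   binary exposure questions. Questions absent from the map use
#'   `default_exposure_prevalence`.
#' @param default_exposure_prevalence fallback Bernoulli rate for binary
#'   exposure questions.
#' @param missing_rate probability that an answered cell is masked missing.
#' @param missing_mechanism `"MCAR"` (default) masks cells completely at
#'   random at `missing_rate`; `"MAR"` makes the rate depend on the always
#'   observed sex column (male respondents are masked at twice the rate),
#'   a missing-at-random hook for sensitivity analyses.
#' @param female_fraction probability a respondent is coded female.
#' @param survey_completion_rates length-3 probabilities of completing the
#'   health, internal-exposome and external-exposome surveys (independent).
#' @param freetext_answer_rate probability a free-text question receives a
#'   non-empty answer.
#' @param freetext_pool_size number of distinct terms respondents draw on
#'   when answering a free-text question (common items dominate real
#'   free-text fields).
#' @param seed integer seed driving all generation.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_respondents = 3000,
                             frd_prevalences = c(endometriosis = 0.07,
                                                 uterine_fibroids = 0.15,
                                                 ovarian_cysts = 0.13),
                             frd_curies = NULL,
                             planted_effects = NULL,
                             exposure_prevalences = NULL,
                             default_exposure_prevalence = 0.2,
                             missing_rate = 0.05,
                             missing_mechanism = c("MCAR", "MAR"),
                             female_fraction = 0.67,
                             survey_completion_rates = c(health = 0.97,
                                                         internal = 0.55,
                                                         external = 0.54),
                             freetext_answer_rate = 0.5,
                             freetext_pool_size = 8,
                             seed = 1L) {
  if (length(n_respondents) != 1 || n_respondents < 1)
    stop_config("n_respondents must be a single count >= 1")
  probs <- c(frd_prevalences, missing_rate, female_fraction,
             survey_completion_rates, freetext_answer_rate,
             default_exposure_prevalence, exposure_prevalences)
  if (any(probs < 0 | probs > 1))
    stop_config("all probabilities must lie in [0, 1]")
  if (is.null(names(frd_prevalences)) || any(!nzchar(names(frd_prevalences))))
    stop_config("frd_prevalences must be named by FRD")
  if (length(survey_completion_rates) != 3)
    stop_config("survey_completion_rates must have length 3")
  if (is.null(planted_effects)) {
    planted_effects <- data.frame(exposure = character(), frd = character(),
                                  odds_ratio = numeric())
  }
  stopifnot(all(c("exposure", "frd", "odds_ratio") %in% names(planted_effects)))
  if (any(planted_effects$odds_ratio <= 0))
    stop_config("planted odds ratios must be > 0")
  structure(list(
    n_respondents = as.integer(n_respondents),
    frd_prevalences = frd_prevalences,
    frd_curies = frd_curies,
    planted_effects = planted_effects,
    exposure_prevalences = exposure_prevalences,
    default_exposure_prevalence = default_exposure_prevalence,
    missing_rate = missing_rate,
    missing_mechanism = match.arg(missing_mechanism),
    female_fraction = female_fraction,
    survey_completion_rates = setNames(survey_completion_rates,
                                       c("health", "internal", "external")),
    freetext_answer_rate = freetext_answer_rate,
    freetext_pool_size = as.integer(freetext_pool_size),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a random rooted is_a DAG ontology
#'
#' Produces a mini-ontology of `n_terms` terms under a single root. Every
#' non-root term receives between 1 and `max_parents` is_a parents drawn from
#' earlier terms (so the graph is acyclic by construction) and 0-3 synonyms.
#' CURIEs are `<PREFIX>:<zero-padded integer>`.
#'
#' @param domain_name human-readable domain (used in labels).
#' @param prefix CURIE prefix, e.g. `"HP"`.
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum is_a parents per non-root term.
#' @param seed integer seed.
#' @return An object of class `ontology_graph` with elements `domain`,
#'   `prefix`, `terms` (data frame `curie`, `label`), `synonyms` (named list)
#'   and `edges` (data frame `child`, `parent`).
#' @export
generate_ontology <- function(domain_name, prefix, n_terms, max_parents = 2,
                              seed = 1L) {
  if (length(n_terms) != 1 || n_terms < 1)
    stop_config("n_terms must be a positive count")
  if (max_parents < 1) stop_config("max_parents must be >= 1")
  set.seed(seed)
  curies <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  labels <- sprintf("%s term %03d", domain_name, seq_len(n_terms))
  synonyms <- lapply(seq_len(n_terms), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) character(0)
    else sprintf("%s synonym %03d-%d", domain_name, i, seq_len(k))
  })
  names(synonyms) <- curies
  edges <- if (n_terms == 1) {
    data.frame(child = character(), parent = character())
  } else {
    do.call(rbind, lapply(2:n_terms, function(i) {
      k <- sample(seq_len(min(max_parents, i - 1)), 1)
      parents <- if (i == 2) 1L else sample(seq_len(i - 1), k)
      data.frame(child = curies[i], parent = curies[parents])
    }))
  }
  structure(list(domain = domain_name, prefix = prefix,
                 terms = data.frame(curie = curies, label = labels),
                 synonyms = synonyms, edges = edges),
            class = "ontology_graph")
}

#' Generate the standard set of mini-ontologies
#'
#' One ontology per node domain: phenotype (HP), disease (MONDO), chemical
#' (CHEBI), food (FOODON), environmental exposure (ECTO) and medical
#' procedure (MAXO).
#'
#' @param sizes named integer vector of term counts per prefix.
#' @param seed integer seed.
#' @return Named list of `ontology_graph` objects keyed by prefix.
#' @export
generate_ontologies <- function(sizes = c(HP = 300, MONDO = 200, CHEBI = 250,
                                          FOODON = 200, ECTO = 200,
                                          MAXO = 60),
                                seed = 1L) {
  domains <- c(HP = "phenotype", MONDO = "disease", CHEBI = "chemical",
               FOODON = "food", ECTO = "exposure", MAXO = "procedure")
  onts <- lapply(seq_along(sizes), function(i) {
    p <- names(sizes)[i]
    generate_ontology(domains[[p]], p, sizes[[i]], max_parents = 2,
                      seed = seed + i)
  })
  names(onts) <- names(sizes)
  onts
}

all_curies <- function(ontologies) {
  unlist(lapply(ontologies, function(o) o$terms$curie), use.names = FALSE)
}

#' Generate a translation-key question bank
#'
#' Builds survey questions of three types. Binary questions map to a single
#' ontology term; categorical questions map each response option to its own
#' term; free-text questions carry no fixed CURIE and are resolved later by
#' lexical mapping. Each question is assigned to the health, internal or
#' external survey according to its term domain.
#'
#' @param ontologies named list of `ontology_graph` objects.
#' @param n_binary,n_categorical,n_freetext question counts. `n_binary`
#'   includes any `required_curies`.
#' @param seed integer seed.
#' @param required_curies CURIEs that must appear as binary questions (e.g.
#'   FRD outcome questions and planted exposures).
#' @param options_per_categorical number of options per categorical question.
#' @return Data frame of translation keys with columns `question_id`,
#'   `question_type`, `option_label`, `curie`, `predicate`, `survey`.
#' @export
generate_question_bank <- function(ontologies, n_binary = 12,
                                   n_categorical = 1, n_freetext = 2,
                                   seed = 1L, required_curies = character(),
                                   options_per_categorical = 3) {
  if (length(ontologies) == 0) stop_config("ontologies must be non-empty")
  set.seed(seed)
  pool <- all_curies(ontologies)
  required_curies <- unique(required_curies)
  if (!all(required_curies %in% pool))
    stop_config("required_curies not found in ontologies")
  n_extra_binary <- n_binary - length(required_curies)
  if (n_extra_binary < 0)
    stop_config("n_binary smaller than the number of required CURIEs")
  avail <- setdiff(pool, required_curies)
  need <- n_extra_binary + n_categorical * options_per_categorical
  if (need > length(avail))
    stop_config("requested question count exceeds available ontology terms")
  picked <- if (need > 0) sample(avail, need) else character()
  binary_curies <- c(required_curies, picked[seq_len(n_extra_binary)])
  cat_curies <- picked[seq_len(n_categorical * options_per_categorical) +
                         n_extra_binary]

  label_of <- function(curie) {
    pref <- curie_prefix(curie)
    o <- ontologies[[pref]]
    o$terms$label[match(curie, o$terms$curie)]
  }

  keys <- list()
  if (n_binary > 0) {
    keys$binary <- data.frame(
      question_id = sprintf("Q_bin_%03d", seq_len(n_binary)),
      question_type = "binary", option_label = "",
      curie = binary_curies,
      predicate = predicate_for_curie(binary_curies),
      survey = survey_for_curie(binary_curies))
  }
  if (n_categorical > 0) {
    idx <- rep(seq_len(n_categorical), each = options_per_categorical)
    keys$categorical <- data.frame(
      question_id = sprintf("Q_cat_%03d", idx),
      question_type = "categorical",
      option_label = vapply(cat_curies, label_of, ""),
      curie = cat_curies,
      predicate = predicate_for_curie(cat_curies),
      survey = survey_for_curie(cat_curies))
    # a categorical question lives on one survey: that of its first option
    first <- !duplicated(keys$categorical$question_id)
    keys$categorical$survey <-
      keys$categorical$survey[first][match(keys$categorical$question_id,
                                           keys$categorical$question_id[first])]
  }
  if (n_freetext > 0) {
    ft_prefixes <- intersect(c("CHEBI", "FOODON", "ECTO"), names(ontologies))
    if (length(ft_prefixes) == 0) ft_prefixes <- names(ontologies)
    target <- sample(ft_prefixes, n_freetext, replace = TRUE)
    proto <- sprintf("%s:%07d", target, 1L) # predicate/survey from the domain
    keys$freetext <- data.frame(
      question_id = sprintf("Q_txt_%03d", seq_len(n_freetext)),
      question_type = "freetext", option_label = "", curie = "",
      predicate = predicate_for_curie(proto),
      survey = survey_for_curie(proto))
  }
  keys <- do.call(rbind, keys)
  rownames(keys) <- NULL
  keys
}

# Ontology prefix a free-text question draws from, recovered from its
# predicate.
freetext_prefix <- function(predicate) {
  map <- c(affected_by = "CHEBI", consumes = "FOODON", exposed_to = "ECTO",
           has_phenotype = "HP", has_disease = "MONDO", undergone = "MAXO")
  unname(map[predicate])
}

# Exact marginal prevalence of a logistic outcome over independent Bernoulli
# planted exposures: enumerate the 2^k exposure patterns.
marginal_prevalence <- function(b0, log_ors, exp_prevs) {
  k <- length(log_ors)
  if (k == 0) return(plogis(b0))
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
  w <- apply(patterns, 1, function(x)
    prod(ifelse(x == 1, exp_prevs, 1 - exp_prevs)))
  sum(w * plogis(b0 + patterns %*% log_ors))
}

# Intercept such that the marginal prevalence hits `target` exactly, found by
# root bisection on the (monotone) exact enumeration above.
calibrate_intercept <- function(target, log_ors, exp_prevs) {
  if (target <= 0 || target >= 1)
    stop_config("unsatisfiable prevalence target %.3f: must be in (0, 1)",
                target)
  uniroot(function(b0) marginal_prevalence(b0, log_ors, exp_prevs) - target,
          interval = c(-40, 40), tol = 1e-12)$root
}

#' Generate a synthetic survey cohort
#'
#' Draws a respondent table under the configured study conditions. Binary
#' exposures are Bernoulli with their configured prevalences. Each FRD is
#' drawn for female respondents from a logistic model
#' `logit(p) = b0 + sum(log(OR) * exposure)` over its planted exposures, with
#' the intercept calibrated so the marginal prevalence among females matches
#' the configured target; male respondents are never positive. Categorical
#' questions receive one uniformly chosen option; free-text questions are
#' answered with a term label or synonym from the question's domain ontology
#' (10\% of answers are upper-cased or whitespace-padded to exercise lexical
#' normalisation). Cells of uncompleted surveys are missing wholesale;
#' answered cells are masked missing completely at random at the configured
#' rate.
#'
#' @param keys translation-key data frame from [generate_question_bank()].
#' @param config a [synthetic_config()].
#' @param ontologies the ontology list the keys were generated from.
#' @return Data frame with one row per respondent: `respondent_id`, `sex`,
#'   three `completed_*` flags, then one column per question (missing cells
#'   are `NA`).
#' @export
generate_cohort <- function(keys, config, ontologies) {
  stopifnot(inherits(config, "synthetic_config"))
  pool <- all_curies(ontologies)
  planted <- config$planted_effects
  if (nrow(planted) > 0 &&
      !all(c(planted$exposure, planted$frd) %in% pool))
    stop_config("planted CURIEs must exist in the generated ontologies")
  frd_curies <- config$frd_curies
  if (is.null(frd_curies))
    stop_config("config$frd_curies must map FRD names to CURIEs")
  bin_keys <- keys[keys$question_type == "binary", ]
  if (!all(frd_curies %in% bin_keys$curie))
    stop_config("every FRD CURIE needs a binary question in the keys")
  if (nrow(planted) > 0 && !all(planted$exposure %in% bin_keys$curie))
    stop_config("planted exposures need binary questions in the keys")

  set.seed(config$seed)
  n <- config$n_respondents
  ids <- sprintf("%07d", seq_len(n))
  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  completed <- vapply(config$survey_completion_rates,
                      function(r) runif(n) < r, logical(n))
  if (n == 1) completed <- matrix(completed, nrow = 1,
                                  dimnames = list(NULL, names(config$survey_completion_rates)))

  exp_prev_of <- function(curie) {
    if (is.null(config$exposure_prevalences))
      return(config$default_exposure_prevalence)
    p <- config$exposure_prevalences[curie]
    ifelse(is.na(p), config$default_exposure_prevalence, unname(p))
  }

  # latent binary exposures (non-FRD binary questions)
  exp_keys <- bin_keys[!(bin_keys$curie %in% frd_curies), ]
  latent <- matrix(0L, n, nrow(exp_keys),
                   dimnames = list(NULL, exp_keys$curie))
  for (j in seq_len(nrow(exp_keys)))
    latent[, j] <- rbinom(n, 1, exp_prev_of(exp_keys$curie[j]))

  cells <- list()
  for (j in seq_len(nrow(exp_keys)))
    cells[[exp_keys$question_id[j]]] <-
      ifelse(latent[, j] == 1, "yes", "no")

  # FRD outcomes from the planted logistic model, females only
  female <- sex == "female"
  for (frd_name in names(config$frd_prevalences)) {
    curie <- frd_curies[[frd_name]]
    target <- config$frd_prevalences[[frd_name]]
    eff <- planted[planted$frd == curie, , drop = FALSE]
    log_ors <- log(eff$odds_ratio)
    prevs <- vapply(eff$exposure, exp_prev_of, 0)
    b0 <- calibrate_intercept(target, log_ors, prevs)
    eta <- rep(b0, n)
    if (nrow(eff) > 0)
      eta <- eta + as.vector(latent[, eff$exposure, drop = FALSE] %*% log_ors)
    y <- rbinom(n, 1, plogis(eta))
    y[!female] <- 0L
    qid <- bin_keys$question_id[match(curie, bin_keys$curie)]
    cells[[qid]] <- ifelse(y == 1, "yes", "no")
  }

  # categorical: uniform option choice
  cat_keys <- keys[keys$question_type == "categorical", ]
  for (qid in unique(cat_keys$question_id)) {
    opts <- cat_keys$option_label[cat_keys$question_id == qid]
    cells[[qid]] <- sample(opts, n, replace = TRUE)
  }

  # free text: term label or a synonym; 10% dirtied
  ft_keys <- keys[keys$question_type == "freetext", ]
  for (i in seq_len(nrow(ft_keys))) {
    pref <- freetext_prefix(ft_keys$predicate[i])
    ont <- ontologies[[pref]]
    ans <- character(n)
    answered <- runif(n) < config$freetext_answer_rate
    pool <- sample(nrow(ont$terms),
                   min(config$freetext_pool_size, nrow(ont$terms)))
    idx <- pool[sample.int(length(pool), n, replace = TRUE)]
    for (r in which(answered)) {
      term <- ont$terms$curie[idx[r]]
      variants <- c(ont$terms$label[idx[r]], ont$synonyms[[term]])
      ans[r] <- variants[sample.int(length(variants), 1)]
    }
    dirty <- answered & runif(n) < 0.10
    flip <- runif(n) < 0.5
    ans[dirty & flip] <- toupper(ans[dirty & flip])
    ans[dirty & !flip] <- paste0("  ", ans[dirty & !flip], " ")
    ans[!answered] <- NA_character_
    cells[[ft_keys$question_id[i]]] <- ans
  }

  tab <- data.frame(respondent_id = ids, sex = sex,
                    completed_health = completed[, "health"],
                    completed_internal = completed[, "internal"],
                    completed_external = completed[, "external"])
  cell_missing_rate <- rep(config$missing_rate, n)
  if (identical(config$missing_mechanism, "MAR"))
    cell_missing_rate[sex == "male"] <-
      pmin(1, 2 * config$missing_rate)
  qmeta <- keys[!duplicated(keys$question_id), c("question_id", "survey")]
  for (qid in qmeta$question_id) {
    col <- cells[[qid]]
    svy <- qmeta$survey[qmeta$question_id == qid]
    col[!completed[, svy]] <- NA_character_
    mask <- runif(n) < cell_missing_rate
    col[mask] <- NA_character_
    tab[[qid]] <- col
  }
  attr(tab, "question_ids") <- qmeta$question_id
  tab
}

#' Generate supplemental crop-chemical and nutrient link tables
#'
#' Emulates agricultural chemical-usage and food-nutrient reference tables:
#' chemical terms linked to food terms with the `applied_to_crop` predicate
#' and nutrient (chemical) terms linked to foods with `nutrient_of`.
#'
#' @param ontologies ontology list; must contain the chemical (`CHEBI`) and
#'   food (`FOODON`) ontologies.
#' @param n_links total number of links to draw.
#' @param seed integer seed.
#' @return Data frame with columns `subject`, `predicate`, `object`.
#' @export
generate_supplemental_links <- function(ontologies, n_links = 30, seed = 1L) {
  chem <- ontologies[["CHEBI"]]
  food <- ontologies[["FOODON"]]
  if (is.null(chem) || is.null(food) ||
      nrow(chem$terms) == 0 || nrow(food$terms) == 0)
    stop_config("chemical and food ontologies must be present and non-empty")
  set.seed(seed)
  if (n_links == 0)
    return(data.frame(subject = character(), predicate = character(),
                      object = character()))
  preds <- rep(c("applied_to_crop", "nutrient_of"), length.out = n_links)
  links <- data.frame(
    subject = sample(chem$terms$curie, n_links, replace = TRUE),
    predicate = preds,
    object = sample(food$terms$curie, n_links, replace = TRUE))
  unique(links)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper that generates the standard ontologies, selects the
#' FRD and planted-exposure CURIEs, builds the question bank, and draws the
#' cohort and supplemental link tables, all from one configuration.
#'
#' @param config optional [synthetic_config()]; when `NULL` the default study
#'   conditions are used, with five planted effects of odds ratio 4 unless
#'   `planted_or` says otherwise.
#' @param seed overrides `config$seed` when given.
#' @param planted_or odds ratio shared by the default planted effects.
#' @param n_null_binary number of null (unplanted) binary exposure questions.
#' @param n_respondents overrides the default cohort size when `config` is
#'   `NULL`.
#' @param ontology_sizes named sizes passed to [generate_ontologies()]
#'   (`NULL` for the standard sizes).
#' @return List with `ontologies`, `keys`, `table`, `supplemental`, `config`,
#'   and `frd_curies`.
#' @export
simulate_study <- function(config = NULL, seed = NULL, planted_or = 4,
                           n_null_binary = 4, n_respondents = NULL,
                           ontology_sizes = NULL) {
  base_seed <- if (!is.null(seed)) as.integer(seed)
               else if (!is.null(config)) config$seed else 1L
  onts <- if (is.null(ontology_sizes)) generate_ontologies(seed = base_seed)
          else generate_ontologies(ontology_sizes, seed = base_seed)
  frd_curies <- c(endometriosis = "MONDO:0000002",
                  uterine_fibroids = "MONDO:0000003",
                  ovarian_cysts = "MONDO:0000004")
  if (is.null(config)) {
    set.seed(base_seed + 101L)
    exposure_pool <- c(sample(onts$CHEBI$terms$curie, 3),
                       sample(onts$ECTO$terms$curie, 2))
    planted <- data.frame(
      exposure = exposure_pool,
      frd = unname(frd_curies[c(1, 1, 2, 2, 3)]),
      odds_ratio = planted_or)
    config <- synthetic_config(
      n_respondents = n_respondents %||% 3000,
      planted_effects = planted, frd_curies = frd_curies,
      seed = base_seed)
  } else {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    if (is.null(config$frd_curies)) config$frd_curies <- frd_curies
  }
  keys <- generate_question_bank(
    onts,
    n_binary = length(config$frd_curies) +
      length(unique(config$planted_effects$exposure)) + n_null_binary,
    n_categorical = 1, n_freetext = 2, seed = config$seed + 1L,
    required_curies = c(config$frd_curies,
                        unique(config$planted_effects$exposure)))
  tab <- generate_cohort(keys, config, onts)
  supp <- generate_supplemental_links(onts, n_links = 30,
                                      seed = config$seed + 2L)
  list(ontologies = onts, keys = keys, table = tab, supplemental = supp,
       config = config, frd_curies = config$frd_curies)
}

#' Write / read a survey response table as CSV
#'
#' Missing cells are written as empty strings, distinct from the literal
#' `"no"` response.
#'
#' @param table survey table from [generate_cohort()].
#' @param path file path.
#' @return `read_survey_csv` returns the table with empty cells restored to
#'   `NA`.
#' @export
write_survey_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  tab <- read.csv(path, colClasses = "character", check.names = FALSE)
  for (j in seq_along(tab)) tab[[j]][tab[[j]] == ""] <- NA
  for (col in c("completed_health", "completed_internal", "completed_external"))
    if (col %in% names(tab)) tab[[col]] <- tab[[col]] == "TRUE"
  attr(tab, "question_ids") <-
    setdiff(names(tab), c("respondent_id", "sex", "completed_health",
                          "completed_internal", "completed_external"))
  tab
}
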