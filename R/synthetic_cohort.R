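# Synthetic cohort generator: checklist, feature norms, child vocabularies,
# the counterbalanced 24-trial design, comprehension ratings and 500 Hz gaze
# streams with a known effect structure (the recovery oracle).

#' Simulation configuration
#'
#' Collects every generator parameter with defaults that emulate the study
#' conditions: 79 children; productive vocabularies drawn from a truncated
#' log-normal calibrated to mean 92.1, median 61 words on a 680-item
#' checklist, truncated to 10--374; category-clustered feature norms; and
#' gaze streams whose post-latency target preference follows
#' `eta = beta0 + beta_condition * related +
#'   sum_k beta_k * x_k * (1 + gamma_k * group_code) + item intercept`
#' on the log-odds scale, with `x_k` the standardized global clustering
#' coefficient, standardized target degree and the sum-coded density
#' condition of the target's category (High = -0.5).
#'
#' @param seed Integer master seed.
#' @param n_children Number of children (>= 2).
#' @param vocab_meanlog,vocab_sdlog Log-normal parameters of the
#'   vocabulary-size distribution.
#' @param vocab_range Truncation bounds (words).
#' @param category_concentration Dirichlet concentration of per-child
#'   category weights; larger values make category composition more uniform
#'   across children.
#' @param p_within,p_between Probability that a within-/between-category
#'   concept pair shares a dedicated pair of perceptual+functional features
#'   (and hence an edge at the default threshold of 2).
#' @param n_private Named integer vector: private features per concept per
#'   class.
#' @param density_mode Normalisation passed to [category_proportions()].
#' @param edge_threshold Shared-feature count required for an edge.
#' @param latency_ms Time after label onset at which gaze preference starts.
#' @param duration_ms Trial length (sampled at 500 Hz, 2 ms steps).
#' @param beta0 Baseline post-latency target/distractor log-odds.
#' @param beta_condition Additive log-odds offset for related trials.
#' @param beta_gcc,beta_degree,beta_density Structure coefficients.
#' @param gamma_gcc,gamma_degree,gamma_density Group-interaction
#'   multipliers: the effect of structure metric `k` for a child with group
#'   code `g` is `beta_k * (1 + gamma_k * g)` (High group `g = -0.5`).
#' @param item_sd SD of the per-item intercepts.
#' @param stay_prob Markov probability of keeping the current gaze state at
#'   each 2 ms step.  The default (0.97, mean state run about 67 ms) keeps
#'   enough effective samples in the analysis window that the trial
#'   log-gaze statistic reads out the stationary log-odds approximately
#'   unbiased, so injected coefficients are interpretable on the response
#'   scale.
#' @param p_other Post-latency share of on-screen looking that falls
#'   outside both AOIs.
#' @param offscreen_base Per-trial off-screen stationary probability for
#'   ordinary trials.
#' @param fussy_prob Probability that a trial is "fussy" (mostly
#'   off-screen), exercising the track-loss filter.
#' @param fussy_rate Off-screen stationary probability on fussy trials.
#' @param p_low_rating Probability that a child x item comprehension rating
#'   falls below 2, exercising the comprehension filter.
#' @return A list of class `lg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_children = 79L,
                       vocab_meanlog = 4.1088,
                       vocab_sdlog = 1.4244,
                       vocab_range = c(10L, 374L),
                       category_concentration = 12,
                       p_within = 0.35,
                       p_between = 0.03,
                       n_private = c(perceptual = 2L, functional = 1L,
                                     taxonomic = 0L, encyclopedic = 1L),
                       density_mode = "per-category-size",
                       edge_threshold = 2L,
                       latency_ms = 500,
                       duration_ms = 4000,
                       beta0 = 1.0,
                       beta_condition = -0.2,
                       beta_gcc = -0.3,
                       beta_degree = 0.15,
                       beta_density = 0.3,
                       gamma_gcc = -1,
                       gamma_degree = 0,
                       gamma_density = 1,
                       item_sd = 0.15,
                       stay_prob = 0.97,
                       p_other = 0.2,
                       offscreen_base = 0.12,
                       fussy_prob = 0.05,
                       fussy_rate = 0.9,
                       p_low_rating = 0.048) {
  cfg <- as.list(environment())
  stopifnot(n_children >= 2, p_within >= 0, p_within <= 1,
            p_between >= 0, p_between <= 1,
            stay_prob > 0, stay_prob < 1,
            p_other >= 0, p_other < 1,
            offscreen_base >= 0, offscreen_base < 1,
            fussy_prob >= 0, fussy_prob <= 1,
            fussy_rate >= 0, fussy_rate < 1,
            p_low_rating >= 0, p_low_rating <= 1,
            latency_ms >= 0, latency_ms < duration_ms,
            duration_ms %% 2 == 0, item_sd >= 0,
            category_concentration > 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "lg_sim_config")
}

#' @export
print.lg_sim_config <- function(x, ...) {
  cat("<sim config> seed ", x$seed, ", ", x$n_children, " children, ",
      "edge threshold ", x$edge_threshold, "\n", sep = "")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return An `lg_sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) abort_with_listing("unknown configuration keys", bad)
  do.call(sim_config, vals)
}

# filler (non-experimental) checklist sections bringing the total to 680
filler_category_sizes <- function() {
  c(`OTHER-NOUNS` = 200L, `ACTION-WORDS` = 103L, `DESCRIPTIVE-WORDS` = 63L,
    PEOPLE = 29L, `GAMES-ROUTINES` = 45L, SOUNDS = 12L,
    `PRONOUNS-QUESTIONS` = 56L, `OTHER-WORDS` = 46L)
}

#' Generate the synthetic checklist
#'
#' The six experimental categories at their canonical sizes (43, 28, 14,
#' 27, 7, 7 items), with the twelve experimental item names included, plus
#' filler sections bringing the checklist to 680 words.
#'
#' @return An `lg_checklist`.
#' @export
gen_checklist <- function() {
  sizes <- cdi_category_sizes()
  items <- experimental_items()
  rows <- lapply(names(sizes), function(cat) {
    real <- items$item[items$category == cat]
    n_extra <- sizes[[cat]] - length(real)
    extra <- sprintf("%s_%02d", tolower(gsub("[^A-Za-z]", "", cat)),
                     seq_len(n_extra))
    data.frame(word_id = c(real, extra), category = cat,
               stringsAsFactors = FALSE)
  })
  fill <- filler_category_sizes()
  rows <- c(rows, lapply(names(fill), function(cat) {
    data.frame(word_id = sprintf("%s_%03d",
                                 tolower(gsub("[^A-Za-z]", "", cat)),
                                 seq_len(fill[[cat]])),
               category = cat, stringsAsFactors = FALSE)
  }))
  checklist_definition(do.call(rbind, rows))
}

#' Generate category-clustered feature norms
#'
#' Concepts are all checklist nouns: the items of the six experimental
#' categories plus the general-noun filler section, mirroring norms that
#' cover every noun on the checklist.  Each concept receives private
#' features per class plus a taxonomic category feature shared by all
#' category members (which the perceptual/functional class filter must
#' ignore).  Each concept pair within one *experimental* category
#' independently receives, with probability `p_within`, a dedicated
#' perceptual + functional feature pair shared by the two concepts (so the
#' pair meets the default edge threshold of 2); all other noun pairs --
#' between categories, or within the unstructured general-noun section --
#' share likewise with probability `p_between`.
#'
#' @param config An [sim_config()].
#' @param checklist Checklist whose experimental items become concepts.
#' @param seed Integer seed (defaults to a sub-stream of `config$seed`).
#' @return An `lg_feature_norms`.
#' @export
gen_norms <- function(config = sim_config(), checklist = gen_checklist(),
                      seed = substream_seed(config$seed, "norms")) {
  if (config$p_within >= 1 && config$p_between >= 1) {
    warning("degenerate norms configuration: every concept pair shares ",
            "features", call. = FALSE)
  }
  set.seed(seed)
  cats <- experimental_categories(checklist)
  noun_cats <- c(cats, intersect("OTHER-NOUNS",
                                 unique(checklist$category)))
  concepts <- checklist$word_id[checklist$category %in% noun_cats]
  concept_cat <- checklist$category[match(concepts, checklist$word_id)]
  np <- config$n_private
  rows <- list()
  for (cl in names(np)) {
    if (np[[cl]] > 0L) {
      rows[[cl]] <- data.frame(
        concept = rep(concepts, each = np[[cl]]),
        feature = sprintf("pr_%s_%s_%d", substr(cl, 1, 1),
                          rep(concepts, each = np[[cl]]),
                          sequence(rep(np[[cl]], length(concepts)))),
        feature_class = cl, stringsAsFactors = FALSE)
    }
  }
  rows$tax <- data.frame(concept = concepts,
                         feature = paste0("tax_", concept_cat),
                         feature_class = "taxonomic",
                         stringsAsFactors = FALSE)
  pairs <- t(combn(seq_along(concepts), 2L))
  # high within-category sharing applies to the semantically coherent
  # experimental categories only; the general-noun section is a grab bag
  same <- concept_cat[pairs[, 1L]] == concept_cat[pairs[, 2L]] &
    concept_cat[pairs[, 1L]] %in% cats
  p <- ifelse(same, config$p_within, config$p_between)
  hit <- which(runif(nrow(pairs)) < p)
  if (length(hit)) {
    a <- concepts[pairs[hit, 1L]]
    b <- concepts[pairs[hit, 2L]]
    rows$pairs <- data.frame(
      concept = c(a, b, a, b),
      feature = c(sprintf("shp_%04d", hit), sprintf("shp_%04d", hit),
                  sprintf("shf_%04d", hit), sprintf("shf_%04d", hit)),
      feature_class = rep(c("perceptual", "functional"),
                          each = 2L * length(hit)),
      stringsAsFactors = FALSE)
  }
  feature_norms(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

# one draw from the truncated log-normal vocabulary-size distribution
draw_vocab_sizes <- function(n, meanlog, sdlog, range) {
  if (range[1] == range[2]) return(rep(as.integer(range[1]), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * n, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Generate a cohort of child vocabularies
#'
#' Vocabulary sizes are i.i.d. draws from the truncated log-normal; each
#' child samples that many checklist words without replacement, with
#' per-child Dirichlet category weights so that category-density rankings
#' vary across children.
#'
#' @inheritParams gen_norms
#' @return List of `lg_child_vocab` named by child id.
#' @export
gen_children <- function(config = sim_config(), checklist = gen_checklist(),
                         seed = substream_seed(config$seed, "children")) {
  set.seed(seed)
  n <- config$n_children
  n_items <- nrow(checklist)
  if (config$vocab_range[2] > n_items) {
    warning("vocabulary-size range exceeds checklist size; capping at ",
            n_items, call. = FALSE)
  }
  sizes <- pmin(draw_vocab_sizes(n, config$vocab_meanlog, config$vocab_sdlog,
                                 config$vocab_range), n_items)
  cats <- unique(checklist$category)
  cat_n <- table(factor(checklist$category, levels = cats))
  base <- as.numeric(cat_n) / n_items
  conc <- config$category_concentration
  item_cat_idx <- match(checklist$category, cats)
  ids <- sprintf("c%03d", seq_len(n))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    w <- if (is.infinite(conc)) base else {
      g <- stats::rgamma(length(cats), shape = conc * base * length(cats))
      if (sum(g) == 0) base else g / sum(g)
    }
    item_p <- w[item_cat_idx] / as.numeric(cat_n)[item_cat_idx]
    produced <- sample(checklist$word_id, sizes[k], prob = item_p)
    out[[k]] <- child_vocabulary(ids[k], produced)
  }
  names(out) <- ids
  out
}

#' Generate the counterbalanced 24-trial design
#'
#' Each child sees 24 trials: 12 related (same-category pairs) and 12
#' unrelated (yoked cross-category pairs).  Every image appears four times
#' -- twice as target and twice as distractor, once per role in each
#' condition -- and equally often on the left and right side.  Trial order
#' is shuffled per child from a seed sub-stream.
#'
#' @param child_ids Character vector of child ids.
#' @param items Item/pairing table, see [experimental_items()].
#' @param seed Integer seed for the per-child order shuffles.
#' @return Data frame: `trial_id`, `child_id`, `trial_index`, `condition`,
#'   `target`, `distractor`, `target_side`.
#' @export
gen_design <- function(child_ids, items = experimental_items(), seed = 1L) {
  stopifnot(nrow(items) == 12L)
  # validate pairing symmetry
  for (col in c("related_partner", "unrelated_partner")) {
    p <- setNames(items[[col]], items$item)
    if (!setequal(names(p), unname(p)) ||
        any(p[p[names(p)]] != names(p)) || any(p == names(p))) {
      stop("inconsistent ", col, " pairing table", call. = FALSE)
    }
  }
  if (any(items$category[match(items$related_partner, items$item)] !=
          items$category)) {
    stop("related partners must share a category", call. = FALSE)
  }
  if (any(items$category[match(items$unrelated_partner, items$item)] ==
          items$category)) {
    stop("unrelated partners must not share a category", call. = FALSE)
  }
  pair_set <- function(col, cond) {
    keep <- items$item < items[[col]]
    data.frame(a = items$item[keep], b = items[[col]][keep],
               condition = cond, stringsAsFactors = FALSE)
  }
  pairs <- rbind(pair_set("related_partner", "related"),
                 pair_set("unrelated_partner", "unrelated"))
  trials <- do.call(rbind, lapply(split(pairs, pairs$condition), function(pp) {
    pp <- pp[order(pp$a, pp$b), , drop = FALSE]
    # alternate the pair's target side so each condition has six
    # target-left and six target-right trials
    side <- ifelse(seq_len(nrow(pp)) %% 2L == 1L, "left", "right")
    rbind(
      data.frame(condition = pp$condition, target = pp$a, distractor = pp$b,
                 target_side = side, stringsAsFactors = FALSE),
      data.frame(condition = pp$condition, target = pp$b, distractor = pp$a,
                 target_side = side, stringsAsFactors = FALSE))
  }))
  rownames(trials) <- NULL
  out <- lapply(child_ids, function(cid) {
    ord <- withr_seed(substream_seed(seed, paste0("order_", cid)),
                      sample.int(nrow(trials)))
    d <- trials[ord, , drop = FALSE]
    d$child_id <- cid
    d$trial_index <- seq_len(nrow(d))
    d$trial_id <- sprintf("%s_%02d", cid, d$trial_index)
    d[, c("trial_id", "child_id", "trial_index", "condition", "target",
          "distractor", "target_side")]
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Generate comprehension ratings
#'
#' Each child x target item receives a parental rating on the 1..4 scale.
#' With probability `p_low_rating` the rating falls below 2 (exercising the
#' comprehension filter); otherwise produced items skew towards 4 and
#' unproduced items towards 2-3.
#'
#' @param children List of `lg_child_vocab`.
#' @param items Character vector of target item ids.
#' @param config An [sim_config()].
#' @param seed Integer seed.
#' @return Data frame `child_id`, `item`, `rating`.
#' @export
gen_ratings <- function(children, items = experimental_items()$item,
                        config = sim_config(),
                        seed = substream_seed(config$seed, "ratings")) {
  set.seed(seed)
  names(children) <- vapply(children, `[[`, character(1), "child_id")
  grid <- expand.grid(child_id = vapply(children, `[[`, character(1),
                                        "child_id"),
                      item = items, stringsAsFactors = FALSE)
  produced <- vapply(seq_len(nrow(grid)), function(i) {
    grid$item[i] %in% children[[grid$child_id[i]]]$produced
  }, logical(1))
  low <- runif(nrow(grid)) < config$p_low_rating
  hi <- ifelse(produced,
               sample(3:4, nrow(grid), replace = TRUE, prob = c(.3, .7)),
               sample(2:4, nrow(grid), replace = TRUE, prob = c(.4, .4, .2)))
  grid$rating <- as.integer(ifelse(low, 1L, hi))
  grid
}

# stationary state distributions (TARGET, DISTRACTOR, OTHER, OFFSCREEN)
stationary_dists <- function(eta, p_off, p_other) {
  on <- 1 - p_off
  pre <- c(on / 3, on / 3, on / 3, p_off)
  pt <- stats::plogis(eta)
  post <- c(on * (1 - p_other) * pt, on * (1 - p_other) * (1 - pt),
            on * p_other, p_off)
  if (any(pre < 0) || any(post < 0) ||
      abs(sum(pre) - 1) > 1e-9 || abs(sum(post) - 1) > 1e-9) {
    stop("unreachable stationary gaze configuration", call. = FALSE)
  }
  list(pre = pre, post = post)
}

# simulate one trial's state sequence (integer codes 1..4)
simulate_states <- function(n_steps, latency_step, pis, stay_prob) {
  u <- runif(n_steps)
  sw <- which(u < 1 - stay_prob)
  if (length(sw) == 0L || sw[1L] != 1L) sw <- c(1L, sw)
  is_pre <- sw <= latency_step
  v <- runif(length(sw))
  st <- integer(length(sw))
  if (any(is_pre)) {
    st[is_pre] <- findInterval(v[is_pre], cumsum(pis$pre)[1:3]) + 1L
  }
  if (any(!is_pre)) {
    st[!is_pre] <- findInterval(v[!is_pre], cumsum(pis$post)[1:3]) + 1L
  }
  rep(st, diff(c(sw, n_steps + 1L)))
}

#' Generate gaze streams for a trial design
#'
#' Each trial is a four-state Markov chain at 2 ms steps over
#' `[0, duration_ms)`: at every step the current state is kept with
#' probability `stay_prob`, otherwise a fresh state is drawn from the
#' stationary distribution -- near-uniform over on-screen states before the
#' latency, and with target/distractor odds `exp(eta)` after it.  A small
#' fraction of trials is "fussy" (high off-screen rate), exercising the
#' track-loss filter.  Each trial draws from its own seed sub-stream keyed
#' by trial id, so trial order never changes the numbers drawn.
#'
#' @param design Data frame from [gen_design()].
#' @param eta Numeric vector of per-trial post-latency log-odds, aligned
#'   with `design` rows.
#' @param ratings Data frame from [gen_ratings()].
#' @param config An [sim_config()].
#' @param seed Integer master seed for the per-trial sub-streams.
#' @return List of `lg_gaze_trial`.
#' @export
gen_gaze <- function(design, eta, ratings, config = sim_config(),
                     seed = substream_seed(config$seed, "gaze")) {
  stopifnot(nrow(design) == length(eta))
  n_steps <- as.integer(config$duration_ms / 2)
  latency_step <- as.integer(config$latency_ms / 2)
  rkey <- paste(ratings$child_id, ratings$item)
  rate <- setNames(ratings$rating, rkey)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    set.seed(substream_seed(seed, d$trial_id))
    fussy <- runif(1) < config$fussy_prob
    p_off <- if (fussy) config$fussy_rate else config$offscreen_base
    pis <- stationary_dists(eta[i], p_off, config$p_other)
    st <- simulate_states(n_steps, latency_step, pis, config$stay_prob)
    out[[i]] <- gaze_trial(d$trial_id, d$child_id, d$condition, d$target,
                           d$distractor, rate[[paste(d$child_id, d$target)]],
                           st, d$target_side)
  }
  names(out) <- design$trial_id
  out
}

# z-score with sample (n-1) SD; all-equal input maps to zeros
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate a complete cohort
#'
#' Runs every generator in sequence -- checklist, norms, children, density
#' and vocabulary-group assignments, structure metrics, trial design,
#' ratings and gaze streams -- and records the realized generative
#' coefficients and item intercepts as the recovery oracle (`$truth`).
#' Fully reproducible from `config$seed`.
#'
#' @param config An [sim_config()].
#' @return A list of class `lg_cohort` with elements `config`, `checklist`,
#'   `norms`, `children`, `density`, `groups`, `metrics`, `design`,
#'   `ratings`, `gaze`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  checklist <- gen_checklist()
  norms <- gen_norms(config, checklist)
  children <- gen_children(config, checklist)
  density <- density_assignments(children, checklist, config$density_mode)
  groups <- split_vocab_groups(children)
  metrics <- structure_metrics(children, norms,
                               targets = experimental_items()$item,
                               threshold = config$edge_threshold)
  design <- gen_design(names(children),
                       seed = substream_seed(config$seed, "design"))
  ratings <- gen_ratings(children, config = config)
  item_ids <- experimental_items()$item
  item_int <- withr_seed(substream_seed(config$seed, "items"),
                         stats::rnorm(length(item_ids), 0, config$item_sd))
  names(item_int) <- item_ids

  gcc_z <- setNames(zscore(metrics$metrics$gcc), metrics$metrics$child_id)
  deg_z <- zscore(metrics$degrees$degree)
  dkey <- paste(metrics$degrees$child_id, metrics$degrees$item)
  deg_z <- setNames(deg_z, dkey)
  item_cat <- setNames(experimental_items()$category,
                       experimental_items()$item)
  dens_code <- setNames(ifelse(density$condition == "High", -0.5, 0.5),
                        paste(density$child_id, density$category))
  grp_code <- setNames(ifelse(groups$group == "High", -0.5, 0.5),
                       groups$child_id)

  g <- grp_code[design$child_id]
  x_gcc <- gcc_z[design$child_id]
  x_deg <- deg_z[paste(design$child_id, design$target)]
  x_den <- dens_code[paste(design$child_id, item_cat[design$target])]
  eta <- config$beta0 +
    config$beta_condition * (design$condition == "related") +
    config$beta_gcc * x_gcc * (1 + config$gamma_gcc * g) +
    config$beta_degree * x_deg * (1 + config$gamma_degree * g) +
    config$beta_density * x_den * (1 + config$gamma_density * g) +
    item_int[design$target]
  eta <- unname(eta)

  gaze <- gen_gaze(design, eta, ratings, config)
  truth <- list(
    coefficients = c(beta0 = config$beta0,
                     beta_condition = config$beta_condition,
                     beta_gcc = config$beta_gcc,
                     beta_degree = config$beta_degree,
                     beta_density = config$beta_density,
                     gamma_gcc = config$gamma_gcc,
                     gamma_degree = config$gamma_degree,
                     gamma_density = config$gamma_density),
    item_intercepts = item_int,
    eta = setNames(eta, design$trial_id),
    seed = config$seed)
  structure(list(config = config, checklist = checklist, norms = norms,
                 children = children, density = density, groups = groups,
                 metrics = metrics, design = design, ratings = ratings,
                 gaze = gaze, truth = truth),
            class = "lg_cohort")
}

#' @export
print.lg_cohort <- function(x, ...) {
  cat("<cohort> ", length(x$children), " children, ", nrow(x$design),
      " trials (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Serialize / restore the generative truth
#'
#' @param truth `$truth` element of an [simulate_cohort()] result.
#' @param path JSON file.
#' @return `write_sim_truth` invisibly returns `path`; `read_sim_truth`
#'   the restored list.
#' @export
write_sim_truth <- function(truth, path) {
  out <- truth
  # named vectors as JSON objects so names survive the round trip
  for (nm in c("coefficients", "item_intercepts", "eta")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$item_intercepts <- unlist(x$item_intercepts)
  x$eta <- unlist(x$eta)
  x
}

#' Write a cohort in the pipeline's input formats
#'
#' The generator doubles as a fixture factory: every table is written as
#' delimited text in exactly the format the corresponding reader expects.
#' Gaze sample streams are large and only written when requested.
#'
#' @param cohort An `lg_cohort`.
#' @param dir Output directory (created if needed).
#' @param include_gaze Also write per-sample gaze states (big files).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir, include_gaze = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name); write_tsv(df, p); paths <<- c(paths, p)
  }
  w(as.data.frame(cohort$checklist), "checklist.tsv")
  vocab <- do.call(rbind, lapply(cohort$children, function(ch) {
    data.frame(child_id = ch$child_id, word_id = ch$produced,
               stringsAsFactors = FALSE)
  }))
  w(vocab, "vocab_reports.tsv")
  w(as.data.frame(cohort$norms), "feature_norms.tsv")
  w(cohort$density, "density_assignments.tsv")
  w(cohort$groups, "vocab_groups.tsv")
  w(cohort$metrics$metrics, "structure_metrics.tsv")
  w(cohort$metrics$degrees, "target_degrees.tsv")
  meta <- cohort$design
  rkey <- paste(cohort$ratings$child_id, cohort$ratings$item)
  meta$rating <- cohort$ratings$rating[match(paste(meta$child_id,
                                                   meta$target), rkey)]
  w(meta, "trial_metadata.tsv")
  if (include_gaze) {
    smp <- do.call(rbind, lapply(cohort$gaze, function(tr) {
      data.frame(trial_id = tr$trial_id, t_ms = trial_times(tr),
                 state = gaze_states()[tr$state], stringsAsFactors = FALSE)
    }))
    w(smp, "gaze_samples.tsv")
  }
  write_sim_truth(cohort$truth, file.path(dir, "sim_truth.json"))
  invisible(c(paths, file.path(dir, "sim_truth.json")))
}
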