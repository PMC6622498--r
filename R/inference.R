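# Predictor coding and the item-intercept mixed models relating structure
# metrics to the trial-level log-gaze statistic.

#' Build the model design table
#'
#' Joins retained trial accuracies with each child's structure metrics,
#' density assignment and vocabulary group, then codes predictors within
#' the modelled subset: categorical factors are sum coded (High = -0.5,
#' Low = +0.5) and continuous metrics (global clustering coefficient,
#' target degree) are centred and standardized with the sample (n-1) SD
#' computed over the modelled subset, so that per-condition and per-group
#' fits each standardize over their own trials.
#'
#' @param acc Retained trial accuracy table ([filter_trials()] `$retained`).
#' @param metrics Result of [structure_metrics()].
#' @param density Data frame from [density_assignments()].
#' @param groups Data frame from [split_vocab_groups()].
#' @param items Item/category table, see [experimental_items()].
#' @param condition Optional condition subset (`"related"`/`"unrelated"`).
#' @param vocab_group Optional vocabulary-group subset (`"High"`/`"Low"`).
#' @return Data frame of class `lg_design_table`: `trial_id`, `child_id`,
#'   `item`, `condition`, `group`, `log_gaze`, `gcc`, `degree`, `gcc_z`,
#'   `degree_z`, `density_code`, `group_code`.
#' @export
code_predictors <- function(acc, metrics, density, groups,
                            items = experimental_items(),
                            condition = NULL, vocab_group = NULL) {
  need <- c("trial_id", "child_id", "condition", "item", "log_gaze")
  stopifnot(all(need %in% names(acc)))
  d <- acc[, intersect(names(acc), c(need, "rating")), drop = FALSE]

  gcc <- setNames(metrics$metrics$gcc, metrics$metrics$child_id)
  dkey <- paste(metrics$degrees$child_id, metrics$degrees$item)
  degree <- setNames(metrics$degrees$degree, dkey)
  grp <- setNames(groups$group, groups$child_id)
  item_cat <- setNames(items$category, items$item)
  dens <- setNames(density$condition,
                   paste(density$child_id, density$category))

  d$gcc <- unname(gcc[d$child_id])
  d$degree <- unname(degree[paste(d$child_id, d$item)])
  d$group <- unname(grp[d$child_id])
  d$density <- unname(dens[paste(d$child_id, item_cat[d$item])])
  bad <- is.na(d$gcc) | is.na(d$degree) | is.na(d$group) | is.na(d$density)
  if (any(bad)) {
    abort_with_listing(
      "trials whose child lacks metrics, density or group assignments",
      utils::head(d$trial_id[bad], 20L))
  }
  if (!is.null(condition)) d <- d[d$condition == condition, , drop = FALSE]
  if (!is.null(vocab_group)) d <- d[d$group == vocab_group, , drop = FALSE]
  if (nrow(d) == 0L) stop("no trials left after subsetting", call. = FALSE)
  for (v in c("gcc", "degree")) {
    if (stats::sd(d[[v]]) == 0) {
      stop("degenerate predictor: ", v,
           " is constant over the modelled subset", call. = FALSE)
    }
  }
  d$gcc_z <- zscore(d$gcc)
  d$degree_z <- zscore(d$degree)
  d$density_code <- ifelse(d$density == "High", -0.5, 0.5)
  d$group_code <- ifelse(d$group == "High", -0.5, 0.5)
  rownames(d) <- NULL
  class(d) <- c("lg_design_table", "data.frame")
  d
}

# shared model-result builder
build_model_result <- function(fit, formula_str, p_method, n_trials,
                               n_items) {
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  terms <- rownames(sm$coefficients)
  est <- co[["Estimate"]]
  se <- co[["Std. Error"]]
  tv <- co[["t value"]]
  if (p_method == "satterthwaite" && "Pr(>|t|)" %in% names(co)) {
    p <- co[["Pr(>|t|)"]]
    df <- co[["df"]]
  } else {
    p_method <- "z"
    p <- 2 * stats::pnorm(-abs(tv))
    df <- rep(NA_real_, length(tv))
  }
  V <- as.matrix(stats::vcov(fit))
  corr <- stats::cov2cor(V)
  dimnames(corr) <- list(terms, terms)
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- if (is.null(msgs)) character(0) else unlist(msgs)
  # a boundary (singular) fit is reported via the `singular` flag, not as a
  # convergence failure
  conv_msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  structure(list(
    coefficients = data.frame(term = terms, estimate = est, se = se,
                              t = tv, df = df, p = p,
                              stringsAsFactors = FALSE),
    corr = corr,
    n_trials = n_trials, n_items = n_items,
    ranef_var = as.data.frame(lme4::VarCorr(fit)),
    converged = length(conv_msgs) == 0L,
    singular = lme4::isSingular(fit),
    messages = msgs,
    formula = formula_str, p_method = p_method,
    grouping = "random intercept per item"),
    class = "lg_model_result")
}

fit_lmm <- function(design, formula_str, p_method) {
  if (stats::sd(design$log_gaze) == 0) return(fit_constant(design,
                                                           formula_str))
  f <- stats::as.formula(formula_str)
  fit <- if (p_method == "satterthwaite" &&
             requireNamespace("lmerTest", quietly = TRUE)) {
    suppressMessages(lmerTest::lmer(f, data = design, REML = TRUE))
  } else {
    p_method <- "z"
    suppressMessages(lme4::lmer(f, data = design, REML = TRUE))
  }
  build_model_result(fit, formula_str, p_method, nrow(design),
                     length(unique(design$item)))
}

# A constant response carries no information about the variance components
# and breaks the REML machinery; fall back to the (exact) fixed-effects
# least-squares solution and flag the fit.
fit_constant <- function(design, formula_str) {
  fixed <- sub("\\s*\\+\\s*\\(1 \\| item\\)", "", formula_str)
  fit0 <- suppressWarnings(stats::lm(stats::as.formula(fixed),
                                     data = design))
  co <- suppressWarnings(as.data.frame(summary(fit0)$coefficients))
  terms <- rownames(co)
  corr <- diag(length(terms))
  dimnames(corr) <- list(terms, terms)
  structure(list(
    coefficients = data.frame(term = terms, estimate = co[["Estimate"]],
                              se = co[["Std. Error"]], t = co[["t value"]],
                              df = rep(NA_real_, length(terms)),
                              p = co[["Pr(>|t|)"]],
                              stringsAsFactors = FALSE),
    corr = corr, n_trials = nrow(design),
    n_items = length(unique(design$item)),
    ranef_var = data.frame(grp = c("item", "Residual"),
                           vcov = c(0, 0)),
    converged = TRUE, singular = TRUE,
    messages = "constant response; fixed-effects-only fall-back",
    formula = formula_str, p_method = "z",
    grouping = "random intercept per item"),
    class = "lg_model_result")
}

#' Fit the full structure x vocabulary-group model for one condition
#'
#' Restricted maximum likelihood fit of
#' `log_gaze ~ (gcc_z + degree_z + density_code) * group_code + (1 | item)`:
#' the three structure predictors, vocabulary group, and all structure x
#' group interactions as fixed effects, with a single random intercept per
#' item (participants are deliberately not a grouping factor).  By default
#' p-values use the normal approximation on t; `p_method = "satterthwaite"`
#' uses the Satterthwaite degrees-of-freedom approximation when available.
#' Non-convergence is flagged in the result, never silently dropped.  A
#' rank-deficient fixed-effect column (for example a structure-by-group
#' interaction when one group's metric is constant) is dropped by the
#' estimation routine and is then absent from the coefficient table.
#'
#' @param design An `lg_design_table`, typically already subset to one
#'   condition.
#' @param p_method `"z"` (default) or `"satterthwaite"`.
#' @param participants Sensitivity mode: also include a random intercept
#'   per child.  Off by default -- with few trials per child over few items
#'   these models routinely fail to converge, which is why items are the
#'   only grouping factor; the result's `converged` flag reports the
#'   outcome.
#' @return A list of class `lg_model_result`: per-term `coefficients`
#'   (estimate, se, t, p), the fixed-effect correlation matrix `corr`,
#'   `n_trials`, `n_items`, `converged`, `singular`, `formula`.
#' @export
fit_condition_model <- function(design, p_method = c("z", "satterthwaite"),
                                participants = FALSE) {
  p_method <- match.arg(p_method)
  if (length(unique(design$item)) < 2L) {
    stop("need at least two items for an item random intercept",
         call. = FALSE)
  }
  f <- paste0("log_gaze ~ (gcc_z + degree_z + density_code) * group_code",
              " + (1 | item)",
              if (participants) " + (1 | child_id)")
  fit_lmm(design, f, p_method)
}

#' Fit the structure-only model for one vocabulary group
#'
#' As [fit_condition_model()] but with fixed effects
#' `gcc_z + degree_z + density_code` only, for a design table subset to a
#' single vocabulary group within a condition.
#'
#' @inheritParams fit_condition_model
#' @return An `lg_model_result`.
#' @export
fit_group_model <- function(design, p_method = c("z", "satterthwaite"),
                            participants = FALSE) {
  p_method <- match.arg(p_method)
  if (length(unique(design$item)) < 2L) {
    stop("need at least two items for an item random intercept",
         call. = FALSE)
  }
  f <- paste0("log_gaze ~ gcc_z + degree_z + density_code + (1 | item)",
              if (participants) " + (1 | child_id)")
  fit_lmm(design, f, p_method)
}

#' @export
print.lg_model_result <- function(x, ...) {
  cat("<mixed model> ", x$formula, "\n  ", x$n_trials, " trials, ",
      x$n_items, " items; ", if (x$converged) "converged" else
        "DID NOT CONVERGE", if (x$singular) " (singular fit)", "\n", sep = "")
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 3)
  co$se <- signif(co$se, 3)
  co$t <- signif(co$t, 3)
  co$p <- signif(co$p, 3)
  print(co[, c("term", "estimate", "se", "t", "p")], row.names = FALSE)
  invisible(x)
}

#' Tabulate and render model results
#'
#' One panel per fitted model, terms in fitted order, with significance
#' flags (`sig` for p < .05, `marginal` for .05 <= p < .1) and the
#' fixed-effect correlation matrix appended.  A footer records the p-value
#' method.
#'
#' @param results Named list of `lg_model_result`.
#' @param file Optional path; when given the rendered text is written there.
#' @return Invisibly, a list with `table` (long data frame over all models)
#'   and `text` (character vector of rendered panels).
#' @export
model_report <- function(results, file = NULL) {
  stopifnot(length(results) >= 1L)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- paste0("model_", seq_along(results))
  }
  rows <- lapply(names(results), function(nm) {
    co <- results[[nm]]$coefficients
    co$model <- nm
    co$sig <- co$p < 0.05
    co$marginal <- co$p >= 0.05 & co$p < 0.1
    co[, c("model", "term", "estimate", "se", "t", "p", "sig", "marginal")]
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  txt <- character(0)
  for (nm in names(results)) {
    r <- results[[nm]]
    txt <- c(txt, sprintf("== %s ==", nm),
             sprintf("  %s", r$formula),
             sprintf("  %d trials, %d items%s%s", r$n_trials, r$n_items,
                     if (r$converged) "" else "  [NOT CONVERGED]",
                     if (r$singular) "  [singular]" else ""))
    co <- r$coefficients
    flag <- ifelse(co$p < 0.05, " *", ifelse(co$p < 0.1, " .", ""))
    txt <- c(txt, sprintf("  %-32s %9.3f %9.3f %8.2f %8.4f%s",
                          co$term, co$estimate, co$se, co$t, co$p, flag))
    txt <- c(txt, "  Correlation of fixed effects:")
    cm <- round(r$corr, 3)
    txt <- c(txt, paste0("    ",
                         utils::capture.output(print(cm))))
    txt <- c(txt, "")
  }
  txt <- c(txt,
           sprintf("p-values: %s; '*' p < .05, '.' p < .1",
                   if (results[[1]]$p_method == "z")
                     "normal approximation on t" else
                       "Satterthwaite approximation"))
  if (!is.null(file)) writeLines(txt, file)
  invisible(list(table = tab, text = txt))
}

#' Serialize model results to JSON
#' @param results Named list of `lg_model_result`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model_results <- function(results, path) {
  out <- lapply(results, function(r) {
    list(formula = r$formula, coefficients = r$coefficients,
         corr = r$corr, n_trials = r$n_trials, n_items = r$n_items,
         converged = r$converged, singular = r$singular,
         p_method = r$p_method)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
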