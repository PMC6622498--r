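# Predictor coding and the item-intercept mixed models.

# small deterministic design table for coding tests
coding_fixture <- function() {
  co <- suppressWarnings(simulate_cohort(sim_config(seed = 23,
                                                    n_children = 12)))
  acc <- trial_accuracy_table(co$gaze)
  f <- filter_trials(acc)
  list(cohort = co, acc = acc, filtered = f)
}

test_that("sum codes: High maps to -0.5, Low to +0.5; z within subset", {
  fx <- coding_fixture()
  co <- fx$cohort
  d <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                       co$groups)
  expect_true(all(d$group_code %in% c(-0.5, 0.5)))
  expect_true(all(d$density_code %in% c(-0.5, 0.5)))
  hi <- d$group == "High"
  expect_true(all(d$group_code[hi] == -0.5))
  expect_true(all(d$group_code[!hi] == 0.5))
  # continuous predictors standardized over the modelled subset
  expect_equal(mean(d$gcc_z), 0, tolerance = 1e-10)
  expect_equal(sd(d$gcc_z), 1, tolerance = 1e-10)
  dr <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                        co$groups, condition = "related")
  expect_equal(sd(dr$degree_z), 1, tolerance = 1e-10)
  expect_true(all(dr$condition == "related"))
})

test_that("two-child toy table standardizes with the sample (n-1) SD", {
  # gcc over the four modelled trials is {0.2, 0.2, 0.4, 0.4}: centred to
  # +/-0.1, sample SD sqrt(0.04/3) = 0.11547 -> z = -/+ 0.86603
  # (population SD would give -/+ 1; the sample-SD convention is the
  # documented choice)
  metrics <- list(
    metrics = data.frame(child_id = c("a", "b"), gcc = c(0.2, 0.4)),
    degrees = data.frame(child_id = rep(c("a", "b"), each = 2),
                         item = rep(c("dog", "bird"), 2),
                         degree = c(1L, 3L, 2L, 4L)))
  density <- data.frame(child_id = rep(c("a", "b"), each = 6),
                        category = rep(names(cdi_category_sizes()), 2),
                        proportion = 0.5,
                        condition = rep(c("High", "High", "High",
                                          "Low", "Low", "Low"), 2))
  groups <- data.frame(child_id = c("a", "b"),
                       total_produced = c(10L, 60L),
                       group = c("Low", "High"))
  acc <- data.frame(trial_id = c("t1", "t2", "t3", "t4"),
                    child_id = c("a", "a", "b", "b"),
                    condition = "related",
                    item = c("dog", "bird", "dog", "bird"),
                    log_gaze = c(0.1, 0.2, 0.3, 0.4))
  d <- code_predictors(acc, metrics, density, groups)
  expect_equal(unique(d$gcc_z[d$child_id == "a"]), -sqrt(3) / 2,
               tolerance = 1e-10)
  expect_equal(unique(d$gcc_z[d$child_id == "b"]), sqrt(3) / 2,
               tolerance = 1e-10)
  # dog is an ANIMALS item and ANIMALS is High for both children
  expect_true(all(d$density_code[d$item == "dog"] == -0.5))
})

test_that("degenerate predictors and missing joins are rejected", {
  metrics <- list(
    metrics = data.frame(child_id = c("a", "b"), gcc = c(0.3, 0.3)),
    degrees = data.frame(child_id = rep(c("a", "b"), each = 1),
                         item = "dog", degree = c(1L, 2L)))
  density <- data.frame(child_id = rep(c("a", "b"), each = 6),
                        category = rep(names(cdi_category_sizes()), 2),
                        proportion = 0.5, condition = "High")
  groups <- data.frame(child_id = c("a", "b"),
                       total_produced = c(10L, 60L),
                       group = c("Low", "High"))
  acc <- data.frame(trial_id = c("t1", "t2"), child_id = c("a", "b"),
                    condition = "related", item = "dog",
                    log_gaze = c(0.1, 0.2))
  expect_error(code_predictors(acc, metrics, density, groups),
               "degenerate predictor: gcc")
  acc2 <- acc
  acc2$child_id[2] <- "zz" # child without metrics
  expect_error(code_predictors(acc2, metrics, density, groups), "t2")
})

test_that("null response yields near-zero estimates", {
  fx <- coding_fixture()
  co <- fx$cohort
  d <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                       co$groups, condition = "related")
  d$log_gaze <- 0
  m <- suppressWarnings(suppressMessages(fit_condition_model(d)))
  expect_true(all(abs(m$coefficients$estimate) < 1e-8))
  # no term can be called significant when the response carries no signal
  p <- m$coefficients$p
  expect_false(any(!is.na(p) & p < 0.05))
})

test_that("flipping both sum codes flips main effects, |t| unchanged", {
  fx <- coding_fixture()
  co <- fx$cohort
  d <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                       co$groups, condition = "unrelated")
  m1 <- fit_condition_model(d)
  d2 <- d
  d2$density_code <- -d2$density_code
  d2$group_code <- -d2$group_code
  m2 <- fit_condition_model(d2)
  g <- function(m, term, col) {
    m$coefficients[[col]][m$coefficients$term == term]
  }
  for (term in c("density_code", "group_code")) {
    expect_equal(g(m2, term, "estimate"), -g(m1, term, "estimate"),
                 tolerance = 1e-6)
    expect_equal(abs(g(m2, term, "t")), abs(g(m1, term, "t")),
                 tolerance = 1e-6)
  }
  # the density x group interaction is invariant (product of two flips)
  expect_equal(g(m2, "density_code:group_code", "estimate"),
               g(m1, "density_code:group_code", "estimate"),
               tolerance = 1e-6)
  # continuous main effects are evaluated at the grand mean either way
  expect_equal(g(m2, "gcc_z", "estimate"), g(m1, "gcc_z", "estimate"),
               tolerance = 1e-6)
})

test_that("fixed-effect correlations are invariant under response rescaling", {
  fx <- coding_fixture()
  co <- fx$cohort
  d <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                       co$groups, condition = "related")
  m1 <- fit_condition_model(d)
  d3 <- d
  d3$log_gaze <- 3.7 * d3$log_gaze
  m3 <- fit_condition_model(d3)
  expect_equal(m1$corr, m3$corr, tolerance = 1e-6)
  expect_true(all(abs(diag(m1$corr) - 1) < 1e-12))
  expect_equal(m1$corr, t(m1$corr))
})

test_that("group models fit on subsets and are deterministic", {
  fx <- coding_fixture()
  co <- fx$cohort
  dg <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                        co$groups, condition = "related",
                        vocab_group = "High")
  m <- fit_group_model(dg)
  expect_equal(m$coefficients$term,
               c("(Intercept)", "gcc_z", "degree_z", "density_code"))
  expect_equal(m$n_trials, nrow(dg))
  m2 <- fit_group_model(dg)
  expect_equal(m$coefficients, m2$coefficients)
})

test_that("participants sensitivity mode adds a child intercept", {
  fx <- coding_fixture()
  co <- fx$cohort
  d <- code_predictors(fx$filtered$retained, co$metrics, co$density,
                       co$groups, condition = "related")
  m <- suppressWarnings(suppressMessages(
    fit_condition_model(d, participants = TRUE)))
  expect_match(m$formula, "child_id")
  expect_true("child_id" %in% m$ranef_var$grp)
  expect_type(m$converged, "logical") # convergence is reported either way
})

test_that("zero item variance shows up as a near-zero random intercept", {
  cfg <- sim_config(seed = 29, n_children = 16, item_sd = 0)
  fx <- fit_recovery_models(29, cfg)
  d <- code_predictors(fx$filtered$retained, fx$cohort$metrics,
                       fx$cohort$density, fx$cohort$groups,
                       condition = "unrelated")
  m <- fit_condition_model(d)
  iv <- m$ranef_var$vcov[m$ranef_var$grp == "item"]
  rv <- m$ranef_var$vcov[m$ranef_var$grp == "Residual"]
  expect_lt(iv / rv, 0.05)
})

test_that("reports flag significance and marginality per the .05/.1 rule", {
  mk <- function(p) {
    structure(list(
      coefficients = data.frame(term = "x", estimate = 1, se = 1,
                                t = 1, df = NA_real_, p = p),
      corr = matrix(1, 1, 1, dimnames = list("x", "x")),
      n_trials = 10L, n_items = 2L,
      ranef_var = data.frame(),
      converged = TRUE, singular = FALSE, messages = character(0),
      formula = "y ~ x + (1 | item)", p_method = "z",
      grouping = "random intercept per item"),
      class = "lg_model_result")
  }
  rep1 <- model_report(list(sig = mk(0.044), marg = mk(0.073),
                            ns = mk(0.4)))
  tab <- rep1$table
  expect_true(tab$sig[tab$model == "sig"])
  expect_false(tab$marginal[tab$model == "sig"])
  expect_true(tab$marginal[tab$model == "marg"])
  expect_false(tab$sig[tab$model == "marg"])
  expect_false(tab$sig[tab$model == "ns"] || tab$marginal[tab$model == "ns"])
  expect_match(paste(rep1$text, collapse = "\n"), "normal approximation")
})
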