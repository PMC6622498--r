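# The synthetic cohort generator: norms, vocabularies, design, ratings,
# gaze streams, determinism and the serialized truth.

test_that("generated checklist has the canonical category sizes", {
  cl <- gen_checklist()
  sz <- table(cl$category)[names(cdi_category_sizes())]
  expect_equal(unname(as.integer(sz)), unname(cdi_category_sizes()))
  expect_equal(nrow(cl), 680L)
  expect_true(all(experimental_items()$item %in% cl$word_id))
})

test_that("norms: class structure and edge-probability control", {
  cfg <- sim_config(seed = 3)
  cl <- gen_checklist()
  norms <- gen_norms(cfg, cl)
  expect_s3_class(norms, "lg_feature_norms")
  expect_setequal(unique(norms$feature_class),
                  c("perceptual", "functional", "taxonomic",
                    "encyclopedic"))
  # norms cover all checklist nouns: the six experimental categories plus
  # the general-noun section
  concepts <- unique(norms$concept)
  exp_items <- cl$word_id[cl$category %in% experimental_categories(cl)]
  expect_true(all(exp_items %in% concepts))
  expect_true(any(cl$category[match(concepts, cl$word_id)] ==
                    "OTHER-NOUNS"))

  # between-category sharing off -> no cross-category edges
  cfg0 <- sim_config(seed = 3, p_between = 0)
  norms0 <- gen_norms(cfg0, cl)
  net <- build_network(concepts, norms0)
  cat_of <- setNames(cl$category, cl$word_id)
  expect_true(all(cat_of[net$edges$from] == cat_of[net$edges$to]))

  # within-category sharing forced on -> every within-category pair linked
  cfg1 <- sim_config(seed = 3, p_within = 1, p_between = 0)
  net1 <- build_network(concepts, gen_norms(cfg1, cl))
  for (cat in experimental_categories(cl)) {
    members <- cl$word_id[cl$category == cat]
    sub <- net1$edges[net1$edges$from %in% members &
                        net1$edges$to %in% members, ]
    expect_equal(nrow(sub), choose(length(members), 2))
  }
  expect_warning(gen_norms(sim_config(seed = 3, p_within = 1,
                                      p_between = 1), cl),
                 "degenerate")
})

test_that("norms: empirical edge rates match the configured probabilities", {
  # 60-concept checklist (10 per category) for a cheap Monte-Carlo check
  cats <- names(cdi_category_sizes())
  cl <- checklist_definition(data.frame(
    word_id = paste0(rep(tolower(cats), each = 10), "_", 1:10),
    category = rep(cats, each = 10)))
  cfg <- sim_config(seed = 5)
  n_within <- 6 * choose(10, 2)
  n_between <- choose(60, 2) - n_within
  hits_w <- 0L
  hits_b <- 0L
  draws <- 50L
  for (r in seq_len(draws)) {
    norms <- gen_norms(cfg, cl, seed = 1000L + r)
    net <- build_network(cl$word_id, norms)
    cat_of <- setNames(cl$category, cl$word_id)
    same <- cat_of[net$edges$from] == cat_of[net$edges$to]
    hits_w <- hits_w + sum(same)
    hits_b <- hits_b + sum(!same)
  }
  p_w <- hits_w / (draws * n_within)
  p_b <- hits_b / (draws * n_between)
  se_w <- sqrt(cfg$p_within * (1 - cfg$p_within) / (draws * n_within))
  se_b <- sqrt(cfg$p_between * (1 - cfg$p_between) / (draws * n_between))
  expect_lt(abs(p_w - cfg$p_within), 3 * se_w)
  expect_lt(abs(p_b - cfg$p_between), 3 * se_b)
})

test_that("children: degenerate size, concentration limit, calibrated mean", {
  cl <- gen_checklist()
  cfg10 <- sim_config(seed = 7, n_children = 10,
                      vocab_range = c(10L, 10L))
  kids10 <- gen_children(cfg10, cl)
  expect_true(all(vapply(kids10, `[[`, integer(1),
                         "total_produced") == 10L))

  # infinite concentration: per-child category weights collapse to the
  # checklist base rates, so six-category proportion profiles are nearly
  # identical across children
  spread <- function(conc) {
    cfg <- sim_config(seed = 7, n_children = 20,
                      vocab_range = c(300L, 300L),
                      category_concentration = conc)
    kids <- gen_children(cfg, cl)
    props <- t(vapply(kids, category_proportions, numeric(6),
                      checklist = cl))
    mean(apply(props, 2, sd))
  }
  expect_lt(spread(Inf), spread(0.5) / 2)

  # vocabulary sizes: grand mean over 100 cohorts within 2 SE of 92.1
  cfg <- sim_config(seed = 7)
  sizes <- unlist(lapply(1:100, function(r) {
    set.seed(r)
    lexigaze:::draw_vocab_sizes(79L, cfg$vocab_meanlog, cfg$vocab_sdlog,
                                cfg$vocab_range)
  }))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 92.1), 2 * se)
  expect_true(all(sizes >= 10 & sizes <= 374))
})

test_that("design: 24 counterbalanced trials per child", {
  des <- gen_design(c("c1", "c2"), seed = 1)
  one <- des[des$child_id == "c1", ]
  expect_equal(nrow(one), 24L)
  expect_equal(sum(one$condition == "related"), 12L)
  expect_equal(sum(one$condition == "unrelated"), 12L)
  for (it in experimental_items()$item) {
    as_t <- one[one$target == it, ]
    as_d <- one[one$distractor == it, ]
    expect_equal(nrow(as_t), 2L) # twice labelled as target
    expect_equal(nrow(as_d), 2L) # twice the unlabelled distractor
    expect_setequal(as_t$condition, c("related", "unrelated"))
    expect_setequal(as_d$condition, c("related", "unrelated"))
    side <- c(as_t$target_side,
              ifelse(as_d$target_side == "left", "right", "left"))
    expect_equal(sum(side == "left"), 2L) # equally often on either side
  }
  # related trials pair within category, unrelated across
  cat_of <- setNames(experimental_items()$category,
                     experimental_items()$item)
  rel <- one$condition == "related"
  expect_true(all(cat_of[one$target[rel]] == cat_of[one$distractor[rel]]))
  expect_true(all(cat_of[one$target[!rel]] != cat_of[one$distractor[!rel]]))

  # inconsistent pairing tables are rejected
  broken <- experimental_items()
  broken$related_partner[1] <- "apple"
  expect_error(gen_design("c1", items = broken), "related")
})

test_that("ratings: filter probabilities at the extremes and in between", {
  cl <- gen_checklist()
  cfg <- sim_config(seed = 13, n_children = 20)
  kids <- gen_children(cfg, cl)
  r0 <- gen_ratings(kids, config = sim_config(seed = 13, n_children = 20,
                                              p_low_rating = 0))
  expect_true(all(r0$rating >= 2))
  r1 <- gen_ratings(kids, config = sim_config(seed = 13, n_children = 20,
                                              p_low_rating = 1))
  expect_true(all(r1$rating < 2))
  # default rate scales to roughly 90 removals per 1892 trials
  cfgd <- sim_config(seed = 13, n_children = 20)
  rd <- gen_ratings(kids, config = cfgd)
  expect_lt(abs(mean(rd$rating < 2) - cfgd$p_low_rating),
            3 * sqrt(0.048 * 0.952 / nrow(rd)))
})

test_that("gaze: symmetric baseline, strong preference, heavy track loss", {
  cl <- gen_checklist()
  cfg0 <- sim_config(seed = 41, n_children = 10, beta0 = 0,
                     beta_condition = 0, beta_gcc = 0, beta_degree = 0,
                     beta_density = 0, gamma_gcc = 0, gamma_degree = 0,
                     gamma_density = 0, item_sd = 0, fussy_prob = 0)
  des <- gen_design(sprintf("c%03d", 1:10), seed = 41)
  rat <- data.frame(child_id = rep(sprintf("c%03d", 1:10), each = 12),
                    item = rep(experimental_items()$item, 10),
                    rating = 4L)
  g0 <- gen_gaze(des, rep(0, nrow(des)), rat, cfg0)
  acc0 <- trial_accuracy_table(g0)
  d <- acc0$n_target - acc0$n_distractor
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))

  # large positive baseline log-odds: target preference on nearly all trials
  g5 <- gen_gaze(des, rep(5, nrow(des)), rat, cfg0)
  acc5 <- trial_accuracy_table(g5)
  expect_gte(mean(acc5$log_gaze > 0), 0.99)

  # off-screen rate 0.9: most trials fail the 20% track-loss criterion
  cfg9 <- sim_config(seed = 41, n_children = 10, offscreen_base = 0.9,
                     fussy_prob = 0)
  g9 <- gen_gaze(des, rep(0, nrow(des)), rat, cfg9)
  acc9 <- trial_accuracy_table(g9)
  expect_gt(mean(acc9$onscreen_prop < 0.2), 0.5)
})

test_that("same seed and config reproduce a cohort exactly", {
  cfg <- sim_config(seed = 57, n_children = 6)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$design, b$design)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$metrics, b$metrics)
  expect_identical(lapply(a$gaze, `[[`, "state"),
                   lapply(b$gaze, `[[`, "state"))
  expect_identical(a$truth, b$truth)
  # and a different seed does not
  c2 <- suppressWarnings(simulate_cohort(sim_config(seed = 58,
                                                    n_children = 6)))
  expect_false(identical(lapply(a$gaze, `[[`, "state"),
                         lapply(c2$gaze, `[[`, "state")))
})

test_that("per-trial sub-streams make draws independent of trial order", {
  cfg <- sim_config(seed = 61, n_children = 2)
  des <- gen_design(c("c001", "c002"),
                    seed = substream_seed(cfg$seed, "design"))
  rat <- data.frame(child_id = rep(c("c001", "c002"), each = 12),
                    item = rep(experimental_items()$item, 2), rating = 4L)
  eta <- rep(0.5, nrow(des))
  g1 <- gen_gaze(des, eta, rat, cfg)
  rev_ord <- rev(seq_len(nrow(des)))
  g2 <- gen_gaze(des[rev_ord, ], eta[rev_ord], rat, cfg)
  expect_identical(g1[["c001_01"]]$state, g2[["c001_01"]]$state)
  expect_identical(g1[["c002_24"]]$state, g2[["c002_24"]]$state)
})

test_that("the generative truth round-trips through JSON exactly", {
  co <- suppressWarnings(simulate_cohort(sim_config(seed = 71,
                                                    n_children = 4)))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(co$truth, tmp)
  back <- read_sim_truth(tmp)
  expect_identical(back$coefficients, co$truth$coefficients)
  expect_identical(back$item_intercepts, co$truth$item_intercepts)
  expect_identical(back$eta, co$truth$eta)
  expect_identical(back$seed, co$truth$seed)
})

test_that("cohorts serialize into the pipeline's input formats", {
  co <- suppressWarnings(simulate_cohort(sim_config(seed = 77,
                                                    n_children = 4)))
  tmp <- withr::local_tempdir()
  write_cohort(co, tmp)
  cl <- read_checklist(file.path(tmp, "checklist.tsv"))
  expect_equal(nrow(cl), nrow(co$checklist))
  kids <- read_vocab_reports(file.path(tmp, "vocab_reports.tsv"), cl)
  expect_equal(length(kids), 4L)
  norms <- read_feature_norms(file.path(tmp, "feature_norms.tsv"))
  expect_equal(nrow(norms), nrow(co$norms))
  expect_true(file.exists(file.path(tmp, "trial_metadata.tsv")))
  expect_true(file.exists(file.path(tmp, "sim_truth.json")))
})
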