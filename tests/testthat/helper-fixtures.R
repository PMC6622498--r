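# Fixtures and independent oracles shared across the test files.  All data
# are built in code; nothing is read from disk.

# a small checklist with all six experimental categories plus a filler
toy_checklist <- function() {
  checklist_definition(data.frame(
    word_id = c("dog", "bird", "cat", "shoe", "hat", "sock",
                "car", "bus", "nose", "ear", "apple", "pear",
                "milk", "juice", "run", "jump"),
    category = c("ANIMALS", "ANIMALS", "ANIMALS", "CLOTHING", "CLOTHING",
                 "CLOTHING", "VEHICLES", "VEHICLES", "BODY-PARTS",
                 "BODY-PARTS", "FRUIT", "FRUIT", "DRINKS", "DRINKS",
                 "ACTION-WORDS", "ACTION-WORDS"),
    stringsAsFactors = FALSE))
}

# norms where shared-feature counts are written by hand
toy_norms <- function() {
  feature_norms(data.frame(
    concept = c(rep("dog", 4), rep("cat", 4), rep("bird", 3),
                rep("car", 3), rep("bus", 3)),
    feature = c("furry", "barks", "has_tail", "is_pet",
                "furry", "meows", "has_tail", "is_pet",
                "flies", "has_tail", "lays_eggs",
                "wheels", "metal", "drives",
                "wheels", "metal", "big"),
    feature_class = c("perceptual", "functional", "perceptual",
                      "encyclopedic",
                      "perceptual", "functional", "perceptual",
                      "encyclopedic",
                      "functional", "perceptual", "encyclopedic",
                      "perceptual", "perceptual", "functional",
                      "perceptual", "perceptual", "functional"),
    stringsAsFactors = FALSE))
}

# build a semantic_network directly from an edge list
make_net <- function(nodes, edges = NULL) {
  e <- if (is.null(edges) || length(edges) == 0L) {
    data.frame(from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  } else {
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    data.frame(from = a, to = b, stringsAsFactors = FALSE)
  }
  structure(list(nodes = sort(nodes), edges = e),
            class = "semantic_network")
}

# Erdos-Renyi random network on n nodes
rand_net <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  if (n < 2) return(make_net(nodes))
  pr <- t(combn(nodes, 2))
  keep <- runif(nrow(pr)) < p
  make_net(nodes, if (any(keep)) cbind(pr[keep, 1], pr[keep, 2]) else NULL)
}

# exhaustive triangle / connected-triple enumeration over all node triples
enum_tri_counts <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- TRUE
    A[cbind(net$edges$to, net$edges$from)] <- TRUE
  }
  tri <- 0L
  trip <- 0L
  if (n >= 3) {
    for (cmb in combn(n, 3, simplify = FALSE)) {
      e <- A[cmb[1], cmb[2]] + A[cmb[1], cmb[3]] + A[cmb[2], cmb[3]]
      if (e == 3L) {
        tri <- tri + 1L
        trip <- trip + 3L
      } else if (e == 2L) {
        trip <- trip + 1L
      }
    }
  }
  c(n_triangles = tri, n_triples = trip)
}

# independent density-rule oracle: a category is High iff fewer than three
# categories lie strictly above it
density_oracle <- function(props) {
  vapply(props, function(v) sum(props > v) < 3L, logical(1))
}

# gaze trial with prescribed state counts inside the analysis window.
# Total stream covers [0, 2000) ms at 2 ms spacing (1000 samples); the
# window [300, 2000) holds 850 samples filled with n_t TARGET, n_d
# DISTRACTOR, n_other OTHER_ONSCREEN and the rest OFFSCREEN.
make_counts_trial <- function(n_t, n_d, n_other = 850 - n_t - n_d,
                              rating = 4, condition = "related",
                              target = "dog", distractor = "bird",
                              trial_id = "t1", child_id = "c1") {
  stopifnot(n_t + n_d + n_other <= 850)
  win <- c(rep("TARGET", n_t), rep("DISTRACTOR", n_d),
           rep("OTHER_ONSCREEN", n_other),
           rep("OFFSCREEN", 850 - n_t - n_d - n_other))
  states <- c(rep("OTHER_ONSCREEN", 150), win)
  gaze_trial(trial_id, child_id, condition, target, distractor, rating,
             states)
}

# swap target and distractor labels of a trial
swap_trial <- function(trial) {
  st <- trial$state
  st[trial$state == 1L] <- 2L
  st[trial$state == 2L] <- 1L
  gaze_trial(trial$trial_id, trial$child_id, trial$condition,
             trial$distractor, trial$target, trial$rating, st,
             trial$target_side)
}

# simulate a cohort and fit the models used in recovery studies
fit_recovery_models <- function(seed, config = sim_config(seed = seed)) {
  config$seed <- as.integer(seed)
  co <- suppressWarnings(simulate_cohort(config))
  acc <- trial_accuracy_table(co$gaze)
  f <- filter_trials(acc)
  list(cohort = co, filtered = f)
}
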