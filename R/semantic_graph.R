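# Per-child lexico-semantic networks from feature norms: edge rule (>= 2
# shared perceptual/functional features), word degree, triangle/triple
# counts and the global clustering coefficient.

FEATURE_CLASSES <- c("perceptual", "functional", "taxonomic", "encyclopedic")

#' Construct a feature-norm table
#'
#' Feature norms list, for each concept, the features adults produce for it,
#' each tagged with one of four classes: perceptual, functional, taxonomic
#' or encyclopedic.  Network edges by default consider only perceptual and
#' functional features.
#'
#' @param df Data frame with columns `concept`, `feature`, `feature_class`.
#' @return The validated data frame with class `lg_feature_norms`.
#' @export
feature_norms <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("concept", "feature", "feature_class") %in% names(df)))
  df$concept <- as.character(df$concept)
  df$feature <- as.character(df$feature)
  df$feature_class <- as.character(df$feature_class)
  bad <- setdiff(unique(df$feature_class), FEATURE_CLASSES)
  if (length(bad)) abort_with_listing("unknown feature classes", bad)
  key <- paste(df$concept, df$feature)
  if (anyDuplicated(key)) {
    abort_with_listing("duplicated concept-feature entries",
                       unique(key[duplicated(key)]))
  }
  structure(df, class = c("lg_feature_norms", "data.frame"))
}

#' @export
print.lg_feature_norms <- function(x, ...) {
  cat("<feature norms> ", length(unique(x$concept)), " concepts, ",
      nrow(x), " concept-feature entries\n", sep = "")
  invisible(x)
}

#' Read feature norms from delimited text
#' @param path File with header columns `concept`, `feature`,
#'   `feature_class`.
#' @return An `lg_feature_norms`.
#' @export
read_feature_norms <- function(path) feature_norms(read_tsv(path))

#' Number of class-restricted features shared by two concepts
#'
#' @param a,b Distinct concept ids present in `norms`.
#' @param norms An `lg_feature_norms`.
#' @param classes Feature classes considered (default perceptual and
#'   functional).
#' @return Integer count of distinct shared features; symmetric in `a`, `b`.
#' @export
shared_feature_count <- function(a, b, norms,
                                 classes = c("perceptual", "functional")) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (a == b) stop("concepts must be distinct", call. = FALSE)
  missing <- setdiff(c(a, b), norms$concept)
  if (length(missing)) {
    abort_with_listing("concept(s) absent from the feature norms", missing)
  }
  keep <- norms$feature_class %in% classes
  fa <- norms$feature[keep & norms$concept == a]
  fb <- norms$feature[keep & norms$concept == b]
  length(intersect(fa, fb))
}

# Pairwise shared-feature count matrix over a set of concepts, restricted to
# the given feature classes.  Sparse incidence crossproduct; diagonal is the
# concept's own feature count and is ignored by callers.
shared_feature_matrix <- function(concepts, norms,
                                  classes = c("perceptual", "functional")) {
  concepts <- unique(as.character(concepts))
  missing <- setdiff(concepts, norms$concept)
  if (length(missing)) {
    abort_with_listing("concept(s) absent from the feature norms", missing)
  }
  sub <- norms[norms$feature_class %in% classes &
                 norms$concept %in% concepts, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(matrix(0L, length(concepts), length(concepts),
                  dimnames = list(concepts, concepts)))
  }
  ci <- factor(sub$concept, levels = concepts)
  fi <- factor(sub$feature)
  inc <- Matrix::sparseMatrix(i = as.integer(ci), j = as.integer(fi), x = 1,
                              dims = c(length(concepts), nlevels(fi)))
  S <- as.matrix(Matrix::tcrossprod(inc))
  dimnames(S) <- list(concepts, concepts)
  S
}

#' Build a child's lexico-semantic network
#'
#' Nodes are the produced nouns; an undirected edge links two nouns when
#' they share at least `threshold` features of the given classes (default:
#' at least two perceptual and/or functional features).  Isolated nouns
#' remain as nodes.
#'
#' @param produced_nouns Character vector of concept ids, all present in
#'   `norms`.
#' @param norms An `lg_feature_norms`.
#' @param threshold Minimum shared-feature count for an edge (>= 1).
#' @param classes Feature classes considered.
#' @return A list of class `semantic_network` with elements `nodes`
#'   (character) and `edges` (data frame `from`, `to`, with `from < to`).
#' @export
build_network <- function(produced_nouns, norms, threshold = 2L,
                          classes = c("perceptual", "functional")) {
  if (threshold < 1) stop("edge threshold must be at least 1", call. = FALSE)
  nodes <- sort(unique(as.character(produced_nouns)))
  S <- shared_feature_matrix(nodes, norms, classes)
  hit <- which(S >= threshold & upper.tri(S), arr.ind = TRUE)
  edges <- data.frame(from = nodes[hit[, 1L]], to = nodes[hit[, 2L]],
                      stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "semantic_network")
}

#' @export
print.semantic_network <- function(x, ...) {
  cat("<semantic network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

# dense logical adjacency matrix of a semantic_network
adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Degree of a word in a semantic network
#'
#' Number of incident edges; 0 for isolated words and for words absent from
#' the network.
#'
#' @param net A `semantic_network`.
#' @param word Concept id.
#' @return Integer degree.
#' @export
word_degree <- function(net, word) {
  if (!word %in% net$nodes) return(0L)
  sum(net$edges$from == word) + sum(net$edges$to == word)
}

#' Degrees of all nodes
#' @param net A `semantic_network`.
#' @return Named integer vector over `net$nodes`.
#' @export
degree_table <- function(net) {
  d <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes))
  setNames(as.integer(d), net$nodes)
}

# triangle / connected-triple counts from an adjacency matrix
tri_counts <- function(A) {
  if (nrow(A) < 2L) return(c(n_triangles = 0L, n_triples = 0L))
  deg <- rowSums(A)
  triples <- sum(choose(deg, 2))
  triangles <- if (nrow(A) < 3L) 0 else sum(A * (A %*% A)) / 6
  c(n_triangles = as.integer(round(triangles)),
    n_triples = as.integer(round(triples)))
}

#' Count closed triangles and connected triples
#'
#' A connected triple is a path of length two (one centre node and an
#' unordered pair of its neighbours), so the triple count is
#' `sum(choose(degree, 2))`; each triangle closes three such triples.
#'
#' @param net A `semantic_network`.
#' @return Named integer vector `n_triangles`, `n_triples`.
#' @export
count_triangles_triples <- function(net) tri_counts(adjacency_matrix(net))

#' Global clustering coefficient (transitivity)
#'
#' The fraction of connected triples that are closed into triangles,
#' `3 * triangles / triples`, ranging from 0 (no closed triples) to 1
#' (every triple closed, e.g. a complete graph).  Defined as 0 when the
#' network has no connected triples.
#'
#' @param net A `semantic_network`.
#' @return Numeric in `[0, 1]`.
#' @export
global_clustering <- function(net) {
  tc <- count_triangles_triples(net)
  if (tc[["n_triples"]] == 0L) return(0)
  3 * tc[["n_triangles"]] / tc[["n_triples"]]
}

#' Structure metrics for a cohort of children
#'
#' For each child, builds the semantic network over the produced nouns that
#' appear in the norms and computes the global clustering coefficient,
#' triangle and triple counts, and the degree of each target word.  Targets
#' the child does not produce are, by default, scored on the network
#' augmented with the target node and its qualifying edges to produced
#' nouns (`target_mode = "augmented"`); `target_mode = "zero"` scores them
#' as degree 0 instead.  Produced words missing from the norms are dropped
#' with a warning.
#'
#' @param children List of `lg_child_vocab`.
#' @param norms An `lg_feature_norms`.
#' @param targets Character vector of target word ids.
#' @param threshold Edge threshold (shared-feature count).
#' @param classes Feature classes considered for edges.
#' @param target_mode `"augmented"` or `"zero"` (see above).
#' @param nouns The noun universe: produced words outside it (for example
#'   verbs or function words) are not network nodes and are skipped
#'   silently.  Defaults to all norms concepts; when supplied explicitly,
#'   nouns missing from the norms are dropped with a warning.
#' @return List with `metrics` (data frame `child_id`, `gcc`, `n_triangles`,
#'   `n_triples`, `n_nodes`, `n_edges`) and `degrees` (data frame
#'   `child_id`, `item`, `degree`).
#' @export
structure_metrics <- function(children, norms, targets,
                              threshold = 2L,
                              classes = c("perceptual", "functional"),
                              target_mode = c("augmented", "zero"),
                              nouns = NULL) {
  target_mode <- match.arg(target_mode)
  targets <- unique(as.character(targets))
  all_produced <- unique(unlist(lapply(children, `[[`, "produced")))
  known <- unique(norms$concept)
  if (!is.null(nouns)) {
    dropped <- setdiff(intersect(all_produced, nouns), known)
    if (length(dropped)) {
      warning(length(dropped), " produced noun(s) absent from the feature ",
              "norms were dropped from the networks: ",
              paste(utils::head(dropped, 10L), collapse = ", "),
              if (length(dropped) > 10L) ", ..." else "", call. = FALSE)
    }
    known <- intersect(known, nouns)
  }
  # targets are validated against the full norms: they are scored even when
  # outside the produced-noun universe
  bad_targets <- setdiff(targets, unique(norms$concept))
  if (length(bad_targets)) {
    abort_with_listing("target word(s) absent from the feature norms",
                       bad_targets)
  }
  universe <- union(intersect(all_produced, known), targets)
  S <- shared_feature_matrix(universe, norms, classes)
  met <- vector("list", length(children))
  deg <- vector("list", length(children))
  for (k in seq_along(children)) {
    ch <- children[[k]]
    nouns <- intersect(ch$produced, known)
    A <- (S[nouns, nouns, drop = FALSE] >= threshold) * 1
    diag(A) <- 0
    tc <- tri_counts(A)
    gcc <- if (tc[["n_triples"]] == 0L) 0 else
      3 * tc[["n_triangles"]] / tc[["n_triples"]]
    met[[k]] <- data.frame(
      child_id = ch$child_id, gcc = gcc,
      n_triangles = tc[["n_triangles"]], n_triples = tc[["n_triples"]],
      n_nodes = length(nouns), n_edges = as.integer(sum(A) / 2),
      stringsAsFactors = FALSE)
    d <- vapply(targets, function(tw) {
      if (tw %in% nouns) {
        as.integer(sum(A[tw, ]))
      } else if (target_mode == "augmented") {
        others <- setdiff(nouns, tw)
        as.integer(sum(S[tw, others] >= threshold))
      } else {
        0L
      }
    }, integer(1))
    deg[[k]] <- data.frame(child_id = ch$child_id, item = targets,
                           degree = as.integer(d), stringsAsFactors = FALSE)
  }
  list(metrics = do.call(rbind, c(met, list(make.row.names = FALSE))),
       degrees = do.call(rbind, c(deg, list(make.row.names = FALSE))))
}

#' Write a network as an edge list
#' @param net A `semantic_network`.
#' @param path Output file (tab-separated `from`, `to`).
#' @return Invisibly, `path`.
#' @export
write_network_edgelist <- function(net, path) write_tsv(net$edges, path)

#' Write a network as GraphML
#' @param net A `semantic_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <graph id=\"G\" edgedefault=\"undirected\">"), con)
  writeLines(sprintf("    <node id=\"%s\"/>", esc(net$nodes)), con)
  if (nrow(net$edges)) {
    writeLines(sprintf("    <edge source=\"%s\" target=\"%s\"/>",
                       esc(net$edges$from), esc(net$edges$to)), con)
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}

#' Write cohort structure metrics as delimited text
#' @param metrics Result of [structure_metrics()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_structure_metrics <- function(metrics, dir) {
  p1 <- file.path(dir, "structure_metrics.tsv")
  p2 <- file.path(dir, "target_degrees.tsv")
  write_tsv(metrics$metrics, p1)
  write_tsv(metrics$degrees, p2)
  invisible(c(p1, p2))
}
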