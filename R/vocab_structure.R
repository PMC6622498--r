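# Vocabulary checklist parsing, category proportions, density assignment and
# the median vocabulary-group split.

#' Checklist item counts of the six experimental categories
#'
#' The six early-acquired semantic categories used in the recognition task
#' and the number of checklist items each contributes.
#'
#' @return Named integer vector of category sizes.
#' @export
#' @examples
#' cdi_category_sizes()
cdi_category_sizes <- function() {
  c(ANIMALS = 43L, CLOTHING = 28L, VEHICLES = 14L,
    `BODY-PARTS` = 27L, FRUIT = 7L, DRINKS = 7L)
}

#' The twelve experimental items and their pairings
#'
#' Two items per category, each paired once with its same-category partner
#' (related trials) and once with an item from a yoked category (unrelated
#' trials: FRUIT-DRINKS, VEHICLES-CLOTHING, BODY-PARTS-ANIMALS).
#'
#' @return Data frame with columns `item`, `category`, `related_partner`,
#'   `unrelated_partner`.
#' @export
experimental_items <- function() {
  data.frame(
    item = c("dog", "bird", "banana", "apple", "shoe", "diaper",
             "car", "airplane", "juice", "milk", "nose", "mouth"),
    category = c("ANIMALS", "ANIMALS", "FRUIT", "FRUIT", "CLOTHING",
                 "CLOTHING", "VEHICLES", "VEHICLES", "DRINKS", "DRINKS",
                 "BODY-PARTS", "BODY-PARTS"),
    related_partner = c("bird", "dog", "apple", "banana", "diaper", "shoe",
                        "airplane", "car", "milk", "juice", "mouth", "nose"),
    unrelated_partner = c("mouth", "nose", "juice", "milk", "car", "airplane",
                          "shoe", "diaper", "banana", "apple", "bird", "dog"),
    stringsAsFactors = FALSE
  )
}

#' Construct a checklist definition
#'
#' A checklist maps every word id to exactly one category.  The six
#' experimental categories must all be present with at least one item;
#' additional (filler) categories are allowed and only contribute to a
#' child's total productive count.
#'
#' @param items Data frame with columns `word_id` and `category`.
#' @param experimental Character vector of the experimental category labels.
#' @return The validated `items` data frame with class `lg_checklist` and an
#'   `"experimental"` attribute.
#' @export
checklist_definition <- function(items,
                                 experimental = names(cdi_category_sizes())) {
  stopifnot(is.data.frame(items),
            all(c("word_id", "category") %in% names(items)))
  items$word_id <- as.character(items$word_id)
  items$category <- as.character(items$category)
  if (anyDuplicated(items$word_id)) {
    abort_with_listing("checklist items assigned to more than one category",
                       unique(items$word_id[duplicated(items$word_id)]))
  }
  missing <- setdiff(experimental, items$category)
  if (length(missing)) {
    abort_with_listing("experimental categories absent from checklist", missing)
  }
  structure(items, class = c("lg_checklist", "data.frame"),
            experimental = experimental)
}

#' @export
print.lg_checklist <- function(x, ...) {
  cat("<checklist> ", nrow(x), " items, ",
      length(unique(x$category)), " categories (",
      length(attr(x, "experimental")), " experimental)\n", sep = "")
  invisible(x)
}

#' Experimental categories of a checklist
#' @param checklist An `lg_checklist`.
#' @return Character vector of category labels.
#' @export
experimental_categories <- function(checklist) attr(checklist, "experimental")

#' Read a checklist from delimited text
#'
#' @param path File with header columns `word_id`, `category`.
#' @param experimental Experimental category labels (see
#'   [checklist_definition()]).
#' @return An `lg_checklist`.
#' @export
read_checklist <- function(path,
                           experimental = names(cdi_category_sizes())) {
  checklist_definition(read_tsv(path), experimental = experimental)
}

#' Construct a child vocabulary record
#'
#' @param child_id Identifier.
#' @param produced Character vector of checklist word ids the child is
#'   reported to produce.
#' @param total_produced Total number of checklist words produced; defaults
#'   to `length(produced)`.
#' @return A list of class `lg_child_vocab`.
#' @export
child_vocabulary <- function(child_id, produced,
                             total_produced = length(unique(produced))) {
  produced <- unique(as.character(produced))
  stopifnot(length(child_id) == 1L, total_produced >= length(produced) ||
              total_produced >= 0)
  structure(list(child_id = as.character(child_id), produced = produced,
                 total_produced = as.integer(total_produced)),
            class = "lg_child_vocab")
}

#' @export
print.lg_child_vocab <- function(x, ...) {
  cat("<child ", x$child_id, "> ", x$total_produced, " words produced\n",
      sep = "")
  invisible(x)
}

#' Read long-format vocabulary reports
#'
#' @param path Delimited text with header columns `child_id`, `word_id`, one
#'   row per produced word.
#' @param checklist An `lg_checklist`; word ids outside it are rejected.
#' @return List of `lg_child_vocab`, one per child.
#' @export
read_vocab_reports <- function(path, checklist) {
  df <- read_tsv(path)
  stopifnot(all(c("child_id", "word_id") %in% names(df)))
  unknown <- setdiff(unique(df$word_id), checklist$word_id)
  if (length(unknown)) {
    abort_with_listing("vocabulary reports contain unknown word ids", unknown)
  }
  ids <- unique(df$child_id) # preserve first-appearance order
  out <- lapply(ids, function(id) {
    child_vocabulary(id, df$word_id[df$child_id == id])
  })
  names(out) <- ids
  out
}

#' Build child vocabularies from a 0/1 child-by-word matrix
#'
#' @param mat Numeric or logical matrix with child ids as row names and
#'   checklist word ids as column names; a nonzero entry marks a produced
#'   word.
#' @param checklist An `lg_checklist`; columns outside it are rejected.
#' @return List of `lg_child_vocab`, one per row.
#' @export
vocab_from_matrix <- function(mat, checklist) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  unknown <- setdiff(colnames(mat), checklist$word_id)
  if (length(unknown)) {
    abort_with_listing("matrix columns outside the checklist", unknown)
  }
  out <- lapply(rownames(mat), function(id) {
    child_vocabulary(id, colnames(mat)[mat[id, ] != 0])
  })
  names(out) <- rownames(mat)
  out
}

#' Per-category production proportions for one child
#'
#' For each experimental category, the proportion of that category produced.
#' Two normalisations are available: `"per-category-size"` (default) divides
#' the number of produced category members by the category's checklist size;
#' `"per-total-produced"` divides by the child's total productive count
#' (0 when nothing is produced).
#'
#' @param child An `lg_child_vocab`.
#' @param checklist An `lg_checklist`.
#' @param mode Normalisation mode.
#' @return Named numeric vector over the experimental categories, each value
#'   in `[0, 1]` (per-total-produced values are also bounded by 1 because
#'   produced category members count towards the total).
#' @export
#' @examples
#' cl <- checklist_definition(data.frame(
#'   word_id = c("dog", "bird", "cat", "shoe", "hat", "car", "nose", "apple",
#'               "milk"),
#'   category = c("ANIMALS", "ANIMALS", "ANIMALS", "CLOTHING", "CLOTHING",
#'                "VEHICLES", "BODY-PARTS", "FRUIT", "DRINKS")))
#' category_proportions(child_vocabulary("c1", c("dog", "bird", "shoe")), cl)
category_proportions <- function(child, checklist,
                                 mode = c("per-category-size",
                                          "per-total-produced")) {
  mode <- match.arg(mode)
  cats <- experimental_categories(checklist)
  unknown <- setdiff(child$produced, checklist$word_id)
  if (length(unknown)) {
    abort_with_listing(
      paste0("child ", child$child_id, " produces words not on the checklist"),
      unknown)
  }
  item_cat <- setNames(checklist$category, checklist$word_id)
  in_cat <- table(factor(item_cat[child$produced], levels = cats))
  if (mode == "per-category-size") {
    size <- table(factor(checklist$category, levels = cats))
    prop <- as.numeric(in_cat) / as.numeric(size)
  } else {
    prop <- if (child$total_produced == 0) rep(0, length(cats)) else
      as.numeric(in_cat) / child$total_produced
  }
  setNames(prop, cats)
}

#' Assign High/Low semantic density conditions from category proportions
#'
#' Category proportions are rank ordered from highest to lowest; the top
#' three categories are assigned to the High-density condition and the
#' bottom three to Low.  If the rank-3 and rank-4 proportions are tied, all
#' categories tied at that value are assigned High, so High may hold more
#' than three categories.  When all six proportions are equal every category
#' is High and a warning is emitted.
#'
#' @param proportions Named numeric vector over exactly six categories.
#' @return Data frame with columns `category`, `proportion`, `condition`
#'   (`"High"`/`"Low"`).
#' @export
#' @examples
#' assign_density(c(ANIMALS = .9, CLOTHING = .8, VEHICLES = .5,
#'                  `BODY-PARTS` = .5, FRUIT = .3, DRINKS = .1))
assign_density <- function(proportions) {
  stopifnot(is.numeric(proportions), length(proportions) == 6L,
            !is.null(names(proportions)), !anyNA(proportions))
  # stable ordering: descending proportion, ties broken by category name so
  # runs are deterministic
  ord <- order(-proportions, names(proportions))
  v <- proportions[ord]
  if (v[3L] == v[4L]) {
    high <- proportions >= v[3L]
    if (all(high)) {
      warning("all six category proportions are equal; ",
              "assigning every category to the High condition",
              call. = FALSE)
    }
  } else {
    high <- logical(6L)
    high[ord[1:3]] <- TRUE
  }
  data.frame(category = names(proportions),
             proportion = as.numeric(proportions),
             condition = ifelse(high, "High", "Low"),
             stringsAsFactors = FALSE)
}

#' Density assignments for a cohort of children
#'
#' @param children List of `lg_child_vocab`.
#' @param checklist An `lg_checklist`.
#' @param mode Normalisation mode passed to [category_proportions()].
#' @return Data frame with columns `child_id`, `category`, `proportion`,
#'   `condition`.
#' @export
density_assignments <- function(children, checklist,
                                mode = "per-category-size") {
  out <- lapply(children, function(ch) {
    a <- assign_density(category_proportions(ch, checklist, mode))
    cbind(child_id = ch$child_id, a, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Median split of productive vocabulary size
#'
#' Children whose total productive count is greater than or equal to the
#' sample median are assigned to the High vocabulary group, the rest to Low.
#'
#' @param children List of `lg_child_vocab` (at least two), or a data frame
#'   with columns `child_id` and `total_produced`.
#' @return Data frame with columns `child_id`, `total_produced`, `group`;
#'   the median is stored in attribute `"split_value"`.
#' @export
#' @examples
#' kids <- list(child_vocabulary("a", letters[1:5], 10),
#'              child_vocabulary("b", letters[1:5], 61),
#'              child_vocabulary("c", letters[1:5], 374))
#' split_vocab_groups(kids)
split_vocab_groups <- function(children) {
  if (is.data.frame(children)) {
    df <- children[, c("child_id", "total_produced")]
  } else {
    if (length(children) < 2L) {
      stop("need at least two children for a median split", call. = FALSE)
    }
    df <- data.frame(
      child_id = vapply(children, function(x) x$child_id, character(1)),
      total_produced = vapply(children, function(x) x$total_produced,
                              integer(1)),
      stringsAsFactors = FALSE)
  }
  if (nrow(df) < 2L) {
    stop("need at least two children for a median split", call. = FALSE)
  }
  grp <- median_split(df$total_produced)
  if (all(grp == "High")) {
    warning("all children fall in the High vocabulary group ",
            "(degenerate split)", call. = FALSE)
  }
  df$group <- as.character(grp)
  attr(df, "split_value") <- attr(grp, "split_value")
  rownames(df) <- NULL
  df
}

#' Write density and group assignments as delimited text
#'
#' @param density Data frame from [density_assignments()].
#' @param groups Data frame from [split_vocab_groups()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_assignments <- function(density, groups, dir) {
  p1 <- file.path(dir, "density_assignments.tsv")
  p2 <- file.path(dir, "vocab_groups.tsv")
  write_tsv(density, p1)
  write_tsv(groups, p2)
  invisible(c(p1, p2))
}
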