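#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed and a character key (for example a trial id or stage
#' name) to a deterministic integer seed below 2^31, so that each simulated
#' unit draws from its own stream and the order of generation never changes
#' the numbers drawn.
#'
#' @param seed Integer master seed.
#' @param key Character scalar naming the sub-stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' substream_seed(1, "c01_03")
substream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  codes <- utf8ToInt(as.character(key))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((as.double(seed) * 48271 + h * 16807 + 1) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median split of a numeric vector
#'
#' Values greater than or equal to the sample median are labelled `"High"`,
#' the rest `"Low"`; the same convention used for the vocabulary-group split.
#'
#' @param x Numeric vector.
#' @param labels Length-2 character vector, labels for the upper and lower
#'   half respectively.
#' @return Character vector of labels, with the median stored in attribute
#'   `"split_value"`.
#' @export
median_split <- function(x, labels = c("High", "Low")) {
  stopifnot(is.numeric(x), length(labels) == 2L)
  m <- stats::median(x)
  out <- ifelse(x >= m, labels[1L], labels[2L])
  attr(out, "split_value") <- m
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

abort_with_listing <- function(msg, offenders) {
  stop(msg, ": ", paste(offenders, collapse = ", "), call. = FALSE)
}
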