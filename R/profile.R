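#' Binarize a group vocabulary into a term-by-name 0/1 matrix
#'
#' Frequencies are converted to presence/absence: a cell is 1 exactly when
#' the name's document frequency for the term is nonzero. No further
#' thresholding is applied.
#'
#' @param vocabulary A `group_vocabulary` (from [select_group_vocabulary()]).
#' @return An integer matrix (terms x names) of 0/1 values with the
#'   vocabulary's row and column order.
#' @export
binarize <- function(vocabulary) {
  if (is.null(vocabulary) || length(vocabulary$terms) == 0L) {
    stop("cannot binarize an empty vocabulary; the group should have been ",
         "excluded as empty_vocabulary", call. = FALSE)
  }
  m <- (vocabulary$freq > 0) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Pairwise presence counts between two binary profiles
#'
#' @param a,b Binary vectors (0/1) of equal length.
#' @return List with `n11` (terms present in both), `n10` (present in `a`
#'   only), `n01` (present in `b` only).
#' @export
pairwise_counts <- function(a, b) {
  if (length(a) != length(b)) {
    stop("binary vectors must have equal length", call. = FALSE)
  }
  a <- a != 0
  b <- b != 0
  list(n11 = sum(a & b), n10 = sum(a & !b), n01 = sum(!a & b))
}

#' Jaccard distance between two binary term profiles
#'
#' `1 - n11 / (n11 + n01 + n10)`: 0 for a perfect match, 1 for no shared
#' term. When both profiles are all-zero the denominator vanishes; the
#' distance is then defined as 1 (no shared vocabulary evidence). In
#' practice that case does not arise because names with empty vocabularies
#' are excluded upstream.
#'
#' @param a,b Binary vectors (0/1) of equal length.
#' @return Distance in \[0, 1\].
#' @examples
#' jaccard_distance(c(1, 1, 0, 1), c(1, 0, 1, 1))  # 0.5
#' @export
jaccard_distance <- function(a, b) {
  cnt <- pairwise_counts(a, b)
  denom <- cnt$n11 + cnt$n01 + cnt$n10
  if (denom == 0L) return(1)
  1 - cnt$n11 / denom
}

#' Classify aliases from precomputed distances
#'
#' The classification rule of the method, separated from profile
#' construction so that worked examples with known distances can be scored
#' directly. The threshold is the smallest official-to-control distance; an
#' alias is `ambiguous` when its distance to the official symbol is greater
#' than or equal to the threshold, otherwise `synonym`. With
#' `strict = TRUE` the alias must instead be at least as far as *every*
#' control (threshold = max), a stricter call useful for sensitivity
#' analyses.
#'
#' @param alias_distances Named numeric vector: distance from each alias to
#'   the official symbol.
#' @param control_distances Numeric vector: distances from the official
#'   symbol to each internal control (>= 1 value).
#' @param strict Use the maximum control distance as threshold
#'   (default `FALSE`: minimum).
#' @return data.frame with columns `alias`, `distance`, `threshold`,
#'   `label`.
#' @export
classify_distances <- function(alias_distances, control_distances,
                               strict = FALSE) {
  if (length(control_distances) < 1L) {
    stop("at least one control distance is required", call. = FALSE)
  }
  threshold <- if (strict) max(control_distances) else min(control_distances)
  data.frame(
    alias = if (is.null(names(alias_distances))) {
      as.character(seq_along(alias_distances))
    } else {
      names(alias_distances)
    },
    distance = unname(alias_distances),
    threshold = threshold,
    label = ifelse(alias_distances >= threshold, "ambiguous", "synonym"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Classify the aliases of a group against its internal controls
#'
#' Computes the Jaccard distance from the official symbol's binary profile
#' to each alias and each internal control, sets the threshold at the
#' smallest official-to-control distance, and labels each alias `ambiguous`
#' when its distance is at or above the threshold, else `synonym`. Aliases
#' and controls with empty collections are not scored (aliases are reported
#' with label `unscored`); a group whose controls all have empty collections
#' cannot be classified.
#'
#' @param matrix Binary term-by-name matrix from [binarize()]; columns must
#'   cover the group's official symbol and its nonempty aliases/controls.
#' @param group The `name_group` the matrix was built from.
#' @param strict Passed to [classify_distances()].
#' @return A `classification_result`: data.frame with columns `group_id`,
#'   `alias`, `n_abstracts`, `distance`, `threshold`, `label`, with the
#'   control distances in attribute `"control_distances"`.
#' @export
classify_group <- function(matrix, group, strict = FALSE) {
  stopifnot(inherits(group, "name_group"))
  official <- group$official$name
  if (!(official %in% colnames(matrix))) {
    stop("matrix does not contain the official symbol '", official, "'",
         call. = FALSE)
  }
  off_vec <- matrix[, official]
  ctrl_names <- vapply(group$controls, `[[`, character(1L), "name")
  ctrl_names <- ctrl_names[ctrl_names %in% colnames(matrix)]
  if (length(ctrl_names) == 0L) {
    stop("group '", group$group_id,
         "' has no control with a nonempty corpus; not classifiable",
         call. = FALSE)
  }
  ctrl_dist <- vapply(ctrl_names,
                      function(nm) jaccard_distance(off_vec, matrix[, nm]),
                      numeric(1L))
  alias_names <- vapply(group$aliases, `[[`, character(1L), "name")
  alias_n <- vapply(group$aliases, `[[`, 0L, "n")
  scored <- alias_names %in% colnames(matrix) & alias_n >= 1L
  dist <- rep(NA_real_, length(alias_names))
  dist[scored] <- vapply(alias_names[scored],
                         function(nm) jaccard_distance(off_vec, matrix[, nm]),
                         numeric(1L))
  threshold <- if (strict) max(ctrl_dist) else min(ctrl_dist)
  label <- ifelse(!scored, "unscored",
                  ifelse(dist >= threshold, "ambiguous", "synonym"))
  res <- data.frame(group_id = group$group_id,
                    alias = alias_names,
                    n_abstracts = alias_n,
                    distance = dist,
                    threshold = threshold,
                    label = label,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "control_distances") <- ctrl_dist
  class(res) <- c("classification_result", "data.frame")
  res
}

#' @export
print.classification_result <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$distance <- round(y$distance, 3)   # display rounding only
  y$threshold <- round(y$threshold, 3)
  print(y, ...)
  invisible(x)
}

#' Export a binary term matrix as TSV
#'
#' @param matrix Binary matrix from [binarize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_matrix <- function(matrix, path) {
  df <- data.frame(term = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
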