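#' Redundancy of a text corpus
#'
#' Percentage of duplicate retrievals relative to the number of unique
#' documents: `100 * (total - unique) / unique`. Duplicates arise when the
#' same abstract is retrieved with several names (typically synonyms of one
#' gene, occasionally different genes discussed together).
#'
#' @param total_abstracts Total number of retrieved abstracts (with
#'   repetitions).
#' @param unique_ids Number of distinct document ids.
#' @return Redundancy in percent.
#' @examples
#' redundancy(13355, 11022)  # ~21
#' @export
redundancy <- function(total_abstracts, unique_ids) {
  if (any(unique_ids < 1)) {
    stop("unique_ids must be >= 1", call. = FALSE)
  }
  if (any(unique_ids > total_abstracts)) {
    stop("unique_ids cannot exceed total_abstracts", call. = FALSE)
  }
  100 * (total_abstracts - unique_ids) / unique_ids
}

#' Fold increase in unique documents retrieved
#'
#' Ratio of the unique documents obtained by querying with the official
#' symbol plus its synonyms over those obtained with the official symbol
#' alone.
#'
#' @param unique_combined Unique documents for official symbol + synonyms.
#' @param official_only Unique documents for the official symbol alone.
#' @return The fold increase (ratio).
#' @examples
#' fold_increase(7523, 2099)  # ~3.6
#' @export
fold_increase <- function(unique_combined, official_only) {
  if (any(official_only < 1)) {
    stop("official_only must be >= 1", call. = FALSE)
  }
  unique_combined / official_only
}

#' Does the official symbol occur in an alias's abstract collection?
#'
#' Coherence check of the classification: synonyms' literature often
#' mentions the official symbol, whereas truly ambiguous aliases' literature
#' essentially never does. The match is case-insensitive on whole tokens
#' (alphanumeric runs, with no minimum length since gene symbols may be
#' short); the symbol itself is tokenized the same way, so a multi-word
#' symbol matches a consecutive token run.
#'
#' @param alias_collection An `abstract_collection`.
#' @param official_symbol The official gene symbol to look for.
#' @return `TRUE` iff the symbol occurs in at least one document.
#' @export
official_occurrence <- function(alias_collection, official_symbol) {
  stopifnot(inherits(alias_collection, "abstract_collection"))
  if (alias_collection$n == 0L) return(FALSE)
  sym <- tokenize_all(official_symbol)
  if (length(sym) == 0L) return(FALSE)
  for (txt in alias_collection$text) {
    toks <- tokenize_all(txt)
    if (contains_run(toks, sym)) return(TRUE)
  }
  FALSE
}

# Tokenization without the 3-character minimum or numeric exclusion:
# used for symbol matching where short tokens ("D5D" -> d5d) matter.
tokenize_all <- function(text) {
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")),
                          "[^a-z0-9]+"), use.names = FALSE)
  toks[nzchar(toks)]
}

contains_run <- function(haystack, needle) {
  nh <- length(haystack)
  nn <- length(needle)
  if (nn == 0L || nh < nn) return(FALSE)
  if (nn == 1L) return(needle %in% haystack)
  starts <- which(haystack == needle[1L])
  starts <- starts[starts <= nh - nn + 1L]
  for (s in starts) {
    if (all(haystack[s:(s + nn - 1L)] == needle)) return(TRUE)
  }
  FALSE
}

#' Occurrence report over classified aliases
#'
#' For each scored alias, flags whether its collection mentions the group's
#' official symbol, and aggregates the fraction of mentioning collections
#' separately for synonym-labelled and ambiguous-labelled aliases.
#'
#' @param results A `classification_result` data.frame (possibly row-bound
#'   over groups).
#' @param collections Named list of `abstract_collection` by name.
#' @param officials Named character vector group_id -> official symbol.
#' @return List with `per_alias` (data.frame: group_id, alias, label,
#'   mentions_official) and `aggregate` (data.frame: label, n, n_mentioning,
#'   fraction).
#' @export
occurrence_report <- function(results, collections, officials) {
  scored <- results[results$label %in% c("synonym", "ambiguous"), ,
                    drop = FALSE]
  flags <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    coll <- collections[[scored$alias[i]]]
    if (is.null(coll)) coll <- abstract_collection(scored$alias[i])
    flags[i] <- official_occurrence(coll, officials[[scored$group_id[i]]])
  }
  per_alias <- data.frame(group_id = scored$group_id, alias = scored$alias,
                          label = scored$label, mentions_official = flags,
                          stringsAsFactors = FALSE, row.names = NULL)
  agg <- do.call(rbind, lapply(c("synonym", "ambiguous"), function(lb) {
    sub <- per_alias[per_alias$label == lb, , drop = FALSE]
    data.frame(label = lb, n = nrow(sub),
               n_mentioning = sum(sub$mentions_official),
               fraction = if (nrow(sub) > 0) mean(sub$mentions_official)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_alias = per_alias, aggregate = agg)
}

#' Set statistics over document-id lists
#'
#' Exact union size and pairwise intersections of the document ids of
#' several collections — the bookkeeping behind case-study statements such
#' as "only one abstract was indexed to both names".
#'
#' @param collections List of `abstract_collection` (or a named list of
#'   character PMID vectors).
#' @return List with `union_size`, `sizes` (named per-collection unique
#'   counts), `pairwise` (data.frame: name_a, name_b, intersection_size)
#'   and `pairwise_ids` (list of the intersecting ids, named "a|b").
#' @export
pmid_set_stats <- function(collections) {
  ids <- lapply(collections, function(x) {
    if (inherits(x, "abstract_collection")) unique(x$doc_id)
    else unique(as.character(x))
  })
  nms <- names(ids)
  if (is.null(nms)) {
    nms <- vapply(collections, function(x) {
      if (inherits(x, "abstract_collection")) x$name else ""
    }, character(1L))
  }
  names(ids) <- nms
  pairs <- if (length(ids) >= 2L) utils::combn(seq_along(ids), 2L) else
    matrix(integer(), nrow = 2L)
  inter_ids <- list()
  pw <- data.frame(name_a = character(), name_b = character(),
                   intersection_size = integer(), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    common <- intersect(ids[[a]], ids[[b]])
    pw <- rbind(pw, data.frame(name_a = nms[a], name_b = nms[b],
                               intersection_size = length(common),
                               stringsAsFactors = FALSE))
    inter_ids[[paste(nms[a], nms[b], sep = "|")]] <- common
  }
  list(union_size = length(unique(unlist(ids, use.names = FALSE))),
       sizes = vapply(ids, length, integer(1L)),
       pairwise = pw,
       pairwise_ids = inter_ids)
}

#' Summarize a corpus the way the dataset tables report it
#'
#' @param collections Named list of `abstract_collection`.
#' @param terminology Optional `terminology` to split counts into officials
#'   and aliases.
#' @return A `corpus_summary` list: `n_official_symbols`, `n_aliases`,
#'   `total_abstracts`, `unique_ids`, `redundancy_pct`.
#' @export
corpus_summary <- function(collections, terminology = NULL) {
  nonempty <- collections[vapply(collections, `[[`, 0L, "n") >= 1L]
  total <- sum(vapply(nonempty, `[[`, 0L, "n"))
  uniq <- length(unique(unlist(lapply(nonempty, `[[`, "doc_id"),
                               use.names = FALSE)))
  n_off <- n_ali <- NA_integer_
  if (!is.null(terminology)) {
    off <- official_symbols(terminology)
    n_off <- sum(names(nonempty) %in% off)
    n_ali <- sum(names(nonempty) %in%
                   terminology$name[terminology$role == "alias"])
  }
  structure(list(n_official_symbols = n_off, n_aliases = n_ali,
                 total_abstracts = total, unique_ids = uniq,
                 redundancy_pct = if (uniq > 0) redundancy(total, uniq)
                                  else NA_real_),
            class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat("<corpus_summary>\n",
      "  official symbols with abstracts: ", x$n_official_symbols, "\n",
      "  aliases with abstracts:          ", x$n_aliases, "\n",
      "  abstracts in text corpus:        ", x$total_abstracts, "\n",
      "  unique document ids:             ", x$unique_ids, "\n",
      "  redundancy (%):                  ",
      round(x$redundancy_pct, 1), "\n", sep = "")
  invisible(x)
}

#' Compare vocabulary sizes across baseline-stringency levels
#'
#' Kruskal-Wallis rank test across the groups defined by the baseline
#' cut-off `c`, followed by Dunn's multiple-comparison post test with the
#' summed-probability (Bonferroni) adjustment. If every observation is
#' identical the test is degenerate and p = 1 is reported with a warning.
#'
#' @param sizes_by_c Named list: one numeric vector of per-group vocabulary
#'   sizes for each `c` level.
#' @return List with `kw_statistic`, `kw_p_value`, `dunn` (data.frame:
#'   level_a, level_b, z, p_value (adjusted, capped at 1)).
#' @export
vocab_size_comparison <- function(sizes_by_c) {
  if (length(sizes_by_c) < 2L) {
    stop("at least two stringency levels are required", call. = FALSE)
  }
  if (any(vapply(sizes_by_c, length, 0L) < 2L)) {
    stop("each level needs at least two observations", call. = FALSE)
  }
  x <- unlist(sizes_by_c, use.names = FALSE)
  g <- factor(rep(names(sizes_by_c), vapply(sizes_by_c, length, 0L)),
              levels = names(sizes_by_c))
  if (length(unique(x)) == 1L) {
    warning("all observations identical; Kruskal-Wallis test is degenerate",
            call. = FALSE)
    lev <- levels(g)
    pairs <- utils::combn(lev, 2L)
    return(list(kw_statistic = 0, kw_p_value = 1,
                dunn = data.frame(level_a = pairs[1L, ], level_b = pairs[2L, ],
                                  z = 0, p_value = 1,
                                  stringsAsFactors = FALSE)))
  }
  kw <- stats::kruskal.test(x, g)
  list(kw_statistic = unname(kw$statistic),
       kw_p_value = kw$p.value,
       dunn = dunn_test(x, g))
}

#' Dunn's multiple-comparison post test
#'
#' Pairwise z statistics on mean ranks with the tie correction, adjusted by
#' the Bonferroni bound (each p multiplied by the number of comparisons and
#' capped at 1) — the "summed probabilities" rule.
#'
#' @param x Numeric observations.
#' @param g Grouping factor, same length.
#' @return data.frame with `level_a`, `level_b`, `z`, `p_value` (adjusted).
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x)
  mean_r <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  n_comp <- ncol(pairs)
  out <- data.frame(level_a = pairs[1L, ], level_b = pairs[2L, ],
                    z = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_comp)) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z <- (mean_r[[a]] - mean_r[[b]]) / se
    out$z[j] <- z
    out$p_value[j] <- min(1, 2 * stats::pnorm(-abs(z)) * n_comp)
  }
  out
}
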