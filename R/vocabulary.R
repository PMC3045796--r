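#' Filter parameters for vocabulary selection
#'
#' Bundles the tunable constants of the two vocabulary filters. `c` is the
#' baseline cut-off: any term whose document frequency in the baseline
#' collection is at or above `c` is dropped as ubiquitous. The difference
#' filter retains a term only when, for at least one name in the group, its
#' collection frequency exceeds its baseline frequency by at least
#' `t + k / max(n, n_floor)` where `n` is that name's abstract count; the
#' `n_floor` clamp keeps the cut-off from exploding for names with very few
#' abstracts.
#'
#' @param c Baseline cut-off fraction in (0, 1]; default 0.05.
#' @param t Minimum threshold of the difference cut-off; default 0.15.
#' @param k Constant of the difference cut-off; default 1.5.
#' @param n_floor Lower clamp on the abstract count n; default 5.
#' @return A `filter_params` list.
#' @export
filter_params <- function(c = 0.05, t = 0.15, k = 1.5, n_floor = 5L) {
  if (!(c > 0 && c <= 1)) stop("c must be in (0, 1]", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (n_floor < 1L) stop("n_floor must be >= 1", call. = FALSE)
  structure(list(c = c, t = t, k = k, n_floor = as.integer(n_floor)),
            class = "filter_params")
}

#' Document-frequency vector of a collection
#'
#' For each canonical term, the fraction of the collection's documents that
#' contain the term at least once (document-level presence, not token
#' counts). Terms with zero frequency are absent from the result.
#'
#' @param collection An `abstract_collection` with `n >= 1`.
#' @return A `term_frequencies` object: list with `name`, `freqs` (named
#'   numeric vector in (0, 1]), and `n`.
#' @export
term_frequencies <- function(collection) {
  stopifnot(inherits(collection, "abstract_collection"))
  if (collection$n < 1L) {
    stop("cannot compute frequencies of an empty collection ('",
         collection$name, "')", call. = FALSE)
  }
  per_doc <- lapply(collection$text, document_terms)
  counts <- table(unlist(per_doc, use.names = FALSE))
  freqs <- as.numeric(counts) / collection$n
  names(freqs) <- names(counts)
  freqs <- freqs[order(names(freqs))]
  structure(list(name = collection$name, freqs = freqs, n = collection$n),
            class = "term_frequencies")
}

#' Baseline term frequencies from a background abstract collection
#'
#' The baseline collection plays the role of "general literature": terms
#' frequent in it are ubiquitous and carry no gene-specific signal. Its
#' document frequencies feed both vocabulary filters. Terms never seen in
#' the baseline have frequency 0.
#'
#' @param collection An `abstract_collection` of background abstracts.
#' @return A `baseline_frequencies` object: list with `freqs` (named numeric
#'   vector) and `n_docs`.
#' @export
baseline_frequencies <- function(collection) {
  tf <- term_frequencies(collection)
  structure(list(freqs = tf$freqs, n_docs = tf$n),
            class = "baseline_frequencies")
}

# Baseline frequency of arbitrary terms, 0 when unseen.
baseline_freq_of <- function(baseline, terms) {
  f <- baseline$freqs[terms]
  f[is.na(f)] <- 0
  unname(f)
}

#' Cache baseline frequencies to / from a TSV file
#'
#' Two tab-separated columns (term, frequency) preceded by a comment header
#' recording the number of baseline documents.
#'
#' @param baseline A `baseline_frequencies` object.
#' @param path File path.
#' @return `write_baseline`: `path` invisibly. `read_baseline`: a
#'   `baseline_frequencies` object.
#' @export
write_baseline <- function(baseline, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_docs=%d", baseline$n_docs), con)
  writeLines(paste(names(baseline$freqs),
                   format(baseline$freqs, digits = 17, scientific = FALSE,
                          trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_docs <- 0L
  hdr <- grepl("^#", lines)
  m <- regmatches(lines[hdr], regexpr("n_docs=[0-9]+", lines[hdr]))
  if (length(m) > 0L) n_docs <- as.integer(sub("n_docs=", "", m[1L]))
  lines <- lines[!hdr & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  freqs <- as.numeric(vapply(parts, `[[`, character(1L), 2L))
  names(freqs) <- vapply(parts, `[[`, character(1L), 1L)
  structure(list(freqs = freqs, n_docs = n_docs),
            class = "baseline_frequencies")
}

#' Corpus-size-adjusted difference cut-off
#'
#' `t + k / max(n, n_floor)`: the minimum excess of a term's collection
#' frequency over its baseline frequency required for retention. The
#' dependence on `n` partially compensates for the unequal number of
#' abstracts retrieved per name; `n` is clamped below at `n_floor` so names
#' with five or fewer abstracts all use n = 5 (with the defaults,
#' `t = 0.15`, `k = 1.5`, the cut-off is then 0.45).
#'
#' @param n Abstract count of the name.
#' @param params A `filter_params` object.
#' @return The cut-off fraction.
#' @examples
#' dynamic_cutoff(100)  # 0.165
#' dynamic_cutoff(3)    # clamped: 0.45
#' @export
dynamic_cutoff <- function(n, params = filter_params()) {
  if (any(n < 0)) stop("n must be >= 0", call. = FALSE)
  params$t + params$k / pmax(n, params$n_floor)
}

#' Baseline (ubiquity) filter
#'
#' Removes every term whose baseline document frequency is greater than or
#' equal to `c`; such terms are broadly spread in the unspecific literature
#' and cannot discriminate a gene. Terms absent from the baseline have
#' frequency 0 and always pass. The comparison operator is configurable via
#' `inclusive` (`TRUE`, the default, excludes at frequency exactly `c`).
#'
#' @param group_terms Character vector of candidate terms.
#' @param baseline A `baseline_frequencies` object.
#' @param c Baseline cut-off fraction.
#' @param inclusive Exclude terms at exactly `c` (default `TRUE`).
#' @return The retained terms, original order preserved.
#' @export
apply_baseline_filter <- function(group_terms, baseline, c = 0.05,
                                  inclusive = TRUE) {
  f <- baseline_freq_of(baseline, group_terms)
  if (inclusive) group_terms[f < c] else group_terms[f <= c]
}

#' Select the group-specific informative vocabulary
#'
#' Pools the canonical terms of every collection in the group (official
#' symbol, aliases and internal controls), removes ubiquitous terms with the
#' baseline filter, and then retains a term only if for at least one name in
#' the group its document frequency exceeds its baseline frequency by at
#' least that name's difference cut-off (see [dynamic_cutoff()]). Names with
#' empty collections contribute nothing and are skipped. The returned term
#' list is sorted lexicographically (byte order, `C` collation) so the
#' vocabulary is deterministic.
#'
#' @param group A `name_group`.
#' @param baseline A `baseline_frequencies` object.
#' @param params A `filter_params` object.
#' @return A `group_vocabulary` object: list with `group_id`, `terms`,
#'   `freq` (term x name matrix of document frequencies over retained
#'   terms), and `n` (named abstract counts per name). Returns `NULL` if no
#'   term survives both filters (the group is then excluded with reason
#'   `empty_vocabulary`).
#' @export
select_group_vocabulary <- function(group, baseline, params = filter_params()) {
  stopifnot(inherits(group, "name_group"))
  colls <- group_collections(group)
  colls <- colls[vapply(colls, `[[`, 0L, "n") >= 1L]
  if (length(colls) == 0L) return(NULL)
  tfs <- lapply(colls, term_frequencies)
  pooled <- sort_c(unique(unlist(lapply(tfs, function(tf) names(tf$freqs)),
                                 use.names = FALSE)))
  candidates <- apply_baseline_filter(pooled, baseline, params$c)
  if (length(candidates) == 0L) return(NULL)
  base_f <- baseline_freq_of(baseline, candidates)
  keep <- rep(FALSE, length(candidates))
  for (tf in tfs) {
    f <- tf$freqs[candidates]
    f[is.na(f)] <- 0
    keep <- keep | (unname(f) - base_f >= dynamic_cutoff(tf$n, params))
  }
  terms <- candidates[keep]
  if (length(terms) == 0L) return(NULL)
  freq <- vapply(tfs, function(tf) {
    f <- tf$freqs[terms]
    f[is.na(f)] <- 0
    unname(f)
  }, numeric(length(terms)))
  freq <- matrix(freq, nrow = length(terms),
                 dimnames = list(terms, names(tfs)))
  structure(list(group_id = group$group_id, terms = terms, freq = freq,
                 n = vapply(tfs, `[[`, 0L, "n")),
            class = "group_vocabulary")
}

#' @export
print.group_vocabulary <- function(x, ...) {
  cat("<group_vocabulary> '", x$group_id, "': ", length(x$terms),
      " term(s) x ", ncol(x$freq), " name(s)\n", sep = "")
  invisible(x)
}

# Locale-independent lexicographic sort.
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old))
  Sys.setlocale("LC_COLLATE", "C")
  sort(x)
}
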