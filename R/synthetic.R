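#' Parameters for the synthetic corpus generator
#'
#' The generator emulates the corpus structure the method assumes: names that
#' are true synonyms of a gene share a planted topic vocabulary over a common
#' Zipfian background, while ambiguous aliases draw their topic tokens from a
#' different, unrelated gene. Each gene receives a topic vocabulary disjoint
#' from every other gene's; each abstract is a bag of tokens where every
#' token comes from the name's topic with probability `topic_weight` and from
#' the shared background otherwise.
#'
#' Defaults: 10 groups of 3 aliases with one third planted ambiguous, 30
#' abstracts per name of 80 tokens each, a half/half topic-background mix,
#' 40-term topics over a 2000-term background with Zipf exponent 1.05, and a
#' 500-document baseline corpus drawn from the background alone.
#'
#' @param n_groups Number of gene groups.
#' @param aliases_per_group Aliases per gene.
#' @param ambiguous_fraction Fraction of aliases planted as ambiguous;
#'   `ambiguous_fraction * aliases_per_group` must be an integer.
#' @param docs_per_name Abstracts generated per name.
#' @param doc_length Tokens per abstract.
#' @param topic_vocab_size Terms in each gene's topic vocabulary.
#' @param background_vocab_size Terms in the shared background vocabulary.
#' @param topic_weight Probability a token is drawn from the name's topic
#'   rather than the background, in \[0, 1\].
#' @param background_zipf_exponent Zipf exponent of the background term
#'   distribution (larger = heavier head).
#' @param n_baseline_docs Documents in the background-only baseline corpus.
#' @param ambiguous_mode `"borrow"` (default): planted-ambiguous aliases use
#'   another randomly chosen gene's topic — the hard confusion mode of a
#'   symbol that means a different gene; `"background"`: pure background.
#' @param inject_plurals Probability of rendering a topic token with a
#'   trailing "s", to exercise inflection merging (default 0).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_groups = 10L,
                             aliases_per_group = 3L,
                             ambiguous_fraction = 1 / 3,
                             docs_per_name = 30L,
                             doc_length = 80L,
                             topic_vocab_size = 40L,
                             background_vocab_size = 2000L,
                             topic_weight = 0.5,
                             background_zipf_exponent = 1.05,
                             n_baseline_docs = 500L,
                             ambiguous_mode = c("borrow", "background"),
                             inject_plurals = 0,
                             seed = 1L) {
  ambiguous_mode <- match.arg(ambiguous_mode)
  if (n_groups < 2L) stop("n_groups must be >= 2", call. = FALSE)
  if (aliases_per_group < 1L) stop("aliases_per_group must be >= 1", call. = FALSE)
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("ambiguous_fraction must be in [0, 1]", call. = FALSE)
  }
  n_amb <- ambiguous_fraction * aliases_per_group
  if (abs(n_amb - round(n_amb)) > 1e-9) {
    stop("ambiguous_fraction * aliases_per_group must be an integer",
         call. = FALSE)
  }
  if (topic_vocab_size < 1L || background_vocab_size < 1L) {
    stop("vocabulary sizes must be >= 1", call. = FALSE)
  }
  if (topic_weight < 0 || topic_weight > 1) {
    stop("topic_weight must be in [0, 1]", call. = FALSE)
  }
  if (background_zipf_exponent <= 0) {
    stop("background_zipf_exponent must be > 0", call. = FALSE)
  }
  structure(list(n_groups = as.integer(n_groups),
                 aliases_per_group = as.integer(aliases_per_group),
                 ambiguous_fraction = ambiguous_fraction,
                 docs_per_name = as.integer(docs_per_name),
                 doc_length = as.integer(doc_length),
                 topic_vocab_size = as.integer(topic_vocab_size),
                 background_vocab_size = as.integer(background_vocab_size),
                 topic_weight = topic_weight,
                 background_zipf_exponent = background_zipf_exponent,
                 n_baseline_docs = as.integer(n_baseline_docs),
                 ambiguous_mode = ambiguous_mode,
                 inject_plurals = inject_plurals,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# Topic vocabularies are disjoint by construction: term strings embed the
# gene index. All tokens are >= 3 alphanumeric characters with digits, so
# they survive tokenization unchanged and are fixed points of singularize().
topic_terms <- function(gene_idx, size) {
  sprintf("g%02dtopic%03d", gene_idx, seq_len(size))
}

background_terms <- function(size) {
  sprintf("bgword%04d", seq_len(size))
}

zipf_probs <- function(size, exponent) {
  w <- seq_len(size)^(-exponent)
  w / sum(w)
}

#' Generate a synthetic corpus with planted alias labels
#'
#' Produces a terminology (one official symbol and `aliases_per_group`
#' aliases per gene), one abstract collection per name, and the planted
#' truth. The official symbol and planted synonyms of a gene draw their
#' topic tokens from the gene's own topic vocabulary; planted-ambiguous
#' aliases draw from another randomly chosen gene's topic (or pure
#' background, see `ambiguous_mode`). Document ids are increasing integers,
#' so they double as recency keys. Abstracts are rendered as space-joined
#' tokens and round-trip exactly through the tokenizer.
#'
#' @param params A `generator_params` object.
#' @return List with `terminology` (a `terminology`), `collections` (named
#'   list of `abstract_collection`), and `truth` (data.frame: `group_id`,
#'   `alias`, `planted` in {"synonym", "ambiguous"}).
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_local_seed(params$seed, generate_corpus_impl(params))
}

generate_corpus_impl <- function(params) {
  p <- params
  bg <- background_terms(p$background_vocab_size)
  bg_probs <- zipf_probs(p$background_vocab_size, p$background_zipf_exponent)
  topics <- lapply(seq_len(p$n_groups), topic_terms, size = p$topic_vocab_size)
  officials <- sprintf("GENE%02d", seq_len(p$n_groups))
  n_amb <- as.integer(round(p$ambiguous_fraction * p$aliases_per_group))

  entries <- list()
  truth <- list()
  collections <- list()
  next_pmid <- 10000001L

  sample_doc <- function(topic) {
    from_topic <- stats::runif(p$doc_length) < p$topic_weight &
      length(topic) > 0L
    toks <- character(p$doc_length)
    n_t <- sum(from_topic)
    if (n_t > 0L) toks[from_topic] <- sample(topic, n_t, replace = TRUE)
    if (n_t < p$doc_length) {
      toks[!from_topic] <- sample(bg, p$doc_length - n_t, replace = TRUE,
                                  prob = bg_probs)
    }
    if (p$inject_plurals > 0) {
      plural <- stats::runif(p$doc_length) < p$inject_plurals
      toks[plural] <- paste0(toks[plural], "s")
    }
    paste(toks, collapse = " ")
  }

  make_collection <- function(name, topic) {
    texts <- vapply(seq_len(p$docs_per_name), function(i) sample_doc(topic),
                    character(1L))
    ids <- as.character(seq.int(next_pmid, length.out = p$docs_per_name))
    next_pmid <<- next_pmid + p$docs_per_name
    abstract_collection(name, ids, texts)
  }

  for (i in seq_len(p$n_groups)) {
    g <- officials[i]
    entries[[length(entries) + 1L]] <-
      data.frame(group_id = g, name = g, role = "official",
                 stringsAsFactors = FALSE)
    collections[[g]] <- make_collection(g, topics[[i]])
    amb_idx <- if (n_amb > 0L) {
      sample(seq_len(p$aliases_per_group), n_amb)
    } else integer()
    for (j in seq_len(p$aliases_per_group)) {
      alias <- sprintf("GENE%02dA%d", i, j)
      is_amb <- j %in% amb_idx
      topic <- if (!is_amb) {
        topics[[i]]
      } else if (p$ambiguous_mode == "borrow") {
        topics[[sample(setdiff(seq_len(p$n_groups), i), 1L)]]
      } else {
        character()
      }
      entries[[length(entries) + 1L]] <-
        data.frame(group_id = g, name = alias, role = "alias",
                   stringsAsFactors = FALSE)
      collections[[alias]] <- make_collection(alias, topic)
      truth[[length(truth) + 1L]] <-
        data.frame(group_id = g, alias = alias,
                   planted = if (is_amb) "ambiguous" else "synonym",
                   stringsAsFactors = FALSE)
    }
  }
  list(terminology = new_terminology(do.call(rbind, entries)),
       collections = collections,
       truth = do.call(rbind, truth))
}

#' Generate a baseline corpus from the background distribution
#'
#' The synthetic stand-in for a general-literature baseline collection:
#' documents contain background tokens only, so planted topic terms have
#' baseline frequency 0 (they always survive the baseline filter) while
#' head background terms have high document frequencies and are excluded at
#' any practical cut-off. Uses its own RNG stream derived from
#' `params$seed`, so corpus and baseline can be generated in either order.
#'
#' @param params A `generator_params` object.
#' @return A `baseline_frequencies` object.
#' @export
generate_baseline <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  with_local_seed(p$seed + 777L, {
    bg <- background_terms(p$background_vocab_size)
    bg_probs <- zipf_probs(p$background_vocab_size, p$background_zipf_exponent)
    texts <- vapply(seq_len(p$n_baseline_docs), function(i) {
      paste(sample(bg, p$doc_length, replace = TRUE, prob = bg_probs),
            collapse = " ")
    }, character(1L))
    baseline_frequencies(
      abstract_collection("baseline",
                          as.character(seq_len(p$n_baseline_docs)), texts))
  })
}

#' Write a synthetic corpus to disk in the package's input formats
#'
#' Writes `terminology.tsv`, one 2-column TSV per name (named with
#' [corpus_file_stem()]) under `dir/corpus/`, `truth.tsv`, and, when a
#' baseline is supplied, `baseline.tsv`. The files round-trip through
#' [read_terminology()] / [read_collections()] / [read_baseline()].
#'
#' @param sim Output of [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @param baseline Optional `baseline_frequencies` to cache alongside.
#' @return `dir`, invisibly.
#' @export
write_synthetic_corpus <- function(sim, dir, baseline = NULL) {
  corpus_dir <- file.path(dir, "corpus")
  dir.create(corpus_dir, recursive = TRUE, showWarnings = FALSE)
  write_terminology(sim$terminology, file.path(dir, "terminology.tsv"))
  for (coll in sim$collections) {
    write_collection(coll,
                     file.path(corpus_dir,
                               paste0(corpus_file_stem(coll$name), ".tsv")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(baseline)) write_baseline(baseline, file.path(dir, "baseline.tsv"))
  invisible(dir)
}
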