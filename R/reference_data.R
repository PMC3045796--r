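#' Bundled case-study PMID lists
#'
#' Per-name PubMed id lists for the FADS1 and ADD2 worked examples, as
#' printed in the reference retrieval exercise (a 2009 PubMed snapshot).
#' They drive the document-set operations of the case studies: e.g. exactly
#' one abstract is indexed to both FADS1 and its synonym D5D.
#'
#' @param case Optional case id (`"FADS1"` or `"ADD2"`) to subset to.
#' @return Named list of character PMID vectors, one per name.
#' @export
case_study_pmids <- function(case = NULL) {
  path <- system.file("extdata", "case_study_pmids.tsv",
                      package = "aliasprofiler", mustWork = TRUE)
  df <- utils::read.delim(path, colClasses = "character")
  if (!is.null(case)) df <- df[df$case == case, , drop = FALSE]
  split(df$pmid, factor(df$name, levels = unique(df$name)))
}

#' Bundled summary counts of the reference retrieval exercise
#'
#' Corpus-level counts (officials and aliases with abstracts, total and
#' unique document ids at each screening stage, ambiguous-alias counts)
#' from the reference 100-gene retrieval exercise. These are the inputs of
#' the evaluation worked examples: redundancy, fold-increase and per-gene
#' averages are recomputed from them.
#'
#' @return Named numeric vector of counts.
#' @export
reference_dataset_counts <- function() {
  path <- system.file("extdata", "reference_dataset_counts.tsv",
                      package = "aliasprofiler", mustWork = TRUE)
  df <- utils::read.delim(path)
  stats::setNames(as.numeric(df$value), df$key)
}
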