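#' Fetch an abstract collection from PubMed (network access required)
#'
#' Optional live retrieval through the NCBI eUtils endpoints: `esearch`
#' finds up to `max_abstracts` most recent PMIDs for the query term,
#' `efetch` downloads the records in Medline format, and the titles and
#' abstracts are parsed into an [abstract_collection()]. Intended for
#' building real corpora interactively; everything else in the package runs
#' offline and no test depends on this function.
#'
#' @param term Query term (gene name); sent quoted.
#' @param max_abstracts Retrieval cap (default 100, most recent first).
#' @param sleep Seconds to pause before each request, as elementary
#'   rate-limit courtesy (default 0.4).
#' @param base_url eUtils base URL.
#' @return An `abstract_collection` for `term` (possibly empty).
#' @export
fetch_pubmed_collection <- function(term, max_abstracts = 100L, sleep = 0.4,
                                    base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  query <- utils::URLencode(sprintf('"%s"', term), reserved = TRUE)
  Sys.sleep(sleep)
  search_url <- sprintf(
    "%s/esearch.fcgi?db=pubmed&term=%s&retmax=%d&sort=pub+date",
    base_url, query, as.integer(max_abstracts))
  search_xml <- readLines(search_url, warn = FALSE)
  ids <- regmatches(search_xml,
                    gregexpr("(?<=<Id>)[0-9]+(?=</Id>)", search_xml,
                             perl = TRUE))
  ids <- unique(unlist(ids, use.names = FALSE))
  if (length(ids) == 0L) return(abstract_collection(term))
  Sys.sleep(sleep)
  fetch_url <- sprintf("%s/efetch.fcgi?db=pubmed&id=%s&rettype=medline&retmode=text",
                       base_url, paste(ids, collapse = ","))
  rec <- parse_medline(readLines(fetch_url, warn = FALSE))
  cap_most_recent(abstract_collection(term, rec$doc_id, rec$text),
                  max_abstracts)
}
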