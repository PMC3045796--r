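#' Construct an abstract collection
#'
#' An abstract collection holds the documents (PubMed-style records) retrieved
#' for one gene name: a document identifier (PMID) and the title + abstract
#' text. Duplicated document ids keep the first occurrence.
#'
#' @param name The gene name (official symbol or alias) the collection belongs to.
#' @param doc_id Character vector of document identifiers.
#' @param text Character vector of document texts, same length as `doc_id`.
#' @return An `abstract_collection` object with fields `name`, `doc_id`,
#'   `text`, and `n` (number of documents).
#' @export
abstract_collection <- function(name, doc_id = character(), text = character()) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  if (length(doc_id) != length(text)) {
    stop("doc_id and text must have equal length", call. = FALSE)
  }
  if (anyDuplicated(doc_id)) {
    warning("collection '", name, "': dropping ",
            sum(duplicated(doc_id)), " duplicated doc id(s)", call. = FALSE)
    keep <- !duplicated(doc_id)
    doc_id <- doc_id[keep]
    text <- text[keep]
  }
  structure(list(name = name, doc_id = doc_id, text = text,
                 n = length(doc_id)),
            class = "abstract_collection")
}

#' @export
print.abstract_collection <- function(x, ...) {
  cat("<abstract_collection> '", x$name, "': ", x$n, " document(s)\n", sep = "")
  invisible(x)
}

#' Read per-name abstract collections from a directory
#'
#' Looks up, for every name in the terminology, a file named after it
#' (case-insensitively; non-alphanumeric characters in the name may be
#' replaced by `_` in the file name) with extension `.tsv` or `.txt`. Two
#' formats are auto-detected per file: a 2-column TSV (`doc_id TAB text`) and
#' the NLM Medline flat format (`PMID-`, `TI  -`, `AB  -` fields). Names with
#' no file map to an empty collection; this is never an error.
#'
#' @param dir Directory containing one file per name.
#' @param terminology A `terminology` object (or character vector of names).
#' @return Named list of `abstract_collection`, one entry per name.
#' @export
read_collections <- function(dir, terminology) {
  if (!dir.exists(dir)) stop("corpus directory not found: ", dir, call. = FALSE)
  names_wanted <- if (inherits(terminology, "terminology")) {
    terminology$name
  } else {
    as.character(terminology)
  }
  files <- list.files(dir, full.names = TRUE)
  stems <- tolower(sub("\\.(tsv|txt)$", "", basename(files)))
  out <- vector("list", length(names_wanted))
  names(out) <- names_wanted
  for (nm in names_wanted) {
    hit <- which(stems == tolower(nm) | stems == tolower(corpus_file_stem(nm)))
    if (length(hit) == 0L) {
      out[[nm]] <- abstract_collection(nm)
    } else {
      out[[nm]] <- read_collection_file(files[hit[1L]], nm)
    }
  }
  out
}

#' Sanitized file stem used for a name's corpus file
#'
#' Multi-word aliases contain characters unsuitable for file names; runs of
#' non-alphanumerics map to a single underscore.
#'
#' @param name A gene name.
#' @return A file-system-safe stem.
#' @export
corpus_file_stem <- function(name) {
  stem <- gsub("[^A-Za-z0-9]+", "_", name)
  gsub("^_|_$", "", stem)
}

#' Read one abstract-collection file
#'
#' @param path File path (2-column TSV or Medline flat format, auto-detected).
#' @param name Name to attach to the collection (default: file stem).
#' @return An `abstract_collection`.
#' @export
read_collection_file <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^PMID- ", lines))) {
    rec <- parse_medline(lines)
    return(abstract_collection(name, rec$doc_id, rec$text))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(abstract_collection(name))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop("malformed corpus row (expected 'doc_id TAB text') in ",
         basename(path), " at line ", bad[1L], call. = FALSE)
  }
  doc_id <- vapply(fields, `[[`, character(1L), 1L)
  text <- vapply(fields, function(f) paste(f[-1L], collapse = " "), character(1L))
  abstract_collection(name, doc_id, text)
}

# Parse NLM Medline flat format. Keeps PMID, TI (title) and AB (abstract);
# continuation lines (6 leading spaces) are appended to the open field.
parse_medline <- function(lines) {
  ids <- character()
  texts <- character()
  cur_id <- NA_character_
  cur_ti <- ""
  cur_ab <- ""
  open_field <- ""
  flush <- function() {
    if (!is.na(cur_id)) {
      ids <<- c(ids, cur_id)
      texts <<- c(texts, trimws(paste(cur_ti, cur_ab)))
    }
  }
  for (ln in lines) {
    tag <- substr(ln, 1L, 6L)
    body <- sub("^.{6}", "", ln)
    if (grepl("^PMID- ", ln)) {
      flush()
      cur_id <- trimws(body)
      cur_ti <- ""
      cur_ab <- ""
      open_field <- ""
    } else if (tag == "TI  - ") {
      cur_ti <- trimws(body); open_field <- "TI"
    } else if (tag == "AB  - ") {
      cur_ab <- trimws(body); open_field <- "AB"
    } else if (grepl("^ {6}", ln)) {
      if (open_field == "TI") cur_ti <- paste(cur_ti, trimws(ln))
      if (open_field == "AB") cur_ab <- paste(cur_ab, trimws(ln))
    } else {
      open_field <- ""
    }
  }
  flush()
  list(doc_id = ids, text = texts)
}

#' Keep only the most recent documents of a collection
#'
#' Emulates the retrieval policy of taking up to a fixed number of the most
#' recent abstracts per name. Recency is given by `recency_key` when supplied
#' (e.g. publication dates); otherwise the numeric PMID is used as a proxy,
#' since PMIDs are assigned in increasing order over time. Ties at the
#' boundary are broken in favour of the lower document id, and the returned
#' documents keep their original relative order.
#'
#' @param collection An `abstract_collection`.
#' @param max_abstracts Maximum number of documents to keep (default 100).
#' @param recency_key Optional numeric vector, one per document; larger =
#'   more recent.
#' @return An `abstract_collection` with at most `max_abstracts` documents.
#' @export
cap_most_recent <- function(collection, max_abstracts = 100L, recency_key = NULL) {
  stopifnot(inherits(collection, "abstract_collection"))
  if (max_abstracts < 0L) stop("max_abstracts must be >= 0", call. = FALSE)
  if (collection$n <= max_abstracts) return(collection)
  key <- if (is.null(recency_key)) {
    suppressWarnings(as.numeric(collection$doc_id))
  } else {
    if (length(recency_key) != collection$n) {
      stop("recency_key length must match the number of documents", call. = FALSE)
    }
    as.numeric(recency_key)
  }
  key[is.na(key)] <- -Inf
  # most recent first; ties broken toward the lexicographically lower doc_id
  ord <- order(-key, collection$doc_id)
  keep <- sort(ord[seq_len(max_abstracts)])
  abstract_collection(collection$name,
                      collection$doc_id[keep],
                      collection$text[keep])
}

#' Write an abstract collection as a 2-column TSV file
#'
#' Tabs and newlines inside the text are flattened to spaces so that the file
#' round-trips through [read_collection_file()].
#'
#' @param collection An `abstract_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collection <- function(collection, path) {
  txt <- gsub("[\t\r\n]+", " ", collection$text)
  writeLines(paste(collection$doc_id, txt, sep = "\t"), path)
  invisible(path)
}
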