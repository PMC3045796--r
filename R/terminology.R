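#' Read a gene terminology file
#'
#' A terminology lists, for each gene group, one official gene symbol and one
#' or more aliases. The expected format is three tab-separated columns:
#' `group_id`, `name`, `role`, where `role` is either `"official"` or
#' `"alias"`. A header line is detected and skipped if its third field equals
#' `"role"`.
#'
#' Duplicate `(group_id, name)` pairs (case-insensitive on the name) collapse
#' to a single entry with a warning. A group with two official symbols, or a
#' name listed under two roles within a group, is a validation error.
#'
#' @param path Path to a 3-column TSV file.
#' @return A `terminology` object: a data.frame with columns `group_id`,
#'   `name`, `role`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("FADS1\tFADS1\tofficial", "FADS1\tD5D\talias",
#'              "FADS1\tTU12\talias"), tf)
#' term <- read_terminology(tf)
#' nrow(term)
#' @export
read_terminology <- function(path) {
  if (!file.exists(path)) {
    stop("terminology file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(new_terminology(data.frame(group_id = character(),
                                      name = character(),
                                      role = character(),
                                      stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad) > 0L) {
    stop("malformed terminology row (expected 3 tab-separated fields) at line ",
         bad[1L], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- data.frame(group_id = trimws(m[, 1L]),
                   name     = trimws(m[, 2L]),
                   role     = tolower(trimws(m[, 3L])),
                   stringsAsFactors = FALSE)
  if (df$role[1L] == "role") df <- df[-1L, , drop = FALSE]
  ok_role <- df$role %in% c("official", "alias")
  if (!all(ok_role)) {
    stop("unknown role '", df$role[which(!ok_role)[1L]],
         "' in terminology (expected 'official' or 'alias')", call. = FALSE)
  }
  key <- paste(df$group_id, tolower(df$name), df$role, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsing ", sum(duplicated(key)),
            " duplicated terminology entr(ies)", call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  new_terminology(df)
}

new_terminology <- function(df) {
  rownames(df) <- NULL
  validate_terminology(df)
  class(df) <- c("terminology", "data.frame")
  df
}

validate_terminology <- function(df) {
  for (g in unique(df$group_id)) {
    sub <- df[df$group_id == g, , drop = FALSE]
    n_off <- sum(sub$role == "official")
    if (n_off != 1L) {
      stop("group '", g, "' has ", n_off,
           " official symbols (exactly one required)", call. = FALSE)
    }
    if (anyDuplicated(tolower(sub$name))) {
      stop("group '", g, "' lists the same name under more than one role",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' @export
print.terminology <- function(x, ...) {
  cat("<terminology> ", length(unique(x$group_id)), " group(s), ",
      sum(x$role == "alias"), " alias(es)\n", sep = "")
  invisible(x)
}

#' Official symbols of a terminology
#'
#' @param terminology A `terminology` object.
#' @return Named character vector of official symbols, names = group ids.
#' @export
official_symbols <- function(terminology) {
  off <- terminology[terminology$role == "official", , drop = FALSE]
  stats::setNames(off$name, off$group_id)
}

#' Aliases of one group
#'
#' @param terminology A `terminology` object.
#' @param group_id Group identifier.
#' @return Character vector of alias names.
#' @export
group_aliases <- function(terminology, group_id) {
  terminology$name[terminology$group_id == group_id &
                   terminology$role == "alias"]
}

#' Write a terminology to a 3-column TSV file
#'
#' @param terminology A `terminology` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_terminology <- function(terminology, path) {
  utils::write.table(as.data.frame(terminology)[, c("group_id", "name", "role")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
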