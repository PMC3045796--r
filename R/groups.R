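#' Assign internal-control symbols to each group
#'
#' Internal controls are unrelated official gene symbols used to calibrate
#' the distance scale of a group: an alias at least as far from its official
#' symbol as the nearest control is called ambiguous. Controls are obtained
#' by a single seeded shuffle of the list of official symbols; group `g`
#' takes the next `k` symbols after its own position in the shuffled cycle,
#' skipping its own official symbol. The assignment is a pure function of
#' `(terminology, k, seed)`.
#'
#' @param terminology A `terminology` object with at least 2 groups.
#' @param k Number of controls per group (default 3); capped at the number
#'   of other groups.
#' @param seed Integer seed for the shuffle.
#' @return Named list: group_id -> character vector of control symbols.
#' @export
assign_controls <- function(terminology, k = 3L, seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  off <- official_symbols(terminology)
  if (length(off) < 2L) {
    stop("at least 2 groups are required to assign controls", call. = FALSE)
  }
  shuffled <- with_local_seed(seed, sample(unname(off)))
  n <- length(shuffled)
  out <- vector("list", n)
  names(out) <- names(off)
  for (i in seq_along(off)) {
    own <- off[[i]]
    pos <- match(own, shuffled)
    ring <- shuffled[((pos + seq_len(n - 1L) - 1L) %% n) + 1L]  # cycle, self excluded
    out[[i]] <- ring[seq_len(min(k, n - 1L))]
  }
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assemble per-gene name groups with eligibility screening
#'
#' A group couples the abstract collection of the official symbol with those
#' of its aliases and internal controls. A group is eligible for
#' classification only when the official symbol, at least one alias and at
#' least one control each have a nonempty collection. Ineligible groups are
#' excluded with a reason code (`no_official_corpus`, `no_alias_corpus`,
#' `no_control_corpus`); a fourth code, `empty_vocabulary`, is assigned
#' downstream when a group's vocabulary does not survive the filters.
#'
#' @param terminology A `terminology` object.
#' @param collections Named list of `abstract_collection` (from
#'   [read_collections()]), indexed by name.
#' @param controls Named list group_id -> control symbols (from
#'   [assign_controls()]).
#' @param max_abstracts Cap applied to every collection via
#'   [cap_most_recent()] (default 100).
#' @return List with `groups` (named list of `name_group`) and `excluded`
#'   (data.frame group_id, reason).
#' @export
build_name_groups <- function(terminology, collections, controls,
                              max_abstracts = 100L) {
  lookup <- function(nm) {
    coll <- collections[[nm]]
    if (is.null(coll)) coll <- abstract_collection(nm)
    cap_most_recent(coll, max_abstracts)
  }
  off <- official_symbols(terminology)
  groups <- list()
  excl_id <- character()
  excl_reason <- character()
  for (g in names(off)) {
    official <- lookup(off[[g]])
    aliases <- lapply(group_aliases(terminology, g), lookup)
    ctrl_names <- controls[[g]]
    ctrls <- lapply(if (is.null(ctrl_names)) character() else ctrl_names, lookup)
    reason <- if (official$n < 1L) {
      "no_official_corpus"
    } else if (!any(vapply(aliases, `[[`, 0L, "n") >= 1L)) {
      "no_alias_corpus"
    } else if (!any(vapply(ctrls, `[[`, 0L, "n") >= 1L)) {
      "no_control_corpus"
    } else {
      NA_character_
    }
    if (is.na(reason)) {
      groups[[g]] <- new_name_group(g, official, aliases, ctrls)
    } else {
      excl_id <- c(excl_id, g)
      excl_reason <- c(excl_reason, reason)
    }
  }
  list(groups = groups,
       excluded = data.frame(group_id = excl_id, reason = excl_reason,
                             stringsAsFactors = FALSE))
}

new_name_group <- function(group_id, official, aliases, controls) {
  structure(list(group_id = group_id, official = official,
                 aliases = aliases, controls = controls),
            class = "name_group")
}

#' @export
print.name_group <- function(x, ...) {
  cat("<name_group> '", x$group_id, "': official '", x$official$name,
      "' (n=", x$official$n, "), ", length(x$aliases), " alias(es), ",
      length(x$controls), " control(s)\n", sep = "")
  invisible(x)
}

# All collections of a group (official first, then aliases, then controls),
# as a named list; empty collections are kept so callers can report them.
group_collections <- function(group) {
  colls <- c(list(group$official), group$aliases, group$controls)
  names(colls) <- vapply(colls, `[[`, character(1L), "name")
  colls
}
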