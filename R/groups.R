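#' Construct a group map (genes / partitions of alignment positions)
#'
#' Groups name disjoint sets of 1-based alignment positions (typically genes;
#' positions may be non-contiguous).  Each group g carries a penalty weight
#' w_g used by the group term of the sparse-group-lasso; the default is
#' sqrt(p(g)), the square root of the group length, the usual group-lasso
#' convention.
#'
#' @param groups named list of integer vectors of 1-based positions.
#' @param p alignment length; all indices must lie in `[1, p]`.
#' @param weights optional named numeric vector of positive per-group weights;
#'   default `sqrt(lengths(groups))`.
#' @return An object of class `esl_groups`: list with elements `groups`
#'   (named list of sorted integer vectors), `weights`, `p`.
#' @examples
#' gm <- group_map(list(g1 = 1:4, g2 = 5:9), p = 9)
#' gm$weights  # sqrt(4), sqrt(5)
#' @export
group_map <- function(groups, p, weights = NULL) {
  if (length(groups) == 0L) stop("no groups supplied", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))) ||
      anyDuplicated(names(groups)))
    stop("groups must have unique non-empty names", call. = FALSE)
  groups <- lapply(groups, function(ix) sort(unique(as.integer(ix))))
  if (any(lengths(groups) == 0L))
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0L], collapse = ", "),
         call. = FALSE)
  all_ix <- unlist(groups, use.names = FALSE)
  if (any(all_ix < 1L) || any(all_ix > p))
    stop("range error: group position index outside [1, ", p, "]",
         call. = FALSE)
  if (anyDuplicated(all_ix)) {
    dup <- unique(all_ix[duplicated(all_ix)])
    stop("overlap error: position(s) ", paste(utils::head(dup, 5L), collapse = ", "),
         " assigned to more than one group", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- sqrt(lengths(groups))
  } else {
    weights <- weights[names(groups)]
    if (any(is.na(weights)) || any(weights <= 0))
      stop("weights must be positive and cover every group", call. = FALSE)
  }
  names(weights) <- names(groups)
  structure(list(groups = groups, weights = weights, p = as.integer(p)),
            class = "esl_groups")
}

#' @export
print.esl_groups <- function(x, ...) {
  cat(sprintf("<esl_groups> %d groups covering %d of %d positions\n",
              length(x$groups), length(unlist(x$groups)), x$p))
  invisible(x)
}

#' Read gene/partition definitions
#'
#' Accepts RAxML-style partition files (`"DNA, name = 1-100, 151-200"`; the
#' leading data-type token is ignored) or a two-column TSV of
#' `position<TAB>group`.  The format is sniffed from the file content.
#' Positions not claimed by any group are an error unless
#' `drop_ungrouped = TRUE`, in which case they are excluded with a message.
#'
#' @param path path to the partition file.
#' @param p alignment length.
#' @param drop_ungrouped allow positions outside all groups (default FALSE).
#' @return An [group_map()] object.
#' @export
read_partitions <- function(path, p, drop_ungrouped = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty partition file", call. = FALSE)
  raxml <- any(grepl("=", lines, fixed = TRUE))
  if (raxml) {
    groups <- list()
    for (ln in lines) {
      halves <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(halves) != 2L)
        stop("cannot parse partition line: ", ln, call. = FALSE)
      lhs <- trimws(strsplit(halves[1L], ",", fixed = TRUE)[[1L]])
      name <- lhs[length(lhs)]  # "DNA, name" or just "name"
      spans <- trimws(strsplit(halves[2L], ",", fixed = TRUE)[[1L]])
      ix <- integer(0)
      for (sp in spans) {
        m <- regmatches(sp, regexec("^(\\d+)\\s*-\\s*(\\d+)(\\\\3)?$", sp))[[1L]]
        if (length(m) >= 3L && nzchar(m[2L])) {
          a <- as.integer(m[2L]); b <- as.integer(m[3L])
          by <- if (length(m) >= 4L && nzchar(m[4L])) 3L else 1L
          ix <- c(ix, seq(a, b, by = by))
        } else if (grepl("^\\d+$", sp)) {
          ix <- c(ix, as.integer(sp))
        } else {
          stop("cannot parse span '", sp, "' in line: ", ln, call. = FALSE)
        }
      }
      if (name %in% names(groups))
        groups[[name]] <- c(groups[[name]], ix)
      else
        groups[[name]] <- ix
    }
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "",
                             col.names = c("position", "group"),
                             colClasses = c("integer", "character"))
    groups <- split(tab$position, tab$group)
    # keep first-appearance order, not alphabetical
    groups <- groups[unique(tab$group)]
  }
  covered <- sort(unique(unlist(groups)))
  missing_ix <- setdiff(seq_len(p), covered)
  if (length(missing_ix) > 0L) {
    if (!drop_ungrouped)
      stop(length(missing_ix), " position(s) not covered by any group ",
           "(first: ", missing_ix[1L], "); set drop_ungrouped = TRUE to exclude",
           call. = FALSE)
    message("dropping ", length(missing_ix), " ungrouped position(s)")
  }
  group_map(groups, p)
}

#' Read a category -> group annotation table
#'
#' Two-column TSV `category<TAB>group`; a group may appear under several
#' categories (overlapping functional annotation is allowed).
#'
#' @param path path to the TSV.
#' @param groups an `esl_groups` object; every referenced group must exist.
#' @return Named list mapping category name to a character vector of groups.
#' @export
read_categories <- function(path, groups) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("category", "group"),
                           colClasses = "character")
  unknown <- setdiff(unique(tab$group), names(groups$groups))
  if (length(unknown) > 0L)
    stop("category table references unknown group(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cats <- split(tab$group, tab$category)
  cats <- cats[unique(tab$category)]
  lapply(cats, unique)
}
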