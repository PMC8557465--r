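#' Build a +1/-1 response vector from a focal taxon set
#'
#' Taxa in `positives` (e.g. the members of a focal clade, or carriers of a
#' trait) are coded +1, all others -1, in the row order of the alignment.
#' Unit sample weights are attached; see [balance_response()] for class
#' balancing.
#'
#' @param taxa ordered taxon names (alignment row order).
#' @param positives names of the +1 class; must be a proper non-empty subset
#'   of `taxa`.
#' @return An object of class `esl_response`: list with named numeric `y`
#'   (+1/-1) and `weights`.
#' @export
build_response <- function(taxa, positives) {
  positives <- unique(as.character(positives))
  unknown <- setdiff(positives, taxa)
  if (length(unknown) > 0L)
    stop("lookup error: taxa not in alignment: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  if (length(positives) == 0L || length(positives) == length(taxa))
    stop("degenerate-class error: the +1 class must be a proper non-empty ",
         "subset of the taxa", call. = FALSE)
  y <- ifelse(taxa %in% positives, 1, -1)
  names(y) <- taxa
  w <- rep(1, length(y)); names(w) <- taxa
  structure(list(y = y, weights = w), class = "esl_response")
}

#' @export
print.esl_response <- function(x, ...) {
  cat(sprintf("<esl_response> %d taxa: %d in class +1, %d in class -1\n",
              length(x$y), sum(x$y > 0), sum(x$y < 0)))
  invisible(x)
}

#' Read a taxon -> class table
#'
#' Two-column TSV `taxon<TAB>label`.  Labels `+1`/`-1` (or `1`/`-1`) are used
#' directly; otherwise `positive_label` names the label mapped to +1 (all
#' other labels map to -1).
#'
#' @param path path to the TSV.
#' @param taxa alignment taxon order; every taxon must be listed.
#' @param positive_label label of the +1 class for non-numeric labels.
#' @return An [build_response()] object.
#' @export
read_classes <- function(path, taxa, positive_label = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("taxon", "label"),
                           colClasses = "character")
  if (anyDuplicated(tab$taxon))
    stop("duplicate taxon in class table", call. = FALSE)
  missing_taxa <- setdiff(taxa, tab$taxon)
  if (length(missing_taxa) > 0L)
    stop("class table missing taxa: ",
         paste(utils::head(missing_taxa, 5L), collapse = ", "), call. = FALSE)
  lab <- tab$label[match(taxa, tab$taxon)]
  if (all(lab %in% c("1", "+1", "-1"))) {
    pos <- taxa[lab %in% c("1", "+1")]
  } else {
    if (is.null(positive_label))
      stop("labels are not +1/-1; supply positive_label", call. = FALSE)
    pos <- taxa[lab == positive_label]
  }
  build_response(taxa, pos)
}

#' Balance the two classes
#'
#' `class_weights` (default) attaches weights w_c = S / (2 S_c) so the two
#' classes carry equal total mass; `upsample` draws the minority class with
#' replacement up to the majority size; `downsample` subsamples the majority
#' class without replacement down to the minority size.  Resampling is
#' deterministic given `seed`.
#'
#' @param resp an [build_response()] object.
#' @param mode `"class_weights"`, `"upsample"` or `"downsample"`.
#' @param seed integer seed used by the resampling modes.
#' @return For `class_weights`, the `esl_response` with updated weights.
#'   For the resampling modes, an integer vector of row indices into the
#'   original taxon order (use it to subset alignment rows and `y`).
#' @export
balance_response <- function(resp,
                             mode = c("class_weights", "upsample", "downsample"),
                             seed = 1L) {
  stopifnot(inherits(resp, "esl_response"))
  mode <- match.arg(mode)
  y <- resp$y
  ipos <- which(y > 0); ineg <- which(y < 0)
  if (length(ipos) == 0L || length(ineg) == 0L)
    stop("degenerate-class error: both classes must be non-empty", call. = FALSE)
  if (mode == "class_weights") {
    S <- length(y)
    w <- ifelse(y > 0, S / (2 * length(ipos)), S / (2 * length(ineg)))
    names(w) <- names(y)
    resp$weights <- w
    return(resp)
  }
  rng <- .seeded_rng(seed)
  minor <- if (length(ipos) <= length(ineg)) ipos else ineg
  major <- if (length(ipos) <= length(ineg)) ineg else ipos
  if (mode == "upsample") {
    extra <- rng$sample(minor, size = length(major), replace = TRUE)
    idx <- sort(c(major, extra))
  } else {
    kept <- rng$sample(major, size = length(minor), replace = FALSE)
    idx <- sort(c(minor, kept))
  }
  idx
}

# Local RNG scope: seeded draws that do not disturb the global .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(
    sample = function(x, size, replace = FALSE)
      run(function() sample(x, size = size, replace = replace)),
    runif = function(n) run(function() stats::runif(n)),
    rbinom = function(n, size, prob) run(function() stats::rbinom(n, size, prob)),
    integer_seed = function() run(function() sample.int(.Machine$integer.max, 1L))
  )
}
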