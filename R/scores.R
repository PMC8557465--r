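#' Sparsity scores of a fitted model (BSS, PSS, GSS, FSS, HSS)
#'
#' BSS is `|beta|` per bit-column; PSS sums the BSS of a position's
#' bit-columns; GSS sums PSS over a group's positions; FSS sums GSS over the
#' groups of a functional category (a group in several categories counts in
#' each); HSS is the sum of all GSS.  Positions and groups absent from the
#' model score 0.
#'
#' @param model an `esl_model`.
#' @param groups an [group_map()] object (defines the position/group
#'   universe; positions outside the model's map score 0).
#' @param categories optional named list category -> group names (see
#'   [read_categories()]).  When absent, no FSS table is produced.
#' @return An object of class `esl_scores`: data frames `bss` (bit,
#'   position, state, bss), `pss` (position, group, pss), `gss` (group, gss,
#'   rank), optionally `fss` (category, fss), and scalar `hss`.
#' @export
score_model <- function(model, groups, categories = NULL) {
  stopifnot(inherits(model, "esl_model"), inherits(groups, "esl_groups"))
  if (nrow(model$map) != length(model$beta))
    stop("integrity error: bit-column map does not match coefficients",
         call. = FALSE)
  bss <- data.frame(bit = seq_along(model$beta),
                    position = model$map$position,
                    state = model$map$state,
                    bss = abs(model$beta),
                    stringsAsFactors = FALSE)
  pos2grp <- rep(NA_character_, groups$p)
  for (g in names(groups$groups)) pos2grp[groups$groups[[g]]] <- g
  covered <- which(!is.na(pos2grp))
  pss_val <- numeric(groups$p)
  agg <- tapply(bss$bss, bss$position, sum)
  pss_val[as.integer(names(agg))] <- as.numeric(agg)
  pss <- data.frame(position = covered, group = pos2grp[covered],
                    pss = pss_val[covered], stringsAsFactors = FALSE)
  gss_val <- vapply(groups$groups, function(ix) sum(pss_val[ix]), numeric(1L))
  gss <- data.frame(group = names(groups$groups), gss = as.numeric(gss_val),
                    stringsAsFactors = FALSE)
  gss$rank <- rank(-gss$gss, ties.method = "min")
  out <- list(bss = bss, pss = pss, gss = gss, hss = sum(gss$gss))
  if (!is.null(categories)) {
    unknown <- setdiff(unique(unlist(categories)), gss$group)
    if (length(unknown) > 0L)
      stop("integrity error: categories reference unknown group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    out$fss <- data.frame(
      category = names(categories),
      fss = vapply(categories, function(gs)
        sum(gss$gss[gss$group %in% gs]), numeric(1L)),
      stringsAsFactors = FALSE)
    rownames(out$fss) <- NULL
  }
  structure(out, class = "esl_scores")
}

#' @export
print.esl_scores <- function(x, ...) {
  cat(sprintf("<esl_scores> HSS = %.4g | %d/%d groups with GSS > 0\n",
              x$hss, sum(x$gss$gss > 0), nrow(x$gss)))
  top <- utils::head(x$gss[order(-x$gss$gss), ], 5L)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Sequence prediction scores and classes
#'
#' Encodes each sequence against the model's bit-column map and computes the
#' sequence prediction score SPS = beta0 + x' beta, the class-(+1)
#' probability SPP = 1 / (1 + exp(-SPS)), and the predicted class (+1 iff
#' SPP >= 0.5).  States at modeled positions that have no bit-column
#' contribute 0, so sequences with novel residues are still scorable.
#'
#' @param object an `esl_model`.
#' @param aln an [esl_alignment()] with the same number of positions as the
#'   training alignment.
#' @param ... unused.
#' @return Data frame with `taxon`, `sps`, `spp`, `class`.
#' @export
predict.esl_model <- function(object, aln, ...) {
  stopifnot(inherits(aln, "esl_alignment"))
  if (ncol(aln) != object$p)
    stop("shape error: alignment has ", ncol(aln), " positions; model expects ",
         object$p, call. = FALSE)
  M <- unclass(aln)
  sps <- rep(object$beta0, nrow(M))
  nz <- which(object$beta != 0)
  for (k in nz) {
    hit <- M[, object$map$position[k]] == object$map$state[k]
    sps[hit] <- sps[hit] + object$beta[k]
  }
  spp <- .sigmoid(sps)
  data.frame(taxon = rownames(M), sps = sps, spp = spp,
             class = ifelse(spp >= 0.5, 1, -1),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC from prediction records
#'
#' Thresholds are placed at every distinct SPS value (ties grouped); the
#' curve reports the true-positive rate against the false-positive rate and
#' the AUC is computed by the trapezoid rule (equal to the Mann-Whitney
#' concordance probability with ties counted 1/2).
#'
#' @param records data frame from [predict.esl_model()] (needs `taxon`,
#'   `sps`).
#' @param resp an `esl_response` (or named +1/-1 vector) giving true classes.
#' @return List with `points` (data frame `threshold`, `tpr`, `fpr`) and
#'   scalar `auc`.
#' @export
esl_roc <- function(records, resp) {
  y <- if (inherits(resp, "esl_response")) resp$y else resp
  y <- y[match(records$taxon, names(y))]
  if (anyNA(y)) stop("true class missing for some records", call. = FALSE)
  if (all(y > 0) || all(y < 0))
    stop("degenerate-ROC error: both classes required", call. = FALSE)
  s <- records$sps
  thr <- sort(unique(s), decreasing = TRUE)
  P <- sum(y > 0); N <- sum(y < 0)
  tpr <- vapply(thr, function(t) sum(s >= t & y > 0) / P, numeric(1L))
  fpr <- vapply(thr, function(t) sum(s >= t & y < 0) / N, numeric(1L))
  pts <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Write score tables as TSV
#'
#' Writes per-position (`<prefix>_pss.tsv`), per-group (`<prefix>_gss.tsv`),
#' optionally per-category (`<prefix>_fss.tsv`) tables, and a run summary
#' JSON (`<prefix>_summary.json`) holding HSS.
#'
#' @param scores an `esl_scores` object.
#' @param prefix output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_scores <- function(scores, prefix) {
  files <- character(0)
  tsv <- function(tab, suffix) {
    f <- paste0(prefix, suffix)
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(files, tsv(scores$pss, "_pss.tsv"),
             tsv(scores$gss[order(scores$gss$rank), ], "_gss.tsv"))
  if (!is.null(scores$fss)) files <- c(files, tsv(scores$fss, "_fss.tsv"))
  f <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(hss = scores$hss,
                            n_groups_selected = sum(scores$gss$gss > 0)),
                       f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Write per-taxon prediction records as TSV
#'
#' @param records data frame from [predict.esl_model()].
#' @param path output TSV path.
#' @param resp optional `esl_response` to add the true class column.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path, resp = NULL) {
  if (!is.null(resp)) {
    y <- if (inherits(resp, "esl_response")) resp$y else resp
    records$true_class <- y[match(records$taxon, names(y))]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
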