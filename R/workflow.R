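# End-to-end orchestration: encode -> sparse-group fit (gene selection) ->
# refit on selected genes -> scores -> predictions -> ROC, for one focal
# branch/trait, and a scan over all eligible internal branches.

# Shared select+refit stage.  `aln` may carry duplicated biological rows
# (bootstrap replicates) as long as row names were made unique upstream.
.select_refit <- function(aln, groups, resp, opts, penalty = "sparse_group",
                          refit_mode = "group_lasso", lambda_refit = NULL,
                          gap_as_state = FALSE, ambiguity_policy = "missing",
                          categories = NULL) {
  enc <- one_hot_encode(aln, gap_as_state = gap_as_state,
                        ambiguity_policy = ambiguity_policy)
  enc <- filter_monomorphic(enc)
  if (ncol(enc$X) == 0L)
    stop("empty-design error: no polymorphic bit-columns", call. = FALSE)
  enc <- map_groups_to_bits(enc, groups)
  selecting <- esl_fit(enc, resp, groups, opts, penalty)
  sel_scores <- score_model(selecting, groups)
  selected <- sel_scores$gss$group[sel_scores$gss$gss > 0]
  if (length(selected) == 0L) {
    return(list(enc = enc, selecting = selecting, refit = NULL,
                scores = sel_scores, selected = character(0)))
  }
  refit <- refit_selected(enc, resp, selected, groups,
                          lambda_refit = lambda_refit, mode = refit_mode,
                          opts = opts)
  scores <- score_model(refit, groups, categories)
  list(enc = enc, selecting = selecting, refit = refit, scores = scores,
       selected = selected)
}

#' Full ESL analysis of one branch / binary trait
#'
#' Runs the standard workflow: one-hot encode with monomorphic filtering,
#' sparse-group-lasso fit to select genes (GSS > 0), robust refit on the
#' selected genes, sparsity scores, per-sequence prediction scores, and the
#' training ROC/AUC.  With zero selected groups an empty-model result is
#' returned (all scores 0, SPS = intercept), not an error.
#'
#' @param aln an [esl_alignment()].
#' @param groups an [group_map()].
#' @param classes the +1 class: an `esl_response`, a character vector of
#'   focal taxa, or a list `list(tree=, branch=)` resolved via
#'   [clade_members()].
#' @param opts an [fit_options()].
#' @param penalty selection penalty (default `"sparse_group"`).
#' @param balance `"class_weights"` (default), `"upsample"`, `"downsample"`
#'   or `"none"`.
#' @param refit_mode `"group_lasso"` (default) or `"ridge"`.
#' @param lambda_refit refit penalty; default 0.01 * lambda_max of the
#'   reduced problem.
#' @param gap_as_state,ambiguity_policy encoding options, see
#'   [one_hot_encode()].
#' @param categories optional category -> groups list for FSS.
#' @return An object of class `esl_analysis`: `selecting` and `refit`
#'   models, `scores`, `selected` group names, `predictions`, `roc` (with
#'   `auc`), and the run parameters in `params`.
#' @export
analyze_branch <- function(aln, groups, classes, opts = fit_options(),
                           penalty = "sparse_group",
                           balance = "class_weights",
                           refit_mode = "group_lasso", lambda_refit = NULL,
                           gap_as_state = FALSE, ambiguity_policy = "missing",
                           categories = NULL) {
  resp <- .resolve_classes(aln, classes)
  fit_aln <- aln
  if (balance == "class_weights") {
    resp <- balance_response(resp, "class_weights")
  } else if (balance %in% c("upsample", "downsample")) {
    idx <- balance_response(resp, balance, seed = opts$seed)
    M <- unclass(aln)[idx, , drop = FALSE]
    rownames(M) <- make.unique(rownames(M))
    fit_aln <- esl_alignment(M, attr(aln, "alphabet"))
    resp <- build_response(rownames(fit_aln),
                           rownames(fit_aln)[resp$y[idx] > 0])
  } else if (balance != "none") {
    stop("usage error: unknown balance mode '", balance, "'", call. = FALSE)
  }
  st <- .select_refit(fit_aln, groups, resp, opts, penalty, refit_mode,
                      lambda_refit, gap_as_state, ambiguity_policy, categories)
  model <- if (is.null(st$refit)) st$selecting else st$refit
  # predictions and ROC are reported on the original (unresampled) alignment
  resp0 <- .resolve_classes(aln, classes)
  preds <- predict(model, aln)
  roc <- esl_roc(preds, resp0)
  structure(list(selecting = st$selecting, refit = st$refit,
                 scores = st$scores, selected = st$selected,
                 predictions = preds, roc = roc,
                 empty_model = is.null(st$refit),
                 params = list(lambda1 = opts$lambda1, lambda2 = opts$lambda2,
                               penalty = penalty, balance = balance,
                               refit_mode = refit_mode,
                               lambda_refit = lambda_refit,
                               gap_as_state = gap_as_state,
                               ambiguity_policy = ambiguity_policy,
                               seed = opts$seed)),
            class = "esl_analysis")
}

.resolve_classes <- function(aln, classes) {
  taxa <- rownames(aln)
  if (inherits(classes, "esl_response")) {
    if (!identical(names(classes$y), taxa))
      stop("shape error: response taxa do not match alignment rows",
           call. = FALSE)
    classes
  } else if (is.list(classes) && !is.null(classes$tree)) {
    build_response(taxa, clade_members(classes$tree, classes$branch))
  } else if (is.character(classes)) {
    build_response(taxa, classes)
  } else {
    stop("usage error: cannot interpret `classes`", call. = FALSE)
  }
}

#' @export
print.esl_analysis <- function(x, ...) {
  cat(sprintf(
    "<esl_analysis> %d/%d groups selected (%.1f%%) | HSS = %.4g | training AUC = %.4f\n",
    length(x$selected), nrow(x$scores$gss),
    100 * length(x$selected) / nrow(x$scores$gss),
    x$scores$hss, x$roc$auc))
  invisible(x)
}

#' Apply the branch analysis to every eligible internal branch
#'
#' Enumerates internal branches of the tree (see [internal_branches()]);
#' branches with fewer than `min_class_size` leaves on either side are
#' skipped with a message.  Each eligible branch is analyzed independently
#' with identical settings, so results do not depend on processing order.
#'
#' @param aln an [esl_alignment()]; row names must match the tree's leaves.
#' @param groups an [group_map()].
#' @param tree a `phylo` object.
#' @param opts an [fit_options()].
#' @param min_class_size minimum leaves per side (default 2).
#' @param ... further arguments passed to [analyze_branch()].
#' @return Named list of `esl_analysis` objects, keyed by internal node id.
#' @export
scan_branches <- function(aln, groups, tree, opts = fit_options(),
                          min_class_size = 2L, ...) {
  .validate_tree(tree)
  if (!setequal(tree$tip.label, rownames(aln)))
    stop("tree leaves and alignment taxa differ", call. = FALSE)
  br <- internal_branches(tree, min_class_size)
  members <- attr(br, "members")
  skipped <- br$node[!br$eligible]
  if (length(skipped) > 0L)
    message("skipping ", length(skipped),
            " branch(es) with a side smaller than ", min_class_size,
            ": nodes ", paste(skipped, collapse = ", "))
  br <- br[br$eligible, , drop = FALSE]
  if (nrow(br) == 0L)
    stop("usage error: no eligible internal branch", call. = FALSE)
  out <- lapply(as.character(br$node), function(nd)
    analyze_branch(aln, groups, members[[nd]], opts, ...))
  names(out) <- as.character(br$node)
  out
}

#' Serialize the parameters of an analysis into a run-manifest JSON
#'
#' @param analysis an `esl_analysis`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(analysis, path) {
  jsonlite::write_json(
    c(analysis$params,
      list(n_selected = length(analysis$selected),
           auc = analysis$roc$auc, hss = analysis$scores$hss,
           empty_model = analysis$empty_model)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
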