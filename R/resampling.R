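# Bootstrap and permutation significance machinery.  Every replicate re-runs
# the full selection + refit pipeline on resampled data, so supports reflect
# the whole procedure, not just one fit.

#' Bootstrap support of genes and positions
#'
#' `mode = "sequence"` resamples sequences with replacement within each
#' class (class sizes preserved exactly); `mode = "site"` resamples
#' alignment positions with replacement, carrying group membership along.
#' Each replicate is re-encoded and re-fitted (selection + refit), and a
#' group/position "appears" in a replicate when its GSS/PSS is positive.
#' Replicates whose fits fail are excluded and counted; more than 10%
#' failures aborts the run.
#'
#' @param aln an [esl_alignment()].
#' @param groups an [group_map()].
#' @param resp an `esl_response` (weights are re-derived per replicate with
#'   class-weight balancing).
#' @param opts an [fit_options()].
#' @param reps number of bootstrap replicates (`>= 2`).
#' @param mode `"sequence"` or `"site"`.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param ... further arguments passed to the pipeline (penalty, refit_mode,
#'   lambda_refit, encoding options).
#' @return An object of class `esl_bootstrap`: per-replicate GSS matrix
#'   (`gss`, reps x groups), per-group `support`, `mean_gss`, `sd_gss`,
#'   `cv` (sd/mean, NA where mean is 0), per-position `support_pos`, `mode`,
#'   `reps` (successful) and `n_failed`.
#' @export
esl_bootstrap <- function(aln, groups, resp, opts = fit_options(),
                          reps = 100L, mode = c("sequence", "site"),
                          seed = opts$seed, ...) {
  mode <- match.arg(mode)
  stopifnot(reps >= 2L)
  rng <- .seeded_rng(seed)
  gnames <- names(groups$groups)
  p <- groups$p
  gss_mat <- matrix(NA_real_, reps, length(gnames),
                    dimnames = list(NULL, gnames))
  pos_in <- matrix(0, reps, p)
  n_failed <- 0L
  M <- unclass(aln)
  ipos <- which(resp$y > 0); ineg <- which(resp$y < 0)
  for (r in seq_len(reps)) {
    if (mode == "sequence") {
      idx <- c(rng$sample(ipos, size = length(ipos), replace = TRUE),
               rng$sample(ineg, size = length(ineg), replace = TRUE))
      stopifnot(sum(resp$y[idx] > 0) == length(ipos))  # class sizes preserved
      Mr <- M[idx, , drop = FALSE]
      rownames(Mr) <- make.unique(rownames(Mr))
      aln_r <- esl_alignment(Mr, attr(aln, "alphabet"))
      resp_r <- build_response(rownames(Mr), rownames(Mr)[resp$y[idx] > 0])
      groups_r <- groups
      src_pos <- seq_len(p)
    } else {
      cols <- rng$sample(seq_len(p), size = p, replace = TRUE)
      Mr <- M[, cols, drop = FALSE]
      aln_r <- esl_alignment(Mr, attr(aln, "alphabet"))
      pos2grp <- rep(NA_character_, p)
      for (g in gnames) pos2grp[groups$groups[[g]]] <- g
      newgrp <- pos2grp[cols]
      keep <- !is.na(newgrp)
      glist <- split(which(keep), newgrp[keep])
      glist <- glist[intersect(gnames, names(glist))]
      groups_r <- group_map(glist, p)
      resp_r <- resp
      src_pos <- cols
    }
    resp_r <- balance_response(resp_r, "class_weights")
    st <- tryCatch(
      .select_refit(aln_r, groups_r, resp_r, opts, ...),
      error = function(e) NULL)
    if (is.null(st) ||
        (!is.null(st$refit) && !st$refit$converged) ||
        !st$selecting$converged) {
      n_failed <- n_failed + 1L
      next
    }
    gss_r <- stats::setNames(rep(0, length(gnames)), gnames)
    gss_r[st$scores$gss$group] <- st$scores$gss$gss
    gss_mat[r, ] <- gss_r
    pss_r <- st$scores$pss
    hit <- unique(src_pos[pss_r$position[pss_r$pss > 0]])
    pos_in[r, hit] <- 1
  }
  ok <- !is.na(gss_mat[, 1L])
  if (n_failed > 0.1 * reps)
    stop("bootstrap error: ", n_failed, " of ", reps,
         " replicates failed to fit", call. = FALSE)
  gss_mat <- gss_mat[ok, , drop = FALSE]
  pos_in <- pos_in[ok, , drop = FALSE]
  mean_gss <- colMeans(gss_mat)
  sd_gss <- apply(gss_mat, 2L, stats::sd)
  cv <- ifelse(mean_gss > 0, sd_gss / mean_gss, NA_real_)
  structure(list(reps = sum(ok), n_failed = n_failed, mode = mode,
                 gss = gss_mat,
                 support = colMeans(gss_mat > 0),
                 mean_gss = mean_gss, sd_gss = sd_gss, cv = cv,
                 support_pos = stats::setNames(colMeans(pos_in),
                                               seq_len(p))),
            class = "esl_bootstrap")
}

#' @export
print.esl_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<esl_bootstrap> %s resampling, %d replicates (%d failed) | %d group(s) with support > 0.95\n",
    x$mode, x$reps, x$n_failed, sum(x$support > 0.95)))
  invisible(x)
}

#' Select groups/positions exceeding a bootstrap support threshold
#'
#' Selection is strict (`support > threshold`), matching the usual
#' "more than 95% of the bootstrap models" reading.
#'
#' @param result an `esl_bootstrap`.
#' @param threshold support proportion in (0, 1].
#' @return List with `groups` and `positions` (1-based) passing the cut.
#' @export
support_select <- function(result, threshold = 0.95) {
  stopifnot(inherits(result, "esl_bootstrap"),
            threshold > 0, threshold <= 1)
  list(groups = names(result$support)[result$support > threshold],
       positions = as.integer(names(result$support_pos)[
         result$support_pos > threshold]))
}

#' Permutation null for group inclusion
#'
#' Each replicate assigns sequences to +1/-1 by a seeded fair coin (redrawn
#' until both classes are non-empty), runs the selection + refit pipeline,
#' and records which groups enter the model (GSS > 0).  The per-group null
#' inclusion frequency and its min/median/max summary quantify how often
#' genes are picked up with no real signal.
#'
#' @param aln an [esl_alignment()].
#' @param groups an [group_map()].
#' @param opts an [fit_options()].
#' @param reps number of permutation replicates (`>= 2`).
#' @param seed integer seed.
#' @param ... further arguments passed to the pipeline.
#' @return An object of class `esl_permutation`: `inclusion` (per-group null
#'   frequency), `per_rep_fraction` (fraction of groups included per
#'   replicate), `summary` (min/median/max of per-group frequencies),
#'   `reps`, `n_failed`.
#' @export
permutation_null <- function(aln, groups, opts = fit_options(), reps = 100L,
                             seed = opts$seed, ...) {
  stopifnot(reps >= 2L)
  rng <- .seeded_rng(seed)
  gnames <- names(groups$groups)
  S <- nrow(aln)
  incl <- matrix(NA_real_, reps, length(gnames),
                 dimnames = list(NULL, gnames))
  n_failed <- 0L
  for (r in seq_len(reps)) {
    for (try in 1:100) {
      lab <- rng$rbinom(S, 1L, 0.5)
      if (any(lab == 1L) && any(lab == 0L)) break
    }
    resp_r <- build_response(rownames(aln), rownames(aln)[lab == 1L])
    resp_r <- balance_response(resp_r, "class_weights")
    st <- tryCatch(.select_refit(aln, groups, resp_r, opts, ...),
                   error = function(e) NULL)
    if (is.null(st) || !st$selecting$converged) {
      n_failed <- n_failed + 1L
      next
    }
    inc_r <- stats::setNames(rep(0, length(gnames)), gnames)
    inc_r[st$scores$gss$group[st$scores$gss$gss > 0]] <- 1
    incl[r, ] <- inc_r
  }
  ok <- !is.na(incl[, 1L])
  if (n_failed > 0.1 * reps)
    stop("permutation error: ", n_failed, " of ", reps,
         " replicates failed to fit", call. = FALSE)
  incl <- incl[ok, , drop = FALSE]
  freq <- colMeans(incl)
  structure(list(reps = sum(ok), n_failed = n_failed,
                 inclusion = freq,
                 per_rep_fraction = rowMeans(incl),
                 summary = c(min = min(freq), median = stats::median(freq),
                             max = max(freq))),
            class = "esl_permutation")
}

#' @export
print.esl_permutation <- function(x, ...) {
  cat(sprintf(
    "<esl_permutation> %d replicates (%d failed) | null inclusion: min %.2f, median %.2f, max %.2f\n",
    x$reps, x$n_failed, x$summary["min"], x$summary["median"],
    x$summary["max"]))
  invisible(x)
}

#' Write bootstrap support tables as TSV + JSON summary
#'
#' @param result an `esl_bootstrap`.
#' @param prefix output path prefix.
#' @param seed the seed used (recorded in the summary JSON).
#' @return Files written, invisibly.
#' @export
write_bootstrap <- function(result, prefix, seed = NA) {
  fg <- paste0(prefix, "_group_support.tsv")
  utils::write.table(
    data.frame(group = names(result$support), support = result$support,
               mean_gss = result$mean_gss, sd_gss = result$sd_gss,
               cv = result$cv),
    fg, sep = "\t", quote = FALSE, row.names = FALSE)
  fp <- paste0(prefix, "_position_support.tsv")
  utils::write.table(
    data.frame(position = as.integer(names(result$support_pos)),
               support = result$support_pos),
    fp, sep = "\t", quote = FALSE, row.names = FALSE)
  fj <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(mode = result$mode, reps = result$reps,
                            n_failed = result$n_failed, seed = seed),
                       fj, auto_unbox = TRUE, digits = NA)
  invisible(c(fg, fp, fj))
}
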