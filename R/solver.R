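# Penalized weighted logistic regression by accelerated proximal gradient.
#
# Objective (normalized by total sample weight W = sum w_j):
#   F(b0, b) = (1/W) sum_j w_j log(1 + exp(-y_j (b0 + x_j' b)))
#              + lambda1 ||b||_1 + lambda2 sum_g w_g ||b_g||_2
# The intercept b0 is never penalized.  The nonsmooth part has an exact
# proximal map (soft-threshold, then per-group Euclidean shrinkage), so
# FISTA with backtracking and a monotone restart applies directly.

# numerically stable log(1 + exp(z))
.log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# sigmoid
.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Weighted logistic loss and its exact gradient
#'
#' Loss `(1/W) sum_j w_j log(1 + exp(-y_j (b0 + x_j' b)))` with
#' `W = sum_j w_j`, and its gradient in `(beta0, beta)`.
#'
#' @param beta0 intercept.
#' @param beta coefficient vector (length = ncol(X)).
#' @param X numeric design matrix (rows = sequences).
#' @param y response in \{+1, -1\} (an `esl_response` is also accepted, in
#'   which case its weights are used).
#' @param weights non-negative sample weights (default all 1).
#' @return List with `loss`, `grad_beta0`, `grad_beta`.
#' @export
logistic_objective <- function(beta0, beta, X, y, weights = NULL) {
  if (inherits(X, "esl_onehot")) X <- X$X
  if (inherits(y, "esl_response")) {
    if (is.null(weights)) weights <- y$weights
    y <- y$y
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(y) != nrow(X) || length(beta) != ncol(X) ||
      length(weights) != length(y))
    stop("shape error: inconsistent dimensions", call. = FALSE)
  W <- sum(weights)
  eta <- beta0 + as.numeric(X %*% beta)
  z <- -y * eta
  loss <- sum(weights * .log1pexp(z)) / W
  d <- weights * (-y) * .sigmoid(z) / W       # d loss / d eta_j
  list(loss = loss,
       grad_beta0 = sum(d),
       grad_beta = as.numeric(crossprod(X, d)))
}

#' Soft-thresholding (proximal map of the l1 norm)
#'
#' @param v numeric vector.
#' @param t threshold, `>= 0`.
#' @return `sign(v) * pmax(|v| - t, 0)`.
#' @export
prox_l1 <- function(v, t) {
  if (length(t) != 1L || is.na(t) || t < 0)
    stop("usage error: threshold t must be a single value >= 0", call. = FALSE)
  sign(v) * pmax(abs(v) - t, 0)
}

#' Proximal map of the sparse-group-lasso penalty
#'
#' Exact proximal operator of `t1 ||.||_1 + t2 sum_g w_g ||._g||_2`:
#' soft-threshold at `t1`, then shrink each group slice toward zero by
#' `max(1 - t2 w_g / ||u_g||_2, 0)`.
#'
#' @param v numeric vector.
#' @param t1 l1 threshold `>= 0`.
#' @param t2 group threshold `>= 0`.
#' @param slices named list of index vectors partitioning `seq_along(v)`
#'   (empty slices allowed).
#' @param wg positive per-group weights, aligned with `slices`.
#' @return The prox, same length as `v`.
#' @export
prox_sparse_group <- function(v, t1, t2, slices, wg) {
  if (t1 < 0 || t2 < 0) stop("usage error: thresholds must be >= 0", call. = FALSE)
  ix <- unlist(slices, use.names = FALSE)
  if (length(ix) != length(v) || anyDuplicated(ix) ||
      !all(sort(ix) == seq_along(v)))
    stop("partition error: slices must partition the coefficient vector",
         call. = FALSE)
  u <- prox_l1(v, t1)
  if (t2 > 0) {
    for (gi in seq_along(slices)) {
      s <- slices[[gi]]
      if (length(s) == 0L) next
      ng <- sqrt(sum(u[s]^2))
      if (ng > 0) u[s] <- u[s] * max(1 - t2 * wg[gi] / ng, 0)
    }
  }
  u
}

#' Solver options
#'
#' @param lambda1 l1 (per-bit) regularization strength `>= 0`.
#' @param lambda2 group regularization strength `>= 0`.
#' @param max_iterations iteration cap for the proximal gradient loop.
#' @param tolerance relative objective-change stopping threshold.
#' @param seed integer seed controlling any randomized step (folds,
#'   subsampling, resampling) built on top of the deterministic fit.
#' @return A list of class `esl_fit_options`.
#' @export
fit_options <- function(lambda1 = 0.05, lambda2 = 0.1,
                        max_iterations = 10000L, tolerance = 1e-6,
                        seed = 1L) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, tolerance > 0, max_iterations >= 1)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "esl_fit_options")
}

# weighted log-odds of class +1: the intercept-only optimum
.weighted_logodds <- function(y, w) {
  log(sum(w[y > 0]) / sum(w[y < 0]))
}

# Core FISTA loop.  ridge > 0 adds ridge * ||b||^2 to the smooth part.
# slices/wg may be NULL (pure lasso).  Returns beta0, beta, diagnostics.
.fit_fista <- function(X, y, w, lambda1, lambda2, slices, wg, ridge = 0,
                       max_iter = 10000L, tol = 1e-6) {
  n <- nrow(X); cc <- ncol(X)
  W <- sum(w)
  sw <- w / W
  prox <- function(v, step) {
    if (is.null(slices) || lambda2 == 0) prox_l1(v, lambda1 * step)
    else prox_sparse_group(v, lambda1 * step, lambda2 * step, slices, wg)
  }
  pen <- function(b) {
    h <- lambda1 * sum(abs(b))
    if (!is.null(slices) && lambda2 > 0)
      h <- h + lambda2 * sum(wg * vapply(slices, function(s)
        sqrt(sum(b[s]^2)), numeric(1L)))
    h
  }
  smooth <- function(b0, b) {
    eta <- b0 + as.numeric(X %*% b)
    z <- -y * eta
    f <- sum(sw * .log1pexp(z)) + ridge * sum(b^2)
    d <- sw * (-y) * .sigmoid(z)
    list(f = f, g0 = sum(d), g = as.numeric(crossprod(X, d)) + 2 * ridge * b)
  }

  # subgradient optimality residual at a point with smooth gradient g
  kkt <- function(b, g) {
    viol <- 0
    sl <- if (is.null(slices) || lambda2 == 0) list(seq_along(b)) else slices
    l2s <- if (is.null(slices) || lambda2 == 0) rep(0, length(sl)) else
      lambda2 * wg
    for (gi in seq_along(sl)) {
      s <- sl[[gi]]
      if (length(s) == 0L) next
      ng <- sqrt(sum(b[s]^2))
      if (ng > 0) {
        gr <- g[s] + l2s[gi] * b[s] / ng
        nz <- b[s] != 0
        if (any(nz)) viol <- max(viol, abs(gr[nz] + lambda1 * sign(b[s][nz])))
        if (any(!nz)) viol <- max(viol, pmax(abs(gr[!nz]) - lambda1, 0))
      } else {
        viol <- max(viol,
                    max(sqrt(sum(pmax(abs(g[s]) - lambda1, 0)^2)) - l2s[gi], 0))
      }
    }
    viol
  }

  b0 <- .weighted_logodds(y, w)
  b <- numeric(cc)
  sm <- smooth(b0, b)
  Fx <- sm$f + pen(b)
  trace <- numeric(0)
  b0_prev <- b0; b_prev <- b
  tmom <- 1
  L <- 1
  converged <- FALSE
  iter <- 0L

  prox_step <- function(p0, p, s) {
    # one backtracked proximal step from point (p0, p) with smooth info s;
    # returns the new point, its smooth value, and the (possibly grown) L
    repeat {
      step <- 1 / L
      z0 <- p0 - step * s$g0
      zb <- prox(p - step * s$g, step)
      smz <- smooth(z0, zb)
      dz0 <- z0 - p0; dzb <- zb - p
      quad <- s$f + s$g0 * dz0 + sum(s$g * dzb) +
        (L / 2) * (dz0^2 + sum(dzb^2))
      if (smz$f <= quad + 1e-12 * abs(quad)) {
        if (!is.finite(smz$f)) stop("divergence error: non-finite objective",
                                    call. = FALSE)
        return(list(b0 = z0, b = zb, sm = smz))
      }
      L <<- L * 2
      if (L > 1e16) stop("divergence error: backtracking failed", call. = FALSE)
    }
  }

  for (k in seq_len(max_iter)) {
    iter <- k
    tnew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
    mom <- (tmom - 1) / tnew
    y0 <- b0 + mom * (b0 - b0_prev)
    yb <- b + mom * (b - b_prev)
    smy <- if (mom == 0) sm else smooth(y0, yb)
    stp <- prox_step(y0, yb, smy)
    Fz <- stp$sm$f + pen(stp$b)
    if (Fz > Fx) {
      # monotone restart: plain proximal step from the current iterate
      stp <- prox_step(b0, b, sm)
      Fz <- stp$sm$f + pen(stp$b)
      tnew <- 1
    }
    b0_prev <- b0; b_prev <- b
    b0 <- stp$b0; b <- stp$b; sm <- stp$sm
    tmom <- tnew
    trace <- c(trace, Fz)
    if (abs(Fx - Fz) <= tol * max(1, abs(Fx)) &&
        abs(sm$g0) < 10 * tol && kkt(b, sm$g) < 10 * tol) {
      Fx <- Fz
      converged <- TRUE
      break
    }
    Fx <- Fz
    L <- max(L * 0.9, 1e-10)   # let the step size recover
  }
  list(beta0 = b0, beta = b, objective = Fx, objective_trace = trace,
       iterations = iter, converged = converged)
}

#' Smallest l1 strength yielding the all-zero model
#'
#' With the intercept at its optimum and all coefficients zero, the largest
#' absolute loss-gradient entry over bit-columns is the smallest `lambda1`
#' at which the lasso (and a fortiori sparse-group) optimum is `beta = 0`.
#'
#' @param enc an `esl_onehot` (or plain design matrix).
#' @param resp an `esl_response` (or a +1/-1 vector; then `weights`).
#' @param weights optional sample weights when `resp` is a plain vector.
#' @return The scalar lambda_max.
#' @export
lambda_max <- function(enc, resp, weights = NULL) {
  X <- if (inherits(enc, "esl_onehot")) enc$X else enc
  if (inherits(resp, "esl_response")) {
    y <- resp$y; w <- resp$weights
  } else {
    y <- resp; w <- if (is.null(weights)) rep(1, length(y)) else weights
  }
  if (ncol(X) == 0L) stop("empty-design error: no bit-columns", call. = FALSE)
  if (all(y > 0) || all(y < 0))
    stop("degenerate-class error: both classes required", call. = FALSE)
  W <- sum(w)
  b0 <- .weighted_logodds(y, w)
  d <- w * (-y) * .sigmoid(-y * b0) / W
  max(abs(as.numeric(crossprod(X, d))))
}

#' Fit a penalized logistic regression model (ESL model)
#'
#' Fits weighted logistic regression with one of three penalties by FISTA
#' with backtracking line search and a monotone restart: `"lasso"`
#' (`lambda1 ||b||_1`), `"group"` (`lambda2 sum w_g ||b_g||_2`) or
#' `"sparse_group"` (both; the bilevel penalty).  The fit is deterministic;
#' the intercept is unpenalized and initialized at the weighted log-odds.
#'
#' @param enc an `esl_onehot`; for group penalties it must carry `group_bits`
#'   (see [map_groups_to_bits()]) or `groups` must be supplied.
#' @param resp an [build_response()] object (weights are honored; see
#'   [balance_response()]).
#' @param groups optional [group_map()]; required for group penalties when
#'   `enc` has no group assignment yet.
#' @param opts an [fit_options()] object.
#' @param penalty `"sparse_group"` (default), `"lasso"` or `"group"`.
#' @return An object of class `esl_model`: intercept `beta0`, coefficients
#'   `beta` (one per retained bit-column), the bit-column map, penalty
#'   configuration and convergence diagnostics.
#' @export
esl_fit <- function(enc, resp, groups = NULL, opts = fit_options(),
                    penalty = c("sparse_group", "lasso", "group")) {
  stopifnot(inherits(enc, "esl_onehot"), inherits(resp, "esl_response"))
  penalty <- match.arg(penalty)
  if (!is.null(groups) && is.null(enc$group_bits))
    enc <- map_groups_to_bits(enc, groups)
  if (penalty != "lasso" && is.null(enc$group_bits))
    stop("group penalty requires a group assignment (map_groups_to_bits)",
         call. = FALSE)
  X <- enc$X
  if (ncol(X) == 0L) stop("empty-design error: no retained bit-columns",
                          call. = FALSE)
  if (!identical(rownames(X), names(resp$y)))
    stop("shape error: response taxa do not match encoded rows", call. = FALSE)
  if (all(resp$y > 0) || all(resp$y < 0))
    stop("degenerate-class error: both classes required", call. = FALSE)
  storage.mode(X) <- "double"
  lam1 <- if (penalty == "group") 0 else opts$lambda1
  lam2 <- if (penalty == "lasso") 0 else opts$lambda2
  slices <- if (penalty == "lasso") NULL else enc$group_bits
  wg <- if (is.null(slices)) NULL else {
    if (!is.null(groups)) groups$weights[names(slices)]
    else enc$group_weights[names(slices)]
  }
  if (!is.null(slices) && (is.null(wg) || anyNA(wg)))
    stop("group weights unavailable; pass `groups`", call. = FALSE)
  fit <- .fit_fista(X, resp$y, resp$weights, lam1, lam2, slices, wg,
                    ridge = 0, max_iter = opts$max_iterations,
                    tol = opts$tolerance)
  structure(list(beta0 = fit$beta0, beta = fit$beta,
                 lambda1 = lam1, lambda2 = lam2, penalty = penalty,
                 group_weights = wg,
                 map = enc$map, group_bits = enc$group_bits,
                 alphabet = enc$alphabet, p = enc$p,
                 gap_as_state = enc$gap_as_state,
                 ambiguity_policy = enc$ambiguity_policy,
                 converged = fit$converged, iterations = fit$iterations,
                 objective = fit$objective,
                 objective_trace = fit$objective_trace),
            class = "esl_model")
}

#' @export
print.esl_model <- function(x, ...) {
  cat(sprintf(
    "<esl_model> penalty=%s lambda1=%.4g lambda2=%.4g | %d bit-columns, %d nonzero | %s in %d iterations\n",
    x$penalty, x$lambda1, x$lambda2, length(x$beta), sum(x$beta != 0),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Subgradient (KKT) optimality residual of a fitted model
#'
#' For nonzero coefficients, the stationarity residual
#' `grad_i + lambda1 sign(b_i) + lambda2 w_g b_i / ||b_g||`; for zero
#' coefficients, the excess of the subgradient interval condition.  Returns
#' the maximum violation (0 means exactly optimal).
#'
#' @param model an `esl_model`.
#' @param enc the `esl_onehot` it was fitted to.
#' @param resp the `esl_response` it was fitted to.
#' @return Scalar maximum KKT violation.
#' @export
kkt_residual <- function(model, enc, resp) {
  X <- enc$X; storage.mode(X) <- "double"
  ob <- logistic_objective(model$beta0, model$beta, X, resp$y, resp$weights)
  g <- ob$grad_beta
  b <- model$beta
  lam1 <- model$lambda1; lam2 <- model$lambda2
  viol <- abs(ob$grad_beta0)
  slices <- model$group_bits
  if (is.null(slices) || lam2 == 0)
    slices <- list(all = seq_along(b))
  wg <- if (!is.null(model$group_weights)) model$group_weights else
    stats::setNames(rep(1, length(slices)), names(slices))
  for (gi in seq_along(slices)) {
    s <- slices[[gi]]
    if (length(s) == 0L) next
    l2 <- if (model$lambda2 > 0 && !is.null(model$group_bits)) lam2 * wg[gi] else 0
    ng <- sqrt(sum(b[s]^2))
    if (ng > 0) {
      gr <- g[s] + l2 * b[s] / ng
      nz <- b[s] != 0
      if (any(nz)) viol <- max(viol, abs(gr[nz] + lam1 * sign(b[s][nz])))
      if (any(!nz)) viol <- max(viol, pmax(abs(gr[!nz]) - lam1, 0))
    } else {
      # whole group at zero: || soft(-g_s, lam1) ||_2 <= lam2 * w_g
      viol <- max(viol, max(sqrt(sum(prox_l1(-g[s], lam1)^2)) - l2, 0))
    }
  }
  viol
}

#' Stratified k-fold cross-validation over a (lambda1, lambda2) grid
#'
#' Folds are stratified by class and seed-deterministic.  For each grid
#' point the mean held-out weighted logistic loss is computed; the returned
#' optimum is the grid point with the lowest mean loss (ties broken toward
#' the sparser model, i.e. the earlier/larger lambda1).
#'
#' @param enc an `esl_onehot` with groups assigned.
#' @param resp an `esl_response`.
#' @param groups an [group_map()].
#' @param lambda1_grid numeric grid; default 20 geometric points from
#'   lambda_max down to 1e-3 lambda_max.
#' @param lambda2_grid numeric grid; default the single value in `opts`.
#' @param k number of folds (`>= 2`).
#' @param opts an [fit_options()]; its seed controls fold assignment.
#' @param penalty passed to [esl_fit()].
#' @return List with `best` (named vector lambda1, lambda2) and `table`
#'   (grid with mean CV loss).
#' @export
cross_validate <- function(enc, resp, groups, lambda1_grid = NULL,
                           lambda2_grid = NULL, k = 5L,
                           opts = fit_options(),
                           penalty = "sparse_group") {
  stopifnot(k >= 2L)
  if (is.null(enc$group_bits)) enc <- map_groups_to_bits(enc, groups)
  lmax <- lambda_max(enc, resp)
  if (is.null(lambda1_grid))
    lambda1_grid <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = 20L))
  if (is.null(lambda2_grid)) lambda2_grid <- opts$lambda2
  y <- resp$y
  rng <- .seeded_rng(opts$seed)
  fold <- integer(length(y))
  for (cl in c(1, -1)) {
    ix <- which(y == cl)
    ix <- rng$sample(ix, size = length(ix), replace = FALSE)
    fold[ix] <- rep(seq_len(k), length.out = length(ix))
  }
  for (f in seq_len(k)) {
    ytr <- y[fold != f]
    if (all(ytr > 0) || all(ytr < 0))
      stop("stratification error: a class is absent from a training fold",
           call. = FALSE)
  }
  grid <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid)
  losses <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    enc_tr <- enc; enc_tr$X <- enc$X[tr, , drop = FALSE]
    resp_tr <- structure(list(y = y[tr], weights = resp$weights[tr]),
                         class = "esl_response")
    Xte <- enc$X[te, , drop = FALSE]; storage.mode(Xte) <- "double"
    for (gi in seq_len(nrow(grid))) {
      o <- opts; o$lambda1 <- grid$lambda1[gi]; o$lambda2 <- grid$lambda2[gi]
      m <- esl_fit(enc_tr, resp_tr, groups, o, penalty)
      losses[gi, f] <- logistic_objective(m$beta0, m$beta, Xte, y[te],
                                          resp$weights[te])$loss
    }
  }
  grid$cv_loss <- rowMeans(losses)
  best <- which.min(grid$cv_loss)
  list(best = c(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best]),
       table = grid)
}

#' Stability selection: per-group selection frequency over subsampled fits
#'
#' Repeatedly fits the model to class-stratified subsamples (without
#' replacement) and reports, per group, the fraction of fits in which the
#' group carries at least one nonzero coefficient.
#'
#' @param enc an `esl_onehot` with groups assigned.
#' @param resp an `esl_response`.
#' @param groups an [group_map()].
#' @param opts an [fit_options()]; its seed controls the subsampling.
#' @param subsample_fraction fraction of each class drawn per replicate
#'   (0 < fraction < 1).
#' @param reps number of replicates (`>= 2`).
#' @param penalty passed to [esl_fit()].
#' @return Named numeric vector of selection frequencies (one per group).
#' @export
stability_select <- function(enc, resp, groups, opts = fit_options(),
                             subsample_fraction = 0.5, reps = 50L,
                             penalty = "sparse_group") {
  stopifnot(subsample_fraction > 0, subsample_fraction < 1, reps >= 2L)
  if (is.null(enc$group_bits)) enc <- map_groups_to_bits(enc, groups)
  y <- resp$y
  rng <- .seeded_rng(opts$seed)
  counts <- stats::setNames(numeric(length(groups$groups)),
                            names(groups$groups))
  for (r in seq_len(reps)) {
    idx <- integer(0)
    for (cl in c(1, -1)) {
      ix <- which(y == cl)
      take <- max(1L, floor(subsample_fraction * length(ix)))
      idx <- c(idx, rng$sample(ix, size = take, replace = FALSE))
    }
    idx <- sort(idx)
    enc_r <- enc; enc_r$X <- enc$X[idx, , drop = FALSE]
    resp_r <- structure(list(y = y[idx], weights = resp$weights[idx]),
                        class = "esl_response")
    m <- esl_fit(enc_r, resp_r, groups, opts, penalty)
    nz <- vapply(m$group_bits, function(s) any(m$beta[s] != 0), logical(1L))
    counts[names(nz)] <- counts[names(nz)] + nz
  }
  counts / reps
}

#' Refit a model on the selected groups only
#'
#' Restricts the design to the bit-columns of the selected groups and refits
#' with a mild penalty for robust coefficient estimation: `"group_lasso"`
#' (default) penalizes `lambda sum w_g ||b_g||_2` with no l1 term, mirroring
#' a group-penalized logistic refit; `"ridge"` penalizes
#' `lambda ||b||_2^2`.  Coefficients of unselected groups are fixed at 0 in
#' the returned full-length model.
#'
#' @param enc an `esl_onehot` with groups assigned.
#' @param resp an `esl_response`.
#' @param selected character vector of selected group names (non-empty).
#' @param groups an [group_map()].
#' @param lambda_refit penalty strength; default 0.01 * lambda_max of the
#'   reduced problem.
#' @param mode `"group_lasso"` or `"ridge"`.
#' @param opts an [fit_options()] (iteration cap and tolerance are used).
#' @return An `esl_model` over the full bit-column map with zeros outside
#'   the selected groups.
#' @export
refit_selected <- function(enc, resp, selected, groups,
                           lambda_refit = NULL,
                           mode = c("group_lasso", "ridge"),
                           opts = fit_options()) {
  mode <- match.arg(mode)
  if (is.null(enc$group_bits)) enc <- map_groups_to_bits(enc, groups)
  selected <- unique(as.character(selected))
  if (length(selected) == 0L)
    stop("empty-selection error: no groups selected", call. = FALSE)
  unknown <- setdiff(selected, names(enc$group_bits))
  if (length(unknown) > 0L)
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  cols <- unlist(enc$group_bits[selected], use.names = FALSE)
  cols <- sort(cols)
  if (length(cols) == 0L)
    stop("empty-selection error: selected groups carry no bit-columns",
         call. = FALSE)
  Xr <- enc$X[, cols, drop = FALSE]
  storage.mode(Xr) <- "double"
  slices_r <- lapply(enc$group_bits[selected], function(s) match(s, cols))
  wg_r <- groups$weights[selected]
  if (is.null(lambda_refit)) {
    lambda_refit <- 0.01 * lambda_max(Xr, resp)
  }
  if (mode == "group_lasso") {
    fit <- .fit_fista(Xr, resp$y, resp$weights, lambda1 = 0,
                      lambda2 = lambda_refit, slices = slices_r, wg = wg_r,
                      ridge = 0, max_iter = opts$max_iterations,
                      tol = opts$tolerance)
  } else {
    fit <- .fit_fista(Xr, resp$y, resp$weights, lambda1 = 0, lambda2 = 0,
                      slices = NULL, wg = NULL, ridge = lambda_refit,
                      max_iter = opts$max_iterations, tol = opts$tolerance)
  }
  beta_full <- numeric(ncol(enc$X))
  beta_full[cols] <- fit$beta
  structure(list(beta0 = fit$beta0, beta = beta_full,
                 lambda1 = 0, lambda2 = if (mode == "group_lasso") lambda_refit else 0,
                 lambda_refit = lambda_refit,
                 penalty = paste0("refit_", mode),
                 group_weights = groups$weights[names(enc$group_bits)],
                 selected_groups = selected,
                 map = enc$map, group_bits = enc$group_bits,
                 alphabet = enc$alphabet, p = enc$p,
                 gap_as_state = enc$gap_as_state,
                 ambiguity_policy = enc$ambiguity_policy,
                 converged = fit$converged, iterations = fit$iterations,
                 objective = fit$objective,
                 objective_trace = fit$objective_trace),
            class = "esl_model")
}

#' Serialize a fitted model to JSON
#'
#' Metadata (penalty, lambdas, convergence, intercept) followed by one
#' record per bit-column: position, state, group, beta.
#'
#' @param model an `esl_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  coefs <- cbind(model$map, beta = model$beta)
  obj <- list(
    penalty = model$penalty, lambda1 = model$lambda1, lambda2 = model$lambda2,
    beta0 = model$beta0, alphabet = model$alphabet, p = model$p,
    gap_as_state = model$gap_as_state, ambiguity_policy = model$ambiguity_policy,
    converged = model$converged, iterations = model$iterations,
    objective = model$objective,
    coefficients = coefs
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
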