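# a small non-separable weighted logistic problem for oracle comparisons
toy_problem <- function(n = 8, p = 6, seed = 2) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  y <- rep(c(1, -1), length.out = n)
  w <- runif(n, 0.5, 2)
  list(X = X, y = y, w = w)
}

test_that("logistic objective has the closed-form null value and exact gradient", {
  tp <- toy_problem()
  ob <- logistic_objective(0, numeric(ncol(tp$X)), tp$X, tp$y, tp$w)
  expect_equal(ob$loss, log(2))  # beta = 0 -> log(1 + exp(0)) everywhere

  # finite-difference oracle at a random point
  set.seed(4)
  b0 <- rnorm(1); b <- rnorm(ncol(tp$X), sd = 0.5)
  ob <- logistic_objective(b0, b, tp$X, tp$y, tp$w)
  h <- 1e-5
  fd0 <- (logistic_objective(b0 + h, b, tp$X, tp$y, tp$w)$loss -
          logistic_objective(b0 - h, b, tp$X, tp$y, tp$w)$loss) / (2 * h)
  expect_equal(ob$grad_beta0, fd0, tolerance = 1e-6)
  for (j in c(1, 3, 6)) {
    e <- numeric(length(b)); e[j] <- h
    fd <- (logistic_objective(b0, b + e, tp$X, tp$y, tp$w)$loss -
           logistic_objective(b0, b - e, tp$X, tp$y, tp$w)$loss) / (2 * h)
    expect_equal(ob$grad_beta[j], fd, tolerance = 1e-6)
  }
  expect_error(logistic_objective(0, numeric(2), tp$X, tp$y, tp$w), "shape")
})

test_that("scaling a separating direction drives the loss toward zero", {
  X <- cbind(c(1, 1, 0, 0))
  y <- c(1, 1, -1, -1)
  b <- 1
  l1 <- logistic_objective(-0.5, b, X, y)$loss
  l2 <- logistic_objective(-5, b * 10, X, y)$loss
  expect_lt(l2, l1)
  expect_lt(l2, 0.01)
})

test_that("soft-thresholding matches its closed form", {
  expect_equal(prox_l1(0.5, 0.2), 0.3)
  expect_equal(prox_l1(-0.1, 0.2), 0)
  v <- c(-2, -0.3, 0, 0.1, 5)
  expect_equal(prox_l1(v, 0), v)  # t = 0 is the identity
  expect_equal(prox_l1(v, 0.5), c(-1.5, 0, 0, 0, 4.5))
  expect_error(prox_l1(v, -1), "usage")
})

test_that("sparse-group prox: closed-form group shrinkage and zeroing", {
  # single group, ||v||=5, factor 1 - 2.5/5 = 0.5
  out <- prox_sparse_group(c(3, 4), t1 = 0, t2 = 2.5,
                           slices = list(g = 1:2), wg = c(g = 1))
  expect_equal(out, c(1.5, 2))
  # group threshold at/above the soft-thresholded norm zeroes the group
  out2 <- prox_sparse_group(c(3, 4), t1 = 0, t2 = 5,
                            slices = list(g = 1:2), wg = c(g = 1))
  expect_equal(out2, c(0, 0))
  expect_error(prox_sparse_group(c(1, 2, 3), 0, 1,
                                 slices = list(g = 1:2), wg = 1),
               "partition")
})

test_that("sparse-group prox beats numerical minimization nowhere", {
  set.seed(11)
  slices <- list(g1 = 1:3, g2 = 4:5, g3 = integer(0))
  wg <- c(g1 = sqrt(3), g2 = sqrt(2), g3 = 1)
  obj <- function(x, v, t1, t2) {
    0.5 * sum((x - v)^2) + t1 * sum(abs(x)) +
      t2 * (wg[1] * sqrt(sum(x[1:3]^2)) + wg[2] * sqrt(sum(x[4:5]^2)))
  }
  for (rep in 1:5) {
    v <- rnorm(5, sd = 2); t1 <- runif(1, 0, 0.8); t2 <- runif(1, 0, 0.8)
    ours <- prox_sparse_group(v, t1, t2, slices, wg)
    num <- optim(ours + rnorm(5, sd = 0.1), obj, v = v, t1 = t1, t2 = t2,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    for (k in 1:3)  # polish: restart the simplex from its own solution
      num <- optim(num$par, obj, v = v, t1 = t1, t2 = t2,
                   method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 5000))
    # the closed form is never beaten by, and agrees with, the numeric optimum
    expect_lte(obj(ours, v, t1, t2), num$value + 1e-8)
    expect_equal(ours, num$par, tolerance = 0.01)
  }
})

test_that("prox reductions: singleton groups compose l1, t1=0 is pure group prox", {
  v <- c(-1.2, 0.4, 2.5)
  singles <- list(a = 1L, b = 2L, c = 3L)
  wg1 <- c(a = 1, b = 1, c = 1)
  # soft-threshold at t1 then per-singleton shrink by t2 = chained soft-thresholds
  expect_equal(prox_sparse_group(v, 0.3, 0.2, singles, wg1),
               prox_l1(prox_l1(v, 0.3), 0.2))
  grp <- list(g = 1:3)
  out <- prox_sparse_group(v, 0, 0.5, grp, c(g = 1))
  nv <- sqrt(sum(v^2))
  expect_equal(out, v * max(1 - 0.5 / nv, 0))
})

test_that("lambda_max is self-consistent and the null fit recovers log-odds", {
  pr <- prep_sim(small_planted())
  lmax <- pr$lmax
  null_fit <- esl_fit(pr$enc, pr$resp, opts = fit_options(lambda1 = 1.01 * lmax),
                      penalty = "lasso")
  expect_equal(sum(null_fit$beta != 0), 0L)
  w <- pr$resp$weights; y <- pr$resp$y
  expect_equal(null_fit$beta0, log(sum(w[y > 0]) / sum(w[y < 0])),
               tolerance = 1e-4)
  half_fit <- esl_fit(pr$enc, pr$resp, opts = fit_options(lambda1 = 0.5 * lmax),
                      penalty = "lasso")
  expect_gt(sum(half_fit$beta != 0), 0L)
})

test_that("the unpenalized fit matches glm on a small instance", {
  tp <- toy_problem(n = 20, p = 5, seed = 6)
  rownames(tp$X) <- sprintf("r%02d", 1:20)
  enc <- structure(list(X = tp$X,
                        map = data.frame(position = 1:5,
                                         state = rep("A", 5)),
                        alphabet = "nucleotide", gap_as_state = FALSE,
                        ambiguity_policy = "missing", p = 5L,
                        n_removed_monomorphic = 0L),
                   class = "esl_onehot")
  resp <- structure(list(y = setNames(tp$y, rownames(tp$X)),
                         weights = setNames(tp$w, rownames(tp$X))),
                    class = "esl_response")
  fit <- esl_fit(enc, resp, opts = fit_options(lambda1 = 0, tolerance = 1e-12,
                                               max_iterations = 50000),
                 penalty = "lasso")
  ref <- suppressWarnings(
    glm((tp$y + 1) / 2 ~ tp$X, family = binomial(), weights = tp$w))
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-4)
  expect_equal(fit$beta, unname(coef(ref)[-1]), tolerance = 1e-4)
})

test_that("objective trace is non-increasing and KKT residuals are small", {
  pr <- prep_sim(small_planted())
  opts <- default_opts(pr$lmax)
  fit <- esl_fit(pr$enc, pr$resp, opts = opts)
  expect_true(fit$converged)
  expect_true(all(diff(fit$objective_trace) <= 1e-12))
  expect_lt(kkt_residual(fit, pr$enc, pr$resp), 10 * opts$tolerance)
  # lasso-only fit satisfies KKT too
  fit_l <- esl_fit(pr$enc, pr$resp, opts = opts, penalty = "lasso")
  expect_lt(kkt_residual(fit_l, pr$enc, pr$resp), 10 * opts$tolerance)
})

test_that("a planted diagnostic bit-column attains the largest coefficient", {
  set.seed(31)
  S <- 40
  clade <- c(rep(TRUE, 12), rep(FALSE, 28))
  M <- matrix(sample(c("A", "C", "G", "T"), S * 51, replace = TRUE), S, 51)
  M[, 1] <- ifelse(clade, "A", "T")  # perfectly diagnostic position
  rownames(M) <- sprintf("t%02d", 1:S)
  aln <- esl_alignment(M, "nucleotide")
  resp <- balance_response(build_response(rownames(M), rownames(M)[clade]))
  enc <- filter_monomorphic(one_hot_encode(aln))
  fit <- esl_fit(enc, resp,
                 opts = fit_options(lambda1 = 0.1 * lambda_max(enc, resp)),
                 penalty = "lasso")
  expect_equal(enc$map$position[which.max(abs(fit$beta))], 1L)
})

test_that("stronger l1 never selects more bit-columns (on this fixture)", {
  pr <- prep_sim(small_planted(seed = 12))
  o1 <- fit_options(lambda1 = 0.01 * pr$lmax, lambda2 = 0.02 * pr$lmax)
  o2 <- fit_options(lambda1 = 0.1 * pr$lmax, lambda2 = 0.02 * pr$lmax)
  f1 <- esl_fit(pr$enc, pr$resp, opts = o1)
  f2 <- esl_fit(pr$enc, pr$resp, opts = o2)
  expect_lte(sum(f2$beta != 0), sum(f1$beta != 0))
})

test_that("cross-validation selects sensibly and is deterministic", {
  pr <- prep_sim(small_planted(seed = 8))
  # null-only grid: held-out loss is log(2) for balanced classes
  cv0 <- cross_validate(pr$enc, pr$resp, NULL,
                        lambda1_grid = 2 * pr$lmax, lambda2_grid = 0,
                        k = 3, opts = fit_options(seed = 5))
  expect_equal(cv0$table$cv_loss, log(2), tolerance = 0.02)
  grid <- c(0.5, 0.05, 0.005) * pr$lmax
  cv <- cross_validate(pr$enc, pr$resp, NULL, lambda1_grid = grid,
                       lambda2_grid = 0.02 * pr$lmax, k = 3,
                       opts = fit_options(seed = 5))
  cv2 <- cross_validate(pr$enc, pr$resp, NULL, lambda1_grid = grid,
                        lambda2_grid = 0.02 * pr$lmax, k = 3,
                        opts = fit_options(seed = 5))
  expect_identical(cv$table, cv2$table)
  # the strong planted signal prefers a fitting (non-null) lambda1
  expect_lt(cv$best["lambda1"], pr$lmax)
  sim8 <- small_planted(seed = 8)
  o <- fit_options(lambda1 = cv$best[["lambda1"]],
                   lambda2 = cv$best[["lambda2"]])
  m <- esl_fit(pr$enc, pr$resp, opts = o)
  sel <- score_model(m, sim8$groups)
  expect_true(all(sim8$truth$diag_genes %in%
                    sel$gss$group[sel$gss$gss > 0]))
})

test_that("stability selection separates planted from noise groups", {
  sim <- small_planted(seed = 21)
  pr <- prep_sim(sim)
  freq <- stability_select(pr$enc, pr$resp, sim$groups,
                           default_opts(pr$lmax, seed = 9),
                           subsample_fraction = 0.6, reps = 20)
  expect_gte(freq[sim$truth$diag_genes], 0.9)
  expect_lt(max(freq[setdiff(names(freq), sim$truth$diag_genes)]),
            freq[sim$truth$diag_genes])
  freq2 <- stability_select(pr$enc, pr$resp, sim$groups,
                            default_opts(pr$lmax, seed = 9),
                            subsample_fraction = 0.6, reps = 20)
  expect_identical(freq, freq2)
})

test_that("refitting selected groups behaves at its limits", {
  sim <- small_planted(seed = 13)
  pr <- prep_sim(sim)
  sel_fit <- esl_fit(pr$enc, pr$resp, opts = default_opts(pr$lmax))
  sc <- score_model(sel_fit, sim$groups)
  sel <- sc$gss$group[sc$gss$gss > 0]
  expect_gt(length(sel), 0)
  refit <- refit_selected(pr$enc, pr$resp, sel, sim$groups,
                          opts = fit_options(tolerance = 1e-8))
  # refit never increases the training logistic loss vs the selecting model
  l_ref <- logistic_objective(refit$beta0, refit$beta, pr$enc$X, pr$resp)$loss
  l_sel <- logistic_objective(sel_fit$beta0, sel_fit$beta, pr$enc$X, pr$resp)$loss
  expect_lte(l_ref, l_sel + 1e-8)
  # coefficients outside selected groups stay exactly zero
  outside <- unlist(pr$enc$group_bits[setdiff(names(pr$enc$group_bits), sel)])
  expect_true(all(refit$beta[outside] == 0))
  # ridge with enormous lambda collapses to the weighted log-odds intercept
  ridge_inf <- refit_selected(pr$enc, pr$resp, sel, sim$groups,
                              lambda_refit = 1e6, mode = "ridge")
  expect_equal(max(abs(ridge_inf$beta)), 0, tolerance = 1e-4)
  w <- pr$resp$weights; y <- pr$resp$y
  expect_equal(ridge_inf$beta0, log(sum(w[y > 0]) / sum(w[y < 0])),
               tolerance = 1e-3)
  expect_error(refit_selected(pr$enc, pr$resp, character(0), sim$groups),
               "empty-selection")
})

test_that("lambda_refit = 0 group refit equals the unpenalized restricted fit", {
  tp <- toy_problem(n = 16, p = 4, seed = 3)
  rownames(tp$X) <- sprintf("r%02d", 1:16)
  enc <- structure(list(X = tp$X,
                        map = data.frame(position = 1:4, state = rep("A", 4)),
                        alphabet = "nucleotide", gap_as_state = FALSE,
                        ambiguity_policy = "missing", p = 4L,
                        n_removed_monomorphic = 0L),
                   class = "esl_onehot")
  gm <- group_map(list(g1 = 1:2, g2 = 3:4), p = 4)
  enc <- map_groups_to_bits(enc, gm)
  resp <- structure(list(y = setNames(tp$y, rownames(tp$X)),
                         weights = setNames(tp$w, rownames(tp$X))),
                    class = "esl_response")
  refit0 <- refit_selected(enc, resp, c("g1", "g2"), gm, lambda_refit = 0,
                           opts = fit_options(tolerance = 1e-12,
                                              max_iterations = 50000))
  ref <- suppressWarnings(
    glm((tp$y + 1) / 2 ~ tp$X, family = binomial(), weights = tp$w))
  expect_equal(refit0$beta, unname(coef(ref)[-1]), tolerance = 1e-3)
})
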