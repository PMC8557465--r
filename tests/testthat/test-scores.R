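# build a model object by hand so score identities are checked independently
# of the solver
hand_model <- function(beta, map, groups, beta0 = 0) {
  pos2grp <- rep(NA_character_, groups$p)
  for (g in names(groups$groups)) pos2grp[groups$groups[[g]]] <- g
  map$group <- pos2grp[map$position]
  gb <- lapply(names(groups$groups),
               function(g) which(map$group == g))
  names(gb) <- names(groups$groups)
  structure(list(beta0 = beta0, beta = beta, lambda1 = 0.1, lambda2 = 0.1,
                 penalty = "sparse_group",
                 group_weights = groups$weights, map = map, group_bits = gb,
                 alphabet = "nucleotide", p = groups$p,
                 gap_as_state = FALSE, ambiguity_policy = "missing",
                 converged = TRUE, iterations = 1L, objective = 0,
                 objective_trace = 0),
            class = "esl_model")
}

test_that("score summation identities hold: BSS -> PSS -> GSS -> HSS", {
  map <- data.frame(position = c(1, 1, 2, 3, 3, 4),
                    state = c("A", "C", "A", "A", "G", "T"))
  gm <- group_map(list(g1 = 1:2, g2 = 3:4), p = 4)
  beta <- c(0.2, -0.3, 0, 1.5, -0.5, 0.25)
  sc <- score_model(hand_model(beta, map, gm), gm)
  expect_equal(sc$pss$pss[sc$pss$position == 1], 0.5)  # |0.2| + |-0.3|
  expect_equal(sc$pss$pss[sc$pss$position == 2], 0)
  expect_equal(sc$gss$gss[sc$gss$group == "g1"], 0.5)
  expect_equal(sc$gss$gss[sc$gss$group == "g2"], 2.25)
  expect_equal(sc$hss, sum(abs(beta)))          # two-route identity
  expect_equal(sum(sc$gss$gss), sum(sc$pss$pss))
  # null model: every score 0
  sc0 <- score_model(hand_model(numeric(6), map, gm), gm)
  expect_equal(sc0$hss, 0)
  expect_true(all(sc0$gss$gss == 0))
})

test_that("random models satisfy the HSS identity and rank by GSS", {
  sim <- small_planted(seed = 17)
  pr <- prep_sim(sim)
  fit <- esl_fit(pr$enc, pr$resp, opts = default_opts(pr$lmax))
  sc <- score_model(fit, sim$groups)
  expect_equal(sc$hss, sum(abs(fit$beta)))
  expect_equal(sc$hss, sum(sc$gss$gss))
  expect_equal(sc$gss$rank[which.max(sc$gss$gss)], 1L)
})

test_that("FSS sums GSS over categories, with overlap counted in each", {
  map <- data.frame(position = 1:4, state = rep("A", 4))
  gm <- group_map(list(g1 = 1:2, g2 = 3L, g3 = 4L), p = 4)
  beta <- c(1, 1, 2, 4)
  cats <- list(catA = c("g1", "g2"), catB = c("g2", "g3"))
  sc <- score_model(hand_model(beta, map, gm), gm, categories = cats)
  expect_equal(sc$fss$fss[sc$fss$category == "catA"], 4)  # 2 + 2
  expect_equal(sc$fss$fss[sc$fss$category == "catB"], 6)  # 2 + 4
  expect_error(score_model(hand_model(beta, map, gm), gm,
                           categories = list(bad = "nope")), "integrity")
})

test_that("prediction scores follow the logistic closed forms", {
  map <- data.frame(position = 1:2, state = c("A", "C"))
  gm <- group_map(list(g = 1:2), p = 2)
  aln <- esl_alignment(c(x = "AC", y = "AG", z = "TT"), "nucleotide")
  # null model: SPS = 0, SPP = 0.5, class +1 by the >= 0.5 tie rule
  p0 <- predict(hand_model(c(0, 0), map, gm), aln)
  expect_equal(p0$sps, rep(0, 3))
  expect_equal(p0$spp, rep(0.5, 3))
  expect_equal(p0$class, rep(1, 3))
  # SPS = ln 3 -> SPP = 0.75; unknown states contribute nothing
  m <- hand_model(c(log(3), 5), map, gm)
  pr <- predict(m, aln)
  expect_equal(pr$sps[2], log(3))   # A matches, G has no bit-column
  expect_equal(pr$spp[2], 0.75)
  expect_equal(pr$sps[3], 0)        # nothing matches
  expect_equal(pr$sps[1], log(3) + 5)
  expect_error(predict(m, esl_alignment(c(q = "ACG"), "nucleotide")), "shape")
})

test_that("SPP is a symmetric, increasing transform of SPS", {
  s <- seq(-4, 4, by = 0.5)
  spp <- 1 / (1 + exp(-s))
  map <- data.frame(position = 1, state = "A")
  gm <- group_map(list(g = 1L), p = 1)
  recs <- lapply(s, function(si) {
    predict(hand_model(0, map, gm, beta0 = si),
            esl_alignment(c(t = "C"), "nucleotide"))
  })
  got <- vapply(recs, function(r) r$spp, numeric(1))
  expect_equal(got, spp)
  expect_true(all(diff(got) > 0))
  expect_equal(got + rev(got), rep(1, length(s)))  # SPP(-s) = 1 - SPP(s)
})

test_that("ROC/AUC agree with brute-force pair counting and pROC", {
  y <- c(1, -1, 1, 1, -1)
  names(y) <- letters[1:5]
  recs <- data.frame(taxon = letters[1:5], sps = c(0.9, 0.8, 0.3, 0.3, 0.1))
  roc <- esl_roc(recs, y)
  expect_equal(roc$auc, pair_auc(recs$sps, y))
  # perfectly separated scores
  recs2 <- data.frame(taxon = letters[1:5], sps = c(5, -1, 4, 3, -2))
  expect_equal(esl_roc(recs2, y)$auc, 1.0)
  # constant scores carry no information
  recs3 <- data.frame(taxon = letters[1:5], sps = rep(0.7, 5))
  expect_equal(esl_roc(recs3, y)$auc, 0.5)
  # random scores, <= 50 records: trapezoid AUC == Mann-Whitney by brute force
  set.seed(6)
  yy <- setNames(sample(c(1, -1), 50, replace = TRUE, prob = c(0.4, 0.6)),
                 sprintf("t%02d", 1:50))
  rr <- data.frame(taxon = names(yy),
                   sps = round(rnorm(50), 1))  # rounding forces ties
  roc50 <- esl_roc(rr, yy)
  expect_equal(roc50$auc, pair_auc(rr$sps, yy))
  expect_equal(roc50$auc,
               as.numeric(suppressMessages(
                 pROC::auc(yy > 0, rr$sps, direction = "<"))))
  expect_error(esl_roc(recs, setNames(rep(1, 5), letters[1:5])),
               "degenerate-ROC")
})

test_that("score and prediction writers emit readable tables", {
  sim <- small_planted(seed = 19)
  pr <- prep_sim(sim)
  fit <- esl_fit(pr$enc, pr$resp, opts = default_opts(pr$lmax))
  sc <- score_model(fit, sim$groups)
  pfx <- tempfile()
  files <- write_scores(sc, pfx)
  gss_back <- read.delim(paste0(pfx, "_gss.tsv"))
  expect_equal(sort(gss_back$group), sort(sc$gss$group))
  summ <- jsonlite::read_json(paste0(pfx, "_summary.json"))
  expect_equal(summ$hss, sc$hss, tolerance = 1e-12)
  preds <- predict(fit, sim$aln)
  fp <- tempfile(fileext = ".tsv")
  write_predictions(preds, fp, pr$resp)
  back <- read.delim(fp)
  expect_equal(nrow(back), nrow(sim$aln))
  expect_true(all(c("sps", "spp", "class", "true_class") %in% names(back)))
})
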