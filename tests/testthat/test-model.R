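# SMOTE, classifier suite, patient-wise CV, metrics, McNemar

toy_blobs <- function(seed, n_per = 100, gap = 7, p = 2) {
  subtracad:::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p, 0), n_per, p),
               matrix(rnorm(n_per * p, gap), n_per, p))
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = rep(0:1, each = n_per))
  })
}

test_that("SMOTE equalizes counts with convex minority combinations", {
  X <- subtracad:::with_seed(1, matrix(rnorm(180), 60, 3))
  y <- c(rep(0, 50), rep(1, 10))
  bal <- smote_balance(X, y, seed = 3)
  expect_equal(as.integer(table(bal$y)), c(50L, 50L))
  expect_equal(nrow(bal$X), 100)
  expect_identical(bal$X[1:60, ], X)            # originals untouched
  # every synthetic point lies on a segment between two minority points
  minority <- X[51:60, ]
  for (i in 61:100) {
    s <- bal$X[i, ]
    on_segment <- FALSE
    for (a in 1:9) for (b in (a + 1):10) {
      d <- minority[b, ] - minority[a, ]
      v <- s - minority[a, ]
      t <- sum(v * d) / sum(d * d)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((v - t * d)^2)) < 1e-9) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
  # already balanced input is returned unchanged
  yb <- rep(0:1, 30)
  balb <- smote_balance(X, yb, seed = 1)
  expect_identical(balb$X, X)
  expect_identical(balb$y, yb)
  expect_error(smote_balance(X, c(rep(0, 59), 1)), "minority")
})

test_that("every classifier spec separates linearly separable data", {
  d <- toy_blobs(2, n_per = 60)
  for (nm in c("LDA", "KNN", "SVM", "RF", "MLP", "ADA", "BAG", "GB",
               "Voting")) {
    fp <- fit_predict(classifier_spec(nm, round = 1, seed = 5), d$X, d$y,
                      d$X)
    expect_equal(mean(fp$labels == d$y), 1, info = nm)
    expect_true(all(fp$scores >= 0 & fp$scores <= 1), info = nm)
  }
  # the network reaches separation with a training schedule sized to the toy
  ann <- build_ann(1, seed = 5, params = list(lr = 0.01, epochs = 300))
  fp <- fit_predict(ann, d$X, d$y, d$X)
  expect_equal(mean(fp$labels == d$y), 1)
})

test_that("soft voting scores equal the mean of member probabilities", {
  d <- toy_blobs(3, n_per = 40)
  mu <- colMeans(d$X); sdv <- apply(d$X, 2, sd)
  Xs <- sweep(sweep(d$X, 2, mu), 2, sdv, "/")
  members <- c("LDA", "KNN", "SVM")
  vspec <- classifier_spec("Voting", round = 1,
                           params = list(members = members), seed = 11)
  vspec$standardize <- FALSE
  v <- fit_predict(vspec, Xs, d$y, Xs)
  member_scores <- sapply(members, function(m) {
    ms <- classifier_spec(m, round = 1,
                          seed = derive_seed(11, "vote", m))
    ms$standardize <- FALSE
    fit_predict(ms, Xs, d$y, Xs)$scores
  })
  expect_equal(v$scores, rowMeans(member_scores))
})

test_that("shuffled labels give chance-level AUC for every spec", {
  aucs <- sapply(c("LDA", "KNN", "SVM", "RF", "MLP", "ADA", "BAG", "GB"),
                 function(nm) {
    mean(sapply(1:6, function(seed) {
      d <- subtracad:::with_seed(seed, {
        X <- matrix(rnorm(240 * 2), 240, 2)
        colnames(X) <- c("f1", "f2")
        list(X = X, y = sample(rep(0:1, 120)))
      })
      tr <- 1:120; te <- 121:240
      spec <- classifier_spec(nm, round = 1, seed = seed,
                              params = if (nm == "GB") list(nrounds = 30)
                                       else list())
      fp <- fit_predict(spec, d$X[tr, ], d$y[tr], d$X[te, ])
      auc_score(d$y[te], fp$scores)
    }))
  })
  expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("ANN specs have the round-specific architecture and seeded init", {
  r1 <- build_ann(1)
  r2 <- build_ann(2)
  expect_length(r1$params$hidden, 5)
  expect_length(r2$params$hidden, 1)
  expect_true(r1$standardize)
  expect_false(r2$standardize)                 # round 2: raw features
  expect_equal(r1$params$batch_size, 128)
  expect_equal(r1$params$lr, 1e-4)
  expect_equal(r1$params$epochs, 100)
  w1 <- mlp_init(10, r1$params$hidden, seed = 7)
  w2 <- mlp_init(10, r1$params$hidden, seed = 7)
  expect_identical(w1, w2)
  expect_false(identical(w1, mlp_init(10, r1$params$hidden, seed = 8)))
  expect_error(build_ann(3), "round")
})

test_that("LOPO produces one clean fold per patient and aces separable cohorts", {
  n_pat <- 10; rois_per <- 6
  patient <- rep(sprintf("P%02d", seq_len(n_pat)), each = rois_per)
  y <- rep(rep(0:1, n_pat / 2), each = rois_per)
  X <- subtracad:::with_seed(4,
    matrix(rnorm(length(y) * 3), ncol = 3) + 5 * y)
  colnames(X) <- paste0("g", 1:3)
  rep_ <- lopo_cv(X, y, patient, classifier_spec("SVM", seed = 2),
                  n_boot = 100)
  expect_length(rep_$folds, n_pat)
  for (fi in seq_len(n_pat)) {
    test_rows <- which(rep_$predictions$fold == fi)
    expect_setequal(unique(patient[test_rows]), rep_$folds[[fi]])
  }
  expect_equal(rep_$accuracy, 100)
  expect_equal(rep_$auc, 1)
  expect_equal(nrow(rep_$predictions), length(y))  # test size never changes
  expect_error(lopo_cv(X, y, rep("P1", length(y)),
                       classifier_spec("LDA")), "2 patients")
})

test_that("patient-grouped k-fold partitions patients evenly and matches LOPO at k = n", {
  n_pat <- 8
  patient <- rep(sprintf("P%02d", seq_len(n_pat)), each = 4)
  y <- rep(rep(0:1, n_pat / 2), each = 4)
  X <- subtracad:::with_seed(5,
    matrix(rnorm(length(y) * 2), ncol = 2) + 4 * y)
  colnames(X) <- c("a", "b")
  rep_k <- kfold_cv(X, y, patient, k = 3, classifier_spec("LDA"),
                    n_boot = 0)
  sizes <- lengths(rep_k$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(unlist(rep_k$folds), unique(patient))
  expect_equal(sum(sizes), n_pat)             # each patient in one test fold
  rep_n <- kfold_cv(X, y, patient, k = n_pat, classifier_spec("LDA"),
                    n_boot = 0)
  expect_length(rep_n$folds, n_pat)
  expect_true(all(lengths(rep_n$folds) == 1))
  expect_error(kfold_cv(X, y, patient, k = 20, classifier_spec("LDA")),
               "exceed")
})

test_that("SMOTE inflates training folds only", {
  patient <- rep(sprintf("P%02d", 1:6), each = 8)
  y <- rep(c(0, 0, 0, 1, 1, 0, 0, 1), 6)
  X <- subtracad:::with_seed(6,
    matrix(rnorm(length(y) * 2), ncol = 2) + 3 * y)
  colnames(X) <- c("a", "b")
  rep_ <- lopo_cv(X, y, patient, classifier_spec("LDA"), smote = TRUE,
                  n_boot = 0)
  expect_equal(nrow(rep_$predictions), length(y))
  expect_true(all(!is.na(rep_$predictions$label)))
})

test_that("confusion metrics reproduce the printed worked example", {
  m <- metrics_from_confusion(tp = 97, fn = 6, tn = 86, fp = 4)
  expect_equal(round(m$sensitivity, 2), 94.17)
  expect_equal(round(m$specificity, 2), 95.56)
  expect_equal(round(m$accuracy, 2), 94.82)
  expect_equal(round(m$mcc, 3), 0.896)
  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
})

test_that("pooled metrics match a brute-force tally and degrade to NA safely", {
  for (seed in 1:50) {
    d <- subtracad:::with_seed(seed, {
      n <- sample(5:40, 1)
      list(truth = sample(0:1, n, replace = TRUE),
           labels = sample(0:1, n, replace = TRUE),
           scores = runif(n))
    })
    if (length(unique(d$truth)) < 2) next
    m <- compute_metrics(d$truth, d$labels, d$scores, n_boot = 0)
    expect_equal(m$sensitivity,
                 100 * sum(d$truth == 1 & d$labels == 1) / sum(d$truth == 1))
    expect_equal(m$specificity,
                 100 * sum(d$truth == 0 & d$labels == 0) / sum(d$truth == 0))
    expect_equal(m$accuracy, 100 * mean(d$truth == d$labels))
  }
  one_class <- compute_metrics(c(1, 1, 1), c(1, 0, 1), n_boot = 0)
  expect_true(is.na(one_class$specificity))
  expect_false(is.nan(one_class$mcc))
})

test_that("AUC matches an independent ROC implementation and monotone invariance", {
  for (seed in 1:10) {
    d <- subtracad:::with_seed(seed, {
      n <- 60
      truth <- sample(0:1, n, replace = TRUE, prob = c(0.4, 0.6))
      list(truth = truth, scores = runif(n) + 0.4 * truth)
    })
    if (length(unique(d$truth)) < 2) next
    ours <- auc_score(d$truth, d$scores)
    ref <- as.numeric(pROC::auc(pROC::roc(d$truth, d$scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-9)
    expect_equal(auc_score(d$truth, qlogis(pmin(pmax(d$scores / 2, 1e-6),
                                                1 - 1e-6))),
                 ours)   # strictly monotone transform
  }
})

test_that("McNemar handles exact and approximate branches", {
  truth <- rep(1, 10)
  same <- mcnemar_compare(rep(1, 10), rep(1, 10), truth)
  expect_equal(same$p_value, 1)
  expect_equal(same$b + same$c, 0)
  ex <- mcnemar_compare(rep(1, 10), rep(0, 10), truth)
  expect_equal(ex$b, 10); expect_equal(ex$c, 0)
  expect_equal(ex$p_value, 2 * 0.5^10)
  expect_equal(ex$method, "exact")
  # chi-square branch tracks the exact binomial at moderate counts
  for (seed in 1:10) {
    b <- subtracad:::with_seed(seed, sample(8:22, 1))
    c_ <- 30 - b
    truth30 <- rep(1, 30)
    a_pred <- c(rep(1, b), rep(0, c_))
    b_pred <- c(rep(0, b), rep(1, c_))
    approx <- mcnemar_compare(a_pred, b_pred, truth30, exact_threshold = 0)
    exact <- mcnemar_compare(a_pred, b_pred, truth30, exact_threshold = 30)
    expect_lt(abs(approx$p_value - exact$p_value), 0.02)
  }
  expect_error(mcnemar_compare(1:3, 1:2, 1:3), "length")
  pairs <- mcnemar_all_pairs(list(A = rep(1, 10), B = rep(0, 10),
                                  C = rep(1, 10)), truth)
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$p_holm >= pairs$p_value))
})

test_that("a voting ensemble finds planted signal in a synthetic cohort", {
  n_pat <- 24; rois_per <- 4; p <- 12
  patient <- rep(sprintf("P%02d", seq_len(n_pat)), each = rois_per)
  y <- rep(rep(0:1, n_pat / 2), each = rois_per)
  X <- subtracad:::with_seed(8, {
    X <- matrix(rnorm(length(y) * p), ncol = p)
    X[, 1:3] <- X[, 1:3] + 1.5 * y
    X
  })
  colnames(X) <- sprintf("F%02d", seq_len(p))
  spec <- classifier_spec("Voting", round = 1, seed = 3,
                          params = list(members = c("KNN", "SVM", "ADA")))
  rep_ <- lopo_cv(X, y, patient, spec, n_boot = 0)
  expect_gt(rep_$auc, 0.8)
})
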