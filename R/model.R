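# two-round classification: SMOTE balancing, classifier suite, patient-wise
# cross-validation, and the full evaluation metric set
#
# Round 1 separates candidate regions into normal tissue vs. true masses;
# round 2 separates true masses into benign vs. malignant. Feature
# selection, standardization, SMOTE and fitting are all re-done inside each
# training fold, so no test-fold information leaks into the fitted model.

#' SMOTE class balancing
#'
#' Equalizes class counts by synthesizing minority samples as convex
#' combinations `x_i + u * (x_j - x_i)` of a minority sample and one of its
#' `k_neighbors` nearest minority neighbors (`u ~ U(0, 1)`). Apply to
#' training data only. An already balanced input is returned unchanged.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (two classes).
#' @param k_neighbors number of minority neighbors to draw from.
#' @param seed integer seed.
#' @return list with balanced `X` and `y` (original rows first).
#' @export
smote_balance <- function(X, y, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  tab <- table(y)
  if (length(tab) != 2) stop("y must have exactly two classes", call. = FALSE)
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  minority <- names(tab)[which.min(tab)]
  need <- abs(diff(tab))
  idx_min <- which(y == minority)
  if (length(idx_min) < 2)
    stop("balancing error: minority class has fewer than 2 samples",
         call. = FALSE)
  Xm <- X[idx_min, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  k <- min(k_neighbors, nrow(Xm) - 1)
  nn <- do.call(rbind, lapply(seq_len(nrow(Xm)),
                              function(r) order(D[r, ])[seq_len(k)]))
  synth <- with_seed(seed, {
    i <- sample.int(nrow(Xm), need, replace = TRUE)
    j <- nn[cbind(i, sample.int(k, need, replace = TRUE))]
    u <- runif(need)
    Xm[i, , drop = FALSE] + u * (Xm[j, , drop = FALSE] - Xm[i, , drop = FALSE])
  })
  y_out <- c(y, rep(minority, need))
  if (is.factor(y)) y_out <- factor(y_out, levels = levels(y))
  list(X = rbind(X, synth), y = y_out)
}

#' Classifier specification
#'
#' Builds a spec for one of the suite's classifiers with round-specific
#' defaults: kNN uses k = 11 in round 1 and k = 5 in round 2 (nearest-
#' neighbor tie-break); the soft-voting ensemble combines kNN, SVM, MLP,
#' AdaBoost and gradient boosting in round 1 and LDA, random forest and
#' gradient boosting in round 2; the SVM uses an RBF kernel; LDA uses equal
#' priors. Any default can be overridden through `params`.
#'
#' @param name one of `"LDA"`, `"KNN"`, `"SVM"`, `"RF"`, `"MLP"`, `"ADA"`,
#'   `"BAG"`, `"GB"`, `"Voting"`, `"ANN"`.
#' @param round classification round (1 = normal vs. mass, 2 = benign vs.
#'   malignant); selects round-specific defaults.
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed for stochastic fitters.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("LDA", "KNN", "SVM", "RF", "MLP", "ADA",
                                     "BAG", "GB", "Voting", "ANN"),
                            round = 1, params = list(), seed = 1) {
  name <- match.arg(name)
  defaults <- switch(name,
    LDA = list(),
    KNN = list(k = if (round == 1) 11 else 5),
    SVM = list(cost = 1, gamma = NULL),
    RF = list(ntree = 300),
    MLP = list(size = 16, decay = 1e-3, maxit = 300),
    ADA = list(n_rounds = 50, maxdepth = 1),
    BAG = list(n_bags = 25),
    GB = list(nrounds = 100, max_depth = 3, eta = 0.1),
    Voting = list(members = if (round == 1)
      c("KNN", "SVM", "MLP", "ADA", "GB") else c("LDA", "RF", "GB"),
      soft = TRUE),
    ANN = list(hidden = if (round == 1) c(32, 24, 16, 12, 8) else c(16),
               lr = 1e-4, epochs = 100, batch_size = 128, dropout = 0.2,
               noise_sd = 0.05, batchnorm = TRUE, val_frac = 0.15,
               patience = 10))
  structure(list(name = name, round = round,
                 params = modifyList(defaults, params),
                 standardize = !(name == "ANN" && round == 2),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' ANN specification for a classification round
#'
#' Round 1 uses five hidden layers, round 2 a single hidden layer; ReLU
#' hidden activations with a softmax output, Adam optimization (batch size
#' 128, learning rate 1e-4, up to 100 epochs), dropout, batch normalization
#' and input Gaussian noise for regularization, and early stopping on
#' validation loss. In round 2 the features are deliberately not
#' standardized.
#'
#' @param round 1 or 2.
#' @param seed integer seed.
#' @param params optional hyperparameter overrides.
#' @return A `classifier_spec`.
#' @export
build_ann <- function(round, seed = 1, params = list()) {
  if (!round %in% c(1, 2)) stop("round must be 1 or 2", call. = FALSE)
  classifier_spec("ANN", round = round, params = params, seed = seed)
}

# deterministic kNN with nearest-neighbor tie-break
knn_fit_predict <- function(X_train, y, X_test, k) {
  k <- min(k, nrow(X_train))
  scores <- numeric(nrow(X_test))
  labels <- integer(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    d <- sqrt(colSums((t(X_train) - X_test[i, ])^2))
    ord <- order(d)
    nb <- ord[seq_len(k)]
    s <- mean(y[nb])
    lab <- if (s > 0.5) 1L else if (s < 0.5) 0L else y[ord[1]]  # nearest breaks tie
    scores[i] <- s
    labels[i] <- lab
  }
  list(labels = labels, scores = scores)
}

# AdaBoost.M1 with rpart stumps
ada_fit <- function(X, y, n_rounds, maxdepth, seed) {
  df <- as.data.frame(X)
  df$.y <- factor(y)
  w <- rep(1 / nrow(df), nrow(df))
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, minsplit = 2, cp = 0,
                               xval = 0)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
      pred <- as.integer(as.character(predict(fit, df, type = "class")))
      err <- sum(w * (pred != y)) / sum(w)
      if (err >= 0.5) break
      err <- max(err, 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      w <- w * exp(alpha * ifelse(pred != y, 1, -1))
      w <- w / sum(w)
      stumps[[m]] <- fit
      alphas[m] <- alpha
      if (err < 1e-9) break
    }
  })
  list(stumps = stumps, alphas = alphas)
}

ada_predict <- function(model, X_test) {
  df <- as.data.frame(X_test)
  F <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- as.integer(as.character(predict(model$stumps[[m]], df,
                                            type = "class")))
    F <- F + model$alphas[m] * ifelse(pred == 1, 1, -1)
  }
  1 / (1 + exp(-2 * F))
}

#' Fit a classifier spec and predict on test samples
#'
#' Features are standardized with training-fold statistics unless the spec
#' opts out (the round-2 ANN). Scores are positive-class probabilities in
#' \[0, 1\]; hard labels use a 0.5 threshold (kNN breaks exact ties by the
#' nearest neighbor). Deterministic given the spec's seed.
#'
#' @param spec a [classifier_spec()].
#' @param X_train,y_train training features and binary labels.
#' @param X_test test features (no test information enters the fit).
#' @return list with `labels` (0/1 integers) and `scores` (probabilities).
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  y <- as.integer(factor(y_train, levels = sort(unique(y_train)))) - 1L
  if (length(unique(y)) != 2)
    stop("training labels must contain both classes", call. = FALSE)
  if (spec$standardize) {
    mu <- colMeans(X_train)
    sdv <- apply(X_train, 2, sd)
    sdv[sdv < 1e-12] <- 1
    X_train <- sweep(sweep(X_train, 2, mu), 2, sdv, "/")
    X_test <- sweep(sweep(X_test, 2, mu), 2, sdv, "/")
  }
  p <- spec$params
  scores <- switch(spec$name,
    LDA = {
      keep <- apply(X_train, 2, function(x) sd(x) > 1e-10)
      fit <- MASS::lda(X_train[, keep, drop = FALSE], grouping = factor(y),
                       prior = c(0.5, 0.5))
      unname(predict(fit, X_test[, keep, drop = FALSE])$posterior[, "1"])
    },
    KNN = return(knn_fit_predict(X_train, y, X_test, p$k)),
    SVM = {
      fit <- with_seed(spec$seed,
        e1071::svm(X_train, factor(y), kernel = "radial", cost = p$cost,
                   gamma = if (is.null(p$gamma)) 1 / ncol(X_train) else p$gamma,
                   probability = TRUE))
      pr <- predict(fit, X_test, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    },
    RF = {
      fit <- with_seed(spec$seed,
        randomForest::randomForest(X_train, factor(y), ntree = p$ntree))
      unname(predict(fit, X_test, type = "prob")[, "1"])
    },
    MLP = {
      fit <- with_seed(spec$seed,
        nnet::nnet(X_train, y, size = p$size, decay = p$decay,
                   maxit = p$maxit, entropy = TRUE, trace = FALSE,
                   MaxNWts = 1e5))
      as.numeric(predict(fit, X_test))
    },
    ADA = {
      model <- ada_fit(X_train, y, p$n_rounds, p$maxdepth, spec$seed)
      ada_predict(model, X_test)
    },
    BAG = {
      df <- as.data.frame(X_train); df$.y <- factor(y)
      dft <- as.data.frame(X_test)
      votes <- with_seed(spec$seed, {
        v <- matrix(0, nrow(dft), p$n_bags)
        for (bnum in seq_len(p$n_bags)) {
          idx <- sample.int(nrow(df), replace = TRUE)
          fit <- rpart::rpart(.y ~ ., data = df[idx, ], method = "class",
                              control = rpart::rpart.control(cp = 0,
                                                             minsplit = 4,
                                                             xval = 0))
          v[, bnum] <- predict(fit, dft, type = "prob")[, "1"]
        }
        v
      })
      rowMeans(votes)
    },
    GB = {
      dtrain <- xgboost::xgb.DMatrix(X_train, label = y, nthread = 1)
      fit <- with_seed(spec$seed,
        xgboost::xgb.train(params = list(objective = "binary:logistic",
                                         max_depth = p$max_depth,
                                         eta = p$eta, nthread = 1),
                           data = dtrain, nrounds = p$nrounds, verbose = 0))
      as.numeric(predict(fit, xgboost::xgb.DMatrix(X_test, nthread = 1)))
    },
    Voting = {
      member_scores <- vapply(p$members, function(m) {
        mspec <- classifier_spec(m, round = spec$round,
                                 seed = derive_seed(spec$seed, "vote", m))
        mspec$standardize <- FALSE   # already standardized here
        fit_predict(mspec, X_train, y, X_test)$scores
      }, numeric(nrow(X_test)))
      if (is.null(dim(member_scores)))
        member_scores <- matrix(member_scores, nrow = 1)
      rowMeans(member_scores)      # soft vote: mean of member probabilities
    },
    ANN = {
      fit <- mlp_train(X_train, y, hidden = p$hidden, lr = p$lr,
                       epochs = p$epochs, batch_size = p$batch_size,
                       dropout = p$dropout, noise_sd = p$noise_sd,
                       batchnorm = p$batchnorm, val_frac = p$val_frac,
                       patience = p$patience, seed = spec$seed)
      predict(fit, X_test)
    },
    stop("unknown classifier spec: ", spec$name, call. = FALSE))
  list(labels = as.integer(scores >= 0.5), scores = scores)
}

# normalize binary labels to 0/1 integers without collapsing single-class
# vectors (numeric input must already be 0/1)
as_binary <- function(y) {
  if (is.numeric(y) || is.logical(y)) {
    if (!all(y %in% c(0, 1)))
      stop("labels must be 0/1 or a two-level factor", call. = FALSE)
    as.integer(y)
  } else {
    f <- factor(y)
    if (nlevels(f) > 2) stop("labels must be binary", call. = FALSE)
    as.integer(f) - 1L
  }
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity and accuracy in percent, Matthews correlation
#' coefficient and Cohen's kappa from the four confusion counts. Undefined
#' denominators give `NA`, never `NaN` propagation.
#'
#' @param tp,fn,tn,fp nonnegative confusion counts.
#' @return Named list of metrics.
#' @export
#' @examples
#' m <- metrics_from_confusion(tp = 97, fn = 6, tn = 86, fp = 4)
#' round(m$sensitivity, 2)   # 94.17
#' round(m$mcc, 3)           # 0.896
metrics_from_confusion <- function(tp, fn, tn, fp) {
  stopifnot(all(c(tp, fn, tn, fp) >= 0), tp + fn + tn + fp > 0)
  total <- tp + fn + tn + fp
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- 100 * safe_div(tp, tp + fn)
  spec <- 100 * safe_div(tn, tn + fp)
  acc <- 100 * (tp + tn) / total
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  po <- (tp + tn) / total
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / total^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = sens, specificity = spec, accuracy = acc,
       mcc = mcc, kappa = kappa)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC via the rank (Mann-Whitney) formulation, which handles
#' tied scores exactly and is invariant under strictly monotone transforms
#' of the scores.
#'
#' @param truth binary truth (0/1).
#' @param scores positive-class scores.
#' @return AUC in \[0, 1\], or `NA` if one class is absent.
#' @export
auc_score <- function(truth, scores) {
  truth <- as_binary(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full evaluation report from pooled predictions
#'
#' Confusion counts, sensitivity/specificity/accuracy (%), AUC, MCC,
#' Cohen's kappa, and seeded bootstrap percentile 95% confidence intervals.
#'
#' @param truth binary truth (0/1).
#' @param labels predicted hard labels (0/1).
#' @param scores optional positive-class scores (for AUC).
#' @param n_boot bootstrap resamples for the CIs (0 disables).
#' @param seed bootstrap seed.
#' @return list of class `evaluation_report`.
#' @export
compute_metrics <- function(truth, labels, scores = NULL, n_boot = 2000,
                            seed = 1) {
  truth <- as_binary(truth)
  labels <- as_binary(labels)
  stopifnot(length(truth) == length(labels))
  tp <- sum(truth == 1 & labels == 1)
  fn <- sum(truth == 1 & labels == 0)
  tn <- sum(truth == 0 & labels == 0)
  fp <- sum(truth == 0 & labels == 1)
  m <- metrics_from_confusion(tp, fn, tn, fp)
  m$auc <- if (is.null(scores)) NA_real_ else auc_score(truth, scores)
  m$n <- length(truth)
  if (n_boot > 0 && length(truth) >= 2) {
    bs <- with_seed(seed, {
      stats <- matrix(NA_real_, n_boot, 4,
                      dimnames = list(NULL, c("sensitivity", "specificity",
                                              "accuracy", "auc")))
      for (b in seq_len(n_boot)) {
        idx <- sample.int(length(truth), replace = TRUE)
        t2 <- truth[idx]; l2 <- labels[idx]
        tp2 <- sum(t2 == 1 & l2 == 1); fn2 <- sum(t2 == 1 & l2 == 0)
        tn2 <- sum(t2 == 0 & l2 == 0); fp2 <- sum(t2 == 0 & l2 == 1)
        stats[b, 1] <- if (tp2 + fn2 > 0) 100 * tp2 / (tp2 + fn2) else NA
        stats[b, 2] <- if (tn2 + fp2 > 0) 100 * tn2 / (tn2 + fp2) else NA
        stats[b, 3] <- 100 * (tp2 + tn2) / length(idx)
        stats[b, 4] <- if (!is.null(scores)) auc_score(t2, scores[idx]) else NA
      }
      stats
    })
    m$ci <- apply(bs, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  }
  structure(m, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("Evaluation report (n = %d)\n",
                     "  TP %d  FN %d  TN %d  FP %d\n",
                     "  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
                     "  AUC %.3f  MCC %.3f  kappa %.3f\n"),
              x$n, x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity,
              x$accuracy, x$auc, x$mcc, x$kappa))
  invisible(x)
}

# shared grouped-CV engine
grouped_cv <- function(X, y, patient, spec, folds, select_cfg = NULL,
                       smote = TRUE, seed = 1, n_boot = 2000) {
  X <- as.matrix(X)
  y <- as_binary(y)
  pred_label <- rep(NA_integer_, length(y))
  pred_score <- rep(NA_real_, length(y))
  fold_id <- rep(NA_integer_, length(y))
  skipped <- character(0)
  selections <- list()
  for (fi in seq_along(folds)) {
    test_pat <- folds[[fi]]
    test_idx <- which(patient %in% test_pat)
    train_idx <- setdiff(seq_along(y), test_idx)
    fold_id[test_idx] <- fi
    if (length(unique(y[train_idx])) < 2) {
      skipped <- c(skipped, paste(test_pat, collapse = "+"))
      warning("skipping fold with single-class training data: ",
              paste(test_pat, collapse = "+"), call. = FALSE)
      next
    }
    Xtr <- X[train_idx, , drop = FALSE]
    ytr <- y[train_idx]
    Xte <- X[test_idx, , drop = FALSE]
    if (!is.null(select_cfg)) {
      rankings <- rank_all_methods(Xtr, ytr,
                                   seed = derive_seed(seed, "select", fi))
      sel <- if (!is.null(select_cfg$target_size))
        tune_consensus_k(rankings, select_cfg$target_size,
                         select_cfg$quorum %||% 5)
      else majority_select(rankings, select_cfg$K,
                           select_cfg$quorum %||% 5)
      if (length(sel$selected) >= 2) {
        Xtr <- Xtr[, sel$selected, drop = FALSE]
        Xte <- Xte[, sel$selected, drop = FALSE]
      }
      selections[[fi]] <- sel
    }
    if (smote && length(unique(ytr)) == 2 && min(table(ytr)) >= 2 &&
        diff(range(table(ytr))) > 0) {
      bal <- smote_balance(Xtr, ytr, seed = derive_seed(seed, "smote", fi))
      Xtr <- bal$X; ytr <- as.integer(bal$y)
    }
    fp <- fit_predict(spec, Xtr, ytr, Xte)
    pred_label[test_idx] <- fp$labels
    pred_score[test_idx] <- fp$scores
  }
  ok <- !is.na(pred_label)
  rep_out <- compute_metrics(y[ok], pred_label[ok], pred_score[ok],
                             n_boot = n_boot, seed = derive_seed(seed, "boot"))
  rep_out$predictions <- data.frame(patient = patient, truth = y,
                                    label = pred_label, score = pred_score,
                                    fold = fold_id)
  rep_out$folds <- folds
  rep_out$skipped_folds <- skipped
  rep_out$selections <- selections
  rep_out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient; all of a patient's ROIs are held out together, so
#' no patient contributes to both training and test. Feature selection,
#' standardization, SMOTE and fitting are re-done inside each training
#' fold; test predictions are pooled before computing metrics.
#'
#' @param X feature matrix (rows = ROIs, named columns).
#' @param y binary labels per ROI.
#' @param patient patient identifier per ROI.
#' @param spec a [classifier_spec()].
#' @param select_cfg optional consensus-selection config: list with either
#'   `K` or `target_size`, plus optional `quorum`.
#' @param smote balance training folds with SMOTE.
#' @param seed seed fanned out to selection, SMOTE, fitting and bootstrap.
#' @param n_boot bootstrap resamples for CIs.
#' @return An `evaluation_report` with per-ROI predictions and fold
#'   bookkeeping.
#' @export
lopo_cv <- function(X, y, patient, spec, select_cfg = NULL, smote = TRUE,
                    seed = 1, n_boot = 2000) {
  pats <- unique(patient)
  if (length(pats) < 2) stop("need at least 2 patients", call. = FALSE)
  folds <- as.list(pats)
  grouped_cv(X, y, patient, spec, folds, select_cfg, smote, seed, n_boot)
}

#' Patient-grouped k-fold cross-validation
#'
#' Folds partition patients, never ROIs; fold sizes differ by at most one
#' patient. `k` equal to the number of patients reproduces the
#' leave-one-patient-out fold structure.
#'
#' @inheritParams lopo_cv
#' @param k number of folds (<= number of patients).
#' @return An `evaluation_report`.
#' @export
kfold_cv <- function(X, y, patient, k, spec, select_cfg = NULL, smote = TRUE,
                     seed = 1, n_boot = 2000) {
  pats <- unique(patient)
  if (k > length(pats))
    stop("k must not exceed the number of patients", call. = FALSE)
  shuffled <- with_seed(derive_seed(seed, "kfold"), sample(pats))
  folds <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  grouped_cv(X, y, patient, spec, unname(folds), select_cfg, smote, seed,
             n_boot)
}

#' McNemar comparison of two classifiers
#'
#' Counts discordant pairs (`b`: A correct, B wrong; `c`: A wrong, B
#' correct) on identical samples. Small discordant totals use the exact
#' two-sided binomial test; larger ones the chi-square approximation with
#' continuity correction.
#'
#' @param preds_a,preds_b predicted labels from the two classifiers.
#' @param truth true labels (same length).
#' @param exact_threshold maximum `b + c` for the exact binomial branch.
#' @return list with `b`, `c`, `statistic`, `p_value`, `method`.
#' @export
#' @examples
#' # b = 10, c = 0: exact p = 2 * 0.5^10
#' truth <- rep(1, 10)
#' mcnemar_compare(rep(1, 10), rep(0, 10), truth)$p_value
mcnemar_compare <- function(preds_a, preds_b, truth, exact_threshold = 25) {
  if (length(preds_a) != length(preds_b) ||
      length(preds_a) != length(truth))
    stop("prediction vectors must have equal length", call. = FALSE)
  ca <- preds_a == truth
  cb <- preds_b == truth
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  n <- b + c_
  if (n == 0)
    return(list(b = b, c = c_, statistic = 0, p_value = 1, method = "exact"))
  if (n <= exact_threshold) {
    p <- min(1, 2 * pbinom(min(b, c_), n, 0.5))
    list(b = b, c = c_, statistic = min(b, c_), p_value = p,
         method = "exact")
  } else {
    stat <- max(abs(b - c_) - 1, 0)^2 / n
    list(b = b, c = c_, statistic = stat,
         p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "chisq")
  }
}

#' All-pairs extended McNemar comparison with Holm correction
#'
#' Compares every pair of classifiers on identical samples and adjusts the
#' p-values with Holm's step-down method.
#'
#' @param pred_list named list of predicted-label vectors.
#' @param truth true labels.
#' @param exact_threshold passed to [mcnemar_compare()].
#' @return data.frame of pairwise comparisons with raw and Holm-adjusted
#'   p-values.
#' @export
mcnemar_all_pairs <- function(pred_list, truth, exact_threshold = 25) {
  nm <- names(pred_list)
  pairs <- utils::combn(seq_along(pred_list), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    r <- mcnemar_compare(pred_list[[a]], pred_list[[b]], truth,
                         exact_threshold)
    data.frame(classifier_a = nm[a], classifier_b = nm[b], b = r$b, c = r$c,
               statistic = r$statistic, p_value = r$p_value,
               method = r$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}
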