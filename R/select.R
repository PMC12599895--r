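# consensus feature selection: 8 ranking methods + majority rule
#
# Filter set spanning univariate and multivariate criteria: t-test score,
# Wilcoxon rank-sum score, mutual information, chi-square on quantile-binned
# features, Fisher score, ReliefF, minimum-redundancy-maximum-relevance, and
# random-forest impurity importance. Rankings are deterministic given the
# data and seed; ties break by catalog order. A feature is selected when it
# appears in the top-K of at least `quorum` of the 8 rankings.

#' The 8 ranking method names
#' @return Character vector of method identifiers.
#' @export
ranking_methods <- function() {
  c("ttest", "wilcoxon", "mutinfo", "chisq", "fisher", "relieff", "mrmr",
    "rf_importance")
}

# equal-frequency binning to `bins` levels; discrete columns with few
# unique values keep one bin per value (constant columns -> single bin)
quantile_bin <- function(x, bins = 5) {
  u <- unique(x)
  if (length(u) <= bins) return(as.integer(factor(x, levels = sort(u))))
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2) return(rep(1L, length(x)))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

mutual_information <- function(xb, yb) {
  tab <- table(xb, yb)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

score_ttest <- function(X, y) {
  apply(X, 2, function(x) {
    x0 <- x[y == 0]; x1 <- x[y == 1]
    d <- abs(mean(x1) - mean(x0))
    if (d < 1e-12) return(0)                  # constant or uninformative
    s <- sqrt(var(x0) / length(x0) + var(x1) / length(x1))
    d / max(s, 1e-12)
  })
}

score_wilcoxon <- function(X, y) {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  apply(X, 2, function(x) {
    r <- rank(x)
    w <- sum(r[y == 1])
    ew <- n1 * (length(x) + 1) / 2
    sdw <- sqrt(n0 * n1 * (length(x) + 1) / 12)
    if (sdw < 1e-12) 0 else abs(w - ew) / sdw
  })
}

score_mutinfo <- function(X, y, bins = 5) {
  apply(X, 2, function(x) mutual_information(quantile_bin(x, bins), y))
}

score_chisq <- function(X, y, bins = 5) {
  apply(X, 2, function(x) {
    xb <- quantile_bin(x, bins)
    if (length(unique(xb)) < 2) return(0)
    suppressWarnings(unname(chisq.test(table(xb, y))$statistic))
  })
}

score_fisher <- function(X, y) {
  apply(X, 2, function(x) {
    x0 <- x[y == 0]; x1 <- x[y == 1]
    d2 <- (mean(x1) - mean(x0))^2
    if (d2 < 1e-24) return(0)                 # constant or uninformative
    d2 / max(var(x0) + var(x1), 1e-12)
  })
}

score_relieff <- function(X, y, k = 10) {
  n <- nrow(X); p <- ncol(X)
  rngs <- apply(X, 2, function(x) max(diff(range(x)), 1e-12))
  Xs <- sweep(X, 2, rngs, "/")
  D <- as.matrix(dist(Xs))
  diag(D) <- Inf
  W <- numeric(p)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_c <- which(y != y[i])
    if (length(same) == 0 || length(diff_c) == 0) next
    hits <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    miss <- diff_c[order(D[i, diff_c])][seq_len(min(k, length(diff_c)))]
    dh <- abs(sweep(Xs[hits, , drop = FALSE], 2, Xs[i, ]))
    dm <- abs(sweep(Xs[miss, , drop = FALSE], 2, Xs[i, ]))
    W <- W - colMeans(dh) / n + colMeans(dm) / n
  }
  W
}

score_mrmr <- function(X, y, bins = 5) {
  p <- ncol(X)
  Xb <- apply(X, 2, quantile_bin, bins = bins)
  rel <- vapply(seq_len(p), function(j) mutual_information(Xb[, j], y),
                numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red <- matrix(NA_real_, p, p)
  order_out <- integer(p)
  for (step in seq_len(p)) {
    if (length(selected) == 0) {
      j <- remaining[which.max(rel[remaining])]
    } else {
      crit <- vapply(remaining, function(r) {
        for (s in selected) {
          if (is.na(red[r, s])) {
            red[r, s] <<- mutual_information(Xb[, r], Xb[, s])
            red[s, r] <<- red[r, s]
          }
        }
        rel[r] - mean(red[r, selected])
      }, numeric(1))
      j <- remaining[which.max(crit)]
    }
    order_out[step] <- j
    selected <- c(selected, j)
    remaining <- setdiff(remaining, j)
  }
  # score: earlier greedy pick = higher score
  score <- numeric(p)
  score[order_out] <- rev(seq_len(p))
  score
}

score_rf <- function(X, y, seed, ntree = 200) {
  with_seed(seed, {
    fit <- randomForest::randomForest(x = as.data.frame(X), y = factor(y),
                                      ntree = ntree)
    unname(fit$importance[, "MeanDecreaseGini"])
  })
}

#' Rank features by one of the 8 methods
#'
#' Produces a complete ranking of all columns of `X` (best first). Constant
#' features get the worst score under variance-dependent methods. Ties break
#' by catalog (column) order, so rankings are deterministic given the data
#' and seed.
#'
#' @param X numeric feature matrix (rows = ROIs) with column names; use
#'   within-training-fold data only.
#' @param y binary labels (0/1 or two-level factor), no missing values.
#' @param method one of [ranking_methods()].
#' @param seed seed for the stochastic methods (random forest).
#' @return list of class `feature_ranking`: `method`, `ranking` (ordered
#'   feature names, best first), `scores` (named, higher = better).
#' @export
rank_features <- function(X, y, method = ranking_methods(), seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  y <- as.integer(factor(y)) - 1L
  if (length(unique(y)) != 2) stop("y must be binary", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  scores <- switch(method,
    ttest = score_ttest(X, y),
    wilcoxon = score_wilcoxon(X, y),
    mutinfo = score_mutinfo(X, y),
    chisq = score_chisq(X, y),
    fisher = score_fisher(X, y),
    relieff = score_relieff(X, y),
    mrmr = score_mrmr(X, y),
    rf_importance = score_rf(X, y, seed))
  scores <- setNames(as.numeric(scores), colnames(X))
  ord <- order(-scores, seq_along(scores))
  structure(list(method = method, ranking = colnames(X)[ord],
                 scores = scores), class = "feature_ranking")
}

#' Rank with all 8 methods
#' @inheritParams rank_features
#' @param methods methods to run (default all 8).
#' @return Named list of `feature_ranking`, one per method.
#' @export
rank_all_methods <- function(X, y, seed = 1, methods = ranking_methods()) {
  setNames(lapply(methods, function(m)
    rank_features(X, y, m, seed = derive_seed(seed, "rank", m))), methods)
}

#' Majority-rule consensus selection
#'
#' A feature is selected iff it appears in the top-`K` of at least `quorum`
#' of the supplied rankings. The result is a set: invariant to the order in
#' which rankings are supplied.
#'
#' @param rankings list of exactly 8 `feature_ranking` objects over the same
#'   catalog (any number is accepted; the study design uses 8).
#' @param K top-K depth per ranking.
#' @param quorum minimum number of rankings that must list the feature in
#'   their top-K (default 5 of 8).
#' @return list of class `consensus_selection`: `selected` (catalog order),
#'   `votes` (named counts), `K`, `quorum`.
#' @export
majority_select <- function(rankings, K, quorum = 5) {
  catalogs <- lapply(rankings, function(r) sort(r$ranking))
  if (length(unique(catalogs)) != 1)
    stop("rankings cover inconsistent feature catalogs", call. = FALSE)
  catalog <- rankings[[1]]$ranking[order(rankings[[1]]$ranking)]
  votes <- setNames(integer(length(catalog)), catalog)
  for (r in rankings) {
    top <- head(r$ranking, K)
    votes[top] <- votes[top] + 1L
  }
  # report votes in the catalog (column) order of the first ranking's scores
  votes <- votes[names(rankings[[1]]$scores)]
  structure(list(selected = names(votes)[votes >= quorum], votes = votes,
                 K = K, quorum = quorum), class = "consensus_selection")
}

#' Tune the top-K depth so the consensus has a target size
#'
#' Scans K and returns the consensus whose selected-set size is closest to
#' `target_size` (smallest K on ties). Used to reproduce round-specific
#' selection sizes (19 features for the detection round, 17 for the
#' benign/malignant round).
#'
#' @param rankings list of `feature_ranking`.
#' @param target_size desired number of selected features.
#' @param quorum majority quorum.
#' @return A `consensus_selection`.
#' @export
tune_consensus_k <- function(rankings, target_size, quorum = 5) {
  p <- length(rankings[[1]]$ranking)
  best <- NULL; best_gap <- Inf
  for (K in seq_len(p)) {
    sel <- majority_select(rankings, K, quorum)
    gap <- abs(length(sel$selected) - target_size)
    if (gap < best_gap) { best <- sel; best_gap <- gap }
    if (length(sel$selected) >= target_size && gap == 0) break
  }
  best
}
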