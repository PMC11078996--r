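# independent oracles, deliberately naive: pixel counting, O(n^2)
# pairwise AUC, exhaustive-coalition Shapley values

# pairwise Mann-Whitney AUC by explicit enumeration
aucBruteForce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# IoU by direct pixel counting
iouBruteForce <- function(a, b, cls) {
  ai <- a == cls; bi <- b == cls
  sum(ai & bi) / sum(ai | bi)
}

# exhaustive-coalition interventional Shapley values for a booster:
# v(S) = mean over reference rows of the margin with features in S taken
# from x; Shapley weights summed over all 2^p coalitions
shapleyBruteForce <- function(booster, x, refs) {
  p <- length(x)
  stopifnot(p <= 12)
  nS <- 2^p
  frank <- vector("list", nS)
  for (S in 0:(nS - 1)) {
    inS <- as.logical(bitwAnd(S, 2^(0:(p - 1))))
    R <- refs
    if (any(inS))
      R[, inS] <- matrix(x[inS], nrow(refs), sum(inS), byrow = TRUE)
    frank[[S + 1]] <- R
  }
  big <- do.call(rbind, frank)
  m <- predict(booster, xgboost::xgb.DMatrix(big), outputmargin = TRUE)
  v <- colMeans(matrix(m, nrow(refs)))
  phi <- numeric(p)
  fact <- factorial(0:p)
  for (i in seq_len(p)) {
    for (S in 0:(nS - 1)) {
      inS <- as.logical(bitwAnd(S, 2^(0:(p - 1))))
      if (inS[i]) next
      s <- sum(inS)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]
      phi[i] <- phi[i] + w * (v[S + 2^(i - 1) + 1] - v[S + 1])
    }
  }
  names(phi) <- names(x)
  phi
}

# small xgboost model on iid features, for attribution tests
fitToyBooster <- function(n = 300, p = 6, beta = c(2, -1.5, 1, rep(0, p - 3)),
                          seed = 1, nrounds = 40, max_depth = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  })
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.2,
                  max_depth = max_depth, nthread = 1, base_score = 0.5,
                  seed = 1),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds, verbose = 0)
  model <- methods::new("ClassifierModel", booster = bst,
                        featureNames = colnames(X), params = list(),
                        bestIteration = NA_integer_,
                        nTrainPos = as.integer(sum(y)),
                        nTrainNeg = as.integer(sum(1 - y)))
  list(model = model, X = X, y = y)
}
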