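# The two benchmark classifiers: gradient boosting over TF-IDF vectors
# (xgboost) and a small sequential neural network over token-index sequences
# (word embedding -> global max pooling -> dense -> sigmoid), trained
# full-batch with Adam. The network is written directly in R; at benchmark
# scale (short template notes, compact vocabularies) this trains in seconds.

#' Fit the gradient-boosting classifier
#'
#' @param features sparse TF-IDF matrix (rows = stays).
#' @param labels 0/1 labels.
#' @param params list of hyperparameters: `nrounds`, `max_depth`, `eta`.
#' @param seed RNG seed.
#' @return an object with class `"hapi_gb"` usable with [predict_classifier()].
#' @export
fit_gradient_boosting <- function(features, labels,
                                  params = list(nrounds = 100, max_depth = 4, eta = 0.3),
                                  seed = 1L) {
  dtrain <- xgboost::xgb.DMatrix(features, label = as.numeric(labels))
  booster <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth %||% 4,
                  eta = params$eta %||% 0.3,
                  nthread = 1),
    data = dtrain,
    nrounds = params$nrounds %||% 100,
    verbose = 0))
  structure(list(booster = booster), class = "hapi_gb")
}

#' Fit the sequential neural-network classifier
#'
#' Architecture: learned word embeddings (`embed_dim`), global max pooling
#' over the token axis (padding positions are masked out), one ReLU dense
#' layer (`hidden`), and a sigmoid output. Binary cross-entropy loss,
#' full-batch Adam.
#'
#' @param sequences integer matrix from [vectorize()] `mode = "sequence"`
#'   (1 = padding, 2 = out-of-vocabulary).
#' @param labels 0/1 labels.
#' @param params list: `embed_dim`, `hidden`, `epochs`, `lr`.
#' @param seed RNG seed for initialization.
#' @return an object with class `"hapi_nn"` usable with [predict_classifier()].
#' @export
fit_sequential_nn <- function(sequences, labels,
                              params = list(embed_dim = 32, hidden = 32,
                                            epochs = 80, lr = 0.05),
                              seed = 1L) {
  d <- params$embed_dim %||% 32
  h <- params$hidden %||% 32
  epochs <- params$epochs %||% 80
  lr <- params$lr %||% 0.05
  y <- as.numeric(labels)
  V <- max(sequences)
  # padding positions are masked out of the pooling, so trailing all-padding
  # columns are inert; trim them for speed
  used <- which(colSums(sequences != 1L) > 0)
  if (length(used)) sequences <- sequences[, seq_len(max(used)), drop = FALSE]
  B <- nrow(sequences); L <- ncol(sequences)
  flat <- as.vector(sequences)

  w <- with_seed(seed, list(
    E = matrix(stats::rnorm(V * d, sd = 0.1), V, d),
    W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h),
    b1 = rep(0, h),
    w2 = matrix(stats::rnorm(h, sd = sqrt(1 / h)), h, 1),
    b2 = 0
  ))
  # Adam state
  mclone <- function(x) lapply(x, function(z) z * 0)
  m1 <- mclone(w); m2 <- mclone(w)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  forward <- function(E, seqs_flat, B, L) {
    P <- matrix(0, B, d); amax <- matrix(1L, B, d)
    for (j in seq_len(d)) {
      vals <- E[seqs_flat, j]
      vals[seqs_flat == 1L] <- -1e30
      Mj <- matrix(vals, B, L)
      idx <- max.col(Mj, ties.method = "first")
      P[, j] <- Mj[cbind(seq_len(B), idx)]
      amax[, j] <- seqs_flat[(idx - 1L) * B + seq_len(B)]
    }
    P[P <= -1e29] <- 0  # all-padding documents pool to zero
    list(P = P, amax = amax)
  }

  for (ep in seq_len(epochs)) {
    fw <- forward(w$E, flat, B, L)
    H <- pmax(fw$P %*% w$W1 + rep(w$b1, each = B), 0)
    z <- as.vector(H %*% w$w2) + w$b2
    yhat <- stats::plogis(z)
    dz <- (yhat - y) / B
    g <- list(E = matrix(0, V, d),
              W1 = crossprod(fw$P, (dz %*% t(w$w2))[, , drop = FALSE] * (H > 0)),
              b1 = colSums((dz %*% t(w$w2)) * (H > 0)),
              w2 = crossprod(H, dz),
              b2 = sum(dz))
    dH <- (dz %*% t(w$w2)) * (H > 0)
    dP <- dH %*% t(w$W1)
    for (j in seq_len(d)) {
      acc <- rowsum(dP[, j], fw$amax[, j])
      rows <- as.integer(rownames(acc))
      g$E[rows, j] <- g$E[rows, j] + acc[, 1]
    }
    g$E[1, ] <- 0  # padding embedding stays fixed
    for (nm in names(w)) {
      m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * g[[nm]]
      m2[[nm]] <- beta2 * m2[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m1[[nm]] / (1 - beta1^ep)
      vhat <- m2[[nm]] / (1 - beta2^ep)
      w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(weights = w, embed_dim = d), class = "hapi_nn")
}

#' Predict scores from a fitted benchmark classifier
#'
#' @param model a `"hapi_gb"` or `"hapi_nn"` object.
#' @param features features in the representation the model was trained on.
#' @return numeric scores in \[0, 1\].
#' @export
predict_classifier <- function(model, features) {
  if (inherits(model, "hapi_gb")) {
    return(stats::predict(model$booster, xgboost::xgb.DMatrix(features)))
  }
  w <- model$weights; d <- model$embed_dim
  used <- which(colSums(features != 1L) > 0)
  if (length(used)) features <- features[, seq_len(max(used)), drop = FALSE]
  B <- nrow(features); L <- ncol(features)
  flat <- as.vector(features)
  # tokens unseen at training time (index beyond E) map to the OOV row
  flat[flat > nrow(w$E)] <- 2L
  P <- matrix(0, B, d)
  for (j in seq_len(d)) {
    vals <- w$E[flat, j]
    vals[flat == 1L] <- -1e30
    Mj <- matrix(vals, B, L)
    P[, j] <- Mj[cbind(seq_len(B), max.col(Mj, ties.method = "first"))]
  }
  P[P <= -1e29] <- 0
  H <- pmax(P %*% w$W1 + rep(w$b1, each = B), 0)
  as.vector(stats::plogis(as.vector(H %*% w$w2) + w$b2))
}
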