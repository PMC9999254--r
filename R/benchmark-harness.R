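# Test-set assembly and the train/evaluate loop. Test sets share all
# consensus cases (every definition labels the stay a case) and all manually
# annotated disagreement stays, and differ only in the random subsample of
# consensus controls. Each definition trains on its own eligible stays
# outside the shared test pool, with its own labels, so that test labels are
# definition-independent while training labels are definition-specific.

#' Consensus and disagreement partition of a stay universe
#'
#' @param label_tables named list of [label_cohort()] outputs over one universe.
#' @return list of character vectors: `consensus_cases` (case under every
#'   definition), `consensus_controls` (control under every definition),
#'   `disagreement` (everything else).
#' @export
consensus_partition <- function(label_tables) {
  universe <- label_tables[[1]]$stay_id
  status <- sapply(label_tables, function(lt) lt$status[match(universe, lt$stay_id)])
  all_case <- rowSums(status == "case") == ncol(status)
  all_ctrl <- rowSums(status == "control") == ncol(status)
  list(consensus_cases = universe[all_case],
       consensus_controls = universe[all_ctrl],
       disagreement = universe[!all_case & !all_ctrl])
}

#' Construct shared test sets and per-definition training sets
#'
#' Each of the `n_sets` test sets contains every consensus case, every
#' annotated disagreement stay, and `n_controls` consensus controls sampled
#' at random (the only part that varies between sets). Training sets, one
#' per definition and test set, are that definition's eligible stays outside
#' the test set, labeled by that definition.
#'
#' @param label_tables named list of [label_cohort()] outputs.
#' @param annotations named character/integer vector (names = stay ids,
#'   values in `c("case", "control")` or 1/0) for manually adjudicated
#'   disagreement stays; may be empty.
#' @param n_sets number of test sets.
#' @param n_controls consensus controls per test set.
#' @param seed RNG seed for the control subsamples.
#' @return list with `test_sets` (list of data frames `stay_id`, `label`)
#'   and `train_sets` (nested list `definition -> set -> data frame`).
#' @export
construct_test_sets <- function(label_tables, annotations = character(),
                                n_sets = 10L, n_controls, seed = 1L) {
  part <- consensus_partition(label_tables)
  ann_ids <- names(annotations)
  if (length(ann_ids)) {
    bad <- setdiff(ann_ids, part$disagreement)
    if (length(bad))
      stop(sprintf("%d annotated stay(s) are not definition-disagreement stays", length(bad)),
           call. = FALSE)
  }
  if (n_controls > length(part$consensus_controls))
    stop(sprintf("n_controls (%d) exceeds the consensus-control pool (%d)",
                 n_controls, length(part$consensus_controls)), call. = FALSE)
  ann_label <- if (length(ann_ids)) {
    as.integer(annotations == "case" | annotations == 1 | annotations == "1")
  } else integer(0)

  fixed <- data.frame(stay_id = c(part$consensus_cases, ann_ids),
                      label = c(rep(1L, length(part$consensus_cases)), ann_label),
                      stringsAsFactors = FALSE)
  test_sets <- with_seed(seed, lapply(seq_len(n_sets), function(k) {
    ctrl <- sample(part$consensus_controls, n_controls)
    out <- rbind(fixed, data.frame(stay_id = ctrl, label = 0L, stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  }))

  train_sets <- lapply(label_tables, function(lt) {
    lapply(test_sets, function(ts) {
      elig <- lt[lt$status != "excluded" & !(lt$stay_id %in% ts$stay_id), , drop = FALSE]
      data.frame(stay_id = elig$stay_id,
                 label = as.integer(elig$status == "case"),
                 stringsAsFactors = FALSE)
    })
  })
  list(test_sets = test_sets, train_sets = train_sets)
}

default_hyper_grid <- function(classifier) {
  if (classifier == "gradient_boosting")
    expand.grid(nrounds = c(50, 100), max_depth = c(3, 5), eta = 0.3)
  else
    expand.grid(embed_dim = 32, hidden = 32, epochs = c(40, 80), lr = 0.05)
}

cv_folds_stratified <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    fold
  })
}

fit_one <- function(classifier, features, labels, params, seed) {
  if (classifier == "gradient_boosting")
    fit_gradient_boosting(features, labels, as.list(params), seed)
  else
    fit_sequential_nn(features, labels, as.list(params), seed)
}

#' Train a classifier with cross-validated hyperparameters and evaluate it
#'
#' Hyperparameters are chosen by `cv_folds`-fold stratified cross-validation
#' on the training split, maximizing mean AUPRC; the winning configuration
#' is refitted on the full training split and scored on every test set.
#' Features are always fitted on the training documents only and reused for
#' the test documents.
#'
#' @param train list with `documents` ([build_documents()] output) and
#'   `labels` (0/1, parallel to documents).
#' @param test_sets list of lists with `documents` and `labels`.
#' @param classifier `"gradient_boosting"` (TF-IDF features) or
#'   `"sequential_nn"` (token sequences).
#' @param cv_folds folds for hyperparameter selection (default 5).
#' @param hyper_grid data frame of candidate hyperparameter rows; `NULL`
#'   uses a small default grid. A single-row grid skips cross-validation.
#' @param seed RNG seed.
#' @param vocab_size,seq_len passed to [vectorize()].
#' @return a `hapi_eval` list: `classifier`, per-set `auprc` and `auroc`
#'   vectors, their means and SDs, and the selected `params`.
#' @export
train_evaluate <- function(train, test_sets,
                           classifier = c("gradient_boosting", "sequential_nn"),
                           cv_folds = 5L, hyper_grid = NULL, seed = 1L,
                           vocab_size = 5000L, seq_len = 800L) {
  classifier <- match.arg(classifier)
  y <- as.integer(train$labels)
  if (length(unique(y)) < 2)
    stop("training labels are single-class; cannot train a classifier", call. = FALSE)
  mode <- if (classifier == "gradient_boosting") "tfidf" else "sequence"
  vt <- vectorize(train$documents, mode, vocab_size = vocab_size, seq_len = seq_len)
  X <- vt$features
  if (is.null(hyper_grid)) hyper_grid <- default_hyper_grid(classifier)

  best <- hyper_grid[1, , drop = FALSE]
  if (nrow(hyper_grid) > 1) {
    fold <- cv_folds_stratified(y, cv_folds, seed)
    cv_score <- vapply(seq_len(nrow(hyper_grid)), function(g) {
      sc <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
        mdl <- fit_one(classifier, X[tr, , drop = FALSE], y[tr], hyper_grid[g, ], seed)
        auprc(predict_classifier(mdl, X[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(sc, na.rm = TRUE)
    }, numeric(1))
    best <- hyper_grid[which.max(cv_score), , drop = FALSE]
  }

  final <- fit_one(classifier, X, y, best, seed)
  n_sets <- length(test_sets)
  pr <- numeric(n_sets); roc <- numeric(n_sets)
  for (k in seq_len(n_sets)) {
    ts <- test_sets[[k]]
    Xt <- vectorize(ts$documents, mode, vocab_size = vocab_size,
                    seq_len = seq_len, model = vt$model)$features
    s <- predict_classifier(final, Xt)
    pr[k] <- auprc(s, ts$labels)
    roc[k] <- auroc(s, ts$labels)
  }
  structure(list(classifier = classifier, params = as.list(best),
                 auprc = pr, auroc = roc,
                 auprc_mean = mean(pr), auprc_sd = stats::sd(pr),
                 auroc_mean = mean(roc), auroc_sd = stats::sd(roc)),
            class = "hapi_eval")
}

#' @export
print.hapi_eval <- function(x, ...) {
  cat(sprintf("<hapi_eval %s> AUPRC %.3f (SD %.3f) | AUROC %.3f (SD %.3f) over %d test sets\n",
              x$classifier, x$auprc_mean, x$auprc_sd, x$auroc_mean, x$auroc_sd,
              length(x$auprc)))
  invisible(x)
}
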