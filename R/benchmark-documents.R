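# Leakage-safe document construction and feature extraction. Only notes
# strictly before a stay's event timestamp ("notes of interest") contribute
# to its document, and no non-negated pressure-injury phrase may survive in
# the concatenated text.

#' Build per-stay documents from notes of interest
#'
#' Concatenates, in time order, the notes of a stay whose timestamp is
#' strictly before the stay's event timestamp. Stays with no notes of
#' interest are dropped. Any residual non-negated lexicon phrase occurrence
#' is scrubbed from the text and counted per stay, so that every returned
#' document satisfies the no-leakage invariant.
#'
#' @param stay_ids stays to build documents for.
#' @param event_ts named `POSIXct` (names = stay_id) of event timestamps.
#' @param notes notes data frame (as in a `cohort_store`).
#' @param lex keyword lexicon.
#' @return data frame `stay_id`, `text`, `n_notes`, `n_scrubbed`.
#' @export
build_documents <- function(stay_ids, event_ts, notes, lex = default_lexicon()) {
  notes <- notes[notes$stay_id %in% stay_ids & !is.na(notes$ts), , drop = FALSE]
  notes <- notes[notes$ts < event_ts[notes$stay_id], , drop = FALSE]
  notes <- notes[order(notes$stay_id, notes$ts), , drop = FALSE]
  if (nrow(notes) == 0)
    return(data.frame(stay_id = character(), text = character(),
                      n_notes = integer(), n_scrubbed = integer(),
                      stringsAsFactors = FALSE))
  texts <- tapply(notes$text, factor(notes$stay_id), paste, collapse = "\n")
  counts <- tapply(notes$text, factor(notes$stay_id), length)
  out <- data.frame(stay_id = names(texts), text = as.character(texts),
                    n_notes = as.integer(counts), n_scrubbed = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    m <- scan_note(out$text[i], lex)
    pos <- m[!m$negated, , drop = FALSE]
    if (nrow(pos) > 0) {
      out$n_scrubbed[i] <- nrow(pos)
      txt <- out$text[i]
      # remove spans back-to-front so offsets stay valid
      for (j in order(-pos$start)) {
        txt <- paste0(substr(txt, 1, pos$start[j]),
                      substr(txt, pos$end[j] + 1, nchar(txt)))
      }
      out$text[i] <- txt
    }
  }
  rownames(out) <- NULL
  out
}

#' Check the leakage invariant on a set of documents
#'
#' @param documents [build_documents()] output.
#' @param lex keyword lexicon.
#' @return logical vector: `TRUE` where the document contains no non-negated
#'   lexicon phrase.
#' @export
documents_leakage_free <- function(documents, lex = default_lexicon()) {
  vapply(documents$text, function(txt) {
    m <- scan_note(txt, lex)
    nrow(m[!m$negated, , drop = FALSE]) == 0
  }, logical(1), USE.NAMES = FALSE)
}

# ---- feature extraction -----------------------------------------------------

tokenize_docs <- function(texts) {
  toks <- strsplit(tolower(texts), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

#' Vectorize documents as TF-IDF matrices or padded token sequences
#'
#' `mode = "tfidf"` returns a sparse document-term matrix over the
#' `vocab_size` most frequent training terms, with smoothed inverse document
#' frequency `log((1 + n) / (1 + df)) + 1` and L2-normalized rows.
#' `mode = "sequence"` returns an integer matrix of the first `seq_len`
#' token indices per document (index 1 = padding, 2 = out-of-vocabulary,
#' terms from 3). The vocabulary is fitted on the supplied documents unless
#' a fitted `model` is passed, in which case it is reused (the leakage-safe
#' path for test splits: fit on training only).
#'
#' @param documents [build_documents()] output (or any data frame with
#'   `stay_id` and `text`).
#' @param mode `"tfidf"` or `"sequence"`.
#' @param vocab_size vocabulary cap (default 5000).
#' @param seq_len sequence length (default 800); longer documents are
#'   truncated at the tail, shorter ones padded.
#' @param model a previously returned `$model` to reuse.
#' @return list with `features` (a `dgCMatrix` for tfidf, an integer matrix
#'   for sequence; rownames = stay ids) and `model` (vocabulary + idf).
#' @export
vectorize <- function(documents, mode = c("tfidf", "sequence"),
                      vocab_size = 5000L, seq_len = 800L, model = NULL) {
  mode <- match.arg(mode)
  if (nrow(documents) == 0) stop("no documents to vectorize", call. = FALSE)
  toks <- tokenize_docs(documents$text)

  if (is.null(model)) {
    tf_all <- table(unlist(toks))
    vocab <- names(sort(tf_all, decreasing = TRUE))[seq_len(min(vocab_size, length(tf_all)))]
    model <- list(mode = mode, vocabulary = vocab)
    if (mode == "tfidf") {
      df <- table(factor(unlist(lapply(toks, unique)), levels = vocab))
      n <- length(toks)
      model$idf <- log((1 + n) / (1 + as.numeric(df))) + 1
      names(model$idf) <- vocab
    }
  }
  vocab <- model$vocabulary

  if (mode == "tfidf") {
    triplets <- lapply(seq_along(toks), function(i) {
      t <- toks[[i]][toks[[i]] %in% vocab]
      if (!length(t)) return(NULL)
      tab <- table(t)
      data.frame(i = i, j = match(names(tab), vocab), x = as.numeric(tab))
    })
    triplets <- do.call(rbind, triplets[!vapply(triplets, is.null, logical(1))])
    m <- Matrix::sparseMatrix(
      i = triplets$i %||% integer(0), j = triplets$j %||% integer(0),
      x = triplets$x %||% numeric(0),
      dims = c(length(toks), length(vocab)),
      dimnames = list(documents$stay_id, vocab))
    m <- m %*% Matrix::Diagonal(x = model$idf[vocab])
    norms <- sqrt(Matrix::rowSums(m^2))
    norms[norms == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / norms) %*% m
    dimnames(m) <- list(documents$stay_id, vocab)
    list(features = methods::as(m, "CsparseMatrix"), model = model)
  } else {
    idx <- lapply(toks, function(t) {
      v <- match(t, vocab)
      v[is.na(v)] <- -1L
      v <- v + 2L            # terms from 3; OOV (-1) becomes 1 -> fix below
      v[v == 1L] <- 2L       # OOV index
      v
    })
    seqs <- t(vapply(idx, function(v) {
      if (length(v) >= seq_len) v[seq_len(seq_len)]
      else c(v, rep(1L, seq_len - length(v)))
    }, integer(seq_len)))
    rownames(seqs) <- documents$stay_id
    list(features = seqs, model = model)
  }
}
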