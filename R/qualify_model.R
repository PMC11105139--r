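# Learned qualification: hashed lexical features, mean pooling over the
# entity's tokens, and a single dense (logistic) layer. The three-step
# shape mirrors a transformer-based snippet classifier (per-token
# embeddings -> mean pooling of the entity tokens -> fully-connected
# layer); the embedding backend here is a hashed bag of lexical features so
# the module trains in seconds on a laptop, and it is isolated behind
# `featurize_snippets()` so a heavier encoder can be substituted.

# Deterministic 31-ary polynomial string hash into 1..d.
hash_string <- function(s, d) {
  vapply(s, function(x) {
    h <- 0
    for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
    as.integer(h %% d) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

# Feature strings for one entity token: identity, position-relative-to-
# entity bucket, and the 2 neighbor tokens on each side (which inject
# snippet context into the pooled vector).
token_features <- function(surfaces, t, entity_first) {
  n <- length(surfaces)
  feats <- c(
    paste0("tok=", surfaces[t]),
    paste0("pos=", min(t - entity_first, 3L))
  )
  if (t > 1L) feats <- c(feats, paste0("prev1=", surfaces[t - 1L]))
  if (t > 2L) feats <- c(feats, paste0("prev2=", surfaces[t - 2L]))
  if (t < n) feats <- c(feats, paste0("next1=", surfaces[t + 1L]))
  if (t < n - 1L) feats <- c(feats, paste0("next2=", surfaces[t + 2L]))
  feats
}

#' Featurize labeled snippets into pooled vectors
#'
#' Each token of a snippet is mapped to a sparse hashed feature vector
#' (token identity, position-relative-to-entity bucket, and its two
#' neighbors on each side); the snippet representation is the arithmetic
#' mean of the vectors of the entity's tokens only, context entering
#' through the neighbor features.
#'
#' @param snippets A tibble with a `tokens` list-column (character vectors)
#'   and integer columns `entity_start`, `entity_end` (1-based token index
#'   range of the entity inside the snippet). See
#'   [make_labeled_snippets()].
#' @param d Hashing dimension (number of feature buckets).
#' @return A sparse `dgCMatrix` with one row per snippet and `d` columns.
#' @export
featurize_snippets <- function(snippets, d = 2^16) {
  stopifnot(nrow(snippets) > 0L, d >= 2L)
  ii <- integer(0); jj <- integer(0); xx <- double(0)
  for (r in seq_len(nrow(snippets))) {
    surfaces <- snippets$tokens[[r]]
    a <- snippets$entity_start[r]; b <- snippets$entity_end[r]
    if (is.na(a) || is.na(b) || a > b || a < 1L || b > length(surfaces)) {
      stop("snippet ", r, ": empty or out-of-range entity token range",
           call. = FALSE)
    }
    ent <- a:b
    js <- unlist(lapply(
      ent, function(t) hash_string(token_features(surfaces, t, a), d)
    ))
    tab <- table(js)
    ii <- c(ii, rep(r, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab) / length(ent))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrow(snippets), d))
}

logistic <- function(z) 1 / (1 + exp(-z))

log_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train the learned qualifier
#'
#' Fits the dense layer (logistic weights over the pooled hashed features)
#' by full-batch gradient descent with a halving line search, so the
#' training loss is nonincreasing over epochs. Weights start at zero,
#' making training deterministic and symmetric under label flips; the seed
#' is recorded in the model for provenance and for any downstream sampling.
#'
#' @param snippets A labeled snippet tibble (`tokens`, `entity_start`,
#'   `entity_end`, `label` with levels `"keep"`/`"discard"`).
#' @param d Hashing dimension.
#' @param seed Integer seed recorded in the model.
#' @param epochs Number of gradient epochs.
#' @param lr Initial learning rate for the line search.
#' @param threshold Decision threshold on the keep-probability: a mention
#'   scoring below it is discarded.
#' @return A `qualifier_model` object.
#' @export
train_qualifier <- function(snippets, d = 2^16, seed = 1L, epochs = 100L,
                            lr = 4, threshold = 0.5) {
  stopifnot(all(snippets$label %in% c("keep", "discard")))
  y <- as.numeric(snippets$label == "keep")
  if (length(unique(y)) < 2L) {
    stop("training snippets must contain both 'keep' and 'discard' labels",
         call. = FALSE)
  }
  X <- featurize_snippets(snippets, d)
  n <- nrow(X)
  w <- numeric(d); b <- 0
  loss_history <- numeric(epochs)
  p <- rep(0.5, n)
  cur_loss <- log_loss(p, y)
  for (e in seq_len(epochs)) {
    r <- p - y
    gw <- as.numeric(Matrix::crossprod(X, r)) / n
    gb <- mean(r)
    step <- lr
    improved <- FALSE
    for (half in 1:30) {
      w_new <- w - step * gw
      b_new <- b - step * gb
      p_new <- logistic(as.numeric(X %*% w_new) + b_new)
      new_loss <- log_loss(p_new, y)
      if (new_loss <= cur_loss) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (improved) {
      w <- w_new; b <- b_new; p <- p_new; cur_loss <- new_loss
    }
    loss_history[e] <- cur_loss
  }
  structure(
    list(
      d = as.integer(d), weights = w, bias = b,
      threshold = threshold, seed = as.integer(seed),
      epochs = as.integer(epochs), loss_history = loss_history,
      n_train = n,
      train_accuracy = mean((p >= 0.5) == y),
      majority_accuracy = max(mean(y), 1 - mean(y))
    ),
    class = "qualifier_model"
  )
}

#' @export
print.qualifier_model <- function(x, ...) {
  cat("<qualifier_model> d=", x$d, ", threshold=", x$threshold,
      ", trained on ", x$n_train, " snippets (train accuracy ",
      round(100 * x$train_accuracy, 1), "%)\n", sep = "")
  invisible(x)
}

#' Score snippets with a trained qualifier
#'
#' @param object A `qualifier_model`.
#' @param snippets A snippet tibble (see [featurize_snippets()]).
#' @param ... Unused.
#' @return Numeric vector of keep-probabilities in (0, 1).
#' @export
predict.qualifier_model <- function(object, snippets, ...) {
  X <- featurize_snippets(snippets, object$d)
  logistic(as.numeric(X %*% object$weights) + object$bias)
}

#' Broom-style summaries of a qualifier model
#'
#' `tidy()` returns the nonzero hashed weights; `glance()` a one-row model
#' summary.
#'
#' @param x A `qualifier_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qualifier_model <- function(x, ...) {
  nz <- which(x$weights != 0)
  tibble::tibble(bucket = nz, weight = x$weights[nz])
}

#' @rdname tidy.qualifier_model
#' @export
glance.qualifier_model <- function(x, ...) {
  tibble::tibble(
    d = x$d, n_train = x$n_train, epochs = x$epochs,
    final_loss = x$loss_history[length(x$loss_history)],
    train_accuracy = x$train_accuracy,
    majority_accuracy = x$majority_accuracy,
    threshold = x$threshold, seed = x$seed
  )
}

#' Serialize and reload a qualifier model
#'
#' The model is written as a single versioned JSON file (format magic,
#' hashing dimension, nonzero weights, bias, threshold, seed) and reloads
#' to identical predictions.
#'
#' @param model A `qualifier_model`.
#' @param path File path.
#' @return `write_qualifier_model()` returns the path invisibly;
#'   `read_qualifier_model()` returns the model.
#' @export
write_qualifier_model <- function(model, path) {
  nz <- which(model$weights != 0)
  payload <- list(
    format = "comorbidr-qualifier-model",
    version = 1L,
    d = model$d,
    bias = model$bias,
    threshold = model$threshold,
    seed = model$seed,
    epochs = model$epochs,
    n_train = model$n_train,
    train_accuracy = model$train_accuracy,
    majority_accuracy = model$majority_accuracy,
    loss_history = model$loss_history,
    idx = nz,
    w = model$weights[nz]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_qualifier_model
#' @export
read_qualifier_model <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(payload$format, "comorbidr-qualifier-model")) {
    stop("not a comorbidr qualifier model file: ", path, call. = FALSE)
  }
  w <- numeric(payload$d)
  w[payload$idx] <- payload$w
  structure(
    list(
      d = as.integer(payload$d), weights = w, bias = payload$bias,
      threshold = payload$threshold, seed = as.integer(payload$seed),
      epochs = as.integer(payload$epochs),
      loss_history = as.numeric(payload$loss_history),
      n_train = as.integer(payload$n_train),
      train_accuracy = payload$train_accuracy,
      majority_accuracy = payload$majority_accuracy
    ),
    class = "qualifier_model"
  )
}

#' Learned qualification of extracted mentions
#'
#' Builds the context snippet of each mention, scores it with the trained
#' qualifier, and discards mentions scoring below the model's threshold.
#' Generic false positives flagged by [apply_exclusions()] stay discarded
#' regardless of score.
#'
#' @param mentions A mentions tibble.
#' @param notes The notes tibble.
#' @param model A `qualifier_model`.
#' @param window Context window (tokens each side) used to build snippets.
#' @return The mentions tibble with `score` and `discarded` set.
#' @export
qualify_learned <- function(mentions, notes, model, window = 8L) {
  if (nrow(mentions) == 0L) return(mentions)
  mentions <- ensure_norm_spans(mentions, notes)
  snippets <- mention_snippets(mentions, notes, window)
  mentions$score <- predict(model, snippets)
  # generic FPs and family-section mentions are positional decisions made
  # upstream; the snippet classifier handles cue-borne irrelevance
  mentions$discarded <- mentions$generic_fp | mentions$family |
    (mentions$score < model$threshold)
  mentions
}

# Snippet tibble (tokens + entity range) for each mention.
mention_snippets <- function(mentions, notes, window = 8L) {
  mentions <- ensure_norm_spans(mentions, notes)
  toks_by_note <- lapply(
    stats::setNames(notes$text, notes$note_id),
    function(text) tokenize(normalize_text(text))
  )
  purrr::map_dfr(seq_len(nrow(mentions)), function(i) {
    tokens <- toks_by_note[[mentions$note_id[i]]]
    tr <- token_range(tokens, mentions$norm_start[i], mentions$norm_end[i])
    if (is.na(tr[1])) {
      stop("mention ", mentions$mention_id[i],
           " does not align with any token", call. = FALSE)
    }
    lo <- max(1L, tr[1] - window)
    hi <- min(nrow(tokens), tr[2] + window)
    tibble::tibble(
      mention_id = mentions$mention_id[i],
      tokens = list(tokens$surface[lo:hi]),
      entity_start = tr[1] - lo + 1L,
      entity_end = tr[2] - lo + 1L
    )
  })
}
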