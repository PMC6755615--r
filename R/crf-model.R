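# Training and decoding for the linear-chain CRF. The objective and its
# gradient (forward-backward) and Viterbi live in compiled code; training
# uses L-BFGS-B from a zero start, so runs are deterministic for fixed
# inputs and hyperparameters.

#' Train a linear-chain CRF sequence tagger
#'
#' Minimizes the L2-penalized negative log-likelihood over SOBIE label
#' sequences with L-BFGS. Feature strings are interned into an index; label
#' order is fixed by [sobie_labels()].
#'
#' @param feat_sentences list of sentences, each a list of character vectors
#'   (feature strings per position) as from [extract_features()].
#' @param label_sentences list of character vectors of SOBIE labels aligned
#'   with `feat_sentences`.
#' @param l2 L2 penalty on all parameters.
#' @param maxit maximum L-BFGS iterations.
#' @return A `crf_model` list: feature dictionary, parameter vector, label
#'   set and config.
#' @export
train_crf <- function(feat_sentences, label_sentences, l2 = 0.1, maxit = 150L) {
  if (length(feat_sentences) == 0L) stop("need at least one sentence")
  if (length(feat_sentences) != length(label_sentences)) {
    stop("feature and label sentence counts differ")
  }
  nonempty <- lengths(feat_sentences) > 0L
  feat_sentences <- feat_sentences[nonempty]
  label_sentences <- label_sentences[nonempty]
  for (i in seq_along(feat_sentences)) {
    if (length(feat_sentences[[i]]) != length(label_sentences[[i]])) {
      stop(sprintf("sentence %d: %d feature positions but %d labels",
                   i, length(feat_sentences[[i]]), length(label_sentences[[i]])))
    }
  }
  labels <- sobie_labels()
  ylab <- lapply(label_sentences, function(ls) {
    y <- match(ls, labels)
    if (anyNA(y)) stop("unknown SOBIE label in training data")
    y
  })
  dict <- sort(unique(unlist(feat_sentences, use.names = FALSE)))
  if (length(dict) == 0L) stop("empty feature set")
  xidx <- lapply(feat_sentences, function(sent) {
    lapply(sent, function(f) match(f, dict))
  })
  nfeat <- length(dict)
  L <- length(labels)
  npar <- nfeat * L + L * L + 2L * L

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$res)
    res <- .crf_negll_grad(par, xidx, ylab, nfeat, L, l2)
    cache$par <- par
    cache$res <- res
    res
  }
  opt <- optim(rep(0, npar),
               fn = function(p) evaluate(p)$value,
               gr = function(p) evaluate(p)$grad,
               method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  structure(list(dict = dict, par = opt$par, labels = labels,
                 nfeat = nfeat, l2 = l2, maxit = maxit,
                 value = opt$value, convergence = opt$convergence),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model> %d features, %d labels, penalized negll %.3f\n",
              x$nfeat, length(x$labels), x$value))
  invisible(x)
}

#' Decode label sequences for featurized sentences
#'
#' @param model a `crf_model`.
#' @param feat_sentences list of sentences as in [train_crf()]; features
#'   unseen in training are dropped.
#' @return List of character vectors of SOBIE labels.
#' @export
predict_crf <- function(model, feat_sentences) {
  xidx <- lapply(feat_sentences, function(sent) {
    lapply(sent, function(f) {
      ix <- match(f, model$dict)
      ix[!is.na(ix)]
    })
  })
  paths <- .crf_viterbi(model$par, xidx, model$nfeat, length(model$labels))
  lapply(paths, function(p) model$labels[p])
}
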