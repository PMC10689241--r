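#' Explained variance regression score
#'
#' `1 - var(y - y') / var(y)`: 1 for perfect prediction, 0 for predicting
#' the mean, negative when predictions are worse than the mean.
#'
#' @param y observed values.
#' @param y_pred predicted values, same length.
#' @return score (<= 1).
#' @export
explained_variance <- function(y, y_pred) {
  stopifnot(length(y) == length(y_pred), length(y) >= 2)
  if (stats::var(y) == 0) stop("constant y: explained variance undefined")
  1 - stats::var(y - y_pred) / stats::var(y)
}

fit_decoder <- function(x, y, model) {
  df <- data.frame(y = y, x)
  switch(model,
    svr = e1071::svm(y ~ ., data = df, type = "eps-regression",
                     kernel = "radial"),
    wiener = stats::lm(y ~ ., data = df),
    wiener_cascade = {
      lin <- stats::lm(y ~ ., data = df)
      z <- stats::fitted(lin)
      poly <- stats::lm(y ~ stats::poly(z, 3, raw = TRUE))
      structure(list(lin = lin, poly = poly), class = "wiener_cascade")
    },
    xgb = xgboost::xgboost(data = as.matrix(x), label = y, nrounds = 50,
                           verbose = 0, nthread = 1))
}

predict_decoder <- function(fit, x) {
  if (inherits(fit, "xgb.Booster")) {
    as.numeric(stats::predict(fit, as.matrix(x)))
  } else if (inherits(fit, "wiener_cascade")) {
    z <- stats::predict(fit$lin, newdata = data.frame(x))
    as.numeric(stats::predict(fit$poly, newdata = data.frame(z = z)))
  } else {
    as.numeric(stats::predict(fit, newdata = data.frame(x)))
  }
}

#' Train per-layer CSD decoders with tenfold cross-validation
#'
#' Predicts layer-resolved CSD values from event coordinates in the
#' original waveform space, a reduced embedding, or a feature space. CSD
#' targets are scaled per layer by their standard deviation without mean
#' subtraction (polarity carries physiological meaning). When
#' `space = "reduced"`, the embedding is refit on each training fold and
#' the test fold is projected into it, keeping folds independent. A
#' shuffled-target control with the same folds defines the chance band.
#'
#' @param X event coordinates (matrix: original D-dim waveforms when
#'   `space = "reduced"`, otherwise the coordinates to decode from
#'   directly).
#' @param csd events x layers matrix of CSD values.
#' @param space `"original"`, `"reduced"` or `"feature"` (tag recorded;
#'   `"reduced"` triggers per-fold embedding refits of `X`).
#' @param folds number of cross-validation folds (default 10).
#' @param model `"svr"` (default), `"wiener"`, `"wiener_cascade"` or
#'   `"xgb"` (gradient-boosted trees).
#' @param d embedding dimension for the reduced space.
#' @param reduce_method embedding method for the reduced space (default
#'   `"umap"`, refit per fold with test folds projected through the uwot
#'   transform; `"pca"` offers a fast deterministic alternative).
#' @param n_shuffle_runs shuffled-target control runs (default 1 per
#'   fold set).
#' @param seed RNG seed.
#' @return a `decoder_bundle`: per-fold per-layer models, fold ids, layer
#'   scaling divisors, `ev` (folds x layers explained variance),
#'   `ev_shuffle` (chance band), `space`, `model`.
#' @export
train_csd_decoder <- function(X, csd, space = c("original", "reduced",
                                                "feature"),
                              folds = 10, model = c("svr", "wiener",
                                                    "wiener_cascade", "xgb"),
                              d = 4, reduce_method = "umap",
                              n_shuffle_runs = 1, seed = NULL) {
  space <- match.arg(space)
  model <- match.arg(model)
  X <- as.matrix(X)
  csd <- as.matrix(csd)
  stopifnot(nrow(X) == nrow(csd))
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  layer_sd <- apply(csd, 2, stats::sd)
  if (any(layer_sd == 0)) {
    message("dropping constant CSD layer(s): ",
            paste(colnames(csd)[layer_sd == 0], collapse = ", "))
    csd <- csd[, layer_sd > 0, drop = FALSE]
    layer_sd <- layer_sd[layer_sd > 0]
    if (ncol(csd) == 0) stop("no CSD layer with nonzero variance")
  }
  Y <- sweep(csd, 2, layer_sd, `/`)       # scale only, no centering

  fold_id <- sample(rep(seq_len(folds), length.out = n))
  run_cv <- function(Ymat) {
    ev <- matrix(NA_real_, folds, ncol(Ymat),
                 dimnames = list(NULL, colnames(csd)))
    fits <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      if (space == "reduced") {
        emb <- reduce_embedding(X[tr, , drop = FALSE], method = reduce_method,
                                d = d, seed = seed)
        xtr <- emb$coords
        xte <- if (reduce_method == "umap")
          uwot::umap_transform(X[te, , drop = FALSE], emb$model, n_threads = 1)
        else
          sweep(X[te, , drop = FALSE], 2, emb$model$center) %*%
            emb$model$rotation[, seq_len(d)]
      } else {
        xtr <- X[tr, , drop = FALSE]; xte <- X[te, , drop = FALSE]
      }
      colnames(xtr) <- colnames(xte) <- paste0("c", seq_len(ncol(xtr)))
      fits[[f]] <- lapply(seq_len(ncol(Ymat)), function(l) {
        fit <- fit_decoder(xtr, Ymat[tr, l], model)
        ev[f, l] <<- explained_variance(Ymat[te, l],
                                        predict_decoder(fit, xte))
        fit
      })
    }
    list(ev = ev, fits = fits)
  }
  cv <- run_cv(Y)
  ev_shuffle <- do.call(rbind, lapply(seq_len(n_shuffle_runs), function(s)
    run_cv(apply(Y, 2, sample))$ev))
  structure(list(fits = cv$fits, fold_id = fold_id, layer_sd = layer_sd,
                 ev = cv$ev, ev_shuffle = ev_shuffle, space = space,
                 model = model, d = d, input_dim = ncol(X),
                 layers = colnames(csd)),
            class = "decoder_bundle")
}

#' Predict per-layer CSD for new coordinates
#'
#' Averages the predictions of all fold models. Coordinates must live in
#' the same space the bundle was trained in. For bundles trained in the
#' reduced space the caller provides coordinates in that reduced space.
#'
#' @param bundle a `decoder_bundle`.
#' @param coords new coordinates.
#' @param rescale return CSD in original units (multiply by the stored
#'   per-layer s.d.) instead of scaled units.
#' @return matrix of predictions, events x layers.
#' @export
predict_csd <- function(bundle, coords, rescale = FALSE) {
  coords <- as.matrix(coords)
  expect_dim <- if (bundle$space == "reduced") bundle$d else bundle$input_dim
  if (ncol(coords) != expect_dim)
    stop("coordinate space mismatch with the decoder bundle")
  colnames(coords) <- paste0("c", seq_len(ncol(coords)))
  n_layers <- length(bundle$layers)
  preds <- array(0, c(nrow(coords), n_layers, length(bundle$fits)))
  for (f in seq_along(bundle$fits))
    for (l in seq_len(n_layers))
      preds[, l, f] <- predict_decoder(bundle$fits[[f]][[l]], coords)
  out <- apply(preds, c(1, 2), mean)
  colnames(out) <- bundle$layers
  if (rescale) out <- sweep(out, 2, bundle$layer_sd, `*`)
  out
}

#' Support-vector classifier of event origin with shuffle control
#'
#' Tenfold cross-validated classification accuracy (fraction correct) of
#' a two-class origin label from embedding coordinates, using a C-SVC
#' with radial basis kernel and C = 1. Optionally the classes are first
#' equalized on a covariate by histogram-bin subsampling (10 bins), so
#' that accuracy cannot stem from a difference in that covariate alone.
#' Significance comes from label permutations.
#'
#' @param coords event coordinates.
#' @param labels two-class factor or character vector.
#' @param folds cross-validation folds.
#' @param cost SVM regularization parameter C.
#' @param equalize optional numeric covariate to match between classes.
#' @param n_shuffles label permutations for the null accuracy.
#' @param seed RNG seed.
#' @return list with `accuracy`, `null` (shuffle accuracies), `p`
#'   (empirical, one-sided), `n_used`.
#' @export
train_origin_classifier <- function(coords, labels, folds = 10, cost = 1,
                                    equalize = NULL, n_shuffles = 100,
                                    seed = NULL) {
  coords <- as.matrix(coords)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need two classes")
  if (!is.null(seed)) set.seed(seed)

  keep <- seq_along(labels)
  if (!is.null(equalize)) {
    br <- seq(min(equalize), max(equalize), length.out = 11)
    bin <- findInterval(equalize, br, rightmost.closed = TRUE,
                        all.inside = TRUE)
    keep <- unlist(lapply(unique(bin), function(b) {
      per_class <- lapply(levels(labels), function(cl)
        which(bin == b & labels == cl))
      m <- min(lengths(per_class))
      unlist(lapply(per_class, function(ix)
        if (m > 0) sample(ix, m) else integer(0)))
    }))
    keep <- sort(keep)
  }
  X <- coords[keep, , drop = FALSE]
  y <- droplevels(labels[keep])
  if (min(table(y)) < folds) stop("too few events per class after equalization")

  cv_acc <- function(yy) {
    fold_id <- sample(rep(seq_len(folds), length.out = length(yy)))
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- e1071::svm(X[tr, , drop = FALSE], yy[tr], type = "C-classification",
                        kernel = "radial", cost = cost)
      hits <- hits + sum(stats::predict(fit, X[!tr, , drop = FALSE]) ==
                           yy[!tr])
    }
    hits / length(yy)
  }
  accuracy <- cv_acc(y)
  null <- vapply(seq_len(n_shuffles), function(s) cv_acc(sample(y)), 0)
  list(accuracy = accuracy, null = null,
       p = (1 + sum(null >= accuracy)) / (n_shuffles + 1),
       n_used = length(y))
}
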