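# Repertoire analysis: per-type summary statistics, correlation-matrix PCA
# with Kaiser retention, linear discriminant analysis on PC scores with
# leave-one-out cross-validation, and a permutation null for the
# classification rate.

# numeric feature matrix from a feature table, canonical row order by call_id
.feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "call_type" %in% names(features))
  if ("call_id" %in% names(features))
    features <- features[order(features$call_id), , drop = FALSE]
  cols <- intersect(feature_names(), names(features))
  if (!length(cols)) cols <- names(features)[vapply(features, is.numeric,
                                                    logical(1))]
  cols <- setdiff(cols, c("seed"))
  X <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, labels = factor(features$call_type),
       ids = features$call_id %||% seq_len(nrow(features)))
}

#' Per-type summary statistics of the acoustic parameters
#'
#' @param features Feature table (`call_type` plus numeric parameter columns).
#' @return Long data frame `call_type`, `parameter`, `mean`, `sd`, `n`; types
#'   with fewer than 2 calls get `NA` SDs and a warning. The `wide` attribute
#'   holds a parameter x type table of `"mean +/- sd"` strings.
#' @export
summarize_repertoire <- function(features) {
  fm <- .feature_matrix(features)
  sp <- split(as.data.frame(fm$X), fm$labels)
  rows <- do.call(rbind, lapply(names(sp), function(ct) {
    data.frame(call_type = ct, parameter = colnames(fm$X),
               mean = vapply(sp[[ct]], mean, numeric(1)),
               sd = if (nrow(sp[[ct]]) >= 2)
                 vapply(sp[[ct]], stats::sd, numeric(1))
               else rep(NA_real_, ncol(fm$X)),
               n = nrow(sp[[ct]]))
  }))
  rownames(rows) <- NULL
  if (any(rows$n < 2))
    warning("call type(s) with < 2 calls: SD undefined")
  wide <- do.call(cbind, lapply(names(sp), function(ct) {
    r <- rows[rows$call_type == ct, ]
    sprintf("%.2f ± %.2f", r$mean, r$sd)
  }))
  dimnames(wide) <- list(colnames(fm$X), names(sp))
  attr(rows, "wide") <- wide
  rows
}

#' Fit the repertoire model: standardised PCA plus discriminant
#'
#' PCA is computed on the correlation matrix (features standardised to zero
#' mean, unit variance — the parameters mix Hz, s and s^-1 scales);
#' components with eigenvalue > 1 are retained (Kaiser criterion) and a
#' linear discriminant with equal class priors is fitted on the retained
#' scores. Constant feature columns are dropped with a warning.
#'
#' @param features Feature table with `call_type`.
#' @param scale Standardise features (correlation PCA); set `FALSE` for
#'   covariance PCA.
#' @return `auk_repertoire`: `center`, `scale`, `loadings`, `eigenvalues`,
#'   `retained`, `scores`, `discriminant` (a `MASS::lda` fit),
#'   `class_labels`, `features_used`.
#' @export
fit_pca <- function(features, scale = TRUE) {
  fm <- .feature_matrix(features)
  X <- fm$X
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (nrow(X) <= ncol(X))
    warning("fewer calls than features; PCA is rank-deficient")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  retained <- which(ev > 1)
  if (!length(retained)) retained <- 1L
  scores <- pc$x
  disc <- if (nlevels(fm$labels) >= 2)
    MASS::lda(scores[, retained, drop = FALSE], grouping = fm$labels,
              prior = rep(1 / nlevels(fm$labels), nlevels(fm$labels)))
  else NULL
  structure(list(center = pc$center,
                 scale = if (scale) pc$scale else rep(1, ncol(X)),
                 loadings = pc$rotation, eigenvalues = ev,
                 retained = retained, scores = scores,
                 discriminant = disc, class_labels = levels(fm$labels),
                 features_used = colnames(X), scaled = scale),
            class = "auk_repertoire")
}

# leave-one-out projections: per held-out call, the training-set PCA
# (label-free, hence shared by every label permutation), the projected
# training scores, the projected held-out score and that fold's retained set
.loo_projections <- function(X, scale = TRUE) {
  n <- nrow(X)
  lapply(seq_len(n), function(i) {
    Xtr <- X[-i, , drop = FALSE]
    sds <- apply(Xtr, 2, stats::sd)
    keep <- sds > 0
    pc <- stats::prcomp(Xtr[, keep, drop = FALSE], center = TRUE,
                        scale. = scale)
    ev <- pc$sdev^2
    ret <- which(ev > 1)
    if (!length(ret)) ret <- 1L
    tr <- pc$x[, ret, drop = FALSE]
    te <- predict(pc, X[i, keep, drop = FALSE])[, ret, drop = FALSE]
    list(train = tr, test = te)
  })
}

# fit lda + predict one held-out call, tolerating folds where a class has
# too few members (that class is dropped for the fold)
.lda_fold <- function(train, test, labels_train) {
  labs <- droplevels(labels_train)
  tab <- table(labs)
  usable <- names(tab)[tab >= 2]
  if (length(usable) < length(tab)) {
    keep <- labs %in% usable
    labs <- droplevels(labs[keep])
    train <- train[keep, , drop = FALSE]
  }
  k <- nlevels(labs)
  fit <- MASS::lda(train, grouping = labs, prior = rep(1 / k, k))
  as.character(stats::predict(fit, test)$class)
}

#' Leave-one-out correct classification rate of the discriminant pipeline
#'
#' In the default `"refit"` mode the standardisation, PCA, Kaiser retention
#' and discriminant are all refit on each fold's n-1 training calls (no
#' leakage). `"global"` mode reproduces the common shortcut of one global
#' PCA followed by `MASS::lda(..., CV = TRUE)`, which leaks the global
#' scaling/rotation into each fold; the two typically differ by a small
#' amount. Class priors are equal (balanced design). Rows are canonicalised
#' by `call_id` so row order never changes the result.
#'
#' @param features Feature table with `call_type` (and `call_id`).
#' @param mode `"refit"` (leak-free, default) or `"global"`.
#' @param scale Standardise features before PCA.
#' @return List: `rate`, `predictions` (per call), `labels`, `confusion`
#'   (table), `mode`.
#' @export
classify_loo <- function(features, mode = c("refit", "global"), scale = TRUE) {
  mode <- match.arg(mode)
  fm <- .feature_matrix(features)
  if (nlevels(fm$labels) < 2) stop("need >= 2 call types")
  n <- nrow(fm$X)
  if (mode == "refit") {
    proj <- .loo_projections(fm$X, scale = scale)
    preds <- vapply(seq_len(n), function(i)
      .lda_fold(proj[[i]]$train, proj[[i]]$test, fm$labels[-i]),
      character(1))
  } else {
    model <- suppressWarnings(fit_pca(features, scale = scale))
    k <- nlevels(fm$labels)
    cv <- MASS::lda(model$scores[, model$retained, drop = FALSE],
                    grouping = fm$labels, prior = rep(1 / k, k), CV = TRUE)
    preds <- as.character(cv$class)
  }
  rate <- mean(preds == as.character(fm$labels))
  list(rate = rate, predictions = preds,
       labels = as.character(fm$labels),
       confusion = table(truth = fm$labels,
                         predicted = factor(preds,
                                            levels = levels(fm$labels))),
       mode = mode)
}

#' Permutation test of the classification rate
#'
#' Call-type labels are shuffled without replacement `n_permutations` times;
#' for each shuffle the full leave-one-out discriminant pipeline is
#' recomputed (the label-free standardisation/PCA per fold is computed once
#' and shared, which is numerically identical to refitting it per shuffle).
#' The p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_permutations)`, so it is never
#' exactly zero.
#'
#' @param features Feature table with `call_type` (and `call_id`).
#' @param n_permutations Number of label shuffles (reference analysis: 1000).
#' @param seed Integer seed for the shuffles.
#' @param mode Passed to [classify_loo()].
#' @param scale Standardise features before PCA.
#' @return `auk_permutation`: `observed_ccr`, `null_ccrs`, `p_value`,
#'   `chance_expectation` (mean of the null), `n_permutations`.
#' @export
permutation_test <- function(features, n_permutations = 1000, seed = 1,
                             mode = c("refit", "global"), scale = TRUE) {
  mode <- match.arg(mode)
  if (n_permutations < 100)
    warning("fewer than 100 permutations gives a coarse null")
  fm <- .feature_matrix(features)
  n <- nrow(fm$X)
  obs <- classify_loo(features, mode = mode, scale = scale)$rate
  if (mode == "refit") {
    proj <- .loo_projections(fm$X, scale = scale)
    loo_rate <- function(labels) {
      correct <- 0L
      for (i in seq_len(n)) {
        p <- .lda_fold(proj[[i]]$train, proj[[i]]$test, labels[-i])
        correct <- correct + (p == as.character(labels[i]))
      }
      correct / n
    }
  } else {
    model <- suppressWarnings(fit_pca(features, scale = scale))
    S <- model$scores[, model$retained, drop = FALSE]
    k <- nlevels(fm$labels)
    loo_rate <- function(labels) {
      cv <- MASS::lda(S, grouping = labels, prior = rep(1 / k, k), CV = TRUE)
      mean(as.character(cv$class) == as.character(labels))
    }
  }
  null_ccrs <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) loo_rate(sample(fm$labels)), numeric(1))
  })
  structure(list(observed_ccr = obs, null_ccrs = null_ccrs,
                 p_value = (1 + sum(null_ccrs >= obs)) / (1 + n_permutations),
                 chance_expectation = mean(null_ccrs),
                 n_permutations = n_permutations, mode = mode),
            class = "auk_permutation")
}
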