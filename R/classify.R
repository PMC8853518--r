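#' Stratified repeated cross-validation fold plan
#'
#' @param labels class labels (factor/character), one per sample.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed; the plan is fully reproducible.
#' @return list of length `repeats`; each element a list of `k` integer
#'   vectors of test indices (disjoint, covering all samples, class ratio
#'   preserved within one sample).
#' @export
repeated_cv_split <- function(labels, k = 5, repeats = 10, seed = 1) {
  stopifnot(k >= 2, repeats >= 1)
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k)) stop("every class needs >= k samples")
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    fold_of <- integer(length(labels))
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) which(fold_of == f))
  })
}

#' Leakage-safe fold normalization
#'
#' Log2-CPM is per sample (library size needs no training information);
#' gene-wise centering and scaling use means and standard deviations
#' estimated on the training samples only and are applied unchanged to the
#' test samples, so the test fold never influences the normalization.
#'
#' @param train,test count matrices (genes x samples) or [count_matrix()]
#'   objects sharing genes.
#' @param prior prior count for log-CPM.
#' @return list: `train`, `test` (samples x genes, ready for classifiers),
#'   `center`, `scale`, `flagged` (genes with zero training sd, scaled by 1).
#' @export
fold_normalize <- function(train, test, prior = 0.5) {
  tr <- if (inherits(train, "count_matrix")) train$counts else as.matrix(train)
  te <- if (inherits(test, "count_matrix")) test$counts else as.matrix(test)
  if (!identical(rownames(tr), rownames(te))) {
    shared <- intersect(rownames(tr), rownames(te))
    if (!length(shared)) stop("no shared genes between folds")
    tr <- tr[shared, , drop = FALSE]; te <- te[shared, , drop = FALSE]
  }
  lc <- function(m) {
    lib <- colSums(m)
    log2(sweep(m + prior, 2, lib + 2 * prior, "/") * 1e6)
  }
  ytr <- lc(tr); yte <- lc(te)
  ctr <- rowMeans(ytr)
  sdev <- apply(ytr, 1, stats::sd)
  flagged <- rownames(ytr)[sdev == 0]
  sdev[sdev == 0] <- 1
  ztr <- (ytr - ctr) / sdev
  zte <- (yte - ctr) / sdev
  list(train = t(ztr), test = t(zte), center = ctr, scale = sdev,
       flagged = flagged)
}

#' Elastic-net logistic regression
#'
#' Penalized logistic likelihood with penalty
#' `lambda * (alpha * |beta|_1 + (1 - alpha)/2 * |beta|_2^2)` fitted by
#' coordinate descent (glmnet). Genes with zero coefficients fall out of the
#' model.
#'
#' @param x samples x genes numeric matrix.
#' @param y binary labels (factor/character/0-1); the second factor level is
#'   the positive class.
#' @param alpha elastic-net mixing in \[0,1\] (1 = lasso, 0 = ridge).
#' @param lambda penalty (> 0) at which coefficients are extracted.
#' @return object of class `en_fit` with `coef` (named, genes only),
#'   `intercept`, `nonzero` (count of genes retained).
#' @export
fit_elastic_net_lr <- function(x, y, alpha, lambda) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("binary labels required")
  # fit along a path that contains the requested lambda exactly, so the
  # extracted coefficients are not path-interpolation artefacts even for
  # penalties below glmnet's default lambda.min.ratio
  path <- sort(unique(c(10^seq(2, -6, length.out = 81), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = path, thresh = 1e-7, maxit = 1e5)
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(x))
  structure(list(glmnet = fit, lambda = lambda, alpha = alpha,
                 levels = levels(y), intercept = cf[1], coef = cf[-1],
                 nonzero = sum(cf[-1] != 0)),
            class = "en_fit")
}

#' @export
predict.en_fit <- function(object, newdata, ...) {
  eta <- drop(newdata %*% object$coef) + object$intercept
  stats::plogis(eta)
}

#' Random forest classifier
#'
#' Bagged CART trees with the Gini split criterion; `mtry` features are
#' sampled at each split. Variable importance is the mean decrease in Gini;
#' genes never used for a split have zero importance and are effectively
#' outside the model.
#'
#' @param x samples x genes matrix.
#' @param y binary labels.
#' @param mtry features available per split.
#' @param n_trees number of trees.
#' @param seed seed for the forest construction.
#' @return object of class `rf_fit`.
#' @export
fit_random_forest <- function(x, y, mtry = floor(sqrt(ncol(x))),
                              n_trees = 500, seed = 1) {
  y <- factor(y)
  mtry <- max(1, min(mtry, ncol(x)))
  # with no variable feature there is no split to search: majority model
  if (all(.col_vars(x) == 0)) {
    return(structure(list(forest = NULL, levels = levels(y), mtry = mtry,
                          constant_prob = mean(y == levels(y)[2]),
                          importance = setNames(rep(0, ncol(x)),
                                                colnames(x))),
                     class = "rf_fit"))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, mtry = mtry, ntree = n_trees,
                                    importance = FALSE)
  structure(list(forest = fit, levels = levels(y), mtry = mtry),
            class = "rf_fit")
}

# column variances without extra dependencies
.col_vars <- function(x) {
  mu <- colMeans(x)
  colSums(sweep(x, 2, mu)^2) / max(1, nrow(x) - 1)
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  if (is.null(object$forest))
    return(rep(object$constant_prob, nrow(newdata)))
  pr <- stats::predict(object$forest, newdata, type = "prob")
  pr[, object$levels[2]]
}

#' PLS discriminant analysis (NIPALS PLS1)
#'
#' Partial least squares against the class label coded 0/1: components are
#' chosen to maximize the covariance between a linear combination of the
#' (centered) genes and the label. The variable importance is the weighted
#' sum of absolute loading weights across components, with weights
#' proportional to each component's reduction in the response sum of
#' squares.
#'
#' @param x samples x genes matrix.
#' @param y binary labels.
#' @param ncomp number of components (< min(n_samples, n_genes) and at most
#'   the rank of the centered predictor matrix).
#' @return object of class `plsda_fit` with regression vector `coef`,
#'   `intercept`, per-gene `importance`, and the training-score class
#'   midpoint `threshold`.
#' @export
fit_plsda <- function(x, y, ncomp = 2) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("binary labels required")
  y01 <- as.numeric(y) - 1
  if (ncomp >= min(nrow(x), ncol(x) + 1))
    stop("ncomp must be < min(n_samples, n_genes + 1)")
  xm <- colMeans(x)
  X <- sweep(x, 2, xm)
  ym <- mean(y01)
  yy <- y01 - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  qv <- ssy <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(X, yy))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("ncomp exceeds the rank of the predictor matrix")
    w <- w / nw
    tvec <- drop(X %*% w)
    tt <- sum(tvec^2)
    if (tt < 1e-12) stop("ncomp exceeds the rank of the predictor matrix")
    pv <- drop(crossprod(X, tvec)) / tt
    q <- sum(yy * tvec) / tt
    X <- X - tcrossprod(tvec, pv)
    yy <- yy - q * tvec
    W[, h] <- w; P[, h] <- pv; qv[h] <- q
    ssy[h] <- q^2 * tt   # response SS removed by this component
  }
  B <- drop(W %*% solve(crossprod(P, W), qv))
  names(B) <- colnames(x)
  wts <- ssy / sum(ssy)
  importance <- drop(abs(W) %*% wts)
  names(importance) <- colnames(x)
  scores <- drop(x %*% B) + (ym - sum(xm * B))
  thr <- mean(c(mean(scores[y01 == 0]), mean(scores[y01 == 1])))
  structure(list(coef = B, intercept = ym - sum(xm * B),
                 importance = importance, levels = levels(y),
                 threshold = thr, ncomp = ncomp, ssy = ssy),
            class = "plsda_fit")
}

#' @export
predict.plsda_fit <- function(object, newdata, ...) {
  drop(newdata %*% object$coef) + object$intercept
}

#' Confusion matrix from predicted and true labels
#'
#' @param predicted,truth logical vectors (TRUE = positive) or labels
#'   matching `positive`.
#' @param positive the positive class label when inputs are not logical.
#' @return object of class `confusion_matrix` with counts TP, FP, TN, FN.
#' @export
confusion_matrix <- function(predicted, truth, positive = NULL) {
  if (!is.logical(predicted)) predicted <- predicted == positive
  if (!is.logical(truth)) truth <- truth == positive
  structure(list(TP = sum(predicted & truth),
                 FP = sum(predicted & !truth),
                 TN = sum(!predicted & !truth),
                 FN = sum(!predicted & truth)),
            class = "confusion_matrix")
}

#' Classification performance metrics
#'
#' accuracy = (TP+TN)/n; sensitivity = TP/(TP+FN);
#' specificity = TN/(TN+FP); FPR = 1 - specificity;
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0
#' when any factor of the denominator is 0.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$TP + cm$TN + cm$FP + cm$FN
  if (n == 0) stop("empty confusion matrix")
  sens <- if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_
  spec <- if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else NA_real_
  den <- (cm$TP + cm$FP) * (cm$TP + cm$FN) * (cm$TN + cm$FP) * (cm$TN + cm$FN)
  mcc <- if (den == 0) 0 else
    (cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(den)
  c(accuracy = (cm$TP + cm$TN) / n, sensitivity = sens, specificity = spec,
    fpr = 1 - spec, mcc = mcc)
}

#' ROC curve and AUROC
#'
#' The ROC curve is traced over every unique score threshold (plus the
#' endpoints (0,0) and (1,1)); the area is computed by trapezoidal
#' integration and equals the Mann-Whitney concordance probability, with
#' tied scores credited one half.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (TRUE = positive) or labels with `positive` given.
#' @param positive positive class label when `labels` is not logical.
#' @return list: `roc` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels)) labels <- labels == positive
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nneg, 0)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                              utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Default hyperparameter grids
#'
#' Elastic net: mixing alpha 0 to 1 in steps of 0.1 and 50 log-spaced
#' penalties; random forest: mtry in {sqrt(p), p/10, p/4}; PLS-DA: 1-5
#' components.
#'
#' @param p number of genes.
#' @param n_lambda number of elastic-net penalty values.
#' @return named list of grids.
#' @export
default_grids <- function(p, n_lambda = 50) {
  list(elastic_net_lr = list(alpha = seq(0, 1, 0.1),
                             lambda = 10^seq(-3, 0.5, length.out = n_lambda)),
       random_forest = list(mtry = unique(pmax(1, floor(
         c(sqrt(p), p / 10, p / 4))))),
       plsda = list(ncomp = 1:5))
}

# inner-CV hyperparameter selection on the training fold only.
# Returns the grid row with the best mean accuracy; ties go to the stronger
# penalty / simpler model (larger lambda, smaller ncomp, smaller mtry).
.select_hyperparams <- function(model, x, y, grid, k_inner, n_trees, seed) {
  labels <- as.character(y)
  k_inner <- min(k_inner, min(table(labels)))
  if (k_inner < 2) stop("too few samples per class for inner CV")
  plan <- repeated_cv_split(labels, k = k_inner, repeats = 1, seed = seed)[[1]]
  pos <- levels(factor(labels))[2]
  if (model == "elastic_net_lr") {
    acc <- matrix(0, length(grid$alpha), length(grid$lambda))
    for (f in seq_along(plan)) {
      te <- plan[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
      if (length(unique(labels[tr])) < 2) next
      for (ai in seq_along(grid$alpha)) {
        # small CV folds routinely trigger glmnet's class-size caution
        fit <- suppressWarnings(
          glmnet::glmnet(x[tr, , drop = FALSE], factor(labels[tr]),
                         family = "binomial", alpha = grid$alpha[ai]))
        pr <- stats::predict(fit, x[te, , drop = FALSE], s = grid$lambda,
                             type = "response")
        acc[ai, ] <- acc[ai, ] + colSums((pr >= 0.5) ==
                                           (labels[te] == pos))
      }
    }
    # prefer larger lambda (sparser), then smaller alpha index
    best <- which(acc == max(acc), arr.ind = TRUE)
    best <- best[order(-best[, 2], best[, 1]), , drop = FALSE][1, ]
    return(list(alpha = grid$alpha[best[1]], lambda = grid$lambda[best[2]]))
  }
  score_one <- function(param_fit, param_pred, thresholded) {
    correct <- 0
    for (f in seq_along(plan)) {
      te <- plan[[f]]; tr <- setdiff(seq_len(nrow(x)), te)
      if (length(unique(labels[tr])) < 2) next
      m <- param_fit(x[tr, , drop = FALSE], labels[tr])
      pred <- param_pred(m, x[te, , drop = FALSE])
      correct <- correct + sum(pred == (labels[te] == pos))
    }
    correct
  }
  if (model == "random_forest") {
    accs <- vapply(grid$mtry, function(mt) score_one(
      function(xx, yy) fit_random_forest(xx, yy, mtry = mt,
                                         n_trees = n_trees, seed = seed),
      function(m, xx) predict(m, xx) >= 0.5, TRUE), 0)
    return(list(mtry = grid$mtry[which.max(accs)]))
  }
  if (model == "plsda") {
    ncomps <- grid$ncomp[grid$ncomp < min(nrow(x) * (k_inner - 1) / k_inner,
                                          ncol(x))]
    if (!length(ncomps)) ncomps <- 1
    accs <- vapply(ncomps, function(nc) score_one(
      function(xx, yy) fit_plsda(xx, yy, ncomp = min(nc, nrow(xx) - 2)),
      function(m, xx) predict(m, xx) >= m$threshold, TRUE), 0)
    return(list(ncomp = ncomps[which.max(accs)]))
  }
  stop("unknown model: ", model)
}

.fit_predict <- function(model, xtr, ytr, xte, params, n_trees, seed) {
  pos <- levels(factor(as.character(ytr)))[2]
  if (model == "elastic_net_lr") {
    fit <- suppressWarnings(
      fit_elastic_net_lr(xtr, ytr, params$alpha, params$lambda))
    sc <- predict(fit, xte)
    list(fit = fit, scores = sc, calls = sc >= 0.5)
  } else if (model == "random_forest") {
    fit <- fit_random_forest(xtr, ytr, mtry = params$mtry,
                             n_trees = n_trees, seed = seed)
    sc <- predict(fit, xte)
    list(fit = fit, scores = sc, calls = sc >= 0.5)
  } else {
    fit <- fit_plsda(xtr, ytr, ncomp = min(params$ncomp, nrow(xtr) - 2))
    sc <- predict(fit, xte)
    list(fit = fit, scores = sc, calls = sc >= fit$threshold)
  }
}

.importance_of <- function(model, fit) {
  imp <- switch(model,
    elastic_net_lr = abs(fit$coef),
    random_forest = if (is.null(fit$forest)) fit$importance else {
      v <- fit$forest$importance[, "MeanDecreaseGini"]
      setNames(as.numeric(v), rownames(fit$forest$importance))
    },
    plsda = fit$importance)
  data.frame(gene = names(imp), importance = as.numeric(imp),
             rank = rank(-imp, ties.method = "min"),
             stringsAsFactors = FALSE)[order(-imp), ]
}

#' Classify dependence status from blood expression
#'
#' Repeated stratified k-fold cross-validation of blood-based CIE vs Air
#' classifiers. Normalization is leakage-safe ([fold_normalize()]); an inner
#' cross-validation on each training fold selects hyperparameters by
#' accuracy; per-repeat metrics come from the pooled fold predictions while
#' AUROC is averaged over folds (pooled optional); all metrics are then
#' averaged over repeats. Variable importance is extracted from a final
#' model fitted to all samples with hyperparameters selected on all data.
#'
#' @param counts [count_matrix()] of blood samples (one tissue, one sex).
#' @param metadata data.frame with sample_id, tissue and group columns
#'   covering the samples.
#' @param models subset of "elastic_net_lr", "random_forest", "plsda".
#' @param k,repeats outer cross-validation folds and repeats.
#' @param seed integer seed for fold plans, forests and selection.
#' @param grids hyperparameter grids as in [default_grids()].
#' @param k_inner inner CV folds for hyperparameter selection.
#' @param n_trees random forest size.
#' @param positive positive class label.
#' @param pooled_auc use pooled predictions instead of fold-averaged AUROC.
#' @return named list of `classifier_report` objects: per-model averaged
#'   metrics, ROC points from the last repeat's pooled predictions, ranked
#'   importance table, selected hyperparameters and nonzero-importance gene
#'   count.
#' @export
run_classification <- function(counts, metadata,
                               models = c("elastic_net_lr", "random_forest",
                                          "plsda"),
                               k = 5, repeats = 10, seed = 1,
                               grids = NULL, k_inner = 5, n_trees = 500,
                               positive = "CIE", pooled_auc = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  md <- metadata[match(counts$samples, metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) stop("samples missing from metadata")
  if (length(unique(md$tissue)) > 1)
    stop("mixed tissues in classifier input")
  y <- md$group
  if (is.null(grids)) grids <- default_grids(length(counts$genes))
  plans <- repeated_cv_split(y, k = k, repeats = repeats, seed = seed)
  reports <- list()
  for (model in models) {
    per_repeat <- list()
    last_pool <- NULL
    for (r in seq_along(plans)) {
      folds <- plans[[r]]
      pool_scores <- numeric(0); pool_calls <- logical(0)
      pool_truth <- logical(0); fold_aucs <- numeric(0)
      for (f in seq_along(folds)) {
        te <- folds[[f]]; tr <- setdiff(seq_along(y), te)
        nz <- fold_normalize(counts$counts[, tr, drop = FALSE],
                             counts$counts[, te, drop = FALSE])
        params <- .select_hyperparams(model, nz$train, y[tr],
                                      grids[[model]], k_inner, n_trees,
                                      seed + 1000L * r + f)
        res <- .fit_predict(model, nz$train, y[tr], nz$test, params,
                            n_trees, seed + 1000L * r + f)
        truth <- y[te] == positive
        pool_scores <- c(pool_scores, res$scores)
        pool_calls <- c(pool_calls, res$calls)
        pool_truth <- c(pool_truth, truth)
        if (any(truth) && any(!truth))
          fold_aucs <- c(fold_aucs, roc_auc(res$scores, truth)$auc)
      }
      cm <- confusion_matrix(pool_calls, pool_truth)
      met <- metrics(cm)
      auc <- if (pooled_auc || !length(fold_aucs))
        roc_auc(pool_scores, pool_truth)$auc else mean(fold_aucs)
      per_repeat[[r]] <- c(met, auroc = auc)
      last_pool <- list(scores = pool_scores, truth = pool_truth)
    }
    avg <- colMeans(do.call(rbind, per_repeat))
    # final model on all samples for importance
    nz_all <- fold_normalize(counts$counts, counts$counts)
    final_params <- .select_hyperparams(model, nz_all$train, y,
                                        grids[[model]], k_inner, n_trees,
                                        seed)
    final <- .fit_predict(model, nz_all$train, y, nz_all$train,
                          final_params, n_trees, seed)
    imp <- .importance_of(model, final$fit)
    reports[[model]] <- structure(list(
      model = model, metrics = avg,
      per_repeat = do.call(rbind, per_repeat),
      roc = roc_auc(last_pool$scores, last_pool$truth)$roc,
      importance = imp,
      hyperparameters = final_params,
      n_nonzero = sum(imp$importance != 0),
      k = k, repeats = repeats, seed = seed),
      class = "classifier_report")
  }
  reports
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("classifier_report:", x$model, sprintf("(%d-fold CV x %d repeats)\n",
                                             x$k, x$repeats))
  print(round(x$metrics, 4))
  cat("selected:", paste(names(x$hyperparameters), "=",
                         unlist(x$hyperparameters), collapse = ", "),
      "|", x$n_nonzero, "genes with nonzero importance\n")
  invisible(x)
}

#' @export
plot.classifier_report <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("%s (mean AUROC %.3f)", x$model, x$metrics["auroc"]),
       ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
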