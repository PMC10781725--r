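#' Prediction configuration
#'
#' Tuning grids and folds for the leave-one-study-out biomarker prediction.
#' Defaults: elastic-net mixing alpha over \{0, 0.25, 0.5, 0.75, 1\} and 50
#' log-spaced regularization values; random forest over ntree \{500, 1000\}
#' and mtry \{sqrt(p), p/3, p/2\}; 5 stratified inner folds.
#'
#' @param model `"elastic_net"` or `"random_forest"`.
#' @param alpha_grid elastic-net mixing parameters in \[0,1\].
#' @param lambda_grid positive regularization values.
#' @param ntree_grid numbers of trees (each at least 100).
#' @param mtry_grid variables sampled per split; `NULL` picks
#'   \{sqrt(p), p/3, p/2\} from the feature count at fit time.
#' @param inner_folds inner cross-validation folds for tuning.
#' @param seed integer seed.
#' @return an object of class `prediction_config`.
#' @export
prediction_config <- function(model = c("elastic_net", "random_forest"),
                              alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                              lambda_grid = 10^seq(1, -4, length.out = 50),
                              ntree_grid = c(500, 1000),
                              mtry_grid = NULL,
                              inner_folds = 5, seed = 1L) {
  model <- match.arg(model)
  if (!length(alpha_grid) || any(alpha_grid < 0 | alpha_grid > 1)) {
    stopf("alpha_grid must be non-empty with values in [0,1]")
  }
  if (!length(lambda_grid) || any(lambda_grid <= 0)) {
    stopf("lambda_grid must be non-empty and positive")
  }
  if (!length(ntree_grid) || any(ntree_grid < 100)) {
    stopf("ntree_grid must be non-empty with ntree >= 100")
  }
  structure(list(model = model, alpha_grid = alpha_grid,
                 lambda_grid = sort(lambda_grid, decreasing = TRUE),
                 ntree_grid = as.integer(ntree_grid),
                 mtry_grid = mtry_grid,
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "prediction_config")
}

#' Standardize expression per gene within each study
#'
#' Centers and scales every gene to mean 0 and standard deviation 1 within
#' each study independently (reducing between-study heterogeneity), restricts
#' to the supplied meta-analysis DEG list, and stacks the studies into one
#' samples-by-genes feature matrix.  Standardization constants are per-study,
#' so no information crosses the leave-one-study-out boundary.
#'
#' @param studies list of normalized `expression_study` objects.
#' @param genes DEG symbols to keep; every gene must be present in every study.
#' @return list: `features` (samples x genes), `labels` (factor,
#'   case/control), `study_ids` (per sample).
#' @export
standardize_per_gene <- function(studies, genes) {
  genes <- unique(normalize_gene(genes))
  parts <- lapply(studies, function(st) {
    stopifnot(inherits(st, "expression_study"))
    missing <- setdiff(genes, st$genes)
    if (length(missing)) {
      stopf("study '%s' lacks genes: %s", st$study_id,
            paste(utils::head(missing, 5), collapse = ", "))
    }
    m <- st$values[match(genes, st$genes), , drop = FALSE]
    mu <- rowMeans(m)
    sdev <- apply(m, 1, stats::sd)
    zero <- sdev == 0
    if (any(zero)) {
      warnf("study '%s': %d genes with zero variance set to 0", st$study_id,
            sum(zero))
      sdev[zero] <- 1
      m[zero, ] <- mu[zero]   # constant rows become all-zero after centering
    }
    z <- t((m - mu) / sdev)
    list(z = z,
         labels = ifelse(st$group == st$case_level, "case", "control"),
         ids = rep(st$study_id, ncol(m)))
  })
  list(features = do.call(rbind, lapply(parts, `[[`, "z")),
       labels = factor(unlist(lapply(parts, `[[`, "labels")),
                       levels = c("control", "case")),
       study_ids = unlist(lapply(parts, `[[`, "ids")))
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every fold keeps the class balance.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

accuracy_at_half <- function(prob_case, labels) {
  pred <- ifelse(prob_case > 0.5, "case", "control")
  mean(pred == as.character(labels))
}

# Inner-CV tuning + final fit on the supplied data, per model family.
# Tuning optimizes mean inner-fold accuracy at the 0.5 threshold; grid ties
# keep the first setting in enumeration order.
tune_and_fit <- function(x, y, cfg) {
  folds <- stratified_folds(y, cfg$inner_folds)
  if (cfg$model == "elastic_net") {
    grid <- expand.grid(alpha = cfg$alpha_grid, lambda = NA)
    acc <- matrix(0, nrow = length(cfg$alpha_grid), ncol = length(cfg$lambda_grid))
    for (f in seq_len(cfg$inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
      for (a in seq_along(cfg$alpha_grid)) {
        fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                              alpha = cfg$alpha_grid[a], lambda = cfg$lambda_grid)
        pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response",
                             s = cfg$lambda_grid, exact = FALSE)
        acc[a, ] <- acc[a, ] + vapply(seq_len(ncol(pr)), function(j) {
          accuracy_at_half(pr[, j], y[!tr])
        }, 0)
      }
    }
    best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
    alpha <- cfg$alpha_grid[best[1]]
    lambda <- cfg$lambda_grid[best[2]]
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = cfg$lambda_grid)
    list(predict = function(newx) {
      as.numeric(stats::predict(fit, newx, type = "response", s = lambda))
    },
    params = list(alpha = alpha, lambda = lambda),
    coefs = {
      b <- as.matrix(stats::coef(fit, s = lambda))[, 1]
      b[names(b) != "(Intercept)"]
    })
  } else {
    mtry_grid <- cfg$mtry_grid %||%
      unique(pmax(1, round(c(sqrt(ncol(x)), ncol(x) / 3, ncol(x) / 2))))
    grid <- expand.grid(ntree = cfg$ntree_grid, mtry = mtry_grid)
    acc <- numeric(nrow(grid))
    for (f in seq_len(cfg$inner_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
      for (gi in seq_len(nrow(grid))) {
        fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                          ntree = grid$ntree[gi],
                                          mtry = grid$mtry[gi])
        pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "prob")[, "case"]
        acc[gi] <- acc[gi] + accuracy_at_half(pr, y[!tr])
      }
    }
    gi <- which.max(acc)
    fit <- randomForest::randomForest(x, y, ntree = grid$ntree[gi],
                                      mtry = grid$mtry[gi], importance = TRUE)
    list(predict = function(newx) {
      stats::predict(fit, newx, type = "prob")[, "case"]
    },
    params = as.list(grid[gi, ]),
    importance = randomForest::importance(fit)[, "MeanDecreaseAccuracy"])
  }
}

#' Leave-one-study-out cross-validated prediction
#'
#' Each study in turn is held out as test data; the model is tuned by nested
#' stratified cross-validation within the remaining (training) studies, refit
#' at the best grid setting, and scored on the held-out study.  Accuracy is
#' the fraction of samples classified correctly at the 0.5 probability
#' threshold; the final reported accuracy is the arithmetic mean over the
#' held-out studies.  Deterministic given the configuration seed.
#'
#' @param features samples x genes matrix from [standardize_per_gene()].
#' @param labels factor of case/control labels.
#' @param study_ids per-sample study ids.
#' @param cfg a [prediction_config()].
#' @return object of class `cv_report`: `per_study` (data.frame of study and
#'   accuracy), `mean_accuracy`, `tuned` (per-fold chosen parameters),
#'   `model`, `seed`.
#' @export
loso_cv <- function(features, labels, study_ids, cfg = prediction_config()) {
  studies <- unique(study_ids)
  if (length(studies) < 3) stopf("leave-one-study-out needs at least 3 studies")
  labels <- factor(as.character(labels), levels = c("control", "case"))
  res <- with_seed(cfg$seed, {
    lapply(studies, function(s) {
      tr <- study_ids != s
      if (length(unique(labels[tr])) < 2) {
        stopf("training fold with study '%s' held out is single-class", s)
      }
      fit <- tune_and_fit(features[tr, , drop = FALSE], labels[tr], cfg)
      prob <- fit$predict(features[!tr, , drop = FALSE])
      list(study = s, accuracy = accuracy_at_half(prob, labels[!tr]),
           params = fit$params)
    })
  })
  per_study <- data.frame(study = vapply(res, `[[`, "", "study"),
                          accuracy = vapply(res, `[[`, 0, "accuracy"),
                          stringsAsFactors = FALSE)
  structure(list(per_study = per_study,
                 mean_accuracy = mean(per_study$accuracy),
                 tuned = lapply(res, `[[`, "params"),
                 model = cfg$model, seed = cfg$seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOSO-CV (%s): mean accuracy %.3f over %d studies\n",
              x$model, x$mean_accuracy, nrow(x$per_study)))
  print(x$per_study)
  invisible(x)
}

#' Rank features from a final model fit on all studies pooled
#'
#' Fits the configured model once on all samples (tuned by the same nested
#' inner CV) and ranks genes: elastic net by absolute coefficient (nonzero
#' only), random forest by permutation importance.
#'
#' @param features,labels,study_ids as in [loso_cv()].
#' @param cfg a [prediction_config()].
#' @param k number of top genes to return.
#' @return list: `ranking` (data.frame gene/score sorted descending),
#'   `top` (character vector of up to k genes), `n_selected` (nonzero
#'   features, elastic net only).
#' @export
top_features <- function(features, labels, study_ids,
                         cfg = prediction_config(), k = 10) {
  labels <- factor(as.character(labels), levels = c("control", "case"))
  fit <- with_seed(derive_seed(cfg$seed, "final"), {
    tune_and_fit(features, labels, cfg)
  })
  score <- if (cfg$model == "elastic_net") {
    s <- abs(fit$coefs)
    s[s > 0]
  } else {
    fit$importance
  }
  ranking <- data.frame(gene = names(score), score = unname(score),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$score, ranking$gene), , drop = FALSE]
  rownames(ranking) <- NULL
  if (k > nrow(ranking)) {
    warnf("k = %d exceeds the %d ranked features; returning all", k, nrow(ranking))
  }
  list(ranking = ranking,
       top = utils::head(ranking$gene, k),
       n_selected = nrow(ranking),
       params = fit$params)
}
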