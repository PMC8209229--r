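# Ensemble prediction of alanine-mutant chromogenic activity from residue
# network features: RBF-kernel SVM, naive Bayes and gradient-boosted trees,
# tuned by grid search under stratified 10-fold cross-validation (mean
# Cohen's Kappa, AUC tie-break), combined by the median of the predicted
# High-class probabilities, with an uncertainty flag band around 0.5.

.DEFAULT_FEATURES <- .CENTRALITY_MEASURES

#' Default hyperparameter grids
#'
#' The scaled-down grids used by default (SVM gamma in steps of 0.05 up to
#' 1.5; tree depth over the odd values 1-25; learning rate 0.3 with the L2
#' penalty at the lattice ends) keep a tuning run fast; \code{full = TRUE}
#' returns the dense
#' grids (gamma step 0.01, every depth 1-25, 0.1-step lattices for the
#' learning rate and L2 penalty).
#'
#' @param full use the dense grids.
#' @return list with \code{svmGamma}, \code{xgbDepth}, \code{xgbEta},
#'   \code{xgbLambda}, \code{xgbNrounds}.
#' @export
classifierGrids <- function(full = FALSE) {
  if (full) {
    list(svmGamma = seq(0.01, 1.5, by = 0.01), xgbDepth = 1:25,
         xgbEta = seq(0, 1, by = 0.1), xgbLambda = seq(0, 1, by = 0.1),
         xgbNrounds = 50L)
  } else {
    list(svmGamma = seq(0.05, 1.5, by = 0.05), xgbDepth = seq(1L, 25L, by = 2L),
         xgbEta = 0.3, xgbLambda = c(0, 1),
         xgbNrounds = 50L)
  }
}

#' Assemble the classifier feature table
#'
#' Joins mutant records to the centrality table by residue key, derives the
#' High/Low label from the 50-percent-of-wild-type rule (records exactly at
#' 50 get the configurable tie label, Low by default), drops mutants whose
#' position is not a network node (logged) and rows with any missing
#' feature (the missing-row rule). Features are stored unnormalized;
#' normalization parameters are estimated on training folds at fit time.
#'
#' @param tab centrality table from [computeCentralities()].
#' @param mutants data.frame with \code{key} and either \code{label} or
#'   \code{chromogenic_pct}.
#' @param features feature columns to use (default: the seven
#'   centralities).
#' @param normalization \code{"zscore"} (default) or \code{"minmax"}.
#' @param tieLabel label for records exactly at 50 percent (default
#'   \code{"Low"}).
#' @return object of class \code{FeatureTable}: list with matrix \code{x},
#'   factor \code{y} (levels Low, High), \code{keys}, \code{features},
#'   \code{normalization}.
#' @export
buildFeatureTable <- function(tab, mutants, features = .DEFAULT_FEATURES,
                              normalization = c("zscore", "minmax"),
                              tieLabel = "Low") {
  normalization <- match.arg(normalization)
  stopifnot(all(features %in% names(tab)), "key" %in% names(mutants))
  idx <- match(mutants$key, tab$key)
  unresolved <- sum(is.na(idx))
  if (unresolved) {
    .logInfo("buildFeatureTable: %d mutant(s) at residues absent from the network dropped", unresolved)
  }
  keep <- !is.na(idx)
  mut <- mutants[keep, , drop = FALSE]
  x <- as.matrix(tab[idx[keep], features, drop = FALSE])

  if (!is.null(mut$label)) {
    y <- mut$label
  } else if (!is.null(mut$chromogenic_pct)) {
    y <- ifelse(mut$chromogenic_pct > 50, "High",
                ifelse(mut$chromogenic_pct < 50, "Low", tieLabel))
  } else stop("mutants need a 'label' or 'chromogenic_pct' column")

  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    .logInfo("buildFeatureTable: %d row(s) with missing feature values dropped", sum(!complete))
  }
  x <- x[complete, , drop = FALSE]
  y <- y[complete]
  keys <- mut$key[complete]
  if (nrow(x) == 0L) stop("no usable instances after filtering")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance feature column(s): ",
         paste(features[v == 0], collapse = ", "))
  }
  structure(list(x = x, y = factor(y, levels = c("Low", "High")),
                 keys = keys, features = features,
                 normalization = normalization),
            class = "FeatureTable")
}

# normalization parameters from a training matrix, and their application
.normParams <- function(x, type) {
  if (type == "zscore") {
    list(type = type, center = colMeans(x), scale = apply(x, 2, stats::sd))
  } else {
    list(type = type, center = apply(x, 2, min),
         scale = apply(x, 2, max) - apply(x, 2, min))
  }
}
.applyNorm <- function(x, p) {
  s <- ifelse(p$scale == 0, 1, p$scale)
  sweep(sweep(x, 2, p$center), 2, s, "/")
}

.stratifiedFolds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.kappa <- function(truth, pred) {
  lv <- union(levels(factor(truth)), levels(factor(pred)))
  t2 <- table(factor(truth, lv), factor(pred, lv))
  n <- sum(t2)
  po <- sum(diag(t2)) / n
  pe <- sum(rowSums(t2) * colSums(t2)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# AUC as the rank (Mann-Whitney) statistic of scores for the High class
.aucRank <- function(score, truth) {
  pos <- truth == "High"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# gradient-boosted trees via the stable xgb.train interface; single thread
# and no subsampling, so fits are deterministic
.fitXgb <- function(x, y, depth, eta, lambda, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "High"))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = depth,
                  eta = eta, lambda = lambda, nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

# one member x one hyperparameter setting: out-of-fold High probabilities
.oofProbs <- function(member, params, x, y, fold, k, seed, nrounds = 50L) {
  p <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    np <- .normParams(x[tr, , drop = FALSE], "zscore")
    xtr <- .applyNorm(x[tr, , drop = FALSE], np)
    xte <- .applyNorm(x[te, , drop = FALSE], np)
    set.seed(seed + 7919L * f)
    if (member == "svm") {
      fit <- e1071::svm(xtr, y[tr], kernel = "radial", gamma = params$gamma,
                        probability = TRUE, scale = FALSE)
      pr <- attr(stats::predict(fit, xte, probability = TRUE), "probabilities")
      p[te] <- pr[, "High"]
    } else if (member == "nb") {
      fit <- e1071::naiveBayes(as.data.frame(xtr), y[tr])
      p[te] <- stats::predict(fit, as.data.frame(xte), type = "raw")[, "High"]
    } else {
      fit <- .fitXgb(xtr, y[tr], params$depth, params$eta, params$lambda, nrounds)
      p[te] <- stats::predict(fit, xgboost::xgb.DMatrix(xte))
    }
  }
  p
}

.foldMetrics <- function(p, y, fold, k) {
  do.call(rbind, lapply(seq_len(k), function(f) {
    te <- fold == f
    pred <- ifelse(p[te] >= 0.5, "High", "Low")
    data.frame(fold = f,
               accuracy = mean(pred == as.character(y[te])),
               kappa = .kappa(as.character(y[te]), pred),
               auc = .aucRank(p[te], as.character(y[te])))
  }))
}

#' Train the three ensemble members
#'
#' Grid search per member (RBF SVM over gamma; naive Bayes with nothing to
#' tune; gradient-boosted trees over depth, learning rate and L2 penalty)
#' under stratified k-fold cross-validation. Normalization parameters are
#' estimated on each training fold only. The setting with the highest mean
#' fold Kappa wins, ties broken by mean AUC, then by grid order. All
#' randomness derives from \code{seed}.
#'
#' @param ft a \code{FeatureTable} from [buildFeatureTable()].
#' @param folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param grids hyperparameter grids from [classifierGrids()].
#' @param flagBand uncertainty band for the ensemble out-of-fold summary
#'   (default \code{c(0.4, 0.6)}).
#' @return object of class \code{EnsembleModel}: fitted members, chosen
#'   hyperparameters, per-fold metrics per member, out-of-fold member and
#'   ensemble probabilities, and the ensemble CV summary (accuracy, Kappa,
#'   AUC, flagged fraction, accuracy on unflagged instances).
#' @export
trainMembers <- function(ft, folds = 10L, seed = 1L, grids = classifierGrids(),
                         flagBand = c(0.4, 0.6)) {
  stopifnot(inherits(ft, "FeatureTable"))
  x <- ft$x; y <- ft$y
  if (nlevels(droplevels(y)) < 2) stop("single-class input")
  if (length(y) < folds * 2) stop("need at least ", folds * 2, " instances")
  if (min(table(y)) < folds) {
    stop("minority class too small for ", folds, " stratified folds")
  }
  fold <- .stratifiedFolds(y, folds, seed)

  searchMember <- function(member, paramGrid) {
    best <- NULL
    for (gi in seq_len(nrow(paramGrid))) {
      params <- as.list(paramGrid[gi, , drop = FALSE])
      p <- .oofProbs(member, params, x, y, fold, folds, seed,
                     nrounds = grids$xgbNrounds)
      fm <- .foldMetrics(p, y, fold, folds)
      score <- c(mean(fm$kappa), mean(fm$auc, na.rm = TRUE))
      if (is.null(best) || score[1] > best$score[1] + 1e-12 ||
          (abs(score[1] - best$score[1]) <= 1e-12 && score[2] > best$score[2] + 1e-12)) {
        best <- list(params = params, oof = p, foldMetrics = fm, score = score)
      }
    }
    best
  }

  members <- list(
    svm = searchMember("svm", data.frame(gamma = grids$svmGamma)),
    nb = searchMember("nb", data.frame(dummy = 0)),
    xgb = searchMember("xgb", expand.grid(depth = grids$xgbDepth,
                                          eta = grids$xgbEta,
                                          lambda = grids$xgbLambda))
  )

  # final fits on all data with the chosen settings
  np <- .normParams(x, ft$normalization)
  xn <- .applyNorm(x, np)
  set.seed(seed)
  fits <- list(
    svm = e1071::svm(xn, y, kernel = "radial",
                     gamma = members$svm$params$gamma,
                     probability = TRUE, scale = FALSE),
    nb = e1071::naiveBayes(as.data.frame(xn), y),
    xgb = .fitXgb(xn, y, members$xgb$params$depth, members$xgb$params$eta,
                  members$xgb$params$lambda, grids$xgbNrounds)
  )

  oof <- cbind(svm = members$svm$oof, nb = members$nb$oof, xgb = members$xgb$oof)
  cmb <- .combineProbs(oof, flagBand)
  med <- cmb$median_probability
  flagged <- cmb$flagged
  pred <- cmb$predicted_label
  ensembleCV <- list(
    accuracy = mean(pred == as.character(y)),
    kappa = .kappa(as.character(y), pred),
    auc = .aucRank(med, as.character(y)),
    flaggedFraction = mean(flagged),
    accuracyUnflagged = if (all(flagged)) NA_real_ else
      mean(pred[!flagged] == as.character(y)[!flagged])
  )

  structure(list(
    fits = fits, norm = np, features = ft$features,
    bestParams = lapply(members, `[[`, "params"),
    foldMetrics = lapply(members, `[[`, "foldMetrics"),
    oofProb = oof, oofMedian = med, folds = fold, seed = seed,
    flagBand = flagBand, ensembleCV = ensembleCV, y = y
  ), class = "EnsembleModel")
}

# median-probability combiner: the median of the three member High-class
# probabilities is the middle order statistic, so it is always bounded by
# the member probabilities; flagged iff the median falls in the closed band
.combineProbs <- function(probs, flagBand) {
  med <- apply(probs, 1, stats::median)
  data.frame(
    median_probability = med,
    predicted_label = ifelse(med >= 0.5, "High", "Low"),
    flagged = med >= flagBand[1] & med <= flagBand[2],
    stringsAsFactors = FALSE
  )
}

#' Ensemble prediction by median member probability
#'
#' Applies the stored normalization, queries the three members for the
#' High-class probability, takes their median (the middle order statistic,
#' so it is always bounded by the member probabilities), labels High when
#' the median is at least 0.5, and flags instances whose median falls
#' inside the uncertainty band.
#'
#' @param model an \code{EnsembleModel} from [trainMembers()].
#' @param x matrix or data.frame with the model's feature columns.
#' @param flagBand closed uncertainty interval (default the model's,
#'   normally \code{c(0.4, 0.6)}).
#' @return data.frame: \code{p_svm}, \code{p_nb}, \code{p_xgb},
#'   \code{median_probability}, \code{predicted_label}, \code{flagged}.
#' @export
ensemblePredict <- function(model, x, flagBand = model$flagBand) {
  stopifnot(inherits(model, "EnsembleModel"),
            flagBand[1] > 0, flagBand[2] < 1, flagBand[1] <= flagBand[2])
  x <- as.matrix(as.data.frame(x)[, model$features, drop = FALSE])
  if (ncol(x) != length(model$features)) stop("feature schema mismatch")
  xn <- .applyNorm(x, model$norm)
  pSvm <- attr(stats::predict(model$fits$svm, xn, probability = TRUE),
               "probabilities")[, "High"]
  pNb <- stats::predict(model$fits$nb, as.data.frame(xn), type = "raw")[, "High"]
  pXgb <- stats::predict(model$fits$xgb, xgboost::xgb.DMatrix(xn))
  out <- .combineProbs(cbind(pSvm, pNb, pXgb), flagBand)
  cbind(data.frame(p_svm = unname(pSvm), p_nb = unname(pNb),
                   p_xgb = unname(pXgb), stringsAsFactors = FALSE), out)
}

#' Evaluate ensemble predictions
#'
#' @param pred data.frame from [ensemblePredict()] (or any frame with
#'   \code{predicted_label}, \code{median_probability}, \code{flagged}).
#' @param truth character/factor of true High/Low labels.
#' @return one-row data.frame: overall accuracy, accuracy on unflagged
#'   instances (NA when everything is flagged), Cohen's Kappa, AUC (rank
#'   statistic over the median probabilities), flagged fraction.
#' @export
evaluatePredictions <- function(pred, truth) {
  stopifnot(length(truth) == nrow(pred), length(truth) >= 2)
  truth <- as.character(truth)
  if (length(unique(truth)) < 2) stop("truth must contain both classes")
  acc <- mean(pred$predicted_label == truth)
  accU <- if (all(pred$flagged)) NA_real_ else
    mean(pred$predicted_label[!pred$flagged] == truth[!pred$flagged])
  data.frame(
    accuracy = acc, accuracy_unflagged = accU,
    kappa = .kappa(truth, pred$predicted_label),
    auc = .aucRank(pred$median_probability, truth),
    flagged_fraction = mean(pred$flagged)
  )
}
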