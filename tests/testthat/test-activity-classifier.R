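# small, well-separated feature tables keep the classifier unit tests fast
fastGrids <- list(svmGamma = c(0.1, 1), xgbDepth = c(2L, 4L),
                  xgbEta = 0.3, xgbLambda = 1, xgbNrounds = 20L)

separableTable <- function(n = 60, gap = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c("Low", "High"), each = n / 2)
  data.frame(key = paste0("A:", 1:n),
             degree = rnorm(n) + ifelse(y == "High", gap, 0),
             betweenness = rnorm(n) + ifelse(y == "High", gap, 0),
             closeness = runif(n),
             label = y, stringsAsFactors = FALSE)
}

test_that("feature tables drop unresolvable mutants and flag degenerate columns", {
  tab <- separableTable()
  mut <- data.frame(key = c(tab$key, "Z:999"), label = c(tab$label, "High"))
  ft <- suppressMessages(buildFeatureTable(tab, mut, features = c("degree", "betweenness", "closeness")))
  expect_equal(nrow(ft$x), 60)  # the off-structure mutant is gone
  expect_s3_class(ft, "FeatureTable")
  tab$flat <- 2
  expect_error(
    suppressMessages(buildFeatureTable(tab, mut, features = c("degree", "flat"))),
    "flat")
  expect_error(
    suppressMessages(buildFeatureTable(tab, data.frame(key = "Z:1", label = "High"),
                                       features = "degree")),
    "no usable instances")
})

test_that("labels follow the 50 percent rule with ties assigned Low", {
  tab <- separableTable()
  mut <- data.frame(key = tab$key[1:4],
                    chromogenic_pct = c(49.9, 50, 50.1, 80))
  ft <- suppressMessages(buildFeatureTable(tab, mut,
                                           features = c("degree", "betweenness")))
  expect_equal(as.character(ft$y), c("Low", "Low", "High", "High"))
})

test_that("training is deterministic under a fixed seed", {
  ft <- suppressMessages(buildFeatureTable(separableTable(),
    data.frame(key = separableTable()$key, label = separableTable()$label),
    features = c("degree", "betweenness", "closeness")))
  m1 <- trainMembers(ft, folds = 5, seed = 42, grids = fastGrids)
  m2 <- trainMembers(ft, folds = 5, seed = 42, grids = fastGrids)
  expect_equal(m1$bestParams, m2$bestParams)
  expect_equal(m1$foldMetrics, m2$foldMetrics)
  expect_equal(m1$oofProb, m2$oofProb)
})

test_that("every member separates linearly separable data", {
  tab <- separableTable(n = 80, gap = 6)
  ft <- suppressMessages(buildFeatureTable(tab,
    data.frame(key = tab$key, label = tab$label),
    features = c("degree", "betweenness", "closeness")))
  m <- trainMembers(ft, folds = 5, seed = 7, grids = fastGrids)
  for (member in names(m$foldMetrics)) {
    expect_gte(mean(m$foldMetrics[[member]]$accuracy), 0.95)
  }
  expect_gte(m$ensembleCV$accuracy, 0.95)
})

test_that("single-class and undersized inputs are rejected", {
  tab <- separableTable()
  ftAll <- suppressMessages(buildFeatureTable(tab,
    data.frame(key = tab$key, label = "High"),
    features = c("degree", "betweenness")))
  expect_error(trainMembers(ftAll, folds = 5, seed = 1, grids = fastGrids),
               "single-class")
  ftSmall <- suppressMessages(buildFeatureTable(tab[1:8, ],
    data.frame(key = tab$key[1:8], label = tab$label[c(1:4, 31:34)]),
    features = c("degree", "betweenness")))
  expect_error(trainMembers(ftSmall, folds = 10, seed = 1, grids = fastGrids))
})

test_that("the median combiner follows the order-statistic contract", {
  cmb <- fviiiRIN:::.combineProbs(rbind(c(0.2, 0.5, 0.9),
                                        c(0.9, 0.8, 0.95),
                                        c(0.1, 0.2, 0.3)), c(0.4, 0.6))
  expect_equal(cmb$median_probability, c(0.5, 0.9, 0.2))
  expect_equal(cmb$predicted_label, c("High", "High", "Low"))
  expect_equal(cmb$flagged, c(TRUE, FALSE, FALSE))
  # median bounded by member extremes on random triples
  set.seed(13)
  probs <- matrix(runif(300), ncol = 3)
  cmb2 <- fviiiRIN:::.combineProbs(probs, c(0.4, 0.6))
  expect_true(all(cmb2$median_probability >= apply(probs, 1, min)))
  expect_true(all(cmb2$median_probability <= apply(probs, 1, max)))
})

test_that("end-to-end predictions evaluate correctly", {
  tab <- separableTable(n = 80, gap = 6)
  ft <- suppressMessages(buildFeatureTable(tab,
    data.frame(key = tab$key, label = tab$label),
    features = c("degree", "betweenness", "closeness")))
  m <- trainMembers(ft, folds = 5, seed = 7, grids = fastGrids)
  pred <- ensemblePredict(m, as.data.frame(ft$x))
  expect_equal(nrow(pred), 80)
  ev <- evaluatePredictions(pred, ft$y)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$auc, 0.95)
  expect_error(ensemblePredict(m, data.frame(degree = 1)), "undefined columns|schema")
})

test_that("evaluation metrics match their closed forms", {
  perfect <- data.frame(predicted_label = c("High", "Low", "High"),
                        median_probability = c(0.9, 0.1, 0.8),
                        flagged = FALSE)
  ev <- evaluatePredictions(perfect, c("High", "Low", "High"))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$kappa, 1)
  expect_equal(ev$auc, 1)
  # all-one-class prediction on balanced truth: chance agreement, Kappa 0
  allHigh <- data.frame(predicted_label = "High",
                        median_probability = 0.7, flagged = FALSE)[rep(1, 10), ]
  ev2 <- evaluatePredictions(allHigh, rep(c("High", "Low"), 5))
  expect_equal(ev2$kappa, 0)
  # printed 2x2 (40,10;10,40) gives Kappa 0.6
  truth <- c(rep("High", 50), rep("Low", 50))
  predlab <- c(rep("High", 40), rep("Low", 10), rep("High", 10), rep("Low", 40))
  ev3 <- evaluatePredictions(
    data.frame(predicted_label = predlab,
               median_probability = ifelse(predlab == "High", 0.8, 0.2),
               flagged = FALSE), truth)
  expect_equal(ev3$kappa, 0.6)
  # all instances flagged: accuracy on unflagged is missing
  ev4 <- evaluatePredictions(
    data.frame(predicted_label = c("High", "Low"),
               median_probability = c(0.55, 0.45), flagged = TRUE),
    c("High", "Low"))
  expect_true(is.na(ev4$accuracy_unflagged))
})

test_that("widening the flag band never lowers accuracy on unflagged instances", {
  set.seed(21)
  med <- runif(200)
  truth <- ifelse(runif(200) < plogis(6 * (med - 0.5)), "High", "Low")
  bands <- list(c(0.45, 0.55), c(0.4, 0.6), c(0.3, 0.7), c(0.2, 0.8))
  accs <- vapply(bands, function(b) {
    flagged <- med >= b[1] & med <= b[2]
    pred <- ifelse(med >= 0.5, "High", "Low")
    mean(pred[!flagged] == truth[!flagged])
  }, 0)
  expect_true(all(diff(accs) >= -1e-12))
})
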