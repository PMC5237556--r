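test_that("pairwise AUC follows the printed double sum with ties scoring 0", {
  expect_equal(auc_from_pairs(c(1, 1), c(0, 0)), 1)
  # P scores {0.9, 0.4}, N scores {0.5, 0.1}: pairs won = 3 of 4
  cp <- c(0.9, 0.4, 0.9, 0.4)
  cn <- c(0.5, 0.5, 0.1, 0.1)
  expect_equal(auc_from_pairs(cp, cn), 3 / 4)
  # all-equal scores: every pair is a tie, worth 0 (faithful rule)
  expect_equal(auc_from_pairs(rep(1, 4), rep(1, 4)), 0)
  expect_equal(auc_from_pairs(rep(1, 4), rep(1, 4), ties = "half"), 0.5)
})

test_that("pairwise AUC equals the rank-based WMW statistic without ties", {
  set.seed(14)
  for (i in 1:50) {
    p <- rnorm(sample(3:8, 1)); n <- rnorm(sample(3:8, 1))
    cp <- rep(p, times = length(n)); cn <- rep(n, each = length(p))
    # brute-force WMW: rank-sum statistic over the pooled scores
    r <- rank(c(p, n))
    U <- sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2
    expect_equal(auc_from_pairs(cp, cn), U / (length(p) * length(n)))
  }
})

test_that("the closed-form AUC variance matches its fixed points", {
  expect_equal(auc_variance(1, 10, 12), 0)
  expect_equal(auc_variance(0.5, 1, 1), 0.25)
  v <- auc_variance(0.93, 99, 99)
  expect_equal(v, 3.6289e-4, tolerance = 1e-3)
  expect_gt(sqrt(v), 0.0187); expect_lt(sqrt(v), 0.0191)
  expect_error(auc_variance(1.2, 5, 5), "0, 1|\\[0, 1\\]")
  # variance decreases monotonically with balanced n at A = 0.5
  ns <- c(5, 10, 20, 50, 100, 500)
  vs <- vapply(ns, function(n) auc_variance(0.5, n, n), 0)
  expect_true(all(diff(vs) < 0))
})

test_that("SMO decisions match a libsvm-style oracle through python", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(20, 0, 0.3) > 0)
  fit <- train_svm(X, y, svm_params(C = 1.3, gamma = 0.7))
  dec <- predict(fit, X)
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(X, y = y), file.path(dir, "d.csv"),
                   row.names = FALSE)
  script <- file.path(dir, "chk.py")
  writeLines(c(
    "import sys, numpy as np, pandas as pd",
    "from sklearn.svm import SVC",
    "d = pd.read_csv(sys.argv[1])",
    "X = d.iloc[:, :2].values; y = d.iloc[:, 2].values",
    "m = SVC(C=1.3, gamma=0.7, kernel='rbf').fit(X, y)",
    "np.savetxt(sys.argv[2], m.decision_function(X))"), script)
  out <- file.path(dir, "dec.txt")
  status <- system2("python", c(script, file.path(dir, "d.csv"), out))
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  expect_lt(max(abs(ref - dec)), 0.02)
})

test_that("training is deterministic and refuses single-class folds", {
  set.seed(4)
  X <- matrix(rnorm(30), 15, 2)
  y <- rep(c(0, 1), length.out = 15)
  d1 <- predict(train_svm(X, y), X)
  d2 <- predict(train_svm(X, y), X)
  expect_identical(d1, d2)
  expect_error(train_svm(X, rep(1, 15)), "single class")
  # 2-point separable set is ordered with its labels
  X2 <- rbind(c(-1, 0), c(1, 0))
  s <- predict(train_svm(X2, c(0, 1), svm_params(C = 10, gamma = 1)), X2)
  expect_gt(s[2], s[1])
})

test_that("LPOCV enumerates all pairs and separates linear blobs", {
  set.seed(6)
  X <- rbind(matrix(rnorm(20, 3), 10), matrix(rnorm(20, -3), 10))
  y <- rep(c(1, 0), each = 10)
  cv <- lpocv(X, y, params = svm_params(C = 1, gamma = 0.1))
  expect_equal(nrow(cv$pairs), 100)
  expect_true(all(cv$pairs$cp > cv$pairs$cn))
  expect_equal(cv$A, 1)
  expect_equal(cv$var, auc_variance(1, 10, 10))
})

test_that("the minimal 2+2 design trains on the other pair only", {
  X <- rbind(c(0, 1), c(0, 2), c(5, 1), c(5, 2))
  y <- c(1, 1, 0, 0)
  seen <- list()
  trainer <- function(Xtr, ytr) {
    seen[[length(seen) + 1L]] <<- nrow(Xtr)
    linear_trainer(Xtr, ytr)
  }
  cv <- lpocv(X, y, trainer = trainer)
  expect_equal(nrow(cv$pairs), 4)
  expect_true(all(unlist(seen) == 2))
})

test_that("exchanging the roles of P and N maps A to 1 - A without ties", {
  set.seed(9)
  X <- rbind(matrix(rnorm(24, 1), 6), matrix(rnorm(24, -1), 6))
  y <- rep(c(1, 0), each = 6)
  cv <- lpocv(X, y, trainer = linear_trainer)
  swapped <- auc_from_pairs(cv$pairs$cn, cv$pairs$cp)
  expect_equal(swapped, 1 - cv$A)   # continuous scores, no ties
  # retraining after a label swap leaves a symmetric trainer's AUC intact
  expect_equal(lpocv(X, 1 - y, trainer = linear_trainer)$A, cv$A)
})

test_that("compiled and R-level LPOCV paths agree for the SVM trainer", {
  set.seed(10)
  X <- rbind(matrix(rnorm(24, 1.5), 6), matrix(rnorm(24, -1.5), 6))
  y <- rep(c(1, 0), each = 6)
  svm_trainer <- function(Xtr, ytr) {
    fit <- train_svm(Xtr, ytr)
    function(Xn) predict(fit, Xn)
  }
  fast <- lpocv(X, y)
  slow <- lpocv(X, y, trainer = svm_trainer)
  expect_equal(fast$A, slow$A)
  expect_equal(fast$pairs$cp, slow$pairs$cp, tolerance = 1e-8)
})

test_that("labels may be factors or group strings", {
  set.seed(11)
  X <- rbind(matrix(rnorm(16, 2), 4), matrix(rnorm(16, -2), 4))
  y <- rep(c("PrADG", "HEG"), each = 4)
  cv <- lpocv(X, y, params = svm_params(C = 1, gamma = 0.2))
  expect_equal(cv$n_pos, 4); expect_equal(cv$n_neg, 4)
  expect_error(lpocv(X, rep("PrADG", 8)), "2 subjects per class")
})
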