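test_that("SMOTE balances classes with convex, collinear synthetics", {
  withr::with_seed(60, {
    x <- rbind(matrix(rnorm(11 * 16, mean = 2), 11),
               matrix(rnorm(5 * 16, mean = -2), 5))
    y <- c(rep("normal", 11), rep("cvd", 5))
    bal <- smote_augment(x, y, seed = 61)
  })
  expect_equal(as.integer(table(bal$labels)[c("cvd", "normal")]),
               c(11L, 11L))
  expect_equal(sum(bal$synthetic_mask), 6L)
  expect_equal(nrow(bal$features), 22L)

  # collinearity: each synthetic point lies on its parent segment
  for (s in which(bal$synthetic_mask)) {
    srow <- s - 16L
    pi_ <- bal$parents[srow, 1]; pj <- bal$parents[srow, 2]
    d <- x[pj, ] - x[pi_, ]
    v <- bal$features[s, ] - x[pi_, ]
    lam <- sum(v * d) / sum(d * d)
    expect_gte(lam, 0); expect_lte(lam, 1)
    expect_lt(sqrt(sum((v - lam * d)^2)), 1e-9)
  }

  # parents are k-nearest minority neighbors
  minority <- which(y == "cvd")
  dmat <- as.matrix(dist(x[minority, ]))
  for (srow in seq_len(nrow(bal$parents))) {
    i <- match(bal$parents[srow, 1], minority)
    j <- match(bal$parents[srow, 2], minority)
    k_nearest <- order(dmat[i, ])[-1][1:4]
    expect_true(j %in% k_nearest)
  }

  # bit-reproducible under a fixed seed
  bal2 <- smote_augment(x, y, seed = 61)
  expect_identical(bal$features, bal2$features)

  # interpolation endpoints
  end0 <- smote_augment(x, y, lambda = 0, seed = 61)
  end1 <- smote_augment(x, y, lambda = 1, seed = 61)
  for (srow in seq_len(6)) {
    expect_equal(end0$features[16 + srow, ], x[end0$parents[srow, 1], ])
    expect_equal(end1$features[16 + srow, ], x[end1$parents[srow, 2], ])
  }

  # error / clamp behavior
  expect_error(smote_augment(x[1:12, ], y[1:12]), "single sample")
  expect_warning(smote_augment(x, y, k = 10, seed = 1), "clamped")
})

test_that("knn matches an exhaustive all-pairs oracle", {
  expect_error(knn_predict(matrix(0, 3, 2), c("a", "b", "a"),
                           matrix(0, 1, 2), k = 0), "positive")
  # memorization at k = 1
  tr <- matrix(c(0, 0, 5, 5), 2, byrow = TRUE)
  expect_equal(knn_predict(tr, c("a", "b"), tr, k = 1), c("a", "b"))

  # two well-separated clusters
  withr::with_seed(62, {
    tr <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 10), 10, 2))
    ty <- rep(c("lo", "hi"), each = 10)
    te <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 10), 5, 2))
    expect_equal(knn_predict(tr, ty, te, k = 3),
                 rep(c("lo", "hi"), each = 5))
  })

  # oracle equivalence on 50 random instances (odd k avoids vote ties)
  withr::with_seed(63, {
    for (i in 1:50) {
      n <- sample(6:20, 1)
      p <- sample(2:5, 1)
      k <- sample(c(1, 3, 5), 1)
      tr <- matrix(rnorm(n * p), n)
      ty <- sample(c("x", "y"), n, replace = TRUE)
      te <- matrix(rnorm(3 * p), 3)
      oracle <- apply(te, 1, function(q) {
        d <- apply(tr, 1, function(r) sqrt(sum((r - q)^2)))
        votes <- sort(table(ty[order(d)[1:k]]), decreasing = TRUE)
        if (length(votes) > 1 && votes[1] == votes[2]) return(NA_character_)
        names(votes)[1]
      })
      mine <- knn_predict(tr, ty, te, k = k)
      idx <- !is.na(oracle)
      expect_equal(mine[idx], unname(oracle[idx]))
    }
  })
})

test_that("decision tree splits by information gain", {
  # pure data: zero entropy, depth-0 tree
  fit <- dt_fit(matrix(rnorm(10), 5), rep("a", 5))
  expect_true(fit$root$leaf)
  expect_equal(entropy_bits(rep("a", 5)), 0)
  # balanced two-class entropy is exactly 1 bit
  expect_equal(entropy_bits(rep(c("a", "b"), 5)), 1)

  # 1-D data perfectly separated at a threshold: depth-1, perfect training
  # accuracy, split at the midpoint found by an exhaustive oracle
  withr::with_seed(64, {
    x <- matrix(c(runif(8, 0, 1), runif(7, 2, 3)), ncol = 1)
    y <- c(rep("lo", 8), rep("hi", 7))
    fit <- dt_fit(x, y)
    expect_false(fit$root$leaf)
    expect_true(fit$root$left$leaf && fit$root$right$leaf)
    expect_equal(dt_predict(fit, x), y)

    cand <- sort(unique(x[, 1]))
    mids <- (cand[-1] + cand[-length(cand)]) / 2
    gains <- vapply(mids, function(thr) {
      l <- y[x[, 1] <= thr]; r <- y[x[, 1] > thr]
      entropy_bits(y) -
        (length(l) * entropy_bits(l) + length(r) * entropy_bits(r)) /
        length(y)
    }, numeric(1))
    expect_equal(fit$root$threshold, mids[which.max(gains)])
  })

  # depth cap respected
  withr::with_seed(65, {
    x <- matrix(rnorm(200), 100, 2)
    y <- sample(c("a", "b"), 100, replace = TRUE)
    depth <- function(node) {
      if (node$leaf) 0L else 1L + max(depth(node$left), depth(node$right))
    }
    expect_lte(depth(dt_fit(x, y, max_depth = 3)$root), 3L)
  })
})

test_that("polynomial svm separates linear and XOR patterns", {
  # linearly separable, degree 1
  withr::with_seed(66, {
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
    y <- rep(c("a", "b"), each = 20)
    fit <- svm_fit(x, y, degree = 1)
    expect_equal(svm_predict(fit, x), y)
  })

  # XOR needs the quadratic kernel
  xor_x <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4)
  xor_y <- c("a", "b", "b", "a")
  fit2 <- svm_fit(xor_x, xor_y, degree = 2, cost = 100)
  expect_equal(svm_predict(fit2, xor_x), xor_y)

  # dual feasibility: 0 <= |alpha_i| <= C
  expect_true(all(abs(fit2$fit$coefs) <= 100 + 1e-6))

  # kernel positivity: K(x, x) = (1 + |x|^2)^d >= 1
  kxx <- (1 + rowSums(xor_x^2))^2
  expect_true(all(kxx >= 1))

  expect_error(svm_fit(xor_x, rep("a", 4)), "two classes")
})

test_that("confusion metrics follow the precision/recall/F1 definitions", {
  perfect <- confusion_matrix(c(rep("cvd", 5), rep("normal", 11)),
                              c(rep("cvd", 5), rep("normal", 11)))
  m <- confusion_metrics(perfect)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  expect_equal(m$accuracy, 100)

  # hand arithmetic: TP=3, FP=1, FN=2, TN=4
  cm <- structure(list(tp = 3, fp = 1, fn = 2, tn = 4, positive = "cvd"),
                  class = "cvd_confusion")
  m <- confusion_metrics(cm)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$accuracy, 70)

  # degenerate: no positives predicted or present
  none <- structure(list(tp = 0, fp = 0, fn = 3, tn = 5, positive = "cvd"),
                    class = "cvd_confusion")
  m <- confusion_metrics(none)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_true(all(c("precision", "f1") %in% m$undefined[[1]]))
})

test_that("stratified cross-validation partitions and reports consistently", {
  withr::with_seed(70, {
    x <- rbind(matrix(rnorm(11 * 4, 3), 11), matrix(rnorm(5 * 4, -3), 5))
    y <- c(rep("normal", 11), rep("cvd", 5))
  })
  rep_ <- kfold_cv(x, y, classifier = "knn", seed = 71)
  expect_s3_class(rep_, "cvd_cv_report")
  expect_length(rep_$fold_accuracies, 5L)
  expect_equal(rep_$mean_accuracy, mean(rep_$fold_accuracies))
  # perfectly separated clusters classify perfectly
  expect_equal(rep_$mean_accuracy, 100)

  # accuracy equals (TP+TN)/total from the pooled confusion matrix exactly
  cm <- rep_$confusion
  total <- cm$tp + cm$tn + cm$fp + cm$fn
  expect_equal(total, 16L)
  expect_equal(rep_$mean_accuracy >= 0 && rep_$mean_accuracy <= 100, TRUE)
  pooled_acc <- 100 * (cm$tp + cm$tn) / total
  # folds have near-equal size, so fold-mean and pooled accuracy agree here
  expect_equal(pooled_acc, 100)

  # same seed reproduces the report; different seeds may not share folds
  rep2 <- kfold_cv(x, y, classifier = "knn", seed = 71)
  expect_identical(rep_$fold_accuracies, rep2$fold_accuracies)

  expect_error(kfold_cv(x, rep("one", 16)), "both classes")
  both <- c(1, 2, 12, 13)   # two per class, still fewer than 5 folds
  expect_error(kfold_cv(x[both, ], y[both], k_folds = 5), "fewer samples")
})

test_that("fold accuracy equals the correct-assignment percentage per fold", {
  withr::with_seed(72, {
    x <- rbind(matrix(rnorm(12 * 3, 2), 12), matrix(rnorm(8 * 3, -2), 8))
    y <- c(rep("normal", 12), rep("cvd", 8))
  })
  for (mode in c("fold_internal", "global", "none")) {
    rep_ <- kfold_cv(x, y, classifier = "dt", smote_mode = mode, seed = 73)
    expect_true(all(rep_$fold_accuracies >= 0 & rep_$fold_accuracies <= 100))
    cm <- rep_$confusion
    n_eval <- cm$tp + cm$tn + cm$fp + cm$fn
    if (mode == "global") {
      expect_equal(n_eval, 24L)  # balanced 12 + 12 after augmentation
    } else {
      expect_equal(n_eval, 20L)
    }
  }
})

test_that("tidy and glance expose report internals as tibbles", {
  withr::with_seed(74, {
    x <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
    y <- rep(c("normal", "cvd"), each = 10)
  })
  rep_ <- kfold_cv(x, y, classifier = "svm", seed = 75)
  td <- generics::tidy(rep_)
  expect_equal(nrow(td), 5L)
  expect_named(td, c("classifier", "feature_set", "fold", "accuracy"))
  gl <- generics::glance(rep_)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$mean_accuracy, rep_$mean_accuracy)
  expect_equal(gl$tp + gl$tn + gl$fp + gl$fn, 20L)

  cm_td <- generics::tidy(rep_$confusion)
  expect_equal(sum(cm_td$count), 20L)
})
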