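test_that("well-separated classes decode perfectly; shuffled labels sit at chance", {
  ds <- separableDataset(sep = 10, seed = 31)
  expect_equal(accuracy(looOvoDecode(ds, seed = 1)), 1)

  set.seed(32)
  accs <- vapply(1:150, function(s) {
    accuracy(looOvoDecode(nullDataset(p = 30, seed = 1000 + s), seed = s))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.2), 3 * sd(accs) / sqrt(150))
})

test_that("the balanced-fold LOO rule matches hand enumeration on a toy dataset", {
  # 1-D, values {0,0,1,1}: every fold trains on {0} vs {1}, midpoint 0.5
  ds <- decodingDataset(matrix(c(0, 0, 1, 1), 4, 1), c("a", "a", "b", "b"))
  res <- looOvoDecode(ds, seed = 1)
  expect_equal(accuracy(res), 1)
  expect_equal(unname(res@perClass), c(1, 1))

  expect_error(looOvoDecode(
    decodingDataset(matrix(rnorm(10), 5, 2), c("a", "a", "a", "b", "b"))),
    "equal trial counts")
})

test_that("decoder accuracy is invariant to joint affine rescaling of the voxels", {
  ds <- separableDataset(sep = 2.5, seed = 33)
  r1 <- looOvoDecode(ds, seed = 5)
  ds2 <- decodingDataset(3.7 * ds@X + 11, ds@y)
  r2 <- looOvoDecode(ds2, seed = 5)
  expect_identical(r1@details$predictions, r2@details$predictions)

  # Fisher with lambda = 0 is invariant to any invertible linear map
  dsf <- separableDataset(nClass = 3, nPerClass = 8, p = 4, sep = 2, seed = 34)
  set.seed(35)
  A <- matrix(rnorm(16), 4) + diag(4)
  f1 <- fisherDecode(dsf, shrinkage = 0, seed = 6)
  f2 <- fisherDecode(decodingDataset(dsf@X %*% A, dsf@y), shrinkage = 0,
                     seed = 6)
  expect_identical(f1@details$predictions, f2@details$predictions)
})

test_that("Fisher decoding matches a brute-force LOO oracle and its limits", {
  dsf <- separableDataset(nClass = 3, nPerClass = 6, p = 3, sep = 1.5,
                          seed = 36)
  X <- dsf@X; y <- dsf@y
  classes <- sort(unique(y))
  for (lam in c(0.3, 1)) {
    got <- fisherDecode(dsf, shrinkage = lam, seed = 7)@details$predictions
    ## naive per-fold recomputation (independent of the rank-1 updates)
    fold <- stats::ave(seq_along(y), y, FUN = seq_along)
    pred <- character(length(y))
    for (f in sort(unique(fold))) {
      te <- which(fold == f); tr <- which(fold != f)
      M <- t(sapply(classes, function(cl)
        colMeans(X[intersect(tr, which(y == cl)), , drop = FALSE])))
      R <- X[tr, ] - M[match(y[tr], classes), ]
      Sig <- crossprod(R) / (length(tr) - length(classes))
      Sg <- (1 - lam) * Sig + lam * diag(diag(Sig), ncol(X))
      for (i in te) {
        votes <- setNames(numeric(3), classes)
        for (a in 1:2) for (b in (a + 1):3) {
          w <- solve(Sg, M[a, ] - M[b, ])
          s <- sum((X[i, ] - (M[a, ] + M[b, ]) / 2) * w)
          if (s > 0) votes[a] <- votes[a] + 1 else votes[b] <- votes[b] + 1
        }
        pred[i] <- classes[which.max(votes)]
      }
    }
    expect_identical(got, pred)
  }

  # isotropic, well-separated data: Fisher and plain decoder agree
  ds <- separableDataset(sep = 8, seed = 37)
  expect_identical(fisherDecode(ds, 0.1, seed = 8)@details$predictions,
                   looOvoDecode(ds, seed = 8)@details$predictions)

  # lambda = 0 with singular covariance (p > n) fails with advice
  big <- nullDataset(nClass = 2, nPerClass = 4, p = 50, seed = 38)
  expect_error(fisherDecode(big, shrinkage = 0), "shrinkage")
})

test_that("covariance normalization beats the plain decoder under correlated noise", {
  ## 2 classes in 2-D: means differ along x; noise is strongly elongated
  ## along the oblique (1,1) axis and tight along (1,-1). The
  ## mean-difference rule projects onto x, where the oblique noise leaks
  ## in; the Fisher direction Sigma^-1 (mu_a - mu_b) exploits the
  ## low-noise combination and separates the classes.
  set.seed(39)
  n <- 20
  u <- c(1, 1) / sqrt(2); vPerp <- c(1, -1) / sqrt(2)
  noise <- function(n) outer(rnorm(n, sd = 3), u) + outer(rnorm(n, sd = 0.15), vPerp)
  X <- rbind(outer(rep(1, n), c(0.5, 0)) + noise(n),
             outer(rep(1, n), c(-0.5, 0)) + noise(n))
  ds <- decodingDataset(X, rep(c("a", "b"), each = n))
  accF <- accuracy(fisherDecode(ds, shrinkage = 0.05, seed = 9))
  accP <- accuracy(looOvoDecode(ds, seed = 9))
  expect_gt(accF, accP)
  expect_gt(accF, 0.9)
})

test_that("pseudo-populations concatenate class-matched trials across slices", {
  ds1 <- nullDataset(nClass = 3, nPerClass = 5, p = 4, seed = 41)
  ds2 <- nullDataset(nClass = 3, nPerClass = 5, p = 7, seed = 42)
  pp <- buildPseudopopulation(list(ds1, ds2), seed = 1)
  expect_equal(dim(pp@X), c(15L, 11L))
  expect_true(all(table(pp@y) == 5))

  # single slice: identity up to trial order
  pp1 <- buildPseudopopulation(list(ds1), seed = 2)
  expect_equal(dim(pp1@X), dim(ds1@X))
  for (cl in unique(ds1@y)) {
    a <- ds1@X[ds1@y == cl, ]; b <- pp1@X[pp1@y == cl, ]
    expect_equal(a[order(a[, 1]), ], b[order(b[, 1]), ])
  }

  # per-slice class means preserved exactly under assembly
  for (seed in 1:10) {
    pp2 <- buildPseudopopulation(list(ds1, ds2), seed = seed)
    for (cl in unique(ds1@y)) {
      expect_equal(colMeans(pp2@X[pp2@y == cl, 1:4, drop = FALSE]),
                   colMeans(ds1@X[ds1@y == cl, , drop = FALSE]),
                   tolerance = 1e-12)
      expect_equal(colMeans(pp2@X[pp2@y == cl, 5:11, drop = FALSE]),
                   colMeans(ds2@X[ds2@y == cl, , drop = FALSE]),
                   tolerance = 1e-12)
    }
  }

  # unequal trials per class -> truncated with warning
  ds3 <- decodingDataset(matrix(rnorm(8 * 3), 8), rep(c("a", "b", "c"),
                                                      c(3, 3, 2)))
  expect_warning(pp3 <- buildPseudopopulation(list(ds1, ds3), seed = 3),
                 "truncated")
  expect_equal(sort(as.integer(table(pp3@y))), c(2L, 3L, 3L))

  expect_error(buildPseudopopulation(list(
    ds1, decodingDataset(matrix(rnorm(8), 4), c("x", "x", "y", "y")))),
    "label set")
})

test_that("permutation testing is calibrated and flags degenerate runs", {
  # perfectly separable data: p at the 1/nPerm floor
  ds <- separableDataset(sep = 10, seed = 43)
  pt <- permutationTest(ds, "ovo", nPerm = 100, seed = 10)
  expect_true(pt@significant)
  expect_lte(pValue(pt), 0.01)
  expect_equal(length(nullDistribution(pt)), 100L)
  # label permutation keeps per-class composition, so on strongly
  # clustered data the null mean can sit somewhat above 1/K; it must
  # still stay far below the observed accuracy
  expect_lt(mean(nullDistribution(pt)), 0.45)
  expect_gt(mean(nullDistribution(pt)), 0.1)

  # nPerm = 1 is flagged as degenerate
  p1 <- permutationTest(ds, "ovo", nPerm = 1, seed = 11)
  expect_true(p1@details$degenerate)
  expect_gte(pValue(p1), 1)

  # determinism under a fixed seed
  pa <- permutationTest(ds, "ovo", nPerm = 20, seed = 12)
  pb <- permutationTest(ds, "ovo", nPerm = 20, seed = 12)
  expect_identical(nullDistribution(pa), nullDistribution(pb))
})

test_that("null-distribution mean approaches 1/K for many permutations", {
  ds <- nullDataset(nClass = 5, nPerClass = 4, p = 10, seed = 44)
  pt <- permutationTest(ds, "ovo", nPerm = 1000, seed = 13)
  nd <- nullDistribution(pt)
  expect_lt(abs(mean(nd) - 0.2), 3 * sd(nd) / sqrt(1000))
})

test_that("repeated-measures ANOVA matches the textbook decomposition and aov", {
  # printed 3-subject x 2-depth toy table, hand-computed
  m <- rbind(c(2, 4), c(3, 5), c(4, 9))
  rm <- repeatedMeasuresAnova(m)
  # hand: grand 4.5; cond means 3, 6; SS_cond = 3*(1.5^2+1.5^2) = 13.5
  # subj means 3, 4, 6.5; SS_subj = 2*(1.5^2+0.5^2+2^2) = 13
  # interaction SS = total - cond - subj
  tot <- sum((m - mean(m))^2)
  expect_equal(rm$table$ss[1], 13.5, tolerance = 1e-9)
  expect_equal(rm$table$ss[2], 13, tolerance = 1e-9)
  expect_equal(rm$table$ss[3], tot - 13.5 - 13, tolerance = 1e-9)
  expect_equal(rm$F, (13.5 / 1) / ((tot - 26.5) / 2), tolerance = 1e-9)

  # against aov with an Error(subject) stratum on a larger table
  set.seed(45)
  acc <- matrix(rnorm(4 * 5, mean = 0.5, sd = 0.1), 4, 5)
  acc[, 3] <- acc[, 3] + 0.15
  rm2 <- repeatedMeasuresAnova(acc)
  df <- data.frame(y = as.vector(acc),
                   subj = factor(rep(1:4, 5)),
                   depth = factor(rep(1:5, each = 4)))
  fit <- summary(stats::aov(y ~ depth + Error(subj / depth), df))
  fTab <- fit[["Error: subj:depth"]][[1]]
  expect_equal(rm2$F, fTab["depth", "F value"], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rm2$p, fTab["depth", "Pr(>F)"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("depth decoding equalizes voxels and detects a planted depth effect", {
  ## 4 subjects x 4 depths; middle depths get 3x response SNR
  mkDepth <- function(snr, p, seed) {
    set.seed(seed)
    mu <- matrix(rnorm(5 * p), 5) * snr / sqrt(p)
    X <- mu[rep(1:5, each = 6), ] * sqrt(p) + matrix(rnorm(30 * p), 30)
    decodingDataset(X, rep(letters[1:5], each = 6))
  }
  snrs <- c(0.4, 1.2, 1.2, 0.4)
  datasets <- lapply(1:4, function(s)
    lapply(1:4, function(d) mkDepth(snrs[d], p = 10 + 2 * d, seed = 50 * s + d)))
  dd <- depthDecoding(datasets, seed = 14)
  expect_equal(dim(dd$accuracy), c(4L, 4L))
  prof <- colMeans(dd$accuracy)
  expect_gt(mean(prof[2:3]), mean(prof[c(1, 4)]))
  expect_lt(dd$anova$p, 0.05)

  # no depth effect -> flat profile, non-significant at this seed
  flat <- lapply(1:3, function(s)
    lapply(1:3, function(d) mkDepth(0, p = 12, seed = 400 + 7 * s + d)))
  df <- depthDecoding(flat, seed = 15)
  expect_gt(df$anova$p, 0.05)

  # depth with zero voxels is excluded with a warning
  datasets2 <- datasets
  datasets2[[2]][[3]] <- decodingDataset(matrix(numeric(), 30, 0),
                                         rep(letters[1:5], each = 6))
  expect_warning(d2 <- depthDecoding(datasets2, seed = 16), "excluded")
  expect_equal(ncol(d2$accuracy), 3L)
})
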