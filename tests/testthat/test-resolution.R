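test_that("pairwise two-way ANOVA matches hand-computed sums of squares", {
  # tiny 2 x 2 x 2 balanced dataset, worked by hand
  a <- matrix(c(1, 3, 2, 6), 2)         # freq1: 1,3  freq2: 2,6
  b <- matrix(c(2, 2, 5, 7), 2)
  pa <- pairAnova(a, b)
  y <- c(1, 3, 2, 6, 2, 2, 5, 7)
  cells <- rbind(c(2, 4), c(2, 6))       # rows = voxel, cols = freq
  g <- mean(y)
  vm <- rowMeans(cells); fm <- colMeans(cells)
  ssV <- 2 * 2 * sum((vm - g)^2)
  ssI <- 2 * sum((cells - outer(vm, rep(1, 2)) - outer(rep(1, 2), fm) + g)^2)
  ssE <- sum((c(1, 3) - 2)^2) + sum((c(2, 6) - 4)^2) +
         sum((c(2, 2) - 2)^2) + sum((c(5, 7) - 6)^2)
  expect_equal(pa$Fvoxel, (ssV / 1) / (ssE / 4), tolerance = 1e-12)
  expect_equal(pa$Finteraction, (ssI / 1) / (ssE / 4), tolerance = 1e-12)

  # b = a exactly: all F zero, nothing dissimilar
  same <- pairAnova(a, a)
  expect_equal(same$Fvoxel, 0)
  expect_equal(same$Finteraction, 0)
  expect_false(same$dissimilarResponsiveness)
  expect_false(same$dissimilarTuning)

  # b = a + constant offset: voxel effect only, interaction SS = 0
  off <- pairAnova(a, a + 50)
  expect_true(off$dissimilarResponsiveness)
  expect_false(off$dissimilarTuning)
  expect_equal(off$Finteraction, 0)

  expect_error(pairAnova(a, matrix(1, 3, 2)), "unbalanced")
})

test_that("pair ANOVA agrees with the aov oracle on random balanced datasets", {
  set.seed(51)
  for (r in 1:50) {
    n <- sample(3:6, 1); nF <- sample(3:5, 1)
    a <- matrix(rnorm(n * nF, sd = 2), n)
    b <- matrix(rnorm(n * nF, mean = rnorm(1), sd = 2), n)
    pa <- pairAnova(a, b)
    df <- data.frame(y = c(as.vector(a), as.vector(b)),
                     vox = factor(rep(c("a", "b"), each = n * nF)),
                     frq = factor(rep(rep(seq_len(nF), each = n), 2)))
    ft <- summary(stats::aov(y ~ vox * frq, df))[[1]]
    rn <- trimws(rownames(ft))
    expect_equal(pa$Fvoxel, ft[rn == "vox", "F value"], tolerance = 1e-9)
    expect_equal(pa$Finteraction, ft[rn == "vox:frq", "F value"],
                 tolerance = 1e-9)
    expect_equal(pa$pVoxel, ft[rn == "vox", "Pr(>F)"], tolerance = 1e-9)
    expect_equal(pa$pInteraction, ft[rn == "vox:frq", "Pr(>F)"],
                 tolerance = 1e-9)
  }
})

test_that("the distance rule rounds the Euclidean distance half-up", {
  expect_equal(pairDistance(c(0, 0), c(1, 0)), 1L)
  expect_equal(pairDistance(c(0, 0), c(1, 1)), 1L)    # round(1.414) = 1
  expect_equal(pairDistance(c(0, 0), c(2, 1)), 2L)    # round(2.236) = 2
  expect_equal(pairDistance(c(0, 0), c(2, 2)), 3L)    # round(2.828) = 3
  # half-up at exactly 0.5 steps: (3,4)-(0,0) = 5 exactly
  expect_equal(pairDistance(c(0, 0), c(3, 4)), 5L)
  expect_equal(pairDistance(rbind(c(0, 0), c(1, 1)),
                            rbind(c(1, 1), c(3, 2))), c(1L, 2L))
})

test_that("pair counts per distance match brute-force enumeration on a 3x3 grid", {
  p <- makeTransitionPatch(3, 3, "responsiveness",
                           list(columnAmplitudes = c(1, 1, 1)),
                           noiseSd = 1, seed = 52)
  obs <- dissimilarityCurves(p$responses, alpha = 0.05)

  # independent oracle: enumerate all voxel pairs directly
  gr <- expand.grid(r = 1:3, c = 1:3)
  cnt <- integer(0)
  for (i in 1:8) for (j in (i + 1):9) {
    d <- floor(sqrt((gr$r[i] - gr$r[j])^2 + (gr$c[i] - gr$c[j])^2) + 0.5)
    cnt[as.character(d)] <- sum(c(cnt[as.character(d)], 1), na.rm = TRUE)
  }
  expect_equal(obs$distance, sort(as.integer(names(cnt))))
  expect_equal(obs$nPairs,
               as.integer(cnt[as.character(obs$distance)]),
               ignore_attr = TRUE)
  expect_equal(sum(obs$nPairs), choose(9, 2))
})

test_that("dissimilar fractions are zero on identical voxels and ~alpha under the null", {
  # all voxels identical and noise-free
  pr <- trialProtocol(trialsPerFrequency = 4)
  p0 <- makeTransitionPatch(3, 3, "responsiveness",
                            list(columnAmplitudes = c(8, 8, 8)),
                            noiseSd = 0, protocol = pr, seed = 1)
  obs0 <- dissimilarityCurves(p0$responses)
  expect_true(all(obs0$fracResponsiveness == 0))
  expect_true(all(obs0$fracTuning == 0))

  # label-independent noise: mean fraction ~ alpha at every distance
  fracs <- sapply(1:30, function(s) {
    pn <- makeTransitionPatch(4, 4, "responsiveness",
                              list(columnAmplitudes = rep(0, 4)),
                              noiseSd = 1, seed = 100 + s)
    ob <- dissimilarityCurves(pn$responses, alpha = 0.05)
    c(weighted.mean(ob$fracResponsiveness, ob$nPairs),
      weighted.mean(ob$fracTuning, ob$nPairs))
  })
  nTot <- 30 * choose(16, 2)
  expect_lt(abs(mean(fracs[1, ]) - 0.05), 4 * sqrt(0.05 * 0.95 / nTot) + 0.01)
  expect_lt(abs(mean(fracs[2, ]) - 0.05), 4 * sqrt(0.05 * 0.95 / nTot) + 0.01)
})

test_that("randomization null curves are deterministic, bounded and calibrated", {
  pn <- makeTransitionPatch(4, 4, "responsiveness",
                            list(columnAmplitudes = rep(0, 4)),
                            noiseSd = 1, seed = 61)
  n1 <- nullCurves(pn$responses, nRand = 20, seed = 5)
  n2 <- nullCurves(pn$responses, nRand = 20, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$respP95 >= 0 & n1$respP95 <= 1))
  expect_true(all(n1$tuneP95 >= 0 & n1$tuneP95 <= 1))
  expect_error(nullCurves(pn$responses, nRand = 1), "nRand")

  # on null data the observed curve exceeds the null p95 at a given
  # distance in roughly 5% of runs (per-distance calibration)
  hits <- vapply(1:40, function(s) {
    pz <- makeTransitionPatch(3, 4, "responsiveness",
                              list(columnAmplitudes = rep(0, 4)),
                              noiseSd = 1, seed = 200 + s)
    ob <- dissimilarityCurves(pz$responses)
    nu <- nullCurves(pz$responses, nRand = 50, seed = 300 + s)
    ob$fracResponsiveness[1] > nu$respP95[1]
  }, logical(1))
  expect_lt(mean(hits), 0.2)
  # family-wise rate of any defined resolution under the global null:
  # measured and reported, should stay well below certainty
  fam <- vapply(1:40, function(s) {
    pz <- makeTransitionPatch(3, 4, "responsiveness",
                              list(columnAmplitudes = rep(0, 4)),
                              noiseSd = 1, seed = 200 + s)
    ra <- resolutionAnalysis(pz$responses, nRand = 50, seed = 400 + s)
    any(!is.na(resolutionOf(ra)))
  }, logical(1))
  expect_lt(mean(fam), 0.5)
})

test_that("functional resolution is the shortest super-null distance in micrometres", {
  obs <- data.frame(distance = 1:4, nPairs = c(10, 10, 10, 10),
                    fracResponsiveness = c(0.05, 0.05, 0.3, 0.4),
                    fracTuning = c(0.05, 0.05, 0.05, 0.05))
  nul <- data.frame(distance = 1:4, respP95 = rep(0.1, 4),
                    tuneP95 = rep(0.1, 4))
  res <- functionalResolution(obs, nul, pitch = 100)
  expect_equal(res[["responsiveness"]], 300)
  expect_true(is.na(res[["tuning"]]))

  # observed identical to the null: undefined for both criteria
  obs2 <- obs; obs2$fracResponsiveness <- nul$respP95
  expect_true(all(is.na(functionalResolution(obs2, nul))))

  expect_error(functionalResolution(obs, nul[1:3, ]), "distance grid")
})

test_that("a strong responsiveness step yields a 100 um functional resolution", {
  p <- makeTransitionPatch(10, 4, "responsiveness",
                           list(columnAmplitudes = c(20, 14, 8, 2)),
                           noiseSd = 2, seed = 71)
  ra <- resolutionAnalysis(p$responses, alpha = 0.05, nRand = 50,
                           seed = 72, pitch = 100)
  expect_equal(resolutionOf(ra)[["responsiveness"]], 100)
})
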