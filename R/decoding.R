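## Multivoxel decoding: leave-one-out one-vs-one linear decoders,
## Fisher (covariance-normalized) variant, pseudo-populations,
## label-permutation nulls, depth-resolved decoding with RM-ANOVA.

## Majority vote over pairwise decisions with seeded uniform tie-breaking.
## votes: n x K matrix of vote counts. Must run inside withSeed().
voteArgmax <- function(votes, classes) {
  n <- nrow(votes)
  pred <- character(n)
  for (i in seq_len(n)) {
    mx <- which(votes[i, ] == max(votes[i, ]))
    pred[i] <- classes[if (length(mx) > 1L) mx[sample.int(length(mx), 1L)]
                       else mx]
  }
  pred
}

.decodingResult <- function(pred, y, details = list()) {
  acc <- mean(pred == y)
  perClass <- vapply(sort(unique(y)), function(cl) mean(pred[y == cl] == cl),
                     numeric(1))
  new("DecodingResult", accuracy = acc, perClass = perClass,
      null = numeric(), pValue = NA_real_, significant = NA,
      details = c(details, list(predictions = pred)))
}

## Balanced leave-one-out folds: fold f holds out the f-th trial of every
## class, so each pairwise boundary trains on equal class counts (9 vs 9
## in the 10-trial design). An unbalanced holdout (one trial in total)
## would train the held-out trial's own class on fewer trials than its
## opponent, biasing the midpoint threshold against the true class and
## pushing chance-level accuracy below 1/K.
looFolds <- function(y, classes) {
  nk <- table(factor(y, levels = classes))
  if (length(unique(as.integer(nk))) != 1L)
    stop("equal trial counts per class required (got ",
         paste(nk, collapse = ", "), ")")
  if (nk[1L] < 2L) stop("every class needs at least 2 trials")
  stats::ave(seq_along(y), y, FUN = seq_along)
}

#' Leave-one-out one-vs-one linear decoder
#'
#' K-class linear classification with a leave-one-out strategy over
#' balanced folds: each fold holds out one trial per class and fits, for
#' every class pair, a linear boundary on the remaining trials (9 of the
#' 10 trials per class in the standard design); each held-out trial is
#' scored by all pairwise boundaries and assigned the majority-vote class,
#' ties broken uniformly at random (seeded). The pairwise boundary is the
#' mean-difference (nearest-centroid) hyperplane through the midpoint of
#' the two class means -- the simplest boundary consistent with a linear
#' rule; [fisherDecode()] provides the covariance-normalized upgrade.
#'
#' @param ds a [DecodingDataset-class] with equal trial counts per class.
#' @param seed integer seed (tie-breaking only; the decoder itself is
#'   deterministic).
#' @return A [DecodingResult-class].
#' @examples
#' X <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 10), 10))
#' ds <- decodingDataset(X, rep(c("a", "b"), each = 10))
#' accuracy(looOvoDecode(ds, seed = 1))
#' @export
looOvoDecode <- function(ds, seed = NULL) {
  X <- ds@X; y <- ds@y
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X)
  yf <- factor(y, levels = classes)
  fold <- looFolds(y, classes)
  m <- n %/% K
  S <- rowsum(X, yf)                               # K x p class sums
  votes <- matrix(0, n, K, dimnames = list(NULL, classes))

  withSeed(seed, {
    for (f in seq_len(m)) {
      te <- which(fold == f)                       # one trial per class
      Sf <- S
      Sf[as.integer(yf[te]), ] <- Sf[as.integer(yf[te]), ] -
        X[te, , drop = FALSE]
      M <- Sf / (m - 1L)                           # training centroids
      for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
        w <- M[a, ] - M[b, ]
        c0 <- sum((M[a, ] + M[b, ]) * w) / 2
        s <- drop(X[te, , drop = FALSE] %*% w) - c0
        zero <- s == 0                             # knife-edge: random vote
        if (any(zero)) s[zero] <- runif(sum(zero)) - 0.5
        votes[te, a] <- votes[te, a] + (s > 0)
        votes[te, b] <- votes[te, b] + (s < 0)
      }
    }
    pred <- voteArgmax(votes, classes)
    .decodingResult(pred, y, list(decoder = "ovo"))
  })
}

#' Leave-one-out Fisher (covariance-normalized) decoder
#'
#' Linear discriminant taking the noise correlation between voxels into
#' account: pairwise boundaries use the direction
#' `solve(Sigma, mu_a - mu_b)` with `Sigma` the pooled within-class
#' covariance of the training trials, regularized as
#' `(1 - lambda) Sigma + lambda diag(Sigma)`. Balanced leave-one-out folds
#' (one trial per class held out) and one-vs-one majority vote as in
#' [looOvoDecode()]. With few trials per class the raw covariance estimate
#' is singular or unstable, so a positive shrinkage is the default.
#'
#' @param ds a [DecodingDataset-class] with equal trial counts per class.
#' @param shrinkage shrinkage weight lambda in \[0, 1\] (default 0.1;
#'   lambda = 1 gives the diagonal-covariance decoder).
#' @param seed integer seed for tie-breaking.
#' @return A [DecodingResult-class].
#' @export
fisherDecode <- function(ds, shrinkage = 0.1, seed = NULL) {
  X <- ds@X; y <- ds@y
  classes <- sort(unique(y))
  K <- length(classes)
  n <- nrow(X); p <- ncol(X)
  yf <- factor(y, levels = classes)
  fold <- looFolds(y, classes)
  m <- n %/% K
  S <- rowsum(X, yf)
  M <- S / m
  R <- X - M[as.integer(yf), , drop = FALSE]
  W <- crossprod(R)                                 # pooled scatter
  votes <- matrix(0, n, K, dimnames = list(NULL, classes))
  pairs <- combn(K, 2L)

  withSeed(seed, {
    for (f in seq_len(m)) {
      te <- which(fold == f)
      Sf <- S
      Sf[as.integer(yf[te]), ] <- Sf[as.integer(yf[te]), ] -
        X[te, , drop = FALSE]
      Mf <- Sf / (m - 1L)
      ## exact downdate of the pooled scatter: removing one trial x from a
      ## class with mean mu subtracts (m/(m-1)) (x - mu)(x - mu)'
      Wi <- W
      for (i in te) {
        r <- X[i, ] - M[as.integer(yf[i]), ]
        Wi <- Wi - tcrossprod(r) * (m / (m - 1L))
      }
      Sig <- Wi / (n - K - K)                       # n-K trials, K means
      Sg <- (1 - shrinkage) * Sig + shrinkage * diag(diag(Sig), p)
      ch <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ch))
        stop("singular pooled covariance",
             if (shrinkage == 0) "; increase shrinkage" else "")
      for (j in seq_len(ncol(pairs))) {
        a <- pairs[1L, j]; b <- pairs[2L, j]
        dmu <- Mf[a, ] - Mf[b, ]
        w <- backsolve(ch, forwardsolve(t(ch), dmu))
        s <- drop((X[te, , drop = FALSE] -
                   rep((Mf[a, ] + Mf[b, ]) / 2, each = K)) %*% w)
        zero <- s == 0
        if (any(zero)) s[zero] <- runif(sum(zero)) - 0.5
        votes[te, a] <- votes[te, a] + (s > 0)
        votes[te, b] <- votes[te, b] + (s < 0)
      }
    }
    pred <- voteArgmax(votes, classes)
    .decodingResult(pred, y, list(decoder = "fisher", shrinkage = shrinkage))
  })
}

#' Assemble a pseudo-population across slices
#'
#' Groups trials with identical stimulus labels across separately recorded
#' slices: pseudo-trial j of class c concatenates the voxel vectors of one
#' randomly drawn (without replacement) class-c trial from each slice.
#' Slices with unequal trial counts per class are truncated to the minimum
#' with a warning.
#'
#' @param datasets list of [DecodingDataset-class] objects sharing the same
#'   label set.
#' @param seed integer seed controlling the trial draws.
#' @return A [DecodingDataset-class] whose voxel dimension is the sum of
#'   the slice voxel counts.
#' @export
buildPseudopopulation <- function(datasets, seed = NULL) {
  labsets <- lapply(datasets, function(d) sort(unique(d@y)))
  if (length(unique(vapply(labsets, paste, character(1), collapse = "|"))) != 1L)
    stop("all slices must share the same label set")
  classes <- labsets[[1L]]
  counts <- sapply(datasets, function(d) table(factor(d@y, levels = classes)))
  mTrial <- apply(as.matrix(counts), 1L, min)
  if (any(as.matrix(counts) != mTrial))
    warning("unequal trials per class across slices; truncated to minimum")
  withSeed(seed, {
    Xc <- NULL; yOut <- NULL
    blocks <- lapply(classes, function(cl) {
      m <- mTrial[[cl]]
      do.call(cbind, lapply(datasets, function(d) {
        idx <- sample(which(d@y == cl))[seq_len(m)]
        d@X[idx, , drop = FALSE]
      }))
    })
    X <- do.call(rbind, blocks)
    y <- rep(classes, times = mTrial[classes])
    decodingDataset(X, y)
  })
}

#' Label-permutation test for decoding accuracy
#'
#' Re-runs the decoder on datasets whose trial labels have been shuffled,
#' building the chance distribution of accuracies. The observed accuracy
#' is significant when it exceeds the `alphaQuantile` quantile of the
#' null; the reported p-value is the fraction of null accuracies at or
#' above the observed one, floored at `1/nPerm` (the resolution limit of
#' the permutation count).
#'
#' @param ds a [DecodingDataset-class].
#' @param decoder `"ovo"` or `"fisher"`.
#' @param nPerm number of permutations (default 100).
#' @param alphaQuantile null quantile defining significance (default 0.95).
#' @param seed integer seed.
#' @param shrinkage passed to [fisherDecode()].
#' @return A [DecodingResult-class] with the null distribution, p-value and
#'   significance flag filled in. With very small `nPerm` the null quantile
#'   is meaningless; such results carry `details$degenerate = TRUE`.
#' @export
permutationTest <- function(ds, decoder = c("ovo", "fisher"), nPerm = 100,
                            alphaQuantile = 0.95, seed = NULL,
                            shrinkage = 0.1) {
  decoder <- match.arg(decoder)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  dec <- function(d, s) switch(decoder,
    ovo = looOvoDecode(d, seed = s),
    fisher = fisherDecode(d, shrinkage = shrinkage, seed = s))
  withSeed(seed, {
    subSeeds <- sample.int(.Machine$integer.max - 1L, nPerm + 1L)
    obs <- dec(ds, subSeeds[1L])
    nullAcc <- vapply(seq_len(nPerm), function(j) {
      dsp <- ds
      dsp@y <- sample(ds@y)
      dec(dsp, subSeeds[j + 1L])@accuracy
    }, numeric(1))
    p <- max(mean(nullAcc >= obs@accuracy), 1 / nPerm)
    sig <- obs@accuracy > quantile(nullAcc, alphaQuantile, names = FALSE)
    new("DecodingResult", accuracy = obs@accuracy, perClass = obs@perClass,
        null = nullAcc, pValue = p, significant = sig,
        details = c(obs@details,
                    list(nPerm = nPerm, alphaQuantile = alphaQuantile,
                         degenerate = nPerm * (1 - alphaQuantile) < 1)))
  })
}

#' Classical one-way repeated-measures ANOVA
#'
#' Two-way (subject x condition) decomposition without sphericity
#' correction: the condition effect is tested against the subject x
#' condition interaction.
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns.
#' @return List with `F`, `df1`, `df2`, `p` and the sums-of-squares table.
#' @export
repeatedMeasuresAnova <- function(mat) {
  mat <- as.matrix(mat)
  S <- nrow(mat); D <- ncol(mat)
  if (S < 2L || D < 2L) stop("need >= 2 subjects and >= 2 conditions")
  g <- mean(mat)
  sm <- rowMeans(mat); dm <- colMeans(mat)
  ssCond <- S * sum((dm - g)^2)
  ssSubj <- D * sum((sm - g)^2)
  ssErr <- sum((mat - outer(sm, rep(1, D)) -
                outer(rep(1, S), dm) + g)^2)
  df1 <- D - 1L; df2 <- (S - 1L) * (D - 1L)
  Fv <- (ssCond / df1) / (ssErr / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE),
       table = data.frame(term = c("condition", "subject", "error"),
                          ss = c(ssCond, ssSubj, ssErr),
                          df = c(df1, S - 1L, df2)))
}

#' Depth-resolved decoding with repeated-measures ANOVA
#'
#' Decodes stimulus identity separately at each cortical depth and tests
#' whether accuracy varies with depth across subjects. The voxel count is
#' first equalized across depths within each subject (random subsample to
#' the minimum, seeded), so depth differences cannot be driven by voxel
#' numbers. Depths with zero voxels in any subject are excluded with a
#' warning.
#'
#' @param datasets nested list: one element per subject, each a list of
#'   [DecodingDataset-class] objects, one per depth (same depth order for
#'   all subjects).
#' @param decoder `"ovo"` or `"fisher"`.
#' @param seed integer seed.
#' @param shrinkage passed to [fisherDecode()].
#' @return List with `accuracy` (subject x depth matrix) and `anova`
#'   (from [repeatedMeasuresAnova()]).
#' @export
depthDecoding <- function(datasets, decoder = "ovo", seed = NULL,
                          shrinkage = 0.1) {
  nS <- length(datasets)
  if (nS < 2L) stop("need >= 2 subjects for the repeated-measures ANOVA")
  nD <- length(datasets[[1L]])
  nvox <- sapply(datasets, function(s) vapply(s, function(d) ncol(d@X), 1L))
  empty <- which(apply(as.matrix(nvox), 1L, min) == 0L)
  keepD <- setdiff(seq_len(nD), empty)
  if (length(empty))
    warning("depth(s) ", paste(empty, collapse = ", "),
            " excluded: no voxels in at least one subject")
  withSeed(seed, {
    acc <- matrix(NA_real_, nS, length(keepD))
    for (s in seq_len(nS)) {
      vmin <- min(vapply(datasets[[s]][keepD], function(d) ncol(d@X), 1L))
      for (j in seq_along(keepD)) {
        d <- datasets[[s]][[keepD[j]]]
        sel <- sample(ncol(d@X))[seq_len(vmin)]
        dsub <- decodingDataset(d@X[, sel, drop = FALSE], d@y)
        res <- if (decoder == "fisher")
          fisherDecode(dsub, shrinkage = shrinkage,
                       seed = sample.int(1e6, 1L))
        else looOvoDecode(dsub, seed = sample.int(1e6, 1L))
        acc[s, j] <- res@accuracy
      }
    }
    list(accuracy = acc, depths = keepD, anova = repeatedMeasuresAnova(acc))
  })
}
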