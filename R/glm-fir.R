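#' FIR-GLM estimation of per-voxel impulse responses
#'
#' Estimates the impulse response of every voxel to each stimulus frequency
#' without assuming a hemodynamic response shape: the design matrix holds
#' one indicator column per frequency x post-onset lag (plus an intercept),
#' and the least-squares solution of `y = X beta` gives the finite impulse
#' response coefficients. Jittered inter-stimulus intervals make the design
#' full rank in expectation; a rank-deficient design is rejected with its
#' condition number.
#'
#' @param cbv a [CBVSeries-class] at 1 Hz.
#' @param events data.frame with columns `onset_s` (on the 1 Hz grid) and
#'   `label`.
#' @param lagWindow c(from, to) post-onset lags in seconds (default 0-8 s,
#'   the typical return-to-baseline duration).
#' @return An [ImpulseResponseSet-class].
#' @examples
#' tr <- makeTrialSeries(trialProtocol(trialsPerFrequency = 4),
#'                       groundTruthMap(c(2, 2)), noiseSd = 0, seed = 1)
#' irs <- glmFIR(tr$cbv, tr$events)
#' @export
glmFIR <- function(cbv, events, lagWindow = c(0, 8)) {
  d <- dim(cbv@values)
  nT <- d[3L]
  Y <- t(matrix(cbv@values, d[1L] * d[2L], nT))      # time x voxel
  fac <- freqFactor(events$label)
  freqs <- levels(fac)
  nF <- length(freqs)
  lags <- seq(ceiling(lagWindow[1L]), floor(lagWindow[2L]))
  nL <- length(lags)
  onsets <- round(events$onset_s)

  X <- matrix(0, nT, nF * nL)
  for (j in seq_len(nF)) {
    on <- onsets[as.integer(fac) == j]
    for (l in seq_len(nL)) {
      idx <- on + lags[l] + 1L
      idx <- idx[idx >= 1L & idx <= nT]
      X[idx, (j - 1L) * nL + l] <- 1
    }
  }
  X <- cbind(1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    kap <- kappa(X)
    stop("rank-deficient FIR design (rank ", qrX$rank, " of ", ncol(X),
         ", condition number ", signif(kap, 4),
         "): stimulus timing does not separate the lags")
  }
  beta <- qr.coef(qrX, Y)
  kern <- array(beta[-1L, , drop = FALSE], c(nL, nF, ncol(Y)))
  new("ImpulseResponseSet", kernels = kern, lags = as.numeric(lags),
      frequencies = freqs)
}
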