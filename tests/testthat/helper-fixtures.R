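## Shared fixtures built in code. All randomness is seeded per call.

smallConfig <- function(nt = 100) {
  acquisitionConfig(framesPerBlock = nt,
                    blockPeriod = max(1, nt / 500))
}

## Small separable 5-class decoding dataset: class means separated by
## `sep` noise sd along random directions.
separableDataset <- function(nClass = 5, nPerClass = 10, p = 50, sep = 5,
                             seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(nClass * p), nClass) * sep / sqrt(p) * sqrt(p)
  mu <- mu / sqrt(rowSums(mu^2)) * sep   # unit directions scaled to sep
  X <- mu[rep(seq_len(nClass), each = nPerClass), ] +
    matrix(rnorm(nClass * nPerClass * p), nClass * nPerClass)
  decodingDataset(X, rep(letters[seq_len(nClass)], each = nPerClass))
}

## Label-independent (null) dataset.
nullDataset <- function(nClass = 5, nPerClass = 10, p = 20, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(nClass * nPerClass * p), nClass * nPerClass)
  decodingDataset(X, rep(letters[seq_len(nClass)], each = nPerClass))
}

## Standard synthetic slice: 3 x 3 voxels, default protocol.
standardSlice <- function(noiseSd = 0, seed = 1, dim = c(3, 3),
                          amplitude = 20) {
  makeTrialSeries(trialProtocol(),
                  groundTruthMap(dim, amplitude = amplitude),
                  noiseSd = noiseSd, seed = seed)
}
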