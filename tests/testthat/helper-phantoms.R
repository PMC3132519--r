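# Shared fixtures: the standard study phantom and a lazily trained standard
# model, cached so the suite trains the SVM once.

standardConfig <- function(seed) phantomConfig(seed = seed)

noiselessConfig <- function(seed, nCells = 75L, width = 128L, height = 128L)
  phantomConfig(width = width, height = height, nCells = nCells,
                noiseSigma = 0, gapFraction = 0, speckleDensity = 0,
                illumCoeffs = rep(0, 6), seed = seed)

.cache <- new.env(parent = emptyenv())

# SVM trained on a 62x62 patch of the standard phantom (seed 100), the
# training protocol used throughout.
standardModel <- function() {
  if (is.null(.cache$model)) {
    ph <- generateMonolayerPhantom(standardConfig(100L))
    patch <- sampleTrainingPatch(ph$image, ph$mask, 62L, seed = 1L)
    fm <- normalizeFeatures(buildFeatureMatrix(patch$image))
    .cache$model <- trainBoundarySvm(fm, rowMajorLabels(patch$mask))
  }
  .cache$model
}

# row-major flattening of a mask, matching feature-matrix row order
rowMajorLabels <- function(mask) as.vector(t(mask))

rawFeatureMatrix <- function(values) {
  new("FeatureMatrix", values = values,
      center = rep(NA_real_, 33), scale = rep(NA_real_, 33),
      constant = rep(NA, 33), normalized = FALSE)
}

# embed an n-column toy problem into the 33-column layout (other columns 0)
embed33 <- function(x) {
  v <- matrix(0, nrow(x), 33)
  v[, seq_len(ncol(x))] <- x
  colnames(v) <- featureNames33()
  v
}
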