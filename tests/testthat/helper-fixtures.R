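# shared fixtures: small phantom specs and toy feature sets built in code

# a deterministic, noise-free spec whose regions are exact ellipses
zeroJitterSpec <- function(imageSize = 256L, zpOuterAxes = c(88, 85),
                           rotation = 0.4) {
  phantomSpec(imageSize = imageSize, zpOuterAxes = zpOuterAxes,
              boundaryNoiseAmplitude = 0, elongationJitter = 0,
              scaleJitter = 0, centerOffsetSd = 0, rotation = rotation,
              noiseSd = 0)
}

# rasterize one stand-alone ellipse as an "ooplasm-only" label image
rasterEllipseLabel <- function(a, b, theta = 0, n = 256,
                               center = c((n - 1) / 2 + 0.3, (n - 1) / 2 - 0.2)) {
  geom <- list(regions = list(ooplasm = list(
    center = center, semiAxes = c(max(a, b), min(a, b)), rotation = theta,
    fourier = list(modes = integer(), amp = numeric(), phase = numeric()))))
  n <- as.integer(n)
  lab <- matrix(0L, n, n)
  g <- oomorph:::pixelGrid(n)
  lab[oomorph:::regionMask(geom$regions$ooplasm, n, g)] <- 1L
  lab
}

# toy OocyteFeatureSet with iid normal features and a logistic outcome;
# groups/regions tags are assignable so ablation logic can be exercised
makeToyFeatureSet <- function(n, beta, seed = 1, patientsOf = 4L,
                              groups = NULL, regions = NULL,
                              sdX = 1) {
  p <- length(beta)
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p, sd = sdX), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  })
  ids <- sprintf("O%05d", seq_len(n))
  pat <- sprintf("P%04d", rep(seq_len(ceiling(n / patientsOf)),
                              each = patientsOf, length.out = n))
  feats <- as.data.frame(X, row.names = ids)
  meta <- data.frame(oocyte_id = ids, patient_id = pat, cycle_id = pat,
                     clinic = "site_A", outcome = y, row.names = ids)
  if (is.null(groups)) groups <- rep("relative", p)
  if (is.null(regions)) regions <- rep("", p)
  schema <- data.frame(column = colnames(feats), group = groups,
                       regions = regions)
  methods::new("OocyteFeatureSet", features = feats, schema = schema,
               meta = meta)
}
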