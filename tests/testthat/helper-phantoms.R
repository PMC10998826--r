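# Shared in-code fixtures: small phantoms and independent oracles.

# single tumor in empty surroundings, optionally with a distant background
# blob; grid world is ~163 mm across at the default 5.08 mm voxels
makeTumorSpec <- function(Te = 30, Aref = 2e6, psfFwhm = 0,
                          noiseModel = "none", seed = 1L, grid = 32L,
                          voxelSize = 5.08, withBackground = TRUE,
                          countsPerBq = 20) {
  regions <- list(phantomRegion("tumor", center = c(60, 60, 60),
                                semiAxes = c(14, 12, 12), Aref = Aref,
                                Te = Te))
  if (withBackground)
    regions <- c(regions, list(
      phantomRegion("background", center = c(115, 115, 115),
                    semiAxes = 28, Aref = 4e6, Te = 8)))
  phantomSpec(gridShape = grid, voxelSize = voxelSize, regions = regions,
              psfFwhm = psfFwhm, noiseModel = noiseModel,
              countsPerBq = countsPerBq, seed = seed)
}

tumorSeedVoxel <- function(voxelSize = 5.08) round(c(60, 60, 60) / voxelSize)

# independent brute-force signed-rank oracle: literal enumeration of all
# 2^n sign assignments
bruteWilcoxonP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# sort-based median/IQR oracle (midpoint median, Tukey hinges)
oracleMedian <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
oracleIqr <- function(x) {
  s <- sort(x); n <- length(s)
  lower <- s[1:ceiling(n / 2)]
  upper <- s[floor(n / 2 + 1):n]
  oracleMedian(upper) - oracleMedian(lower)
}
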