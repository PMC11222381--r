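# Internal helpers: seeded evaluation, quadrature, grid geometry.

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All generator functions route their draws
# through this so no global random state leaks.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Cumulative trapezoidal integral of y over x (same length as y, starts at 0).
cumTrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# World-mm coordinates (voxel centers) of all voxels on a grid; 1-based voxel
# index i maps to (i - 0.5) * spacing so voxel 1 is centered at spacing/2.
gridCoordinates <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# n x 3 integer matrix of all voxel indices in a shape (column-major order).
allVoxelIndices <- function(shape) {
  as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                        k = seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
}

# Convert between n x 3 voxel-index matrices and linear indices.
voxLinear <- function(idx, shape) {
  (idx[, 3L] - 1L) * shape[1L] * shape[2L] + (idx[, 2L] - 1L) * shape[1L] +
    idx[, 1L]
}
linearVox <- function(lin, shape) {
  lin <- lin - 1L
  k <- lin %/% (shape[1L] * shape[2L])
  r <- lin %% (shape[1L] * shape[2L])
  cbind(i = r %% shape[1L] + 1L, j = r %/% shape[1L] + 1L, k = k + 1L)
}

# Rician magnitude noise: Gaussian noise of SD `sd` on two quadrature
# channels, magnitude taken. `signal` is the noiseless magnitude.
riceNoise <- function(signal, sd) {
  if (sd < 0) stop("noise SD must be >= 0")
  if (sd == 0) return(signal)
  sqrt((signal + rnorm(length(signal), 0, sd))^2 +
         rnorm(length(signal), 0, sd)^2)
}

#' Published regional PS and vp reference values
#'
#' Cohort-average permeability-surface area product (PS, 1e-3 min^-1) and
#' fractional plasma volume (vp, percent) for the 15-region inventory
#' (5 cortical lobes, 5 white-matter lobes, 5 subcortical gray-matter
#' structures), with 95% CIs and the within-region PS-vp correlation, plus the
#' cortical and white-matter vp aggregates. Shipped as a plain-text table;
#' used as default region means for synthetic cohorts and for reference
#' arithmetic (e.g. the relative white-matter vp deficit).
#'
#' @return data.frame with columns region, tissue_class, ps_mean, ps_ci_low,
#'   ps_ci_high, vp_mean, vp_ci_low, vp_ci_high, ps_vp_r.
#' @export
publishedRegionValues <- function() {
  path <- system.file("extdata", "region_reference_values.csv",
                      package = "bbbflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Relative white-matter vp deficit
#'
#' Percent reduction of the white-matter fractional plasma volume relative to
#' the cortical value: 100 * (1 - vp_WM / vp_cortex). With the shipped
#' reference aggregates this quantifies how much sparser the white-matter
#' microvasculature is than the overlying cortex.
#'
#' @param vpCortex cortical vp (percent or fraction, consistently).
#' @param vpWm white-matter vp (same units).
#' @return percent deficit.
#' @export
vpDeficitPercent <- function(vpCortex, vpWm) {
  if (vpCortex <= 0) stop("cortical vp must be positive")
  100 * (1 - vpWm / vpCortex)
}
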