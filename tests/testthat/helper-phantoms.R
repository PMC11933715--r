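# shared fixtures: voxelized phantoms are built once per run and cached

.fixtureCache <- new.env(parent = emptyenv())

STUDY_SPACING <- c(0.65, 0.65, 2)

# voxelize + profile + reference volume, cached under `key`
cachedPhantom <- function(key, spec, spacing = STUDY_SPACING,
                          distalEnd = "low_index") {
  if (is.null(.fixtureCache[[key]])) {
    vol <- voxelize(spec, spacing, distalEnd = distalEnd)
    raw <- suppressWarnings(sliceAreas(vol, 1L))
    prof <- resampleProfile(raw)
    .fixtureCache[[key]] <- list(
      spec = spec, vol = vol, raw = raw, prof = prof,
      mv = referenceVolume(vol, 1L))
  }
  .fixtureCache[[key]]
}

# the three reference geometries used for the shape-factor oracle
oracleCylinder <- function()
  cachedPhantom("cyl300", PhantomSpec("cylinder", 300, 2000))
oracleCone <- function()
  cachedPhantom("cone300", PhantomSpec("cone", 300, 2000))
oracleSpindle <- function()
  cachedPhantom("spindle300",
                PhantomSpec("beta_spindle", 300, 2000,
                            peakLocation = 0.5, sharpness = 2))

# profile built from the closed-form areas, bypassing voxelization
analyticProfile <- function(spec)
  AcsaProfile(analyticAcsa(spec, seq(0, 1, 0.01)), spec@lengthMm)

# shape factor of a voxelized phantom, the full measurement chain
measuredShapeFactor <- function(ph)
  shapeFactor(ph$mv, muscleLength(ph$prof), acsaMax(ph$prof))
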