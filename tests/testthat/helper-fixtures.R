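# Shared fixtures: a reduced-geometry configuration for fast unit tests
# (small host on a 64 px raster) and convenience wrappers.

smallConfig <- function(...) {
  args <- list(gridSize = c(64L, 64L), hostAxes = c(6, 3),
               nDiazoplasts = 2L, diazoplastRadius = 0.8,
               vacuoleFraction = 0.08, nVacuoles = 1L, seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(SimConfig, args)
}

# class code lookup mirroring the package's label convention
classCode <- function(cls)
  c(background = 0L, host_N = 1L, host_minusN = 2L, diazoplast = 3L)[[cls]]

# Segment and quantify every cell of a simulated population.
quantifyPopulation <- function(pop, params = segmentationParams()) {
  do.call(rbind, lapply(pop, function(cell) {
    m <- segmentCell(cell$image, params)
    cm <- segmentCompartments(cell$image, m, params)
    quantifyRois(cell$image, cm, cellId = cell$truth@cellId)
  }))
}

# Pixels whose 8-neighbourhood crosses a true class change (the raster
# boundary band excluded from exact-agreement checks).
boundaryBand <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  band <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- labels[pmin(pmax(row(labels) + dr, 1), nr) +
                        (pmin(pmax(col(labels) + dc, 1), nc) - 1) * nr]
    band <- band | (shifted != labels)
  }
  band
}
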