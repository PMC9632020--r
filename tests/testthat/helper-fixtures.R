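# Shared fixtures, all generated in code.

cubeFixturePath <- function() {
  system.file("extdata", "cube10mm.stl", package = "airwaymorph")
}

# Digitized sphere occupancy mask (centers inside radius), centered grid.
sphereMask <- function(radius, spacing) {
  n <- as.integer(ceiling(2 * radius / spacing)) + 2L
  half <- n * spacing / 2
  ax <- (seq_len(n) - 0.5) * spacing - half
  occ <- array(outer(ax^2, outer(ax^2, ax^2, "+"), "+") <= radius^2,
               c(n, n, n))
  methods::new("VoxelMask", occupancy = occ, spacing = rep(spacing, 3),
               origin = rep(-half, 3))
}

# Silhouette built directly from a cell pattern (1-based cell indices of the
# occupied cells), padded with one empty margin cell; origin at (0, 0).
silhouetteFromCells <- function(cells, cellSize = 1) {
  m <- matrix(FALSE, max(cells[, 1]) + 1L, max(cells[, 2]) + 1L)
  m[cells] <- TRUE
  methods::new("Silhouette", plane = "horizontal", cells = m,
               cellSize = cellSize, origin = c(0, 0))
}

# Hand-built MorphRecord with constant plane measures, for cohort-stats tests.
makeTestRecord <- function(subject, position, volume, group = "A_normal",
                           planeValue = 100) {
  planes <- data.frame(
    plane = c("coronal", "sagittal", "horizontal"),
    S = planeValue, L_T = planeValue / 10, L_L = planeValue / 10,
    alpha_lower = 90, alpha_left = 90, degenerate = FALSE,
    stringsAsFactors = FALSE)
  methods::new("MorphRecord", subjectId = subject, group = group,
               position = position, volume = volume, watertight = TRUE,
               planes = planes)
}

# Specification grid shared by the volume-oracle and Pappus-closure suites.
phantomGrid <- function() {
  expand.grid(r = c(3, 5, 8), s = c(60, 80, 100), theta = c(0, 45, 90))
}
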