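planeAxes <- function(plane) {
  # (u, v) world axis indices per anatomical plane; the dropped axis is the
  # plane normal.  u is the transverse direction, v the longitudinal.
  switch(plane,
         coronal    = c(u = 1L, v = 3L),  # drops Y (posterior-anterior)
         sagittal   = c(u = 2L, v = 3L),  # drops X (right-left)
         horizontal = c(u = 1L, v = 2L),  # drops Z (inferior-superior)
         stop("unknown plane '", plane, "'"))
}

#' @describeIn projectSilhouette Orthographic silhouette of a triangle mesh.
#'   Each triangle is projected by dropping the plane's normal coordinate;
#'   a grid cell is occupied iff its center lies inside any projected
#'   triangle (closed predicate: centers exactly on a triangle edge count as
#'   inside, within 1e-9).  The grid is anchored at
#'   `floor(min projected coordinate / cellSize) - 1` cells, giving a
#'   deterministic origin and one empty margin cell on every side.
#' @export
setMethod("projectSilhouette", "AirwayMesh",
          function(x, plane = c("coronal", "sagittal", "horizontal"),
                   cellSize = 1, ...) {
  plane <- match.arg(plane)
  stopifnot(length(cellSize) == 1, is.finite(cellSize), cellSize > 0)
  ax <- planeAxes(plane)
  V2 <- x@vertices[, ax, drop = FALSE]
  lo <- apply(V2, 2, min); hi <- apply(V2, 2, max)
  origin <- (floor(lo / cellSize) - 1) * cellSize
  n <- as.integer(ceiling((hi - origin) / cellSize)) + 1L  # + trailing margin
  occ <- rasterize_silhouette_cpp(V2, x@faces - 1L, cellSize,
                                  origin[1], origin[2], n[1], n[2])
  if (!any(occ))
    stop("empty silhouette: all faces degenerate under the ", plane,
         " projection")
  methods::new("Silhouette", plane = plane, cells = occ,
               cellSize = as.numeric(cellSize), origin = as.numeric(origin))
})

# world (u, v) coordinates of cell centers for given 1-based cell indices
cellCenters <- function(s, iu, iv) {
  cbind(s@origin[1] + (iu - 0.5) * s@cellSize,
        s@origin[2] + (iv - 0.5) * s@cellSize)
}

#' Export a silhouette raster
#'
#' `writeSilhouettePGM` writes a plain-text PGM (P1 bitmap, rows = v from top
#' to bottom) for quick visual inspection; `writeSilhouetteCSV` writes the
#' occupied cell indices and world cell-center coordinates.
#'
#' @param s a [Silhouette-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeSilhouettePGM <- function(s, path) {
  m <- s@cells
  lines <- c("P1",
             sprintf("# airwaymorph silhouette %s cell %g mm", s@plane,
                     s@cellSize),
             paste(nrow(m), ncol(m)),
             vapply(rev(seq_len(ncol(m))), function(j)
               paste(as.integer(m[, j]), collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSilhouettePGM
#' @export
writeSilhouetteCSV <- function(s, path) {
  idx <- which(s@cells, arr.ind = TRUE)
  ctr <- cellCenters(s, idx[, 1], idx[, 2])
  df <- data.frame(u_index = idx[, 1], v_index = idx[, 2],
                   u_mm = ctr[, 1], v_mm = ctr[, 2])
  df <- df[order(df$u_index, df$v_index), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
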