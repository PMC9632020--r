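#' @include AllGenerics.R
NULL

#' AirwayMesh: closed triangle surface of an airway-filling model
#'
#' Vertices are 3D points in millimetres under the package's fixed anatomical
#' axis convention: X = right to left, Y = posterior to anterior,
#' Z = inferior to superior.  Faces are triples of vertex indices (1-based)
#' and are kept consistently wound so that the enclosed volume is well
#' defined.  Use [airwayMesh()] to construct (it merges duplicate vertices,
#' drops degenerate faces and harmonises the winding); the raw constructor
#' only validates structure.
#'
#' @slot vertices numeric matrix, one row per vertex, columns X/Y/Z (mm)
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices
#' @seealso [airwayMesh()], [readMesh()], [enclosedVolume()], [isWatertight()]
#' @export
setClass("AirwayMesh",
         representation(vertices = "matrix", faces = "matrix"),
         validity = function(object) {
           v <- object@vertices; f <- object@faces
           if (!is.numeric(v) || ncol(v) != 3)
             return("'vertices' must be a numeric matrix with 3 columns")
           if (ncol(f) != 3)
             return("'faces' must be a matrix with 3 columns")
           if (nrow(f) > 0) {
             if (any(!is.finite(f)) || any(f != round(f)))
               return("'faces' must contain integer indices")
             if (min(f) < 1 || max(f) > nrow(v))
               return("face indices out of vertex range")
           }
           if (any(!is.finite(v))) return("non-finite vertex coordinates")
           TRUE
         })

#' VoxelMask: occupancy grid representation of a segmented region
#'
#' The grid is axis-aligned in world millimetres.  `origin` is the world
#' position of the grid corner, so the center of voxel `(i, j, k)` (1-based)
#' is at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @slot occupancy 3D logical array
#' @slot spacing numeric(3), voxel edge lengths in mm, all > 0
#' @slot origin numeric(3), world mm position of the grid corner
#' @seealso [readMask()], [maskToSurface()], [voxelVolume()]
#' @export
setClass("VoxelMask",
         representation(occupancy = "array", spacing = "numeric",
                        origin = "numeric"),
         validity = function(object) {
           if (length(dim(object@occupancy)) != 3)
             return("'occupancy' must be a 3D array")
           if (!is.logical(object@occupancy))
             return("'occupancy' must be logical")
           if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
               any(object@spacing <= 0))
             return("'spacing' must be 3 strictly positive values")
           if (length(object@origin) != 3 || any(!is.finite(object@origin)))
             return("'origin' must be 3 finite values")
           TRUE
         })

#' Silhouette: binary occupancy grid of an orthographic projection
#'
#' One anatomical plane, square cells (1 mm^2 by default).  The in-plane axes
#' are fixed by the plane: coronal drops Y and uses (u = X, v = Z); sagittal
#' drops X and uses (u = Y, v = Z); horizontal drops Z and uses
#' (u = X, v = Y).  `u` is the transverse direction, `v` the longitudinal.
#' `cells[i, j]` covers the square with corner
#' `origin + (c(i, j) - 1) * cellSize`; a cell is occupied iff its center lies
#' inside the projected model.  The grid always carries one empty margin cell
#' on every side.
#'
#' @slot plane character, one of `"coronal"`, `"sagittal"`, `"horizontal"`
#' @slot cells logical matrix indexed (u, v)
#' @slot cellSize numeric cell edge length, mm
#' @slot origin numeric(2), world (u, v) of the grid corner, mm
#' @seealso [projectSilhouette()], [projectedArea()], [keyPoints()]
#' @export
setClass("Silhouette",
         representation(plane = "character", cells = "matrix",
                        cellSize = "numeric", origin = "numeric"),
         validity = function(object) {
           if (!object@plane %in% c("coronal", "sagittal", "horizontal"))
             return("unknown plane")
           if (!is.logical(object@cells)) return("'cells' must be logical")
           if (length(object@cellSize) != 1 || object@cellSize <= 0)
             return("'cellSize' must be a single positive value")
           if (!any(object@cells)) return("silhouette has no occupied cell")
           if (length(object@origin) != 2) return("'origin' must be length 2")
           TRUE
         })

#' Quadrilateral: the four key points of a silhouette
#'
#' The key points mark where the silhouette touches its bounding box: `pLeft`
#' and `pRight` on the transverse extremes, `pInf` and `pSup` on the
#' longitudinal extremes, each at the midpoint of the contiguous run of
#' extreme occupied cells.  Polygon traversal order is sup, right, inf, left.
#' `degenerate` flags silhouettes whose occupied cells lie in a single row or
#' column, where the quadrilateral collapses to a sliver.
#'
#' @slot pLeft,pRight,pSup,pInf numeric(2) in-plane (u, v) points, mm
#' @slot degenerate logical
#' @seealso [keyPoints()], [cornerAngles()]
#' @export
setClass("Quadrilateral",
         representation(pLeft = "numeric", pRight = "numeric",
                        pSup = "numeric", pInf = "numeric",
                        degenerate = "logical"),
         validity = function(object) {
           for (nm in c("pLeft", "pRight", "pSup", "pInf"))
             if (length(slot(object, nm)) != 2 || any(!is.finite(slot(object, nm))))
               return(sprintf("'%s' must be 2 finite values", nm))
           if (object@pLeft[1] > object@pRight[1])
             return("pLeft must not lie right of pRight")
           if (object@pInf[2] > object@pSup[2])
             return("pInf must not lie above pSup")
           TRUE
         })

#' VolumeResult: an enclosed-volume measurement
#'
#' @slot volume numeric, mm^3
#' @slot method `"surface_integral"` (divergence theorem over the closed
#'   surface) or `"voxel_count"` (fallback for non-watertight input)
#' @slot watertight logical, whether the input surface was watertight
#' @seealso [enclosedVolume()]
#' @export
setClass("VolumeResult",
         representation(volume = "numeric", method = "character",
                        watertight = "logical"),
         validity = function(object) {
           if (length(object@volume) != 1 || !is.finite(object@volume))
             return("'volume' must be a single finite value")
           if (!object@method %in% c("surface_integral", "voxel_count"))
             return("unknown method")
           TRUE
         })

#' MorphRecord: the full descriptor set for one subject in one position
#'
#' Houses the model volume plus, for each of the three anatomical planes, the
#' projected area S, the transverse and longitudinal radial lengths L_T and
#' L_L, and the lower and left corner angles of the key-point quadrilateral.
#' In the conventional nomenclature the symbols are position- and
#' plane-subscripted (e.g. S_SC / S_EC for coronal area supine / extension,
#' L_STS for the sagittal transverse radial length supine, alpha_EIH for the
#' horizontal lower corner angle in extension); here the position lives in
#' the `position` field and the serialized column names are
#' `S_<plane>`, `L_T_<plane>`, `L_L_<plane>`, `alpha_lower_<plane>`,
#' `alpha_left_<plane>` with plane codes `cor`, `sag`, `hor`.
#'
#' @slot subjectId character label
#' @slot group character, `"A_normal"` or `"B_difficult"` (free-form allowed)
#' @slot position character, `"supine"` or `"extension"`
#' @slot volume numeric, enclosed volume in mm^3
#' @slot watertight logical, whether the surface-integral volume was used
#' @slot planes data.frame with one row per plane: `plane`, `S`, `L_T`,
#'   `L_L`, `alpha_lower`, `alpha_left`, `degenerate`
#' @seealso [measureSubject()], [writeMorphTable()]
#' @export
setClass("MorphRecord",
         representation(subjectId = "character", group = "character",
                        position = "character", volume = "numeric",
                        watertight = "logical", planes = "data.frame"),
         validity = function(object) {
           need <- c("plane", "S", "L_T", "L_L", "alpha_lower", "alpha_left",
                     "degenerate")
           if (!all(need %in% names(object@planes)))
             return("'planes' missing required columns")
           if (!object@position %in% c("supine", "extension"))
             return("'position' must be 'supine' or 'extension'")
           TRUE
         })

# ---- show methods ----------------------------------------------------------

setMethod("show", "AirwayMesh", function(object) {
  cat("AirwayMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("  bounding box (mm): X [%.2f, %.2f]  Y [%.2f, %.2f]  Z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("VoxelMask: %d x %d x %d grid, %d occupied voxels\n",
              d[1], d[2], d[3], sum(object@occupancy)))
  cat(sprintf("  spacing (mm): %.4g x %.4g x %.4g\n",
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "Silhouette", function(object) {
  cat(sprintf("Silhouette [%s]: %d x %d grid of %.3g mm cells, %d occupied\n",
              object@plane, nrow(object@cells), ncol(object@cells),
              object@cellSize, sum(object@cells)))
})

setMethod("show", "Quadrilateral", function(object) {
  cat("Quadrilateral (u, v in mm):\n")
  p <- rbind(sup = object@pSup, right = object@pRight,
             inf = object@pInf, left = object@pLeft)
  colnames(p) <- c("u", "v")
  print(round(p, 3))
  if (object@degenerate) cat("  [degenerate silhouette]\n")
})

setMethod("show", "VolumeResult", function(object) {
  cat(sprintf("Volume: %.3f mm^3 (%s%s)\n", object@volume, object@method,
              if (object@watertight) "" else ", non-watertight input"))
})

setMethod("show", "MorphRecord", function(object) {
  cat(sprintf("MorphRecord %s [%s, %s]: volume %.2f mm^3\n",
              object@subjectId, object@group, object@position, object@volume))
  print(object@planes, digits = 5, row.names = FALSE)
})

# ---- accessors -------------------------------------------------------------

#' @describeIn AirwayMesh-class vertex coordinate matrix (mm)
#' @param x,object an `AirwayMesh`
#' @export
meshVertices <- function(x) x@vertices

#' @describeIn AirwayMesh-class 1-based face index matrix
#' @export
meshFaces <- function(x) x@faces

#' @rdname nVertices
setMethod("nVertices", "AirwayMesh", function(x) nrow(x@vertices))

#' @rdname nVertices
setMethod("nFaces", "AirwayMesh", function(x) nrow(x@faces))

#' Accessors for measurement results
#'
#' @param x a [VolumeResult-class], [VoxelMask-class], [Silhouette-class] or
#'   [MorphRecord-class]
#' @return the corresponding slot value
#' @export
volumeValue <- function(x) x@volume

#' @rdname volumeValue
#' @export
volumeMethod <- function(x) x@method

#' @rdname volumeValue
#' @export
maskSpacing <- function(x) x@spacing

#' @rdname volumeValue
#' @export
maskOrigin <- function(x) x@origin

#' @rdname volumeValue
#' @export
maskOccupancy <- function(x) x@occupancy

#' @rdname volumeValue
#' @export
silhouetteCells <- function(x) x@cells

#' @rdname volumeValue
#' @export
silhouettePlane <- function(x) x@plane

#' @rdname volumeValue
#' @export
planeMeasures <- function(x) x@planes
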