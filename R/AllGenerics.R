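#' Enclosed volume of a closed surface
#'
#' @param x an object with a well-defined enclosed volume
#' @param ... further arguments passed to methods
#' @return a [VolumeResult-class] object
#' @export
setGeneric("enclosedVolume", function(x, ...) standardGeneric("enclosedVolume"))

#' Watertightness check
#'
#' An object is watertight when every undirected edge of its triangulation is
#' shared by exactly two faces (edge-manifold, closed).
#'
#' @param x object to check
#' @return logical scalar
#' @export
setGeneric("isWatertight", function(x) standardGeneric("isWatertight"))

#' Voxelize a closed mesh
#'
#' @param x an [AirwayMesh-class]
#' @param spacing voxel edge length in mm
#' @param ... further arguments passed to methods
#' @return a [VoxelMask-class]
#' @export
setGeneric("voxelize", function(x, spacing = 0.25, ...) standardGeneric("voxelize"))

#' Orthographic silhouette of a mesh on an anatomical plane
#'
#' @param x an [AirwayMesh-class]
#' @param plane one of `"coronal"`, `"sagittal"`, `"horizontal"`
#' @param cellSize grid cell edge length in mm (default 1, i.e. 1 mm^2 cells)
#' @param ... further arguments passed to methods
#' @return a [Silhouette-class]
#' @export
setGeneric("projectSilhouette",
           function(x, plane, cellSize = 1, ...) standardGeneric("projectSilhouette"))

#' Number of vertices / faces
#' @param x a mesh-like object
#' @return integer scalar
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname nVertices
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
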