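#' Construct an AirwayMesh
#'
#' Builds a validated triangle mesh from raw vertex and face arrays:
#' duplicate vertices are merged within `mergeTol` (mm), zero-area faces are
#' dropped, and the face winding is harmonised by breadth-first propagation
#' over shared edges so that, where the surface is closed, all faces are
#' wound consistently outward (the winding is flipped globally if the signed
#' volume comes out negative).
#'
#' @param vertices numeric matrix (n x 3), mm
#' @param faces integer matrix (m x 3) of 1-based vertex indices
#' @param mergeTol vertex merge tolerance in mm (default 1e-6)
#' @param orient harmonise face winding (default TRUE)
#' @return an [AirwayMesh-class]
#' @examples
#' cube <- makePrimitive("cube", side = 10)
#' nVertices(cube)  # 8
#' @export
airwayMesh <- function(vertices, faces, mergeTol = 1e-6, orient = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop("empty mesh: no vertices or faces")
  m <- mergeDuplicateVertices(vertices, faces, tol = mergeTol)
  f <- dropDegenerateFaces(m$vertices, m$faces)
  if (nrow(f) == 0L) stop("empty mesh: all faces degenerate")
  if (orient) {
    f <- orientFacesConsistently(f)
    if (signedVolume(m$vertices, f) < 0) f <- f[, c(1L, 3L, 2L), drop = FALSE]
  }
  methods::new("AirwayMesh", vertices = m$vertices, faces = f)
}

# Merge vertices that coincide within tol by snapping to a tol-grid.
mergeDuplicateVertices <- function(vertices, faces, tol = 1e-6) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  newIdx <- match(key, key[first])
  vkeep <- vertices[first, , drop = FALSE]
  f <- matrix(newIdx[faces], ncol = 3)
  storage.mode(f) <- "integer"
  list(vertices = vkeep, faces = f)
}

dropDegenerateFaces <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(cr^2))
  keep <- area2 > 0 &
    faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces[keep, , drop = FALSE]
}

# Breadth-first winding harmonisation over the face-adjacency graph.  Faces in
# components with non-manifold edges are left as found.
orientFacesConsistently <- function(faces) {
  nf <- nrow(faces)
  if (nf <= 1L) return(faces)
  eKey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edges <- rbind(cbind(faces[, 1], faces[, 2]),
                 cbind(faces[, 2], faces[, 3]),
                 cbind(faces[, 3], faces[, 1]))
  keys <- eKey(edges[, 1], edges[, 2])
  faceOf <- rep(seq_len(nf), 3L)
  byEdge <- split(seq_along(keys), keys)
  # adjacency only across clean 2-manifold edges
  adj <- vector("list", nf)
  for (ids in byEdge) {
    if (length(ids) != 2L) next
    f1 <- faceOf[ids[1]]; f2 <- faceOf[ids[2]]
    adj[[f1]] <- c(adj[[f1]], ids[2])
    adj[[f2]] <- c(adj[[f2]], ids[1])
  }
  dirEdges <- edges  # directed as wound
  flipped <- logical(nf)
  visited <- logical(nf)
  queue <- integer(nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    queue[1] <- seed; head <- 1L; tail <- 1L
    visited[seed] <- TRUE
    while (head <= tail) {
      f <- queue[head]; head <- head + 1L
      myFlip <- flipped[f]
      myIds <- f + c(0L, nf, 2L * nf)  # my three directed-edge rows
      for (slotId in adj[[f]]) {
        g <- faceOf[slotId]
        if (visited[g]) next
        myId <- myIds[keys[myIds] == keys[slotId]][1]
        sameDir <- dirEdges[myId, 1] == dirEdges[slotId, 1]
        # consistent winding <=> shared edge traversed in opposite directions,
        # accounting for a possible pending flip of either face
        flipped[g] <- xor(myFlip, sameDir)
        visited[g] <- TRUE
        tail <- tail + 1L
        queue[tail] <- g
      }
    }
  }
  if (any(flipped))
    faces[flipped, ] <- faces[flipped, c(1L, 3L, 2L), drop = FALSE]
  faces
}

# Signed enclosed volume via the divergence theorem (sum of signed
# origin-tetrahedra); positive for consistently outward-wound surfaces.
signedVolume <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det3) / 6
}

#' @describeIn isWatertight every undirected edge of the mesh is shared by
#'   exactly two faces
#' @export
setMethod("isWatertight", "AirwayMesh", function(x) {
  f <- x@faces
  if (nrow(f) == 0L) return(FALSE)
  a <- c(f[, 1], f[, 2], f[, 3])
  b <- c(f[, 2], f[, 3], f[, 1])
  keys <- paste(pmin(a, b), pmax(a, b))
  all(table(keys) == 2L)
})

# Rigid / affine convenience used throughout the tests.
#' Transform a mesh
#'
#' Applies `x %*% t(rotation) + translation` to all vertices.
#'
#' @param mesh an [AirwayMesh-class]
#' @param rotation 3 x 3 matrix (default identity)
#' @param translation numeric(3) in mm (default none)
#' @param scale scalar uniform scale factor (default 1)
#' @return the transformed [AirwayMesh-class]
#' @export
transformMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                          scale = 1) {
  v <- scale * (mesh@vertices %*% t(rotation))
  v <- sweep(v, 2, translation, "+")
  methods::new("AirwayMesh", vertices = v, faces = mesh@faces)
}

rotationMatrix <- function(axis = c("x", "y", "z"), degrees) {
  axis <- match.arg(axis)
  th <- degrees * pi / 180
  c_ <- cos(th); s <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, byrow = TRUE),
         z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}
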