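#' Projected area of a silhouette
#'
#' Occupied-cell count times the cell area, i.e. the area of the model's
#' orthographic shadow measured on the 1 mm^2 grid.
#'
#' @param s a [Silhouette-class]
#' @return area in mm^2
#' @export
projectedArea <- function(s) {
  stopifnot(is(s, "Silhouette"))
  n <- sum(s@cells)
  if (n == 0L) stop("empty silhouette")
  n * s@cellSize^2
}

#' Transverse and longitudinal radial lengths
#'
#' The maximum in-plane extents of the silhouette along the two plane axes:
#' `L_T` over the transverse (u) axis and `L_L` over the longitudinal (v)
#' axis.  Extents are occupied-cell index ranges including the cell width,
#' so a single occupied cell has lengths (cellSize, cellSize).
#'
#' @param s a [Silhouette-class]
#' @return named numeric `c(L_T = , L_L = )` in mm
#' @export
radialLengths <- function(s) {
  stopifnot(is(s, "Silhouette"))
  idx <- which(s@cells, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty silhouette")
  c(L_T = (max(idx[, 1]) - min(idx[, 1]) + 1L) * s@cellSize,
    L_L = (max(idx[, 2]) - min(idx[, 2]) + 1L) * s@cellSize)
}

# Midpoint of the first contiguous run of sorted integer indices.  Runs of
# even length resolve to the cell boundary between the two central cells;
# returned on the continuous index scale (cell i spans [i - 1, i]).
runMidpoint <- function(sortedIdx) {
  d <- which(diff(sortedIdx) != 1L)
  run <- if (length(d)) sortedIdx[seq_len(d[1])] else sortedIdx
  (min(run) - 1 + max(run)) / 2
}

#' Four key points of a silhouette
#'
#' Marks where the silhouette touches its bounding box: `pLeft` / `pRight`
#' at the minimal / maximal transverse (u) extremes and `pInf` / `pSup` at
#' the minimal / maximal longitudinal (v) extremes.  Each point lies on the
#' bounding-box edge, at the midpoint of the first contiguous run of extreme
#' occupied cells, so the quadrilateral's diagonals equal the radial lengths
#' `L_T` and `L_L` and all coordinates fall on the half-cell lattice.
#' Joining the points sup - right - inf - left yields the quadrilateral whose
#' lower and left corner angles are reported (see [cornerAngles()]).
#' A silhouette whose occupied cells fall in a single row or column gives a
#' sliver quadrilateral and is flagged `degenerate` (with a warning).
#'
#' @param s a [Silhouette-class]
#' @return a [Quadrilateral-class]
#' @export
keyPoints <- function(s) {
  stopifnot(is(s, "Silhouette"))
  idx <- which(s@cells, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty silhouette")
  iu <- idx[, 1]; iv <- idx[, 2]
  o <- s@origin; h <- s@cellSize
  uMin <- min(iu); uMax <- max(iu); vMin <- min(iv); vMax <- max(iv)
  # boundary coordinate of the extreme cell face + run midpoint along it
  pLeft  <- c(o[1] + (uMin - 1) * h,
              o[2] + runMidpoint(sort(iv[iu == uMin])) * h)
  pRight <- c(o[1] + uMax * h,
              o[2] + runMidpoint(sort(iv[iu == uMax])) * h)
  pInf   <- c(o[1] + runMidpoint(sort(iu[iv == vMin])) * h,
              o[2] + (vMin - 1) * h)
  pSup   <- c(o[1] + runMidpoint(sort(iu[iv == vMax])) * h,
              o[2] + vMax * h)
  degenerate <- (uMin == uMax) || (vMin == vMax)
  if (degenerate)
    warning("degenerate silhouette: occupied cells span a single ",
            if (uMin == uMax) "column" else "row",
            "; quadrilateral collapses to a sliver")
  methods::new("Quadrilateral", pLeft = pLeft, pRight = pRight,
               pSup = pSup, pInf = pInf, degenerate = degenerate)
}

interiorAngle <- function(vertex, nbr1, nbr2) {
  a <- nbr1 - vertex; b <- nbr2 - vertex
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("degenerate quadrilateral: coincident vertices")
  cosang <- max(-1, min(1, sum(a * b) / (na * nb)))
  acos(cosang) * 180 / pi
}

#' Corner angles of the key-point quadrilateral
#'
#' Interior angles of the quadrilateral traversed sup - right - inf - left.
#' The lower corner angle sits at `pInf` (between the edges to `pRight` and
#' `pLeft`); the left corner angle sits at `pLeft` (between the edges to
#' `pInf` and `pSup`).  Angles are in degrees, in (0, 180).  With `all =
#' TRUE` the upper and right angles are returned as well; for any valid
#' (convex) key-point quadrilateral the four sum to 360 degrees.
#'
#' @param q a [Quadrilateral-class]
#' @param all return all four interior angles instead of lower/left only
#' @return named numeric, degrees
#' @examples
#' q <- methods::new("Quadrilateral", pSup = c(20, 20), pRight = c(40, 10),
#'                   pInf = c(20, 0), pLeft = c(0, 10), degenerate = FALSE)
#' cornerAngles(q)  # 126.87, 53.13
#' @export
cornerAngles <- function(q, all = FALSE) {
  stopifnot(is(q, "Quadrilateral"))
  pts <- list(sup = q@pSup, right = q@pRight, inf = q@pInf, left = q@pLeft)
  if (any(duplicated(do.call(rbind, pts))))
    stop("degenerate quadrilateral: coincident vertices")
  ang <- c(
    alpha_lower = interiorAngle(q@pInf, q@pRight, q@pLeft),
    alpha_left  = interiorAngle(q@pLeft, q@pInf, q@pSup),
    alpha_upper = interiorAngle(q@pSup, q@pLeft, q@pRight),
    alpha_right = interiorAngle(q@pRight, q@pSup, q@pInf))
  if (all) ang else ang[c("alpha_lower", "alpha_left")]
}

#' Measure the full descriptor set for one subject
#'
#' Runs the whole measurement pipeline on one airway-filling surface:
#' enclosed volume, then for each anatomical plane the silhouette at
#' `cellSize` mm cells, its projected area, radial lengths and corner
#' angles.  A plane whose silhouette or quadrilateral is degenerate is
#' flagged in the record rather than failing the subject.
#'
#' @param mesh an [AirwayMesh-class]
#' @param subjectId subject label
#' @param group group label (e.g. `"A_normal"`, `"B_difficult"`)
#' @param position `"supine"` or `"extension"`
#' @param cellSize silhouette cell edge in mm (default 1)
#' @return a [MorphRecord-class]
#' @export
measureSubject <- function(mesh, subjectId, group = "A_normal",
                           position = c("supine", "extension"),
                           cellSize = 1) {
  position <- match.arg(position)
  vol <- enclosedVolume(mesh)
  rows <- lapply(c("coronal", "sagittal", "horizontal"), function(pl) {
    out <- data.frame(plane = pl, S = NA_real_, L_T = NA_real_,
                      L_L = NA_real_, alpha_lower = NA_real_,
                      alpha_left = NA_real_, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    sil <- tryCatch(projectSilhouette(mesh, pl, cellSize = cellSize),
                    error = function(e) NULL)
    if (is.null(sil)) return(out)
    out$S <- projectedArea(sil)
    rl <- radialLengths(sil)
    out$L_T <- rl[["L_T"]]; out$L_L <- rl[["L_L"]]
    q <- withCallingHandlers(keyPoints(sil),
                             warning = function(w) invokeRestart("muffleWarning"))
    out$degenerate <- q@degenerate
    ang <- tryCatch(cornerAngles(q), error = function(e) NULL)
    if (!is.null(ang)) {
      out$alpha_lower <- ang[["alpha_lower"]]
      out$alpha_left <- ang[["alpha_left"]]
    }
    out
  })
  methods::new("MorphRecord", subjectId = as.character(subjectId),
               group = as.character(group), position = position,
               volume = volumeValue(vol), watertight = vol@watertight,
               planes = do.call(rbind, rows))
}
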