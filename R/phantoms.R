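#' PhantomSpec: parametric airway-filling phantom
#'
#' A stylized stand-in for an upper-airway filling model: a tube of radius
#' `tubeRadius` (optionally modulated along the path by `radiusProfile`)
#' swept along a circular-arc centerline of length `pathLength` lying in the
#' sagittal (Y-Z) plane and subtending `bendAngle` degrees.  `bendAngle = 0`
#' is a straight tube.  The supine position uses the spec as given (default
#' bend 90 degrees, the oral-pharyngeal-laryngeal axes crossing); the
#' maximum-extension position straightens the bend to `extensionBend` and
#' lengthens the path by `extensionGain` (straightening the path from the
#' incisors to the glottis gains length).
#'
#' @slot tubeRadius tube radius in mm
#' @slot pathLength centerline arc length in mm (supine)
#' @slot bendAngle supine bend in degrees subtended by the arc
#' @slot sections number of sweep steps along the path (>= 8)
#' @slot ringVertices cross-section polygon resolution (>= 8)
#' @slot radiusProfile a function r(t) of t in \code{[0, 1]} giving the local
#'   radius in mm, or NULL for a constant radius
#' @slot extensionBend bend in degrees used for the extension position
#' @slot extensionGain multiplicative path-length gain under extension
#' @seealso [phantomSpec()], [makeAirwayPhantom()], [phantomVolumeAnalytic()]
#' @export
setClass("PhantomSpec",
         representation(tubeRadius = "numeric", pathLength = "numeric",
                        bendAngle = "numeric", sections = "integer",
                        ringVertices = "integer", radiusProfile = "ANY",
                        extensionBend = "numeric", extensionGain = "numeric"),
         validity = function(object) {
           if (object@tubeRadius <= 0) return("tubeRadius must be positive")
           if (object@pathLength <= 0) return("pathLength must be positive")
           if (object@bendAngle < 0 || object@bendAngle >= 360)
             return("bendAngle must be in [0, 360)")
           if (object@sections < 8L) return("sections must be >= 8")
           if (object@ringVertices < 8L) return("ringVertices must be >= 8")
           if (!is.null(object@radiusProfile) &&
               !is.function(object@radiusProfile))
             return("radiusProfile must be NULL or a function of t in [0,1]")
           TRUE
         })

#' Construct a phantom specification
#'
#' @param tubeRadius tube radius, mm (default 5)
#' @param pathLength supine centerline length, mm (default 80)
#' @param bendAngle supine bend, degrees (default 90)
#' @param sections sweep steps (default 64)
#' @param ringVertices cross-section resolution (default 64)
#' @param radiusProfile optional function r(t), t in \code{[0, 1]}
#' @param extensionBend extension-position bend, degrees (default 15)
#' @param extensionGain extension path-length multiplier (default 1.25)
#' @return a [PhantomSpec-class]
#' @examples
#' spec <- phantomSpec(tubeRadius = 5, pathLength = 80, bendAngle = 90)
#' phantomVolumeAnalytic(spec)  # pi * 25 * 80 = 6283.19 mm^3
#' @export
phantomSpec <- function(tubeRadius = 5, pathLength = 80, bendAngle = 90,
                        sections = 64L, ringVertices = 64L,
                        radiusProfile = NULL, extensionBend = 15,
                        extensionGain = 1.25) {
  obj <- methods::new("PhantomSpec", tubeRadius = tubeRadius,
                      pathLength = pathLength, bendAngle = bendAngle,
                      sections = as.integer(sections),
                      ringVertices = as.integer(ringVertices),
                      radiusProfile = radiusProfile,
                      extensionBend = extensionBend,
                      extensionGain = extensionGain)
  checkNoSelfIntersection(obj, positionParams(obj, "supine"))
  obj
}

positionParams <- function(spec, position) {
  if (position == "supine") {
    list(bend = spec@bendAngle, s = spec@pathLength)
  } else {
    list(bend = spec@extensionBend, s = spec@pathLength * spec@extensionGain)
  }
}

phantomRadiusAt <- function(spec, t) {
  if (is.null(spec@radiusProfile)) rep(spec@tubeRadius, length(t))
  else vapply(t, spec@radiusProfile, numeric(1))
}

checkNoSelfIntersection <- function(spec, par) {
  if (par$bend <= 0) return(invisible(TRUE))
  R <- par$s * 180 / (pi * par$bend)
  rmax <- max(phantomRadiusAt(spec, seq(0, 1, length.out = 65)))
  if (R <= rmax)
    stop("self-intersecting phantom: arc radius ", signif(R, 4),
         " mm does not exceed the maximum tube radius ", signif(rmax, 4),
         " mm")
  invisible(TRUE)
}

#' Primitive test meshes
#'
#' Watertight meshes of simple solids with known volume: an axis-aligned
#' cube, an icosphere (subdivided icosahedron with vertices on the sphere)
#' and a capped cylinder.
#'
#' @param kind `"cube"`, `"sphere"` or `"cylinder"`
#' @param side cube edge length, mm
#' @param radius sphere/cylinder radius, mm
#' @param height cylinder height, mm
#' @param subdivisions icosphere subdivision level (default 4)
#' @param ringVertices cylinder cross-section resolution (default 64)
#' @param axis cylinder axis, `"x"`, `"y"` or `"z"` (default z)
#' @param center numeric(3) center of the solid (default origin; the cube
#'   spans `[0, side]^3` from `center`)
#' @return an [AirwayMesh-class]
#' @examples
#' volumeValue(enclosedVolume(makePrimitive("cube", side = 10)))  # 1000
#' @export
makePrimitive <- function(kind = c("cube", "sphere", "cylinder"), side = 10,
                          radius = 10, height = 30, subdivisions = 4L,
                          ringVertices = 64L, axis = c("z", "x", "y"),
                          center = c(0, 0, 0)) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  switch(kind,
         cube = {
           if (side <= 0) stop("cube side must be positive")
           cubeMesh(side, center)
         },
         sphere = {
           if (radius <= 0) stop("sphere radius must be positive")
           icosphereMesh(radius, as.integer(subdivisions), center)
         },
         cylinder = {
           if (radius <= 0 || height <= 0)
             stop("cylinder radius and height must be positive")
           cylinderMesh(radius, height, as.integer(ringVertices), axis, center)
         })
}

# mesh helpers build exact shared vertices with outward winding; the cheap
# constructor skips the merge/orient passes and just fixes the global sign
newMeshRaw <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  if (signedVolume(vertices, faces) < 0)
    faces <- faces[, c(1L, 3L, 2L), drop = FALSE]
  methods::new("AirwayMesh", vertices = vertices, faces = faces)
}

cubeMesh <- function(side, center = c(0, 0, 0)) {
  g <- expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1))
  v <- sweep(as.matrix(g) * side, 2, center, "+")
  # two triangles per face, outward winding (verified by signed volume)
  quads <- rbind(c(1, 3, 4, 2),  # z = 0
                 c(5, 6, 8, 7),  # z = 1
                 c(1, 2, 6, 5),  # y = 0
                 c(3, 7, 8, 4),  # y = 1
                 c(1, 5, 7, 3),  # x = 0
                 c(2, 4, 8, 6))  # x = 1
  f <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  newMeshRaw(v, f)
}

icosphereMesh <- function(radius, subdivisions = 4L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (lev in seq_len(subdivisions)) {
    nv <- nrow(v)
    edgeId <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edgeId[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      id <- nrow(v)
      edgeId[[key]] <- id
      id
    }
    fNew <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      fNew[(4 * k - 3):(4 * k), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- fNew
  }
  newMeshRaw(sweep(v * radius, 2, center, "+"), f)
}

cylinderMesh <- function(radius, height, ringVertices = 64L, axis = "z",
                         center = c(0, 0, 0)) {
  n <- ringVertices
  a <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(radius * cos(a), radius * sin(a))
  v <- rbind(cbind(ring, -height / 2), cbind(ring, height / 2),
             c(0, 0, -height / 2), c(0, 0, height / 2))
  lowC <- 2L * n + 1L; topC <- 2L * n + 2L
  nxt <- c(seq_len(n)[-1], 1L)
  f <- rbind(cbind(seq_len(n), nxt, n + nxt),              # side lower tris
             cbind(seq_len(n), n + nxt, n + seq_len(n)),   # side upper tris
             cbind(lowC, nxt, seq_len(n)),                 # bottom cap
             cbind(topC, n + seq_len(n), n + nxt))         # top cap
  perm <- switch(axis, z = c(1, 2, 3), x = c(3, 1, 2), y = c(1, 3, 2))
  v <- v[, perm, drop = FALSE]
  newMeshRaw(sweep(v, 2, center, "+"), f)
}

#' Build an airway-filling phantom mesh
#'
#' Sweeps a circular (or profiled) cross-section along a circular-arc
#' centerline in the sagittal (Y-Z) plane and caps the ends, producing a
#' watertight tube.  The centerline starts at the origin with tangent +Y
#' (anterior, the oral segment) and bends towards -Z (inferior, down the
#' pharynx towards the larynx); at zero bend the tube is straight.  The
#' supine position uses the spec's bend and path length; the extension
#' position uses the straighter, longer parameters (see
#' [PhantomSpec-class]).
#'
#' @param spec a [PhantomSpec-class]
#' @param position `"supine"` or `"extension"`
#' @return an [AirwayMesh-class]
#' @examples
#' m <- makeAirwayPhantom(phantomSpec(tubeRadius = 5, pathLength = 80))
#' volumeValue(enclosedVolume(m))  # about pi * 25 * 80
#' @export
makeAirwayPhantom <- function(spec, position = c("supine", "extension")) {
  position <- match.arg(position)
  stopifnot(is(spec, "PhantomSpec"))
  par <- positionParams(spec, position)
  checkNoSelfIntersection(spec, par)
  S <- spec@sections; n <- spec@ringVertices
  t <- seq(0, 1, length.out = S + 1L)
  r <- phantomRadiusAt(spec, t)
  th <- par$bend * pi / 180
  if (th > 1e-9) {
    R <- par$s / th
    psi <- t * th
    cy <- R * sin(psi); cz <- -R * (1 - cos(psi))
    # in-plane unit normal to the tangent (0, cos psi, -sin psi)
    ny <- sin(psi); nz <- cos(psi)
  } else {
    cy <- par$s * t; cz <- rep(0, length(t))
    ny <- rep(0, length(t)); nz <- rep(1, length(t))
  }
  a <- 2 * pi * (seq_len(n) - 1) / n
  # ring k: C_k + r_k (cos a * nvec_k + sin a * xhat)
  V <- matrix(0, (S + 1L) * n + 2L, 3)
  for (k in seq_len(S + 1L)) {
    rows <- ((k - 1L) * n + 1L):(k * n)
    V[rows, 1] <- r[k] * sin(a)
    V[rows, 2] <- cy[k] + r[k] * cos(a) * ny[k]
    V[rows, 3] <- cz[k] + r[k] * cos(a) * nz[k]
  }
  startC <- (S + 1L) * n + 1L; endC <- startC + 1L
  V[startC, ] <- c(0, cy[1], cz[1])
  V[endC, ] <- c(0, cy[S + 1L], cz[S + 1L])
  nxt <- c(seq_len(n)[-1], 1L)
  f <- vector("list", S + 2L)
  for (k in seq_len(S)) {
    lo <- (k - 1L) * n
    hi <- k * n
    f[[k]] <- rbind(cbind(lo + seq_len(n), lo + nxt, hi + nxt),
                    cbind(lo + seq_len(n), hi + nxt, hi + seq_len(n)))
  }
  f[[S + 1L]] <- cbind(startC, nxt, seq_len(n))
  f[[S + 2L]] <- cbind(endC, S * n + seq_len(n), S * n + nxt)
  newMeshRaw(V, do.call(rbind, f))
}

#' Analytic phantom volume (ground-truth oracle)
#'
#' For a constant radius the swept-tube volume follows the Pappus centroid
#' theorem: the cross-section centroid travels the centerline, so
#' `V = pi r^2 s` exactly (valid while the arc radius exceeds the tube
#' radius).  For a profiled radius the volume is the quadrature of
#' `pi r(t)^2 s dt`, and the result carries `attr(, "numeric") = TRUE`.
#'
#' @param spec a [PhantomSpec-class]
#' @param position `"supine"` or `"extension"`
#' @return volume in mm^3
#' @export
phantomVolumeAnalytic <- function(spec, position = c("supine", "extension")) {
  position <- match.arg(position)
  par <- positionParams(spec, position)
  checkNoSelfIntersection(spec, par)
  if (is.null(spec@radiusProfile)) {
    pi * spec@tubeRadius^2 * par$s
  } else {
    q <- stats::integrate(function(t) pi * phantomRadiusAt(spec, t)^2, 0, 1,
                          rel.tol = 1e-10)
    structure(q$value * par$s, numeric = TRUE)
  }
}

#' Generative targets for the simulated cohort
#'
#' Default group-by-position volume means and SDs (mm^3) of the cohorts the
#' generator emulates: a normal-airway group around 6,300 mm^3 supine /
#' 9,200 mm^3 extension and a difficult-airway group around 5,300 / 6,700.
#'
#' @return data.frame with columns `group`, `position`, `mean`, `sd`
#' @export
defaultCohortTargets <- function() {
  data.frame(
    group = rep(c("A_normal", "B_difficult"), each = 2),
    position = rep(c("supine", "extension"), 2),
    mean = c(6323.83, 9186.58, 5336.22, 6735.46),
    sd = c(156.06, 512.61, 316.13, 794.63),
    stringsAsFactors = FALSE)
}

#' Simulate a two-group, two-position phantom cohort
#'
#' Draws a target volume for every subject and position from the
#' group-by-position normal distributions and solves the phantom radius so
#' the analytic (Pappus) volume equals the draw: `r = sqrt(V / (pi s))` at
#' the position's path length.  The supine and extension draws of one
#' subject share the subject-level standard-normal effect `z`, which (with
#' the default targets) makes the extension volume exceed the supine volume
#' for every subject.  Draws below half the target mean, or pairs with
#' extension <= supine, are redrawn; the redraw count is recorded.
#' Everything is deterministic given `seed`.
#'
#' @param n subjects per group (default 20)
#' @param seed integer random seed (mandatory, echoed in the manifest)
#' @param targets data.frame as [defaultCohortTargets()]
#' @param pathLengthSupine,pathLengthExtension centerline lengths, mm
#' @param bendSupine,bendExtension bend angles, degrees
#' @param sections,ringVertices mesh resolution of the generated phantoms
#' @param meshes also build the phantom meshes (default TRUE); with
#'   `FALSE` only the manifest of sampled volumes and solved radii is
#'   returned
#' @return list with `manifest` (data.frame: `subject_id`, `group`,
#'   `position`, `seed`, `true_volume`, `tube_radius`, `path_length`,
#'   `bend_angle`), `meshes` (named list of [AirwayMesh-class] keyed
#'   `subject.position`, or NULL), and `redraws` (count)
#' @examples
#' coh <- simulateCohort(n = 3, seed = 1, meshes = FALSE)
#' coh$manifest
#' @export
simulateCohort <- function(n = 20, seed,
                           targets = defaultCohortTargets(),
                           pathLengthSupine = 80, pathLengthExtension = 100,
                           bendSupine = 90, bendExtension = 15,
                           sections = 48L, ringVertices = 48L,
                           meshes = TRUE) {
  if (missing(seed)) stop("a seed is mandatory for cohort simulation")
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  groups <- unique(targets$group)
  rows <- list(); meshList <- list(); redraws <- 0L
  for (g in groups) {
    tg <- targets[targets$group == g, ]
    sup <- tg[tg$position == "supine", ]; ext <- tg[tg$position == "extension", ]
    for (i in seq_len(n)) {
      repeat {
        z <- stats::rnorm(1)
        vS <- sup$mean + sup$sd * z
        vE <- ext$mean + ext$sd * z
        if (vS > 0.5 * sup$mean && vE > 0.5 * ext$mean && vE > vS) break
        redraws <- redraws + 1L
      }
      id <- sprintf("%s_%02d", sub("_.*$", "", g), i)
      for (pos in c("supine", "extension")) {
        vol <- if (pos == "supine") vS else vE
        s <- if (pos == "supine") pathLengthSupine else pathLengthExtension
        bend <- if (pos == "supine") bendSupine else bendExtension
        r <- sqrt(vol / (pi * s))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = id, group = g, position = pos, seed = as.integer(seed),
          true_volume = vol, tube_radius = r, path_length = s,
          bend_angle = bend, stringsAsFactors = FALSE)
        if (meshes) {
          spec <- phantomSpec(tubeRadius = r, pathLength = s,
                              bendAngle = bend, sections = sections,
                              ringVertices = ringVertices)
          meshList[[paste(id, pos, sep = ".")]] <-
            makeAirwayPhantom(spec, position = "supine")
        }
      }
    }
  }
  list(manifest = do.call(rbind, rows),
       meshes = if (meshes) meshList else NULL,
       redraws = redraws)
}
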