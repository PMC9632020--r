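rectangleSilhouette <- function(w = 40, h = 20) {
  # box spanning [0, w] x [0, h] in the horizontal plane (w on X, h on Y)
  box <- makePrimitive("cube", side = 1)
  v <- meshVertices(box)
  v[, 1] <- v[, 1] * w; v[, 2] <- v[, 2] * h; v[, 3] <- v[, 3] * 5
  projectSilhouette(airwayMesh(v, meshFaces(box)), "horizontal")
}

test_that("projected area counts occupied cells times cell area", {
  s <- rectangleSilhouette(10, 10)
  expect_equal(projectedArea(s), 100)
  sp <- makePrimitive("sphere", radius = 10, subdivisions = 4)
  a1 <- projectedArea(projectSilhouette(sp, "coronal"))
  expect_equal(a1, pi * 100, tolerance = 0.02)
  a05 <- projectedArea(projectSilhouette(sp, "coronal", cellSize = 0.5))
  expect_equal(a05 / a1, 1, tolerance = 0.01)
})

test_that("radial lengths are occupied extents including the cell width", {
  expect_equal(unname(radialLengths(rectangleSilhouette(40, 20))), c(40, 20))
  disc <- projectSilhouette(makePrimitive("sphere", radius = 10,
                                          subdivisions = 4), "horizontal")
  rl <- radialLengths(disc)
  expect_true(all(rl >= 19 & rl <= 21))
  single <- silhouetteFromCells(cbind(2, 2))
  expect_equal(unname(radialLengths(single)), c(1, 1))
})

test_that("key points sit on the bounding box at tied-run midpoints", {
  q <- keyPoints(rectangleSilhouette(40, 20))
  expect_equal(q@pLeft, c(0, 10))
  expect_equal(q@pRight, c(40, 10))
  expect_equal(q@pInf, c(20, 0))
  expect_equal(q@pSup, c(20, 20))
  expect_false(q@degenerate)

  # L-shaped triomino: occupied cells (2,2), (3,2), (2,3) on a unit grid
  q2 <- keyPoints(silhouetteFromCells(rbind(c(2, 2), c(3, 2), c(2, 3))))
  expect_equal(q2@pRight, c(3, 1.5))  # single extreme cell: its edge midpoint
  expect_equal(q2@pSup, c(1.5, 3))
  expect_equal(q2@pLeft, c(1, 2))     # tie run rows 2:3 -> boundary midpoint
  expect_equal(q2@pInf, c(2, 1))
})

test_that("disc key points form a square with ~14.14 mm sides", {
  disc <- projectSilhouette(makePrimitive("sphere", radius = 10,
                                          subdivisions = 4), "coronal")
  q <- keyPoints(disc)
  pts <- rbind(q@pSup, q@pRight, q@pInf, q@pLeft, q@pSup)
  sides <- sqrt(rowSums(diff(pts)^2))
  expect_equal(sides, rep(10 * sqrt(2), 4), tolerance = 0.08)
  expect_equal(unname(cornerAngles(q)), c(90, 90), tolerance = 0.03)
})

test_that("corner angles reproduce the rhombus geometry of the extents", {
  q <- keyPoints(rectangleSilhouette(40, 20))
  ang <- cornerAngles(q, all = TRUE)
  expect_equal(unname(ang["alpha_lower"]), 2 * atan(2) * 180 / pi,
               tolerance = 1e-9)  # 126.87
  expect_equal(unname(ang["alpha_left"]), 2 * atan(0.5) * 180 / pi,
               tolerance = 1e-9)  # 53.13
  expect_equal(sum(ang), 360, tolerance = 1e-6)
})

test_that("interior angles stay in (0, 180) and sum to 360 on random shapes", {
  set.seed(7)
  for (rep in 1:12) {
    rot <- rotationMatrix("x", stats::runif(1, 0, 90)) %*%
      rotationMatrix("z", stats::runif(1, 0, 90))
    scales <- diag(stats::runif(3, 0.5, 2.5))
    sp <- makePrimitive("sphere", radius = stats::runif(1, 6, 12),
                        subdivisions = 2)
    mesh <- airwayMesh(meshVertices(sp) %*% scales %*% rot, meshFaces(sp))
    s <- projectSilhouette(mesh, sample(c("coronal", "sagittal",
                                          "horizontal"), 1))
    q <- keyPoints(s)
    ang <- cornerAngles(q, all = TRUE)
    expect_true(all(ang > 0 & ang < 180))
    expect_equal(sum(ang), 360, tolerance = 1e-6)
    # quadrilateral vertices bounded by the occupied bounding box
    idx <- which(silhouetteCells(s), arr.ind = TRUE)
    uRange <- s@origin[1] + c(min(idx[, 1]) - 1, max(idx[, 1])) * s@cellSize
    vRange <- s@origin[2] + c(min(idx[, 2]) - 1, max(idx[, 2])) * s@cellSize
    pts <- rbind(q@pSup, q@pRight, q@pInf, q@pLeft)
    expect_true(all(pts[, 1] >= uRange[1] - 1e-9 & pts[, 1] <= uRange[2] + 1e-9))
    expect_true(all(pts[, 2] >= vRange[1] - 1e-9 & pts[, 2] <= vRange[2] + 1e-9))
  }
})

test_that("degenerate silhouettes are flagged and bad quads rejected", {
  expect_warning(q <- keyPoints(silhouetteFromCells(cbind(2, 2))),
                 "degenerate")
  expect_true(q@degenerate)
  expect_warning(keyPoints(silhouetteFromCells(cbind(2:5, 2))), "row")
  bad <- methods::new("Quadrilateral", pSup = c(0, 1), pRight = c(0, 1),
                      pInf = c(0, 0), pLeft = c(0, 0.5), degenerate = TRUE)
  expect_error(cornerAngles(bad), "degenerate quadrilateral")
})

test_that("measureSubject assembles volume and per-plane descriptors", {
  cube <- makePrimitive("cube", side = 10)
  rec <- measureSubject(cube, "cube", "A_normal", "supine")
  expect_s4_class(rec, "MorphRecord")
  expect_equal(rec@volume, 1000, tolerance = 1e-9)
  p <- planeMeasures(rec)
  expect_equal(p$S, rep(100, 3))
  expect_equal(p$L_T, rep(10, 3))
  expect_equal(p$L_L, rep(10, 3))
  expect_equal(p$alpha_lower, rep(90, 3), tolerance = 1e-9)
  expect_equal(p$alpha_left, rep(90, 3), tolerance = 1e-9)

  tube <- makePrimitive("cylinder", radius = 5, height = 100,
                        ringVertices = 128)
  recT <- measureSubject(tube, "tube", "A_normal", "supine")
  expect_equal(recT@volume, pi * 25 * 100, tolerance = 0.01)
  hor <- planeMeasures(recT)[planeMeasures(recT)$plane == "horizontal", ]
  expect_equal(hor$L_T, 10, tolerance = 0.11)
  expect_equal(hor$L_L, 10, tolerance = 0.11)
})
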