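test_that("primitive meshes are watertight with analytic volumes", {
  cube <- makePrimitive("cube", side = 10)
  expect_true(isWatertight(cube))
  expect_equal(volumeValue(enclosedVolume(cube)), 1000, tolerance = 1e-12)

  cyl <- makePrimitive("cylinder", radius = 5, height = 100,
                       ringVertices = 256)
  expect_true(isWatertight(cyl))
  expect_equal(volumeValue(enclosedVolume(cyl)), pi * 25 * 100,
               tolerance = 0.002)

  sp <- makePrimitive("sphere", radius = 10, subdivisions = 4)
  expect_true(isWatertight(sp))
  edges <- unique(t(apply(rbind(meshFaces(sp)[, 1:2], meshFaces(sp)[, 2:3],
                                meshFaces(sp)[, c(3, 1)]), 1, sort)))
  euler <- nVertices(sp) - nrow(edges) + nFaces(sp)
  expect_equal(euler, 2L)

  expect_error(makePrimitive("cube", side = -1), "positive")
  expect_error(makePrimitive("cylinder", radius = 0), "positive")
})

test_that("cylinder axis choices give matching volumes and orientations", {
  for (ax in c("x", "y", "z")) {
    cyl <- makePrimitive("cylinder", radius = 4, height = 20, axis = ax)
    expect_true(isWatertight(cyl))
    expect_equal(volumeValue(enclosedVolume(cyl)), pi * 16 * 20,
                 tolerance = 0.01)
    ext <- apply(meshVertices(cyl), 2, function(x) diff(range(x)))
    expect_equal(unname(ext[match(ax, c("x", "y", "z"))]), 20)
  }
})

test_that("swept-tube phantoms close the Pappus analytic volume", {
  spec <- phantomSpec(tubeRadius = 5, pathLength = 80, bendAngle = 90)
  m <- makeAirwayPhantom(spec, "supine")
  expect_true(isWatertight(m))
  expect_equal(volumeValue(enclosedVolume(m)), pi * 25 * 80,
               tolerance = 0.01)
  # straight limit matches the cylinder volume
  straight <- makeAirwayPhantom(phantomSpec(tubeRadius = 5, pathLength = 100,
                                            bendAngle = 0), "supine")
  expect_equal(volumeValue(enclosedVolume(straight)), pi * 25 * 100,
               tolerance = 0.01)
})

test_that("analytic phantom volume follows Pappus and its scaling law", {
  expect_equal(phantomVolumeAnalytic(phantomSpec(tubeRadius = 5,
                                                 pathLength = 80)),
               6283.19, tolerance = 1e-5)
  expect_equal(phantomVolumeAnalytic(phantomSpec(tubeRadius = 5,
                                                 pathLength = 100,
                                                 bendAngle = 0)),
               7853.98, tolerance = 1e-5)
  v1 <- phantomVolumeAnalytic(phantomSpec(tubeRadius = 4, pathLength = 80))
  v2 <- phantomVolumeAnalytic(phantomSpec(tubeRadius = 8, pathLength = 80))
  expect_equal(v2 / v1, 4, tolerance = 1e-12)
})

test_that("profiled radii reduce volume and are integrated numerically", {
  narrow <- function(t) 5 - 2.5 * sin(pi * t)   # mid-path narrowing to 2.5 mm
  spec <- phantomSpec(tubeRadius = 5, pathLength = 80, bendAngle = 90,
                      radiusProfile = narrow)
  vN <- phantomVolumeAnalytic(spec)
  expect_true(attr(vN, "numeric"))
  # closed form of integral pi (5 - 2.5 sin(pi t))^2 dt over [0,1]
  closed <- pi * (25 - 2 * 5 * 2.5 * 2 / pi + 6.25 / 2) * 80
  expect_equal(as.numeric(vN), closed, tolerance = 1e-8)
  expect_lt(as.numeric(vN),
            phantomVolumeAnalytic(phantomSpec(tubeRadius = 5,
                                              pathLength = 80,
                                              bendAngle = 90)))
  mesh <- makeAirwayPhantom(spec, "supine")
  expect_true(isWatertight(mesh))
  expect_equal(volumeValue(enclosedVolume(mesh)), as.numeric(vN),
               tolerance = 0.01)
})

test_that("self-intersecting phantom specs are rejected", {
  expect_error(phantomSpec(tubeRadius = 8, pathLength = 10, bendAngle = 90),
               "self-intersecting")
  expect_error(phantomSpec(tubeRadius = 5, pathLength = 80, sections = 4),
               "sections")
})

test_that("straightening increases sagittal area and transverse length", {
  for (r in c(4, 5, 6)) {
    spec <- phantomSpec(tubeRadius = r, pathLength = 80)
    sup <- measureSubject(makeAirwayPhantom(spec, "supine"), "s", "A_normal",
                          "supine")
    ext <- measureSubject(makeAirwayPhantom(spec, "extension"), "s",
                          "A_normal", "extension")
    sSup <- planeMeasures(sup)[planeMeasures(sup)$plane == "sagittal", ]
    sExt <- planeMeasures(ext)[planeMeasures(ext)$plane == "sagittal", ]
    expect_gt(sExt$S, sSup$S)
    expect_gt(sExt$L_T, sSup$L_T)
    expect_gt(ext@volume, sup@volume)
  }
})

test_that("cohort simulation is seed-deterministic with paired structure", {
  c1 <- simulateCohort(n = 5, seed = 42, meshes = FALSE)
  c2 <- simulateCohort(n = 5, seed = 42, meshes = FALSE)
  expect_identical(c1$manifest, c2$manifest)
  c3 <- simulateCohort(n = 5, seed = 43, meshes = FALSE)
  expect_false(identical(c1$manifest$true_volume, c3$manifest$true_volume))

  man <- c1$manifest
  expect_equal(nrow(man), 5 * 2 * 2)
  expect_true(all(man$seed == 42L))
  wide <- merge(man[man$position == "supine", c("subject_id", "true_volume")],
                man[man$position == "extension", c("subject_id", "true_volume")],
                by = "subject_id", suffixes = c("_sup", "_ext"))
  expect_true(all(wide$true_volume_ext > wide$true_volume_sup))
  # solved radius reproduces the drawn volume through Pappus
  expect_equal(pi * man$tube_radius^2 * man$path_length, man$true_volume,
               tolerance = 1e-9)
})

test_that("large simulated cohorts recover the generative volume targets", {
  coh <- simulateCohort(n = 500, seed = 7, meshes = FALSE)
  man <- coh$manifest
  tg <- defaultCohortTargets()
  for (i in seq_len(nrow(tg))) {
    sel <- man$group == tg$group[i] & man$position == tg$position[i]
    se <- tg$sd[i] / sqrt(500)
    expect_lt(abs(mean(man$true_volume[sel]) - tg$mean[i]), 3 * se)
  }
})

test_that("simulated meshes measure back their drawn volumes", {
  coh <- simulateCohort(n = 3, seed = 5, sections = 32L, ringVertices = 32L)
  vols <- vapply(coh$meshes, function(m) volumeValue(enclosedVolume(m)), 0)
  key <- paste(coh$manifest$subject_id, coh$manifest$position, sep = ".")
  expect_equal(unname(vols[key]) / coh$manifest$true_volume,
               rep(1, nrow(coh$manifest)), tolerance = 0.01)
})
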