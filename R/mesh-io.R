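#' Read a triangle surface mesh
#'
#' Supports STL (binary and ASCII), ASCII PLY, and Wavefront OBJ.  Coordinates
#' are taken to be millimetres.  On load, duplicate vertices are merged within
#' 1e-6 mm, zero-area faces are dropped and the face winding is harmonised
#' (see [airwayMesh()]).
#'
#' @param path file path
#' @param format `"auto"` (from the extension) or one of `"stl"`, `"ply"`,
#'   `"obj"`
#' @return an [AirwayMesh-class]
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty mesh file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("stl", "ply", "obj"))
      stop("cannot infer mesh format from extension '", ext, "'")
    format <- ext
  }
  raw <- switch(format,
                stl = readSTL(path),
                ply = readPLY(path),
                obj = readOBJ(path))
  if (nrow(raw$vertices) == 0L || nrow(raw$faces) == 0L)
    stop("empty mesh: ", path)
  airwayMesh(raw$vertices, raw$faces)
}

readSTL <- function(path) {
  size <- file.size(path)
  isBinary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    on.exit(close(con))
    header <- readBin(con, "raw", 80)
    ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (!is.na(ntri) && size == 84 + 50 * as.numeric(ntri)) {
      isBinary <- TRUE
      v <- matrix(0, ntri * 3, 3)
      for (i in seq_len(ntri)) {
        vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
        readBin(con, "raw", 2)
        v[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      }
      f <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
      return(list(vertices = v, faces = f))
    }
    close(con)
    on.exit()
  }
  # ASCII STL
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3 != 0L)
    stop("unparseable STL file: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  if (any(!is.finite(v))) stop("unparseable STL file: ", path)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  list(vertices = v, faces = f)
}

readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("unparseable PLY file: ", path)
  endHdr <- match("end_header", trimws(lines))
  if (is.na(endHdr)) stop("unparseable PLY file (no end_header): ", path)
  hdr <- trimws(lines[seq_len(endHdr)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("unparseable PLY header: ", path)
  body <- lines[(endHdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtok <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- do.call(rbind, lapply(vtok, function(tok) as.numeric(tok[1:3])))
  ftok <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- do.call(rbind, lapply(ftok, function(tok) {
    cnt <- as.integer(tok[1])
    idx <- as.integer(tok[1 + seq_len(cnt)]) + 1L  # PLY indices are 0-based
    if (cnt < 3L) return(NULL)
    cbind(idx[1], idx[2:(cnt - 1)], idx[3:cnt])    # fan-triangulate
  }))
  if (any(!is.finite(v))) stop("unparseable PLY file: ", path)
  list(vertices = v, faces = f)
}

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L)
    stop("unparseable OBJ file: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(tok)
    as.numeric(tok[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(tok) {
    idx <- as.integer(vapply(strsplit(tok[-1], "/"), `[`, "", 1L))
    if (length(idx) < 3L) return(NULL)
    cbind(idx[1], idx[2:(length(idx) - 1)], idx[3:length(idx)])
  }))
  if (any(!is.finite(v))) stop("unparseable OBJ file: ", path)
  list(vertices = v, faces = f)
}

#' Write a triangle surface mesh
#'
#' STL is written in ASCII for portability; PLY and OBJ likewise.
#'
#' @param mesh an [AirwayMesh-class]
#' @param path output file path; format inferred from the extension unless
#'   given
#' @param format `"auto"`, `"stl"`, `"ply"` or `"obj"`
#' @return `path`, invisibly
#' @export
writeMesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  v <- mesh@vertices; f <- mesh@faces
  out <- switch(format,
    stl = {
      a <- v[f[, 1], , drop = FALSE]
      b <- v[f[, 2], , drop = FALSE]
      c_ <- v[f[, 3], , drop = FALSE]
      e1 <- b - a; e2 <- c_ - a
      n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      n <- n / pmax(sqrt(rowSums(n^2)), .Machine$double.xmin)
      c("solid airwaymorph",
        as.vector(rbind(
          sprintf("facet normal %.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]),
          "  outer loop",
          sprintf("    vertex %.9g %.9g %.9g", a[, 1], a[, 2], a[, 3]),
          sprintf("    vertex %.9g %.9g %.9g", b[, 1], b[, 2], b[, 3]),
          sprintf("    vertex %.9g %.9g %.9g", c_[, 1], c_[, 2], c_[, 3]),
          "  endloop",
          "endfacet")),
        "endsolid airwaymorph")
    },
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(v)),
            "property double x", "property double y", "property double z",
            paste("element face", nrow(f)),
            "property list uchar int vertex_indices", "end_header",
            sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]),
            sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
    obj = c(sprintf("v %.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]),
            sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
    stop("unknown mesh format '", format, "'"))
  writeLines(out, path)
  invisible(path)
}

#' Read a NIfTI segmentation mask
#'
#' Loads a 3D single-volume NIfTI image (.nii or .nii.gz) and thresholds it
#' at 0.5: voxels with intensity > 0.5 are foreground.  Spacing comes from
#' the header `pixdim`; the world origin of the grid corner is derived from
#' the header transform for axis-aligned images and defaults to 0 otherwise.
#'
#' @param path NIfTI file path
#' @return a [VoxelMask-class]
#' @seealso [maskToSurface()]
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI image: ",
                                           path, " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D single-volume image, got ", length(d), " dimensions")
  spacing <- RNifti::pixdim(img)[1:3]
  occ <- array(as.vector(img) > 0.5, dim = d)
  if (!any(occ)) stop("empty mask: no voxel above threshold in ", path)
  origin <- c(0, 0, 0)
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  if (!is.null(xf) && all(dim(xf) == c(4, 4))) {
    rot <- xf[1:3, 1:3]
    if (all(abs(rot - diag(spacing)) < 1e-6)) {
      # voxel (1,1,1) center maps from index (0,0,0): corner = center - s/2
      origin <- xf[1:3, 4] - spacing / 2
    }
  }
  methods::new("VoxelMask", occupancy = occ, spacing = as.numeric(spacing),
               origin = as.numeric(origin))
}

#' Extract a watertight surface from a voxel mask
#'
#' Marching tetrahedra over the Kuhn 6-tetrahedron decomposition of the voxel
#' lattice, at the given iso-level of the binary occupancy field (values 0/1
#' sampled at voxel centers).  The mask is padded with one empty voxel layer
#' on every side first, so surfaces close at the grid boundary.  The
#' iso-surface of the piecewise-linear field at a regular value is a closed
#' manifold, so the result is watertight by construction.
#'
#' @param mask a [VoxelMask-class]
#' @param iso iso-level in (0, 1); default 0.5 (surface midway between
#'   foreground and background voxel centers)
#' @return an [AirwayMesh-class] in world mm coordinates
#' @examples
#' m <- methods::new("VoxelMask",
#'                   occupancy = array(TRUE, c(2, 2, 2)),
#'                   spacing = c(1, 1, 1), origin = c(0, 0, 0))
#' s <- maskToSurface(m)
#' isWatertight(s)
#' @export
maskToSurface <- function(mask, iso = 0.5) {
  stopifnot(iso > 0, iso < 1)
  occ <- mask@occupancy
  if (!any(occ)) stop("empty mask")
  d <- dim(occ)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  res <- marching_tets_cpp(as.vector(padded), dim(padded), iso)
  v <- res$vertices
  # index space: padded voxel (i,j,k) center at (i,j,k); world center of the
  # unpadded voxel (i,j,k) is origin + (i - 0.5) * spacing, so padded index i
  # maps to origin + (i - 1.5) * spacing
  for (ax in 1:3)
    v[, ax] <- mask@origin[ax] + (v[, ax] - 1.5) * mask@spacing[ax]
  mesh <- airwayMesh(v, res$faces, mergeTol = 1e-9)
  mesh
}

# ---- descriptor tables -----------------------------------------------------

morphTableColumns <- function() {
  planes <- c("cor", "sag", "hor")
  c("subject_id", "group", "position", "volume_mm3", "watertight",
    as.vector(t(outer(c("S_", "L_T_", "L_L_", "alpha_lower_", "alpha_left_",
                        "degenerate_"),
                      planes, paste0))))
}

#' Serialize / read morphometry descriptor tables
#'
#' One CSV row per subject-position record.  Column names carry the plane
#' code (`cor`, `sag`, `hor`): `S_cor` is the coronal projected area in
#' mm^2, `L_T_sag` / `L_L_sag` the sagittal transverse / longitudinal radial
#' lengths in mm, `alpha_lower_hor` / `alpha_left_hor` the horizontal-plane
#' lower / left corner angles in degrees.  Together with the `position`
#' column these carry the conventional subscripted symbols (e.g. the
#' supine coronal area S_SC is the `S_cor` value of a `position == "supine"`
#' row).  The round trip through [readMorphTable()] is lossless to full
#' double precision.
#'
#' @param records a list of [MorphRecord-class] objects
#' @param path CSV file path
#' @return `writeMorphTable`: `path` invisibly; `readMorphTable`: a list of
#'   [MorphRecord-class]; `morphRecordsToFrame`: a data.frame with one row
#'   per record
#' @export
writeMorphTable <- function(records, path) {
  df <- morphRecordsToFrame(records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMorphTable
#' @export
morphRecordsToFrame <- function(records) {
  if (inherits(records, "MorphRecord")) records <- list(records)
  if (length(records) == 0L) stop("empty record list")
  rows <- lapply(records, function(r) {
    stopifnot(is(r, "MorphRecord"))
    p <- r@planes
    row <- data.frame(subject_id = r@subjectId, group = r@group,
                      position = r@position, volume_mm3 = r@volume,
                      watertight = r@watertight, stringsAsFactors = FALSE)
    for (pl in c("coronal", "sagittal", "horizontal")) {
      code <- c(coronal = "cor", sagittal = "sag", horizontal = "hor")[[pl]]
      i <- match(pl, p$plane)
      row[[paste0("S_", code)]] <- p$S[i]
      row[[paste0("L_T_", code)]] <- p$L_T[i]
      row[[paste0("L_L_", code)]] <- p$L_L[i]
      row[[paste0("alpha_lower_", code)]] <- p$alpha_lower[i]
      row[[paste0("alpha_left_", code)]] <- p$alpha_left[i]
      row[[paste0("degenerate_", code)]] <- p$degenerate[i]
    }
    row
  })
  df <- do.call(rbind, rows)
  df[, morphTableColumns()]
}

#' @rdname writeMorphTable
#' @export
readMorphTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(morphTableColumns(), names(df))
  if (length(missing))
    stop("not a morphometry table, missing columns: ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) frameRowToRecord(df[i, ]))
}

frameRowToRecord <- function(row) {
  planes <- data.frame(
    plane = c("coronal", "sagittal", "horizontal"),
    S = c(row$S_cor, row$S_sag, row$S_hor),
    L_T = c(row$L_T_cor, row$L_T_sag, row$L_T_hor),
    L_L = c(row$L_L_cor, row$L_L_sag, row$L_L_hor),
    alpha_lower = c(row$alpha_lower_cor, row$alpha_lower_sag, row$alpha_lower_hor),
    alpha_left = c(row$alpha_left_cor, row$alpha_left_sag, row$alpha_left_hor),
    degenerate = as.logical(c(row$degenerate_cor, row$degenerate_sag,
                              row$degenerate_hor)),
    stringsAsFactors = FALSE)
  methods::new("MorphRecord", subjectId = as.character(row$subject_id),
               group = as.character(row$group),
               position = as.character(row$position),
               volume = as.numeric(row$volume_mm3),
               watertight = as.logical(row$watertight), planes = planes)
}
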