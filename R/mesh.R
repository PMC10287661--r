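#' Icosphere triangle mesh
#'
#' Unit sphere obtained by subdividing a regular icosahedron and projecting
#' new vertices onto the sphere; the workhorse base shape for synthetic
#' corresponded surfaces. Closed orientable 2-manifold with Euler
#' characteristic 2 and 10 * 4^s + 2 vertices at subdivision level s.
#'
#' @param subdivisions nonnegative integer subdivision level.
#' @return list with `vertices` (V x 3) and `faces` (F x 3, 1-based,
#'   counter-clockwise seen from outside).
#' @export
icosphere <- function(subdivisions = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)
  )
  for (s in seq_len(subdivisions)) {
    mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      k <- mid[[key]]
      if (is.null(k)) {
        p <- (verts[i, ] + verts[j, ]) / 2
        p <- p / sqrt(sum(p^2))
        verts <<- rbind(verts, p)
        k <- nrow(verts)
        mid[[key]] <- k
      }
      k
    }
    nf <- matrix(0L, 0, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c3 <- f[r, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- verts; f <- nf
  }
  list(vertices = v, faces = f)
}

sg_triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c3 <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c3 - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# closed orientable manifold check: every directed edge appears exactly once
# and its reverse exactly once
sg_mesh_closed <- function(faces, n_vertices) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rkey <- paste(e[, 2], e[, 1])
  !anyDuplicated(key) && all(key %in% rkey) &&
    length(unique(as.vector(faces))) == n_vertices
}

#' Per-vertex local surface area
#'
#' Barycentric allocation: each triangle's area is split equally among its
#' three vertices, so the vertex areas sum exactly to the total mesh surface
#' area.
#'
#' @param vertices V x 3 coordinate matrix (mm).
#' @param faces F x 3 triangle index matrix (1-based).
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_local_area <- function(vertices, faces) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  if (max(faces) > nrow(vertices) || min(faces) < 1)
    stop("face indices outside the vertex range")
  ek <- paste(pmin(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)]),
              pmax(faces[, c(1, 2, 3)], faces[, c(2, 3, 1)]))
  tab <- table(ek)
  if (any(tab > 2)) {
    bad <- which(matrix(ek %in% names(tab)[tab > 2], nrow(faces)), arr.ind = TRUE)
    stop(sprintf("non-manifold mesh: edge shared by >2 triangles (triangle %d)",
                 bad[1, 1]))
  }
  ar <- sg_triangle_areas(vertices, faces)
  scale <- mean(ar)
  if (any(ar <= scale * 1e-12)) {
    stop(sprintf("degenerate (zero-area) triangle %d", which(ar <= scale * 1e-12)[1]))
  }
  va <- numeric(nrow(vertices))
  third <- ar / 3
  for (k in 1:3) {
    acc <- tapply(rep(third, 1), faces[, k], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va
}

#' Generate corresponded synthetic meshes for a cohort
#'
#' Every scan gets a deformed icosphere sharing one triangulation, so vertex
#' k corresponds across all scans. The radius at vertex v and age t is
#' `R_subject * (1 + growth_total * mult_v * t/810) * (1 + jitter)`, where
#' `mult_v` is 1 in the background, `high_mult` inside a contiguous planted
#' high-growth cap and `low_mult` inside an antipodal low-growth cap. The
#' planted vertex sets and rate field are returned as ground truth.
#'
#' @param records scan records (one mesh per row) from [generate_cohort()].
#' @param n_vertices minimum vertex count (>= 12); the smallest icosphere
#'   level with at least this many vertices is used.
#' @param growth_total total fractional radius growth over 810 days for the
#'   background field (area grows by about `(1+growth_total)^2 - 1`).
#' @param patch_frac sphere-area fraction of each planted cap (0 disables
#'   the patches, giving a uniform growth field).
#' @param high_mult,low_mult rate multipliers inside the caps.
#' @param noise_sd SD of the multiplicative per-vertex radial jitter.
#' @param subject_scale_sd SD of the per-subject global size factor.
#' @param seed integer seed.
#' @return list with `series` (a `mesh_series`: shared `faces`, per-scan
#'   `coords`, `meta`) and `mesh_truth` (`high`, `low` vertex index sets,
#'   `mult` field, `growth_total`).
#' @export
generate_meshes <- function(records, n_vertices = 42, growth_total = 0.3,
                            patch_frac = 0.10, high_mult = 2, low_mult = 0.5,
                            noise_sd = 0.005, subject_scale_sd = 0.03,
                            seed = 1L) {
  if (n_vertices < 12) stop("'n_vertices' must be at least 12")
  s <- 0L
  while (10 * 4^s + 2 < n_vertices) s <- s + 1L
  ico <- icosphere(s)
  V <- nrow(ico$vertices)
  mult <- rep(1, V)
  high <- low <- integer(0)
  if (patch_frac > 0) {
    thresh <- 1 - 2 * patch_frac   # spherical cap of area fraction patch_frac
    high <- which(ico$vertices[, 1] >= thresh)
    low <- which(-ico$vertices[, 1] >= thresh)
    mult[high] <- high_mult
    mult[low] <- low_mult
  }
  subj <- unique(records$subject_id)
  sg_with_seed(seed, {
    rs <- setNames(1 + rnorm(length(subj), 0, subject_scale_sd), subj)
    coords <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      t <- records$age_days[i]
      grow <- 1 + growth_total * mult * (t / 810)
      for (try in 1:10) {
        jit <- if (noise_sd > 0) 1 + rnorm(V, 0, noise_sd) else rep(1, V)
        r <- rs[records$subject_id[i]] * grow * jit
        xyz <- ico$vertices * r
        ar <- sg_triangle_areas(xyz, ico$faces)
        if (all(ar > mean(ar) * 1e-9)) break
        message(sprintf("degenerate triangle in scan %d; regenerating jitter", i))
      }
      coords[[i]] <- xyz
    }
    meta <- data.frame(scan_id = sprintf("%s_%04d", records$subject_id,
                                         records$age_days),
                       subject_id = records$subject_id,
                       age_days = records$age_days,
                       stringsAsFactors = FALSE)
    series <- structure(list(faces = ico$faces, coords = coords, meta = meta),
                        class = "mesh_series")
    list(series = series,
         mesh_truth = list(high = high, low = low, mult = mult,
                           growth_total = growth_total,
                           base_vertices = ico$vertices))
  })
}

#' @export
print.mesh_series <- function(x, ...) {
  cat(sprintf("Corresponded mesh series: %d scans, %d vertices, %d triangles\n",
              length(x$coords), nrow(x$coords[[1]]), nrow(x$faces)))
  invisible(x)
}

#' Write a triangle mesh as ASCII PLY
#'
#' @param vertices V x 3 matrix.
#' @param faces F x 3 1-based triangle indices.
#' @param path output file.
#' @param scalars optional named list of per-vertex numeric properties.
#' @param comment optional comment line.
#' @export
write_ply <- function(vertices, faces, path, scalars = NULL, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nrow(vertices); F <- nrow(faces)
  hdr <- c("ply", "format ascii 1.0")
  if (!is.null(comment)) hdr <- c(hdr, paste("comment", comment))
  hdr <- c(hdr, sprintf("element vertex %d", V),
           "property double x", "property double y", "property double z")
  for (nm in names(scalars)) hdr <- c(hdr, sprintf("property double %s", nm))
  hdr <- c(hdr, sprintf("element face %d", F),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- vertices
  for (nm in names(scalars)) vm <- cbind(vm, scalars[[nm]])
  writeLines(apply(format(vm, digits = 17, trim = TRUE, scientific = FALSE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY or OFF triangle mesh
#'
#' @param path mesh file (`.ply` ASCII, or `.off`).
#' @return list with `vertices`, `faces` (1-based) and any extra per-vertex
#'   `scalars`.
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  if (length(lines) && toupper(trimws(lines[1])) == "OFF") {
    counts <- scan(text = lines[2], quiet = TRUE)
    V <- counts[1]; F <- counts[2]
    verts <- matrix(scan(text = lines[3:(2 + V)], quiet = TRUE), V, byrow = TRUE)[, 1:3]
    fl <- matrix(scan(text = lines[(3 + V):(2 + V + F)], quiet = TRUE),
                 F, byrow = TRUE)
    if (any(fl[, 1] != 3)) stop("only triangle OFF meshes are supported")
    return(list(vertices = verts, faces = fl[, 2:4] + 1L, scalars = NULL))
  }
  if (!length(lines) || tolower(trimws(lines[1])) != "ply")
    stop(sprintf("'%s' is not a PLY or OFF mesh", path))
  if (!any(grepl("^format ascii", lines)))
    stop("only ASCII PLY meshes are supported")
  endh <- match("end_header", trimws(lines))
  hdr <- lines[seq_len(endh)]
  V <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  F <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vi <- grep("^element vertex", hdr)
  fi <- grep("^element face", hdr)
  props <- sub("^property \\S+ ", "", grep("^property ", hdr[vi:fi], value = TRUE))
  vl <- lines[(endh + 1):(endh + V)]
  vm <- matrix(scan(text = vl, quiet = TRUE), V, byrow = TRUE)
  colnames(vm) <- props[seq_len(ncol(vm))]
  fl <- matrix(scan(text = lines[(endh + V + 1):(endh + V + F)], quiet = TRUE),
               F, byrow = TRUE)
  if (any(fl[, 1] != 3)) stop("only triangle PLY meshes are supported")
  scal <- NULL
  if (ncol(vm) > 3) scal <- as.list(as.data.frame(vm[, -(1:3), drop = FALSE]))
  list(vertices = unname(vm[, 1:3]), faces = fl[, 2:4] + 1L, scalars = scal)
}

#' Write a corresponded mesh series to a directory
#'
#' One ASCII PLY per scan, named `<scan_id>.ply`.
#' @param series a `mesh_series`.
#' @param dir output directory (created if missing).
#' @export
write_mesh_series <- function(series, dir) {
  stopifnot(inherits(series, "mesh_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(series$coords)) {
    write_ply(series$coords[[i]], series$faces,
              file.path(dir, paste0(series$meta$scan_id[i], ".ply")))
  }
  invisible(dir)
}

#' Read a corresponded mesh series from a directory
#'
#' Reads every `.ply`/`.off` in the directory, validates that all meshes
#' share a byte-identical triangle list and that the mesh is closed and
#' orientable, and joins scan metadata from the cohort table via file names
#' `<subject_id>_<age_days>`.
#'
#' @param dir directory of mesh files.
#' @param records cohort scan records used for the metadata join.
#' @return a `mesh_series`.
#' @export
read_mesh_series <- function(dir, records) {
  files <- sort(list.files(dir, pattern = "\\.(ply|off)$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no mesh files found in '%s'", dir))
  ref <- NULL
  coords <- list()
  meta <- list()
  key <- paste(records$subject_id, sprintf("%04d", records$age_days), sep = "_")
  for (f in files) {
    m <- read_mesh(f)
    if (is.null(ref)) {
      ref <- m$faces
      if (!sg_mesh_closed(ref, nrow(m$vertices)))
        stop(sprintf("mesh '%s' is not a closed orientable manifold", basename(f)))
    } else if (!identical(unname(ref), unname(m$faces))) {
      stop(sprintf("triangulation of '%s' does not match the series", basename(f)))
    }
    id <- sub("\\.(ply|off)$", "", basename(f))
    j <- match(id, key)
    if (is.na(j))
      stop(sprintf("no cohort record for mesh '%s'", basename(f)))
    coords[[length(coords) + 1L]] <- m$vertices
    meta[[length(meta) + 1L]] <- data.frame(
      scan_id = id, subject_id = records$subject_id[j],
      age_days = records$age_days[j], stringsAsFactors = FALSE)
  }
  structure(list(faces = ref, coords = coords, meta = do.call(rbind, meta)),
            class = "mesh_series")
}
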