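#' Generate a synthetic packing of cardiomyocyte cross-sections
#'
#' Builds a histology-like set of convex polygonal cell cross-sections by
#' computing the Voronoi diagram of a jittered hexagonal lattice, clipping it
#' to the bounding box and shrinking every cell inwards so that the gaps form
#' a connected extracellular space.  The packing stands in for a manually
#' segmented histology region of interest and is the starting point for
#' extracellular-volume-fraction (ECV) morphing with [morph_ecv()].
#'
#' @param n_cells Number of cardiomyocyte cross-sections (>= 1).
#' @param mean_diameter Target centre-to-centre lattice spacing in micrometres;
#'   cardiomyocytes are typically 10-25 um across, default 18.
#' @param jitter Lattice jitter as a fraction of the spacing (0 = regular
#'   hexagons, values around 0.3 give histology-like irregularity).
#' @param seed Integer seed; the same seed reproduces the same vertex lists.
#' @param inset_frac Initial inward offset of each cell as a fraction of the
#'   lattice spacing.  The default lands near the healthy myocardial ECV of
#'   about 25%; use [morph_ecv()] to hit an exact target.
#' @return An object of class `cross_section_set`: a list with `polygons`
#'   (list of CCW n x 2 vertex matrices, um), `cell_ids`, and bounding box
#'   `Lx`, `Ly` (um).
#' @seealso [morph_ecv()], [tissue_block()], [build_substrate()]
#' @export
generate_cross_sections <- function(n_cells, mean_diameter = 18, jitter = 0.3,
                                    seed = 1L, inset_frac = 0.062) {
  stopifnot(n_cells >= 1, mean_diameter > 0, jitter >= 0)
  withr_seed(seed)
  s <- mean_diameter
  ncol_ <- max(1L, ceiling(sqrt(n_cells)))
  nrow_ <- ceiling(n_cells / ncol_)
  dy <- s * sqrt(3) / 2
  Lx <- ncol_ * s
  Ly <- max(nrow_ * dy, s)
  pts <- matrix(0, nrow_ * ncol_, 2)
  k <- 0
  for (r in seq_len(nrow_)) {
    for (cc in seq_len(ncol_)) {
      k <- k + 1
      off <- if (r %% 2 == 0) s / 2 else 0
      pts[k, ] <- c(((cc - 0.5) * s + off) %% Lx, (r - 0.5) * dy)
    }
  }
  pts <- pts[seq_len(n_cells), , drop = FALSE]
  pts <- pts + matrix(stats::runif(2 * n_cells, -jitter * s / 2, jitter * s / 2),
                      ncol = 2)
  pts[, 1] <- pmin(pmax(pts[, 1], 1e-3), Lx - 1e-3)
  pts[, 2] <- pmin(pmax(pts[, 2], 1e-3), Ly - 1e-3)

  box <- matrix(c(0, 0, Lx, 0, Lx, Ly, 0, Ly), 4, 2, byrow = TRUE)
  polys <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- box
    for (j in seq_len(n_cells)) {
      if (i == j) next
      nvec <- pts[j, ] - pts[i, ]
      cval <- sum(nvec * (pts[i, ] + pts[j, ]) / 2)
      cell <- clip_halfplane(cell, nvec, cval)
      if (is.null(cell)) break
    }
    if (is.null(cell)) stop("degenerate Voronoi cell; reduce jitter")
    polys[[i]] <- ensure_ccw(cell)
  }

  cs <- new_cross_section_set(polys, seq_len(n_cells), Lx, Ly)
  cs <- offset_all(cs, inset_frac * s)
  if (ecv(cs) > 0.98) {
    stop("requested packing is geometrically infeasible (cells vanish)")
  }
  cs
}

new_cross_section_set <- function(polygons, cell_ids, Lx, Ly) {
  structure(list(polygons = polygons, cell_ids = as.integer(cell_ids),
                 Lx = Lx, Ly = Ly),
            class = "cross_section_set")
}

offset_all <- function(cs, t) {
  polys <- lapply(cs$polygons, convex_offset, t = t)
  keep <- !vapply(polys, is.null, logical(1))
  if (!any(keep)) stop("all cells vanished during offsetting")
  new_cross_section_set(polys[keep], cs$cell_ids[keep], cs$Lx, cs$Ly)
}

#' Extracellular volume fraction of a cross-section set
#'
#' One minus the summed polygon area over the bounding-box area.
#'
#' @param cs A `cross_section_set`.
#' @return ECV as a fraction in (0, 1).
#' @export
ecv <- function(cs) {
  stopifnot(inherits(cs, "cross_section_set"))
  1 - sum(vapply(cs$polygons, polygon_area, numeric(1))) / (cs$Lx * cs$Ly)
}

#' Morph a cross-section set to a target extracellular volume fraction
#'
#' Shrinks or grows every cell by a uniform offset distance, found by binary
#' search, until the ECV is within `tol` of `target_ecv`.  This emulates
#' morphing segmented cardiomyocytes between a healthy ECV of 24.69% and the
#' extremes 18.8% and 41.82%.  Growing is refused when cells would overlap
#' (fully merge) and shrinking when cells would vanish.
#'
#' @param cs A `cross_section_set`.
#' @param target_ecv Target ECV fraction in (0, 1).
#' @param tol Absolute ECV tolerance of the search (default 1e-3).
#' @return A morphed `cross_section_set`.
#' @export
morph_ecv <- function(cs, target_ecv, tol = 1e-3) {
  stopifnot(inherits(cs, "cross_section_set"),
            target_ecv > 0, target_ecv < 1)
  cur <- ecv(cs)
  if (abs(cur - target_ecv) <= tol) return(cs)

  f <- function(t) {
    polys <- lapply(cs$polygons, convex_offset, t = t)
    keep <- !vapply(polys, is.null, logical(1))
    area <- sum(vapply(polys[keep], polygon_area, numeric(1)))
    1 - area / (cs$Lx * cs$Ly)
  }
  lo <- 0; hi <- 0
  if (target_ecv > cur) {            # shrink cells
    hi <- max(cs$Lx, cs$Ly)
    while (f(hi) < target_ecv) hi <- hi * 2
  } else {                           # grow cells
    lo <- -1
    while (f(lo) > target_ecv && lo > -max(cs$Lx, cs$Ly)) lo <- lo * 2
    if (f(lo) > target_ecv) stop("target ECV infeasible: cells fully merge")
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target_ecv) <= tol) { lo <- hi <- mid; break }
    if (v < target_ecv) lo <- mid else hi <- mid
  }
  t_star <- (lo + hi) / 2
  out <- offset_all(cs, t_star)
  if (abs(ecv(out) - target_ecv) > tol) {
    stop("target ECV infeasible within tolerance (cells vanish or merge)")
  }
  if (t_star < 0 && has_overlaps(out)) {
    stop("target ECV infeasible: grown cells overlap")
  }
  out
}

has_overlaps <- function(cs, rel_tol = 1e-6) {
  polys <- cs$polygons
  n <- length(polys)
  if (n < 2) return(FALSE)
  bb <- t(vapply(polys, function(p) {
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }, numeric(4)))
  areas <- vapply(polys, polygon_area, numeric(1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[i, 2] < bb[j, 1] || bb[j, 2] < bb[i, 1] ||
          bb[i, 4] < bb[j, 3] || bb[j, 4] < bb[i, 3]) next
      if (convex_intersection_area(polys[[i]], polys[[j]]) >
          rel_tol * min(areas[i], areas[j])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Extrude cross-sections into a three-dimensional tissue block
#'
#' The cell cross-sections are extruded along the cardiomyocyte long axis
#' (the Z direction) over a length `Lz`, mimicking the repeating
#' 495 x 392 x 127 um^3 histology block.  Cell end caps at the block faces
#' represent intercalated disks (ICD); the low-permeability ICD region also
#' covers the side walls within `icd_depth` of each cap so that the whole
#' junction is inside it regardless of geometric irregularity.
#'
#' @param cross_sections A `cross_section_set`.
#' @param Lz Extrusion length in micrometres (default 127).
#' @param icd_depth Axial extension of the low-permeability end-cap region in
#'   micrometres (default 2; must satisfy `0 <= icd_depth < Lz / 2`).
#' @return An object of class `tissue_block`.
#' @export
tissue_block <- function(cross_sections, Lz = 127, icd_depth = 2) {
  stopifnot(inherits(cross_sections, "cross_section_set"),
            Lz > 0, icd_depth >= 0, icd_depth < Lz / 2)
  structure(list(cross_sections = cross_sections, Lz = Lz,
                 icd_depth = icd_depth),
            class = "tissue_block")
}

#' Tile a tissue block into a periodic, helix-angle-rotated substrate
#'
#' The block is tiled periodically over all space.  Each row of blocks along
#' the myocardial radial direction (Y) is rigidly rotated about the Y axis by
#' `ha_rate` degrees per millimetre of depth, reproducing the transmural
#' helix-angle variation; with the default 10 deg/mm a point one block-row
#' deeper sits in a frame rotated by `ha_rate * Ly` relative to the first row.
#' Alternate block columns along X are shifted by half a block in Z to break
#' up long straight extracellular channels.
#'
#' @param block A `tissue_block`.
#' @param voxel Length-3 voxel dimensions in micrometres
#'   (default `c(2800, 2800, 8000)`, a typical DT-CMR voxel).
#' @param ha_rate Helix-angle rotation rate in degrees per millimetre about Y
#'   (default 10).
#' @param half_shift Shift alternate block columns half a block in Z
#'   (default TRUE).
#' @param buffer Seeding buffer width in micrometres around the voxel, or
#'   `NULL` to derive it from the sequence duration at run time as
#'   `4 * sqrt(2 * D_ECS * T)`.
#' @return An object of class `substrate`.
#' @export
build_substrate <- function(block, voxel = c(2800, 2800, 8000), ha_rate = 10,
                            half_shift = TRUE, buffer = NULL) {
  stopifnot(inherits(block, "tissue_block"), length(voxel) == 3,
            all(voxel > 0))
  structure(list(block = block, voxel = as.numeric(voxel),
                 ha_rate = ha_rate, half_shift = isTRUE(half_shift),
                 buffer = buffer),
            class = "substrate")
}

# Flatten a substrate into the plain list consumed by the C++ engine.
substrate_cdata <- function(s) {
  stopifnot(inherits(s, "substrate"))
  cs <- s$block$cross_sections
  list(polys = lapply(cs$polygons, function(p) t(p)),
       Lx = cs$Lx, Ly = cs$Ly, Lz = s$block$Lz,
       icd = s$block$icd_depth,
       ha_rad_per_um = s$ha_rate * pi / 180 / 1000,
       half_shift = s$half_shift)
}

#' Locate points in a substrate
#'
#' Resolves each point to exactly one compartment: intracellular space (ICS,
#' with its cell id) or extracellular space (ECS).  Points exactly on a
#' membrane resolve to ECS.  The query honours the periodic tiling, the
#' per-row helix-angle rotation and the half-block shift.
#'
#' @param s A `substrate`.
#' @param points An n x 3 matrix or data frame with columns x, y, z (um).
#' @return A tibble with columns `x`, `y`, `z`, `compartment`
#'   (`"ICS"`/`"ECS"`) and `cell_id` (`NA` in ECS).
#' @export
locate <- function(s, points) {
  pts <- as.matrix(as.data.frame(points)[, 1:3])
  ids <- mw_locate(substrate_cdata(s), pts)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                 compartment = ifelse(ids >= 0, "ICS", "ECS"),
                 cell_id = ifelse(ids >= 0, ids + 1L, NA_integer_))
}

#' First membrane crossing along a segment
#'
#' Finds the earliest intersection of the directed segment `p0 -> p1` with a
#' cell membrane: polygon side walls (sarcolemma) or prism end caps and the
#' side-wall band within `icd_depth` of a cap (intercalated disk, ICD).  The
#' parametric interval is half-open, `t` in (0, 1], so a segment starting on
#' a membrane does not immediately re-hit it.
#'
#' @param s A `substrate`.
#' @param p0,p1 Length-3 numeric start and end points (um).
#' @return `NULL` when the segment stays within one compartment, otherwise a
#'   one-row tibble with the hit position, unit normal, membrane `kind`
#'   (`"sarcolemma"`/`"ICD"`), parametric `t`, entry distance `dx` along the
#'   normal, and the compartments on both sides.
#' @export
intersect_segment <- function(s, p0, p1) {
  stopifnot(length(p0) == 3, length(p1) == 3, any(p0 != p1))
  h <- mw_intersect(substrate_cdata(s), as.numeric(p0), as.numeric(p1))
  if (h$t < 0) return(NULL)
  tibble::tibble(t = h$t,
                 x = h$pos[1], y = h$pos[2], z = h$pos[3],
                 nx = h$normal[1], ny = h$normal[2], nz = h$normal[3],
                 kind = if (h$kind == 1L) "ICD" else "sarcolemma",
                 dx = h$dx,
                 from = if (h$from >= 0) "ICS" else "ECS",
                 to = if (h$to >= 0) "ICS" else "ECS",
                 from_cell = ifelse(h$from >= 0, h$from + 1L, NA_integer_),
                 to_cell = ifelse(h$to >= 0, h$to + 1L, NA_integer_))
}

#' Write a tissue block to the plain-text substrate format
#'
#' The format is line-oriented: a comment header, one line `Lx Ly Lz
#' icd_depth`, then one polygon per line as `cell_id n x1 y1 ... xn yn`
#' (all lengths in micrometres).
#'
#' @param block A `tissue_block`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_substrate <- function(block, path) {
  stopifnot(inherits(block, "tissue_block"))
  cs <- block$cross_sections
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# myowalk substrate: Lx Ly Lz icd_depth; cell_id n x1 y1 ...", con)
  writeLines(paste(format(c(cs$Lx, cs$Ly, block$Lz, block$icd_depth),
                          digits = 17, trim = TRUE), collapse = " "), con)
  for (i in seq_along(cs$polygons)) {
    p <- cs$polygons[[i]]
    writeLines(paste(c(cs$cell_ids[i], nrow(p),
                       format(as.vector(t(p)), digits = 17, trim = TRUE)),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a tissue block from the plain-text substrate format
#'
#' @param path File written by [write_substrate()].
#' @return A `tissue_block`.
#' @export
read_substrate <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  stopifnot(length(hdr) == 4)
  polys <- list(); ids <- integer(0)
  for (ln in lines[-1]) {
    v <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    id <- as.integer(v[1]); n <- as.integer(v[2])
    stopifnot(length(v) == 2 + 2 * n)
    polys[[length(polys) + 1]] <-
      ensure_ccw(matrix(v[-(1:2)], ncol = 2, byrow = TRUE))
    ids <- c(ids, id)
  }
  cs <- new_cross_section_set(polys, ids, hdr[1], hdr[2])
  tissue_block(cs, Lz = hdr[3], icd_depth = hdr[4])
}

#' @export
print.cross_section_set <- function(x, ...) {
  cat(sprintf("<cross_section_set> %d cells, box %.1f x %.1f um, ECV %.1f%%\n",
              length(x$polygons), x$Lx, x$Ly, 100 * ecv(x)))
  invisible(x)
}

#' @export
print.tissue_block <- function(x, ...) {
  cs <- x$cross_sections
  cat(sprintf(
    "<tissue_block> %d cells, %.1f x %.1f x %.1f um, ICD depth %.1f um\n",
    length(cs$polygons), cs$Lx, cs$Ly, x$Lz, x$icd_depth))
  invisible(x)
}

#' @export
print.substrate <- function(x, ...) {
  print(x$block)
  cat(sprintf("  voxel %s um, HA %.1f deg/mm, half shift %s\n",
              paste(x$voxel, collapse = " x "), x$ha_rate, x$half_shift))
  invisible(x)
}

withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
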