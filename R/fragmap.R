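#' FragMap grid of grid free energies
#'
#' A `fragmap_grid` is an axis-aligned 3D grid of grid free energy (GFE)
#' values in kcal/mol for one FragMap type. FragMap types label the
#' functional-group class whose binding free energy the map encodes; the
#' default vocabulary is apolar (`GENN`), hydrogen-bond donor (`GEND`),
#' hydrogen-bond acceptor (`GENA`), positively charged (`MAMN`) and
#' negatively charged (`ACEO`).
#'
#' Values are capped at `gfe_cap` on construction: voxels never visited by
#' a functional group carry a finite unfavorable penalty rather than an
#' infinite one, so that poses sticking out of the sampled region score
#' badly but comparably. The default cap of +3 kcal/mol is roughly 5 kBT
#' at 300 K.
#'
#' @param values 3D numeric array of GFE values (kcal/mol), indexed
#'   `[ix, iy, iz]`.
#' @param origin numeric length-3, Cartesian coordinates (Angstrom) of the
#'   center of voxel `[1, 1, 1]`.
#' @param spacing numeric length-3 (or scalar) voxel spacing in Angstrom;
#'   must be positive.
#' @param map_type character scalar FragMap-type label.
#' @param gfe_cap numeric scalar, maximum GFE (kcal/mol); values above it
#'   are clamped and out-of-bounds lookups return it.
#' @return An object of class `fragmap_grid`.
#' @export
fragmap_grid <- function(values, origin = c(0, 0, 0), spacing = 1,
                         map_type = "GENN", gfe_cap = 3.0) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .stopf("'values' must be a 3D array")
  if (!all(is.finite(values)))
    .stopf("grid values must all be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing <= 0)) .stopf("grid spacing must be positive in each axis")
  if (!.is_number(gfe_cap)) .stopf("'gfe_cap' must be a finite number")
  values[values > gfe_cap] <- gfe_cap
  structure(list(
    map_type = as.character(map_type),
    origin = as.numeric(origin),
    spacing = as.numeric(spacing),
    dims = dim(values),
    values = values,
    gfe_cap = gfe_cap
  ), class = "fragmap_grid")
}

#' @export
print.fragmap_grid <- function(x, ...) {
  cat(sprintf(
    "<fragmap_grid> %s  %dx%dx%d voxels, spacing (%.2f, %.2f, %.2f) A\n",
    x$map_type, x$dims[1], x$dims[2], x$dims[3],
    x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A, GFE range [%.3f, %.3f], cap %.2f kcal/mol\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values), x$gfe_cap))
  invisible(x)
}

#' Bundle congruent FragMap grids into a set
#'
#' All member grids must share origin, spacing and dimensions so that a
#' single voxel index addresses the same point in space in every map.
#'
#' @param grids list of [fragmap_grid] objects; names are taken from each
#'   grid's `map_type`.
#' @return An object of class `fragmap_set` (a named list of grids).
#' @export
fragmap_set <- function(grids) {
  if (length(grids) == 0L) .stopf("a fragmap_set must contain at least one grid")
  if (!all(vapply(grids, inherits, logical(1), "fragmap_grid")))
    .stopf("all elements must be fragmap_grid objects")
  ref <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$origin, ref$origin)) ||
        !isTRUE(all.equal(g$spacing, ref$spacing)) ||
        !identical(g$dims, ref$dims))
      .stopf("grids '%s' and '%s' are not geometrically congruent",
             ref$map_type, g$map_type)
  }
  names(grids) <- vapply(grids, function(g) g$map_type, character(1))
  if (anyDuplicated(names(grids)))
    .stopf("duplicate map_type in fragmap_set")
  structure(grids, class = "fragmap_set")
}

#' @export
print.fragmap_set <- function(x, ...) {
  cat(sprintf("<fragmap_set> %d maps: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Boltzmann transformation of occupancy probabilities to GFE
#'
#' Converts a normalized 3D occupancy-probability distribution into grid
#' free energies: `GFE = -kB * T * ln(p)` where `p > 0`, capped at
#' `gfe_cap`; voxels with zero occupancy get `gfe_cap`.
#'
#' @param prob nonnegative numeric array of occupancy probabilities (a
#'   value of 1 means bulk-like occupancy, GFE 0).
#' @param temperature simulation temperature in K (default 300).
#' @param gfe_cap cap in kcal/mol applied to unfavorable values and to
#'   zero-occupancy voxels.
#' @return Numeric array of GFE values with the shape of `prob`.
#' @export
boltzmann_transform <- function(prob, temperature = 300, gfe_cap = 3.0) {
  if (!all(is.finite(prob))) .stopf("probabilities must be finite")
  if (any(prob < 0)) .stopf("probabilities must be nonnegative")
  if (!.is_number(temperature) || temperature <= 0)
    .stopf("'temperature' must be a positive number")
  gfe <- prob
  pos <- prob > 0
  gfe[pos] <- -.kB * temperature * log(prob[pos])
  gfe[!pos] <- gfe_cap
  gfe[gfe > gfe_cap] <- gfe_cap
  gfe
}

# nearest-voxel index lookup for an n x 3 coordinate matrix; returns GFE
# vector with gfe_cap for points outside the grid. Half-way points round up.
.gfe_lookup <- function(grid, coords) {
  n <- nrow(coords)
  ix <- floor((coords[, 1] - grid$origin[1]) / grid$spacing[1] + 0.5) + 1
  iy <- floor((coords[, 2] - grid$origin[2]) / grid$spacing[2] + 0.5) + 1
  iz <- floor((coords[, 3] - grid$origin[3]) / grid$spacing[3] + 0.5) + 1
  out <- rep(grid$gfe_cap, n)
  inb <- ix >= 1 & ix <= grid$dims[1] &
         iy >= 1 & iy <= grid$dims[2] &
         iz >= 1 & iz <= grid$dims[3]
  if (any(inb))
    out[inb] <- grid$values[cbind(ix[inb], iy[inb], iz[inb])]
  out
}

#' Look up the GFE at a Cartesian point
#'
#' Uses the nearest-voxel convention: the returned value is that of the
#' voxel whose center is closest to `xyz` (index
#' `floor((x - origin)/spacing + 0.5)` per axis, half-way points rounding
#' up). Points outside the grid return the grid's `gfe_cap`. Nearest-voxel
#' lookup, rather than trilinear interpolation, keeps the ligand score
#' exactly linear in per-map weights, which the reweighting machinery
#' relies on.
#'
#' @param grid a [fragmap_grid].
#' @param xyz numeric length-3 Cartesian point (Angstrom), or an n x 3
#'   matrix of points.
#' @return GFE in kcal/mol (vector of length n for a matrix input).
#' @export
gfe_at <- function(grid, xyz) {
  stopifnot(inherits(grid, "fragmap_grid"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L)
  if (ncol(xyz) != 3L) .stopf("'xyz' must have 3 columns")
  if (!all(is.finite(xyz))) .stopf("coordinates must be finite")
  .gfe_lookup(grid, xyz)
}

#' Read a GFE FragMap from an OpenDX scalar-field file
#'
#' Parses the OpenDX volumetric dialect (`object 1 class gridpositions
#' counts ...`) used as the de-facto interchange format for molecular
#' volumetric maps. Data ordering is row-major with z fastest. The
#' FragMap type is inferred from the filename convention
#' `<prefix>.<maptype>.dx` unless given explicitly.
#'
#' @param path path to a `.dx` file.
#' @param map_type FragMap-type label; default inferred from the filename.
#' @param gfe_cap cap passed to [fragmap_grid()].
#' @return A [fragmap_grid].
#' @export
read_gfe_map <- function(path, map_type = NULL, gfe_cap = 3.0) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  grab <- function(pattern, what) {
    i <- grep(pattern, lines)
    if (length(i) == 0L) .stopf("malformed OpenDX file %s: missing '%s' line", path, what)
    i[1]
  }
  ipos <- grab("^object 1 class gridpositions counts", "gridpositions")
  dims <- as.integer(strsplit(trimws(sub(
    "^object 1 class gridpositions counts", "", lines[ipos])), "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims <= 0))
    .stopf("malformed OpenDX file %s: bad counts on line '%s'", path, lines[ipos])
  iorg <- grab("^origin", "origin")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", lines[iorg])), "\\s+")[[1]])
  if (length(origin) != 3L || any(is.na(origin)))
    .stopf("malformed OpenDX file %s: bad origin line", path)
  idel <- grep("^delta", lines)
  if (length(idel) != 3L)
    .stopf("malformed OpenDX file %s: expected 3 delta lines, found %d", path, length(idel))
  deltas <- t(vapply(lines[idel], function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "\\s+")[[1]]),
    numeric(3), USE.NAMES = FALSE))
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12))
    .stopf("non-axis-aligned grid in %s: only diagonal delta vectors are supported", path)
  spacing <- diag(deltas)
  idat <- grab("class array.*data follows", "data array")
  n_items <- suppressWarnings(as.integer(sub(".*items\\s+(\\d+)\\s+data follows.*", "\\1",
                                             lines[idat])))
  n_expect <- prod(dims)
  if (!is.na(n_items) && n_items != n_expect)
    .stopf("OpenDX file %s declares %d items for %d voxels (line '%s')",
           path, n_items, n_expect, lines[idat])
  body <- lines[(idat + 1L):length(lines)]
  body <- body[!grepl("^(attribute|object|component|end)\\b", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_expect)
    .stopf("OpenDX file %s: %d data values for %d declared voxels",
           path, length(vals), n_expect)
  # dx payload is z-fastest: fill (z, y, x) then transpose to [x, y, z]
  arr <- aperm(array(vals, dim = rev(dims)), 3:1)
  if (is.null(map_type)) {
    parts <- strsplit(basename(path), ".", fixed = TRUE)[[1]]
    map_type <- if (length(parts) >= 3L) parts[length(parts) - 1L] else
      sub("\\.dx$", "", basename(path))
  }
  fragmap_grid(arr, origin = origin, spacing = spacing,
               map_type = map_type, gfe_cap = max(gfe_cap, max(vals)))
}

#' Write a GFE FragMap as an OpenDX scalar field
#'
#' Inverse of [read_gfe_map()]; values are written with 17 significant
#' digits so that a read-back round trip reproduces them exactly.
#'
#' @param grid a [fragmap_grid].
#' @param path output path (conventionally `<prefix>.<maptype>.dx`).
#' @return `path`, invisibly.
#' @export
write_gfe_map <- function(grid, path) {
  stopifnot(inherits(grid, "fragmap_grid"))
  d <- grid$dims
  head_ <- c(
    sprintf("# GFE FragMap type %s (kcal/mol)", grid$map_type),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.17g %.17g %.17g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.17g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.17g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.17g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d))
  )
  vals <- as.vector(aperm(grid$values, 3:1))  # z fastest
  n <- length(vals)
  pad <- (3L - n %% 3L) %% 3L
  rows <- matrix(c(sprintf("%.17g", vals), rep("", pad)), ncol = 3L, byrow = TRUE)
  body <- trimws(apply(rows, 1L, paste, collapse = " "))
  tail_ <- c('attribute "dep" string "positions"',
             'object "regular positions regular connections" class field',
             'component "positions" value 1',
             'component "connections" value 2',
             'component "data" value 3')
  writeLines(c(head_, body, tail_), path)
  invisible(path)
}

#' Read a directory of FragMaps into a set
#'
#' Reads every `<prefix>.<maptype>.dx` file in `dir` and bundles them.
#'
#' @param dir directory containing `.dx` files.
#' @param gfe_cap cap passed through to [read_gfe_map()].
#' @return A [fragmap_set].
#' @export
read_fragmap_dir <- function(dir, gfe_cap = 3.0) {
  files <- list.files(dir, pattern = "\\.dx$", full.names = TRUE)
  if (length(files) == 0L) .stopf("no .dx files in %s", dir)
  fragmap_set(lapply(sort(files), read_gfe_map, gfe_cap = gfe_cap))
}

#' Write a FragMap set to a directory
#'
#' @param maps a [fragmap_set].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix; files are `<prefix>.<maptype>.dx`.
#' @return The written paths, invisibly.
#' @export
write_fragmap_dir <- function(maps, dir, prefix = "maps") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(maps, function(g) {
    p <- file.path(dir, sprintf("%s.%s.dx", prefix, g$map_type))
    write_gfe_map(g, p)
    p
  }, character(1))
  invisible(paths)
}
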