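#' Construct a ligand
#'
#' A `ligand` is a molecular graph with 3D coordinates: an atom table
#' (element, formal charge, aromatic flag, Cartesian coordinates in
#' Angstrom) and a bond table (1-based atom indices and bond order).
#'
#' @param name identifier string.
#' @param atoms data.frame with columns `element` (character), `charge`
#'   (integer formal charge, e), `aromatic` (logical), `x`, `y`, `z`
#'   (numeric, Angstrom). Missing `charge`/`aromatic` default to 0/FALSE.
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices)
#'   and `order` (integer bond order).
#' @param ionization_state `"neutral"` or `"charged"`; a bookkeeping label
#'   for multi-state scoring, not validated against the formal charges.
#' @return An object of class `ligand`.
#' @export
ligand <- function(name, atoms, bonds,
                   ionization_state = c("neutral", "charged")) {
  ionization_state <- match.arg(ionization_state)
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  req <- c("element", "charge", "aromatic", "x", "y", "z")
  if (!all(req %in% names(atoms)))
    .stopf("atom table must have columns: %s", paste(req, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    .stopf("ligand '%s': non-finite coordinates", name)
  n <- nrow(atoms)
  if (n == 0L) .stopf("ligand '%s' has no atoms", name)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0L) {
    if (!all(c("i", "j", "order") %in% names(bonds)))
      .stopf("bond table must have columns i, j, order")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      .stopf("ligand '%s': bond endpoint out of range", name)
    if (any(bonds$i == bonds$j))
      .stopf("ligand '%s': self-bond", name)
  }
  lig <- structure(list(
    name = as.character(name),
    atoms = atoms[, req],
    bonds = bonds,
    ionization_state = ionization_state
  ), class = "ligand")
  if (n > 1L && igraph::components(.ligand_graph(lig))$no > 1L)
    .warnf("ligand '%s' is a disconnected graph", name)
  lig
}

.ligand_graph <- function(lig) {
  g <- igraph::make_empty_graph(nrow(lig$atoms), directed = FALSE)
  if (nrow(lig$bonds) > 0L)
    g <- igraph::add_edges(g, as.vector(t(as.matrix(lig$bonds[, c("i", "j")]))))
  g
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand> %s (%s): %d atoms (%d heavy), %d bonds\n",
              x$name, x$ionization_state, nrow(x$atoms),
              sum(x$atoms$element != "H"), nrow(x$bonds)))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param lig a [ligand].
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(lig) {
  as.matrix(lig$atoms[, c("x", "y", "z")])
}

#' A conformer: alternative coordinates for a ligand
#'
#' @param parent the parent [ligand].
#' @param xyz n_atoms x 3 coordinate matrix (Angstrom); defaults to the
#'   parent's own coordinates.
#' @return An object of class `conformer`.
#' @export
conformer <- function(parent, xyz = coords(parent)) {
  stopifnot(inherits(parent, "ligand"))
  xyz <- as.matrix(xyz)
  if (!identical(dim(xyz), c(nrow(parent$atoms), 3L)) &&
      !all(dim(xyz) == c(nrow(parent$atoms), 3L)))
    .stopf("conformer coordinates must be %d x 3", nrow(parent$atoms))
  if (!all(is.finite(xyz))) .stopf("conformer coordinates must be finite")
  dimnames(xyz) <- NULL
  structure(list(parent = parent, xyz = xyz), class = "conformer")
}

#' Pair of ionization states of one compound
#'
#' Both states share the heavy-atom scaffold; the charged state differs in
#' protonation. The pKa and the kind of ionizable group (acid or base)
#' drive Henderson-Hasselbalch mixing of the two state scores.
#'
#' @param neutral,charged [ligand] objects for the two states.
#' @param pKa numeric pKa of the ionizable group.
#' @param kind `"acid"` or `"base"`.
#' @return An object of class `ionization_pair`.
#' @export
ionization_pair <- function(neutral, charged, pKa, kind = c("base", "acid")) {
  kind <- match.arg(kind)
  stopifnot(inherits(neutral, "ligand"), inherits(charged, "ligand"))
  if (!.is_number(pKa)) .stopf("'pKa' must be a finite number")
  n_heavy <- function(l) sum(l$atoms$element != "H")
  if (n_heavy(neutral) != n_heavy(charged))
    .stopf("ionization pair '%s': states differ in heavy-atom count", neutral$name)
  structure(list(neutral = neutral, charged = charged,
                 pKa = pKa, kind = kind), class = "ionization_pair")
}

# ---------------------------------------------------------------------------
# SDF (MDL V2000) I/O. Hand-written because formal charges (M CHG lines)
# must survive the round trip; they decide the charged FragMap classes.

.CHARGE_CODES <- c("3" = 1L, "2" = 2L, "1" = 3L, "0" = 0L, "5" = -1L,
                   "6" = -2L, "7" = -3L)

.parse_sdf_record <- function(lines, index) {
  if (length(lines) < 4L) .stopf("record %d: too short", index)
  name <- trimws(lines[1])
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    .stopf("record %d ('%s'): bad counts line", index, name)
  if (length(lines) < 4L + natoms + nbonds)
    .stopf("record %d ('%s'): truncated atom/bond block", index, name)
  at <- lines[5:(4L + natoms)]
  x <- as.numeric(substr(at, 1L, 10L))
  y <- as.numeric(substr(at, 11L, 20L))
  z <- as.numeric(substr(at, 21L, 30L))
  element <- trimws(substr(at, 32L, 34L))
  if (any(is.na(x)) || any(is.na(y)) || any(is.na(z)) || any(element == ""))
    .stopf("record %d ('%s'): bad atom line", index, name)
  ccode <- trimws(substr(at, 37L, 39L))
  charge <- unname(.CHARGE_CODES[ccode])
  charge[is.na(charge)] <- 0L
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (nbonds > 0L) {
    bl <- lines[(5L + natoms):(4L + natoms + nbonds)]
    bonds <- data.frame(
      i = as.integer(substr(bl, 1L, 3L)),
      j = as.integer(substr(bl, 4L, 6L)),
      order = as.integer(substr(bl, 7L, 9L)))
    if (any(is.na(as.matrix(bonds))))
      .stopf("record %d ('%s'): bad bond line", index, name)
  }
  # M CHG supersedes the atom-block charge column when present
  mchg <- grep("^M  CHG", lines, value = TRUE)
  if (length(mchg) > 0L) {
    charge <- rep(0L, natoms)
    for (l in mchg) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      npairs <- f[1]
      for (k in seq_len(npairs))
        charge[f[2 * k]] <- f[2 * k + 1L]
    }
  }
  ligand(if (nzchar(name)) name else sprintf("mol_%d", index),
         atoms = data.frame(element = element, charge = charge,
                            aromatic = FALSE, x = x, y = y, z = z),
         bonds = bonds)
}

#' Read ligands from an SDF file
#'
#' Parses MDL V2000 records, preserving 3D coordinates, elements, bond
#' orders, names and formal charges (both the legacy atom-block charge
#' column and `M CHG` lines, the latter taking precedence). Records that
#' fail structural sanity checks are skipped with a warning rather than
#' aborting the whole file.
#'
#' @param path SDF file path.
#' @return List of [ligand] objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  # split on $$$$ delimiters
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  ligs <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:min(ends[k], length(lines))]
    block <- block[!grepl("^\\$\\$\\$\\$\\s*$", block)]
    if (all(!nzchar(trimws(block)))) next
    lig <- tryCatch(.parse_sdf_record(block, k), error = function(e) {
      .warnf("skipping SDF record %d in %s: %s", k, basename(path),
             conditionMessage(e))
      NULL
    })
    if (!is.null(lig)) ligs[[length(ligs) + 1L]] <- lig
  }
  if (length(ligs) == 0L) .stopf("no parsable records in %s", path)
  ligs
}

.format_sdf_record <- function(lig, tags = NULL) {
  n <- nrow(lig$atoms)
  nb <- nrow(lig$bonds)
  out <- c(lig$name, "  gfedock", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n))
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          lig$atoms$x[a], lig$atoms$y[a], lig$atoms$z[a],
                          lig$atoms$element[a]))
  for (b in seq_len(nb))
    out <- c(out, sprintf("%3d%3d%3d  0",
                          lig$bonds$i[b], lig$bonds$j[b], lig$bonds$order[b]))
  chg <- which(lig$atoms$charge != 0L)
  if (length(chg) > 0L)
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                         paste0(sprintf("%4d%4d", chg, lig$atoms$charge[chg]),
                                collapse = "")))
  out <- c(out, "M  END")
  if (!is.null(tags))
    for (tn in names(tags))
      out <- c(out, sprintf(">  <%s>", tn), as.character(tags[[tn]]), "")
  c(out, "$$$$")
}

#' Write ligands to an SDF file
#'
#' @param ligs a [ligand] or list of ligands.
#' @param path output path.
#' @param tags optional named list (one per ligand) of named data tags,
#'   written as SDF data fields (e.g. LGFE scores on docked poses).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(ligs, path, tags = NULL) {
  if (inherits(ligs, "ligand")) ligs <- list(ligs)
  out <- character(0)
  for (k in seq_along(ligs))
    out <- c(out, .format_sdf_record(ligs[[k]],
                                     if (!is.null(tags)) tags[[k]] else NULL))
  writeLines(out, path)
  invisible(path)
}

#' Replace a ligand's coordinates with a conformer's
#'
#' @param conf a [conformer].
#' @return A [ligand] with the conformer geometry.
#' @export
as_ligand <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  lig <- conf$parent
  lig$atoms$x <- conf$xyz[, 1]
  lig$atoms$y <- conf$xyz[, 2]
  lig$atoms$z <- conf$xyz[, 3]
  lig
}
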