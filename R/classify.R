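#' Default FragMap atom-classification rules
#'
#' A generic-apolar-scale style rule table mapping heavy atoms to FragMap
#' types. Rules are applied in order (first match wins), encoding the
#' precedence charged > donor > acceptor > apolar:
#'
#' * nitrogen with formal charge +1 -> `MAMN` (positive)
#' * oxygen with formal charge -1 -> `ACEO` (negative)
#' * N/O bearing at least one hydrogen -> `GEND` (donor)
#' * N/O without hydrogens -> `GENA` (acceptor)
#' * carbon (aromatic or aliphatic) -> `GENN` (apolar)
#'
#' Hydrogens are never classified (they carry no GFE; FragMaps are built
#' from heavy-atom densities), and elements no rule covers are labeled
#' `UNCLASSIFIED` with a warning. The table is a plain data.frame so users
#' can substitute their own scheme, e.g. a published classification table,
#' via [read_classification_rules()].
#'
#' @return data.frame with columns `label`, `elements`
#'   (comma-separated element list), `charge` (exact formal charge or NA
#'   for any), `needs_h` (TRUE = requires a bonded H, FALSE = requires
#'   none, NA = either).
#' @export
default_classification_rules <- function() {
  data.frame(
    label    = c("MAMN", "ACEO", "GEND", "GENA", "GENN"),
    elements = c("N", "O", "N,O", "N,O", "C"),
    charge   = c(1L, -1L, 0L, 0L, 0L),
    needs_h  = c(NA, NA, TRUE, FALSE, NA),
    stringsAsFactors = FALSE
  )
}

#' Read / write a classification rule table (YAML)
#'
#' The YAML file is a list of rules with fields `label`, `elements`,
#' `charge` (may be `.na`), `needs_h` (may be `.na`), in precedence order.
#'
#' @param path YAML file path.
#' @return data.frame in the format of [default_classification_rules()].
#' @export
read_classification_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(rules, function(r) {
    data.frame(label = r$label,
               elements = paste(r$elements, collapse = ","),
               charge = if (is.null(r$charge)) NA_integer_ else as.integer(r$charge),
               needs_h = if (is.null(r$needs_h)) NA else as.logical(r$needs_h),
               stringsAsFactors = FALSE)
  }))
  out
}

#' @rdname read_classification_rules
#' @param rules a rule data.frame.
#' @export
write_classification_rules <- function(rules, path) {
  lst <- lapply(seq_len(nrow(rules)), function(k) {
    r <- as.list(rules[k, ])
    r$elements <- strsplit(r$elements, ",")[[1]]
    if (is.na(r$charge)) r$charge <- NULL
    if (is.na(r$needs_h)) r$needs_h <- NULL
    r
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Assign FragMap types to ligand atoms
#'
#' A pure function of the molecular graph and formal charges: coordinates
#' never enter, so the assignment is valid for every conformer of the
#' ligand. Each heavy atom gets exactly one label; hydrogens are
#' `UNCLASSIFIED` and contribute zero GFE.
#'
#' @param lig a [ligand].
#' @param rules rule table, default [default_classification_rules()].
#' @return character vector of per-atom labels (class
#'   `atom_class_assignment`), names = atom indices.
#' @export
classify_atoms <- function(lig, rules = default_classification_rules()) {
  stopifnot(inherits(lig, "ligand"))
  n <- nrow(lig$atoms)
  elem <- lig$atoms$element
  chg <- lig$atoms$charge
  # bonded-H count per atom
  nH <- integer(n)
  if (nrow(lig$bonds) > 0L) {
    for (b in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds$i[b]; j <- lig$bonds$j[b]
      if (elem[j] == "H") nH[i] <- nH[i] + 1L
      if (elem[i] == "H") nH[j] <- nH[j] + 1L
    }
  }
  labels <- rep("UNCLASSIFIED", n)
  rule_elems <- strsplit(rules$elements, ",")
  for (a in seq_len(n)) {
    if (elem[a] == "H") next
    for (r in seq_len(nrow(rules))) {
      if (!(elem[a] %in% rule_elems[[r]])) next
      if (!is.na(rules$charge[r]) && chg[a] != rules$charge[r]) next
      if (!is.na(rules$needs_h[r]) && (nH[a] > 0L) != rules$needs_h[r]) next
      labels[a] <- rules$label[r]
      break
    }
    if (labels[a] == "UNCLASSIFIED")
      .warnf("ligand '%s': atom %d (%s, charge %+d) matches no rule; UNCLASSIFIED",
             lig$name, a, elem[a], chg[a])
  }
  structure(labels, names = seq_len(n), class = "atom_class_assignment")
}

#' Rotatable bonds and their torsions
#'
#' A bond is rotatable when it is a single, acyclic (bridge) bond between
#' two heavy atoms that each have at least two heavy neighbors; bonds to
#' terminal atoms or inside rings are excluded. For each rotatable bond a
#' torsion quadruple `(i, j, k, l)` is reported, together with the set of
#' atom indices on the `k` side (the side moved by a torsion rotation).
#'
#' @param lig a [ligand].
#' @return List of torsions, each a list with `i`, `j`, `k`, `l` (atom
#'   indices) and `movable` (integer vector of atoms rotated by the move,
#'   hydrogens included). Empty list for rigid molecules.
#' @export
rotatable_bonds <- function(lig) {
  stopifnot(inherits(lig, "ligand"))
  if (nrow(lig$bonds) == 0L) return(list())
  g <- .ligand_graph(lig)
  elem <- lig$atoms$element
  heavy <- elem != "H"
  # heavy-neighbor counts
  nbr <- lapply(seq_len(nrow(lig$atoms)), function(a)
    as.integer(igraph::neighbors(g, a)))
  n_heavy_nbr <- vapply(nbr, function(v) sum(heavy[v]), integer(1))
  bridges <- igraph::bridges(g)
  bridge_ids <- as.integer(bridges)
  tors <- list()
  for (b in seq_len(nrow(lig$bonds))) {
    j <- lig$bonds$i[b]; k <- lig$bonds$j[b]
    if (lig$bonds$order[b] != 1L) next
    if (!heavy[j] || !heavy[k]) next
    if (n_heavy_nbr[j] < 2L || n_heavy_nbr[k] < 2L) next
    eid <- igraph::get_edge_ids(g, c(j, k))
    if (!(eid %in% bridge_ids)) next  # ring bond
    # torsion reference atoms: a heavy neighbor on each side
    i <- setdiff(nbr[[j]][heavy[nbr[[j]]]], k)[1]
    l <- setdiff(nbr[[k]][heavy[nbr[[k]]]], j)[1]
    # movable side: component containing k after deleting the bond
    g2 <- igraph::delete_edges(g, eid)
    comp <- igraph::components(g2)$membership
    movable <- which(comp == comp[k])
    tors[[length(tors) + 1L]] <- list(i = i, j = j, k = k, l = l,
                                      movable = as.integer(movable))
  }
  tors
}
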