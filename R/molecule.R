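#' @importFrom stats coef cor lm lm.influence predict rnorm runif setNames
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Bondi van der Waals radii (Angstrom), pinned so every geometry descriptor
# is reproducible.  Only the elements occurring in the compound series and
# in the synthetic molecule generator are listed.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 Cl = 1.75, F = 1.47, Br = 1.85, P = 1.80)

# Standard atomic weights (Da), used for the mass-weighted inertia tensor
# and molecular formula reporting.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, Cl = 35.45, F = 18.998, Br = 79.904,
                   P = 30.974)

#' Construct a molecule object
#'
#' A `qsar_molecule` is the substrate of every descriptor engine in the
#' package: an ordered atom table, a bond list over atom indices, and the
#' net formal charge.  Atoms may carry partial charges and 3D coordinates
#' once those have been assigned by [gasteiger_charges()] and [embed_3d()].
#'
#' @param id compound label.
#' @param atoms data frame with columns `element`, `formal_charge`,
#'   `n_implicit_h`; optional `partial_charge`, `x`, `y`, `z`.
#' @param bonds data frame with columns `i`, `j`, `order` indexing rows of
#'   `atoms`.
#' @return object of class `qsar_molecule`.
#' @export
new_molecule <- function(id, atoms, bonds) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  atoms$element <- as.character(atoms$element)
  bad <- setdiff(atoms$element, names(BONDI_RADII))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$n_implicit_h)) atoms$n_implicit_h <- 0L
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- NA_real_
  if (!all(c("x", "y", "z") %in% names(atoms)))
    atoms$x <- atoms$y <- atoms$z <- NA_real_
  atoms$vdw_radius <- unname(BONDI_RADII[atoms$element])
  atoms$mass <- unname(ATOMIC_MASSES[atoms$element])
  n <- nrow(atoms)
  if (nrow(bonds)) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-bond not allowed")
  }
  has_xyz <- !is.na(atoms$x)
  if (any(has_xyz) && !all(has_xyz))
    stop("either all atoms have coordinates or none do")
  structure(list(id = id, atoms = atoms,
                 bonds = bonds[, c("i", "j", "order"), drop = FALSE],
                 charge = sum(atoms$formal_charge)),
            class = "qsar_molecule")
}

#' @export
print.qsar_molecule <- function(x, ...) {
  cat(sprintf("<qsar_molecule> %s: %s, %d atoms (%d heavy), %d bonds%s%s\n",
              x$id, molecular_formula(x), nrow(x$atoms),
              sum(x$atoms$element != "H"), nrow(x$bonds),
              if (has_coords(x)) ", 3D" else "",
              if (has_charges(x)) ", charged" else ""))
  invisible(x)
}

has_coords <- function(mol) all(!is.na(mol$atoms$x))
has_charges <- function(mol) all(!is.na(mol$atoms$partial_charge))

#' Hydrogen-inclusive molecular formula
#'
#' Counts explicit atoms plus implicit hydrogens, in Hill order
#' (C, H, then alphabetical).
#'
#' @param mol a `qsar_molecule`.
#' @return formula string, e.g. `"C15H12N2O6S2"`.
#' @export
molecular_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  nh <- sum(mol$atoms$n_implicit_h) + sum(mol$atoms$element == "H")
  counts <- counts[names(counts) != "H"]
  elems <- c(intersect(c("C"), names(counts)),
             if (nh > 0) "H",
             sort(setdiff(names(counts), "C")))
  paste0(vapply(elems, function(e) {
    k <- if (e == "H") nh else as.integer(counts[[e]])
    paste0(e, if (k > 1) k else "")
  }, ""), collapse = "")
}

# Heavy-atom adjacency list (hydrogen-suppressed graph), used by the
# topological descriptor engines.  Returns list(deg=, adj=, idx=) where idx
# maps heavy-atom positions back to atom-table rows.
heavy_graph <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  remap <- integer(nrow(mol$atoms))
  remap[heavy] <- seq_along(heavy)
  adj <- vector("list", length(heavy))
  b <- mol$bonds
  keep <- b$i %in% heavy & b$j %in% heavy
  for (k in which(keep)) {
    i <- remap[b$i[k]]; j <- remap[b$j[k]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  list(deg = lengths(adj), adj = adj, idx = heavy,
       edges = cbind(remap[b$i[keep]], remap[b$j[keep]]))
}

coords_matrix <- function(mol) {
  if (!has_coords(mol)) stop("molecule '", mol$id, "' has no 3D coordinates")
  as.matrix(mol$atoms[, c("x", "y", "z")])
}
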