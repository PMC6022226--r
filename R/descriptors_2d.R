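# Topological descriptors computed from the hydrogen-suppressed chemical
# graph alone: Kier-Hall simple (and valence-corrected) connectivity chi
# indices, and the Shannon information content of the atomic composition.

# vertex degree set delta for the chi family; valence = Kier-Hall valence
# delta (Zv - h for second-row elements, (Zv - h)/(Z - Zv - 1) beyond)
chi_delta <- function(mol, valence = FALSE) {
  g <- heavy_graph(mol)
  if (!valence) return(list(g = g, delta = g$deg))
  ZV <- c(C = 4, N = 5, O = 6, S = 6, Cl = 7, F = 7, Br = 7, P = 5)
  Z  <- c(C = 6, N = 7, O = 8, S = 16, Cl = 17, F = 9, Br = 35, P = 15)
  el <- mol$atoms$element[g$idx]
  nh <- mol$atoms$n_implicit_h[g$idx]
  # count explicit hydrogens too
  hy <- which(mol$atoms$element == "H")
  if (length(hy)) {
    b <- mol$bonds
    for (k in seq_len(nrow(b))) {
      if (b$i[k] %in% hy && !(b$j[k] %in% hy)) {
        pos <- match(b$j[k], g$idx); nh[pos] <- nh[pos] + 1L
      } else if (b$j[k] %in% hy && !(b$i[k] %in% hy)) {
        pos <- match(b$i[k], g$idx); nh[pos] <- nh[pos] + 1L
      }
    }
  }
  dv <- (ZV[el] - nh) / pmax(Z[el] - ZV[el] - 1, 1)
  list(g = g, delta = unname(dv))
}

#' Kier-Hall connectivity index
#'
#' Simple molecular connectivity: the sum over connected subgraphs of the
#' requested edge count (`order`) and class (`kind`) of the reciprocal
#' square root of the product of vertex degrees, taken on the
#' hydrogen-suppressed graph.  Supported subgraphs: paths of 0-3 edges and
#' the 3-edge cluster (star).  With `valence = TRUE` the Kier-Hall valence
#' delta replaces the simple degree.
#'
#' @param mol a `qsar_molecule`.
#' @param order subgraph edge count, 0 to 3.
#' @param kind `"path"` or `"cluster"` (cluster only defined for order 3).
#' @param valence use valence-corrected deltas.
#' @return the connectivity index (>= 0).
#' @export
#' @examples
#' chi_index(parse_structure("CCCC"), 1)        # n-butane, 1.9142
#' chi_index(parse_structure("CC(C)C"), 3, "cluster")  # isobutane, 0.5774
chi_index <- function(mol, order, kind = c("path", "cluster"),
                      valence = FALSE) {
  kind <- match.arg(kind)
  if (!order %in% 0:3)
    stop("unsupported chi order: ", order)
  if (kind == "cluster" && order != 3)
    stop("cluster subgraphs are only defined for order 3 here")
  cd <- chi_delta(mol, valence)
  d <- cd$delta; adj <- cd$g$adj; n <- length(d)
  if (n == 0) stop("empty molecule")
  rs <- function(v) 1 / sqrt(v)
  if (order == 0) return(sum(rs(d)))
  E <- cd$g$edges
  if (order == 1) {
    if (is.null(E) || nrow(E) == 0) return(0)
    return(sum(rs(d[E[, 1]] * d[E[, 2]])))
  }
  if (order == 2) {
    tot <- 0
    for (m in seq_len(n)) {
      nb <- adj[[m]]
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        tot <- tot + sum(rs(d[pr[1, ]] * d[m] * d[pr[2, ]]))
      }
    }
    return(tot)
  }
  if (kind == "cluster") {
    tot <- 0
    for (m in seq_len(n)) {
      nb <- adj[[m]]
      if (length(nb) >= 3) {
        tr <- utils::combn(nb, 3)
        tot <- tot + sum(rs(d[m] * d[tr[1, ]] * d[tr[2, ]] * d[tr[3, ]]))
      }
    }
    return(tot)
  }
  # order-3 paths: 4 distinct vertices i-j-k-l over each central edge (j,k)
  tot <- 0
  if (!is.null(E) && nrow(E)) {
    for (e in seq_len(nrow(E))) {
      j <- E[e, 1]; k <- E[e, 2]
      for (i in setdiff(adj[[j]], k))
        for (l in setdiff(adj[[k]], c(j, i)))
          tot <- tot + rs(d[i] * d[j] * d[k] * d[l])
    }
  }
  tot
}

#' Third-order cluster connectivity (CHI_3_C)
#'
#' Sum over all 3-edge star subgraphs (three edges sharing one central
#' atom) of the reciprocal square root of the degree product of the four
#' atoms involved; zero when no atom has degree >= 3.
#'
#' @inheritParams chi_index
#' @return the cluster index.
#' @export
chi_cluster_3 <- function(mol, valence = FALSE) {
  chi_index(mol, 3, "cluster", valence)
}

#' Information content of the atomic composition
#'
#' Shannon entropy of the element-composition distribution of the molecule:
#' with `ni` atoms of element `i` out of `n` total,
#' `IAC_total = n log2 n - sum(ni log2 ni)` bits and
#' `IAC_mean = IAC_total / n` bits per atom.  Hydrogens (implicit and
#' explicit) are counted by default.
#'
#' @param mol a `qsar_molecule`.
#' @param include_hydrogens count hydrogens in the composition.
#' @return `iac_mean()`: bits per atom; `iac_total()`: bits.
#' @export
#' @examples
#' iac_mean(parse_structure("C"))   # methane: 0.7219 bits
iac_mean <- function(mol, include_hydrogens = TRUE) {
  iac(mol, include_hydrogens)$mean
}

#' @rdname iac_mean
#' @export
iac_total <- function(mol, include_hydrogens = TRUE) {
  iac(mol, include_hydrogens)$total
}

iac <- function(mol, include_hydrogens = TRUE) {
  el <- mol$atoms$element
  if (include_hydrogens)
    el <- c(el, rep("H", sum(mol$atoms$n_implicit_h)))
  else {
    keep <- el != "H"
    el <- el[keep]
  }
  n <- length(el)
  if (n == 0) stop("empty composition")
  ni <- as.numeric(table(el))
  total <- n * log2(n) - sum(ni * log2(ni))
  list(total = total, mean = total / n)
}

# All topological descriptor columns for one molecule, in the fixed schema
# order used by descriptor_table().
topo_descriptors <- function(mol) {
  out <- c(CHI_0 = chi_index(mol, 0),
           CHI_1 = chi_index(mol, 1),
           CHI_2 = chi_index(mol, 2),
           CHI_3_P = chi_index(mol, 3, "path"),
           CHI_3_C = chi_index(mol, 3, "cluster"),
           IAC_Total = iac_total(mol),
           IAC_Mean = iac_mean(mol),
           CHI_V_0 = chi_index(mol, 0, valence = TRUE),
           CHI_V_1 = chi_index(mol, 1, valence = TRUE),
           CHI_V_2 = chi_index(mol, 2, valence = TRUE),
           CHI_V_3_P = chi_index(mol, 3, "path", valence = TRUE),
           CHI_V_3_C = chi_index(mol, 3, "cluster", valence = TRUE))
  out
}
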