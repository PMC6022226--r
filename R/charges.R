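# Gasteiger-Marsili partial charges by iterative partial equalization of
# orbital electronegativity (PEOE).  Electronegativity of atom i at charge
# q is chi_i = a + b q + c q^2; at iteration k a charge increment
# (chi_hi - chi_lo) / chi_plus(lo) * (1/2)^k flows across every bond from
# the less to the more electronegative end, where chi_plus is the cation
# electronegativity (a + b + c) of the donor atom (20.02 for hydrogen).

# orbital electronegativity parameters (a, b, c) keyed by element and
# hybridization state
PEOE_PARAMS <- list(
  "H"      = c(7.17,  6.24, -0.56),
  "C.sp3"  = c(7.98,  9.18,  1.88),
  "C.sp2"  = c(8.79,  9.32,  1.51),
  "C.sp"   = c(10.39, 9.45,  0.73),
  "N.sp3"  = c(11.54, 10.82, 1.36),
  "N.sp2"  = c(12.87, 11.15, 0.85),
  "N.sp"   = c(15.68, 11.70, -0.27),
  "O.sp3"  = c(14.18, 12.92, 1.39),
  "O.sp2"  = c(17.07, 13.79, 0.47),
  "F"      = c(14.66, 13.85, 2.31),
  "Cl"     = c(11.00, 9.69,  1.35),
  "Br"     = c(10.08, 8.47,  1.16),
  "S.sp3"  = c(10.14, 9.13,  1.38),
  "S.sp2"  = c(10.88, 9.49,  1.33))

# hybridization-state key per atom, from the (kekulized) bond orders.
# A nitrogen or oxygen carrying only single bonds is demoted from sp3 to
# sp2 when its lone pair can conjugate into an adjacent pi system, i.e.
# when some neighbour of degree <= 3 carries a multiple bond (the
# amide/aniline/ester/nitro case); hypervalent sulfonyl neighbours do not
# trigger the demotion.
peoe_key <- function(mol) {
  el <- mol$atoms$element
  n <- nrow(mol$atoms)
  ndb <- ntr <- deg <- integer(n)
  nbrs <- vector("list", n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    if (b$order[k] == 2) {
      ndb[i] <- ndb[i] + 1L; ndb[j] <- ndb[j] + 1L
    } else if (b$order[k] == 3) {
      ntr[i] <- ntr[i] + 1L; ntr[j] <- ntr[j] + 1L
    }
  }
  # in-ring double-bond lookup for aromatic-sulfur detection
  has_db_between <- function(i, j) {
    any((b$i == i & b$j == j & b$order == 2) |
        (b$i == j & b$j == i & b$order == 2))
  }
  vapply(seq_len(n), function(i) {
    e <- el[i]
    if (e %in% c("H", "F", "Cl", "Br")) return(e)
    hyb <- if (ntr[i] > 0 || ndb[i] >= 2) "sp"
           else if (ndb[i] == 1) "sp2"
           else "sp3"
    if (e == "S") {
      # pi-bonded low-valent S (thiocarbonyl) is sp2; divalent ring S is
      # sp2 only in the aromatic (thiophene/thiazole) pattern, i.e. a ring
      # of <= 6 atoms in which both ring neighbours of S carry an in-ring
      # double bond; hypervalent sulfonyl/sulfoxide S stays sp3
      shyb <- if (ndb[i] >= 1 && deg[i] <= 2) "sp2"
              else if (deg[i] == 2 && ndb[i] == 0 &&
                       in_aromatic_s_ring(i, nbrs, has_db_between)) "sp2"
              else "sp3"
      return(paste("S", shyb, sep = "."))
    }
    if (hyb == "sp3" && e %in% c("N", "O")) {
      conj <- any(vapply(nbrs[[i]], function(j)
        deg[j] <= 3 && (ndb[j] > 0 || ntr[j] > 0), TRUE))
      if (conj) hyb <- "sp2"
    }
    paste(e, hyb, sep = ".")
  }, "")
}

# Is divalent sulfur atom s part of a ring (size <= 6) whose two
# s-adjacent ring atoms both have an in-ring double bond?  Depth-limited
# path search between the two neighbours of s avoiding s itself.
in_aromatic_s_ring <- function(s, nbrs, has_db_between) {
  nb <- nbrs[[s]]
  if (length(nb) != 2) return(FALSE)
  a <- nb[1]; z <- nb[2]
  # find simple paths a ... z of length <= 4 edges not through s
  found <- FALSE
  walk <- function(v, path) {
    if (found) return()
    if (v == z && length(path) >= 2) {
      ring <- c(s, path)
      k <- length(ring)
      # ring neighbours of s are path[1] (=a-side) and v(=z)
      da <- has_db_between(ring[2], ring[3])
      dz <- has_db_between(ring[k], ring[k - 1])
      if (da && dz) found <<- TRUE
      return()
    }
    if (length(path) >= 5) return()
    for (w in nbrs[[v]])
      if (w != s && !(w %in% path)) walk(w, c(path, w))
  }
  walk(a, a)
  found
}

#' Gasteiger (PEOE) partial atomic charges
#'
#' Computes partial charges on a hydrogen-explicit molecule by iterative
#' partial equalization of orbital electronegativity with damping factor
#' `(1/2)^k` at iteration `k`.  Formal charges seed the iteration, so the
#' total charge is conserved exactly.
#'
#' @param mol a `qsar_molecule` with explicit hydrogens (e.g. from
#'   [embed_3d()]); coordinates are not required.
#' @param n_iterations number of damped equalization sweeps.
#' @return the molecule with `partial_charge` filled in; the charge set
#'   metadata is stored in attribute-like fields `charge_method` and
#'   `charge_iterations`.
#' @export
#' @examples
#' mol <- gasteiger_charges(embed_3d(parse_structure("CCO")))
#' sum(mol$atoms$partial_charge)  # ~0
gasteiger_charges <- function(mol, n_iterations = 8) {
  if (any(mol$atoms$n_implicit_h > 0))
    stop("gasteiger_charges needs explicit hydrogens; embed or add H first")
  key <- peoe_key(mol)
  unknown <- !key %in% names(PEOE_PARAMS)
  if (any(unknown))
    stop("no PEOE parameters for: ",
         paste(unique(key[unknown]), collapse = ", "))
  abc <- do.call(rbind, PEOE_PARAMS[key])
  chi_plus <- rowSums(abc)
  chi_plus[key == "H"] <- 20.02
  q <- seed_charges(mol)
  bi <- mol$bonds$i; bj <- mol$bonds$j
  for (k in seq_len(n_iterations)) {
    damp <- 0.5^k
    chi <- abc[, 1] + abc[, 2] * q + abc[, 3] * q^2
    lo <- ifelse(chi[bi] < chi[bj], bi, bj)
    hi <- ifelse(chi[bi] < chi[bj], bj, bi)
    d <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
    dq <- numeric(length(q))
    for (e in seq_along(d)) {
      dq[lo[e]] <- dq[lo[e]] + d[e]
      dq[hi[e]] <- dq[hi[e]] - d[e]
    }
    q <- q + dq
  }
  mol$atoms$partial_charge <- q
  mol$charge_method <- "gasteiger"
  mol$charge_iterations <- n_iterations
  mol
}

# Initial charges for the PEOE iteration: formal charges, with the charge
# of a resonance-delocalized terminal atom (carboxylate, nitro, ...)
# shared equally among the same-element terminal atoms bound to the same
# pi-bearing central atom of degree <= 3.  Hypervalent centres (sulfonate
# S) do not delocalize.
seed_charges <- function(mol) {
  q <- as.numeric(mol$atoms$formal_charge)
  el <- mol$atoms$element
  n <- length(q)
  b <- mol$bonds
  deg_h <- ndb <- integer(n)   # heavy degree / multiple-bond count
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]
    if (el[i] != "H" && el[j] != "H") {
      deg_h[i] <- deg_h[i] + 1L; deg_h[j] <- deg_h[j] + 1L
      nbrs[[i]] <- c(nbrs[[i]], j); nbrs[[j]] <- c(nbrs[[j]], i)
    }
    if (b$order[k] >= 2) { ndb[i] <- ndb[i] + 1L; ndb[j] <- ndb[j] + 1L }
  }
  done <- logical(n)
  for (a in which(q != 0 & el != "H")) {
    if (done[a] || deg_h[a] != 1) next
    m <- nbrs[[a]][1]
    if (deg_h[m] > 3 || ndb[m] == 0) next
    grp <- nbrs[[m]][el[nbrs[[m]]] == el[a] & deg_h[nbrs[[m]]] == 1]
    if (length(grp) > 1) {
      q[grp] <- sum(q[grp]) / length(grp)
      done[grp] <- TRUE
    }
  }
  q
}
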