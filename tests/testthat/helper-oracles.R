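# Shared helpers: hand-built molecules, independent brute-force oracles,
# and a per-session cache for the expensive fixture computations.

# build a plain all-carbon molecule from an edge list (oracle substrate)
graph_mol <- function(edges, n = max(edges), elements = rep("C", n),
                      id = "g") {
  new_molecule(id,
               data.frame(element = elements, formal_charge = 0L,
                          n_implicit_h = 0L),
               data.frame(i = edges[, 1], j = edges[, 2],
                          order = 1L))
}

# random connected graph on n vertices: spanning tree + extra edges
random_graph_mol <- function(n, extra = 2) {
  edges <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), 0L))
  all_pairs <- t(utils::combn(n, 2))
  have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cand <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% have, ,
                    drop = FALSE]
  if (extra > 0 && nrow(cand))
    edges <- rbind(edges, cand[sample(nrow(cand), min(extra, nrow(cand))), ,
                               drop = FALSE])
  graph_mol(edges, n)
}

# Brute-force Kier-Hall chi: enumerate every subset of `order` edges of
# the heavy-atom graph, keep the connected ones of the requested class,
# and sum (prod degree)^(-1/2) over the atoms each touches.
brute_chi <- function(mol, order, kind = "path") {
  g <- coumarinQSAR:::heavy_graph(mol)
  deg <- g$deg
  E <- g$edges
  if (order == 0) return(sum(1 / sqrt(deg)))
  if (is.null(E) || nrow(E) < order) return(0)
  total <- 0
  for (rows in utils::combn(nrow(E), order, simplify = FALSE)) {
    sub <- E[rows, , drop = FALSE]
    verts <- unique(as.vector(sub))
    # connectivity of the edge-induced subgraph
    reach <- verts[1]
    repeat {
      nxt <- unique(c(reach, sub[sub[, 1] %in% reach, 2],
                      sub[sub[, 2] %in% reach, 1]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    if (length(reach) != length(verts)) next
    subdeg <- table(factor(as.vector(sub), levels = verts))
    # a k-edge path has k+1 distinct vertices (max sub-degree <= 2); a
    # k-edge cycle has k vertices and is its own subgraph class
    class <- if (max(subdeg) <= 2 && length(verts) == order + 1) "path"
             else if (order == 3 && max(subdeg) == 3 &&
                      length(verts) == 4) "cluster"
             else "other"
    if (class != kind) next
    total <- total + 1 / sqrt(prod(deg[verts]))
  }
  total
}

# Leave-one-out PRESS by literally refitting n times (oracle for the
# leverage-based computation in fit_mlr)
refit_press <- function(X, y) {
  X <- as.matrix(X)
  sum(vapply(seq_along(y), function(i) {
    d <- data.frame(.y = y[-i], X[-i, , drop = FALSE], check.names = FALSE)
    fit <- lm(.y ~ ., data = d)
    nd <- as.data.frame(X)[i, , drop = FALSE]
    (y[i] - predict(fit, newdata = nd))^2
  }, 0))
}

# session cache for fixtures and their descriptor table
.cache <- new.env(parent = emptyenv())
cached_fixtures <- function() {
  if (is.null(.cache$fx)) .cache$fx <- load_fixtures(parse = TRUE)
  .cache$fx
}
cached_embedded <- function() {
  if (is.null(.cache$embedded))
    .cache$embedded <- coumarinQSAR:::embed_batch(
      lapply(cached_fixtures(), `[[`, "molecule"), seed = 1L)
  .cache$embedded
}
cached_descriptors <- function() {
  if (is.null(.cache$desc))
    .cache$desc <- descriptor_table(lapply(cached_fixtures(), `[[`,
                                           "molecule"), seed = 1L)
  .cache$desc
}

expected_formulas <- c(
  "4a" = "C15H12N2O6S2", "4b" = "C20H15N3O6S2", "6" = "C17H13NO5S",
  "8a" = "C23H19N3O4S", "8b" = "C23H17N5O8S", "8c" = "C23H16Cl3N3O4S",
  "8d" = "C24H21N3O6S2", "9" = "C18H16N4O4S2", "11a" = "C21H18N4O4S2",
  "11b" = "C24H22N4O6S2", "11c" = "C27H21ClN6O4S2", "11d" = "C28H24N6O4S2",
  "13a" = "C26H20N4O4S2", "13b" = "C29H20N4O6S2", "15a" = "C20H16N4O5S2",
  "15b" = "C21H18N4O5S2", "15c" = "C22H18N4O7S2")

# random proper rotation matrix
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
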