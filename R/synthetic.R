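# Seeded generators emulating the statistical structure of the study:
# small descriptor matrices (tens of samples by tens-to-hundreds of
# correlated columns), activities from sparse linear models with Gaussian
# noise at the scale of the published mean squared residuals (~0.017),
# and random coumarin-sulfonamide-like molecules for end-to-end pipeline
# tests.

#' Simulation specification
#'
#' Defaults mirror the study conditions: 17 samples (the compound count),
#' a 50-descriptor pool, 3 informative terms, and a noise standard
#' deviation of 0.13 pIC50 units, which gives residual mean squares near
#' the published least-squared errors (about 0.017).
#'
#' @param n_samples number of compounds.
#' @param n_descriptors pool size.
#' @param informative named list/vector: `beta` coefficients and `index`
#'   descriptor indices, plus `intercept`.
#' @param noise_sd Gaussian noise standard deviation on the activity.
#' @param rho common pairwise correlation between descriptor columns.
#' @param rng_seed integer seed.
#' @return list of class `sim_spec`.
#' @export
sim_spec <- function(n_samples = 17, n_descriptors = 50,
                     informative = NULL,
                     noise_sd = 0.13, rho = 0, rng_seed = 1L) {
  if (is.null(informative)) {
    # three informative terms spread across the pool
    idx <- unique(pmax(1, round(n_descriptors * c(0.1, 0.5, 0.9))))
    informative <- list(index = idx,
                        beta = c(1.0, -0.8, 0.6)[seq_along(idx)],
                        intercept = -1.6)
  }
  stopifnot(n_samples >= 3, n_descriptors >= 1,
            length(informative$index) == length(informative$beta),
            all(informative$index >= 1),
            all(informative$index <= n_descriptors),
            noise_sd >= 0, abs(rho) < 1)
  structure(list(n_samples = n_samples, n_descriptors = n_descriptors,
                 informative = informative, noise_sd = noise_sd,
                 rho = rho, rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

with_seed <- function(seed, expr) {
  runif(1)
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic descriptor matrix
#'
#' Standard-normal columns with common pairwise correlation `rho`
#' (equicorrelated Gaussian construction: sqrt(rho) * shared factor +
#' sqrt(1-rho) * independent noise), deterministic in the seed.
#'
#' @param spec a [sim_spec()].
#' @return numeric matrix `n_samples x n_descriptors` with columns
#'   `D1..Dk`.
#' @export
gen_descriptor_matrix <- function(spec) {
  with_seed(spec$rng_seed, {
    n <- spec$n_samples; p <- spec$n_descriptors
    Z <- matrix(rnorm(n * p), n, p)
    if (spec$rho != 0) {
      shared <- rnorm(n)
      s <- sign(spec$rho) * sqrt(abs(spec$rho))
      Z <- s * shared + sqrt(1 - abs(spec$rho)) * Z
    }
    colnames(Z) <- paste0("D", seq_len(p))
    Z
  })
}

#' Generate activities from a sparse linear model
#'
#' `y = intercept + X[, index] %*% beta + N(0, noise_sd^2)`, seeded from
#' `spec$rng_seed + 1` so the noise is independent of the descriptor draw.
#'
#' @param X descriptor matrix matching `spec`.
#' @param spec a [sim_spec()].
#' @return numeric activity vector with attribute `truth` (the generating
#'   intercept, indices and betas).
#' @export
gen_activities <- function(X, spec) {
  stopifnot(nrow(X) == spec$n_samples, ncol(X) == spec$n_descriptors)
  inf <- spec$informative
  mu <- inf$intercept +
    as.matrix(X)[, inf$index, drop = FALSE] %*% inf$beta
  y <- with_seed(spec$rng_seed + 1L,
                 drop(mu) + rnorm(spec$n_samples, 0, spec$noise_sd))
  attr(y, "truth") <- inf
  y
}

# substituent fragments for the molecule generator; each is valid as a
# single branch attachment, ring digits start at 3 to avoid clashes with
# the open core rings
SYNTH_FRAGMENTS <- c("C", "CC", "CCC", "C(C)C", "Cl", "OC", "N", "NC",
                     "C=O", "C(=O)OC", "c3ccccc3", "c3ccc(Cl)cc3",
                     "c3ccncc3", "C(C)=O", "S(N)(=O)=O", "O", "C#N")
SYNTH_CORES <- c(
  "O=C1C=Cc2cc(ccc2O1)S(=O)(=O)N%s",        # coumarin-6-sulfonamide
  "O=C1C=Cc2cc(ccc2O1)S(=O)(=O)Nc1ccc(%s)cc1",
  "O=S(=O)(N%s)c1ccc2ccccc2c1",
  "O=C1C=Cc2cc(%s)ccc2O1")

#' Generate random small organic molecules
#'
#' Seeded grammar over coumarin-sulfonamide-like scaffolds with random
#' substituents; every emitted SMILES parses to a connected neutral
#' molecule of C/N/O/S/Cl plus hydrogens.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return character vector of `n` SMILES strings (names `gen1..genN`).
#' @export
gen_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  with_seed(seed, {
    out <- character(n)
    for (k in seq_len(n)) {
      core <- sample(SYNTH_CORES, 1)
      sub <- sample(SYNTH_FRAGMENTS, 1)
      out[k] <- sprintf(core, sub)
    }
    names(out) <- paste0("gen", seq_len(n))
    out
  })
}
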