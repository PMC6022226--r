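# End-to-end descriptor computation: parse -> embed -> charges -> align ->
# surface/shape/electronic descriptors, one row per molecule.

# fixed schema of the descriptor table / TSV
DESCRIPTOR_COLUMNS <- c(
  "CHI_0", "CHI_1", "CHI_2", "CHI_3_P", "CHI_3_C",
  "IAC_Total", "IAC_Mean",
  "Dipole_X", "Dipole_Y", "Dipole_Z", "Dipole_mag",
  paste0("Jurs_", c("PPSA_1", "PPSA_2", "PPSA_3",
                    "PNSA_1", "PNSA_2", "PNSA_3",
                    "FNSA_1", "FNSA_2", "FNSA_3",
                    "FPSA_1", "FPSA_2", "FPSA_3",
                    "WPSA_1", "WPSA_2", "WPSA_3",
                    "WNSA_1", "WNSA_2", "WNSA_3",
                    "RPCG", "RNCG", "RPCS", "RNCS",
                    "TASA", "TPSA", "RASA", "RPSA")),
  "Shadow_XY", "Shadow_YZ", "Shadow_XZ",
  "Shadow_Xlength", "Shadow_Ylength", "Shadow_Zlength",
  "Shadow_XYfrac", "Shadow_YZfrac", "Shadow_XZfrac",
  # supplementary pool columns (valence-corrected chi, CPSA differences)
  "CHI_V_0", "CHI_V_1", "CHI_V_2", "CHI_V_3_P", "CHI_V_3_C",
  "Jurs_DPSA_1", "Jurs_DPSA_2", "Jurs_DPSA_3")

#' Compute all molecular descriptors for one molecule
#'
#' Topological descriptors come from the heavy-atom graph; the molecule is
#' then embedded ([embed_3d()]), charged ([gasteiger_charges()]), aligned
#' ([inertial_align()]) and the surface, shadow, Jurs and dipole
#' descriptors are computed in the aligned frame.
#'
#' @param mol a `qsar_molecule` (coordinates not required).
#' @param seed embedding seed.
#' @param probe_radius,n_points [sasa()] settings.
#' @param grid_step [shadow_descriptors()] setting.
#' @param gasteiger_iterations [gasteiger_charges()] sweeps.
#' @return named numeric vector over the full descriptor schema.
#' @export
compute_descriptors <- function(mol, seed = 1L, probe_radius = 1.4,
                                n_points = 960, grid_step = 0.1,
                                gasteiger_iterations = 8) {
  topo <- topo_descriptors(mol)
  embedded <- if (has_coords(mol) && !any(mol$atoms$n_implicit_h > 0))
    mol else embed_3d(mol, seed)
  m3 <- inertial_align(gasteiger_charges(embedded, gasteiger_iterations))
  ar <- sasa(m3, probe_radius, n_points)
  out <- c(topo,
           dipole_descriptors(m3),
           jurs_descriptors(ar, m3),
           shadow_descriptors(m3, grid_step))
  out[DESCRIPTOR_COLUMNS]
}

#' Descriptor table for a set of molecules
#'
#' One row per molecule over the fixed descriptor schema.  A failure in
#' one molecule does not stop the run: its row is filled with `NA` and the
#' error message is collected in the `"errors"` attribute.
#'
#' @param mols list of `qsar_molecule` objects (or a single one).
#' @param seed embedding seed shared by all rows.
#' @param ... passed to [compute_descriptors()].
#' @return data frame, row names = molecule ids, with attribute `errors`
#'   (named character vector, zero length when everything succeeded).
#' @export
#' @examples
#' \donttest{
#' fx <- load_fixtures()
#' dt <- descriptor_table(lapply(fx, `[[`, "molecule")[1:2], seed = 1)
#' dt[, c("CHI_3_C", "IAC_Mean")]
#' }
descriptor_table <- function(mols, seed = 1L, ...) {
  if (inherits(mols, "qsar_molecule")) mols <- list(mols)
  errs <- character()
  # one backend call embeds everything that still needs coordinates
  need <- vapply(mols, function(m)
    !(has_coords(m) && !any(m$atoms$n_implicit_h > 0)), TRUE)
  if (any(need)) {
    emb <- tryCatch(embed_batch(mols[need], seed = seed),
                    error = function(e) NULL)
    if (!is.null(emb)) {
      errs <- attr(emb, "errors")
      ok <- !vapply(emb, is.null, TRUE)
      mols[which(need)[ok]] <- emb[ok]
    }
  }
  rows <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    na_row <- setNames(rep(NA_real_, length(DESCRIPTOR_COLUMNS)),
                       DESCRIPTOR_COLUMNS)
    rows[[k]] <- if (mols[[k]]$id %in% names(errs)) na_row
    else tryCatch(compute_descriptors(mols[[k]], seed = seed, ...),
                  error = function(e) {
                    errs[[mols[[k]]$id]] <<- conditionMessage(e)
                    na_row
                  })
  }
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- vapply(mols, `[[`, "", "id")
  attr(out, "errors") <- errs
  attr(out, "seed") <- seed
  out
}

#' Write / read a descriptor table as TSV
#'
#' @param table data frame from [descriptor_table()].
#' @param file path of the tab-separated file (first column `compound`).
#' @export
write_descriptor_table <- function(table, file) {
  out <- cbind(compound = rownames(table), table)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(file) {
  d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(d) <- d$compound
  d$compound <- NULL
  d
}

#' Descriptor table for the packaged compound series
#'
#' Convenience wrapper: descriptors for all 17 fixtures.
#'
#' @param seed embedding seed.
#' @param ... passed to [compute_descriptors()].
#' @return data frame as from [descriptor_table()].
#' @export
fixture_descriptors <- function(seed = 1L, ...) {
  fx <- load_fixtures(parse = TRUE)
  descriptor_table(lapply(fx, `[[`, "molecule"), seed = seed, ...)
}
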