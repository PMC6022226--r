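# The 17 synthesized coumarin-6-sulfonamides and their assay tables, shipped
# as plain-text fixtures.  SMILES were encoded from the systematic compound
# names and are validated (in the test suite) against the published
# hydrogen-inclusive molecular formulas.

extdata <- function(name) {
  f <- system.file("extdata", name, package = "coumarinQSAR")
  if (!nzchar(f)) {
    # during in-source development
    f <- file.path("inst", "extdata", name)
  }
  if (!file.exists(f)) stop("packaged file not found: ", name)
  f
}

FIXTURE_LABELS <- c("4a", "4b", "6", "8a", "8b", "8c", "8d", "9",
                    "11a", "11b", "11c", "11d", "13a", "13b",
                    "15a", "15b", "15c")

#' Load the packaged compound fixtures
#'
#' Returns the 17 synthesized coumarin-6-sulfonamide derivatives with their
#' SMILES structures and IC50 activities (micromolar) against the HepG2,
#' MCF7 and Caco-2 cell lines.  Activities reported as ">200" are carried
#' as censored observations (`ic50_um = NA`, `censored = TRUE`), never as
#' numbers.
#'
#' @param parse if `TRUE` (default) each SMILES is parsed into a
#'   `qsar_molecule`; set `FALSE` to get the raw records only.
#' @return a list of 17 fixtures; each has `label`, `smiles`, `ic50` (data
#'   frame with `cell_line`, `ic50_um`, `se`, `censored`) and, when
#'   `parse = TRUE`, `molecule`.
#' @export
#' @examples
#' fx <- load_fixtures(parse = FALSE)
#' length(fx)
#' fx[["13a"]]$ic50
load_fixtures <- function(parse = TRUE) {
  lines <- readLines(extdata("coumarin_compounds.smi"))
  lines <- lines[nzchar(trimws(lines))]
  smi <- do.call(rbind, strsplit(lines, "\t"))
  act <- activity_table()
  act <- act[act$compound != "doxorubicin", ]
  stopifnot(identical(sort(smi[, 2]), sort(FIXTURE_LABELS)))
  fx <- lapply(seq_len(nrow(smi)), function(k) {
    label <- smi[k, 2]
    rec <- list(label = label, smiles = smi[k, 1],
                ic50 = act[act$compound == label,
                           c("cell_line", "ic50_um", "se", "censored")])
    if (parse) rec$molecule <- parse_structure(rec$smiles, id = label)
    rec
  })
  names(fx) <- smi[, 2]
  fx[FIXTURE_LABELS]
}

#' Printed activity table (IC50, micromolar)
#'
#' The in-vitro anti-proliferative IC50 values of the compound series (and
#' the doxorubicin reference) against HepG2, MCF7 and Caco-2 cells, one row
#' per compound and cell line.  Entries above the assay ceiling are flagged
#' `censored` with `ic50_um = NA`.
#'
#' @return data frame with columns `compound`, `cell_line`, `ic50_um`,
#'   `se`, `censored`.
#' @export
activity_table <- function() {
  d <- read.csv(extdata("activities_table1.csv"), stringsAsFactors = FALSE)
  d$censored <- as.logical(d$censored)
  d
}

#' Printed training-set activity/prediction/residual table
#'
#' Experimental pIC50, model-predicted pIC50 and residual for the training
#' compounds of the HepG2 (13 rows) and Caco-2 (14 rows) regression models.
#'
#' @return data frame with columns `compound`, `cell_line`, `experimental`,
#'   `predicted`, `residual`.
#' @export
training_table <- function() {
  read.csv(extdata("qsar_table4.csv"), stringsAsFactors = FALSE)
}

#' Printed external-validation table
#'
#' Held-out compounds with experimental and predicted pIC50.  Note: the
#' Caco-2 row printed "13a" carries the experimental activity of compound
#' 11a (−1.0052 = −log10(10.12 µM)); the label is kept as printed and the
#' resolved identity is available from [training_split()].
#'
#' @return data frame with columns `compound`, `cell_line`, `experimental`,
#'   `predicted`, `residual`.
#' @export
external_table <- function() {
  read.csv(extdata("qsar_table5.csv"), stringsAsFactors = FALSE)
}

#' Printed selectivity table (normal WI-38 cells)
#' @return data frame of WI-38 and HepG2 IC50s with the selectivity index.
#' @export
selectivity_table <- function() {
  read.csv(extdata("selectivity_table2.csv"), stringsAsFactors = FALSE)
}

#' Printed apoptosis-marker table
#' @return data frame of caspase-3, Bax and Bcl-2 levels with fold-of-control.
#' @export
apoptosis_table <- function() {
  read.csv(extdata("apoptosis_table3.csv"), stringsAsFactors = FALSE)
}

#' Annexin V-FITC positive fractions
#' @return data frame with `condition` and `percent_positive`.
#' @export
annexin_table <- function() {
  read.csv(extdata("annexin_fractions.csv"), stringsAsFactors = FALSE)
}

#' Training/test membership of the two regression models
#'
#' The HepG2 model excludes compounds 6, 8d, 15a and 15c as statistical
#' outliers (13 training compounds).  The Caco-2 model excludes 6, 9 and
#' 11a (14 training compounds), following the populated rows of the printed
#' training table: the external-table row labelled "13a" carries 11a's
#' experimental activity, so the label is resolved to 11a.
#'
#' @param endpoint `"HepG2"` or `"Caco-2"`.
#' @return list with `endpoint`, `train` and `test` label vectors.
#' @export
training_split <- function(endpoint = c("HepG2", "Caco-2")) {
  endpoint <- match.arg(endpoint)
  test <- switch(endpoint,
                 "HepG2" = c("6", "8d", "15a", "15c"),
                 "Caco-2" = c("6", "9", "11a"))
  list(endpoint = endpoint,
       train = setdiff(FIXTURE_LABELS, test),
       test = test)
}
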