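# Structure input/output.  SMILES interpretation and 3D coordinate
# generation are delegated to Open Babel through ChemmineOB; the resulting
# connection tables are rehosted in the package's own molecule objects so
# that every descriptor engine works from one explicit data model.

ob_convert <- function(from, to, source, opts = character()) {
  tryCatch({
    if (length(opts))
      ChemmineOB::convertFormat(from, to, source = source,
                                options = data.frame(names = opts,
                                                     args = rep("", length(opts))))
    else
      ChemmineOB::convertFormat(from, to, source = source)
  }, error = function(e) "")
}

# Parse the first molecule of a V2000 SD block into a qsar_molecule.
# Formal charges are taken from M CHG lines (the modern convention Open
# Babel writes); hydrogens present as atoms are kept as atoms.
parse_molblock <- function(txt, id = "mol") {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("empty mol block")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) stop("mol block has no atoms")
  at <- lines[4 + seq_len(na)]
  atoms <- data.frame(
    element = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    formal_charge = 0L, n_implicit_h = 0L)
  bl <- lines[4 + na + seq_len(nb)]
  bonds <- data.frame(
    i = as.integer(substr(bl, 1, 3)),
    j = as.integer(substr(bl, 4, 6)),
    order = as.integer(substr(bl, 7, 9)))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- f[1]
    for (e in seq_len(k))
      atoms$formal_charge[f[2 * e]] <- f[2 * e + 1]
  }
  if (all(atoms$x == 0 & atoms$y == 0 & atoms$z == 0) && na > 1)
    atoms$x <- atoms$y <- atoms$z <- NA_real_
  new_molecule(id, atoms, bonds)
}

#' Parse a SMILES string into a molecule
#'
#' Interprets the SMILES through Open Babel, producing a hydrogen-suppressed
#' heavy-atom graph with per-atom implicit hydrogen counts and formal
#' charges.
#'
#' @param smiles a single SMILES string.
#' @param id compound label stored on the molecule.
#' @return a `qsar_molecule` without coordinates.
#' @export
#' @examples
#' mol <- parse_structure("CC(C)C", id = "isobutane")
#' molecular_formula(mol)
parse_structure <- function(smiles, id = "mol") {
  stopifnot(is.character(smiles), length(smiles) == 1)
  txt <- ob_convert("SMI", "SDF", smiles, "h")
  if (!nzchar(txt) || !grepl("V2000", txt))
    stop(structure(class = c("qsar_parse_error", "error", "condition"),
                   list(message = paste0("SMILES parse failure for '", id,
                                         "': not interpretable at or before end of input: ",
                                         smiles),
                        call = sys.call(-1))))
  full <- parse_molblock(txt, id)
  # collapse explicit hydrogens back to implicit counts on the heavy graph
  hy <- which(full$atoms$element == "H")
  if (length(hy) == nrow(full$atoms)) {
    full$smiles <- smiles
    return(full)  # H2 etc.
  }
  nh <- integer(nrow(full$atoms))
  b <- full$bonds
  for (k in seq_len(nrow(b))) {
    if (b$i[k] %in% hy) nh[b$j[k]] <- nh[b$j[k]] + 1L
    if (b$j[k] %in% hy) nh[b$i[k]] <- nh[b$i[k]] + 1L
  }
  heavy <- setdiff(seq_len(nrow(full$atoms)), hy)
  remap <- integer(nrow(full$atoms)); remap[heavy] <- seq_along(heavy)
  atoms <- full$atoms[heavy, c("element", "formal_charge"), drop = FALSE]
  atoms$n_implicit_h <- nh[heavy]
  keep <- !(b$i %in% hy) & !(b$j %in% hy)
  bonds <- data.frame(i = remap[b$i[keep]], j = remap[b$j[keep]],
                      order = b$order[keep])
  out <- new_molecule(id, atoms, bonds)
  out$smiles <- smiles
  out
}

embed_backend_script <- function() {
  f <- system.file("python", "embed3d.py", package = "coumarinQSAR")
  if (!nzchar(f)) f <- file.path("inst", "python", "embed3d.py")
  if (!file.exists(f)) stop("embedding backend script not found")
  f
}

# Batched deterministic embedding: one python/RDKit process embeds all
# molecules (ETKDG with the given random seed, then MMFF94/UFF
# relaxation).  Returns a named list of qsar_molecule objects; failures
# come back as NULL entries with the message in attr(, "errors").
embed_batch <- function(mols, seed = 1L) {
  if (inherits(mols, "qsar_molecule")) mols <- list(mols)
  ids <- vapply(mols, `[[`, "", "id")
  smis <- vapply(mols, function(m)
    if (!is.null(m$smiles)) m$smiles else molecule_to_smiles(m), "")
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste(smis, ids, sep = "\t"), fin)
  status <- suppressWarnings(
    system2("python", c(shQuote(embed_backend_script()), shQuote(fin),
                        shQuote(fout), as.integer(seed)),
            stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(fout))
    stop("embedding backend failed (python/rdkit unavailable?)")
  blocks <- strsplit(paste(readLines(fout), collapse = "\n"),
                     "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(mols))
    stop("embedding backend returned ", length(blocks), " records for ",
         length(mols), " molecules")
  errs <- character()
  out <- lapply(seq_along(mols), function(k) {
    if (startsWith(blocks[k], "__FAILED__")) {
      errs[[ids[k]]] <<- paste0("3D embedding failed for '", ids[k], "'")
      return(NULL)
    }
    m <- parse_molblock(paste0(blocks[k], "\n"), ids[k])
    if (!has_coords(m)) {
      errs[[ids[k]]] <<- paste0("no coordinates for '", ids[k], "'")
      return(NULL)
    }
    m$smiles <- smis[k]
    m$embed_seed <- as.integer(seed)
    m
  })
  names(out) <- ids
  attr(out, "errors") <- errs
  out
}

#' Generate one 3D conformer
#'
#' Embeds the molecule (hydrogens made explicit) into a single low-energy
#' conformer: deterministic seeded distance-geometry embedding (ETKDG,
#' through the system python's RDKit) followed by MMFF94 (or UFF)
#' force-field relaxation.  The generator is an exact function of the
#' structure and the seed, so identical input always yields
#' bitwise-identical coordinates.
#'
#' @param mol a `qsar_molecule` (coordinates, if any, are discarded).
#' @param seed integer random seed of the conformer generator.
#' @return a `qsar_molecule` with explicit hydrogens and 3D coordinates.
#' @export
embed_3d <- function(mol, seed = 1L) {
  out <- embed_batch(list(mol), seed = seed)
  if (is.null(out[[1]]))
    stop(attr(out, "errors")[[mol$id]])
  out[[1]]
}

#' Make all hydrogens explicit
#'
#' Expands implicit hydrogen counts into explicit H atoms (no coordinates),
#' e.g. for charge assignment on molecules that do not need a conformer.
#'
#' @param mol a `qsar_molecule`.
#' @return a `qsar_molecule` with explicit hydrogens.
#' @export
add_hydrogens <- function(mol) {
  smi <- if (!is.null(mol$smiles)) mol$smiles else molecule_to_smiles(mol)
  txt <- ob_convert("SMI", "SDF", smi, "h")
  if (!nzchar(txt) || !grepl("V2000", txt))
    stop("hydrogen expansion failed for '", mol$id, "'")
  out <- parse_molblock(txt, mol$id)
  out$smiles <- smi
  out
}

# Serialise a molecule back to SMILES (via its mol block) for re-entry into
# Open Babel tools.
molecule_to_smiles <- function(mol) {
  txt <- write_molblock(mol)
  smi <- ob_convert("SDF", "SMI", txt)
  smi <- strsplit(trimws(smi), "[\t ]")[[1]][1]
  if (!nzchar(smi)) stop("could not serialise molecule '", mol$id, "'")
  smi
}

# Minimal V2000 writer for qsar_molecule objects.
write_molblock <- function(mol) {
  a <- mol$atoms
  xyz <- if (has_coords(mol)) as.matrix(a[, c("x", "y", "z")]) else
    matrix(0, nrow(a), 3)
  hdr <- c(mol$id, "  coumarinQSAR", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(mol$bonds)))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                xyz[, 1], xyz[, 2], xyz[, 3], a$element)
  bd <- if (nrow(mol$bonds))
    sprintf("%3d%3d%3d  0  0  0  0",
            mol$bonds$i, mol$bonds$j, mol$bonds$order) else character()
  chg <- which(a$formal_charge != 0)
  chgl <- if (length(chg)) {
    grp <- split(chg, ceiling(seq_along(chg) / 8))
    vapply(grp, function(g)
      paste0(sprintf("M  CHG%3d", length(g)),
             paste0(sprintf("%4d%4d", g, a$formal_charge[g]), collapse = "")),
      "")
  } else character()
  paste(c(hdr, at, bd, chgl, "M  END", "$$$$", ""), collapse = "\n")
}

#' Write molecules to an SD file
#'
#' @param mols a `qsar_molecule` or list of them.
#' @param file output path.
#' @export
write_sdf <- function(mols, file) {
  if (inherits(mols, "qsar_molecule")) mols <- list(mols)
  writeLines(paste0(vapply(mols, write_molblock, ""), collapse = ""),
             con = file, sep = "")
  invisible(file)
}

#' Read molecules from an SD file
#'
#' Hydrogens stored as explicit atoms are kept explicit; implicit hydrogen
#' counts for hydrogen-suppressed records are reconstructed from standard
#' valences (C 4, N 3, O 2, S 2, halogens 1, adjusted by formal charge).
#'
#' @param file SD file path.
#' @return list of `qsar_molecule` objects.
#' @export
read_sdf <- function(file) {
  txt <- paste(readLines(file), collapse = "\n")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  lapply(seq_along(blocks), function(k) {
    id <- trimws(strsplit(blocks[k], "\n")[[1]][1])
    if (!nzchar(id)) id <- paste0("mol", k)
    mol <- parse_molblock(paste0(blocks[k], "\n"), id)
    if (!any(mol$atoms$element == "H"))
      mol$atoms$n_implicit_h <- implicit_h_by_valence(mol)
    mol
  })
}

implicit_h_by_valence <- function(mol) {
  default <- c(C = 4, N = 3, O = 2, S = 2, Cl = 1, F = 1, Br = 1, P = 3,
               H = 1)
  bs <- numeric(nrow(mol$atoms))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    bs[b$i[k]] <- bs[b$i[k]] + b$order[k]
    bs[b$j[k]] <- bs[b$j[k]] + b$order[k]
  }
  # formal charge raises valence for cations (e.g. N+ -> 4) and lowers it
  # for anions (e.g. O- -> 1); hypervalent S (sulfonyl) saturates to 0
  v <- default[mol$atoms$element] + mol$atoms$formal_charge
  pmax(0L, as.integer(round(v - bs)))
}

#' Read a SMILES file
#'
#' One molecule per line: a SMILES string optionally followed by a
#' whitespace-separated identifier.
#'
#' @param file path to a `.smi` file.
#' @return list of `qsar_molecule` objects.
#' @export
read_smiles_file <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "[ \t]+")[[1]]
    parse_structure(f[1], id = if (length(f) > 1) f[2] else paste0("mol", k))
  })
}
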