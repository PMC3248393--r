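#' Read a protein structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL into a flat atom table.
#' Alternate locations are collapsed to a single conformer by keeping, within
#' each (residue, atom name) group, the record with the highest occupancy;
#' ties prefer the blank or 'A' altloc indicator.
#'
#' @param pdb Either a path to a PDB file or a character vector of PDB text
#'   (multi-line strings are split on newlines).
#' @param id Structure identifier carried into microenvironment names; when
#'   `pdb` is a file path the default is the file's base name without
#'   extension.
#' @return An object of class `pdb_structure`: a list with elements `id` and
#'   `atom`, a data frame with one row per atom and columns `elety` (atom
#'   name), `elesy` (element symbol), `resid` (residue name), `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `o` (occupancy), `b` (B-factor),
#'   `hetero` (logical) and `reskey` (unique residue key).
#' @examples
#' txt <- c(
#'   "ATOM      1  CA  LEU A   6       1.000   2.000   3.000  1.00  0.00           C",
#'   "END")
#' s <- read_pdb(txt, id = "toy")
#' s$atom$resid
#' @export
read_pdb <- function(pdb, id = NULL) {
  if (length(pdb) == 0L || all(!nzchar(pdb))) {
    stop("empty PDB input: no ATOM or HETATM records")
  }
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
    if (is.null(id)) id <- ""
    path <- NULL
  }
  .validate_pdb_records(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, rm.insert = FALSE,
                       verbose = FALSE)
  at <- p$atom
  if (nrow(at) == 0L) stop("empty PDB input: no ATOM or HETATM records")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$elesy[is.na(at$elesy)] <- .element_from_name(at$elety[is.na(at$elesy)])
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  at <- .collapse_altlocs(at)
  atom <- data.frame(
    elety = at$elety, elesy = toupper(at$elesy), resid = at$resid,
    chain = at$chain, resno = at$resno, insert = at$insert,
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b,
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE)
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z))) {
    stop("non-finite atom coordinates in PDB input")
  }
  atom$reskey <- residue_key(atom$chain, atom$resno, atom$insert, atom$resid)
  structure(list(id = id, atom = atom), class = "pdb_structure")
}

# Coordinate fields of ATOM/HETATM records must be numeric; reports the
# 1-based line number of the first offending record.
.validate_pdb_records <- function(lines) {
  rec <- substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")
  if (!any(rec)) stop("empty PDB input: no ATOM or HETATM records")
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d: too short", i))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinates", i))
    }
  }
  invisible(TRUE)
}

.element_from_name <- function(elety) {
  if (length(elety) == 0L) return(character(0))
  toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
}

# Keep one altloc per (residue, atom name): highest occupancy, ties resolved
# in favor of blank then 'A' then alphabetical.
.collapse_altlocs <- function(at) {
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  altrank <- match(at$alt, c("", "A"), nomatch = 3L)
  ord <- order(key, -at$o, altrank, at$alt)
  at <- at[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  at <- at[keep, , drop = FALSE]
  at[order(as.integer(rownames(at))), , drop = FALSE]
}

#' Canonical residue key
#'
#' @param chain,resno,insert,resid Components of the residue identity.
#' @return Character key `chain:resno:insert:resid`.
#' @keywords internal
#' @export
residue_key <- function(chain, resno, insert, resid) {
  paste(chain, resno, insert, resid, sep = ":")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure '%s': %d atoms, %d residues (%d hetero atoms)\n",
              x$id, nrow(x$atom), length(unique(x$atom$reskey)),
              sum(x$atom$hetero)))
  invisible(x)
}

# Hetero residue names never treated as ligands.
.WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")
.ION_CODES <- c("NA", "K", "CL", "MG", "CA", "ZN", "MN", "FE", "CU", "NI",
                "CO", "CD", "HG", "BR", "IOD", "F", "SO4", "PO4", "NO3")
.ADDITIVE_CODES <- c("GOL", "EDO", "PEG", "PG4", "MPD", "DMS", "ACT", "FMT",
                     "EOH", "MOH", "BME", "TRS", "EPE", "MES", "IMD")

#' Default het-code exclusion list for ligand selection
#'
#' Waters, common monoatomic/small ions and frequent crystallization
#' additives; the "specifically bound" ligand filter removes these buffer
#' components before pockets are defined.
#'
#' @return Character vector of 3-character het codes.
#' @export
default_ligand_exclusions <- function() {
  c(.WATER_CODES, .ION_CODES, .ADDITIVE_CODES)
}

#' Select bound small-molecule ligands from a structure
#'
#' One ligand instance is produced per hetero residue (chain + residue number
#' + insertion code + het code) whose het code is not excluded and whose
#' heavy-atom count exceeds `min_heavy_atoms`. Waters are always excluded.
#'
#' @param s A `pdb_structure`.
#' @param min_heavy_atoms Minimum number of non-hydrogen atoms a ligand must
#'   exceed (default 5).
#' @param exclusions Character vector of het codes never selected; defaults
#'   to [default_ligand_exclusions()].
#' @return List of `ligand_instance` objects, each a list with `het_code`,
#'   `reskey`, `atoms` (subset of `s$atom`) and `heavy_atom_count`.
#' @export
select_ligands <- function(s, min_heavy_atoms = 5,
                           exclusions = default_ligand_exclusions()) {
  stopifnot(inherits(s, "pdb_structure"))
  exclusions <- unique(toupper(c(exclusions, .WATER_CODES)))
  het <- s$atom[s$atom$hetero, , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  out <- list()
  for (key in unique(het$reskey)) {
    grp <- het[het$reskey == key, , drop = FALSE]
    code <- toupper(grp$resid[1])
    if (code %in% exclusions) next
    heavy <- sum(grp$elesy != "H" & grp$elesy != "D")
    if (heavy <= min_heavy_atoms) next
    out[[length(out) + 1L]] <- structure(
      list(het_code = code, reskey = key, atoms = grp,
           heavy_atom_count = heavy),
      class = "ligand_instance")
  }
  out
}

#' Extract the pocket around a bound ligand
#'
#' The pocket is the set of protein residues having at least one atom within
#' `cutoff` (closed bound, default 6 Angstrom) of any ligand atom; each pocket
#' residue contributes the functional-center microenvironments defined by
#' `centers_table`.
#'
#' @param s A `pdb_structure`.
#' @param lig A `ligand_instance` from [select_ligands()].
#' @param cutoff Contact distance in Angstrom (default 6.0).
#' @param centers_table Functional-center rules; defaults to
#'   [default_functional_centers()].
#' @return An object of class `pocket`: list with `structure_id`, `het_code`,
#'   `ligand_reskey`, `residues` (character residue keys) and `centers`, a
#'   data frame (chain, resno, insert, resid, tag, name, x, y, z).
#' @export
extract_pocket <- function(s, lig, cutoff = 6.0,
                           centers_table = default_functional_centers()) {
  stopifnot(inherits(s, "pdb_structure"), inherits(lig, "ligand_instance"))
  if (nrow(lig$atoms) == 0L) stop("ligand has no atoms")
  prot <- s$atom[!s$atom$hetero, , drop = FALSE]
  if (nrow(prot) == 0L) {
    return(.new_pocket(s, lig, character(0), .empty_centers(), cutoff))
  }
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig$atoms[, c("x", "y", "z")])
  # min distance of each protein atom to any ligand atom
  d2min <- rep(Inf, nrow(pm))
  for (j in seq_len(nrow(lm))) {
    d2 <- (pm[, 1] - lm[j, 1])^2 + (pm[, 2] - lm[j, 2])^2 +
      (pm[, 3] - lm[j, 3])^2
    d2min <- pmin(d2min, d2)
  }
  contact <- d2min <= cutoff^2
  residues <- unique(prot$reskey[contact])
  cen <- .pocket_centers(prot, residues, centers_table, s$id)
  .new_pocket(s, lig, residues, cen, cutoff)
}

.empty_centers <- function() {
  data.frame(chain = character(0), resno = integer(0), insert = character(0),
             resid = character(0), tag = character(0), name = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             stringsAsFactors = FALSE)
}

.new_pocket <- function(s, lig, residues, centers, cutoff) {
  structure(list(structure_id = s$id, het_code = lig$het_code,
                 ligand_reskey = lig$reskey, residues = residues,
                 centers = centers, cutoff = cutoff),
            class = "pocket")
}

.pocket_centers <- function(prot, residues, centers_table, structure_id) {
  rows <- list()
  for (key in residues) {
    res <- prot[prot$reskey == key, , drop = FALSE]
    fc <- functional_center(res, centers_table)
    if (length(fc) == 0L) next
    for (entry in fc) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = res$chain[1], resno = res$resno[1], insert = res$insert[1],
        resid = res$resid[1], tag = entry$tag,
        name = name_microenvironment(res$resno[1], entry$tag, structure_id,
                                     insert = res$insert[1]),
        x = entry$point[1], y = entry$point[2], z = entry$point[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(.empty_centers())
  do.call(rbind, rows)
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("pocket %s/%s: %d residues, %d microenvironment centers (%.1f A rule)\n",
              x$structure_id, x$het_code, length(x$residues),
              nrow(x$centers), x$cutoff))
  invisible(x)
}

#' Compute functional-center points for one residue
#'
#' Each residue type maps to one microenvironment center (two for tryptophan
#' and tyrosine: a polar W1/Y1 and an aromatic W2/Y2 center). The center is
#' the centroid of the rule's atom set; atoms missing from the model are
#' skipped, and a center whose atoms are all missing raises an error.
#'
#' @param residue_atoms Data frame of one residue's atoms (as in
#'   `pdb_structure$atom`).
#' @param table Functional-center table from
#'   [default_functional_centers()] or [read_functional_centers()].
#' @return List of entries `list(tag =, point = c(x, y, z))`; unknown residue
#'   names yield an empty list with a warning.
#' @export
functional_center <- function(residue_atoms, table = default_functional_centers()) {
  resname <- toupper(residue_atoms$resid[1])
  rules <- table[table$resid == resname, , drop = FALSE]
  if (nrow(rules) == 0L) {
    warning(sprintf("no functional-center rule for residue '%s'; skipped", resname))
    return(list())
  }
  out <- list()
  for (i in seq_len(nrow(rules))) {
    wanted <- strsplit(rules$atoms[i], ",", fixed = TRUE)[[1]]
    hit <- residue_atoms[residue_atoms$elety %in% wanted, , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop(sprintf("all atoms (%s) of center %s missing from residue %s %s%s",
                   rules$atoms[i], rules$tag[i], resname,
                   residue_atoms$chain[1], residue_atoms$resno[1]))
    }
    out[[length(out) + 1L]] <- list(
      tag = rules$tag[i],
      point = c(mean(hit$x), mean(hit$y), mean(hit$z)))
  }
  out
}

#' Default functional-center table (22 microenvironment types)
#'
#' Twenty residue types map to 22 center types: tryptophan and tyrosine each
#' contribute a polar center (W1: indole nitrogen; Y1: hydroxyl oxygen) and
#' an aromatic center (W2/Y2: six-membered-ring centroid). Charged residues
#' use the charged-group centroid, polar amides the amide group, nonpolar
#' residues the side-chain centroid and glycine its alpha carbon.
#'
#' @return Data frame with columns `resid` (3-letter residue name), `tag`
#'   (one of the 22 type tags) and `atoms` (comma-separated atom names whose
#'   centroid is the center).
#' @export
default_functional_centers <- function() {
  tab <- rbind(
    c("ALA", "A",  "CB"),
    c("CYS", "C",  "SG"),
    c("ASP", "D",  "CG,OD1,OD2"),
    c("GLU", "E",  "CD,OE1,OE2"),
    c("PHE", "F",  "CG,CD1,CD2,CE1,CE2,CZ"),
    c("GLY", "G",  "CA"),
    c("HIS", "H",  "CG,ND1,CD2,CE1,NE2"),
    c("ILE", "I",  "CB,CG1,CG2,CD1"),
    c("LYS", "K",  "NZ"),
    c("LEU", "L",  "CB,CG,CD1,CD2"),
    c("MET", "M",  "CG,SD,CE"),
    c("ASN", "N",  "CG,OD1,ND2"),
    c("PRO", "P",  "CB,CG,CD"),
    c("GLN", "Q",  "CD,OE1,NE2"),
    c("ARG", "R",  "NE,CZ,NH1,NH2"),
    c("SER", "S",  "OG"),
    c("THR", "T",  "OG1"),
    c("VAL", "V",  "CB,CG1,CG2"),
    c("TRP", "W1", "NE1"),
    c("TRP", "W2", "CD2,CE2,CE3,CZ2,CZ3,CH2"),
    c("TYR", "Y1", "OH"),
    c("TYR", "Y2", "CG,CD1,CD2,CE1,CE2,CZ"))
  data.frame(resid = tab[, 1], tag = tab[, 2], atoms = tab[, 3],
             stringsAsFactors = FALSE)
}

#' The 22 microenvironment type tags
#' @return Character vector of the 22 tags.
#' @export
microenvironment_types <- function() {
  sort(unique(default_functional_centers()$tag))
}

#' Read / write a functional-center table (TSV)
#'
#' Format: three tab-separated columns `resid`, `tag`, `atoms`
#' (comma-separated atom names).
#'
#' @param path File path.
#' @param table Table as returned by [default_functional_centers()].
#' @return `read_functional_centers` returns the table data frame;
#'   `write_functional_centers` returns `path` invisibly.
#' @export
read_functional_centers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("resid", "tag", "atoms") %in% names(tab)))
  tab
}

#' @rdname read_functional_centers
#' @export
write_functional_centers <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Name a microenvironment
#'
#' The convention is `"m"` followed by the residue index and the
#' microenvironment type tag, with `"/"` and the structure identifier
#' appended when one is given, e.g. `m6L/1nhp` for the microenvironment
#' centered on the leucine at position 6 of structure 1nhp.
#'
#' @param resno Author-assigned residue index.
#' @param tag Microenvironment type tag (one of the 22 types).
#' @param structure_id Optional structure identifier.
#' @param insert Optional insertion code appended to the index.
#' @return Character name.
#' @examples
#' name_microenvironment(6, "L", "1nhp")   # "m6L/1nhp"
#' name_microenvironment(338, "T")         # "m338T"
#' @export
name_microenvironment <- function(resno, tag, structure_id = NULL,
                                  insert = "") {
  if (is.null(insert) || is.na(insert)) insert <- ""
  nm <- paste0("m", resno, insert, tag)
  if (!is.null(structure_id) && nzchar(structure_id)) {
    nm <- paste0(nm, "/", structure_id)
  }
  nm
}

#' Write / read a pocket table (TSV)
#'
#' One row per microenvironment center: structure id, chain, residue index,
#' insertion code, residue name, type tag and center coordinates.
#'
#' @param pocket A `pocket` object.
#' @param path File path.
#' @return `write_pocket` returns `path` invisibly; `read_pocket` returns a
#'   `pocket` object (with `residues` reconstructed from the center rows).
#' @export
write_pocket <- function(pocket, path) {
  cen <- pocket$centers
  out <- data.frame(structure_id = rep(pocket$structure_id, nrow(cen)),
                    het_code = rep(pocket$het_code, nrow(cen)),
                    cen, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pocket
#' @export
read_pocket <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(insert = "character"))
  tab$insert[is.na(tab$insert)] <- ""
  cen <- tab[, c("chain", "resno", "insert", "resid", "tag", "name",
                 "x", "y", "z")]
  structure(list(
    structure_id = if (nrow(tab)) tab$structure_id[1] else "",
    het_code = if (nrow(tab)) tab$het_code[1] else "",
    ligand_reskey = NA_character_,
    residues = unique(residue_key(cen$chain, cen$resno, cen$insert, cen$resid)),
    centers = cen, cutoff = NA_real_), class = "pocket")
}
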