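#' Default microenvironment property schema
#'
#' The microenvironment vector accumulates 80 physicochemical properties in
#' each of six concentric shells of width 1.25 Angstrom (total radius 7.5
#' Angstrom), giving a 480-element vector. The default property catalogue
#' covers element counts, per-residue-type and residue-class counts, atom
#' roles (backbone/side chain, hydrogen-bond donors/acceptors, ring and
#' formally charged atoms), common side-chain atom names, summed atomic
#' descriptors (mass, van der Waals volume, electronegativity, crude partial
#' charge, residue hydrophobicity), B-factor and occupancy statistics, and
#' secondary-structure class counts (zero unless a per-residue annotation is
#' supplied). The schema is a contract of vector geometry, not a fixed
#' chemistry: it can be replaced wholesale with [read_schema()] as long as
#' backgrounds and vectors are built with the same schema.
#'
#' @param n_shells Number of concentric shells (default 6).
#' @param total_radius Outer radius of the microenvironment in Angstrom
#'   (default 7.5).
#' @return Object of class `property_schema`: list with `properties` (data
#'   frame name/kind/rule/param), `n_shells`, `total_radius`, `shell_width`.
#' @export
default_schema <- function(n_shells = 6, total_radius = 7.5) {
  p <- function(name, kind, rule, param = "") {
    data.frame(name = name, kind = kind, rule = rule, param = param,
               stringsAsFactors = FALSE)
  }
  aa1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
           "Q", "R", "S", "T", "V", "W", "Y")
  props <- rbind(
    p(paste0("elem_", c("C", "N", "O", "S", "P")), "count", "element",
      c("C", "N", "O", "S", "P")),
    p("elem_other", "count", "element_other"),
    p(paste0("res_", aa1), "count", "residue", aa1),
    p(paste0("class_", c("positive", "negative", "polar", "nonpolar",
                         "aromatic")), "count", "res_class",
      c("positive", "negative", "polar", "nonpolar", "aromatic")),
    p(paste0("bb_", c("N", "CA", "C", "O")), "count", "backbone",
      c("N", "CA", "C", "O")),
    p("sidechain", "count", "sidechain"),
    p("hbond_donor", "count", "hbond_donor"),
    p("hbond_acceptor", "count", "hbond_acceptor"),
    p("ring_atom", "count", "ring_atom"),
    p("pos_charge_atom", "count", "pos_charge_atom"),
    p("neg_charge_atom", "count", "neg_charge_atom"),
    p("hydroxyl", "count", "hydroxyl"),
    p("amide_sidechain", "count", "amide_sidechain"),
    p("aliphatic_carbon", "count", "aliphatic_carbon"),
    p("aromatic_carbon", "count", "aromatic_carbon"),
    p("sidechain_N", "count", "sidechain_elem", "N"),
    p("sidechain_O", "count", "sidechain_elem", "O"),
    p(paste0("atom_", c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE",
                        "CE1", "CE2", "CZ", "OG", "OD1", "NZ")), "count",
      "atom_name", c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE",
                     "CE1", "CE2", "CZ", "OG", "OD1", "NZ")),
    p("atom_count", "count", "any_atom"),
    p("hetero_count", "count", "hetero_atom"),
    p("charge_sum", "sum", "partial_charge"),
    p("abs_charge_sum", "sum", "abs_partial_charge"),
    p("hydrophobicity_sum", "sum", "hydrophobicity"),
    p("bfactor_sum", "sum", "bfactor"),
    p("bfactor_sq_sum", "sum", "bfactor_sq"),
    p("occupancy_sum", "sum", "occupancy"),
    p("mass_sum", "sum", "mass"),
    p("vdw_volume_sum", "sum", "vdw_volume"),
    p("electronegativity_sum", "sum", "electronegativity"),
    p(paste0("ss_", c("helix", "sheet", "coil")), "count", "ss_class",
      c("H", "E", "C")),
    p("res_small", "count", "res_size", "small"),
    p("res_large", "count", "res_size", "large"),
    p("res_aliphatic", "count", "res_set", "A,V,L,I"),
    p("res_tiny", "count", "res_set", "G,A,S"),
    p("peptide_amide", "count", "backbone_amide"))
  stopifnot(nrow(props) == 80L, !anyDuplicated(props$name))
  new_schema(props, n_shells, total_radius)
}

#' Construct a property schema
#'
#' @param properties Data frame with columns `name`, `kind` (one of
#'   `count`, `sum`, `fraction`), `rule`, `param`.
#' @param n_shells,total_radius Shell geometry.
#' @return A `property_schema` object.
#' @export
new_schema <- function(properties, n_shells = 6, total_radius = 7.5) {
  stopifnot(is.data.frame(properties),
            all(c("name", "kind", "rule", "param") %in% names(properties)),
            all(properties$kind %in% c("count", "sum", "fraction")),
            n_shells >= 1, total_radius > 0)
  structure(list(properties = properties, n_shells = as.integer(n_shells),
                 total_radius = total_radius,
                 shell_width = total_radius / n_shells),
            class = "property_schema")
}

#' @export
print.property_schema <- function(x, ...) {
  cat(sprintf("property_schema: %d properties x %d shells (width %.4g A, radius %.4g A) = %d cells\n",
              nrow(x$properties), x$n_shells, x$shell_width, x$total_radius,
              nrow(x$properties) * x$n_shells))
  invisible(x)
}

#' Length and cell names of a schema's vectors
#' @param schema A `property_schema`.
#' @return `schema_length`: integer vector length. `schema_cell_names`:
#'   character vector `<property>@shell<k>` in shell-major order (all
#'   properties of shell 0, then shell 1, ...).
#' @export
schema_length <- function(schema) {
  nrow(schema$properties) * schema$n_shells
}

#' @rdname schema_length
#' @export
schema_cell_names <- function(schema) {
  as.vector(vapply(seq_len(schema$n_shells) - 1L, function(k) {
    paste0(schema$properties$name, "@shell", k)
  }, character(nrow(schema$properties))))
}

#' Read / write a property schema (TSV)
#' @param path File path.
#' @param schema A `property_schema`.
#' @export
read_schema <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, regexec("# *n_shells=([0-9]+) +total_radius=([0-9.]+)", hdr))[[1]]
  if (length(meta) == 3L) {
    tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                             colClasses = "character")
    new_schema(tab, as.integer(meta[2]), as.numeric(meta[3]))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    new_schema(tab)
  }
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_shells=%d total_radius=%g", schema$n_shells,
                     schema$total_radius), con)
  utils::write.table(schema$properties, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- per-atom chemistry tables ----------------------------------------------

.AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
             GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
             MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
             SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

.RES_CLASS <- c(R = "positive", H = "positive", K = "positive",
                D = "negative", E = "negative",
                S = "polar", T = "polar", Q = "polar", N = "polar",
                W = "polar", Y = "polar",
                A = "nonpolar", C = "nonpolar", G = "nonpolar",
                I = "nonpolar", L = "nonpolar", M = "nonpolar",
                P = "nonpolar", V = "nonpolar",
                F = "aromatic")

.KD_HYDRO <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
               H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
               P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
               W = -0.9, Y = -1.3)

.ELEM_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                H = 1.008)
.ELEM_VDW_VOL <- c(C = 20.58, N = 15.60, O = 14.71, S = 24.43, P = 24.43,
                   H = 7.24)
.ELEM_EN <- c(C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19, H = 2.20)

.RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

.DONOR_ATOMS <- list(
  `*` = "N",  # backbone amide nitrogen of every residue
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG")

.ACCEPTOR_ATOMS <- list(
  `*` = "O",  # backbone carbonyl oxygen
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

# crude formal charges spread over the charged group's terminal atoms
.CHARGE_ATOMS <- list(
  ARG = c(NE = 1 / 3, NH1 = 1 / 3, NH2 = 1 / 3),
  LYS = c(NZ = 1),
  HIS = c(ND1 = 0.05, NE2 = 0.05),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5))

.RES_SMALL <- c("G", "A", "S", "C", "T", "P", "D", "N", "V")
.RES_LARGE <- c("F", "W", "Y", "R", "K", "H", "E", "Q", "M", "I", "L")

# per-atom rule evaluation: returns numeric contribution of each atom row
.atom_rule_value <- function(atoms, rule, param, aa1, ss) {
  n <- nrow(atoms)
  switch(rule,
    element = as.numeric(atoms$elesy == param),
    element_other = as.numeric(!(atoms$elesy %in% c("C", "N", "O", "S", "P"))),
    residue = as.numeric(!is.na(aa1) & aa1 == param),
    res_class = as.numeric(!is.na(aa1) & .RES_CLASS[aa1] == param &
                             !is.na(.RES_CLASS[aa1])),
    backbone = as.numeric(!atoms$hetero & atoms$elety == param),
    sidechain = as.numeric(!atoms$hetero & !is.na(aa1) &
                             !(atoms$elety %in% c("N", "CA", "C", "O", "OXT"))),
    sidechain_elem = as.numeric(!atoms$hetero & !is.na(aa1) &
                                  atoms$elesy == param &
                                  !(atoms$elety %in% c("N", "CA", "C", "O", "OXT"))),
    hbond_donor = .named_atom_flag(atoms, .DONOR_ATOMS),
    hbond_acceptor = .named_atom_flag(atoms, .ACCEPTOR_ATOMS),
    ring_atom = .named_atom_flag(atoms, .RING_ATOMS),
    pos_charge_atom = .charge_flag(atoms, positive = TRUE),
    neg_charge_atom = .charge_flag(atoms, positive = FALSE),
    hydroxyl = as.numeric(atoms$elety %in% c("OG", "OG1", "OH")),
    amide_sidechain = as.numeric(
      (toupper(atoms$resid) == "ASN" & atoms$elety %in% c("OD1", "ND2")) |
      (toupper(atoms$resid) == "GLN" & atoms$elety %in% c("OE1", "NE2"))),
    aliphatic_carbon = as.numeric(atoms$elesy == "C" &
                                    .named_atom_flag(atoms, .RING_ATOMS) == 0),
    aromatic_carbon = as.numeric(atoms$elesy == "C" &
                                   .named_atom_flag(atoms, .RING_ATOMS) == 1),
    atom_name = as.numeric(atoms$elety == param),
    any_atom = rep(1, n),
    hetero_atom = as.numeric(atoms$hetero),
    partial_charge = .partial_charge(atoms),
    abs_partial_charge = abs(.partial_charge(atoms)),
    hydrophobicity = ifelse(is.na(aa1), 0, .KD_HYDRO[aa1]),
    bfactor = atoms$b,
    bfactor_sq = atoms$b^2,
    occupancy = atoms$o,
    mass = .elem_lookup(atoms$elesy, .ELEM_MASS, 12),
    vdw_volume = .elem_lookup(atoms$elesy, .ELEM_VDW_VOL, 18),
    electronegativity = .elem_lookup(atoms$elesy, .ELEM_EN, 2.5),
    ss_class = if (is.null(ss)) rep(0, n) else {
      key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = ":")
      as.numeric(!is.na(ss[key]) & ss[key] == param)
    },
    res_size = as.numeric(!is.na(aa1) & aa1 %in%
                            (if (param == "small") .RES_SMALL else .RES_LARGE)),
    res_set = as.numeric(!is.na(aa1) &
                           aa1 %in% strsplit(param, ",", fixed = TRUE)[[1]]),
    backbone_amide = as.numeric(!atoms$hetero & atoms$elety %in% c("N", "O")),
    stop(sprintf("unknown property rule '%s'", rule)))
}

.named_atom_flag <- function(atoms, table) {
  res <- toupper(atoms$resid)
  flag <- numeric(nrow(atoms))
  star <- table[["*"]]
  if (!is.null(star)) flag[!atoms$hetero & atoms$elety %in% star] <- 1
  for (rn in setdiff(names(table), "*")) {
    flag[res == rn & atoms$elety %in% table[[rn]]] <- 1
  }
  flag
}

.charge_flag <- function(atoms, positive) {
  res <- toupper(atoms$resid)
  flag <- numeric(nrow(atoms))
  for (rn in names(.CHARGE_ATOMS)) {
    q <- .CHARGE_ATOMS[[rn]]
    keep <- names(q)[if (positive) q > 0 else q < 0]
    flag[res == rn & atoms$elety %in% keep] <- 1
  }
  flag
}

.partial_charge <- function(atoms) {
  res <- toupper(atoms$resid)
  q <- numeric(nrow(atoms))
  for (rn in names(.CHARGE_ATOMS)) {
    tbl <- .CHARGE_ATOMS[[rn]]
    for (an in names(tbl)) q[res == rn & atoms$elety == an] <- tbl[[an]]
  }
  q
}

.elem_lookup <- function(elesy, table, default) {
  v <- table[elesy]
  v[is.na(v)] <- default
  unname(v)
}

# n_atoms x n_properties contribution matrix
.atom_property_matrix <- function(atoms, schema, ss = NULL) {
  pr <- schema$properties
  aa1 <- unname(.AA3TO1[toupper(atoms$resid)])
  m <- matrix(0, nrow(atoms), nrow(pr),
              dimnames = list(NULL, pr$name))
  for (j in seq_len(nrow(pr))) {
    m[, j] <- .atom_rule_value(atoms, pr$rule[j], pr$param[j], aa1, ss)
  }
  m
}

# ---- shell binning and featurization ----------------------------------------

#' Shell index of a distance
#'
#' Shells are half-open intervals `[k*w, (k+1)*w)` of width
#' `w = total_radius / n_shells`; a distance at or beyond the total radius
#' falls outside the microenvironment.
#'
#' @param distance Distance(s) from the functional center, in Angstrom.
#' @param schema A `property_schema`.
#' @return Integer shell index in `0 .. n_shells-1`, or `NA` for distances at
#'   or beyond the total radius.
#' @examples
#' s <- default_schema()
#' shell_index(0, s)     # 0
#' shell_index(1.25, s)  # 1
#' shell_index(7.5, s)   # NA (outside)
#' @export
shell_index <- function(distance, schema = default_schema()) {
  if (any(distance < 0)) stop("distance must be non-negative")
  k <- as.integer(floor(distance / schema$shell_width))
  k[distance >= schema$total_radius] <- NA_integer_
  k
}

#' Featurize one microenvironment
#'
#' Accumulates the schema's per-atom property contributions of every atom
#' within the total radius of `center` into (shell, property) cells. The
#' returned vector is shell-major: the 80 properties of shell 0, then shell
#' 1, and so on. Hetero atoms (the bound ligand, waters, ions) are excluded
#' by default so that the vector describes the protein environment only.
#'
#' @param s A `pdb_structure`.
#' @param center Numeric length-3 point (Angstrom).
#' @param schema A `property_schema`.
#' @param ss Optional named character vector of secondary-structure classes
#'   (`"H"`, `"E"`, `"C"`), named by `chain:resno:insert`.
#' @param include_hetero Include HETATM atoms in the accumulation
#'   (default `FALSE`).
#' @return Named numeric vector of length `schema_length(schema)`.
#' @export
featurize <- function(s, center, schema = default_schema(), ss = NULL,
                      include_hetero = FALSE) {
  stopifnot(inherits(s, "pdb_structure"), length(center) == 3,
            all(is.finite(center)))
  atoms <- s$atom
  if (!include_hetero) atoms <- atoms[!atoms$hetero, , drop = FALSE]
  v <- numeric(schema_length(schema))
  names(v) <- schema_cell_names(schema)
  if (nrow(atoms) == 0L) return(v)
  d <- sqrt((atoms$x - center[1])^2 + (atoms$y - center[2])^2 +
              (atoms$z - center[3])^2)
  inside <- d < schema$total_radius
  atoms <- atoms[inside, , drop = FALSE]
  if (nrow(atoms) == 0L) return(v)
  shell <- shell_index(d[inside], schema)
  contrib <- .atom_property_matrix(atoms, schema, ss)
  acc <- rowsum(contrib, group = shell)
  kidx <- as.integer(rownames(acc))
  np <- nrow(schema$properties)
  for (i in seq_along(kidx)) {
    v[kidx[i] * np + seq_len(np)] <- acc[i, ]
  }
  frac <- schema$properties$kind == "fraction"
  if (any(frac)) {
    counts <- tabulate(shell + 1L, nbins = schema$n_shells)
    for (k in seq_len(schema$n_shells)) {
      if (counts[k] > 0) {
        idx <- (k - 1L) * np + which(frac)
        v[idx] <- v[idx] / counts[k]
      }
    }
  }
  v
}

#' Featurize all microenvironments of a pocket
#'
#' @param s A `pdb_structure`.
#' @param pocket A `pocket` from [extract_pocket()].
#' @inheritParams featurize
#' @return A `microenv_set` (see [microenvironment_set()]) with one row per
#'   pocket center, in pocket order.
#' @export
featurize_pocket <- function(s, pocket, schema = default_schema(), ss = NULL,
                             include_hetero = FALSE) {
  stopifnot(inherits(pocket, "pocket"))
  cen <- pocket$centers
  vecs <- matrix(0, nrow(cen), schema_length(schema),
                 dimnames = list(cen$name, schema_cell_names(schema)))
  for (i in seq_len(nrow(cen))) {
    vecs[i, ] <- featurize(s, c(cen$x[i], cen$y[i], cen$z[i]), schema,
                           ss = ss, include_hetero = include_hetero)
  }
  microenvironment_set(vecs, cen$tag, cen$name, site_id = pocket$structure_id)
}

#' Construct a set of featurized microenvironments
#'
#' @param vectors Numeric matrix, one row per microenvironment.
#' @param tags Character vector of type tags (one of the 22 types).
#' @param names Character vector of microenvironment names.
#' @param site_id Optional identifier of the originating site.
#' @return Object of class `microenv_set`: list with `vectors`, `tags`,
#'   `names`, `site_id`.
#' @export
microenvironment_set <- function(vectors, tags, names = NULL, site_id = "") {
  vectors <- as.matrix(vectors)
  if (is.null(names)) names <- rownames(vectors)
  if (is.null(names)) names <- paste0("me", seq_len(nrow(vectors)))
  stopifnot(nrow(vectors) == length(tags), length(names) == nrow(vectors))
  rownames(vectors) <- names
  structure(list(vectors = vectors, tags = as.character(tags),
                 names = as.character(names), site_id = site_id),
            class = "microenv_set")
}

#' @export
print.microenv_set <- function(x, ...) {
  cat(sprintf("microenv_set '%s': %d microenvironments x %d cells\n",
              x$site_id, nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' @export
length.microenv_set <- function(x) nrow(x$vectors)

#' Write / read microenvironment vectors (TSV)
#'
#' Header names every cell `<property>@shell<k>`; one row per
#' microenvironment with its name and type tag first.
#'
#' @param mset A `microenv_set`.
#' @param path File path.
#' @export
write_vectors <- function(mset, path) {
  out <- data.frame(name = mset$names, tag = mset$tags,
                    site_id = rep(mset$site_id, length(mset$names)),
                    mset$vectors, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vectors
#' @export
read_vectors <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- c("name", "tag", "site_id")
  stopifnot(all(meta %in% names(tab)))
  vec <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  microenvironment_set(vec, tab$tag, tab$name,
                       site_id = if (nrow(tab)) tab$site_id[1] else "")
}
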