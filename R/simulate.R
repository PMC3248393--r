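#' Generate a toy PDB structure with a planted pocket
#'
#' Builds valid PDB text containing one bound ligand (a small cluster of
#' hetero atoms around the origin) and `length(distances)` protein residues
#' whose nearest atom sits at exactly the requested minimum distance from
#' the ligand (to ~1e-12 Angstrom, found by root solving along the placement
#' ray); remaining residue atoms are placed strictly farther out. The true
#' pocket membership under any contact cutoff is therefore known by
#' construction. Output is a pure function of the arguments and seed.
#'
#' @param distances Numeric vector of planted minimum residue-ligand
#'   distances in Angstrom (one residue per entry, all >= 2).
#' @param residues Character vector of 3-letter residue names recycled over
#'   the planted residues; defaults to a deterministic mix of the 20 types.
#' @param het_code 3-character het code of the ligand (default "LIG").
#' @param n_ligand_atoms Number of ligand heavy atoms (default 8; must be
#'   >= 2).
#' @param seed Integer seed controlling placement directions.
#' @return Character scalar of PDB text. Attribute `planted` carries a data
#'   frame of the ground truth: `resno`, `resid`, `distance` (the achieved
#'   minimum distance, exact at PDB coordinate precision) and `requested`
#'   (the asked-for distance; the two agree to within 5e-3 Angstrom).
#' @export
make_toy_structure <- function(distances, residues = NULL, het_code = "LIG",
                               n_ligand_atoms = 8, seed = 1L) {
  stopifnot(length(distances) >= 1L, all(distances >= 2),
            n_ligand_atoms >= 2)
  if (is.null(residues)) {
    pool <- c("ALA", "SER", "LEU", "ASP", "ARG", "THR", "GLY", "TRP", "TYR",
              "VAL", "GLU", "LYS", "PHE", "ILE", "ASN", "GLN", "HIS", "MET",
              "PRO", "CYS")
    residues <- rep_len(pool, length(distances))
  }
  residues <- rep_len(toupper(residues), length(distances))
  set.seed(.derive_seed(seed, "make_toy_structure"))
  # ligand: ring of atoms of radius 0.7 about the origin, plus center atom
  ang <- seq(0, 2 * pi, length.out = n_ligand_atoms)[-n_ligand_atoms]
  lig <- rbind(c(0, 0, 0),
               cbind(0.7 * cos(ang), 0.7 * sin(ang),
                     0.1 * seq_along(ang)))
  lig <- round(lig[seq_len(n_ligand_atoms), , drop = FALSE], 3)
  atoms <- list()
  serial <- 0L
  add_atom <- function(type, name, resid, chain, resno, xyz, elesy) {
    serial <<- serial + 1L
    atoms[[length(atoms) + 1L]] <<- sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      type, serial, name, "", resid, chain, resno, "",
      xyz[1], xyz[2], xyz[3], 1.0, 10.0, elesy)
  }
  # protein residues planted at exact minimum distances
  planted <- data.frame(resno = integer(0), resid = character(0),
                        distance = numeric(0), requested = numeric(0),
                        stringsAsFactors = FALSE)
  for (r in seq_along(distances)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    d <- distances[r]
    mind <- function(p) min(sqrt(colSums((t(lig) - p)^2)))
    f <- function(t) mind(t * u) - d
    t_star <- stats::uniroot(f, c(d - 1, d + 2), tol = 1e-14)$root
    ca <- t_star * u
    # two orthonormal vectors perpendicular to u for side-chain jitter
    w1 <- .perp_unit(u)
    w2 <- .cross3(u, w1)
    names_r <- .residue_atom_names(residues[r])
    offs <- seq(0.4, by = 0.35, length.out = length(names_r) - 1L)
    jit <- 0.12 * cbind(cos(seq_along(offs)), sin(seq_along(offs)))
    coords <- rbind(ca, t(vapply(seq_along(offs), function(i) {
      ca + offs[i] * u + jit[i, 1] * w1 + jit[i, 2] * w2
    }, numeric(3))))
    # quantize to PDB coordinate precision (0.001 A) and record the achieved
    # minimum distance exactly, so the planted truth survives serialization
    coords <- round(coords, 3)
    dmins <- apply(coords, 1, mind)
    if (abs(dmins[1] - d) > 5e-3 || any(dmins[-1] <= dmins[1])) {
      stop("internal placement failure in make_toy_structure")
    }
    d <- dmins[1]
    # CA first so the planted nearest atom is the alpha carbon
    ordered_names <- c("CA", setdiff(names_r, "CA"))
    for (i in seq_along(ordered_names)) {
      add_atom("ATOM", ordered_names[i], residues[r], "A", r, coords[i, ],
               substr(ordered_names[i], 1, 1))
    }
    planted <- rbind(planted, data.frame(resno = r, resid = residues[r],
                                         distance = d,
                                         requested = distances[r],
                                         stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(lig))) {
    add_atom("HETATM", paste0("C", i), het_code, "A",
             length(distances) + 1L, lig[i, ], "C")
  }
  all_xyz <- do.call(rbind, lapply(atoms, function(a) {
    as.numeric(c(substr(a, 31, 38), substr(a, 39, 46), substr(a, 47, 54)))
  }))
  if (min(stats::dist(all_xyz)) < 1e-6) {
    stop("overlapping atom placements in make_toy_structure")
  }
  txt <- paste(c(atoms, "END"), collapse = "\n")
  attr(txt, "planted") <- planted
  txt
}

.perp_unit <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- .cross3(u, v)
  w / sqrt(sum(w^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# atom sets sufficient for backbone plus the functional-center rules
.residue_atom_names <- function(resid) {
  bb <- c("N", "CA", "C", "O")
  sc <- switch(resid,
    ALA = "CB", CYS = c("CB", "SG"), ASP = c("CB", "CG", "OD1", "OD2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    GLY = character(0),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    MET = c("CB", "CG", "SD", "CE"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    PRO = c("CB", "CG", "CD"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    SER = c("CB", "OG"), THR = c("CB", "OG1", "CG2"),
    VAL = c("CB", "CG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    stop(sprintf("unknown residue name '%s'", resid)))
  c(bb, sc)
}

#' Sample a synthetic microenvironment set with engineered similarity
#'
#' Draws base vectors cell-by-cell (absolute-normal values on a random
#' nonzero support mask) and, optionally, a "sibling" for each base vector
#' engineered so a target fraction of the shared nonzero cells is similar
#' under the one-STD rule. With unit per-cell STDs and sibling fraction `f`
#' of similar cells among `m` shared nonzero cells, the expected adjusted
#' Tanimoto is approximately `f / (2 - f)`; [sibling_fraction_for_tc()]
#' inverts this to engineer a target Tc.
#'
#' @param n Number of base microenvironments.
#' @param n_cells Vector length (default 480).
#' @param tags Type tags recycled over the base vectors; default cycles the
#'   22 types.
#' @param support_frac Fraction of nonzero cells per vector (default 0.5).
#' @param siblings Engineer one sibling per base vector (default `FALSE`).
#' @param similar_frac Fraction of shared nonzero cells made similar in
#'   siblings (see [sibling_fraction_for_tc()]).
#' @param seed Integer seed.
#' @return List with `base` and (when requested) `sibling`, both
#'   `microenv_set` objects sharing support masks pairwise, plus
#'   `expected_tc` when siblings are engineered.
#' @export
sample_microenvironment_set <- function(n, n_cells = 480,
                                        tags = NULL, support_frac = 0.5,
                                        siblings = FALSE, similar_frac = 0.5,
                                        seed = 1L) {
  stopifnot(n >= 1, n_cells >= 2, support_frac > 0, support_frac <= 1)
  if (is.null(tags)) tags <- rep_len(microenvironment_types(), n)
  tags <- rep_len(tags, n)
  set.seed(.derive_seed(seed, "sample_microenvironment_set"))
  m <- max(2L, round(support_frac * n_cells))
  base <- matrix(0, n, n_cells)
  sib <- matrix(0, n, n_cells)
  for (i in seq_len(n)) {
    support <- sample.int(n_cells, m)
    vals <- 5 + abs(stats::rnorm(m, sd = 2))  # nonzero by construction
    base[i, support] <- vals
    if (siblings) {
      sim <- stats::runif(m) < similar_frac
      # similar: within one (unit) STD; dissimilar: well beyond it
      delta <- ifelse(sim, stats::runif(m, -0.45, 0.45),
                      1.5 + stats::runif(m, 0, 1))
      sib[i, support] <- pmax(vals + delta, 0.5)
    }
  }
  names_b <- sprintf("me%d%s", seq_len(n), tags)
  out <- list(base = microenvironment_set(base, tags, paste0(names_b, "/siteA"),
                                          site_id = "siteA"))
  if (siblings) {
    out$sibling <- microenvironment_set(sib, tags, paste0(names_b, "/siteB"),
                                        site_id = "siteB")
    out$expected_tc <- similar_frac / (2 - similar_frac)
  }
  out
}

#' Sibling similar-cell fraction achieving a target expected Tc
#'
#' With `a = b = m` nonzero cells and `c = f*m` similar cells,
#' `Tc = c/(a+b-c) = f/(2-f)`; solving for `f` gives `2*Tc/(1+Tc)`.
#'
#' @param tc Target expected adjusted Tanimoto in `[0, 1)`.
#' @return The similar-cell fraction `f`.
#' @export
sibling_fraction_for_tc <- function(tc) {
  stopifnot(tc >= 0, tc < 1)
  2 * tc / (1 + tc)
}

#' Generate synthetic benchmark scores with known AUC
#'
#' Positive-pair scores are drawn from `Normal(mu - delta, sigma)` and
#' negative-pair scores from `Normal(mu, sigma)` (more negative = more
#' similar), so the theoretical ROC AUC is
#' `pnorm(delta / (sigma * sqrt(2)))`, recorded in the result.
#'
#' @param n_pos,n_neg Numbers of positive and negative pairs.
#' @param delta Separation of the positive mean below the negative mean.
#' @param sigma Common standard deviation.
#' @param mu Negative-pair mean score (default -2).
#' @param seed Integer seed.
#' @return Data frame with columns `a`, `b`, `score`, `label`; attribute
#'   `theoretical_auc`.
#' @export
make_benchmark_scores <- function(n_pos, n_neg, delta, sigma, mu = -2,
                                  seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, sigma > 0)
  set.seed(.derive_seed(seed, "make_benchmark_scores"))
  scores <- c(stats::rnorm(n_pos, mu - delta, sigma),
              stats::rnorm(n_neg, mu, sigma))
  out <- data.frame(
    a = c(sprintf("pos%d", seq_len(n_pos)), sprintf("neg%d", seq_len(n_neg))),
    b = "query",
    score = scores,
    label = rep(c("positive", "control"), c(n_pos, n_neg)),
    stringsAsFactors = FALSE)
  attr(out, "theoretical_auc") <- stats::pnorm(delta / (sigma * sqrt(2)))
  out
}

#' Generate a synthetic background model
#'
#' A complete background over the 72 permissible pair types with specified
#' (or defaulted) per-pair-type normal parameters and unit per-cell STDs;
#' used to exercise scoring and alignment without building a background from
#' structures.
#'
#' @param n_cells Vector length (default 480).
#' @param mu,sigma Normal parameters applied to every pair type (defaults
#'   0.55 and 0.10).
#' @param std Per-cell property STD (scalar or length `n_cells`, default 1).
#' @param partition Residue-group partition.
#' @return A `background_model`.
#' @export
synthetic_background <- function(n_cells = 480, mu = 0.55, sigma = 0.10,
                                 std = 1, partition = default_partition()) {
  keys <- enumerate_pair_types(partition)
  pairs <- lapply(keys, function(k) {
    structure(list(mu = mu, sigma = sigma, tc0 = mu, n_samples = 1000L),
              class = "pair_background")
  })
  names(pairs) <- keys
  structure(list(
    stats = structure(list(std = rep_len(std, n_cells), n_samples = 1000L),
                      class = "property_stats"),
    partition = partition, pairs = pairs,
    missing_pair_types = character(0),
    provenance = list(seed = NA_integer_, n_sites = 0L,
                      n_microenvironments = 0L, synthetic = TRUE)),
    class = "background_model")
}
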