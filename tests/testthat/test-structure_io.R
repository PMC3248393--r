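pdb_line <- function(type, serial, name, resid, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = substr(name, 1, 1), alt = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resid, chain, resno, x, y, z, occ, b, elem)
}

test_that("read_pdb parses single records, first model only, hetero flags", {
  s <- read_pdb(c(pdb_line("ATOM", 1, "CA", "LEU", "A", 6, 1, 2, 3), "END"),
                id = "t")
  expect_equal(nrow(s$atom), 1L)
  expect_equal(unname(unlist(s$atom[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(s$atom$reskey, "A:6::LEU")
  expect_false(s$atom$hetero)

  multi <- c("MODEL        1",
             pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
             "ENDMDL", "MODEL        2",
             pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 9, 9, 9),
             "ENDMDL", "END")
  s2 <- read_pdb(multi)
  expect_equal(nrow(s2$atom), 1L)
  expect_equal(s2$atom$x, 0)

  s3 <- read_pdb(c(pdb_line("HETATM", 1, "C1", "ATP", "A", 401, 0, 0, 0),
                   "END"))
  expect_true(s3$atom$hetero)
})

test_that("read_pdb rejects malformed and empty input with line numbers", {
  expect_error(read_pdb("ATOM      1  CA  LEU A   6      bad coords here"),
               "line 1")
  expect_error(read_pdb(c("REMARK ok",
                          substr(pdb_line("ATOM", 1, "CA", "GLY", "A", 1,
                                          0, 0, 0), 1, 40))),
               "line 2")
  expect_error(read_pdb(""), "empty")
  expect_error(read_pdb(c("REMARK nothing", "END")), "empty")
})

test_that("altloc collapse keeps the highest-occupancy conformer", {
  lines <- c(pdb_line("ATOM", 1, "CA", "SER", "A", 5, 0, 0, 0, occ = 0.4,
                      alt = "A"),
             pdb_line("ATOM", 2, "CA", "SER", "A", 5, 1, 0, 0, occ = 0.6,
                      alt = "B"),
             pdb_line("ATOM", 3, "CB", "SER", "A", 5, 2, 0, 0, occ = 0.5,
                      alt = "A"),
             pdb_line("ATOM", 4, "CB", "SER", "A", 5, 3, 0, 0, occ = 0.5,
                      alt = "B"),
             "END")
  s <- read_pdb(lines)
  expect_equal(nrow(s$atom), 2L)
  expect_equal(s$atom$x[s$atom$elety == "CA"], 1)  # occupancy 0.6 wins
  expect_equal(s$atom$x[s$atom$elety == "CB"], 2)  # tie -> altloc A
})

test_that("select_ligands excludes waters and sub-threshold het groups", {
  lines <- c(
    pdb_line("ATOM", 1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "O", "HOH", "A", 501, 5, 5, 5),
    vapply(1:7, function(i) pdb_line("HETATM", 2 + i, paste0("C", i), "ATP",
                                     "A", 401, i, 0, 0), character(1)),
    vapply(1:3, function(i) pdb_line("HETATM", 9 + i, paste0("C", i), "XYZ",
                                     "A", 402, i, 9, 0), character(1)),
    "END")
  ligs <- select_ligands(read_pdb(lines), min_heavy_atoms = 5)
  expect_length(ligs, 1L)
  expect_equal(ligs[[1]]$het_code, "ATP")
  expect_equal(ligs[[1]]$heavy_atom_count, 7L)
})

test_that("select_ligands returns one instance per copy", {
  lines <- c(unlist(lapply(seq_along(c("A", "B")), function(c_i) {
    ch <- c("A", "B")[c_i]
    vapply(1:6, function(i) pdb_line("HETATM", (c_i - 1) * 6 + i,
                                     paste0("C", i), "ATP",
                                     ch, 401, i, 0, 0), character(1))
  })), "END")
  ligs <- select_ligands(read_pdb(lines))
  expect_length(ligs, 2L)
  expect_setequal(vapply(ligs, `[[`, character(1), "reskey"),
                  c("A:401::ATP", "B:401::ATP"))
})

test_that("extract_pocket applies the closed 6 A rule on planted coordinates", {
  txt <- make_toy_structure(c(4, 5.9, 6.1), residues = c("ALA", "ALA", "ALA"),
                            seed = 7)
  s <- read_pdb(txt, id = "toy")
  lig <- select_ligands(s)[[1]]
  p <- extract_pocket(s, lig, cutoff = 6.0)
  resnos <- sort(unique(as.integer(sub(":.*", "", sub("^A:", "", p$residues)))))
  expect_equal(resnos, c(1L, 2L))

  p0 <- extract_pocket(s, lig, cutoff = 0)
  expect_length(p0$residues, 0L)
})

test_that("extract_pocket equals a brute-force all-pairs distance scan", {
  set.seed(11)
  for (rep in 1:5) {
    d <- runif(20, 2.5, 12)
    txt <- make_toy_structure(d, seed = rep)
    s <- read_pdb(txt, id = "toy")
    lig <- select_ligands(s)[[1]]
    p <- extract_pocket(s, lig, cutoff = 6.0)
    prot <- s$atom[!s$atom$hetero, ]
    lm <- as.matrix(lig$atoms[, c("x", "y", "z")])
    keep <- character(0)
    for (key in unique(prot$reskey)) {
      ra <- prot[prot$reskey == key, ]
      hit <- FALSE
      for (i in seq_len(nrow(ra))) {
        for (j in seq_len(nrow(lm))) {
          dd <- sqrt(sum((c(ra$x[i], ra$y[i], ra$z[i]) - lm[j, ])^2))
          if (dd <= 6.0) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) keep <- c(keep, key)
    }
    expect_setequal(p$residues, keep)
  }
})

test_that("pocket membership is invariant under rigid motion", {
  txt <- make_toy_structure(c(3, 5, 6.5, 9), seed = 3)
  s <- read_pdb(txt, id = "toy")
  p1 <- extract_pocket(s, select_ligands(s)[[1]])
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(s$atom[, c("x", "y", "z")]) %*% t(R)
  s2 <- s
  s2$atom$x <- xyz[, 1] + 10
  s2$atom$y <- xyz[, 2] - 4
  s2$atom$z <- xyz[, 3] + 2.5
  p2 <- extract_pocket(s2, select_ligands(s2)[[1]])
  expect_setequal(p1$residues, p2$residues)
})

test_that("functional centers: 22 distinct tags, W/Y doubled, centroids", {
  tab <- default_functional_centers()
  expect_length(unique(tab$tag), 22L)
  expect_equal(sum(tab$resid == "TRP"), 2L)
  expect_equal(sum(tab$resid == "TYR"), 2L)
  expect_length(unique(tab$resid), 20L)

  gly <- data.frame(elety = c("N", "CA", "C", "O"), resid = "GLY",
                    chain = "A", resno = 1L, insert = "",
                    x = 1:4, y = 1:4, z = 1:4, stringsAsFactors = FALSE)
  fc <- functional_center(gly)
  expect_length(fc, 1L)
  expect_equal(fc[[1]]$tag, "G")
  expect_equal(fc[[1]]$point, c(2, 2, 2))  # the CA atom

  trp_atoms <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1",
                 "CE2", "CE3", "CZ2", "CZ3", "CH2")
  trp <- data.frame(elety = trp_atoms, resid = "TRP", chain = "A",
                    resno = 2L, insert = "", x = seq_along(trp_atoms),
                    y = 0, z = 0, stringsAsFactors = FALSE)
  tags <- vapply(functional_center(trp), `[[`, character(1), "tag")
  expect_setequal(tags, c("W1", "W2"))

  ala <- data.frame(elety = c("N", "CA", "CB"), resid = "ALA", chain = "A",
                    resno = 3L, insert = "", x = c(0, 0, 1), y = c(0, 0, 1),
                    z = c(0, 0, 1), stringsAsFactors = FALSE)
  expect_equal(functional_center(ala)[[1]]$point, c(1, 1, 1))

  expect_warning(fc_unknown <- functional_center(
    transform(ala, resid = "XXX")), "XXX")
  expect_length(fc_unknown, 0L)
  expect_error(functional_center(ala[1:2, ]), "missing")
})

test_that("microenvironment naming follows the m<index><type>/<id> convention", {
  expect_equal(name_microenvironment(6, "L", "1nhp"), "m6L/1nhp")
  expect_equal(name_microenvironment(338, "T"), "m338T")
  expect_equal(name_microenvironment(248, "W2", "1fdr"), "m248W2/1fdr")
})

test_that("pocket and functional-center tables round-trip through TSV", {
  txt <- make_toy_structure(c(3, 4, 5), seed = 5)
  s <- read_pdb(txt, id = "toy")
  p <- extract_pocket(s, select_ligands(s)[[1]])
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_pocket(p, tf)
  p2 <- read_pocket(tf)
  expect_equal(p2$centers$name, p$centers$name)
  expect_equal(p2$centers$x, p$centers$x, tolerance = 1e-10)
  expect_setequal(p2$residues, p$residues)

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_functional_centers(default_functional_centers(), tf2)
  expect_equal(read_functional_centers(tf2), default_functional_centers())
})
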