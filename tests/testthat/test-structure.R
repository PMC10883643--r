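# PDB reading/writing, minimal-case extraction, truncation, interface split

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", altloc = " ", occ = 1) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z, occ, 0)
}

test_that("only ATOM records survive reading; waters and HETATM are dropped", {
  txt <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
    pdb_line(2, "FE", "HEM", "A", 90, 5, 5, 5, record = "HETATM"),
    pdb_line(3, "O", "HOH", "A", 91, 9, 9, 9),
    "END", sep = "\n")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$name, "CA")
})

test_that("altloc collapse keeps the highest occupancy, ties alphabetical", {
  txt <- paste(
    pdb_line(1, "CA", "ALA", "A", 1, 1, 0, 0, altloc = "A", occ = 0.6),
    pdb_line(2, "CA", "ALA", "A", 1, 2, 0, 0, altloc = "B", occ = 0.4),
    pdb_line(3, "CB", "ALA", "A", 1, 3, 0, 0, altloc = "A", occ = 0.5),
    pdb_line(4, "CB", "ALA", "A", 1, 4, 0, 0, altloc = "B", occ = 0.5),
    sep = "\n")
  m <- read_structure(txt)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 1)   # occupancy wins
  expect_equal(m$atoms$x[m$atoms$name == "CB"], 3)   # tie -> altloc A
  m2 <- read_structure(txt, altloc_policy = "first")
  expect_equal(m2$atoms$x[m2$atoms$name == "CA"], 1)
})

test_that("malformed coordinates and empty models are parse errors", {
  bad <- sub("   1.000", "  1.0.00", pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
             fixed = TRUE)
  expect_error(read_structure(paste(bad, "END", sep = "\n")),
               "malformed.*line 1")
  expect_error(read_structure("REMARK nothing\nEND"), "empty model")
})

test_that("hydrogens are parsed but flagged for exclusion", {
  txt <- paste(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "HA", "ALA", "A", 1, 0.5, 0, 0), sep = "\n")
  m <- read_structure(txt)
  expect_equal(m$atoms$hydrogen, c(FALSE, TRUE))
})

test_that("read-write-read round-trips a generated multi-chain fixture", {
  cs <- generate_toy_case(fixture_spec(antibody = "mab", seed = 21))
  m <- cs$bound
  m2 <- read_structure(write_structure(m), id = m$id)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(chain_ids(m2), chain_ids(m))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_equal(m2$atoms$resno, m$atoms$resno)
  expect_equal(m2$atoms$x, m$atoms$x, tolerance = 5e-4)
  expect_equal(m2$atoms$y, m$atoms$y, tolerance = 5e-4)
  expect_equal(m2$atoms$z, m$atoms$z, tolerance = 5e-4)
  # write is idempotent once coordinates are at PDB precision
  expect_identical(write_structure(m2), write_structure(read_structure(
    write_structure(m2))))
})

test_that("writing rejects empty models and field-overflowing coordinates", {
  cs <- generate_toy_case(fixture_spec(seed = 3))
  empty <- cs$bound; empty$atoms <- empty$atoms[0, , drop = FALSE]
  expect_error(write_structure(empty), "empty")
  big <- cs$bound; big$atoms$x[1] <- 123456.0
  expect_error(write_structure(big), "fixed-width")
})

test_that("a one-atom model writes exactly ATOM + TER + END", {
  m <- read_structure(paste(pdb_line(1, "CA", "ALA", "A", 1, 1, 2, 3),
                            sep = "\n"))
  lines <- strsplit(write_structure(m), "\n")[[1]]
  expect_equal(length(lines), 3L)
  expect_match(lines[1], "^ATOM  ")
  expect_equal(lines[2], "TER")
  expect_equal(lines[3], "END")
})

test_that("parser agrees with an independent PDB reader on a fixture", {
  skip_if_not_installed("bio3d")
  cs <- generate_toy_case(fixture_spec(antibody = "mab", seed = 9))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cs$bound, path)
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), sum(ref$atom$type == "ATOM"))
  expect_equal(m$atoms$x, ref$atom$x[ref$atom$type == "ATOM"])
  expect_equal(m$atoms$resno, ref$atom$resno[ref$atom$type == "ATOM"])
})

test_that("minimal-case extraction keeps exactly the named chains", {
  cs <- generate_toy_case(fixture_spec(antibody = "mab", seed = 5))
  m <- cs$bound   # chains H, L, A
  extra <- abagbench:::helix_chain("X", 10, origin = c(0, -40, 0))
  extra2 <- abagbench:::helix_chain("Y", 10, origin = c(0, -60, 0))
  m$atoms <- rbind(m$atoms, extra, extra2)
  m$roles <- c(m$roles, X = "unknown", Y = "unknown")
  case <- extract_minimal_case(m, c("H", "L"), "A")
  expect_setequal(chain_ids(case$bound), c("H", "L", "A"))
  expect_equal(case$pairing_state, "BB")
  expect_error(extract_minimal_case(m, "H", "Z"), "available")
  all_case <- extract_minimal_case(m, c("H", "L"), c("A", "X", "Y"))
  expect_equal(nrow(all_case$bound$atoms), nrow(m$atoms))
})

test_that("truncation trims to the aligned region and never reorders", {
  cs <- generate_toy_case(fixture_spec(seed = 2))
  bound_ag <- subset_chains(cs$bound, "A")
  unb <- cs$unbound_antigen[[1]]

  # identical sequence: unchanged copy
  same <- truncate_unbound(unb, bound_ag)
  expect_equal(nrow(same$atoms), nrow(unb$atoms))

  # 20 extra N-terminal residues: trimmed back to the bound length
  extra <- abagbench:::helix_chain("A", 20, origin = c(-40, 0, 0))
  extra$resno <- extra$resno - 20L
  long <- unb; long$atoms <- rbind(extra, unb$atoms[, names(extra)])
  tr <- truncate_unbound(long, bound_ag)
  expect_equal(nchar(chain_sequence(tr, "A")),
               nchar(chain_sequence(bound_ag, "A")))
  expect_equal(chain_residues(tr, "A")$resno,
               sort(chain_residues(tr, "A")$resno))
})

test_that("truncation keeps exactly the residues an independent alignment maps", {
  # bound chain with an internal deletion relative to the unbound chain:
  # unbound residues 21..30 have no bound counterpart
  cs <- generate_toy_case(fixture_spec(n_res_ag = 50L, seed = 13))
  unb <- cs$unbound_antigen[[1]]
  bound_ag <- subset_chains(cs$bound, "A")
  # give residues distinguishable identities so the alignment is unambiguous
  aa <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE",
          "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
          "VAL", "CYS")
  set.seed(99)
  # deleted block drawn from a disjoint alphabet so the alignment cannot
  # wobble across the deletion boundary
  resnames <- sample(aa[1:10], 50, replace = TRUE)
  resnames[21:30] <- sample(aa[11:20], 10, replace = TRUE)
  for (m in list("unb", "bound_ag")) {
    obj <- get(m)
    obj$atoms$resname <- resnames[obj$atoms$resno]
    assign(m, obj)
  }
  del <- bound_ag$atoms$resno %in% 21:30
  bound_ag$atoms <- bound_ag$atoms[!del, , drop = FALSE]
  tr <- truncate_unbound(unb, bound_ag)
  expect_equal(chain_residues(tr, "A")$resno, setdiff(1:50, 21:30))
})

test_that("interface splitting yields independent suffixed cases", {
  cs <- generate_toy_case(fixture_spec(antibody = "mab", seed = 4))
  sp <- split_interfaces(cs$bound, list(
    list(antibody = c("H", "L"), antigen = "A"),
    list(antibody = "H", antigen = "A")))
  expect_equal(vapply(sp, function(x) x$case_id, character(1)),
               paste0(cs$bound$id, "_", 1:2))
  expect_setequal(chain_ids(sp[[1]]$bound), c("H", "L", "A"))
  expect_setequal(chain_ids(sp[[2]]$bound), c("H", "A"))
  # independence: mutating one case leaves the other untouched
  before <- sp[[2]]$bound$atoms$x
  sp[[1]]$bound$atoms$x <- sp[[1]]$bound$atoms$x + 99
  expect_identical(sp[[2]]$bound$atoms$x, before)
  expect_error(split_interfaces(cs$bound, list(
    list(antibody = "H", antigen = "Q"))), "available")
})
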