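# Interface definitions, contacts, I-RMSD and f_non-nat

two_residue_case <- function(gap) {
  # two single-residue chains with C-alphas `gap` apart
  mk <- function(chain, x) {
    data.frame(serial = 1L, name = "CA", altloc = "", resname = "ALA",
               chain = chain, resno = 1L, insert = "", x = x, y = 0, z = 0,
               occ = 1, element = "C", hydrogen = FALSE,
               stringsAsFactors = FALSE)
  }
  m <- abagbench:::new_structure("pair", rbind(mk("H", 0), mk("A", gap)),
                                 c(H = "single_domain", A = "antigen"))
  complex_case(m, "H", "A")
}

test_that("interface membership follows the distance cutoff exactly", {
  near <- two_residue_case(8)
  iface <- interface_residues(near, 10)
  expect_equal(nrow(iface$antibody), 1L)
  expect_equal(nrow(iface$antigen), 1L)
  expect_equal(nrow(contacts(near, 5)), 0L)   # 8 A apart: no 5 A contact

  far <- two_residue_case(60)
  iface_far <- interface_residues(far, 10)
  expect_equal(nrow(iface_far$antibody), 0L)
  expect_equal(nrow(iface_far$antigen), 0L)
  expect_equal(nrow(contacts(far, 5)), 0L)
})

test_that("interface and contact sets equal the quadratic brute-force scan", {
  for (seed in c(1, 2, 8, 15, 33)) {
    cs <- random_small_case(seed)
    iface <- interface_residues(cs, 10)
    oracle <- brute_interface(cs, 10)
    expect_identical(iface_keys(iface$antibody), oracle$antibody)
    expect_identical(iface_keys(iface$antigen), oracle$antigen)
    ct <- contacts(cs, 5)
    expect_identical(contact_key_strings(ct), brute_contacts(cs, 5))
    # 5 A contacts imply 10 A interface membership on both sides
    expect_true(all(paste(ct$chain_ab, ct$resno_ab, ct$insert_ab) %in%
                      iface_keys(iface$antibody)))
    expect_true(all(paste(ct$chain_ag, ct$resno_ag, ct$insert_ag) %in%
                      iface_keys(iface$antigen)))
  }
})

test_that("hydrogens never enter distance computations", {
  cs <- two_residue_case(12)
  h <- cs$bound$atoms[1, ]
  h$name <- "HA"; h$element <- "H"; h$hydrogen <- TRUE; h$x <- 6
  cs$bound$atoms <- rbind(cs$bound$atoms, h)  # hydrogen bridging the gap
  iface <- interface_residues(cs, 10)
  expect_equal(nrow(iface$antibody), 0L)      # would be 1 if H counted
})

test_that("I-RMSD is zero for identical conformations and localized per side", {
  cs <- generate_toy_case(fixture_spec(seed = 41))
  expect_lt(i_rmsd(cs, "antibody"), 1e-9)
  expect_lt(i_rmsd(cs, "antigen"), 1e-9)
  expect_lt(i_rmsd(cs, "combined"), 1e-9)

  shifted <- generate_toy_case(fixture_spec(perturbation = "rigid_shift",
                                            magnitude = 2,
                                            perturb_side = "antibody",
                                            seed = 42))
  expect_lt(i_rmsd(shifted, "antigen"), 1e-9)
  expect_gt(i_rmsd(shifted, "antibody"), 1)
})

test_that("a constructed interface displacement is recovered exactly", {
  for (d in c(0.8, 2.5)) {
    cs <- generate_toy_case(fixture_spec(perturbation = "rigid_shift",
                                         magnitude = d, seed = 50 + d))
    expect_equal(i_rmsd(cs, "antigen"), d, tolerance = 1e-3)
    # combined pools both sides; antibody side is unperturbed
    iface <- interface_residues(cs, 10)
    n_ab <- nrow(iface$antibody); n_ag <- nrow(iface$antigen)
    expect_equal(i_rmsd(cs, "combined"),
                 d * sqrt(n_ag / (n_ab + n_ag)), tolerance = 1e-3)
  }
})

test_that("f_non-nat is 0 for unperturbed pairs and bounded in [0,1]", {
  cs <- generate_toy_case(fixture_spec(seed = 61))
  expect_equal(as.numeric(f_non_nat(cs)), 0)
  for (seed in c(5, 9)) {
    pert <- generate_toy_case(fixture_spec(perturbation = "rigid_shift",
                                           magnitude = 2.5,
                                           perturb_side = "both",
                                           seed = seed))
    v <- as.numeric(f_non_nat(pert))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("f_non-nat matches hand-constructed contact sets", {
  # perturb so that we can compute the expected fraction from the two
  # contact maps directly: model contacts recomputed after superposition,
  # native membership checked pair by pair
  cs <- generate_toy_case(fixture_spec(perturbation = "rigid_shift",
                                       magnitude = 3, perturb_side = "both",
                                       seed = 71))
  native <- contact_key_strings(contacts(cs, 5))
  iface <- interface_residues(cs, 10)
  maps <- abagbench:::case_maps(cs)
  sup_side <- function(s) {
    pr <- abagbench:::interface_ca_pairs(cs, s, iface, maps)
    sup <- kabsch_superpose(pr$bound, pr$unbound)
    unb <- if (s == "antibody") cs$unbound_antibody[[1]]
    else cs$unbound_antigen[[1]]
    at <- unb$atoms
    xyz <- apply_superposition(cbind(at$x, at$y, at$z), sup)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    at
  }
  ab <- sup_side("antibody"); ag <- sup_side("antigen")
  d <- sqrt(outer(ab$x, ag$x, "-")^2 + outer(ab$y, ag$y, "-")^2 +
              outer(ab$z, ag$z, "-")^2)
  idx <- which(d <= 5, arr.ind = TRUE)
  model <- unique(paste(
    paste(ab$chain[idx[, 1]], ab$resno[idx[, 1]], ab$insert[idx[, 1]],
          sep = "|"),
    paste(ag$chain[idx[, 2]], ag$resno[idx[, 2]], ag$insert[idx[, 2]],
          sep = "|"), sep = "~"))
  # fixture chains keep bound numbering, so keys are directly comparable
  native_keys <- unique(paste(
    abagbench:::contact_keys(contacts(cs, 5))))
  expected <- mean(!(model %in% native_keys))
  expect_equal(as.numeric(f_non_nat(cs)), expected, tolerance = 1e-12)
})

test_that("a contact-free superposed pair reports f_non-nat of 1 with a flag", {
  # both unbound components reduced to their C-alpha traces: the interface
  # fits are exact (identity), but C-alpha/C-alpha separations across this
  # interface all exceed 5 A, so the superposed pair makes no contacts
  cs <- generate_toy_case(fixture_spec(seed = 81))
  ca_only <- function(chains, id) {
    m <- subset_chains(cs$bound, chains, id = id)
    m$atoms <- m$atoms[m$atoms$name == "CA", , drop = FALSE]
    m
  }
  cs$unbound_antibody[[1]] <- ca_only("H", "ab_ca")
  cs$unbound_antigen[[1]] <- ca_only("A", "ag_ca")
  v <- f_non_nat(cs)
  expect_equal(as.numeric(v), 1)
  expect_true(isTRUE(attr(v, "no_model_contacts")))
})

test_that("component RMSD reports whole-chain conformational change", {
  cs <- generate_toy_case(fixture_spec(perturbation = "hinge_rotation",
                                       magnitude = 30, seed = 91))
  expect_gt(component_rmsd(cs, "antigen"), 0.5)
  expect_lt(component_rmsd(cs, "antibody"), 1e-9)
})

test_that("the metrics table carries every column the report needs", {
  cs <- generate_toy_case(fixture_spec(seed = 31))
  cfg <- run_config(sasa_points = 240L)
  m <- interface_metrics(cs, cfg)
  expect_true(all(c("case_id", "rmsd_ab", "rmsd_ag", "i_rmsd_ab",
                    "i_rmsd_ag", "i_rmsd_combined", "f_non_nat",
                    "delta_asa", "cdr_cdr1", "cdr_cdr2", "cdr_cdr3")
                  %in% names(m)))
  expect_true(all(m$delta_asa > 0))
  expect_equal(m$f_non_nat, 0)
})
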