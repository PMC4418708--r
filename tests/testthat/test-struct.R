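toy_pdb_file <- function(n_a = 8, n_b = 5) {
  xyz_a <- cbind(3.8 * seq_len(n_a), 0, 0)
  xyz_b <- cbind(3.8 * seq_len(n_b), 6, 0)
  st <- make_two_chain_structure(xyz_a, xyz_b)
  f <- tempfile(fileext = ".pdb")
  write_pdb(st, f)
  f
}

test_that("PDB parsing handles chains, models and degenerate files", {
  f <- toy_pdb_file(8, 5)
  st <- parse_pdb(f)
  ch <- split(st$atoms, st$atoms$chain)
  expect_equal(length(unique(ch$A$resno)), 8)
  expect_equal(length(unique(ch$B$resno)), 5)

  # only the first MODEL is read
  lines <- readLines(f)
  atoms <- grep("^ATOM", lines, value = TRUE)
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", atoms[1:4], "ENDMDL",
               "MODEL     2", atoms, "ENDMDL", "END"), f2)
  expect_equal(nrow(parse_pdb(f2)$atoms), 4)

  f3 <- tempfile(fileext = ".pdb")
  writeLines(character(0), f3)
  expect_error(parse_pdb(f3), "ATOM")
  expect_error(parse_pdb(tempfile()), class = "dmi_missing_input")
})

test_that("interfacial residues use an inclusive distance cutoff", {
  mk <- function(gap) {
    st <- make_two_chain_structure(cbind(0, 0, 0), cbind(gap, 0, 0))
    template_complex(st, "T", "A", "B")
  }
  expect_equal(interfacial_residues(mk(4.4)), "A:1")
  expect_length(interfacial_residues(mk(4.6)), 0)
  expect_equal(interfacial_residues(mk(4.5)), "A:1")
})

test_that("interfacial set is isometry-invariant and cutoff-monotone", {
  tc <- generate_toy_complex(12, "PPLPA", gap = 4.0)
  base <- interfacial_residues(tc$template)
  expect_gt(length(base), 0)

  shifted <- tc$template
  shifted$structure <- transform_structure(tc$structure,
                                           shift = c(10, 10, 10))
  expect_identical(interfacial_residues(shifted), base)

  withr::with_seed(3, rot <- random_rotation())
  rotated <- tc$template
  rotated$structure <- transform_structure(tc$structure, rot = rot,
                                           shift = c(-5, 2, 7))
  expect_identical(interfacial_residues(rotated), base)

  for (cut in c(4.5, 5.5, 7, 10)) {
    expect_true(all(base %in% interfacial_residues(tc$template, cut)))
    base <- interfacial_residues(tc$template, cut)
  }
})

test_that("ASA matches closed forms for isolated and paired spheres", {
  iso <- make_point_structure(cbind(0, 0, 0))
  asa <- residue_asa(iso)
  expect_equal(unname(asa), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)

  # two-atom system vs the analytic spherical-cap formula
  R <- 1.7 + 1.4
  withr::with_seed(13, d_values <- runif(5, 1.5, 2 * R - 0.3))
  for (d in d_values) {
    st <- make_point_structure(cbind(c(0, d), 0, 0))
    asa2 <- residue_asa(st)
    exact <- oracle_two_sphere_asa(R, R, d)
    expect_equal(unname(asa2), exact, tolerance = 0.02)
  }

  # deterministic point set: identical runs agree exactly
  tc <- generate_toy_complex(10, "PPLPA", gap = 4.5)
  expect_identical(residue_asa(tc$structure), residue_asa(tc$structure))
})

test_that("a fully enclosed atom is buried", {
  # central atom caged by a dense icosphere-like shell at 2.4 A
  pts <- sphere_shell <- NULL
  n <- 60
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  th <- i * pi * (3 - sqrt(5))
  shell <- cbind(2.4 * sqrt(1 - z^2) * cos(th),
                 2.4 * sqrt(1 - z^2) * sin(th), 2.4 * z)
  st <- make_point_structure(rbind(c(0, 0, 0), shell))
  asa <- residue_asa(st)
  expect_lt(asa[["A:1"]], 1)
  surf <- accessible_surface(st)
  expect_false("A:1" %in% surf)
})

test_that("surface ASA is stable under rigid motion", {
  # translation leaves the fixed point set aligned with the molecule: exact
  tc <- generate_toy_complex(10, "PPLPA", gap = 4.0)
  asa0 <- residue_asa(tc$structure)
  shifted <- transform_structure(tc$structure, shift = c(3, -8, 1))
  expect_equal(residue_asa(shifted), asa0, tolerance = 1e-9)
  # rotation re-samples occlusion with the same point density: within the
  # 2% sampling tolerance, and surface membership away from the threshold
  # is unchanged
  withr::with_seed(7, rot <- random_rotation())
  rotated <- transform_structure(tc$structure, rot = rot)
  asa_r <- residue_asa(rotated)
  expect_equal(asa_r, asa0, tolerance = 0.02)
  margin <- abs(asa0 - 10) > 2
  expect_identical((asa_r >= 10)[margin], (asa0 >= 10)[margin])
})

test_that("unknown elements fall back to the default radius with warning", {
  st <- make_point_structure(cbind(0, 0, 0), element = "ZZ")
  expect_warning(asa <- residue_asa(st), "unknown element")
  expect_equal(unname(asa), 4 * pi * (1.8 + 1.4)^2, tolerance = 0.02)
})

test_that("interface coverage applies the inclusive 75% rule", {
  interf <- sprintf("A:%d", 1:8)
  surface <- sprintf("B:%d", 1:6)
  aln6 <- struct_alignment("T", "P", 0.2,
                           setNames(sprintf("B:%d", 1:6), sprintf("A:%d", 1:6)))
  cov <- interface_coverage(aln6, interf, surface)
  expect_equal(cov$fraction, 0.75)
  expect_true(cov$pass)

  aln5 <- struct_alignment("T", "P", 0.2,
                           setNames(sprintf("B:%d", 1:5), sprintf("A:%d", 1:5)))
  cov5 <- interface_coverage(aln5, interf, surface)
  expect_equal(cov5$fraction, 0.625)
  expect_false(cov5$pass)

  aln0 <- struct_alignment("T", "P", 0.2, setNames(character(0), character(0)))
  cov0 <- interface_coverage(aln0, interf, surface)
  expect_equal(cov0$fraction, 0)
  expect_false(cov0$pass)

  expect_error(interface_coverage(aln6, character(0), surface),
               "degenerate")
})

test_that("PSD bins follow the printed edges and reject >= 0.65", {
  expect_equal(assign_psd_bin(0.25), "P1")
  expect_equal(assign_psd_bin(0.30), "P1")
  expect_equal(assign_psd_bin(0.50), "P2")
  expect_true(is.na(assign_psd_bin(0.70)))
  expect_true(is.na(assign_psd_bin(0.65)))
  expect_error(assign_psd_bin(-0.1), "non-negative")
})

test_that("template filter enforces peptide length and monomer rules", {
  mk <- function(len, multimer = FALSE) {
    seqs <- paste(rep("A", len), collapse = "")
    st <- make_two_chain_structure(cbind(3.8 * 1:4, 0, 0),
                                   cbind(3.8 * seq_len(len), 5, 0))
    template_complex(st, paste0("T", len), "A", "B",
                     multimer_flag = multimer)
  }
  kept <- filter_templates(list(mk(4), mk(5), mk(35), mk(36),
                                mk(10, multimer = TRUE)))
  expect_equal(vapply(kept, `[[`, "", "template_id"), c("T5", "T35"))
})
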