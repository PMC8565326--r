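test_that("a minimal AT duplex builds and recovers its defaults", {
  s <- build_duplex("AT")
  info <- residue_info(s)
  expect_equal(sum(info$class == "nucleotide"), 4)
  gp <- geometry_profile(s, "A", "B")
  expect_equal(gp$twist[1], 36, tolerance = 1e-3)
  expect_equal(gp$rise[1], 3.38, tolerance = 1e-4)
})

test_that("invalid sequences and tables are rejected", {
  expect_error(duplex_spec("ATXGC"), "invalid base")
  expect_error(duplex_spec("A"), "length >= 2")
  expect_error(duplex_spec("ATGC", step = data.frame(twist = 1:2)),
               "rows")
  expect_error(duplex_spec("ATGC", overhangs = list(left = "T")),
               "overhang")
})

test_that("overhang duplexes count nucleotides and pairs correctly", {
  spec <- duplex_spec("TTAAAAAAAAAGGC",
                      overhangs = list(strand1_5p = "T", strand2_5p = "A"))
  s <- build_duplex(spec)
  info <- residue_info(s)
  expect_equal(sum(info$class == "nucleotide" & info$chain == "A"), 15)
  expect_equal(sum(info$class == "nucleotide" & info$chain == "B"), 15)
  expect_equal(nrow(detect_base_pairs(s)), 14)
  # overhangs (and 5' termini generally) carry no phosphate
  a1 <- residue_atoms(s, "A", 1)
  expect_false(any(a1$name %in% c("P", "OP1", "OP2")))
})

test_that("build-then-analyze recovers injected parameters exactly", {
  intra <- as.data.frame(matrix(0, 8, 6))
  names(intra) <- c("shear", "stretch", "stagger", "buckle", "propeller",
                    "opening")
  intra$propeller[4] <- -14.5
  intra$shear[2] <- 0.3
  step <- as.data.frame(matrix(rep(c(0, 0, 3.38, 0, 0, 36), each = 7), 7))
  names(step) <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  step$roll[3] <- 8
  step$twist[5] <- 31.2
  s <- build_duplex(duplex_spec("ATGGTACC", step = step, intra = intra))
  gp <- geometry_profile(s, "A", "B")
  expect_equal(gp$propeller[4], -14.5, tolerance = 1e-3)
  expect_equal(gp$shear[2], 0.3, tolerance = 1e-4)
  expect_equal(gp$roll[3], 8, tolerance = 1e-3)
  expect_equal(gp$twist[5], 31.2, tolerance = 1e-3)
  expect_equal(gp$roll[c(1:2, 4:7)], rep(0, 6), tolerance = 1e-3)
})

test_that("by-construction pairing agrees with geometric detection", {
  spec <- duplex_spec("ATGCATGC")
  s <- build_duplex(spec)
  built <- built_duplex_pairs(spec)
  det <- detect_base_pairs(s)
  key <- function(p) sort(paste(p$chain1, p$resseq1, p$chain2, p$resseq2))
  expect_identical(key(built), key(det))
  gp1 <- geometry_profile(s, "A", "B")
  gp2 <- geometry_profile(s, "A", "B", pairs = built)
  expect_equal(gp2$propeller, gp1$propeller, tolerance = 1e-12)
  expect_equal(gp2$twist, gp1$twist, tolerance = 1e-12)
})

test_that("fixture generation is deterministic for a given spec", {
  s1 <- build_duplex(random_duplex_spec(6, seed = 7))
  s2 <- build_duplex(random_duplex_spec(6, seed = 7))
  expect_identical(coords3d(s1), coords3d(s2))
  s3 <- build_duplex(random_duplex_spec(6, seed = 8))
  expect_false(identical(coords3d(s1), coords3d(s3)))
})

test_that("generated duplexes survive write/read and analysis", {
  s <- build_duplex(random_duplex_spec(6, seed = 3))
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  expect_lte(max(abs(coords3d(s2) - coords3d(s))), 0.001)
  expect_silent(gp <- geometry_profile(s2, "A", "B"))
  expect_equal(nrow(gp), 6)
})

test_that("backbone closure keeps O3'-P bonds near ideal", {
  s <- build_duplex(random_duplex_spec(8, seed = 5))
  info <- residue_info(s)
  for (ch in c("A", "B")) {
    strand <- info[info$chain == ch, ]
    strand <- strand[order(strand$resseq), ]
    for (i in 2:nrow(strand)) {
      prv <- nickscope:::res_coords(residue_atoms(s, ch,
                                                  strand$resseq[i - 1]))
      cur <- nickscope:::res_coords(residue_atoms(s, ch, strand$resseq[i]))
      expect_lt(abs(nickscope:::vnorm(cur["P", ] - prv["O3'", ]) - 1.607),
                0.25)
    }
  }
})

test_that("zero-change phosphate rotation leaves the structure unchanged", {
  s <- fix_target()
  s2 <- rotate_phosphate(s, c("A", 6), 0, 0)
  expect_identical(coords3d(s2), coords3d(s))
})

test_that("phosphate rotation preserves flanking sugars within 0.2 A", {
  s <- fix_target()
  s2 <- rotate_phosphate(s, c("A", 6), 100, -90)
  expect_lt(attr(s2, "sugar_shift"), 0.2)
  # upstream sugar untouched exactly
  up0 <- nickscope:::res_coords(residue_atoms(s, "A", 5))
  up1 <- nickscope:::res_coords(residue_atoms(s2, "A", 5))
  expect_equal(up1[c("C4'", "C3'", "O3'"), ], up0[c("C4'", "C3'", "O3'"), ],
               tolerance = 1e-12)
})

test_that("phosphate rotation preserves covalent geometry", {
  s <- fix_target()
  s2 <- rotate_phosphate(s, c("A", 6), 100, -90)
  lk0 <- nickscope:::linkage_extract(s, "A", 6)
  lk1 <- nickscope:::linkage_extract(s2, "A", 6)
  expect_equal(lk1$bonds, lk0$bonds, tolerance = 1e-6)
  expect_equal(lk1$angles, lk0$angles, tolerance = 1e-4)
})

test_that("terminal nucleotides without phosphate are rejected", {
  s <- fix_target()
  expect_error(rotate_phosphate(s, c("A", 1), 90, -90), "terminal")
})

test_that("altloc conformers are well separated at the phosphate", {
  s <- fix_two_conformer()
  ka <- resolve_altlocs(s, "keep_all")
  for (nm in c("P", "OP1", "OP2")) {
    pp <- ka$atoms[ka$atoms$chain == "A" & ka$atoms$resseq == 6 &
                     ka$atoms$name == nm, c("x", "y", "z")]
    expect_equal(nrow(pp), 2)
  }
  pp <- ka$atoms[ka$atoms$chain == "A" & ka$atoms$resseq == 6 &
                   ka$atoms$name == "P", c("x", "y", "z")]
  expect_gt(nickscope:::vnorm(as.numeric(pp[1, ]) - as.numeric(pp[2, ])),
            0.5)
})

test_that("ion shells are built at the requested geometry", {
  s <- build_ion_shell("MG", n_waters = 4, distance = 2.1)
  ions <- ion_atoms(s)
  expect_equal(nrow(ions), 1)
  w <- water_atoms(s)
  expect_equal(nrow(w), 4)
  ctr <- as.numeric(ions[1, c("x", "y", "z")])
  d <- unname(sqrt(rowSums(sweep(as.matrix(w[, c("x", "y", "z")]), 2,
                                 ctr)^2)))
  expect_equal(d, rep(2.1, 4), tolerance = 1e-9)
  # mutual angles are 90 or 180 degrees
  for (i in 1:3) for (j in (i + 1):4) {
    ang <- bond_angle(as.numeric(w[i, c("x", "y", "z")]), ctr,
                      as.numeric(w[j, c("x", "y", "z")]))
    expect_true(min(abs(ang - 90), abs(ang - 180)) < 1e-6)
  }
  expect_error(build_ion_shell(n_waters = 7), "at most")
  expect_error(build_ion_shell(distance = -1), "invalid")
})

test_that("probe poses satisfy the constructed anchor distance", {
  s <- fix_ideal12()
  pose <- make_protein_dna_pose(s, list(
    list(name = "HIS", anchor = "NE2", target = "A:5:O4'", distance = 3.0)))
  ne2 <- atom_xyz(resolve_atom(pose, "P:1:NE2"))
  o4 <- atom_xyz(resolve_atom(pose, "A:5:O4'"))
  expect_equal(nickscope:::vnorm(ne2 - o4), 3.0, tolerance = 1e-9)
  # empty probe list returns the duplex unchanged
  expect_identical(coords3d(make_protein_dna_pose(s, list())),
                   coords3d(s))
  expect_error(make_protein_dna_pose(s, list(
    list(name = "XYZ", anchor = "Q", target = "A:5:O4'", distance = 3))),
    "unsupported")
})
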