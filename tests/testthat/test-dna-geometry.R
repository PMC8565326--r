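test_that("pair detection finds exactly the built pairs, all canonical", {
  s <- fix_target()
  pr <- detect_base_pairs(s)
  expect_equal(nrow(pr), 7)
  expect_true(all(pr$canonical))
  # each nucleotide in at most one pair
  keys <- c(paste(pr$chain1, pr$resseq1), paste(pr$chain2, pr$resseq2))
  expect_false(any(duplicated(keys)))
})

test_that("distant parallel strands are never paired", {
  s <- fix_ideal12()
  at <- s$atoms
  bsel <- at$chain == "B"
  at[bsel, "x"] <- at[bsel, "x"] + 50
  far <- structure3d(at)
  expect_equal(nrow(detect_base_pairs(far)), 0)
})

test_that("a base swung out of the pair plane loses its pair", {
  s <- fix_target()
  at <- s$atoms
  res <- at$chain == "A" & at$resseq == 4
  base_sel <- res & !grepl("'", at$name) & !(at$name %in% c("P", "OP1",
                                                            "OP2"))
  c1 <- as.numeric(at[res & at$name == "C1'", c("x", "y", "z")])
  n1 <- as.numeric(at[res & at$name == "N1", c("x", "y", "z")])
  c2 <- as.numeric(at[res & at$name == "C2", c("x", "y", "z")])
  c6 <- as.numeric(at[res & at$name == "C6", c("x", "y", "z")])
  # swing the Watson-Crick edge out of the pair plane: rotate about the
  # in-plane axis perpendicular to the glycosidic bond
  normal <- nickscope:::cross3(c2 - n1, c6 - n1)
  axis <- nickscope:::cross3(normal, n1 - c1)
  R <- rot_axis(axis, 60)
  xyz <- as.matrix(at[base_sel, c("x", "y", "z")])
  at[base_sel, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, c1) %*% t(R), 2, -c1)
  bent <- structure3d(at)
  pr <- detect_base_pairs(bent)
  expect_equal(nrow(pr), 6)
  expect_false(any(pr$chain1 == "A" & pr$resseq1 == 4) ||
                 any(pr$chain2 == "A" & pr$resseq2 == 4))
})

test_that("constructed dihedrals are measured exactly", {
  set.seed(31)
  a <- c(0, 1.4, 0); b <- c(0, 0, 0); c <- c(1.5, 0, 0)
  d <- nickscope:::place_atom(a, b, c, 1.4, 109.5, 60)
  expect_equal(dihedral(a, b, c, d), 60, tolerance = 1e-6)
})

test_that("builder-template torsions sit in canonical B-DNA regions", {
  tor <- backbone_torsions(fix_ideal12(), "A")
  inner <- tor[3:10, ]
  expect_true(all(inner$alpha > -120 & inner$alpha < -20))  # gauche-
  expect_true(all(inner$gamma > 10 & inner$gamma < 100))    # gauche+
  expect_true(all(abs(inner$delta - 125) < 40))             # C2'-endo
  # 5'-terminal residue has no phosphate: alpha/beta/zeta undefined there
  expect_true(is.na(tor$alpha[1]))
})

test_that("alpha/gamma rotations are recovered by torsion measurement", {
  s <- fix_target()
  t0 <- backbone_torsions(s, "A")
  s2 <- rotate_phosphate(s, c("A", 6), 120, -120)
  t1 <- backbone_torsions(s2, "A")
  expect_equal(nickscope:::angle_diff(t1$alpha[6], t0$alpha[6]), 120,
               tolerance = 1e-6)
  expect_equal(nickscope:::angle_diff(t1$gamma[6], t0$gamma[6]), -120,
               tolerance = 1e-6)
})

test_that("torsions agree with a brute-force dihedral implementation", {
  s <- fix_target()
  tor <- backbone_torsions(s, "A")
  cc5 <- nickscope:::res_coords(residue_atoms(s, "A", 5))
  cc6 <- nickscope:::res_coords(residue_atoms(s, "A", 6))
  expect_equal(tor$alpha[6],
               bf_dihedral(cc5["O3'", ], cc6["P", ], cc6["O5'", ],
                           cc6["C5'", ]), tolerance = 1e-9)
  expect_equal(tor$gamma[6],
               bf_dihedral(cc6["O5'", ], cc6["C5'", ], cc6["C4'", ],
                           cc6["C3'", ]), tolerance = 1e-9)
})

test_that("ideal B-DNA interior groove widths are constant", {
  gw <- groove_widths(fix_ideal12(), "A", "B")
  minor <- na.omit(gw$minor_width)
  major <- na.omit(gw$major_width)
  expect_gt(length(minor), 4)
  expect_lte(max(minor) - min(minor), 0.01)
  expect_lte(max(major) - min(major), 0.01)
  expect_lt(mean(minor), mean(major))  # minor groove is the narrow one
})

test_that("a localized perturbation changes widths only locally", {
  n <- 12
  step <- data.frame(propeller = numeric(0))
  spec0 <- duplex_spec(strrep("AT", 6))
  intra <- as.data.frame(matrix(0, n, 6))
  names(intra) <- c("shear", "stretch", "stagger", "buckle", "propeller",
                    "opening")
  intra$propeller[6] <- -18
  spec1 <- duplex_spec(strrep("AT", 6), intra = intra)
  g0 <- groove_widths(build_duplex(spec0), "A", "B")
  g1 <- groove_widths(build_duplex(spec1), "A", "B")
  dmin <- abs(g1$minor_width - g0$minor_width)
  affected <- which(dmin > 0.02)
  expect_true(all(abs(affected - 6) <= 2))
  expect_gt(max(dmin, na.rm = TRUE), 0.02)
})

test_that("groove widths are invariant under rigid motion and relabeling", {
  set.seed(32)
  s <- fix_ideal12()
  g0 <- groove_widths(s, "A", "B")
  s2 <- transform_structure(s, random_rotation(), rnorm(3, sd = 8))
  g2 <- groove_widths(s2, "A", "B")
  expect_equal(g2$minor_width, g0$minor_width, tolerance = 1e-9)
  expect_equal(g2$major_width, g0$major_width, tolerance = 1e-9)
  # strand relabeling: minor stays minor
  gswap <- groove_widths(s, "B", "A")
  expect_equal(sort(na.omit(gswap$minor_width)),
               sort(na.omit(g0$minor_width)), tolerance = 1e-9)
})

test_that("refined groove widths subtract the phosphate radii", {
  g0 <- groove_widths(fix_ideal12(), "A", "B")
  g1 <- groove_widths(fix_ideal12(), "A", "B", refined_grooves = TRUE)
  expect_equal(g1$minor_width, g0$minor_width - 5.8, tolerance = 1e-12)
})

test_that("profile comparison: self-comparison is identically zero", {
  gp <- geometry_profile(fix_target(), "A", "B")
  cmp <- compare_profiles(gp, gp)
  num <- cmp$deltas[, setdiff(names(cmp$deltas), "position")]
  expect_true(all(abs(as.matrix(num)) < 1e-12, na.rm = TRUE))
})

test_that("profile comparison locates an injected propeller spike", {
  n <- 7
  intra <- as.data.frame(matrix(0, n, 6))
  names(intra) <- c("shear", "stretch", "stagger", "buckle", "propeller",
                    "opening")
  intra$propeller[6] <- 10   # position +1 once numbered
  bound <- build_duplex(duplex_spec("TTTTTAA", intra = intra))
  bound <- assign_relative_numbering(bound, c("A", 6))
  ref <- fix_target()
  gb <- geometry_profile(bound, "A", "B")
  gr <- geometry_profile(ref, "A", "B")
  cmp <- compare_profiles(gb, gr)
  expect_equal(cmp$summary$extreme_propeller_pos, 1)
  expect_equal(abs(cmp$summary$extreme_propeller), 10, tolerance = 1e-6)
  expect_equal(cmp$summary$scissile_between, c(-1, 1))
})

test_that("profiles with disjoint positions cannot be aligned", {
  gp <- geometry_profile(fix_target(), "A", "B")
  gp2 <- gp
  gp2$position <- gp2$position + 100
  expect_error(compare_profiles(gp, gp2), "no positions")
})
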