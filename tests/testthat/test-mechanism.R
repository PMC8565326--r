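conformer_pair <- function() {
  fix_cached("conformer_pair", function() {
    s <- fix_two_conformer()
    list(A = resolve_altlocs(s, "label:A"),
         B = resolve_altlocs(s, "label:B"))
  })
}

path_fixture <- function(n_steps = 20) {
  fix_cached(paste0("path", n_steps), function() {
    cp <- conformer_pair()
    torsion_drive(cp$A, cp$B, c("A", 6), n_steps = n_steps)
  })
}

test_that("driving a conformer onto itself is the identity path", {
  cp <- conformer_pair()
  path <- torsion_drive(cp$A, cp$A, c("A", 6), n_steps = 5)
  for (k in 2:6)
    expect_equal(path$frames[[k]], path$frames[[1]], tolerance = 1e-6)
  expect_true(all(path$driven$energy < 1e-8))
})

test_that("driven torsions are exactly affine in the step index", {
  path <- path_fixture()
  d <- path$driven
  k <- d$step
  a_expect <- nickscope:::wrap_angle(
    d$alpha[1] + k / max(k) * nickscope:::angle_diff(d$alpha[nrow(d)],
                                                     d$alpha[1]))
  g_expect <- nickscope:::wrap_angle(
    d$gamma[1] + k / max(k) * nickscope:::angle_diff(d$gamma[nrow(d)],
                                                     d$gamma[1]))
  expect_equal(d$alpha, a_expect, tolerance = 1e-9)
  expect_equal(d$gamma, g_expect, tolerance = 1e-9)
  # and the torsions measured from the coordinates agree with the schedule
  ps <- path_to_structure(path)
  mid <- 11
  frame_at <- ps$atoms[ps$atoms$model == mid, ]
  frame_at$model <- 1L
  frame_s <- structure3d(frame_at)
  tor <- backbone_torsions(frame_s, "A")
  # alpha involves only fixed-upstream + mobile atoms: exact; gamma is
  # exact in the linkage's internal coordinates, but measured against the
  # fixed context sugar it carries the mid-path anchor residual
  expect_equal(tor$alpha[6], d$alpha[mid], tolerance = 1e-6)
  expect_lt(abs(nickscope:::angle_diff(tor$gamma[6], d$gamma[mid])), 25)
})

test_that("interpolated rotation fractions match the requested totals", {
  cp <- conformer_pair()
  path <- torsion_drive(cp$A, cp$B, c("A", 6), n_steps = 10)
  d <- path$driven
  # the fixture flip drove alpha by +140 exactly; gamma by about -90 (its
  # measured value differs slightly because the shared sugar carries the
  # small compensation residual)
  expect_equal(nickscope:::angle_diff(d$alpha[2], d$alpha[1]), 14,
               tolerance = 0.01)
  # the measured total differs from -90 by the shared-sugar residual
  tot_g <- nickscope:::angle_diff(d$gamma[11], d$gamma[1])
  expect_lt(abs(tot_g + 90), 25)
  expect_equal(nickscope:::angle_diff(d$gamma[2], d$gamma[1]), tot_g / 10,
               tolerance = 1e-6)
})

test_that("path frames conserve covalent bond lengths and angles", {
  path <- path_fixture()
  lk <- path$linkage
  ch <- nickscope:::.linkage_chain
  for (k in c(5, 11, 21)) {
    # rebuild full positions for this frame and compare internal coords
    d <- path$driven[k, ]
    built <- nickscope:::linkage_rebuild(lk, d$epsilon, d$zeta, d$alpha,
                                         d$beta, d$gamma)
    bonds <- vapply(2:9, function(j)
      nickscope:::vnorm(built[ch[j], ] - built[ch[j - 1], ]), 0)
    angs <- vapply(3:9, function(j)
      bond_angle(built[ch[j - 2], ], built[ch[j - 1], ], built[ch[j], ]), 0)
    expect_equal(bonds, lk$bonds, tolerance = 1e-3)
    expect_equal(angs, lk$angles, tolerance = 0.1)
  }
})

test_that("path endpoints reproduce the input conformers", {
  cp <- conformer_pair()
  path <- path_fixture()
  mobile <- path$mobile_atoms
  a6_A <- nickscope:::res_coords(residue_atoms(cp$A, "A", 6))
  a6_B <- nickscope:::res_coords(residue_atoms(cp$B, "A", 6))
  expect_lte(max(abs(path$frames[[1]][mobile, ] - a6_A[mobile, ])), 0.05)
  expect_lte(max(abs(path$frames[[21]][mobile, ] - a6_B[mobile, ])), 0.05)
})

test_that("free torsions vary continuously along the path", {
  cp <- conformer_pair()
  path <- torsion_drive(cp$A, cp$B, c("A", 6), n_steps = 50)
  d <- path$driven
  for (col in c("epsilon", "zeta", "beta")) {
    steps <- abs(nickscope:::angle_diff(d[[col]][-1],
                                        d[[col]][-nrow(d)]))
    expect_lte(max(steps), 15)
  }
})

test_that("a 101-frame path exports 101 MODEL records", {
  cp <- conformer_pair()
  path <- torsion_drive(cp$A, cp$B, c("A", 6), n_steps = 100)
  ps <- path_to_structure(path)
  tf <- tempfile(fileext = ".pdb")
  write_structure(ps, tf, multi_model = TRUE)
  expect_equal(sum(startsWith(readLines(tf), "MODEL")), 101)
})

test_that("distance reports behave at probes with known geometry", {
  path <- path_fixture()
  p0 <- path$frames[[1]]["P", ]
  rep0 <- path_distance_report(path, list(start_P = p0))
  tab <- rep0$table
  expect_equal(tab$distance[tab$frame == 0 & tab$atom == "P"], 0,
               tolerance = 1e-9)
  # monotone-increasing start segment of the P trace
  ptrace <- tab$distance[tab$atom == "P"]
  expect_true(all(diff(ptrace[1:5]) > -1e-9))
  # probe equidistant from both endpoints gives equal end distances
  pend <- path$frames[[21]]["P", ]
  midprobe <- (p0 + pend) / 2
  rep1 <- path_distance_report(path, list(mid = midprobe))
  tr <- rep1$table[rep1$table$atom == "P", ]
  expect_equal(tr$distance[1], tr$distance[nrow(tr)], tolerance = 1e-6)
  # two probes produce 2 x (n+1) P rows and a full table
  rep2 <- path_distance_report(path, list(a = p0, b = pend))
  expect_equal(nrow(rep2$table), 2 * 21 * 4)  # P, OP1, OP2, O5'
  expect_equal(nrow(rep2$argmin), 2)
  expect_error(path_distance_report(path, list()), "no probes")
})

test_that("phosphorane placement on exact TBP vertices has zero residual", {
  # synthetic conformer whose five oxygens already sit at ideal vertices
  R <- rot_axis(c(1, 1, 0), 25)
  p <- c(3, -2, 5)
  ax <- 1.76; eq <- 1.60
  verts <- rbind(
    o3 = ax * c(0, 0, 1), nuc = ax * c(0, 0, -1), o5 = eq * c(1, 0, 0),
    op1 = eq * c(cos(2 * pi / 3), sin(2 * pi / 3), 0),
    op2 = eq * c(cos(4 * pi / 3), sin(4 * pi / 3), 0))
  verts <- sweep(verts %*% t(R), 2, -p)
  fit <- nickscope:::tbp_fit(p, verts[1, ], verts[2, ], verts[3, ],
                             verts[4, ], verts[5, ], 1.76, 1.60)
  expect_lt(fit$residual, 1e-9)
})

test_that("phosphorane models satisfy TBP invariants under vertex noise", {
  set.seed(61)
  cp <- conformer_pair()
  sB <- cp$B
  lk <- nickscope:::linkage_extract(sB, "A", 6)
  attack <- lk$pos["P", ] + c(2.2, 0.4, -0.8)
  for (noise in c(0, 0.1, 0.2, 0.3)) {
    sN <- sB
    sel <- sN$atoms$chain == "A" & sN$atoms$resseq == 6 &
      sN$atoms$name %in% c("OP1", "OP2", "O5'")
    sN$atoms[sel, c("x", "y", "z")] <-
      sN$atoms[sel, c("x", "y", "z")] + rnorm(sum(sel) * 3, sd = noise)
    ph <- build_phosphorane(sN, c("A", 6), attack + rnorm(3, sd = noise))
    expect_equal(unname(ph$bonds[ph$axial]), c(1.76, 1.76),
                 tolerance = 1e-9)
    expect_equal(unname(ph$bonds[ph$equatorial]), rep(1.60, 3),
                 tolerance = 1e-9)
    expect_equal(ph$angles[ph$axial[1], ph$axial[2]], 180,
                 tolerance = 1e-6)
    eqs <- ph$angles[ph$equatorial, ph$equatorial]
    expect_equal(sort(eqs[upper.tri(eqs)]), rep(120, 3), tolerance = 1e-6)
    axeq <- ph$angles[ph$axial, ph$equatorial]
    expect_equal(as.numeric(axeq), rep(90, 6), tolerance = 1e-6)
    if (noise > 0) expect_gt(ph$residual, 0)
  }
})

test_that("perfect octahedral shells score zero deviation", {
  shell6 <- build_ion_shell("MG", 6, distance = 2.1)
  sh <- coordination_shell(shell6, "MG")
  expect_equal(sh$coordination_number, 6)
  expect_false(sh$sub_octahedral)
  expect_lt(sh$octahedricity, 1e-6)
})

test_that("five-ligand shells are flagged sub-octahedral", {
  shell5 <- build_ion_shell("MG", 5, distance = 2.1)
  sh <- coordination_shell(shell5, "MG")
  expect_equal(sh$coordination_number, 5)
  expect_true(sh$sub_octahedral)
  expect_lt(sh$octahedricity, 1e-6)  # five ideal vertices still fit
  expect_setequal(sh$ligands$label, paste0("W", 1:5))
})

test_that("shell enumeration equals a brute-force distance scan", {
  set.seed(62)
  for (rep in 1:20) {
    n <- 12
    at <- data.frame(record = "HETATM", name = "O", resname = "HOH",
                     chain = "W", resseq = seq_len(n),
                     x = rnorm(n, sd = 2), y = rnorm(n, sd = 2),
                     z = rnorm(n, sd = 2), element = "O")
    mg <- data.frame(record = "HETATM", name = "MG", resname = "MG",
                     chain = "M", resseq = 1, x = 0, y = 0, z = 0,
                     element = "MG")
    s <- structure3d(rbind(at, mg))
    cutoff <- runif(1, 1.5, 3.5)
    sh <- coordination_shell(s, "MG", cutoff = cutoff)
    d <- sqrt(at$x^2 + at$y^2 + at$z^2)
    expect_equal(sh$coordination_number, sum(d <= cutoff))
    expect_setequal(sh$ligands$resseq, at$resseq[d <= cutoff])
  }
})

test_that("coordination count grows monotonically with the cutoff", {
  set.seed(63)
  shell6 <- build_ion_shell("MG", 6, distance = 2.1)
  counts <- vapply(seq(1.0, 3.0, by = 0.25), function(ct)
    coordination_shell(shell6, "MG", cutoff = ct)$coordination_number, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("water displacement follows the clash threshold", {
  shell <- build_ion_shell("MG", 4, distance = 2.1)
  sh <- coordination_shell(shell, "MG")
  w1 <- atom_xyz(resolve_atom(shell, "W1"))
  # an atom between the ion and W1: displaces W1, clashes with the ion
  near <- matrix(c(1.3, 0, 0), 1, 3)
  out <- water_displacement(sh, near, context = shell)
  expect_equal(out$displaced, "W1")
  expect_setequal(out$kept, c("W2", "W3", "W4"))
  far <- matrix(w1 + c(5, 5, 5), 1, 3)
  out2 <- water_displacement(sh, far, context = shell)
  expect_equal(length(out2$displaced), 0)
  expect_true(nrow(out$clashes) >= 1)  # the ion clash is reported
})

test_that("morphing a structure onto itself is the identity", {
  s <- fix_target()
  m <- restrained_morph(s, s)
  expect_identical(coords3d(m$structure), coords3d(s))
  expect_lt(utils::tail(m$energy, 1), 1e-12)
})

test_that("a small rigid offset morphs onto the target", {
  s <- fix_target()
  xyz <- coords3d(s)
  tgt <- set_coords3d(s, sweep(xyz, 2, c(-0.3, 0.1, 0.2)))
  m <- restrained_morph(s, tgt, max_iter = 500)
  expect_lte(max(abs(coords3d(m$structure) - coords3d(tgt))), 0.02)
  expect_lte(m$max_bond_violation, 0.1)
})

test_that("morph energies are non-increasing and the core stays fixed", {
  s <- fix_target()
  shell <- build_ion_shell("MG", 2, site = c(0, 0, -6))
  sys <- nickscope:::bind_structures(s, shell, id = "sys")
  sys$water_labels <- shell$water_labels
  xyz <- coords3d(sys)
  tgt <- set_coords3d(sys, sweep(xyz, 2, c(-0.3, 0, 0)))
  m <- restrained_morph(sys, tgt, fixed_center = "MG", fixed_radius = 8)
  expect_true(all(diff(m$energy) <= 1e-9))
  expect_gt(m$fixed_atoms, 0)
  d0 <- sqrt(rowSums(sweep(xyz, 2, c(0, 0, -6))^2))
  fixed_idx <- which(d0 <= 8)
  expect_identical(coords3d(m$structure)[fixed_idx, ], xyz[fixed_idx, ])
  free_idx <- which(d0 > 12)
  expect_lt(max(abs(coords3d(m$structure)[free_idx, ] -
                      coords3d(tgt)[free_idx, ])), 0.3)
})
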