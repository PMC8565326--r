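test_that("a minimal one-atom PDB parses with default occupancy", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.104  13.207   2.100  1.00 20.00           C",
    "END"), tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$occ, 1.0)
  expect_equal(s$atoms$name, "CA")
  expect_equal(as.numeric(s$atoms[1, c("x", "y", "z")]),
               c(11.104, 13.207, 2.100))
})

test_that("write-then-read is a fixed point for coordinates and identity", {
  s <- fix_target()
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$resname, s$atoms$resname)
  expect_equal(s2$atoms$chain, s$atoms$chain)
  expect_lte(max(abs(coords3d(s2) - coords3d(s))), 0.001)
  # second generation: identical to the first re-read
  tf2 <- tempfile(fileext = ".pdb")
  write_structure(s2, tf2)
  s3 <- read_structure(tf2)
  expect_identical(coords3d(s3), coords3d(s2))
})

test_that("unreadable or absent files raise parse errors", {
  expect_error(read_structure(tempfile()), "not found")
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", bad)
  expect_error(read_structure(bad))
})

test_that("coordinate overflow and long names are refused on write", {
  at <- data.frame(name = "CA", resname = "GLY", chain = "A", resseq = 1,
                   x = 123456.0, y = 0, z = 0)
  s <- structure3d(at)
  expect_error(write_structure(s, tempfile(fileext = ".pdb")), "overflow")
  at2 <- data.frame(name = "ABCDE", resname = "GLY", chain = "A",
                    resseq = 1, x = 0, y = 0, z = 0)
  expect_error(write_structure(structure3d(at2),
                               tempfile(fileext = ".pdb")), "4 characters")
})

test_that("an empty structure writes a valid header-only file", {
  s <- structure3d(data.frame())
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  lines <- readLines(tf)
  expect_true(any(startsWith(lines, "REMARK")))
  expect_equal(lines[length(lines)], "END")
  expect_false(any(startsWith(lines, "ATOM")))
})

test_that("multi-model export writes one MODEL block per frame", {
  s <- fix_target()
  at <- do.call(rbind, lapply(1:5, function(m) {
    a <- s$atoms
    a$model <- m
    a
  }))
  ms <- structure3d(at)
  tf <- tempfile(fileext = ".pdb")
  write_structure(ms, tf, multi_model = TRUE)
  lines <- readLines(tf)
  expect_equal(sum(startsWith(lines, "MODEL")), 5)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 5)
  s2 <- read_structure(tf)
  expect_equal(length(unique(s2$atoms$model)), 5)
})

test_that("alternate locations survive a write/read roundtrip", {
  s <- fix_two_conformer()
  tf <- tempfile(fileext = ".pdb")
  write_structure(s, tf)
  s2 <- read_structure(tf)
  pp <- s2$atoms[s2$atoms$chain == "A" & s2$atoms$resseq == 6 &
                   s2$atoms$name == "P", ]
  expect_equal(nrow(pp), 2)
  expect_setequal(pp$altloc, c("A", "B"))
  expect_equal(pp$occ, c(0.5, 0.5))
})

test_that("altloc policies behave as documented", {
  s <- fix_two_conformer()
  # keep_all preserves both conformers of the scissile phosphate
  ka <- resolve_altlocs(s, "keep_all")
  pp <- ka$atoms[ka$atoms$chain == "A" & ka$atoms$resseq == 6 &
                   ka$atoms$name == "P", ]
  expect_equal(nrow(pp), 2)
  # highest_occupancy: ties resolved alphabetically -> A survives
  hi <- resolve_altlocs(s, "highest_occupancy")
  expect_false(any(hi$atoms$altloc != ""))
  expect_equal(nrow(hi$atoms), nrow(fix_target()$atoms))
  pA <- s$atoms[s$atoms$name == "P" & s$atoms$altloc == "A" &
                  s$atoms$resseq == 6, c("x", "y", "z")]
  pH <- hi$atoms[hi$atoms$name == "P" & hi$atoms$resseq == 6 &
                   hi$atoms$chain == "A", c("x", "y", "z")]
  expect_equal(as.numeric(pH), as.numeric(pA))
  # explicit label returns that conformer's coordinates exactly
  sB <- resolve_altlocs(s, "label:B")
  pB <- s$atoms[s$atoms$name == "P" & s$atoms$altloc == "B" &
                  s$atoms$resseq == 6, c("x", "y", "z")]
  pBsel <- sB$atoms[sB$atoms$name == "P" & sB$atoms$resseq == 6 &
                      sB$atoms$chain == "A", c("x", "y", "z")]
  expect_equal(as.numeric(pBsel), as.numeric(pB))
  expect_error(resolve_altlocs(s, "label:Z"), "not present")
})

test_that("occupancy-weighted selection keeps the heavier conformer", {
  at <- data.frame(name = c("P", "P"), altloc = c("A", "B"),
                   resname = "DA", chain = "A", resseq = 1,
                   x = c(0, 5), y = 0, z = 0, occ = c(0.6, 0.4))
  s <- structure3d(at)
  hi <- resolve_altlocs(s)
  expect_equal(nrow(hi$atoms), 1)
  expect_equal(hi$atoms$x, 0)
})

test_that("altloc resolution preserves residues and removes only extras", {
  s <- fix_two_conformer()
  before <- residue_info(s)
  after_s <- resolve_altlocs(s)
  after <- residue_info(after_s)
  expect_equal(nrow(after), nrow(before))
  n_extra <- sum(s$atoms$altloc == "B")
  expect_equal(nrow(after_s$atoms), nrow(s$atoms) - n_extra)
})

test_that("relative numbering matches the consensus-site convention", {
  s <- fix_target()   # TTTTTAA, scissile before the first A
  info <- residue_info(s)
  a <- info[info$chain == "A", ]
  a <- a[order(a$resseq), ]
  expect_equal(a$rel_pos, c(-5, -4, -3, -2, -1, 1, 2))
  expect_false(any(na.omit(info$rel_pos) == 0))
  # opposite strand follows its paired base
  b <- info[info$chain == "B", ]
  expect_setequal(na.omit(b$rel_pos), c(-5, -4, -3, -2, -1, 1, 2))
  # relabeling is idempotent
  s2 <- assign_relative_numbering(s, c("A", 6))
  expect_identical(s2$atoms$rel_pos, s$atoms$rel_pos)
})

test_that("relative numbering labels follow strand order monotonically", {
  s <- fix_target()
  info <- residue_info(s)
  a <- info[info$chain == "A", ]
  rel <- a$rel_pos[order(a$resseq)]
  expect_true(all(diff(rel) %in% c(1, 2)))
  expect_true(sum(diff(rel) == 2) == 1)  # exactly one skip, across the bond
})

test_that("a single-nucleotide chain is labeled +1 with no negatives", {
  s <- fix_target()
  keep <- s$atoms$chain == "A" & s$atoms$resseq == 3
  single <- structure3d(s$atoms[keep, ])
  out <- assign_relative_numbering(single, c("A", 3))
  expect_true(all(out$atoms$rel_pos == 1))
})

test_that("numbering rejects bad anchors", {
  s <- fix_target()
  expect_error(assign_relative_numbering(s, c("A", 99)), "not found")
  pose <- make_protein_dna_pose(fix_ideal12(), list(
    list(name = "HIS", anchor = "NE2", target = "A:5:O4'", distance = 3)))
  expect_error(assign_relative_numbering(pose, c("P", 1)),
               "not a nucleotide")
})

test_that("water labels bind to residues and resolve as probes", {
  shell <- build_ion_shell(n_waters = 4)
  w <- resolve_atom(shell, "W3")
  expect_equal(w$resseq, 103)
  expect_error(label_waters(shell, W9 = "Z:1"), "no residue")
})
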