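# Consensus standard-reference-frame base geometries (Olson et al. 2001).
# Coordinates are in the base's own reference frame: origin between the
# Watson-Crick edges, x toward the major groove, y along the pseudo-dyad
# toward the paired strand's sugar, z along the helix axis for strand 1.
# All base atoms are planar (z = 0) by construction; C1' is included for
# glycosidic geometry but is not part of the ring-fit atom set.

.std_base_coords <- list(
  DA = matrix(c(
    -2.479, 5.346, 0.000,   # C1'
    -1.291, 4.498, 0.000,   # N9
     0.024, 4.897, 0.000,   # C8
     0.877, 3.902, 0.000,   # N7
     0.071, 2.771, 0.000,   # C5
     0.369, 1.398, 0.000,   # C6
     1.611, 0.909, 0.000,   # N6
    -0.668, 0.532, 0.000,   # N1
    -1.912, 1.023, 0.000,   # C2
    -2.320, 2.290, 0.000,   # N3
    -1.267, 3.124, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "N6",
                      "N1", "C2", "N3", "C4"), c("x", "y", "z"))),
  DG = matrix(c(
    -2.477, 5.399, 0.000,   # C1'
    -1.289, 4.551, 0.000,   # N9
     0.023, 4.962, 0.000,   # C8
     0.870, 3.969, 0.000,   # N7
     0.071, 2.833, 0.000,   # C5
     0.424, 1.460, 0.000,   # C6
     1.554, 0.955, 0.000,   # O6
    -0.700, 0.641, 0.000,   # N1
    -1.999, 1.087, 0.000,   # C2
    -2.949, 0.139, -0.001,  # N2
    -2.342, 2.364, 0.001,   # N3
    -1.265, 3.177, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N9", "C8", "N7", "C5", "C6", "O6",
                      "N1", "C2", "N2", "N3", "C4"), c("x", "y", "z"))),
  DC = matrix(c(
    -2.477, 5.402, 0.000,   # C1'
    -1.285, 4.542, 0.000,   # N1
    -1.472, 3.158, 0.000,   # C2
    -2.628, 2.709, 0.001,   # O2
    -0.391, 2.344, 0.000,   # N3
     0.837, 2.868, 0.000,   # C4
     1.875, 2.027, 0.001,   # N4
     1.056, 4.275, 0.000,   # C5
    -0.023, 5.068, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "N4",
                      "C5", "C6"), c("x", "y", "z"))),
  DT = matrix(c(
    -2.481, 5.354, 0.000,   # C1'
    -1.284, 4.500, 0.000,   # N1
    -1.462, 3.135, 0.000,   # C2
    -2.562, 2.608, 0.000,   # O2
    -0.298, 2.407, 0.000,   # N3
     0.994, 2.897, 0.000,   # C4
     1.944, 2.119, 0.000,   # O4
     1.106, 4.338, 0.000,   # C5
     2.466, 4.961, 0.001,   # C7
    -0.024, 5.057, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("C1'", "N1", "C2", "O2", "N3", "C4", "O4",
                      "C5", "C7", "C6"), c("x", "y", "z")))
)

.purines <- c("DA", "DG", "A", "G")
.pyrimidines <- c("DC", "DT", "C", "T", "DU", "U")

# Ring atoms used for the least-squares reference-frame fit.
.ring_atoms <- list(
  purine = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6")
)

normalize_base_name <- function(name) {
  nm <- toupper(sub("^\\s+|\\s+$", "", name))
  map <- c(A = "DA", G = "DG", C = "DC", T = "DT",
           DA = "DA", DG = "DG", DC = "DC", DT = "DT",
           ADE = "DA", GUA = "DG", CYT = "DC", THY = "DT")
  out <- unname(map[nm])
  out
}

is_purine_base <- function(name) normalize_base_name(name) %in% c("DA", "DG")

#' Standard base geometry in the base reference frame
#'
#' @param base one of "DA", "DG", "DC", "DT" (one-letter codes accepted).
#' @return matrix of atom coordinates (rows named by atom).
#' @keywords internal
std_base <- function(base) {
  nb <- normalize_base_name(base)
  if (is.na(nb)) stop("unknown base: ", base)
  .std_base_coords[[nb]]
}

ring_atom_names <- function(base) {
  if (is_purine_base(base)) .ring_atoms$purine else .ring_atoms$pyrimidine
}

complement_base <- function(base) {
  nb <- normalize_base_name(base)
  unname(c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")[nb])
}

# Minor-/major-groove edge tables for base atoms, derived from the sign of x
# in the standard reference frame (+x points toward the major groove).
# Heavier than a runtime sign test only in that the assignment is fixed and
# inspectable.
base_edge_table <- function(base) {
  nb <- normalize_base_name(base)
  coords <- .std_base_coords[[nb]]
  atoms <- setdiff(rownames(coords), "C1'")
  side <- ifelse(coords[atoms, "x"] > 0, "major", "minor")
  names(side) <- atoms
  side
}
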