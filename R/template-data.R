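# Idealized B-form sugar-phosphate backbone template, expressed in the
# standard base reference frame (shared by all four bases; the glycosidic
# attachment uses the purine N9 position, which coincides with the
# pyrimidine N1 to within a few hundredths of an Angstrom). Derived once by
# restrained optimization of ideal bond lengths/angles and canonical B-DNA
# torsions under the helical continuity constraint (twist 36 deg, rise
# 3.38 A): the O3'(i)-P(i+1) bond closes at 1.60 A when the template is
# repeated helically. C1' is part of the template (not taken from the base)
# so the sugar is identical for purines and pyrimidines.

.backbone_template <- matrix(c(
  -2.4790,  5.3460,  0.0000,   # C1'
  -2.4086,  6.2119, -1.1117,   # O4'
  -2.6959,  6.1903,  1.2415,   # C2'
  -3.2013,  7.5308,  0.7158,   # C3'
  -2.9626,  7.5005, -0.7939,   # C4'
  -4.5986,  7.6320,  0.9575,   # O3'
  -2.0172,  8.5665, -1.2779,   # C5'
  -0.8111,  8.5090, -0.5214,   # O5'
   0.4523,  9.3757, -0.9342,   # P
   1.6218,  8.9981, -0.1007,   # OP1
   0.0752, 10.8087, -1.0326),  # OP2
  ncol = 3, byrow = TRUE,
  dimnames = list(c("C1'", "O4'", "C2'", "C3'", "C4'", "O3'", "C5'", "O5'",
                    "P", "OP1", "OP2"), c("x", "y", "z")))

#' Backbone template in the standard base frame
#'
#' @return matrix of sugar-phosphate atom coordinates (rows named by atom).
#' @keywords internal
backbone_template <- function() .backbone_template
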