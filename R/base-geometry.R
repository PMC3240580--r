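# Idealised deoxyribonucleotide geometry in the standard base reference
# frame (base plane at z = 0, origin on the pseudo-dyad, y toward the C1'
# of the owning strand; the Watson-Crick partner of a base placed at frame
# F sits at F %*% diag(1,-1,-1), a 180 degree rotation about the frame x
# axis).  Base-ring coordinates follow the standard reference-frame
# convention used by helical-parameter programs; a single idealised
# sugar-phosphate template (rigid superposition of ideal component
# geometry onto the ring, averaged over the four bases) is shared by all
# nucleotides so that a uniform fibre-model duplex is exactly
# sequence-independent in its backbone.  Distances in Angstrom.

std_base_geometry <- list(
  DA = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    x = c(-2.183, -1.187, -3.041, -2.630, -2.789, -3.195, -2.387, -3.384, -4.539, -2.956, -2.433, -1.259, 0.046, 0.820, 0.061, 0.334, 1.638, -0.689, -1.935, -2.239, -1.283),
    y = c(8.922, 8.628, 9.789, 8.227, 7.801, 7.141, 6.285, 6.660, 7.062, 5.639, 5.438, 4.543, 4.930, 3.884, 2.761, 1.383, 0.920, 0.535, 0.968, 2.248, 3.172),
    z = c(0.039, -0.052, 0.596, -0.179, 0.464, 0.217, -0.217, 0.888, 0.962, 0.761, -0.000, -0.000, -0.001, -0.001, 0.005, -0.001, -0.001, -0.000, -0.000, -0.000, -0.001),
    stringsAsFactors = FALSE),
  DT = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    x = c(-2.183, -1.187, -3.041, -2.630, -2.789, -3.195, -2.387, -3.384, -4.539, -2.956, -2.433, -1.297, -1.483, -2.589, -0.305, 0.995, 1.988, 1.110, 2.479, -0.017),
    y = c(8.922, 8.628, 9.789, 8.227, 7.801, 7.141, 6.285, 6.660, 7.062, 5.639, 5.438, 4.535, 3.136, 2.591, 2.382, 2.865, 2.144, 4.348, 4.948, 5.073),
    z = c(0.039, -0.052, 0.596, -0.179, 0.464, 0.217, -0.217, 0.888, 0.962, 0.761, -0.000, -0.000, 0.000, -0.000, 0.001, 0.000, -0.001, 0.001, 0.001, -0.000),
    stringsAsFactors = FALSE),
  DG = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    x = c(-2.183, -1.187, -3.041, -2.630, -2.789, -3.195, -2.387, -3.384, -4.539, -2.956, -2.433, -1.251, 0.056, 0.830, 0.067, 0.352, 1.504, -0.683, -1.966, -2.997, -2.243, -1.271),
    y = c(8.922, 8.628, 9.789, 8.227, 7.801, 7.141, 6.285, 6.660, 7.062, 5.639, 5.438, 4.604, 4.994, 3.947, 2.827, 1.441, 1.041, 0.574, 1.032, 0.127, 2.316, 3.236),
    z = c(0.039, -0.052, 0.596, -0.179, 0.464, 0.217, -0.217, 0.888, 0.962, 0.761, -0.000, 0.000, 0.001, 0.000, -0.001, -0.001, -0.002, 0.005, -0.001, -0.002, -0.001, 0.001),
    stringsAsFactors = FALSE),
  DC = data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    x = c(-2.183, -1.187, -3.041, -2.630, -2.789, -3.195, -2.387, -3.384, -4.539, -2.956, -2.433, -1.299, -1.458, -2.583, -0.406, 0.828, 1.907, 1.029, -0.050),
    y = c(8.922, 8.628, 9.789, 8.227, 7.801, 7.141, 6.285, 6.660, 7.062, 5.639, 5.438, 4.525, 3.190, 2.720, 2.373, 2.857, 2.003, 4.252, 5.070),
    z = c(0.039, -0.052, 0.596, -0.179, 0.464, 0.217, -0.217, 0.888, 0.962, 0.761, -0.000, -0.001, 0.000, 0.002, 0.000, -0.001, 0.000, 0.003, -0.002),
    stringsAsFactors = FALSE)
)

base_ring_atoms <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6")
)
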