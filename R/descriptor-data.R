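# Vendored amino-acid property tables and group partitions used by the
# classical descriptor families. All vectors follow the fixed alphabetical
# ordering ACDEFGHIKLMNPQRSTVWY. The scales are standard published values:
# Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, side-chain mass,
# residue volume, Grantham polarity, Charton polarizability, isoelectric
# point and net side-chain charge (His counted 0.1 for its partial
# protonation at neutral pH).

.aaScale <- function(v) stats::setNames(v, .AA20)

.AA_SCALES <- list(
  hydropathy = .aaScale(c(1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9,
                          3.8, 1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2,
                          -0.9, -1.3)),
  hydrophilicity = .aaScale(c(-0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8,
                              3.0, -1.8, -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4,
                              -1.5, -3.4, -2.3)),
  sidechain_mass = .aaScale(c(15.0, 47.0, 59.0, 73.0, 91.1, 1.0, 81.1, 57.1,
                              72.1, 57.1, 75.1, 58.1, 42.1, 72.1, 101.1,
                              31.0, 45.0, 43.1, 130.2, 107.1)),
  volume = .aaScale(c(88.6, 108.5, 111.1, 138.4, 189.9, 60.1, 153.2, 166.7,
                      168.6, 166.7, 162.9, 114.1, 112.7, 143.8, 173.4, 89.0,
                      116.1, 140.0, 227.8, 193.6)),
  polarity = .aaScale(c(8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
                        5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2)),
  polarizability = .aaScale(c(0.046, 0.128, 0.105, 0.151, 0.290, 0.000, 0.230,
                              0.186, 0.219, 0.186, 0.221, 0.134, 0.131, 0.180,
                              0.291, 0.062, 0.108, 0.140, 0.409, 0.298)),
  isoelectric = .aaScale(c(6.00, 5.07, 2.77, 3.22, 5.48, 5.97, 7.59, 6.02,
                           9.74, 5.98, 5.74, 5.41, 6.30, 5.65, 10.76, 5.68,
                           5.60, 5.96, 5.89, 5.66)),
  net_charge = .aaScale(c(0, 0, -1, -1, 0, 0, 0.1, 0, 1,
                          0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0))
)

# Five-group amino-acid partition (aliphatic / aromatic / positively
# charged / negatively charged / uncharged polar) for the grouped
# composition families.
.AA_GROUPS5 <- list(
  aliphatic = c("G", "A", "V", "L", "M", "I"),
  aromatic = c("F", "Y", "W"),
  positive = c("K", "R", "H"),
  negative = c("D", "E"),
  uncharged = c("S", "T", "C", "P", "N", "Q")
)

# Seven conjoint-triad classes (dipole / side-chain-volume clustering).
.AA_GROUPS7 <- list(
  g1 = c("A", "G", "V"),
  g2 = c("I", "L", "F", "P"),
  g3 = c("Y", "M", "T", "S"),
  g4 = c("H", "N", "Q", "W"),
  g5 = c("R", "K"),
  g6 = c("D", "E"),
  g7 = c("C")
)

# Classical three-class partitions for composition/transition/distribution.
.CTD_CLASSICAL <- list(
  hydrophobicity = list(c("R", "K", "E", "D", "Q", "N"),
                        c("G", "A", "S", "T", "P", "H", "Y"),
                        c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(c("G", "A", "S", "T", "P", "D", "C"),
                    c("N", "V", "E", "Q", "I", "L"),
                    c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(c("L", "I", "F", "W", "C", "M", "V", "Y"),
                  c("P", "A", "T", "G", "S"),
                  c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(c("G", "A", "S", "D", "T"),
                        c("C", "P", "N", "V", "E", "Q", "I", "L"),
                        c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(c("K", "R"),
                c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S",
                  "T", "W", "Y", "V"),
                c("D", "E")),
  secondary_structure = list(c("E", "A", "L", "M", "Q", "K", "R", "H"),
                             c("V", "I", "Y", "C", "W", "F", "T"),
                             c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(c("A", "L", "F", "C", "G", "I", "V", "W"),
                               c("R", "K", "Q", "E", "N", "D"),
                               c("M", "S", "P", "T", "H", "Y"))
)

# Tertile partition (sizes 7/6/7 in rank order, alphabetical tie-break) of
# the 20 residues under a numeric scale; extends the classical partitions
# to the 13 groupings used by the CTD families.
.tertilePartition <- function(scale) {
  ord <- order(scale, names(scale))
  aa <- names(scale)[ord]
  list(aa[1:7], aa[8:13], aa[14:20])
}

.CTD_GROUPS <- c(
  .CTD_CLASSICAL,
  list(
    hydropathy_tertiles = .tertilePartition(.AA_SCALES$hydropathy),
    hydrophilicity_tertiles = .tertilePartition(.AA_SCALES$hydrophilicity),
    mass_tertiles = .tertilePartition(.AA_SCALES$sidechain_mass),
    volume_tertiles = .tertilePartition(.AA_SCALES$volume),
    isoelectric_tertiles = .tertilePartition(.AA_SCALES$isoelectric),
    polarity_tertiles = .tertilePartition(.AA_SCALES$polarity)
  )
)

# Codon multiplicities per residue (standard genetic code, 61 sense codons);
# used by the dipeptide-deviation-from-expected-mean family.
.AA_CODONS <- .aaScale(c(4, 2, 2, 2, 2, 4, 2, 3, 2, 6, 1, 2, 4, 2, 6, 6, 4,
                         4, 1, 2))

# z-standardize a scale over the 20 residues (population sd).
.stdScale <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  (v - m) / s
}

# Residue-pair distance matrices for the sequence-order families, derived
# as Euclidean distances in standardized property space and normalized to
# unit maximum: one over all eight scales, one over the
# hydropathy/polarity/volume subspace.
.distMatrixFromScales <- function(scaleNames) {
  P <- vapply(.AA_SCALES[scaleNames], .stdScale, numeric(20))
  D <- as.matrix(stats::dist(P))
  D / max(D)
}

.SO_DIST <- NULL  # built lazily in .soDistMatrices()

.soDistMatrices <- function() {
  list(
    physchem = .distMatrixFromScales(names(.AA_SCALES)),
    hpv = .distMatrixFromScales(c("hydropathy", "polarity", "volume"))
  )
}
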