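# Small real molecules built in code (coordinates in Angstrom).

mol_benzene <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  atoms <- data.frame(elem = "C", x = 1.39 * cos(ang),
                      y = 1.39 * sin(ang), z = 0, charge = 0L)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1),
                      order = c(2L, 1L, 2L, 1L, 2L, 1L))
  phmol("benzene", atoms, bonds)
}

mol_butane <- function() {
  atoms <- data.frame(elem = "C",
                      x = c(0, 1.53, 2.078, 3.608),
                      y = c(0, 0, 1.428, 1.428),
                      z = c(0, 0, 0, 0), charge = 0L)
  bonds <- data.frame(a1 = 1:3, a2 = 2:4, order = 1L)
  phmol("butane", atoms, bonds)
}

mol_methylammonium <- function() {
  atoms <- data.frame(elem = c("C", "N"), x = c(0, 1.5), y = 0, z = 0,
                      charge = c(0L, 1L))
  phmol("methylammonium", atoms, data.frame(a1 = 1, a2 = 2, order = 1L))
}

mol_acetone <- function() {
  atoms <- data.frame(elem = c("C", "C", "O", "C"),
                      x = c(-1.29, 0, 0, 1.29),
                      y = c(-0.75, 0, 1.22, -0.75),
                      z = 0, charge = 0L)
  bonds <- data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                      order = c(1L, 2L, 1L))
  phmol("acetone", atoms, bonds)
}

mol_acetate <- function() {
  atoms <- data.frame(elem = c("C", "C", "O", "O"),
                      x = c(-1.5, 0, 0.65, 0.65),
                      y = c(0, 0, 1.1, -1.1),
                      z = 0, charge = c(0L, 0L, 0L, -1L))
  bonds <- data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                      order = c(1L, 2L, 1L))
  phmol("acetate", atoms, bonds)
}
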