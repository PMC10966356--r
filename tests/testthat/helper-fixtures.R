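# Fixtures are built in code: literal PDB records for column-level
# parser checks, generator-based structures for everything else.

pdb_atom_line <- function(eleno, name, resname, chain, resno, x, y, z,
                          occ = 1, altloc = " ", icode = " ", element = NULL,
                          record = "ATOM  ") {
  if (is.null(element)) element <- substr(sub("^[0-9]+", "", name), 1L, 1L)
  nm <- if (nchar(name) < 4L) paste0(" ", formatC(name, width = -3)) else name
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, eleno, nm, altloc, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

# one ALA residue: 5 heavy atoms + 2 hydrogens
write_ala_fixture <- function(path) {
  h <- make_helix(4)
  a <- subset(h$atoms, res_index == 2)
  lines <- character(0)
  k <- 0L
  for (r in seq_len(nrow(a))) {
    k <- k + 1L
    lines <- c(lines, pdb_atom_line(k, a$name[r], "ALA", "A", 1,
                                    a$x[r], a$y[r], a$z[r]))
  }
  # amide H and HA at plausible positions
  lines <- c(lines,
             pdb_atom_line(k + 1L, "H", "ALA", "A", 1,
                           a$x[1] - 0.6, a$y[1] - 0.8, a$z[1], element = "H"),
             pdb_atom_line(k + 2L, "HA", "ALA", "A", 1,
                           a$x[2] + 0.9, a$y[2] + 0.4, a$z[2], element = "H"))
  writeLines(c(lines, "END"), path)
  path
}

# two chains of 3 glycines each (no CB)
write_gly2_fixture <- function(path) {
  res <- build_gly_chain(3)
  lines <- character(0); k <- 0L
  for (ch in c("A", "B")) {
    dz <- if (ch == "A") 0 else 20
    for (i in seq_along(res)) {
      for (nm in c("N", "CA", "C", "O")) {
        k <- k + 1L
        p <- res[[i]][[nm]]
        lines <- c(lines, pdb_atom_line(k, nm, "GLY", ch, i,
                                        p[1], p[2], p[3] + dz))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}

build_gly_chain <- function(n) {
  res <- cdosc:::build_chain(n, -120, 120)
  lapply(res, function(r) r[c("N", "CA", "C", "O")])
}

# altloc A/B on one atom (occupancies 0.4 / 0.6)
write_altloc_fixture <- function(path) {
  h <- make_helix(4)
  a <- subset(h$atoms, res_index == 2)
  lines <- character(0)
  for (r in seq_len(nrow(a))) {
    if (a$name[r] == "CB") {
      lines <- c(lines,
                 pdb_atom_line(r, "CB", "ALA", "A", 1, a$x[r], a$y[r], a$z[r],
                               occ = 0.4, altloc = "A"),
                 pdb_atom_line(r + 100L, "CB", "ALA", "A", 1,
                               a$x[r] + 1, a$y[r], a$z[r],
                               occ = 0.6, altloc = "B"))
    } else {
      lines <- c(lines, pdb_atom_line(r, a$name[r], "ALA", "A", 1,
                                      a$x[r], a$y[r], a$z[r]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

element3_typing <- function() {
  load_typing_table(system.file("extdata", "typing_element3.yaml",
                                package = "cdosc"))
}

# single-type table: every atom maps to one label
uniform_typing <- function(label = "uni") {
  rules <- lapply(c("H", "C", "N", "O", "S"), function(el)
    list(element = el, role = "*", ss = "*", label = label))
  fb <- as.list(rep(label, 5))
  names(fb) <- c("H", "C", "N", "O", "S")
  list(name = "uniform", labels = label, rules = rules, fallback = fb)
}

# constant-curve library with one base entry
const_library <- function(value, content = c(a = 1, b = 0, c = 0, o = 0),
                          grid = default_grid(), label = "uni", id = "e1") {
  curves <- matrix(as.complex(value), length(grid), 1L,
                   dimnames = list(NULL, label))
  polar_library(grid, base = list(list(id = id, content = content,
                                       curves = curves)))
}

prepared_helix <- function(n = 12L) {
  prepare_structure(make_helix(n), typing = element3_typing())
}

lorentz3 <- function() make_lorentzian_library(3L)
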