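# PDB ingestion and the internal point-dipole structure model.
#
# A protein_structure holds an atom table (one row per point dipole) and
# a residue table. Parsing follows the wwPDB 3.3 fixed-column layout:
# first MODEL only, altloc resolved to the highest-occupancy record
# (ties broken toward 'A'), HETATM kept only for D-amino acids and MSE,
# waters dropped.

ATOM_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
ALLOWED_ELEMENTS <- names(ATOM_MASS)

.cdosc_env <- new.env(parent = emptyenv())

topology <- function() {
  if (is.null(.cdosc_env$topology)) {
    .cdosc_env$topology <- yaml::read_yaml(
      pkg_file("extdata", "residue_topology.yaml"))
  }
  .cdosc_env$topology
}

standard_residues <- function() names(topology()$residues)

#' Construct a protein structure object
#'
#' Low-level constructor; most users obtain structures from [read_pdb()]
#' or the fixture generators ([make_helix()], [make_strand()]).
#'
#' @param atoms data.frame with columns `eleno`, `name`, `resname`,
#'   `chain`, `resno`, `icode`, `x`, `y`, `z`, `occupancy`, `element`.
#' @param title free-text title.
#' @return An object of class `protein_structure` with `atoms`,
#'   `residues`, `nres` and `title` components. The residue table gains
#'   an `ss` column (NA until [assign_ss()] runs) and `is_D` flags.
#' @export
protein_structure <- function(atoms, title = "") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  need <- c("eleno", "name", "resname", "chain", "resno", "icode",
            "x", "y", "z", "occupancy", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  bad <- !(atoms$element %in% ALLOWED_ELEMENTS)
  if (any(bad))
    stop("unknown element for atom ", atoms$name[which(bad)[1L]],
         " (", atoms$element[which(bad)[1L]], ")")

  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  res_index <- match(key, unique(key))
  atoms$res_index <- res_index

  topo <- topology()
  first <- !duplicated(res_index)
  residues <- data.frame(
    res_index = res_index[first],
    resname   = atoms$resname[first],
    chain     = atoms$chain[first],
    resno     = atoms$resno[first],
    icode     = atoms$icode[first],
    stringsAsFactors = FALSE
  )
  residues$template <- template_name(residues$resname)
  residues$is_D <- residues$resname %in% names(topo$d_aliases)
  residues$ss <- NA_character_

  atoms$is_D <- residues$is_D[atoms$res_index]
  if (is.null(atoms$type_label)) atoms$type_label <- NA_character_
  for (col in c("ex", "ey", "ez")) if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_

  structure(
    list(atoms = atoms, residues = residues, nres = nrow(residues),
         title = title),
    class = "protein_structure")
}

template_name <- function(resname) {
  topo <- topology()
  out <- resname
  d <- match(resname, names(topo$d_aliases))
  out[!is.na(d)] <- unlist(topo$d_aliases)[d[!is.na(d)]]
  h <- match(out, names(topo$het_aliases))
  out[!is.na(h)] <- unlist(topo$het_aliases)[h[!is.na(h)]]
  out
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$title, "\n", sep = "")
  cat("  atoms:    ", nrow(x$atoms), "\n", sep = "")
  cat("  residues: ", x$nres, "\n", sep = "")
  if (!all(is.na(x$residues$ss))) {
    ct <- ss_content(x)
    cat(sprintf("  ss: %.1f%% helix, %.1f%% strand, %.1f%% coil, %.1f%% other\n",
                100 * ct[["a"]], 100 * ct[["b"]], 100 * ct[["c"]], 100 * ct[["o"]]))
  }
  invisible(x)
}

infer_element <- function(name, el_field) {
  el <- toupper(trimws(el_field))
  if (nzchar(el) && el %in% c("SE")) return("S")
  if (nzchar(el)) return(el)
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9]+", "", nm)
  if (startsWith(nm, "H")) return("H")
  substr(nm, 1L, 1L)
}

#' Read a protein structure from a PDB file
#'
#' Column-based parsing of ATOM/HETATM records (wwPDB 3.3 layout).
#' Only the first MODEL of multi-model files is read. Alternate
#' locations are resolved to the highest-occupancy record, ties broken
#' toward altloc 'A'. HETATM records are kept only for D-amino acids
#' and MSE (read as MET, SE mapped to S); waters are always skipped.
#' Elements come from columns 77-78 with an atom-name fallback.
#'
#' @param path path to a PDB file.
#' @param unknown_residues `"skip"` (default, with a message) or
#'   `"error"` for residue names without a template.
#' @return A [protein_structure()] with chirality flags set from both
#'   residue naming and geometry ([detect_chirality()]).
#' @export
read_pdb <- function(path, unknown_residues = c("skip", "error")) {
  unknown_residues <- match.arg(unknown_residues)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("format error: empty PDB file: ", path)

  title <- sub("^TITLE\\s+[0-9]*\\s*", "", grep("^TITLE", lines, value = TRUE)[1L])
  if (is.na(title)) title <- basename(path)

  # first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1L] - 1L)]

  rec <- substr(lines, 1L, 6L)
  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) stop("format error: no ATOM/HETATM records in ", path)
  lines <- lines[keep]
  is_het <- substr(lines, 1L, 6L) == "HETATM"

  fld <- function(a, b) substr(lines, a, b)
  atoms <- data.frame(
    eleno     = suppressWarnings(as.integer(fld(7, 11))),
    name      = trimws(fld(13, 16)),
    altloc    = fld(17, 17),
    resname   = trimws(fld(18, 20)),
    chain     = fld(22, 22),
    resno     = suppressWarnings(as.integer(fld(23, 26))),
    icode     = fld(27, 27),
    x         = suppressWarnings(as.numeric(fld(31, 38))),
    y         = suppressWarnings(as.numeric(fld(39, 46))),
    z         = suppressWarnings(as.numeric(fld(47, 54))),
    occupancy = suppressWarnings(as.numeric(fld(55, 60))),
    stringsAsFactors = FALSE
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  el_field <- substr(lines, 77, 78)
  atoms$element <- mapply(infer_element, atoms$name, el_field, USE.NAMES = FALSE)

  bad_coord <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (all(bad_coord)) stop("format error: unparseable coordinates in ", path)
  atoms <- atoms[!bad_coord, , drop = FALSE]
  is_het <- is_het[!bad_coord]

  topo <- topology()
  water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  het_ok <- atoms$resname %in% c(names(topo$d_aliases), names(topo$het_aliases))
  drop <- (is_het & !het_ok) | water
  atoms <- atoms[!drop, , drop = FALSE]

  known <- template_name(atoms$resname) %in% standard_residues()
  if (any(!known)) {
    bad_names <- unique(atoms$resname[!known])
    if (unknown_residues == "error")
      stop("unknown residue name(s): ", paste(bad_names, collapse = ", "))
    message("skipping unknown residue name(s): ", paste(bad_names, collapse = ", "))
    atoms <- atoms[known, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("empty structure: no protein atoms in ", path)

  # MSE: selenium becomes the thioether sulfur
  mse <- atoms$resname == "MSE" & atoms$name == "SE"
  if (any(mse)) { atoms$name[mse] <- "SD"; atoms$element[mse] <- "S" }

  # altloc resolution: highest occupancy, ties toward 'A'/' '
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$occupancy, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$name, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(atoms$eleno), , drop = FALSE]
  }

  s <- protein_structure(atoms, title = title)
  chir <- detect_chirality(s)
  geo_D <- chir == "D"
  s$residues$is_D <- s$residues$is_D | geo_D
  s$atoms$is_D <- s$residues$is_D[s$atoms$res_index]
  s
}

#' Write a protein structure to a PDB file
#'
#' Standard fixed-column ATOM records (coordinates at PDB precision,
#' 0.001 A); a TER record per chain and END.
#'
#' @param s a [protein_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  recs <- sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$eleno, nm, a$resname, a$chain, a$resno,
                  ifelse(nzchar(a$icode), a$icode, " "),
                  a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(sprintf("TITLE     %s", s$title), recs, "TER", "END"), path)
  invisible(path)
}

# ---- covalent bond graph ----------------------------------------------------

# Attach a hydrogen to its heavy atom by name ("HB2" -> "CB", "H" -> "N").
h_parent <- function(hname, heavy_names) {
  nm <- toupper(hname)
  nm <- sub("^([0-9]+)(.*)$", "\\2\\1", nm)  # 1HB -> HB1
  if (nm %in% c("H", "HN", "H1", "H2", "H3", "HT1", "HT2", "HT3")) return("N")
  if (nm %in% c("HA", "HA2", "HA3")) return("CA")
  rest <- sub("^H", "", nm)
  cand <- character(0)
  while (nchar(rest) > 0L) {
    cand <- c(cand, paste0(c("C", "N", "O", "S"), rest))
    if (grepl("[0-9]$", rest)) rest <- sub("[0-9]$", "", rest) else break
  }
  hit <- cand[cand %in% heavy_names]
  if (length(hit)) hit[1L] else NA_character_
}

# List of integer neighbor vectors, one per atom row.
bond_graph <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  nb <- vector("list", n)
  add <- function(i, j) {
    nb[[i]] <<- c(nb[[i]], j)
    nb[[j]] <<- c(nb[[j]], i)
  }
  topo <- topology()
  idx_by_res <- split(seq_len(n), a$res_index)
  for (ri in seq_len(s$nres)) {
    rows <- idx_by_res[[as.character(ri)]]
    names_r <- a$name[rows]
    find <- function(nm) rows[match(nm, names_r)]
    tmpl <- s$residues$template[ri]
    bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
    if (!(tmpl %in% topo$no_cb)) bonds <- c(bonds, list(c("CA", "CB")))
    if ("OXT" %in% names_r) bonds <- c(bonds, list(c("C", "OXT")))
    side <- topo$residues[[tmpl]]$bonds
    if (length(side)) bonds <- c(bonds, side)
    for (b in bonds) {
      i <- find(b[[1L]]); j <- find(b[[2L]])
      if (!is.na(i) && !is.na(j)) add(i, j)
    }
    heavy <- names_r[a$element[rows] != "H"]
    for (k in which(a$element[rows] == "H")) {
      p <- h_parent(names_r[k], heavy)
      if (!is.na(p)) {
        j <- find(p)
        if (!is.na(j)) add(rows[k], j)
      }
    }
  }
  # peptide bonds between consecutive residues of the same chain
  for (ri in seq_len(s$nres - 1L)) {
    if (s$residues$chain[ri] != s$residues$chain[ri + 1L]) next
    i <- idx_by_res[[as.character(ri)]]
    j <- idx_by_res[[as.character(ri + 1L)]]
    ci <- i[match("C", a$name[i])]
    nj <- j[match("N", a$name[j])]
    if (!is.na(ci) && !is.na(nj)) {
      d <- vnorm(c(a$x[ci] - a$x[nj], a$y[ci] - a$y[nj], a$z[ci] - a$z[nj]))
      if (d < 2.0) add(ci, nj)
    }
  }
  lapply(nb, unique)
}

#' Assign induced-dipole directions
#'
#' Default rule: the unit dipole direction of atom i points along the
#' bond from i to its heaviest covalently bonded neighbor (ties broken
#' by atom-name lexicographic order). Atoms without a template bond
#' fall back to the direction toward the residue centroid (logged via
#' `message()`). The rule is configurable through `rule`.
#'
#' @param s a [protein_structure()].
#' @param rule `"heaviest_neighbor"` (default) or a function
#'   `f(atom_row, neighbor_rows, atoms)` returning a 3-vector.
#' @return The structure with unit `ex`, `ey`, `ez` columns filled.
#' @export
assign_dipole_directions <- function(s, rule = "heaviest_neighbor") {
  a <- s$atoms
  nb <- bond_graph(s)
  pos <- as.matrix(a[, c("x", "y", "z")])
  e <- matrix(NA_real_, nrow(a), 3L)
  custom <- is.function(rule)
  if (!custom && !identical(rule, "heaviest_neighbor"))
    stop("unknown dipole rule: ", rule)
  for (i in seq_len(nrow(a))) {
    js <- nb[[i]]
    if (custom) {
      e[i, ] <- unitize(rule(a[i, ], js, a))
      next
    }
    if (length(js) == 0L) {
      rows <- which(a$res_index == a$res_index[i])
      ctr <- colMeans(pos[rows, , drop = FALSE])
      v <- ctr - pos[i, ]
      if (vnorm(v) < 1e-8) {
        warning("atom ", a$name[i], " has no bonds and no centroid direction; using x-axis")
        v <- c(1, 0, 0)
      } else {
        message("atom ", a$name[i], " (residue ", a$res_index[i],
                "): no template bond, centroid fallback")
      }
      e[i, ] <- unitize(v)
      next
    }
    m <- ATOM_MASS[a$element[js]]
    best <- js[m == max(m)]
    if (length(best) > 1L) best <- best[order(a$name[best])][1L]
    e[i, ] <- unitize(pos[best, ] - pos[i, ])
  }
  s$atoms$ex <- e[, 1L]; s$atoms$ey <- e[, 2L]; s$atoms$ez <- e[, 3L]
  s
}

#' Detect residue chirality from geometry
#'
#' The sign of the signed volume (N-CA, C-CA, CB-CA) — equivalently the
#' improper dihedral N-CA-C-CB — separates L from D; positive is L.
#' Glycine is achiral; D-prefixed residue names (DAL, DSN, ...) force D;
#' a missing CB on a non-glycine residue yields achiral with a warning.
#'
#' @param s a [protein_structure()].
#' @return Character vector (length `nres`) in `{"L","D","achiral"}`.
#' @export
detect_chirality <- function(s) {
  a <- s$atoms
  out <- character(s$nres)
  for (ri in seq_len(s$nres)) {
    if (s$residues$resname[ri] %in% names(topology()$d_aliases)) {
      out[ri] <- "D"; next
    }
    if (s$residues$template[ri] == "GLY") { out[ri] <- "achiral"; next }
    rows <- which(a$res_index == ri)
    get <- function(nm) {
      k <- rows[match(nm, a$name[rows])]
      if (is.na(k)) return(NULL)
      c(a$x[k], a$y[k], a$z[k])
    }
    N <- get("N"); CA <- get("CA"); C <- get("C"); CB <- get("CB")
    if (is.null(N) || is.null(CA) || is.null(C) || is.null(CB)) {
      warning("residue ", ri, " (", s$residues$resname[ri],
              "): missing backbone/CB atoms, chirality set to achiral")
      out[ri] <- "achiral"; next
    }
    v <- sum(cross3(N - CA, C - CA) * (CB - CA))
    out[ri] <- if (v > 0) "L" else "D"
  }
  out
}
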