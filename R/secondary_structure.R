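# Four-group secondary-structure assignment: alpha-helix (H), beta-
# strand (E), coil (C) and other (O; turns, bridges and the rest).
# The assigner combines backbone hydrogen-bond energetics (electrostatic
# model with partial charges on N-H and C=O, amide H rebuilt from the
# preceding peptide group) with a right-handed phi/psi gate for helices,
# then collapses to the four groups. Precomputed STRIDE or DSSP output
# can be ingested instead, which is the route to bit-compatibility with
# the reference assigners on real PDB entries.

#' Secondary-structure assignment constants
#'
#' All tunables of [assign_ss()] in one list: hydrogen-bond partial
#' charges and cutoff (kcal/mol), the N-H bond length used to rebuild
#' amide hydrogens, and the right-handed helical phi/psi window
#' (degrees) that a residue must satisfy to be classed H.
#'
#' @param hb_q1q2f electrostatic prefactor q1*q2*f (kcal/mol * A).
#' @param hb_cutoff hydrogen-bond energy threshold (kcal/mol).
#' @param nh_bond N-H bond length (A).
#' @param phi_helix,psi_helix numeric length-2 windows (degrees).
#' @return Named list of constants.
#' @export
ss_config <- function(hb_q1q2f = 0.42 * 0.20 * 332,
                      hb_cutoff = -0.5,
                      nh_bond = 1.0,
                      phi_helix = c(-100, -30),
                      psi_helix = c(-80, 10)) {
  list(hb_q1q2f = hb_q1q2f, hb_cutoff = hb_cutoff, nh_bond = nh_bond,
       phi_helix = phi_helix, psi_helix = psi_helix)
}

backbone_coords <- function(s) {
  a <- s$atoms
  pick <- function(nm) {
    m <- matrix(NA_real_, s$nres, 3L)
    rows <- which(a$name == nm)
    m[a$res_index[rows], ] <- cbind(a$x[rows], a$y[rows], a$z[rows])
    m
  }
  list(N = pick("N"), CA = pick("CA"), C = pick("C"), O = pick("O"),
       chain = s$residues$chain)
}

# Rebuild amide H: along the bisector of (N - C_prev) and (N - O_prev).
amide_h <- function(bb, nh_bond) {
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3L)
  for (i in 2:n) {
    if (bb$chain[i] != bb$chain[i - 1L]) next
    if (any(is.na(bb$N[i, ])) || any(is.na(bb$C[i - 1L, ])) ||
        any(is.na(bb$O[i - 1L, ]))) next
    d1 <- unitize(bb$N[i, ] - bb$C[i - 1L, ])
    d2 <- unitize(bb$N[i, ] - bb$O[i - 1L, ])
    H[i, ] <- bb$N[i, ] + nh_bond * unitize(d1 + d2)
  }
  H
}

# hb[i, j]: TRUE when the amide N-H of residue i donates to the C=O of
# residue j with electrostatic energy below the cutoff.
hbond_matrix <- function(bb, H, cfg) {
  n <- nrow(bb$N)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ])) || any(is.na(bb$N[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L && bb$chain[i] == bb$chain[j]) next
      if (any(is.na(bb$C[j, ])) || any(is.na(bb$O[j, ]))) next
      rON <- vnorm(bb$O[j, ] - bb$N[i, ])
      if (rON > 5.2) next
      rCH <- vnorm(bb$C[j, ] - H[i, ])
      rOH <- vnorm(bb$O[j, ] - H[i, ])
      rCN <- vnorm(bb$C[j, ] - bb$N[i, ])
      e <- cfg$hb_q1q2f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[i, j] <- is.finite(e) && e < cfg$hb_cutoff
    }
  }
  hb
}

phi_psi <- function(bb) {
  n <- nrow(bb$N)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && bb$chain[i] == bb$chain[i - 1L] &&
        !any(is.na(c(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ]))))
      phi[i] <- dihedral(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i < n && bb$chain[i] == bb$chain[i + 1L] &&
        !any(is.na(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ]))))
      psi[i] <- dihedral(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])
  }
  list(phi = phi, psi = psi)
}

#' Assign four-group secondary structure
#'
#' Residues are classed H (alpha- and 3-10 helices), E (extended
#' strands in ladders), O (turns, isolated bridges) or C (coil). Helix
#' detection requires both the i -> i+4 (or i -> i+3) hydrogen-bond
#' pattern and right-handed helical backbone torsions, so mirror-image
#' (left-handed) helices are not classed H.
#'
#' @param s a [protein_structure()].
#' @param config constants from [ss_config()].
#' @return The structure with `residues$ss` filled.
#' @export
assign_ss <- function(s, config = ss_config()) {
  n <- s$nres
  bb <- backbone_coords(s)
  usable <- rowSums(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O)) == 0
  if (n < 3L || sum(usable) < 3L) {
    warning("chain too short for secondary-structure patterns; all residues set to coil")
    s$residues$ss <- rep("C", n)
    s$atoms$ss <- s$residues$ss[s$atoms$res_index]
    return(s)
  }
  H <- amide_h(bb, config$nh_bond)
  hb <- hbond_matrix(bb, H, config)
  tor <- phi_psi(bb)

  same_chain_run <- function(i, j) {
    all(bb$chain[i:j] == bb$chain[i])
  }
  helical_torsion <- function(i) {
    ok_phi <- is.na(tor$phi[i]) ||
      (tor$phi[i] >= config$phi_helix[1L] && tor$phi[i] <= config$phi_helix[2L])
    ok_psi <- is.na(tor$psi[i]) ||
      (tor$psi[i] >= config$psi_helix[1L] && tor$psi[i] <= config$psi_helix[2L])
    ok_phi && ok_psi && !(is.na(tor$phi[i]) && is.na(tor$psi[i]))
  }

  cls <- rep("C", n)
  turnish <- rep(FALSE, n)

  # helices: two consecutive i -> i+4 (alpha) or i -> i+3 (3-10) H-bonds
  for (step in c(4L, 3L)) {
    hbk <- function(i) i + step <= n && same_chain_run(i, i + step) && hb[i + step, i]
    for (i in seq_len(max(0L, n - step - 1L))) {
      if (hbk(i) && hbk(i + 1L)) {
        for (r in (i + 1L):(i + step)) if (helical_torsion(r)) cls[r] <- "H"
      }
    }
    # lone helical turns count toward "other"
    for (i in seq_len(max(0L, n - step))) if (hbk(i)) turnish[(i + 1L):(i + step - 1L)] <- TRUE
  }

  # beta bridges (DSSP geometry), ladders -> E, isolated bridges -> other
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1L)) {
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L && bb$chain[i] == bb$chain[j]) next
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      para <- (hb[j, i - 1L] && hb[i + 1L, j]) || (hb[i, j - 1L] && hb[j + 1L, i])
      if (anti || para) bridge[i, j] <- TRUE
    }
  }
  bridged <- apply(bridge, 1L, any)
  for (i in which(bridged)) {
    ladder <- (i > 1L && bridged[i - 1L]) || (i < n && bridged[i + 1L])
    if (cls[i] != "H") cls[i] <- if (ladder) "E" else "O"
  }
  cls[cls == "C" & turnish] <- "O"

  s$residues$ss <- cls
  s$atoms$ss <- cls[s$atoms$res_index]
  s
}

#' Secondary-structure content fractions
#'
#' Residue counts per class divided by the residue count Nr.
#'
#' @param s a [protein_structure()] after [assign_ss()] (or with
#'   externally ingested classes), or a character vector of classes.
#' @return Named numeric `c(a, b, c, o)` (helix, strand, coil, other),
#'   summing to 1.
#' @export
ss_content <- function(s) {
  cls <- if (is.character(s)) s else s$residues$ss
  if (length(cls) == 0L) stop("empty structure: no residues")
  if (any(is.na(cls))) stop("secondary structure not assigned; run assign_ss() first")
  n <- length(cls)
  c(a = sum(cls == "H") / n, b = sum(cls == "E") / n,
    c = sum(cls == "C") / n, o = sum(cls == "O") / n)
}

map_ss_code <- function(code) {
  code <- toupper(code)
  out <- rep("O", length(code))
  out[code %in% c("H", "G", "I")] <- "H"
  out[code %in% c("E", "B")] <- "E"
  out[code == "C" | code == " " | code == "-"] <- "C"
  out
}

#' Read a STRIDE output file
#'
#' Parses ASG records and collapses the STRIDE classes to the four
#' groups (H/G/I -> H, E/B -> E, C -> C, turns and the rest -> O).
#'
#' @param path STRIDE output containing ASG records.
#' @return data.frame with `chain`, `resno`, `icode`, `ss`.
#' @export
read_stride <- function(path) {
  lines <- grep("^ASG", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) stop("format error: no ASG records in ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  df <- do.call(rbind, lapply(tok, function(t) {
    data.frame(chain = t[3L], resno_raw = t[4L], ss_code = t[6L],
               stringsAsFactors = FALSE)
  }))
  ic <- sub("^[-0-9]+", "", df$resno_raw)
  data.frame(chain = df$chain,
             resno = as.integer(sub("[A-Za-z]$", "", df$resno_raw)),
             icode = ifelse(nzchar(ic), ic, " "),
             ss = map_ss_code(df$ss_code),
             stringsAsFactors = FALSE)
}

#' Read a classic DSSP output file
#'
#' Fixed-column parse of the per-residue block; classes are collapsed
#' to the four groups (H/G/I -> H, E/B -> E, blank -> C, rest -> O).
#'
#' @param path DSSP (.dssp) file.
#' @return data.frame with `chain`, `resno`, `icode`, `ss`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr)) stop("format error: not a classic DSSP file: ", path)
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
  data.frame(chain = substr(body, 12, 12),
             resno = as.integer(substr(body, 6, 10)),
             icode = ifelse(nzchar(trimws(substr(body, 11, 11))),
                            substr(body, 11, 11), " "),
             ss = map_ss_code(substr(body, 17, 17)),
             stringsAsFactors = FALSE)
}

#' Apply an external secondary-structure assignment
#'
#' Matches on (chain, resno, icode); residues absent from the table are
#' classed C with a warning.
#'
#' @param s a [protein_structure()].
#' @param ss_table data.frame from [read_stride()] or [read_dssp()].
#' @return The structure with `residues$ss` filled.
#' @export
apply_ss <- function(s, ss_table) {
  key_s <- paste(s$residues$chain, s$residues$resno, s$residues$icode)
  key_t <- paste(ss_table$chain, ss_table$resno, ss_table$icode)
  idx <- match(key_s, key_t)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " residue(s) missing from the external assignment; set to coil")
  cls <- ifelse(is.na(idx), "C", ss_table$ss[idx])
  s$residues$ss <- cls
  s$atoms$ss <- cls[s$atoms$res_index]
  s
}
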