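# Complex atomic polarizability curves, the library that houses them,
# content-weighted blending of a protein-specific set, atom typing and
# the D-residue sign flip.
#
# Units are arbitrary-but-consistent: only the products
# alpha_i * alpha_j * C_ij * G_ij are physical, so the overall scale
# lives in the library (fixed there by calibration), never in the
# forward-model kernel.

#' Construct a polarizability curve
#'
#' @param type_label identifier of the atom type the curve belongs to.
#' @param grid wavelengths in nm, strictly increasing.
#' @param values complex polarizability at each wavelength.
#' @return Object of class `polar_curve`.
#' @export
polar_curve <- function(type_label, grid, values) {
  grid <- as.numeric(grid)
  values <- as.complex(values)
  if (length(grid) != length(values)) stop("grid/values length mismatch")
  if (length(grid) > 1L && any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("non-finite polarizability values")
  structure(list(type_label = type_label, grid = grid, values = values),
            class = "polar_curve")
}

#' Negate the real part of a polarizability curve (D-residues)
#'
#' Atoms of D-amino-acid residues carry the mirror-image polarizability:
#' the real (dispersive) part changes sign, the imaginary (absorptive)
#' part is unchanged. Applying the flip twice restores the input.
#'
#' @param curve a [polar_curve()], or a complex vector/matrix.
#' @return Object of the same shape with `Re` negated pointwise.
#' @export
flip_for_D <- function(curve) {
  if (inherits(curve, "polar_curve")) {
    curve$values <- complex(real = -Re(curve$values), imaginary = Im(curve$values))
    return(curve)
  }
  v <- as.complex(curve)
  out <- complex(real = -Re(v), imaginary = Im(v))
  if (is.matrix(curve)) out <- matrix(out, nrow(curve), dimnames = dimnames(curve))
  out
}

# validate an SSContent vector
check_content <- function(x, what = "content") {
  if (!all(c("a", "b", "c", "o") %in% names(x)))
    stop(what, " must be a named vector with components a, b, c, o")
  x <- x[c("a", "b", "c", "o")]
  if (any(x < -1e-9) || any(x > 1 + 1e-9) || abs(sum(x) - 1) > 1e-6)
    stop(what, " fractions must lie in [0,1] and sum to 1")
  x
}

#' Structural-proximity blend weight
#'
#' Weight of a library base entry for a query protein,
#' `100 * exp(-50 * (|a_i - p_a| + |b_i - p_b| + |c_i - p_c| +
#' |o_i - p_o|)) / ct`: identical secondary-structure contents give the
#' maximal weight 100/ct and the weight decays exponentially with the
#' L1 distance between contents.
#'
#' @param base_content,query_content named fractions `c(a, b, c, o)`.
#' @param ct positive normalization constant.
#' @return Non-negative scalar.
#' @export
blend_weight <- function(base_content, query_content, ct = 1) {
  if (!is.numeric(ct) || length(ct) != 1L || ct <= 0)
    stop("parameter error: ct must be a positive scalar")
  b <- check_content(base_content, "base_content")
  q <- check_content(query_content, "query_content")
  100 * exp(-50 * sum(abs(b - q))) / ct
}

#' Construct a polarizability library
#'
#' Houses base entries (one per training protein: its secondary-
#' structure content plus one curve per atom type) and optional group
#' entries. All entries must share one wavelength grid and one set of
#' type labels.
#'
#' @param grid common wavelength grid (nm).
#' @param base list of entries `list(id, content, curves)` where
#'   `curves` is a complex matrix `length(grid) x n_types` with type
#'   labels as column names.
#' @param groups optional list of entries `list(id, curves)`.
#' @param group_mass total weight allotted to group curves during
#'   blending (split equally among groups); base entries receive the
#'   remaining `1 - group_mass`.
#' @return Object of class `polar_library`.
#' @export
polar_library <- function(grid, base, groups = list(), group_mass = 0.1) {
  if (length(base) == 0L) stop("empty library: at least one base entry is required")
  labels <- colnames(base[[1L]]$curves)
  if (is.null(labels)) stop("entry curves must have type labels as column names")
  for (e in c(base, groups)) {
    if (!identical(dim(e$curves), c(length(grid), length(labels))) ||
        !identical(colnames(e$curves), labels))
      stop("grid/type mismatch across library entries")
    if (!all(is.finite(Re(e$curves)) & is.finite(Im(e$curves))))
      stop("non-finite curves in entry ", e$id)
  }
  for (e in base) e$content <- check_content(e$content, paste0("entry ", e$id))
  if (length(groups) && (group_mass < 0 || group_mass >= 1))
    stop("group_mass must lie in [0, 1)")
  structure(list(grid = as.numeric(grid), labels = labels, base = base,
                 groups = groups, group_mass = if (length(groups)) group_mass else 0),
            class = "polar_library")
}

#' @export
print.polar_library <- function(x, ...) {
  cat(sprintf("<polar_library> %d base entr%s, %d group(s), %d types, %d wavelengths\n",
              length(x$base), if (length(x$base) == 1L) "y" else "ies",
              length(x$groups), length(x$labels), length(x$grid)))
  invisible(x)
}

#' Blend a protein-specific polarizability set
#'
#' Forms one curve per atom type as the weighted sum of group curves
#' (fixed equal weights summing to the library's `group_mass`) and base
#' curves (structural-proximity weights from [blend_weight()]), with the
#' normalization constant ct chosen so all weights sum to 1. The same
#' set serves every atom of the protein (a mean-field-like choice).
#'
#' @param query_content named fractions `c(a, b, c, o)` of the query
#'   protein.
#' @param lib a [polar_library()].
#' @return List with `grid`, `labels`, `curves` (complex matrix
#'   `n_grid x n_types`), `weights` (named, summing to 1) and `ct`.
#' @export
assign_protein_polarizabilities <- function(query_content, lib) {
  if (!inherits(lib, "polar_library")) stop("lib must be a polar_library")
  q <- check_content(query_content, "query_content")
  u <- vapply(lib$base, function(e)
    100 * exp(-50 * sum(abs(check_content(e$content) - q))), numeric(1))
  cg_total <- lib$group_mass
  su <- sum(u)
  if (su <= 0) stop("degenerate blend: all base weights underflowed to zero")
  ct <- su / (1 - cg_total)
  cb <- u / ct
  cg <- if (length(lib$groups)) rep(cg_total / length(lib$groups), length(lib$groups)) else numeric(0)

  curves <- matrix(0 + 0i, length(lib$grid), length(lib$labels),
                   dimnames = list(NULL, lib$labels))
  for (k in seq_along(lib$groups)) curves <- curves + cg[k] * lib$groups[[k]]$curves
  for (k in seq_along(lib$base))   curves <- curves + cb[k] * lib$base[[k]]$curves

  w <- c(cg, cb)
  names(w) <- c(vapply(lib$groups, `[[`, "", "id"), vapply(lib$base, `[[`, "", "id"))
  list(grid = lib$grid, labels = lib$labels, curves = curves, weights = w, ct = ct)
}

# ---- atom typing ------------------------------------------------------------

#' Load an atom-typing table
#'
#' The table is data, not code: a YAML file with `labels`, `rules`
#' (element/role/ss patterns, "*" wildcards, optional exact atom name)
#' and per-element `fallback` labels. The package ships a 21-type
#' default and a minimal 3-type element table for synthetic corpora.
#'
#' @param path YAML file; default is the shipped 21-type table.
#' @return List with `name`, `labels`, `rules`, `fallback`.
#' @export
load_typing_table <- function(path = pkg_file("extdata", "typing_default.yaml")) {
  tab <- yaml::read_yaml(path)
  if (is.null(tab$labels) || is.null(tab$rules) || is.null(tab$fallback))
    stop("typing table needs labels, rules and fallback sections: ", path)
  tab
}

atom_role <- function(name) {
  if (name %in% c("N", "C", "O", "OXT")) return("backbone")
  if (name == "CA") return("calpha")
  if (name %in% c("H", "HN", "H1", "H2", "H3")) return("amide_h")
  if (name %in% c("HA", "HA2", "HA3")) return("backbone_h")
  "sidechain"
}

#' Type a single atom
#'
#' Deterministic table lookup keyed on (element, structural role,
#' residue secondary-structure class); unmatched atoms fall back to the
#' per-element default label (logged via `message()`).
#'
#' @param element one of H, C, N, O, S.
#' @param name PDB atom name (decides the role).
#' @param ss residue class in `{H, E, C, O}`.
#' @param table typing table from [load_typing_table()].
#' @return A type label from `table$labels`.
#' @export
type_atom <- function(element, name, ss, table = load_typing_table()) {
  role <- atom_role(name)
  for (r in table$rules) {
    if (r$element != element) next
    if (!identical(r$role, "*") && r$role != role) next
    if (!identical(r$ss, "*") && r$ss != ss) next
    if (!is.null(r$atom) && r$atom != name) next
    return(r$label)
  }
  fb <- table$fallback[[element]]
  if (is.null(fb)) stop("typing error: no rule or fallback for element ", element,
                        " (atom ", name, ")")
  message("atom ", name, " (", element, "): fallback label ", fb)
  fb
}

#' Assign polarizability type labels to every atom
#'
#' @param s a [protein_structure()] with secondary structure assigned.
#' @param table typing table from [load_typing_table()].
#' @return The structure with `atoms$type_label` filled.
#' @export
assign_atom_types <- function(s, table = load_typing_table()) {
  if (any(is.na(s$residues$ss)))
    stop("secondary structure not assigned; run assign_ss() first")
  ss <- s$residues$ss[s$atoms$res_index]
  labs <- character(nrow(s$atoms))
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(s$atoms))) {
    key <- paste(s$atoms$element[i], s$atoms$name[i], ss[i])
    hit <- memo[[key]]
    if (is.null(hit)) {
      hit <- suppressMessages(
        type_atom(s$atoms$element[i], s$atoms$name[i], ss[i], table))
      memo[[key]] <- hit
    }
    labs[i] <- hit
  }
  s$atoms$type_label <- labs
  s
}

# ---- library file format ----------------------------------------------------

entry_to_tsv <- function(entry, grid, path) {
  labs <- colnames(entry$curves)
  df <- data.frame(wavelength = grid)
  for (l in labs) {
    df[[paste0(l, "_re")]] <- Re(entry$curves[, l])
    df[[paste0(l, "_im")]] <- Im(entry$curves[, l])
  }
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

tsv_to_curves <- function(path, labels) {
  df <- utils::read.delim(path, check.names = FALSE)
  grid <- df$wavelength
  curves <- matrix(0 + 0i, length(grid), length(labels),
                   dimnames = list(NULL, labels))
  for (l in labels)
    curves[, l] <- complex(real = df[[paste0(l, "_re")]],
                           imaginary = df[[paste0(l, "_im")]])
  list(grid = grid, curves = curves)
}

#' Write a polarizability library to a directory
#'
#' One TSV per entry (columns wavelength, then Re/Im per type) plus a
#' YAML manifest carrying the grid, type labels, per-entry secondary-
#' structure contents and the group mass.
#'
#' @param lib a [polar_library()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_polar_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "cdosc-polar-library-1",
    labels = as.list(lib$labels),
    grid = list(min = min(lib$grid), max = max(lib$grid), n = length(lib$grid)),
    group_mass = lib$group_mass,
    base = lapply(lib$base, function(e)
      list(id = e$id, file = paste0("base_", e$id, ".tsv"),
           content = as.list(e$content))),
    groups = lapply(lib$groups, function(e)
      list(id = e$id, file = paste0("group_", e$id, ".tsv")))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (e in lib$base) entry_to_tsv(e, lib$grid, file.path(dir, paste0("base_", e$id, ".tsv")))
  for (e in lib$groups) entry_to_tsv(e, lib$grid, file.path(dir, paste0("group_", e$id, ".tsv")))
  invisible(dir)
}

#' Read a polarizability library from a directory
#'
#' Strict grid equality across entries is enforced at load.
#'
#' @param dir directory written by [write_polar_library()].
#' @return A [polar_library()].
#' @export
read_polar_library <- function(dir) {
  mf <- file.path(dir, "manifest.yaml")
  if (!file.exists(mf)) stop("no such library: missing ", mf)
  manifest <- yaml::read_yaml(mf)
  labels <- unlist(manifest$labels)
  grid <- NULL
  load_entry <- function(rec, with_content) {
    parsed <- tsv_to_curves(file.path(dir, rec$file), labels)
    if (is.null(grid)) grid <<- parsed$grid
    else if (!isTRUE(all.equal(grid, parsed$grid)))
      stop("grid mismatch across entries in ", dir)
    e <- list(id = rec$id, curves = parsed$curves)
    if (with_content) e$content <- unlist(rec$content)
    e
  }
  base <- lapply(manifest$base, load_entry, with_content = TRUE)
  groups <- lapply(manifest$groups, load_entry, with_content = FALSE)
  polar_library(grid, base, groups,
                group_mass = if (length(groups)) manifest$group_mass else 0.1)
}
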