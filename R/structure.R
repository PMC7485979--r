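#' Hierarchical protein structure container
#'
#' A `pdb_structure` stores heavy-atom coordinates as a flat atom table
#' (one row per atom) plus a structure id. Residues are identified throughout
#' the package by *residue keys* of the form `"<chain>:<number><icode>"`
#' (author numbering, e.g. `"A:310"` or `"H:100A"`); no renumbering is ever
#' performed, so positions quoted in the literature (EU antibody numbering
#' and the like) can be used verbatim.
#'
#' @param atom data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter residue name), `elety` (atom name), `elesy` (element symbol),
#'   `x`, `y`, `z`, `o` (occupancy).
#' @param id character label for the structure.
#' @return An object of class `pdb_structure`.
#' @examples
#' s <- make_toy_complex(toy_spec(3, 3, contacts = cbind(1:3, 1:3)))
#' s
#' residue_keys(s)
#' @export
pdb_structure <- function(atom, id = "structure") {
  stopifnot(is.data.frame(atom))
  needed <- c("chain", "resno", "insert", "resid", "elety", "elesy",
              "x", "y", "z", "o")
  miss <- setdiff(needed, names(atom))
  if (length(miss) > 0L)
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atom) == 0L) stop("empty structure: no atoms")
  atom$insert[is.na(atom$insert)] <- ""
  atom$o[is.na(atom$o)] <- 1
  if (any(!is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)))
    stop("non-finite coordinates in atom table")
  if (any(atom$o < 0 | atom$o > 1))
    stop("occupancy outside [0, 1]")
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  ch <- chain_ids(x)
  nres <- vapply(ch, function(cc)
    length(unique(residue_key(x$atom$chain, x$atom$resno, x$atom$insert)[
      x$atom$chain == cc])), integer(1))
  cat(sprintf("<pdb_structure '%s'> %d atoms, %d chain(s)\n",
              x$id, nrow(x$atom), length(ch)))
  cat(paste(sprintf("  chain %s: %d residues", ch, nres), collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

#' Build residue keys from components
#'
#' @param chain,resno,insert vectors of chain id, author residue number and
#'   insertion code (`""` or `NA` for none).
#' @return Character vector `"<chain>:<number><icode>"`.
#' @export
residue_key <- function(chain, resno, insert = "") {
  insert[is.na(insert)] <- ""
  paste0(chain, ":", resno, insert)
}

#' Split residue keys into components
#'
#' @param key character vector of residue keys as produced by [residue_key()].
#' @return data.frame with columns `chain`, `resno`, `insert`.
#' @export
parse_residue_key <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", key))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed residue key(s): ", paste(key[bad], collapse = ", "))
  data.frame(chain  = vapply(m, `[`, character(1), 2L),
             resno  = as.integer(vapply(m, `[`, character(1), 3L)),
             insert = vapply(m, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Chain identifiers of a structure, in order of first appearance
#' @param s a [pdb_structure()].
#' @export
chain_ids <- function(s) unique(s$atom$chain)

#' Residue keys of a structure, in atom-table order
#'
#' @param s a [pdb_structure()].
#' @param chains optional chain ids to restrict to.
#' @return Character vector of unique residue keys.
#' @export
residue_keys <- function(s, chains = NULL) {
  a <- s$atom
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  unique(residue_key(a$chain, a$resno, a$insert))
}

## atom-table rows with residue keys attached
.akeys <- function(s) residue_key(s$atom$chain, s$atom$resno, s$atom$insert)

#' Coordinates of a structure as an n x 3 matrix
#'
#' @param s a [pdb_structure()].
#' @param keys optional residue keys to restrict to.
#' @param elety optional atom names to restrict to (e.g. `"CA"` or
#'   `c("N","CA","C","O")`).
#' @return Numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(s, keys = NULL, elety = NULL) {
  sel <- rep(TRUE, nrow(s$atom))
  if (!is.null(keys))  sel <- sel & (.akeys(s) %in% keys)
  if (!is.null(elety)) sel <- sel & (s$atom$elety %in% elety)
  as.matrix(s$atom[sel, c("x", "y", "z"), drop = FALSE])
}

#' One-letter sequence of a chain
#'
#' Unknown 3-letter codes map to `X`.
#' @param s a [pdb_structure()].
#' @param chain a single chain id.
#' @return Single character string.
#' @export
chain_sequence <- function(s, chain) {
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no such chain: ", chain)
  keys <- residue_key(a$chain, a$resno, a$insert)
  res3 <- a$resid[!duplicated(keys)]
  paste(vapply(res3, function(r) {
    one <- bio3d::aa321(r)
    if (is.na(one)) "X" else one
  }, character(1)), collapse = "")
}

#' Apply a rigid transform to (part of) a structure
#'
#' Rotates coordinates by `rotation` (about the origin) and then adds
#' `translation`. Used to build decoys and to test rigid invariance.
#'
#' @param s a [pdb_structure()].
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @param chains chains to transform (default: all).
#' @return The transformed [pdb_structure()].
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0), chains = NULL) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  sel <- if (is.null(chains)) rep(TRUE, nrow(s$atom)) else s$atom$chain %in% chains
  xyz <- as.matrix(s$atom[sel, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) +
    matrix(translation, nrow(xyz), 3, byrow = TRUE)
  s$atom[sel, c("x", "y", "z")] <- xyz
  s
}

## rotation matrix about an axis (degrees)
.rot_about <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}
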