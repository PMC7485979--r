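#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired point sets, with the usual determinant correction so that
#' reflections are never returned.
#'
#' @param ref_coords,mov_coords n x 3 matrices of paired points (n >= 3,
#'   non-collinear).
#' @return An object of class `superposition`: a list with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3) and `rmsd` (Angstrom). Applying
#'   `mov %*% t(rotation) + translation` (row-wise) superposes the moving set
#'   onto the reference.
#' @examples
#' pts <- matrix(rnorm(15), 5, 3)
#' sup <- kabsch_superpose(pts, pts + 5) # pure translation
#' sup$rmsd
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref <- as.matrix(ref_coords); mov <- as.matrix(mov_coords)
  if (!all(dim(ref) == dim(mov)) || ncol(ref) != 3L)
    stop("point sets must be equal-sized n x 3 matrices")
  n <- nrow(ref)
  if (n < 3L) stop("need at least 3 points to superpose, got ", n)
  cm_ref <- colMeans(ref); cm_mov <- colMeans(mov)
  rc <- sweep(ref, 2, cm_ref); mc <- sweep(mov, 2, cm_mov)
  ## collinear (or coincident) points leave the rotation underdetermined
  sv_ref <- svd(rc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("degenerate geometry: reference points are collinear")
  h <- crossprod(mc, rc)                 # 3 x 3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- mc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cm_ref - rot %*% cm_mov),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

## paired CA coordinate matrices for two structures
.pair_ca <- function(a, b, pairing) {
  ka <- .akeys(a); kb <- .akeys(b)
  ca_a <- a$atom$elety == "CA"; ca_b <- b$atom$elety == "CA"
  ## one CA per residue (first occurrence wins)
  ia <- which(ca_a)[!duplicated(ka[ca_a])]
  ib <- which(ca_b)[!duplicated(kb[ca_b])]
  if (pairing == "by_author_number") {
    common <- intersect(ka[ia], kb[ib])
    ma <- ia[match(common, ka[ia])]
    mb <- ib[match(common, kb[ib])]
    n_unpaired <- (length(ia) - length(common)) + (length(ib) - length(common))
    list(a = as.matrix(a$atom[ma, c("x", "y", "z")]),
         b = as.matrix(b$atom[mb, c("x", "y", "z")]),
         n_unpaired = n_unpaired)
  } else {
    ## global sequence alignment, chains paired in order of appearance
    cha <- chain_ids(a); chb <- chain_ids(b)
    npair <- min(length(cha), length(chb))
    rows_a <- integer(0); rows_b <- integer(0)
    tot_a <- 0L; tot_b <- 0L
    for (j in seq_len(npair)) {
      ja <- ia[a$atom$chain[ia] == cha[j]]
      jb <- ib[b$atom$chain[ib] == chb[j]]
      tot_a <- tot_a + length(ja); tot_b <- tot_b + length(jb)
      if (length(ja) == 0L || length(jb) == 0L) next
      seq_a <- paste(vapply(a$atom$resid[ja], function(r) {
        v <- bio3d::aa321(r); if (is.na(v)) "X" else v }, character(1)),
        collapse = "")
      seq_b <- paste(vapply(b$atom$resid[jb], function(r) {
        v <- bio3d::aa321(r); if (is.na(v)) "X" else v }, character(1)),
        collapse = "")
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      ii <- 0L; kk <- 0L
      for (col in seq_along(pa)) {
        if (pa[col] != "-") ii <- ii + 1L
        if (pb[col] != "-") kk <- kk + 1L
        if (pa[col] != "-" && pb[col] != "-") {
          rows_a <- c(rows_a, ja[ii]); rows_b <- c(rows_b, jb[kk])
        }
      }
    }
    list(a = as.matrix(a$atom[rows_a, c("x", "y", "z")]),
         b = as.matrix(b$atom[rows_b, c("x", "y", "z")]),
         n_unpaired = (tot_a - length(rows_a)) + (tot_b - length(rows_b)))
  }
}

#' C-alpha RMSD between two structures
#'
#' Pairs residues either by identical author numbering (`by_author_number`,
#' the default, for structures sharing a numbering scheme) or by global
#' sequence alignment of chain sequences (`by_alignment`, for cross-entry
#' comparisons such as an unbound target vs its complexed form), superposes
#' the paired C-alpha atoms by [kabsch_superpose()] and returns the minimized
#' RMSD. Unpaired residues are excluded; their count is reported in the
#' `n_unpaired` attribute (`n_paired` holds the pair count).
#'
#' @param a,b [pdb_structure()] objects.
#' @param pairing `"by_author_number"` or `"by_alignment"`.
#' @return Numeric RMSD (Angstrom) with attributes `n_paired`, `n_unpaired`.
#' @export
ca_rmsd <- function(a, b, pairing = c("by_author_number", "by_alignment")) {
  pairing <- match.arg(pairing)
  pr <- .pair_ca(a, b, pairing)
  if (nrow(pr$a) < 3L)
    stop("fewer than 3 paired C-alpha residues (", nrow(pr$a), ")")
  sup <- kabsch_superpose(pr$a, pr$b)
  structure(sup$rmsd, n_paired = nrow(pr$a), n_unpaired = pr$n_unpaired)
}
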