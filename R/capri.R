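#' Fraction of native contacts (f_nat)
#'
#' The fraction of the reference complex's residue-residue interface
#' contacts (5 Angstrom heavy-atom cutoff by default) that a docking model
#' reproduces. Residues are matched between model and reference by residue
#' key, so both structures must share author numbering.
#'
#' @param model,reference [pdb_structure()] objects of the same complex.
#' @param part a [chain_partition()] valid for both.
#' @param cutoff contact cutoff (Angstrom).
#' @return Fraction in `[0, 1]`; when the reference has no contacts at all
#'   the value is undefined and a flagged `NA` (attribute `undefined`) is
#'   returned with a warning.
#' @export
fnat <- function(model, reference, part, cutoff = 5.0) {
  ref <- residue_contacts(reference, part, cutoff)
  if (nrow(ref) == 0L) {
    warning("reference complex has no contacts: f_nat undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  mod <- residue_contacts(model, part, cutoff)
  rp <- paste(ref$binder_res, ref$target_res, sep = "\r")
  mp <- paste(mod$binder_res, mod$target_res, sep = "\r")
  length(intersect(rp, mp)) / length(rp)
}

## reference-defined interface residue keys (both sides of the partition)
.iface_residues <- function(s, part, iface_cutoff) {
  cc <- .cross_contacts(s, part, iface_cutoff)
  sort(unique(c(cc$binder_res, cc$target_res)))
}

#' Interface RMSD (I-RMSD)
#'
#' Backbone (N, CA, C, O) RMSD over the reference-defined interface residues
#' (any heavy atom within `iface_cutoff` of the other side; 10 Angstrom per
#' CAPRI practice) after optimal superposition on those same atoms. The
#' residue set comes from the reference, not the model, so models are
#' compared on equal footing.
#'
#' @inheritParams fnat
#' @param iface_cutoff interface-residue inclusion distance (Angstrom).
#' @return RMSD in Angstrom (>= 0).
#' @export
irmsd <- function(model, reference, part, iface_cutoff = 10.0) {
  .check_partition(reference, part)
  iface <- .iface_residues(reference, part, iface_cutoff)
  if (length(iface) < 3L)
    stop("fewer than 3 interface residues in the reference (",
         length(iface), ")")
  bb <- c("N", "CA", "C", "O")
  kr <- .akeys(reference); km <- .akeys(model)
  ri <- which(kr %in% iface & reference$atom$elety %in% bb)
  ## match model atoms by (residue key, atom name)
  tag_r <- paste(kr[ri], reference$atom$elety[ri], sep = "\r")
  tag_m <- paste(km, model$atom$elety, sep = "\r")
  mi <- match(tag_r, tag_m)
  ok <- !is.na(mi)
  if (sum(ok) < 9L)
    stop("too few matched interface backbone atoms (", sum(ok), ")")
  kabsch_superpose(as.matrix(reference$atom[ri[ok], c("x", "y", "z")]),
                   as.matrix(model$atom[mi[ok], c("x", "y", "z")]))$rmsd
}

#' Interface-residue recovery of a docking model
#'
#' The fraction of the model's predicted target-side interface residues
#' (its epitope at the contact cutoff) that are interface residues in the
#' reference complex — a precision-style measure of epitope correctness
#' that is insensitive to the binder's orientation.
#'
#' @inheritParams fnat
#' @return Fraction in `[0, 1]`; flagged `NA` with a warning when the model
#'   has an empty interface.
#' @export
interface_recovery <- function(model, reference, part, cutoff = 5.0) {
  pred <- epitope_of_model(model, part, cutoff)
  if (length(pred) == 0L) {
    warning("model has an empty interface: recovery undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  ref <- epitope_of_model(reference, part, cutoff)
  length(intersect(pred, ref)) / length(pred)
}
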