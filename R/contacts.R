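#' Declare the binder/target chain partition of a complex
#'
#' @param binder,target character vectors of chain ids; must be disjoint and
#'   non-empty. Conventionally the binder is the engineered scaffold (e.g. a
#'   repebody) and the target the antigen (e.g. the IgG Fc homodimer).
#' @return An object of class `chain_partition`.
#' @export
chain_partition <- function(binder, target) {
  binder <- as.character(binder); target <- as.character(target)
  if (length(binder) == 0L || length(target) == 0L)
    stop("both sides of the partition must be non-empty")
  if (length(intersect(binder, target)) > 0L)
    stop("binder and target chains overlap: ",
         paste(intersect(binder, target), collapse = ", "))
  structure(list(binder = binder, target = target), class = "chain_partition")
}

.check_partition <- function(s, part) {
  stopifnot(inherits(s, "pdb_structure"), inherits(part, "chain_partition"))
  ch <- chain_ids(s)
  miss <- setdiff(c(part$binder, part$target), ch)
  if (length(miss) > 0L)
    stop("partition chain(s) absent from structure: ",
         paste(miss, collapse = ", "))
  if (!any(s$atom$chain %in% part$binder) || !any(s$atom$chain %in% part$target))
    stop("one side of the partition has no atoms")
  invisible(TRUE)
}

## all cross-partition residue pairs with min heavy-atom distance < cutoff;
## strict inequality at the cutoff for determinism
.cross_contacts <- function(s, part, cutoff) {
  ab <- s$atom[s$atom$chain %in% part$binder, , drop = FALSE]
  at <- s$atom[s$atom$chain %in% part$target, , drop = FALSE]
  xb <- as.matrix(ab[, c("x", "y", "z")])
  xt <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xb^2), rowSums(xt^2), "+") - 2 * tcrossprod(xb, xt)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  kb <- residue_key(ab$chain, ab$resno, ab$insert)
  kt <- residue_key(at$chain, at$resno, at$insert)
  if (nrow(hit) == 0L)
    return(data.frame(binder_res = character(0), target_res = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE))
  pair <- paste(kb[hit[, 1]], kt[hit[, 2]], sep = "\r")
  mind <- tapply(sqrt(d2[hit]), pair, min)
  parts <- strsplit(names(mind), "\r", fixed = TRUE)
  out <- data.frame(binder_res = vapply(parts, `[`, character(1), 1L),
                    target_res = vapply(parts, `[`, character(1), 2L),
                    min_dist = as.numeric(mind), stringsAsFactors = FALSE)
  out[order(out$binder_res, out$target_res), , drop = FALSE]
}

#' Residue-residue contacts across a binder/target partition
#'
#' A binder residue and a target residue are in contact when their minimum
#' heavy-atom distance is strictly below `cutoff` (default 5.0 Angstrom, the
#' CAPRI native-contact convention; a pair exactly at the cutoff is excluded
#' so the result is deterministic under coordinate round-tripping).
#'
#' @param s a [pdb_structure()] of the complex.
#' @param part a [chain_partition()].
#' @param cutoff contact distance in Angstrom.
#' @return A data.frame of class `contact_set` with columns `binder_res`,
#'   `target_res`, `min_dist`, sorted by residue key; the cutoff is stored in
#'   the `cutoff` attribute.
#' @export
residue_contacts <- function(s, part, cutoff = 5.0) {
  .check_partition(s, part)
  out <- .cross_contacts(s, part, cutoff)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_set", class(out))
  out
}

#' Target-side epitope of a docking model
#'
#' Projects the model's contact set onto the target side: the set of target
#' residues contacted by any binder residue. Each docking model thereby
#' hypothesizes an epitope that designed mutations can probe.
#'
#' @inheritParams residue_contacts
#' @return Sorted character vector of target residue keys.
#' @export
epitope_of_model <- function(s, part, cutoff = 5.0) {
  sort(unique(residue_contacts(s, part, cutoff)$target_res))
}

#' Declare structurally equivalent chains (e.g. homodimer protomers)
#'
#' For a C2-symmetric target such as an IgG Fc, every designed mutation is
#' physically duplicated on both protomers. A symmetry map records which
#' chains are copies of each other so positions can be expanded accordingly.
#'
#' @param groups list of character vectors; each vector is one group of
#'   equivalent chain ids. Groups must be disjoint.
#' @return An object of class `symmetry_map`.
#' @export
symmetry_map <- function(groups = list()) {
  groups <- lapply(groups, as.character)
  all_ch <- unlist(groups)
  if (anyDuplicated(all_ch))
    stop("symmetry groups are not disjoint")
  structure(list(groups = groups), class = "symmetry_map")
}

#' Expand target positions over symmetry-equivalent chains
#'
#' For each position, adds the residue with the same author number and
#' insertion code on every chain declared equivalent to the position's chain.
#' Chains not mentioned in the map pass through unchanged. The operation is
#' idempotent and order-independent. If a structure is supplied, equivalent
#' chains lacking the residue raise a warning and the position is kept on the
#' chains where it exists.
#'
#' @param positions character vector of target residue keys.
#' @param sym a [symmetry_map()] (an empty map is the identity).
#' @param s optional [pdb_structure()] used to check that expanded residues
#'   exist.
#' @return Sorted character vector of expanded residue keys.
#' @export
symmetry_expand <- function(positions, sym = symmetry_map(), s = NULL) {
  stopifnot(inherits(sym, "symmetry_map"))
  if (length(positions) == 0L) return(character(0))
  pk <- parse_residue_key(positions)
  out <- character(0)
  have <- if (!is.null(s)) residue_keys(s) else NULL
  for (i in seq_along(positions)) {
    grp <- NULL
    for (g in sym$groups) if (pk$chain[i] %in% g) { grp <- g; break }
    if (is.null(grp)) { out <- c(out, positions[i]); next }
    cand <- residue_key(grp, pk$resno[i], pk$insert[i])
    if (!is.null(have)) {
      missing <- setdiff(cand, have)
      if (length(missing) > 0L) {
        warning("symmetry-equivalent residue(s) absent: ",
                paste(missing, collapse = ", "),
                "; keeping position on existing chains only")
        cand <- intersect(cand, have)
      }
    }
    out <- c(out, cand)
  }
  sort(unique(out))
}
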