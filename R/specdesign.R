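#' Build a homolog alignment with a structural column map
#'
#' Pre-aligned homolog sequences (e.g. the target's orthologs from several
#' species) together with a map from alignment columns to target residue
#' keys, derived from the non-gap columns of the reference species.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (gaps as `-`); names are species labels.
#' @param reference name of the reference species (default: first).
#' @param ref_keys residue keys, in order, for the reference species'
#'   non-gap columns (length must equal the reference's ungapped length).
#' @return An object of class `homolog_alignment`: list with `seqs`,
#'   `reference` and `colmap` (named integer: residue key -> column).
#' @export
homolog_alignment <- function(seqs, reference = names(seqs)[1], ref_keys) {
  seqs <- vapply(seqs, toupper, character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences differ in length")
  if (!reference %in% names(seqs))
    stop("reference species '", reference, "' not in the alignment")
  refc <- strsplit(seqs[[reference]], "")[[1]]
  nongap <- which(refc != "-")
  if (length(ref_keys) != length(nongap))
    stop("ref_keys length (", length(ref_keys),
         ") does not match the reference's ungapped length (",
         length(nongap), ")")
  structure(list(seqs = seqs, reference = reference,
                 colmap = setNames(nongap, ref_keys)),
            class = "homolog_alignment")
}

#' @rdname homolog_alignment
#' @param path FASTA file of pre-aligned sequences (read via
#'   [Biostrings::readAAStringSet()]).
#' @export
read_homolog_alignment <- function(path, reference = NULL, ref_keys) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  if (is.null(reference)) reference <- names(seqs)[1]
  homolog_alignment(seqs, reference, ref_keys)
}

#' Classify target positions by cross-species conservation
#'
#' Each alignment column is classified by the number of distinct amino
#' acids among the species (gaps count as distinct): with three species,
#' one distinct residue means `shared_by_all`, two means `shared_by_two`
#' and three means `unique`. More generally, a fully conserved column is
#' `shared_by_all`, a fully divergent one `unique`, anything between
#' `shared_by_two`. The classification is invariant to species order.
#'
#' @param aln a [homolog_alignment()].
#' @param positions target residue keys to classify (must be mapped to
#'   alignment columns).
#' @return data.frame with columns `position`, `class`, `column`.
#' @export
classify_conservation <- function(aln, positions) {
  stopifnot(inherits(aln, "homolog_alignment"))
  cols <- aln$colmap[positions]
  if (anyNA(cols))
    stop("position(s) not mapped to the alignment: ",
         paste(positions[is.na(cols)], collapse = ", "))
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  nsp <- nrow(mat)
  cls <- vapply(cols, function(cc) {
    nd <- length(unique(mat[, cc]))
    if (nd == 1L) "shared_by_all"
    else if (nd >= nsp) "unique"
    else "shared_by_two"
  }, character(1))
  data.frame(position = positions, class = cls, column = as.integer(cols),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank binder residues by contacts to divergent target positions
#'
#' For each binder residue of the confirmed complex model, counts the
#' contacted target positions whose conservation class is not
#' `shared_by_all`. Binder residues touching many species-divergent
#' positions are the prime candidates for specificity engineering (e.g.
#' loop truncation or reshaping). Ties are broken by residue key.
#'
#' @param model the confirmed complex [pdb_structure()].
#' @param part a [chain_partition()].
#' @param classes output of [classify_conservation()] covering the target
#'   positions of interest (unclassified contacted positions count as
#'   conserved).
#' @param cutoff contact cutoff (Angstrom).
#' @return data.frame with columns `binder_res`, `divergent_contacts`,
#'   `total_contacts`, ranked by descending divergent count.
#' @export
specificity_candidates <- function(model, part, classes, cutoff = 5.0) {
  cc <- residue_contacts(model, part, cutoff)
  if (nrow(cc) == 0L)
    return(data.frame(binder_res = character(0),
                      divergent_contacts = integer(0),
                      total_contacts = integer(0), stringsAsFactors = FALSE))
  divergent <- classes$position[classes$class != "shared_by_all"]
  by_res <- split(cc$target_res, cc$binder_res)
  out <- data.frame(
    binder_res = names(by_res),
    divergent_contacts = vapply(by_res, function(tt)
      length(intersect(unique(tt), divergent)), integer(1)),
    total_contacts = vapply(by_res, function(tt)
      length(unique(tt)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$divergent_contacts, out$binder_res), , drop = FALSE]
}

## charge/hydrophobicity complementarity of two amino acids facing each
## other across an interface
.complementarity <- function(a, b) {
  ca <- .AA_CLASS[[a]]; cb <- .AA_CLASS[[b]]
  if ((ca == "positive" && cb == "negative") ||
      (ca == "negative" && cb == "positive")) return(1)
  if (ca %in% c("positive", "negative") && ca == cb) return(-1)
  if (ca %in% c("nonpolar", "aromatic") && cb %in% c("nonpolar", "aromatic"))
    return(0.5)
  0
}

#' Scan substitutions at binder positions against multiple targets
#'
#' For every (position, substitution, target) triple, predicts the change in
#' binding relative to wild type; negative scores mean a predicted affinity
#' gain. With per-target delta-delta-G tables the tabulated values are
#' returned verbatim (the faithful route when an external predictor is
#' available). The built-in proxy scores a substitution by the loss of
#' charge/hydrophobic complementarity summed over the target residues the
#' position contacts (< 5 Angstrom heavy-atom), relative to wild type — so a
#' substitution that introduces a salt bridge across the interface scores
#' negative. Cysteine and proline are excluded by default. Wild-type
#' "substitutions" score 0 by convention and are excluded from the matrix
#' unless `include_wt = TRUE`.
#'
#' @param positions binder residue keys to scan.
#' @param targets named list of complexes; each element is a list with
#'   `structure` ([pdb_structure()]) and `partition` ([chain_partition()]).
#'   Every scanned position must exist in each complex's binder chains.
#' @param tables optional named list (same names as `targets`) of
#'   [read_ddg_table()] data.frames.
#' @param exclude 1-letter codes never substituted (default `c("C","P")`).
#' @param include_wt keep wild-type rows (score 0)?
#' @param cutoff contact cutoff for the proxy (Angstrom).
#' @return data.frame of class `scan_matrix` with columns `position`, `wt`,
#'   `sub`, `target`, `score`; complete and deterministic.
#' @export
scan_mutations <- function(positions, targets, tables = NULL,
                           exclude = c("C", "P"), include_wt = FALSE,
                           cutoff = 5.0) {
  stopifnot(is.list(targets), length(targets) > 0L)
  if (is.null(names(targets))) stop("targets must be named")
  subs_all <- setdiff(.AA20, exclude)
  rows <- list()
  for (tg in names(targets)) {
    s <- targets[[tg]]$structure
    part <- targets[[tg]]$partition
    .check_partition(s, part)
    keys <- .akeys(s)
    for (p in positions) {
      i <- match(p, keys)
      if (is.na(p) || is.na(i))
        stop("position ", p, " absent from target complex '", tg, "'")
      pk <- parse_residue_key(p)
      if (!(pk$chain %in% part$binder))
        stop("position ", p, " is not on a binder chain of '", tg, "'")
      wt <- bio3d::aa321(s$atom$resid[i])
      if (is.na(wt)) wt <- "A"
      if (is.null(tables)) {
        ## contacted target residues of this position
        xa <- atom_coords(s, keys = p)
        at <- s$atom[s$atom$chain %in% part$target, , drop = FALSE]
        xo <- as.matrix(at[, c("x", "y", "z")])
        d2 <- outer(rowSums(xa^2), rowSums(xo^2), "+") - 2 * tcrossprod(xa, xo)
        hitcols <- unique(which(d2 < cutoff^2, arr.ind = TRUE)[, 2])
        tkeys <- residue_key(at$chain, at$resno, at$insert)[hitcols]
        taa <- vapply(at$resid[hitcols][!duplicated(tkeys)], function(r) {
          v <- bio3d::aa321(r); if (is.na(v)) "A" else v }, character(1))
        base <- sum(vapply(taa, .complementarity, numeric(1), a = wt))
      } else {
        tab <- tables[[tg]]
        if (is.null(tab)) stop("no ddG table for target '", tg, "'")
      }
      for (sb in subs_all) {
        if (sb == wt && !include_wt) next
        sc <- if (sb == wt) 0 else if (is.null(tables)) {
          -(sum(vapply(taa, .complementarity, numeric(1), a = sb)) - base)
        } else {
          key <- paste0(p, ":", wt, ">", sb)
          hit <- match(key, tab$key)
          if (is.na(hit)) stop("mutation absent from ddG table: ", key,
                               " (target '", tg, "')")
          tab$ddg[hit]
        }
        rows[[length(rows) + 1L]] <-
          data.frame(position = p, wt = wt, sub = sb, target = tg,
                     score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scan_matrix", class(out))
  out
}

## aggregate a per-target score vector
.aggregate_scores <- function(v, aggregate) {
  if (aggregate == "worst_case") max(v) else sum(v)
}

#' Greedy two-position design across multiple targets
#'
#' Stage 1 picks, at `pos1`, the substitution minimizing the aggregate score
#' across all targets (`worst_case` = max over targets, the default: the
#' design must help every target; `sum` trades targets off). Stage 2 fixes
#' that choice and picks the best substitution at `pos2`, either from the
#' supplied matrix (additive assumption) or from a `rescan` callback that
#' re-evaluates `pos2` in the mutated background. Ties are broken
#' alphabetically for reproducibility.
#'
#' @param matrix a [scan_mutations()] result covering both positions for all
#'   targets.
#' @param pos1,pos2 binder residue keys.
#' @param aggregate `"worst_case"` or `"sum"`.
#' @param rescan optional `function(sub1)` returning a `scan_matrix` for
#'   `pos2` given the stage-1 substitution.
#' @return An object of class `design_record`: list with `mutations` (two
#'   [mutation_spec()]s), `stage_scores` (per-target scores of each stage)
#'   and `aggregate`.
#' @export
greedy_double_design <- function(matrix, pos1, pos2,
                                 aggregate = c("worst_case", "sum"),
                                 rescan = NULL) {
  aggregate <- match.arg(aggregate)
  pick <- function(mat, pos) {
    m <- mat[mat$position == pos, , drop = FALSE]
    if (nrow(m) == 0L) stop("no candidate substitutions at ", pos)
    agg <- tapply(m$score, m$sub, .aggregate_scores, aggregate = aggregate)
    best <- sort(names(agg)[agg == min(agg)])[1]
    per_target <- setNames(m$score[m$sub == best], m$target[m$sub == best])
    list(sub = best, wt = m$wt[1], per_target = per_target,
         aggregate_value = min(agg))
  }
  s1 <- pick(matrix, pos1)
  mat2 <- if (is.null(rescan)) matrix else rescan(s1$sub)
  s2 <- pick(mat2, pos2)
  structure(list(
    mutations = list(mutation_spec(pos1, s1$wt, s1$sub),
                     mutation_spec(pos2, s2$wt, s2$sub)),
    stage_scores = list(stage1 = s1$per_target, stage2 = s2$per_target),
    aggregate = aggregate,
    aggregate_values = c(stage1 = s1$aggregate_value,
                         stage2 = s2$aggregate_value)),
    class = "design_record")
}

#' @export
print.design_record <- function(x, ...) {
  if (!is.null(x$segment)) {
    cat(sprintf("<design_record> loop replacement at %s: %s -> %s\n",
                x$segment$start, x$segment$removed, x$segment$inserted))
  } else {
    cat("<design_record>",
        paste(vapply(x$mutations, format, character(1)), collapse = " + "),
        sprintf("(aggregate: %s)\n", x$aggregate))
  }
  invisible(x)
}

#' Record a segment (loop) replacement design
#'
#' Sequence-level record of replacing a binder loop, e.g. truncating a
#' specificity-carrying loop to a flexible Gly-Gly linker. The removed and
#' inserted sequences are stored verbatim; no structural remodeling is
#' attempted.
#'
#' @param start_key binder residue key where the removed segment starts.
#' @param removed,inserted amino-acid sequences (1-letter strings).
#' @return An object of class `design_record` with a `segment` field.
#' @export
loop_replacement <- function(start_key, removed, inserted) {
  stopifnot(is.character(removed), is.character(inserted),
            nchar(removed) >= 1L)
  parse_residue_key(start_key)   # validates
  structure(list(segment = list(start = start_key,
                                removed = toupper(removed),
                                inserted = toupper(inserted))),
            class = "design_record")
}
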