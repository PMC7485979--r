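## physicochemical classes used by the disruption proxy and the scan proxy
.AA_CLASS <- c(A = "nonpolar", V = "nonpolar", L = "nonpolar", I = "nonpolar",
               M = "nonpolar", G = "nonpolar",
               F = "aromatic", W = "aromatic", Y = "aromatic",
               S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
               K = "positive", R = "positive", H = "positive",
               D = "negative", E = "negative",
               P = "proline")

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specify a single point mutation
#'
#' @param position target residue key (e.g. `"A:310"`).
#' @param wt,sub wild-type and substituted 1-letter amino-acid codes;
#'   must differ.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(position, wt, sub) {
  stopifnot(length(position) == 1L, wt %in% .AA20, sub %in% .AA20)
  if (wt == sub) stop("wild-type and substitution are identical: ", wt)
  structure(list(position = position, wt = wt, sub = sub),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) {
  pk <- parse_residue_key(x$position)
  sprintf("%s:%s%d%s%s", pk$chain, x$wt, pk$resno, pk$insert, x$sub)
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation>", format(x), "\n"); invisible(x)
}

#' Parse compact mutation strings
#'
#' Accepts the format emitted by [format.mutation_spec()]:
#' `"<chain>:<wt><number><icode><sub>"`, e.g. `"A:H310A"`.
#'
#' @param x character vector of mutation strings.
#' @return A list of [mutation_spec()] objects.
#' @export
parse_mutation <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([A-Z])(-?[0-9]+)([A-Z]?[a-z]?)([A-Z])$", x))
  bad <- vapply(m, length, integer(1)) != 6L
  if (any(bad)) stop("malformed mutation string(s): ",
                     paste(x[bad], collapse = ", "))
  lapply(m, function(g)
    mutation_spec(residue_key(g[2], as.integer(g[4]),
                              toupper(g[5])), g[3], g[6]))
}

#' Cluster epitope residues into spatial binding patches
#'
#' Single-linkage clustering of the union of all models' epitope residues,
#' using C-beta coordinates (C-alpha for glycine) and a joining radius
#' (default 8 Angstrom). Each patch is annotated with the docking models
#' whose epitope intersects it; mutations for one variant are later drawn
#' from a single patch.
#'
#' @param epitopes named list of character vectors: per-model target residue
#'   keys (see [epitope_of_model()]).
#' @param s the target-bearing [pdb_structure()] (used for coordinates).
#' @param radius single-linkage joining distance in Angstrom.
#' @return A list of patches; each patch is a list with `residues` (sorted
#'   keys) and `member_models` (model ids). Patches are ordered by their
#'   smallest residue key.
#' @export
cluster_patches <- function(epitopes, s, radius = 8.0) {
  stopifnot(is.list(epitopes), length(epitopes) > 0L)
  if (is.null(names(epitopes)))
    names(epitopes) <- sprintf("M%02d", seq_along(epitopes))
  univ <- sort(unique(unlist(epitopes)))
  if (length(univ) == 0L) stop("all epitopes are empty")
  have <- residue_keys(s)
  miss <- setdiff(univ, have)
  if (length(miss) > 0L)
    stop("structure lacks epitope residue(s): ", paste(miss, collapse = ", "))
  ## representative point: CB, falling back to CA (glycine)
  coords <- t(vapply(univ, function(k) {
    xyz <- atom_coords(s, keys = k, elety = "CB")
    if (nrow(xyz) == 0L) xyz <- atom_coords(s, keys = k, elety = "CA")
    if (nrow(xyz) == 0L)
      stop("residue ", k, " has neither CB nor CA atom")
    xyz[1, ]
  }, numeric(3)))
  memb <- if (length(univ) == 1L) 1L else
    cutree(hclust(dist(coords), method = "single"), h = radius)
  patches <- lapply(sort(unique(memb)), function(g) {
    res <- sort(univ[memb == g])
    mm <- names(epitopes)[vapply(epitopes, function(e)
      length(intersect(e, res)) > 0L, logical(1))]
    list(residues = res, member_models = mm)
  })
  patches[order(vapply(patches, function(p) p$residues[1], character(1)))]
}

#' Read a per-mutation delta-delta-G table
#'
#' TSV with columns `chain`, `number`, `icode`, `wt`, `sub`, `ddg` — e.g. the
#' output of an external stability/binding predictor run on the candidate
#' mutations.
#'
#' @param path path to the TSV file.
#' @return data.frame with a `key` column (`"chain:numbericode:wt>sub"`).
#' @export
read_ddg_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chain = "character", icode = "character",
                                 wt = "character", sub = "character"))
  needed <- c("chain", "number", "icode", "wt", "sub", "ddg")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0L)
    stop("ddG table lacks column(s): ", paste(miss, collapse = ", "))
  d$icode[is.na(d$icode)] <- ""
  d$key <- paste0(residue_key(d$chain, d$number, d$icode), ":",
                  d$wt, ">", d$sub)
  d
}

#' Predicted binding disruption of a point mutation
#'
#' With an external delta-delta-G table the tabulated value is returned
#' verbatim. Otherwise a coarse built-in proxy is used: the number of
#' cross-partition heavy-atom contacts (< 5 Angstrom) made by the mutated
#' position, multiplied by a substitution-dissimilarity weight (0 when
#' wild type and substitution share a physicochemical class, 1 otherwise).
#' Higher scores mean more disruptive; non-interface positions score 0.
#'
#' @param s the complex [pdb_structure()].
#' @param m a [mutation_spec()] on a target residue.
#' @param part a [chain_partition()].
#' @param table optional data.frame from [read_ddg_table()].
#' @return A single numeric score (arbitrary energy units).
#' @export
score_disruption <- function(s, m, part, table = NULL) {
  stopifnot(inherits(m, "mutation_spec"))
  if (!is.null(table)) {
    pk <- parse_residue_key(m$position)
    key <- paste0(m$position, ":", m$wt, ">", m$sub)
    hit <- match(key, table$key)
    if (is.na(hit)) stop("mutation absent from ddG table: ", key)
    return(table$ddg[hit])
  }
  keys <- .akeys(s)
  if (!(m$position %in% keys)) stop("no such residue: ", m$position)
  res3 <- s$atom$resid[match(m$position, keys)]
  wt_obs <- bio3d::aa321(res3)
  if (!is.na(wt_obs) && wt_obs != m$wt)
    stop("wild-type mismatch at ", m$position, ": structure has ", wt_obs,
         ", mutation says ", m$wt)
  .check_partition(s, part)
  ## heavy-atom contacts of this position across the partition
  pk <- parse_residue_key(m$position)
  side <- if (pk$chain %in% part$target) "target" else "binder"
  other <- if (side == "target") part$binder else part$target
  xa <- atom_coords(s, keys = m$position)
  xo <- as.matrix(s$atom[s$atom$chain %in% other, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xo^2), "+") - 2 * tcrossprod(xa, xo)
  ncontact <- sum(d2 < 25)
  w <- if (identical(.AA_CLASS[[m$wt]], .AA_CLASS[[m$sub]])) 0 else 1
  ncontact * w
}

#' Propose a disruptive substitution for a position
#'
#' A deterministic convention for turning panel positions into concrete
#' mutations: charge reversal for charged residues (D/E -> K, K/R -> E),
#' alanine for histidine and aromatics, lysine otherwise (introducing a
#' charge into a polar/nonpolar site).
#'
#' @param s a [pdb_structure()].
#' @param positions character vector of residue keys.
#' @return A list of [mutation_spec()] objects.
#' @export
propose_substitutions <- function(s, positions) {
  keys <- .akeys(s)
  lapply(positions, function(p) {
    i <- match(p, keys)
    if (is.na(i)) stop("no such residue: ", p)
    wt <- bio3d::aa321(s$atom$resid[i])
    if (is.na(wt)) wt <- "A"
    sub <- switch(.AA_CLASS[[wt]],
                  negative = "K", positive = "E",
                  aromatic = "A",
                  "K")
    if (wt == "H") sub <- "A"
    if (sub == wt) sub <- "E"
    mutation_spec(p, wt, sub)
  })
}

## coverage of a candidate variant: models whose epitope meets the rule
.covers <- function(positions, epitopes, rule) {
  names(epitopes)[vapply(epitopes, function(e) {
    if (rule == "any") length(intersect(positions, e)) > 0L
    else all(positions %in% e)
  }, logical(1))]
}

#' Design a minimal variant panel covering all docking models
#'
#' Builds candidate variants of at most `k` mutations, each drawn from a
#' single spatial patch, and solves the exact minimum set cover: the smallest
#' panel such that every docking model is covered. Under the default
#' coverage rule a variant covers a model when at least one mutated position
#' lies in the model's epitope (so a disrupted binding readout implicates the
#' model). Ties between equal-sized panels are broken by maximal summed
#' disruption score, then lexicographic variant order, so results are
#' reproducible. The best panel is returned together with the next-best
#' distinct panels.
#'
#' @param epitopes named list of per-model target residue keys.
#' @param patches patches from [cluster_patches()].
#' @param k maximum mutations per variant (default 3).
#' @param alternates number of next-best panels to also return (default 2).
#' @param disruption optional named numeric of per-position disruption scores
#'   (names are residue keys); defaults to 0 for all.
#' @param coverage `"any"` (default: one mutated position in the epitope
#'   suffices) or `"all"` (every mutated position must be in the epitope).
#' @param max_candidates safety cap on the candidate pool after coverage
#'   deduplication.
#' @return A list of class `panel_set`: `panels` (list; each panel has
#'   `variants` — each with `positions`, `patch`, `covered_models` — and
#'   `objective` = c(size, total disruption)), and `uncoverable` (model ids
#'   no candidate variant can cover).
#' @export
design_variant_panel <- function(epitopes, patches, k = 3L, alternates = 2L,
                                 disruption = NULL,
                                 coverage = c("any", "all"),
                                 max_candidates = 2000L) {
  coverage <- match.arg(coverage)
  stopifnot(length(epitopes) > 0L, length(patches) > 0L)
  if (is.null(names(epitopes)))
    names(epitopes) <- sprintf("M%02d", seq_along(epitopes))
  if (is.null(disruption)) disruption <- numeric(0)
  dscore <- function(pos) sum(disruption[pos], na.rm = TRUE)

  ## candidate variants: all subsets of size min(k, |patch|) per patch
  ## (coverage is monotone in the mutation set, so smaller subsets are
  ## dominated and need not be enumerated)
  cands <- list()
  for (pi in seq_along(patches)) {
    res <- patches[[pi]]$residues
    take <- min(k, length(res))
    if (length(res) > 16L) {
      ## keep the instance exact but bounded: top residues by disruption
      ord <- order(-ifelse(is.na(disruption[res]), 0, disruption[res]), res)
      res <- sort(res[ord][seq_len(16L)])
    }
    subs <- combn(res, take, simplify = FALSE)
    for (ss in subs)
      cands[[length(cands) + 1L]] <- list(positions = ss, patch = pi)
  }
  cov <- lapply(cands, function(cc) .covers(cc$positions, epitopes, coverage))
  ## models no candidate can cover
  uncoverable <- setdiff(names(epitopes), unique(unlist(cov)))
  todo <- setdiff(names(epitopes), uncoverable)

  ## deduplicate by coverage signature: keep max disruption, then lexicographic
  sig <- vapply(cov, function(x) paste(sort(x), collapse = ","), character(1))
  keep <- logical(length(cands))
  for (u in unique(sig)) {
    idx <- which(sig == u)
    sc <- vapply(idx, function(i) dscore(cands[[i]]$positions), numeric(1))
    lex <- vapply(idx, function(i)
      paste(cands[[i]]$positions, collapse = ","), character(1))
    keep[idx[order(-sc, lex)][1]] <- TRUE
  }
  ## drop candidates covering nothing still to cover
  keep <- keep & vapply(cov, function(x) length(intersect(x, todo)) > 0L,
                        logical(1))
  cands <- cands[keep]; cov <- cov[keep]
  if (length(cands) > max_candidates)
    stop("candidate pool too large (", length(cands), "); raise k or reduce patches")

  if (length(todo) == 0L || length(cands) == 0L) {
    return(structure(list(panels = list(), uncoverable = uncoverable),
                     class = "panel_set"))
  }

  lexkey <- vapply(cands, function(cc)
    paste(cc$positions, collapse = ","), character(1))
  want <- 1L + alternates
  found <- list()
  ## enumerate covers by increasing panel size; within a size, order panels
  ## by total disruption (desc) then lexicographic variant order
  for (size in seq_len(min(length(todo), length(cands)))) {
    hits <- list()
    sel <- combn(length(cands), size, simplify = FALSE)
    for (ss in sel) {
      if (length(unique(unlist(cov[ss]))) >= length(todo) &&
          all(todo %in% unlist(cov[ss])))
        hits[[length(hits) + 1L]] <- ss
    }
    if (length(hits) > 0L) {
      sc <- vapply(hits, function(ss)
        sum(vapply(ss, function(i) dscore(cands[[i]]$positions), numeric(1))),
        numeric(1))
      lx <- vapply(hits, function(ss)
        paste(sort(lexkey[ss]), collapse = ";"), character(1))
      hits <- hits[order(-sc, lx)]
      for (ss in hits) {
        found[[length(found) + 1L]] <- ss
        if (length(found) >= want) break
      }
    }
    if (length(found) >= want) break
  }

  panels <- lapply(found, function(ss) {
    variants <- lapply(sort(lexkey[ss], index.return = TRUE)$ix, function(j) {
      i <- ss[j]
      list(positions = cands[[i]]$positions,
           patch = cands[[i]]$patch,
           covered_models = sort(intersect(cov[[i]], todo)))
    })
    list(variants = variants,
         objective = c(size = length(ss),
                       disruption = sum(vapply(ss, function(i)
                         dscore(cands[[i]]$positions), numeric(1)))))
  })
  structure(list(panels = panels, uncoverable = uncoverable),
            class = "panel_set")
}

#' @export
print.panel_set <- function(x, ...) {
  if (length(x$panels) == 0L) {
    cat("<panel_set> no feasible panel\n")
  } else {
    b <- x$panels[[1]]
    cat(sprintf("<panel_set> best panel: %d variant(s), %d alternate(s)\n",
                b$objective[["size"]], length(x$panels) - 1L))
    for (v in b$variants)
      cat("  variant:", paste(v$positions, collapse = "/"),
          " covers:", paste(v$covered_models, collapse = ","), "\n")
  }
  if (length(x$uncoverable) > 0L)
    cat("  uncoverable models:", paste(x$uncoverable, collapse = ","), "\n")
  invisible(x)
}
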