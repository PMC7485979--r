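#' Construct or read a binding-assay table
#'
#' Kd values (nM) per variant, as measured e.g. by isothermal titration
#' calorimetry. The table must contain a wild-type row with variant id
#' `"WT"` and empty mutation list; variant rows carry semicolon-joined
#' mutation strings in the compact format of [parse_mutation()]
#' (e.g. `"A:H310A;A:N315K;A:H435K"`).
#'
#' @param variant character vector of variant ids (one must be `"WT"`).
#' @param mutations character vector of semicolon-joined mutation strings
#'   (`""` for WT).
#' @param kd_nm positive numeric Kd values in nM.
#' @param n_rep integer replicate counts (default 1).
#' @return data.frame of class `assay_table`; the wild-type Kd is stored in
#'   the `wt_kd` attribute.
#' @export
assay_table <- function(variant, mutations, kd_nm, n_rep = 1L) {
  d <- data.frame(variant = as.character(variant),
                  mutations = as.character(mutations),
                  kd_nm = as.numeric(kd_nm),
                  n_rep = as.integer(n_rep),
                  stringsAsFactors = FALSE)
  if (!"WT" %in% d$variant) stop("assay table lacks a WT row")
  if (any(!is.finite(d$kd_nm) | d$kd_nm <= 0))
    stop("Kd values must be finite and > 0")
  attr(d, "wt_kd") <- d$kd_nm[match("WT", d$variant)]
  class(d) <- c("assay_table", class(d))
  d
}

#' @rdname assay_table
#' @param path CSV file with columns `variant`, `mutations`, `kd_nm`,
#'   `n_rep`.
#' @export
read_assay_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(variant = "character",
                               mutations = "character"))
  needed <- c("variant", "mutations", "kd_nm")
  miss <- setdiff(needed, names(d))
  if (length(miss) > 0L)
    stop("assay table lacks column(s): ", paste(miss, collapse = ", "))
  d$mutations[is.na(d$mutations)] <- ""
  if (is.null(d$n_rep)) d$n_rep <- 1L
  assay_table(d$variant, d$mutations, d$kd_nm, d$n_rep)
}

#' @rdname assay_table
#' @param x an `assay_table`.
#' @export
write_assay_table <- function(x, path) {
  write.csv(as.data.frame(unclass(x))[, c("variant", "mutations", "kd_nm",
                                          "n_rep")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Call per-position binding involvement from Kd fold changes
#'
#' For every single-mutation variant the fold change Kd(variant)/Kd(WT) is
#' computed and the mutated position is called `disrupted` when the fold
#' change is at least `threshold` (default 1.5: a ~1.5-fold Kd increase is
#' treated as a meaningful loss of binding), `neutral` when it is at most
#' `threshold / neutral_slack` (default slack 1, i.e. at most the threshold;
#' the disrupted call takes precedence exactly at the threshold), and
#' `untested` in the slack band between the two. Multi-mutation variants
#' yield variant-level calls only (returned in the `variant_calls`
#' attribute); positions tested only inside multi-mutants remain untested.
#'
#' @param assay an [assay_table()].
#' @param threshold fold-change threshold for a disrupted call.
#' @param neutral_slack >= 1; widens the untested band between neutral and
#'   disrupted.
#' @return data.frame of class `position_calls` with columns `position`,
#'   `status` (`disrupted`/`neutral`), `fold_change`, plus attribute
#'   `variant_calls` (data.frame `variant`, `fold_change`, `status`).
#' @export
call_positions <- function(assay, threshold = 1.5, neutral_slack = 1.0) {
  stopifnot(inherits(assay, "assay_table"), neutral_slack >= 1)
  wt_kd <- attr(assay, "wt_kd")
  if (is.null(wt_kd)) stop("assay table lacks wild-type Kd")
  rows <- assay[assay$variant != "WT", , drop = FALSE]
  classify <- function(fold) {
    if (fold >= threshold) "disrupted"
    else if (fold <= threshold / neutral_slack) "neutral"
    else "untested"
  }
  muts <- strsplit(rows$mutations, ";", fixed = TRUE)
  single <- lengths(muts) == 1L & rows$mutations != ""
  pos <- data.frame(position = character(0), status = character(0),
                    fold_change = numeric(0), stringsAsFactors = FALSE)
  if (any(single)) {
    specs <- lapply(unlist(muts[single]), function(m) parse_mutation(m)[[1]])
    fold <- rows$kd_nm[single] / wt_kd
    pos <- data.frame(
      position = vapply(specs, `[[`, character(1), "position"),
      status = vapply(fold, classify, character(1)),
      fold_change = fold, stringsAsFactors = FALSE)
    pos <- pos[order(pos$position), , drop = FALSE]
    rownames(pos) <- NULL
  }
  vc <- data.frame(variant = rows$variant,
                   fold_change = rows$kd_nm / wt_kd,
                   status = vapply(rows$kd_nm / wt_kd, classify, character(1)),
                   stringsAsFactors = FALSE)
  attr(pos, "variant_calls") <- vc
  class(pos) <- c("position_calls", class(pos))
  pos
}

#' Filter docking models for consistency with position calls
#'
#' A model is consistent when it contacts every disrupted position and no
#' neutral position; untested positions impose no constraint. A position
#' counts as contacted when any of its symmetry-equivalent copies lies in
#' the model's epitope (a monomeric binder engages one protomer of a
#' homodimeric target, but the designed mutation exists on both).
#' Contradictory calls on one position (disrupted and neutral) make every
#' model inconsistent; an empty result is a valid outcome.
#'
#' @param epitopes named list of per-model target residue keys.
#' @param calls a [call_positions()] result (or a data.frame with `position`
#'   and `status` columns).
#' @param sym optional [symmetry_map()] for homodimeric targets.
#' @return Character vector of consistent model ids, in input order.
#' @export
filter_models <- function(epitopes, calls, sym = symmetry_map()) {
  if (is.null(names(epitopes)))
    names(epitopes) <- sprintf("M%02d", seq_along(epitopes))
  if (nrow(calls) == 0L) return(names(epitopes))
  disrupted <- calls$position[calls$status == "disrupted"]
  neutral <- calls$position[calls$status == "neutral"]
  contacted <- function(p, epi)
    length(intersect(symmetry_expand(p, sym), epi)) > 0L
  ok <- vapply(epitopes, function(epi) {
    all(vapply(disrupted, contacted, logical(1), epi = epi)) &&
      !any(vapply(neutral, contacted, logical(1), epi = epi))
  }, logical(1))
  names(epitopes)[ok]
}

## coarse nonbonded parameters per element (sigma in Angstrom, epsilon in
## arbitrary energy units) and integer formal side-chain charges spread over
## the terminal atoms
.LJ_SIGMA <- c(C = 3.40, N = 3.25, O = 2.96, S = 3.56)
.LJ_EPS   <- c(C = 0.086, N = 0.17, O = 0.21, S = 0.25)
.SIGMA_DEFAULT <- 3.30
.EPS_DEFAULT   <- 0.10

.atom_charge <- function(resid, elety) {
  q <- numeric(length(resid))
  q[resid == "ASP" & elety %in% c("OD1", "OD2")] <- -0.5
  q[resid == "GLU" & elety %in% c("OE1", "OE2")] <- -0.5
  q[resid == "LYS" & elety == "NZ"] <- 1
  q[resid == "ARG" & elety %in% c("NH1", "NH2")] <- 0.5
  q
}

#' Coarse interface energy of a docking model
#'
#' The built-in scorer sums, over cross-partition heavy-atom pairs within
#' `cutoff` (default 10 Angstrom), a Lennard-Jones term
#' `4*eps*((sigma/r)^12 - (sigma/r)^6)` with fixed per-element parameters
#' (Lorentz-Berthelot combination) plus a Coulomb term `q_i*q_j/(4*r^2)`
#' using a distance-dependent dielectric of `4r` and integer formal charges
#' on Asp/Glu/Lys/Arg side-chain termini. It is a deterministic coarse
#' stand-in for a minimized all-atom force-field energy; externally computed
#' energies can be supplied instead via `scorer = "table"` (see
#' [read_energy_table()]), which is the faithful route when a force-field
#' pipeline is available. Lower values indicate better interfaces.
#'
#' @param s the complex [pdb_structure()].
#' @param part a [chain_partition()].
#' @param scorer `"builtin"` or `"table"`.
#' @param table named numeric of model energies (required for `"table"`).
#' @param cutoff pair-inclusion distance (Angstrom).
#' @return An object of class `energy_score`: list with `model_id`, `value`,
#'   `source` and `clash` (TRUE when any pair distance < 0.5 Angstrom).
#' @export
score_interface <- function(s, part, scorer = c("builtin", "table"),
                            table = NULL, cutoff = 10.0) {
  scorer <- match.arg(scorer)
  if (scorer == "table") {
    if (is.null(table) || is.na(match(s$id, names(table))))
      stop("model id '", s$id, "' absent from energy table")
    return(structure(list(model_id = s$id,
                          value = as.numeric(table[[s$id]]),
                          source = "imported", clash = FALSE),
                     class = "energy_score"))
  }
  .check_partition(s, part)
  ab <- s$atom[s$atom$chain %in% part$binder, , drop = FALSE]
  at <- s$atom[s$atom$chain %in% part$target, , drop = FALSE]
  xb <- as.matrix(ab[, c("x", "y", "z")])
  xt <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(xb^2), rowSums(xt^2), "+") - 2 * tcrossprod(xb, xt)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(structure(list(model_id = s$id, value = 0,
                          source = "builtin", clash = FALSE),
                     class = "energy_score"))
  r <- pmax(sqrt(d2[hit]), 1e-3)
  clash <- any(r < 0.5)
  eb <- ab$elesy[hit[, 1]]; et <- at$elesy[hit[, 2]]
  sb <- ifelse(eb %in% names(.LJ_SIGMA), .LJ_SIGMA[eb], .SIGMA_DEFAULT)
  st <- ifelse(et %in% names(.LJ_SIGMA), .LJ_SIGMA[et], .SIGMA_DEFAULT)
  epb <- ifelse(eb %in% names(.LJ_EPS), .LJ_EPS[eb], .EPS_DEFAULT)
  ept <- ifelse(et %in% names(.LJ_EPS), .LJ_EPS[et], .EPS_DEFAULT)
  sig <- (sb + st) / 2
  eps <- sqrt(epb * ept)
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  qb <- .atom_charge(ab$resid[hit[, 1]], ab$elety[hit[, 1]])
  qt <- .atom_charge(at$resid[hit[, 2]], at$elety[hit[, 2]])
  coul <- qb * qt / (4 * r^2)
  structure(list(model_id = s$id, value = sum(lj + coul),
                 source = "builtin", clash = clash),
            class = "energy_score")
}

#' @export
print.energy_score <- function(x, ...) {
  cat(sprintf("<energy_score> %s: %.4f (%s)%s\n", x$model_id, x$value,
              x$source, if (x$clash) " [clash]" else ""))
  invisible(x)
}

#' Read an external per-model energy table
#'
#' TSV with columns `model_id`, `energy` (e.g. minimized force-field total
#' energies computed outside the package).
#'
#' @param path path to the TSV file.
#' @return Named numeric vector of energies.
#' @export
read_energy_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(model_id = "character"))
  if (!all(c("model_id", "energy") %in% names(d)))
    stop("energy table must have columns model_id, energy")
  setNames(as.numeric(d$energy), d$model_id)
}

#' Rank filtered models by energy and select the best
#'
#' Sorts the consistent models ascending by energy (ties broken
#' lexicographically by model id) and selects the first. Models outside the
#' filtered set are excluded even when they hold the global energy minimum:
#' energy ranking alone is not a reliable selector, which is exactly why the
#' mutational filter is applied first.
#'
#' @param scores named numeric of energies, a list of `energy_score`
#'   objects, or a data.frame with `model_id` and `value` columns.
#' @param filtered model ids that passed [filter_models()]; default all.
#' @return An object of class `model_ranking`: list with `ranking`
#'   (data.frame `model_id`, `value` in ascending order), `selected` (best
#'   model id, or `NA` when no model is consistent) and `no_consistent`.
#' @export
rank_and_select <- function(scores, filtered = NULL) {
  if (is.list(scores) && length(scores) > 0L &&
      inherits(scores[[1]], "energy_score")) {
    scores <- setNames(vapply(scores, `[[`, numeric(1), "value"),
                       vapply(scores, `[[`, character(1), "model_id"))
  }
  if (is.data.frame(scores))
    scores <- setNames(scores$value, scores$model_id)
  if (is.null(names(scores))) stop("scores must carry model ids")
  if (is.null(filtered)) filtered <- names(scores)
  miss <- setdiff(filtered, names(scores))
  if (length(miss) > 0L)
    stop("filtered model(s) missing from scores: ",
         paste(miss, collapse = ", "))
  keep <- scores[names(scores) %in% filtered]
  if (length(keep) == 0L)
    return(structure(list(
      ranking = data.frame(model_id = character(0), value = numeric(0)),
      selected = NA_character_, no_consistent = TRUE),
      class = "model_ranking"))
  ord <- order(keep, names(keep))
  structure(list(ranking = data.frame(model_id = names(keep)[ord],
                                      value = as.numeric(keep[ord]),
                                      stringsAsFactors = FALSE),
                 selected = names(keep)[ord][1],
                 no_consistent = FALSE),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  if (x$no_consistent) {
    cat("<model_ranking> no consistent model\n")
  } else {
    cat("<model_ranking> selected:", x$selected, "\n")
    print(x$ranking)
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, via [stats::cor()]. A
#' constant input vector leaves the correlation undefined; `NA` is returned
#' with attribute `undefined = TRUE` and a warning.
#'
#' @param x,y equal-length numeric vectors (length >= 3).
#' @return Correlation in `[-1, 1]`, or flagged `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: Spearman correlation undefined")
    return(structure(NA_real_, undefined = TRUE))
  }
  cor(x, y, method = "spearman")
}
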