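## compact idealized residue: heavy-atom offsets around the residue center,
## all within 0.9 Angstrom, so inter-residue distances are controlled by the
## center-to-center geometry
.RES_OFFSETS <- matrix(c(
  -0.60,  0.35, 0.00,   # N
   0.00,  0.00, 0.00,   # CA
   0.60,  0.35, 0.00,   # C
   0.75, -0.40, 0.20,   # O
   0.00, -0.45, 0.60),  # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), c("x", "y", "z")))

.ELEM <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

## emit the atom rows of one residue centered at `center`
.residue_atoms <- function(chain, resno, aa1, center) {
  res3 <- bio3d::aa123(aa1)
  nm <- rownames(.RES_OFFSETS)
  if (aa1 == "G") nm <- setdiff(nm, "CB")   # glycine has no C-beta
  data.frame(chain = chain, resno = resno, insert = "",
             resid = res3, elety = nm, elesy = unname(.ELEM[nm]),
             x = center[1] + .RES_OFFSETS[nm, 1],
             y = center[2] + .RES_OFFSETS[nm, 2],
             z = center[3] + .RES_OFFSETS[nm, 3],
             o = 1, stringsAsFactors = FALSE)
}

#' Specify a deterministic toy binder-target complex
#'
#' Geometry parameters for [make_toy_complex()]: a target chain `T` laid out
#' along the x axis and a binder chain `R` parked `separation` Angstrom away,
#' except that binder residues named in `contacts` hover `contact_gap`
#' Angstrom above their target partner, planting exactly those residue
#' contacts under the 5 Angstrom cutoff.
#'
#' @param n_binder,n_target chain lengths (residues).
#' @param contacts two-column matrix (or data.frame) of planted contacts:
#'   binder residue index, target residue index. May be `NULL` (no
#'   contacts).
#' @param spacing residue-center spacing along the chain (Angstrom); at the
#'   default 6.5 only the planted pairs fall below the 5 Angstrom cutoff.
#' @param separation binder-target distance for non-contacting residues.
#' @param contact_gap center-to-center gap of a planted contact.
#' @param binder_seq,target_seq optional 1-letter sequences (default
#'   poly-Ala).
#' @param seed recorded for provenance; construction is deterministic.
#' @return An object of class `toy_spec`.
#' @export
toy_spec <- function(n_binder, n_target, contacts = NULL, spacing = 6.5,
                     separation = 30, contact_gap = 4.0,
                     binder_seq = NULL, target_seq = NULL, seed = 1L) {
  if (!is.null(contacts)) {
    contacts <- as.matrix(contacts)
    stopifnot(ncol(contacts) == 2L)
    if (any(contacts[, 1] < 1 | contacts[, 1] > n_binder |
            contacts[, 2] < 1 | contacts[, 2] > n_target))
      stop("planted contact indices out of range")
  }
  if (is.null(binder_seq)) binder_seq <- strrep("A", n_binder)
  if (is.null(target_seq)) target_seq <- strrep("A", n_target)
  stopifnot(nchar(binder_seq) == n_binder, nchar(target_seq) == n_target)
  structure(list(n_binder = n_binder, n_target = n_target,
                 contacts = contacts, spacing = spacing,
                 separation = separation, contact_gap = contact_gap,
                 binder_seq = toupper(binder_seq),
                 target_seq = toupper(target_seq), seed = seed),
            class = "toy_spec")
}

#' Generate a toy two-chain complex with a planted contact set
#'
#' Builds idealized poly-peptide chains (compact backbone + C-beta residues)
#' such that [residue_contacts()] at the default 5 Angstrom cutoff returns
#' exactly the planted contact list. The construction is deterministic and
#' self-verifying: if the realized contact set differs from the planted one
#' (e.g. an unrealizable request), an error is raised.
#'
#' @param spec a [toy_spec()].
#' @param id structure id.
#' @return A [pdb_structure()] with binder chain `R` and target chain `T`.
#' @examples
#' s <- make_toy_complex(toy_spec(5, 8, contacts = cbind(1:3, c(2, 3, 6))))
#' residue_contacts(s, chain_partition("R", "T"))
#' @export
make_toy_complex <- function(spec, id = "toy") {
  stopifnot(inherits(spec, "toy_spec"))
  bs <- strsplit(spec$binder_seq, "")[[1]]
  ts <- strsplit(spec$target_seq, "")[[1]]
  ## binder residue -> planted target partner(s)
  partners <- vector("list", spec$n_binder)
  if (!is.null(spec$contacts))
    for (r in seq_len(nrow(spec$contacts)))
      partners[[spec$contacts[r, 1]]] <-
        c(partners[[spec$contacts[r, 1]]], spec$contacts[r, 2])
  ## how many binder residues already placed on each target residue
  stack <- integer(spec$n_target)
  rows <- list()
  for (j in seq_len(spec$n_target))
    rows[[length(rows) + 1L]] <-
      .residue_atoms("T", j, ts[j], c(j * spec$spacing, 0, 0))
  for (i in seq_len(spec$n_binder)) {
    pp <- partners[[i]]
    if (is.null(pp)) {
      center <- c(i * spec$spacing, spec$separation, 0)
    } else if (length(pp) == 1L) {
      stack[pp] <- stack[pp] + 1L
      center <- c(pp * spec$spacing, spec$contact_gap,
                  1.5 * (stack[pp] - 1L))
    } else if (length(pp) == 2L && abs(diff(sort(pp))) == 1L) {
      ## one binder residue bridging two adjacent target residues
      center <- c(mean(pp) * spec$spacing, 3.0, 0)
    } else {
      stop("unrealizable planted contacts for binder residue ", i,
           ": partners must be a single target residue or two adjacent ones")
    }
    rows[[length(rows) + 1L]] <- .residue_atoms("R", i, bs[i], center)
  }
  s <- pdb_structure(do.call(rbind, rows), id = id)
  ## self-verify the planted contact set
  got <- residue_contacts(s, chain_partition("R", "T"), 5.0)
  gp <- paste(got$binder_res, got$target_res)
  want <- if (is.null(spec$contacts)) character(0) else
    paste(residue_key("R", spec$contacts[, 1]),
          residue_key("T", spec$contacts[, 2]))
  if (!setequal(gp, want))
    stop("unrealizable contact list: realized contacts differ from planted ",
         "(", length(setdiff(gp, want)), " extra, ",
         length(setdiff(want, gp)), " missing)")
  s
}

#' Specify a rigid-body decoy schedule
#'
#' Each perturbation rotates the binder about its centroid (z axis) and
#' translates it along `axis`. The identity perturbation — the planted
#' native pose — is always included (prepended if absent).
#'
#' @param rot_deg,trans equal-length numeric vectors of rotations (degrees)
#'   and translations (Angstrom).
#' @param axis translation direction (default away from the interface,
#'   `c(0, 1, 0)` in toy-complex coordinates).
#' @param seed recorded for provenance.
#' @return An object of class `decoy_schedule`.
#' @export
decoy_schedule <- function(rot_deg, trans, axis = c(0, 1, 0), seed = 1L) {
  stopifnot(length(rot_deg) == length(trans), length(axis) == 3L)
  if (!any(rot_deg == 0 & trans == 0)) {
    rot_deg <- c(0, rot_deg); trans <- c(0, trans)
  }
  structure(list(rot_deg = rot_deg, trans = trans,
                 axis = axis / sqrt(sum(axis^2)), seed = seed),
            class = "decoy_schedule")
}

#' Generate a decoy ensemble with oracle quality labels
#'
#' Applies each scheduled rigid perturbation to the binder chains of the
#' native complex and computes the true f_nat and I-RMSD of every decoy
#' against the native (oracle labels for benchmarking scorers and filters).
#'
#' @param native the native complex [pdb_structure()].
#' @param schedule a [decoy_schedule()].
#' @param part a [chain_partition()]; defaults to binder `R`, target `T`
#'   (the toy-complex convention).
#' @return List with `decoys` (named list of structures, `D01`, `D02`, ...,
#'   `D01` being the planted native) and `metrics` (data.frame `model_id`,
#'   `rot_deg`, `trans`, `fnat`, `irmsd`).
#' @export
make_decoy_set <- function(native, schedule,
                           part = chain_partition("R", "T")) {
  stopifnot(inherits(schedule, "decoy_schedule"))
  if (nrow(residue_contacts(native, part)) == 0L)
    stop("native complex has no contacts")
  n <- length(schedule$rot_deg)
  ids <- sprintf("D%02d", seq_len(n))
  bsel <- native$atom$chain %in% part$binder
  centroid <- colMeans(native$atom[bsel, c("x", "y", "z")])
  decoys <- vector("list", n); names(decoys) <- ids
  for (i in seq_len(n)) {
    rot <- .rot_about(c(0, 0, 1), schedule$rot_deg[i])
    d <- native
    xyz <- as.matrix(d$atom[bsel, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, centroid)
    xyz <- xyz %*% t(rot)
    xyz <- sweep(xyz, 2, centroid, "+")
    xyz <- xyz + matrix(schedule$trans[i] * schedule$axis,
                        nrow(xyz), 3, byrow = TRUE)
    d$atom[bsel, c("x", "y", "z")] <- xyz
    d$id <- ids[i]
    decoys[[i]] <- d
  }
  metrics <- data.frame(
    model_id = ids, rot_deg = schedule$rot_deg, trans = schedule$trans,
    fnat = vapply(decoys, function(d)
      as.numeric(fnat(d, native, part)), numeric(1)),
    irmsd = vapply(decoys, function(d) irmsd(d, native, part), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(decoys = decoys, metrics = metrics)
}

#' Generate a C2 homodimer target bound by a monomeric binder
#'
#' Two target chains (`A`, `B`) related by an exact 2-fold rotation about
#' the z axis — the geometry of a homodimer such as an IgG Fc — with a
#' binder chain `R` contacting residues of chain A only. Every designed
#' mutation on such a target is physically duplicated on both protomers,
#' which is what the returned [symmetry_map()] records.
#'
#' @param n_protomer residues per target chain.
#' @param n_binder binder residues.
#' @param contacts two-column matrix: binder residue index, chain-A residue
#'   index.
#' @param spacing,contact_gap geometry as in [toy_spec()].
#' @param offset distance of each protomer from the symmetry axis.
#' @param seed recorded for provenance; construction is deterministic.
#' @return List with `structure` (a [pdb_structure()]), `sym` (the
#'   [symmetry_map()] declaring A and B equivalent), `partition` (binder
#'   `R` vs target `A`,`B`) and `epitope` (the contacted chain-A keys).
#' @export
make_homodimer_complex <- function(n_protomer = 10L, n_binder = 6L,
                                   contacts = cbind(1:3, 3:5),
                                   spacing = 6.5, contact_gap = 4.0,
                                   offset = 15, seed = 1L) {
  contacts <- as.matrix(contacts)
  stopifnot(ncol(contacts) == 2L,
            all(contacts[, 1] >= 1 & contacts[, 1] <= n_binder),
            all(contacts[, 2] >= 1 & contacts[, 2] <= n_protomer))
  rows <- list()
  ## protomer A along +x starting at `offset`
  centersA <- cbind(offset + seq_len(n_protomer) * spacing, 0, 0)
  for (j in seq_len(n_protomer))
    rows[[length(rows) + 1L]] <- .residue_atoms("A", j, "A", centersA[j, ])
  ## protomer B: exact C2 copy (180 degrees about z)
  rot <- .rot_about(c(0, 0, 1), 180)
  for (j in seq_len(n_protomer)) {
    rb <- .residue_atoms("B", j, "A", c(0, 0, 0))
    xyz <- as.matrix(rb[, c("x", "y", "z")]) +
      matrix(centersA[j, ], nrow(rb), 3, byrow = TRUE)
    xyz <- xyz %*% t(rot)
    rb[, c("x", "y", "z")] <- xyz
    rows[[length(rows) + 1L]] <- rb
  }
  ## binder hovers above its chain-A partners
  partners <- setNames(contacts[, 2], contacts[, 1])
  for (i in seq_len(n_binder)) {
    if (as.character(i) %in% names(partners)) {
      j <- partners[[as.character(i)]]
      center <- c(centersA[j, 1], contact_gap, 0)
    } else {
      center <- c(offset + i * spacing, 40, 0)
    }
    rows[[length(rows) + 1L]] <- .residue_atoms("R", i, "A", center)
  }
  s <- pdb_structure(do.call(rbind, rows), id = "homodimer")
  part <- chain_partition("R", c("A", "B"))
  epi <- epitope_of_model(s, part)
  if (any(parse_residue_key(epi)$chain != "A"))
    stop("internal geometry error: binder contacts both protomers")
  list(structure = s, sym = symmetry_map(list(c("A", "B"))),
       partition = part, epitope = epi)
}

#' Simulate binding-assay outcomes for a variant panel
#'
#' Emulates an ITC-style readout: each variant's Kd is the wild-type Kd
#' multiplied by `effect` for every mutated position that lies inside the
#' native epitope (after symmetry expansion), times multiplicative
#' log-normal noise — matching the fold-change character of binding-assay
#' measurements. Single-mutant entries are generated for every panel
#' position in addition to the multi-point variants themselves.
#'
#' @param epitope native target epitope (residue keys).
#' @param panel list of character vectors of position keys (one vector per
#'   variant), or a `panel_set` from [design_variant_panel()] (its best
#'   panel is used).
#' @param wt_kd wild-type Kd in nM (default 128, a typical mid-nanomolar
#'   scaffold-binder affinity).
#' @param effect multiplicative Kd penalty per epitope-contacting mutation
#'   (> 1; default 3, a clearly detectable ~3-fold disruption).
#' @param noise_sd standard deviation of log-normal noise on Kd (default
#'   0.1, i.e. ~10% multiplicative scatter typical of assay replicates).
#' @param seed integer RNG seed; tables are identical for identical seeds.
#' @param sym optional [symmetry_map()] applied to positions before the
#'   epitope-overlap count.
#' @param s optional [pdb_structure()] used to derive wild-type residue
#'   identities for the mutation strings (defaults to Ala -> Lys).
#' @return An [assay_table()].
#' @export
simulate_assay_outcomes <- function(epitope, panel, wt_kd = 128,
                                    effect = 3, noise_sd = 0.1, seed = 1L,
                                    sym = symmetry_map(), s = NULL) {
  stopifnot(effect > 1)
  if (inherits(panel, "panel_set")) {
    if (length(panel$panels) == 0L) stop("panel_set holds no panel")
    panel <- lapply(panel$panels[[1]]$variants, `[[`, "positions")
  }
  stopifnot(is.list(panel), length(panel) > 0L)
  mut_str <- function(p) {
    if (!is.null(s)) format(propose_substitutions(s, p)[[1]])
    else {
      pk <- parse_residue_key(p)
      sprintf("%s:A%d%sK", pk$chain, pk$resno, pk$insert)
    }
  }
  overlap <- function(positions) sum(vapply(positions, function(p)
    length(intersect(symmetry_expand(p, sym), epitope)) > 0L, logical(1)))
  set.seed(seed)
  singles <- sort(unique(unlist(panel)))
  variant <- c("WT", sprintf("Var%d", seq_along(panel)),
               vapply(singles, mut_str, character(1)))
  mutations <- c("", vapply(panel, function(pp)
    paste(vapply(pp, mut_str, character(1)), collapse = ";"), character(1)),
    vapply(singles, mut_str, character(1)))
  nov <- c(0, vapply(panel, overlap, numeric(1)),
           vapply(singles, function(p) overlap(p), numeric(1)))
  noise <- c(1, rlnorm(length(nov) - 1L, 0, noise_sd))
  if (noise_sd == 0) noise[] <- 1
  kd <- wt_kd * effect^nov * noise
  assay_table(variant, mutations, kd, n_rep = 1L)
}
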