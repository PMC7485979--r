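#' Read a PDB file into a structure
#'
#' Parses ATOM (and optionally HETATM) records via [bio3d::read.pdb()] and
#' applies the package's canonical clean-up: hydrogens and deuteriums are
#' dropped (all contact and energy computations concern heavy atoms); for
#' alternate locations of the same atom the highest-occupancy copy is kept,
#' ties broken by alphabetical altloc code; multi-model (e.g. NMR) files
#' contribute a single model chosen by `model_policy`.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` (default) keeps model 1 of a multi-model
#'   file; `"index"` keeps model number `model`.
#' @param model model number used when `model_policy = "index"`.
#' @param include_het if `TRUE`, HETATM records are retained (waters and
#'   ligands are excluded from residue-level analyses by default).
#' @param id structure id; defaults to the file name without extension.
#' @return A [pdb_structure()].
#' @export
read_pdb <- function(path, model_policy = c("first", "index"), model = 1L,
                     include_het = FALSE, id = NULL) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  ## validate coordinate fields before handing to the parser so that a
  ## malformed record is reported with its line number
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("unparseable ATOM record (truncated) at line ", i, " of ", path)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("unparseable coordinate field at line ", i, " of ", path)
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  a <- p$atom
  if (!include_het) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure after record filtering: ", path)
  ## choose the model
  if (!is.null(p$xyz) && is.matrix(p$xyz) && nrow(p$xyz) > 1L) {
    idx <- if (model_policy == "first") 1L else as.integer(model)
    if (idx < 1L || idx > nrow(p$xyz))
      stop("model index ", idx, " out of range (file has ",
           nrow(p$xyz), " models)")
    xyz <- matrix(p$xyz[idx, ], ncol = 3, byrow = TRUE)
    keep_rows <- as.integer(rownames(a))
    if (is.null(keep_rows) || anyNA(keep_rows)) keep_rows <- seq_len(nrow(a))
    a$x <- xyz[keep_rows, 1]; a$y <- xyz[keep_rows, 2]; a$z <- xyz[keep_rows, 3]
  }
  ## element symbol: fall back to first letter of the atom name
  ele <- a$elesy
  guess <- toupper(sub("^[0-9']*", "", a$elety))
  guess <- substr(guess, 1, 1)
  ele[is.na(ele) | ele == ""] <- guess[is.na(ele) | ele == ""]
  a$elesy <- ele
  ## drop hydrogens/deuteriums
  a <- a[!(a$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure (hydrogens only): ", path)
  ## altloc policy: highest occupancy, alphabetical tie-break
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(akey, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")),
         , drop = FALSE]
  ## restore original file order
  a <- a[order(as.integer(a$eleno)), , drop = FALSE]
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb_structure(a[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                      "x", "y", "z", "o")], id = id)
}

#' Write a structure to a PDB file
#'
#' Emits standard fixed-width ATOM records with a TER record after each chain
#' and a final END. Coordinates are rendered to 3 decimals, so a
#' read/write/read round trip is coordinate-stable to 1e-3 Angstrom.
#'
#' @param s a [pdb_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atom
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  if (any(nchar(a$chain) != 1L))
    stop("PDB chain ids must be exactly 1 character; offending: ",
         paste(unique(a$chain[nchar(a$chain) != 1L]), collapse = ", "))
  if (any(a$resno < -999L | a$resno > 9999L))
    stop("residue number outside the PDB field range [-999, 9999]")
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinate outside the PDB field range")
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (ch in unique(a$chain)) {
    rows <- which(a$chain == ch)
    for (i in rows) {
      serial <- serial + 1L
      nm <- a$elety[i]
      nm <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, nm, a$resid[i], ch, a$resno[i],
        ifelse(a$insert[i] == "", " ", a$insert[i]),
        a$x[i], a$y[i], a$z[i], a$o[i], 0, a$elesy[i]), con)
    }
    last <- rows[length(rows)]
    serial <- serial + 1L
    writeLines(sprintf("TER   %5d      %-3s %1s%4d%1s", serial %% 100000L,
                       a$resid[last], ch, a$resno[last],
                       ifelse(a$insert[last] == "", " ", a$insert[last])), con)
  }
  writeLines("END", con)
  invisible(path)
}
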