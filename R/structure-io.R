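#' Read a protein structure from PDB or mmCIF
#'
#' Parses a single-chain protein structure, keeping atoms in file order and
#' hydrogens if present.  The element is taken from the file's element
#' column when available, otherwise inferred from the atom name; electron
#' counts and masses come from the built-in element table (unknown elements
#' are an error).  Per-atom confidence is copied from the B-factor column,
#' where predicted models (AlphaFold) store the per-residue pLDDT.
#'
#' @param path file path.
#' @param format \code{"pdb"}, \code{"mmcif"} or \code{"auto"} (by file
#'   extension: .cif/.mmcif are mmCIF, anything else PDB).
#' @return A [ProteinStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("could not parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  .structure_from_bio3d(parsed$atom, source = basename(path))
}

## Build a ProteinStructure from a bio3d atom data.frame (file order kept).
.structure_from_bio3d <- function(at, title = "", source = "") {
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("no atoms found")
  ## drop waters (hydration shells are not part of the dry structure)
  at <- at[!at$resid %in% c("HOH", "WAT", "TIP", "SOL"), , drop = FALSE]
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1)
    stop("multi-chain structures are not supported; found chains: ",
         paste(chains, collapse = ", "))
  el <- at$elesy
  missing_el <- is.na(el) | !nzchar(trimws(el))
  el[missing_el] <- .element_from_name(at$elety[missing_el])
  el <- toupper(trimws(el))
  const <- .lookup_element(el)
  ## renumber residues 1..n in order of first appearance, preserving file
  ## order and contiguous grouping
  resno <- match(at$resno, unique(at$resno))
  atoms <- data.frame(name = trimws(at$elety), element = el,
                      electrons = const$electrons, mass = const$mass,
                      resno = as.integer(resno), resid = at$resid,
                      confidence = as.numeric(at$b),
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  .new_structure(atoms, xyz,
                 chainId = if (length(chains)) chains else "A",
                 title = title, source = source)
}

#' Write a conformer pool as an NMR-style multi-model PDB
#'
#' One MODEL/ENDMDL block per frame; the MODEL serial is the frame's
#' original model number, so selections written this way stay traceable to
#' the original Monte Carlo output.
#'
#' @param pool a non-empty [ConformerPool-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMultimodelPDB <- function(pool, path) {
  if (is.null(pool) || !is(pool, "ConformerPool") || nFrames(pool) == 0)
    stop("pool must be a non-empty ConformerPool")
  a <- pool@template@atoms
  ch <- pool@template@chainId
  con <- file(path, "w")
  on.exit(close(con))
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- formatC(name4, width = -4)
  for (f in seq_len(nFrames(pool))) {
    xyz <- pool@coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), name4, a$resid, ch, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.0,
      pmin(a$confidence, 999.99), substr(a$element, 1, 2))
    writeLines(c(sprintf("MODEL     %4d", pool@modelNumbers[f]),
                 lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read back a multi-model PDB into a conformer pool
#'
#' Inverse of [writeMultimodelPDB()]: frames keyed by their MODEL serials.
#' Coordinates round-trip within PDB precision (1e-3 Angstrom).
#'
#' @param path multi-model PDB file.
#' @return A [ConformerPool-class] (acceptance log empty: unknown here).
#' @export
readMultimodelPDB <- function(path) {
  lines <- readLines(path)
  model_at <- grep("^MODEL", lines)
  if (!length(model_at)) stop("no MODEL records in ", path)
  serials <- as.integer(substr(lines[model_at], 11, 14))
  end_at <- grep("^ENDMDL", lines)
  if (length(end_at) != length(model_at))
    stop("unbalanced MODEL/ENDMDL records")
  blocks <- mapply(function(s, e) lines[(s + 1):(e - 1)],
                   model_at, end_at, SIMPLIFY = FALSE)
  first <- .parse_atom_lines(blocks[[1]])
  template <- .structure_from_bio3d(first, source = basename(path))
  n <- nrow(template@atoms)
  coords <- array(NA_real_, dim = c(n, 3, length(blocks)))
  coords[, , 1] <- template@xyz
  if (length(blocks) > 1) for (f in 2:length(blocks)) {
    at <- .parse_atom_lines(blocks[[f]])
    if (nrow(at) != n)
      stop("frame ", serials[f], " has ", nrow(at),
           " atoms, expected ", n)
    coords[, , f] <- cbind(at$x, at$y, at$z)
  }
  rg <- apply(coords, 3, function(m) .rg_xyz(m, template@atoms$electrons))
  new("ConformerPool", template = template, coords = coords,
      modelNumbers = serials, rg = rg, acceptanceLog = logical())
}

.parse_atom_lines <- function(lines) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) stop("no ATOM records in model block")
  data.frame(type = trimws(substr(rec, 1, 6)),
             elety = trimws(substr(rec, 13, 16)),
             resid = trimws(substr(rec, 18, 20)),
             chain = trimws(substr(rec, 22, 22)),
             resno = as.integer(substr(rec, 23, 26)),
             x = as.numeric(substr(rec, 31, 38)),
             y = as.numeric(substr(rec, 39, 46)),
             z = as.numeric(substr(rec, 47, 54)),
             b = as.numeric(substr(rec, 61, 66)),
             elesy = trimws(substr(rec, 77, 78)),
             stringsAsFactors = FALSE)
}

#' Write curves that share one grid to a labelled CSV
#'
#' Column 1 is the shared abscissa (q or r), one labelled column per curve.
#' Values round-trip within 1e-9 relative.
#'
#' @param curves list of [ScatteringCurve-class] or [PofR-class] objects on
#'   an identical grid.
#' @param labels column labels, one per curve.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCurvesCSV <- function(curves, labels, path) {
  stopifnot(length(curves) >= 1, length(labels) == length(curves))
  grid_of <- function(cv) if (is(cv, "PofR")) cv@r else cv@q
  val_of <- function(cv) if (is(cv, "PofR")) cv@p else cv@intensity
  g <- grid_of(curves[[1]])
  for (cv in curves)
    if (length(grid_of(cv)) != length(g) ||
        any(abs(grid_of(cv) - g) > 1e-9 * pmax(abs(g), 1)))
      stop("all curves must share one abscissa grid")
  df <- data.frame(grid = g)
  names(df) <- if (is(curves[[1]], "PofR")) "r" else "q"
  for (k in seq_along(curves)) df[[labels[k]]] <- val_of(curves[[k]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
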