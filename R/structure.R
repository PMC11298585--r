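## Coordinate I/O and atom selection.  Parsing is delegated to bio3d
## (read.pdb / read.cif); author residue numbering with insertion codes is
## used throughout and internal indices are never exposed.

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame with at least `chain`, `resno`, `elety`, `x`,
#'   `y`, `z`; missing bookkeeping columns (`type`, `insert`, `resid`,
#'   `elesy`, `o`) are filled with defaults, the element being derived from
#'   the atom name when absent.
#' @param title free-text provenance.
#' @return a [ProteinStructure-class].
#' @export
proteinStructure <- function(atoms, title = "") {
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$elesy)) atoms$elesy <- guessElement(atoms$elety)
  atoms$insert[is.na(atoms$insert)] <- ""
  keep <- c("type", "chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o")
  new("ProteinStructure", atoms = atoms[, keep], title = title)
}

guessElement <- function(elety) {
  two <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE", "CU", "NI",
           "CO", "CD", "HG", "PB")
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  out <- substr(nm, 1, 1)
  isTwo <- nm %in% two & !(nm %in% c("CA", "CB", "CD", "CG", "CE", "NA"))
  out[isTwo] <- nm[isTwo]
  out
}

#' Read a PDB or mmCIF structure
#'
#' Parses a coordinate file into a flat atom table.  The first model is
#' kept by default; one alternate location is retained per atom (highest
#' occupancy, ties broken by altloc letter); waters may be dropped.
#'
#' @param path path ending in `.pdb`/`.ent` (PDB) or `.cif`/`.mmcif`
#'   (mmCIF).
#' @param dropWaters remove HOH/WAT residues.
#' @return a [ProteinStructure-class].
#' @export
readStructure <- function(path, dropWaters = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  isCif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (isCif) suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE)) else
      suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE)),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$elesy[is.na(a$elesy) | a$elesy == ""] <- NA
  a$elesy <- ifelse(is.na(a$elesy), guessElement(a$elety), a$elesy)
  if (dropWaters) a <- a[!(a$resid %in% c("HOH", "WAT", "DOD")), ]
  ## altloc: keep the highest-occupancy alternate per atom
  if (any(nzchar(a$alt))) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
    ord <- order(key, -a$o, a$alt)
    a <- a[ord, ]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety,
                             sep = "\r")), ]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  rownames(a) <- NULL
  proteinStructure(a[, c("type", "chain", "resno", "insert", "resid",
                         "elety", "elesy", "x", "y", "z", "o")],
                   title = basename(path))
}

#' Parse a selection string
#'
#' Selections are written `"chain:start-end"` with optional comma-separated
#' terms, e.g. `"A:2660-2722"`, `"A:2723-2979,B:10-20"`, or just `"A"` for
#' a whole chain.
#'
#' @param s selection string.
#' @return data.frame with columns `chain`, `from`, `to` (`NA` = whole
#'   chain).
#' @export
parseSelection <- function(s) {
  terms <- strsplit(s, ",")[[1]]
  rows <- lapply(terms, function(t) {
    t <- trimws(t)
    if (!nzchar(t)) stop("empty selection term in '", s, "'")
    if (grepl(":", t)) {
      parts <- strsplit(t, ":")[[1]]
      if (length(parts) != 2L || !grepl("^-?[0-9]+--?[0-9]*$|^-?[0-9]+$",
                                        parts[2]))
        stop("bad selection token '", t,
             "' (expected chain:start-end)")
      rng <- strsplit(parts[2], "(?<=[0-9])-", perl = TRUE)[[1]]
      from <- as.integer(rng[1])
      to <- if (length(rng) > 1L) as.integer(rng[2]) else from
      data.frame(chain = parts[1], from = from, to = to,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chain = t, from = NA_integer_, to = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Select atoms of a structure
#'
#' @param s a [ProteinStructure-class].
#' @param selection selection string (see [parseSelection()]) or `NULL`
#'   for all atoms.
#' @param elety optional atom-name filter (e.g. `"CA"`).
#' @param proteinOnly drop HETATM records.
#' @return logical vector over the atom rows.
#' @export
selectAtoms <- function(s, selection = NULL, elety = NULL,
                        proteinOnly = FALSE) {
  a <- s@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection)) {
    sel <- parseSelection(selection)
    keep <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(sel))) {
      m <- a$chain == sel$chain[i]
      if (!is.na(sel$from[i]))
        m <- m & a$resno >= sel$from[i] & a$resno <= sel$to[i]
      keep <- keep | m
    }
  }
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (proteinOnly) keep <- keep & a$type == "ATOM"
  keep
}

#' Extract coordinates
#'
#' @param s a [ProteinStructure-class].
#' @param selection optional selection string.
#' @param elety optional atom-name filter.
#' @return n x 3 numeric matrix.
#' @export
atomCoords <- function(s, selection = NULL, elety = NULL) {
  a <- s@atoms[selectAtoms(s, selection, elety), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' C-alpha coordinates keyed by residue
#'
#' @param s a [ProteinStructure-class].
#' @param selection optional selection string.
#' @return data.frame `chain`, `resno`, `insert`, `x`, `y`, `z` (one CA
#'   per residue).
#' @export
caTable <- function(s, selection = NULL) {
  a <- s@atoms[selectAtoms(s, selection, elety = "CA", proteinOnly = TRUE), ]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert)), ]
  a[, c("chain", "resno", "insert", "x", "y", "z")]
}

#' Write a minimal PDB file
#'
#' Plain ATOM/HETATM records, sufficient for round trips through
#' [readStructure()].
#'
#' @param s a [ProteinStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(s, path) {
  a <- s@atoms
  name <- ifelse(nchar(a$elety) < 4 & nchar(a$elesy) == 1,
                 paste0(" ", a$elety), a$elety)
  lines <- sprintf(
    "%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$type, seq_len(nrow(a)), name,
    a$resid, a$chain, a$resno, ifelse(nzchar(a$insert), a$insert, " "),
    a$x, a$y, a$z, a$o, 0, a$elesy)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
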