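#' Protein structures as atom tables
#'
#' A `pdb_structure` is a data frame of atoms with one row per atom and
#' columns `serial`, `name`, `element`, `resname`, `chain`, `resseq`,
#' `altloc`, `occupancy`, `x`, `y`, `z`, plus the derived physical
#' properties `vdw` (van der Waals radius, set by
#' [assign_atom_properties()]) and `hydrophobic`. Coordinates are in
#' Angstrom. A `conformer_set` is an ordered, labelled list of such
#' structures sharing atom count and ordering (e.g. the models of an NMR
#' ensemble, or the combinatorial expansion of alternate conformations).
#'
#' @param atoms data frame with at least the coordinate and identity
#'   columns listed above.
#' @param model_id label of the model this structure came from.
#' @return `new_structure()` returns a `pdb_structure`.
#' @export
new_structure <- function(atoms, model_id = "1") {
  required <- c("serial", "name", "element", "resname", "chain", "resseq",
                "altloc", "occupancy", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(atoms$vdw)) atoms$vdw <- NA_real_
  if (is.null(atoms$hydrophobic)) atoms$hydrophobic <- NA
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(atoms, model_id = as.character(model_id),
            class = c("pdb_structure", "data.frame"))
}

#' @rdname new_structure
#' @param x object to test or extract from.
#' @export
is_structure <- function(x) inherits(x, "pdb_structure")

#' @rdname new_structure
#' @export
model_id <- function(x) attr(x, "model_id")

#' Coordinate matrix of a structure
#'
#' @param s a `pdb_structure`.
#' @param heavy if `TRUE`, restrict to non-hydrogen atoms.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(s, heavy = FALSE) {
  if (heavy) s <- heavy_atoms(s)
  cbind(x = s$x, y = s$y, z = s$z)
}

#' @rdname coords
#' @export
heavy_atoms <- function(s) {
  s[s$element != "H" & s$element != "D", , drop = FALSE]
}

#' @rdname new_structure
#' @param conformers list of `pdb_structure` objects.
#' @param label label for the set.
#' @export
new_conformer_set <- function(conformers, label = "") {
  stopifnot(is.list(conformers), length(conformers) >= 1)
  structure(list(label = label, conformers = conformers),
            class = "conformer_set")
}

#' @export
length.conformer_set <- function(x) length(x$conformers)

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set '%s': %d conformer(s) of %d atoms>\n",
              x$label, length(x$conformers), nrow(x$conformers[[1]])))
  invisible(x)
}

# Fall back to the PDB atom-name convention when the element columns
# (77-78) are absent: first letter of the name that is not a digit,
# honouring the two-character elements seen in protein/water files.
infer_element <- function(name) {
  nm <- toupper(gsub("[ 0-9']", "", name))
  two <- substr(nm, 1L, 2L)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"),
         two, substr(nm, 1L, 1L))
}

validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM record at line %d: record too short", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop(sprintf("malformed ATOM record at line %d: bad coordinate field", i))
  }
  invisible(TRUE)
}

#' Read a PDB file or text into a conformer set
#'
#' Parses `ATOM`/`HETATM` records (via bio3d), one structure per `MODEL`
#' block (a single structure when no `MODEL` records are present).
#' Alternate-location indicators and occupancies are preserved verbatim.
#'
#' @param pdb path to a PDB file, or PDB text (a single string with
#'   newlines, or a character vector of lines).
#' @param model_filter optional set of model labels to keep.
#' @return a [new_conformer_set()] with one structure per model.
#' @examples
#' cs <- read_models(make_altloc_fixture())
#' length(cs)
#' @export
read_models <- function(pdb, model_filter = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    label <- basename(pdb)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    label <- "pdb_text"
  }
  validate_pdb_lines(lines)

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdbobj <- bio3d::read.pdb(tmp, multi = TRUE, rm.alt = FALSE,
                            verbose = FALSE)
  at <- pdbobj$atom
  nmodel <- nrow(pdbobj$xyz)

  model_lines <- grep("^MODEL", lines, value = TRUE)
  labels <- if (length(model_lines) >= nmodel) {
    trimws(substr(model_lines[seq_len(nmodel)], 11, 14))
  } else {
    as.character(seq_len(nmodel))
  }

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- infer_element(at$elety[bad])

  conformers <- vector("list", nmodel)
  for (m in seq_len(nmodel)) {
    xyz <- matrix(pdbobj$xyz[m, ], ncol = 3L, byrow = TRUE)
    conformers[[m]] <- new_structure(data.frame(
      serial = at$eleno,
      name = at$elety,
      element = toupper(elem),
      resname = at$resid,
      chain = ifelse(is.na(at$chain), " ", at$chain),
      resseq = at$resno,
      altloc = ifelse(is.na(at$alt), "", at$alt),
      occupancy = ifelse(is.na(at$o), 1, at$o),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE
    ), model_id = labels[m])
  }
  names(conformers) <- labels

  if (!is.null(model_filter)) {
    keep <- labels %in% as.character(model_filter)
    if (!any(keep))
      stop("model_filter selects no model; available: ",
           paste(labels, collapse = ", "))
    conformers <- conformers[keep]
  }
  new_conformer_set(conformers, label = label)
}

#' Expand alternate conformations into a conformer set
#'
#' Residues resolved with two or more alternate locations (`altloc`
#' A/B/...) are expanded combinatorially: each output conformer contains
#' exactly one alternative per such residue, with blank-altloc atoms
#' shared. Labels encode the chosen letters in residue order (e.g.
#' `"aab"`), lower-cased.
#'
#' @param s a `pdb_structure`.
#' @return a `conformer_set` with `prod(alternatives per residue)`
#'   conformers.
#' @export
expand_altlocs <- function(s) {
  stopifnot(is_structure(s))
  has_alt <- s$altloc != ""
  if (!any(has_alt))
    return(new_conformer_set(list(s), label = model_id(s)))

  reskey <- paste(s$chain, s$resseq)
  alt_res <- unique(reskey[has_alt])
  letters_per_res <- lapply(alt_res, function(k) {
    sel <- reskey == k & has_alt
    letters <- sort(unique(s$altloc[sel]))
    if (length(letters) < 2)
      stop("residue ", k, " has a single alternate location '",
           letters, "'; incomplete alternative set")
    # every alternative must provide the same atom names
    name_sets <- lapply(letters, function(l) sort(s$name[sel & s$altloc == l]))
    if (length(unique(vapply(name_sets, paste, "", collapse = "|"))) != 1L)
      stop("residue ", k, " is missing a complete alternative set: ",
           "altloc letters cover different atoms")
    letters
  })
  names(letters_per_res) <- alt_res

  grid <- expand.grid(rev(letters_per_res), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(letters_per_res)), drop = FALSE]
  names(grid) <- alt_res

  conformers <- vector("list", nrow(grid))
  labels <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    choice <- as.character(grid[i, ])
    names(choice) <- alt_res
    keep <- !has_alt | s$altloc == choice[reskey]
    sub <- s[keep, , drop = FALSE]
    sub$altloc <- ""
    labels[i] <- paste(tolower(choice), collapse = "")
    conformers[[i]] <- new_structure(sub, model_id = labels[i])
  }
  names(conformers) <- labels
  new_conformer_set(conformers, label = model_id(s))
}

#' Bondi van der Waals radii
#'
#' The default element-to-radius table (Angstrom) used for contact and
#' clash geometry; override by passing a named vector to
#' [assign_atom_properties()].
#'
#' @return named numeric vector of radii by element symbol.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
    S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    "NA" = 2.27, K = 2.75, MG = 1.73, ZN = 1.39, FE = 1.63, X = 1.70)
}

#' Assign per-atom physical properties
#'
#' Sets the van der Waals radius of each atom from an element table and
#' flags hydrophobic heavy atoms. Under the default rule (`"CS"`) the
#' heavy atoms of carbon and sulfur are hydrophobic; hydrogens carry
#' `NA`.
#'
#' @param s a `pdb_structure`.
#' @param radius_table named radii vector (Angstrom), element -> radius.
#' @param hydrophobic_rule currently `"CS"`.
#' @return the structure with `vdw` and `hydrophobic` populated.
#' @export
assign_atom_properties <- function(s, radius_table = bondi_radii(),
                                   hydrophobic_rule = c("CS")) {
  stopifnot(is_structure(s))
  hydrophobic_rule <- match.arg(hydrophobic_rule)
  el <- toupper(s$element)
  unknown <- !(el %in% names(radius_table))
  if (any(unknown)) {
    off <- unique(sprintf("%s (atom %s %s%d)", el[unknown], s$name[unknown],
                          s$resname[unknown], s$resseq[unknown]))
    stop("unknown element(s) in radius table: ",
         paste(utils::head(off, 10), collapse = "; "))
  }
  s$vdw <- unname(radius_table[el])
  s$hydrophobic <- ifelse(el %in% c("H", "D"), NA, el %in% c("C", "S"))
  s
}

format_atom_record <- function(s) {
  name <- vapply(seq_len(nrow(s)), function(i) {
    nm <- s$name[i]
    # PDB convention: 1-letter elements start in column 14
    if (nchar(nm) < 4 && nchar(s$element[i]) == 1L) paste0(" ", nm) else nm
  }, "")
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          s$serial %% 100000L, name, s$altloc, s$resname,
          substr(paste0(s$chain, " "), 1, 1), s$resseq,
          s$x, s$y, s$z, s$occupancy, 0, toupper(s$element))
}

#' Write structures to PDB
#'
#' Writes a structure (or every conformer of a set, wrapped in
#' `MODEL`/`ENDMDL` blocks) as positional PDB `ATOM` records; coordinates
#' round to the format's 3-decimal precision, so
#' `read_models(write_model(s))` reproduces coordinates to 1e-3 Angstrom.
#'
#' @param s a `pdb_structure` or `conformer_set`.
#' @param path output file; when `NULL` the PDB text is returned
#'   invisibly instead.
#' @return the PDB text, invisibly.
#' @export
write_model <- function(s, path = NULL) {
  models <- if (inherits(s, "conformer_set")) s$conformers else list(s)
  txt <- character(0)
  multi <- length(models) > 1L
  for (i in seq_along(models)) {
    if (multi) txt <- c(txt, sprintf("MODEL     %4d", i))
    txt <- c(txt, format_atom_record(models[[i]]))
    if (multi) txt <- c(txt, "ENDMDL")
  }
  txt <- c(txt, "END")
  if (!is.null(path)) {
    ok <- tryCatch({ writeLines(txt, path); TRUE },
                   error = function(e) stop("cannot write PDB to '", path,
                                            "': ", conditionMessage(e)))
  }
  invisible(paste(txt, collapse = "\n"))
}
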