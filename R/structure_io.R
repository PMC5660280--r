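#' Construct a Trajectory object
#'
#' A `Trajectory` couples a fixed topology (one row per atom: serial, atom
#' name, element, residue name, residue number, chain) with an ordered list of
#' coordinate frames. Every frame is an `n_atoms x 3` matrix of Cartesian
#' coordinates in Angstrom. Residue numbering is kept verbatim (no
#' renumbering), so selections can use the numbering of the source structure.
#'
#' @param topology data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`.
#' @param frames list of numeric matrices, each `nrow(topology) x 3`, Angstrom.
#' @param frame_spacing optional time per frame in ps (metadata only).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(topology, frames, frame_spacing = NULL) {
  stopifnot(is.data.frame(topology))
  req <- c("serial", "name", "element", "resname", "resno", "chain")
  missing_cols <- setdiff(req, names(topology))
  if (length(missing_cols)) {
    stop("topology is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!length(frames)) stop("a Trajectory needs at least one frame")
  n <- nrow(topology)
  if (n == 0L) stop("empty topology")
  if (any(!nzchar(topology$element))) stop("topology contains empty element symbols")
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    f <- as.matrix(f)
    if (!is.numeric(f) || ncol(f) != 3L || nrow(f) != n) {
      stop(sprintf("frame %d does not have one coordinate triple per topology atom", i))
    }
    if (any(!is.finite(f))) stop(sprintf("frame %d contains non-finite coordinates", i))
    dimnames(f) <- NULL
    f
  })
  structure(
    list(topology = topology, frames = frames, frame_spacing = frame_spacing),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d atoms, %d frame(s), %d residue(s)\n",
    nrow(x$topology), length(x$frames),
    length(unique(paste(x$topology$chain, x$topology$resno)))
  ))
  if (!is.null(x$frame_spacing)) {
    cat(sprintf("  frame spacing: %g ps\n", x$frame_spacing))
  }
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param trajectory a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

# Two-letter element symbols that can appear in atom names. CA is resolved to
# calcium only when the residue itself is the ion (resname CA); otherwise CA is
# an alpha-carbon. CL and ZN have no common carbon/nitrogen collision.
.two_letter_elements <- c("ZN", "CL", "BR", "FE", "MG", "MN", "CU", "SE", "NA", "CA")

.infer_element <- function(name, resname) {
  token <- gsub("[^A-Za-z]", "", name)
  if (!nzchar(token)) return("")
  token_up <- toupper(token)
  two <- substr(token_up, 1L, 2L)
  resname_up <- toupper(trimws(resname))
  if (two %in% .two_letter_elements) {
    ambiguous <- two %in% c("CA", "NA")  # alpha-carbon / amide nitrogen clash
    if (!ambiguous || resname_up == two) {
      return(paste0(substr(token, 1L, 1L), tolower(substr(token_up, 2L, 2L))))
    }
  }
  substr(token_up, 1L, 1L)
}

.parse_atom_lines <- function(lines, line_numbers) {
  n <- length(lines)
  num_field <- function(start, stop, what) {
    raw <- substr(lines, start, stop)
    out <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(out))
    if (length(bad)) {
      stop(sprintf(
        "unparseable %s field '%s' at line %d",
        what, trimws(raw[bad[1]]), line_numbers[bad[1]]
      ))
    }
    out
  }
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[!is.finite(serial)] <- NA_integer_
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  resno_raw <- substr(lines, 23, 26)
  resno <- suppressWarnings(as.integer(resno_raw))
  bad <- which(is.na(resno))
  if (length(bad)) {
    stop(sprintf(
      "unparseable residue number '%s' at line %d",
      trimws(resno_raw[bad[1]]), line_numbers[bad[1]]
    ))
  }
  x <- num_field(31, 38, "x coordinate")
  y <- num_field(39, 46, "y coordinate")
  z <- num_field(47, 54, "z coordinate")
  elem_col <- trimws(substr(lines, 77, 78))
  element <- character(n)
  for (i in seq_len(n)) {
    element[i] <- if (nzchar(elem_col[i])) {
      paste0(
        toupper(substr(elem_col[i], 1L, 1L)),
        tolower(substr(elem_col[i], 2L, nchar(elem_col[i])))
      )
    } else {
      .infer_element(name[i], resname[i])
    }
  }
  if (any(!nzchar(element))) {
    stop(sprintf(
      "could not infer an element for atom at line %d",
      line_numbers[which(!nzchar(element))[1]]
    ))
  }
  list(
    topology = data.frame(
      serial = serial, name = name, element = element,
      resname = resname, resno = resno, chain = chain,
      stringsAsFactors = FALSE
    ),
    coords = cbind(x, y, z)
  )
}

#' Read a multi-model PDB file as a Trajectory
#'
#' The topology (atom names, elements, residues) is taken from the first
#' MODEL; subsequent MODELs are matched to it by record order and contribute
#' only coordinates. A file without MODEL records yields a single-frame
#' trajectory. Elements are taken from columns 77-78 when present, otherwise
#' inferred from the atom name (digits stripped, leading alphabetic token,
#' with a fixed lookup for two-letter elements such as Zn and Cl; CA is read
#' as calcium only for resname CA).
#'
#' @param path PDB file path.
#' @param frame_spacing optional ps per frame, stored as metadata.
#' @return a [trajectory()] object.
#' @export
read_multimodel_pdb <- function(path, frame_spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  if (!length(model_starts)) {
    parsed <- .parse_atom_lines(lines[is_atom], which(is_atom))
    return(trajectory(parsed$topology, list(parsed$coords), frame_spacing))
  }

  # assign each atom line to the MODEL block it follows
  model_id <- findInterval(which(is_atom), model_starts)
  if (any(model_id == 0L)) {
    stop("ATOM records before the first MODEL record")
  }
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  first <- .parse_atom_lines(atom_lines[model_id == 1L], atom_lineno[model_id == 1L])
  n_atoms <- nrow(first$topology)
  frames <- vector("list", max(model_id))
  frames[[1L]] <- first$coords
  for (m in setdiff(seq_len(max(model_id)), 1L)) {
    sel <- model_id == m
    if (sum(sel) != n_atoms) {
      stop(sprintf(
        "topology error: model %d has %d atoms, model 1 has %d",
        m, sum(sel), n_atoms
      ))
    }
    frames[[m]] <- .parse_atom_lines(atom_lines[sel], atom_lineno[sel])$coords
  }
  trajectory(first$topology, frames, frame_spacing)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Coordinates are written in the fixed-width `%8.3f` PDB fields, so a
#' read/write round trip preserves them to 0.001 Angstrom. Coordinates that do
#' not fit the 8-column field are refused.
#'
#' @param trajectory a [trajectory()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "Trajectory"))
  top <- trajectory$topology
  coords_ok <- vapply(trajectory$frames, function(f) all(abs(f) < 10000) && all(f > -1000), TRUE)
  if (!all(coords_ok)) {
    stop("coordinate magnitude exceeds the fixed-width %8.3f PDB field")
  }
  serial <- top$serial
  if (any(is.na(serial))) serial <- seq_len(nrow(top))
  # PDB convention: atom names of <4 characters start in column 14
  name_field <- ifelse(
    nchar(top$name) >= 4L,
    sprintf("%-4s", top$name),
    sprintf(" %-3s", top$name)
  )
  elem_field <- sprintf("%2s", substr(paste0(
    toupper(substr(top$element, 1, 1)), substr(top$element, 2, 2)
  ), 1, 2))
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- length(trajectory$frames) > 1L
  for (i in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[i]]
    if (multi) writeLines(sprintf("MODEL %8d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %s",
      serial, name_field, top$resname, top$chain, top$resno,
      f[, 1], f[, 2], f[, 3], elem_field
    ), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms from a Trajectory topology
#'
#' Resolves a selection to an ordered (topology-order) integer index set.
#' All supplied criteria are combined with AND; values within one criterion
#' are combined with OR (e.g. `resno = c(134, 135)`). An empty result is not
#' an error.
#'
#' @param trajectory a [trajectory()] object.
#' @param resno residue numbers to keep.
#' @param resname residue names to keep.
#' @param name atom names to keep.
#' @param element element symbols to keep (case-insensitive).
#' @param chain chain identifiers to keep.
#' @param heavy if `TRUE`, drop hydrogens.
#' @return integer vector of topology indices (possibly empty).
#' @export
select_atoms <- function(trajectory, resno = NULL, resname = NULL, name = NULL,
                         element = NULL, chain = NULL, heavy = FALSE) {
  stopifnot(inherits(trajectory, "Trajectory"))
  top <- trajectory$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(resno)) keep <- keep & top$resno %in% resno
  if (!is.null(resname)) keep <- keep & top$resname %in% resname
  if (!is.null(name)) keep <- keep & top$name %in% name
  if (!is.null(element)) keep <- keep & toupper(top$element) %in% toupper(element)
  if (!is.null(chain)) keep <- keep & top$chain %in% chain
  if (isTRUE(heavy)) keep <- keep & toupper(top$element) != "H"
  which(keep)
}

# Resolve a selection given either an index vector or a named list of
# select_atoms() criteria (used by the pipeline config).
.resolve_selection <- function(trajectory, sel, what = "selection") {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > nrow(trajectory$topology))) {
      stop(what, ": index out of range")
    }
    return(idx)
  }
  if (is.list(sel)) {
    allowed <- c("resno", "resname", "name", "element", "chain", "heavy", "serial")
    unknown <- setdiff(names(sel), allowed)
    if (length(unknown)) {
      stop(what, ": unknown selection field(s): ", paste(unknown, collapse = ", "))
    }
    if (!is.null(sel$serial)) {
      idx <- match(as.integer(sel$serial), trajectory$topology$serial)
      if (any(is.na(idx))) stop(what, ": serial not found in topology")
      return(idx)
    }
    return(select_atoms(
      trajectory,
      resno = sel$resno, resname = sel$resname, name = sel$name,
      element = sel$element, chain = sel$chain, heavy = isTRUE(sel$heavy)
    ))
  }
  stop(what, ": selection must be an index vector or a named criteria list")
}
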