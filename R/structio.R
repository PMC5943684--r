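# Structure, sequence and ensemble input/output.
#
# The coordinate model is a `structure_model`: a flat atom table in author
# (PDB) numbering plus provenance. Author numbering is canonical throughout
# the package; sequential 1..N indices are derived views only.

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a flat atom table. Waters are discarded;
#' other HETATM groups are retained but flagged `hetero`. Alternate locations
#' are resolved per `altloc_policy`.
#'
#' @param path Path to a PDB file.
#' @param model_index Which MODEL block to read (1-based; default first).
#' @param altloc_policy `"occupancy"` keeps, per atom, the altloc with the
#'   highest occupancy (ties broken alphabetically, so 'A' wins); `"first"`
#'   keeps the first record encountered.
#' @return A `structure_model`: list with `id`, `atoms` (data frame with
#'   columns serial, name, altloc, resname, chain, resseq, icode, x, y, z,
#'   occupancy, bfactor, element, hetero), `seqres` (named 3-letter vector,
#'   or NULL) and `source`.
#' @export
read_structure <- function(path, model_index = 1L,
                           altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop2("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  atom_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(atom_idx) == 0) stop2("no ATOM records in %s", path)
  bad <- atom_idx[nchar(lines[atom_idx]) < 54]
  if (length(bad) == 0) {
    coords <- suppressWarnings(cbind(
      as.numeric(substr(lines[atom_idx], 31, 38)),
      as.numeric(substr(lines[atom_idx], 39, 46)),
      as.numeric(substr(lines[atom_idx], 47, 54))))
    bad <- atom_idx[!stats::complete.cases(coords)]
  }
  if (length(bad) > 0) {
    stop2("malformed ATOM record at line %d of %s", bad[1], path)
  }

  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > n_models) {
    stop2("model %d not found (file has %d MODEL block%s)",
          model_index, n_models, if (n_models == 1) "" else "s")
  }
  at <- pdb$atom
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  at$x <- xyz[seq(1, length(xyz), by = 3)]
  at$y <- xyz[seq(2, length(xyz), by = 3)]
  at$z <- xyz[seq(3, length(xyz), by = 3)]

  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    resname = toupper(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resseq = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[!(atoms$hetero & atoms$resname %in% WATER_RESNAMES), ,
                 drop = FALSE]

  if (altloc_policy == "occupancy" && any(atoms$altloc != "")) {
    akey <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), akey), function(i) {
      if (length(i) == 1) return(i)
      occ <- atoms$occupancy[i]
      i[order(-occ, atoms$altloc[i])][1]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  } else if (any(atoms$altloc != "")) {
    akey <- paste(atoms$chain, atoms$resseq, atoms$icode, atoms$name)
    atoms <- atoms[!duplicated(akey), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres) > 0) seqres <- pdb$seqres

  new_structure_model(
    id = sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE),
    atoms = atoms, source = path, seqres = seqres)
}

new_structure_model <- function(id, atoms, source = NA_character_,
                                seqres = NULL) {
  stopifnot(is.data.frame(atoms))
  std <- atoms[!atoms$hetero & atoms$resname %in% STANDARD_AA, , drop = FALSE]
  if (nrow(std) == 0) stop2("structure '%s' has no standard residues", id)
  rk <- res_key(atoms$chain, atoms$resseq, atoms$icode)
  dup <- tapply(atoms$resname, rk, function(r) length(unique(r)))
  if (any(dup > 1)) {
    stop2("duplicate residue key with conflicting residue name: %s",
          names(dup)[dup > 1][1])
  }
  structure(list(id = id, atoms = atoms, source = source, seqres = seqres),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  rs <- residue_table(x)
  cat(sprintf("structure_model '%s': %d atoms, %d residues (%d standard), chains: %s\n",
              x$id, nrow(x$atoms), length(unique(res_key(x$atoms$chain,
                                                         x$atoms$resseq,
                                                         x$atoms$icode))),
              nrow(rs), paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Per-residue table of a structure
#'
#' One row per standard amino-acid residue, in file order, with the
#' canonical residue key (`chain:resseq[icode]`) and derived 1-letter code.
#'
#' @param model A `structure_model`.
#' @param chain_id Optional chain filter.
#' @return Data frame: key, chain, resseq, icode, resname, one.
#' @export
residue_table <- function(model, chain_id = NULL) {
  at <- model$atoms
  at <- at[!at$hetero & at$resname %in% STANDARD_AA, , drop = FALSE]
  if (!is.null(chain_id)) at <- at[at$chain == chain_id, , drop = FALSE]
  key <- res_key(at$chain, at$resseq, at$icode)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = at$chain[first],
             resseq = at$resseq[first], icode = at$icode[first],
             resname = at$resname[first], one = aa_one(at$resname[first]),
             stringsAsFactors = FALSE)
}

# Coordinates of one named atom per residue key; NA rows where absent.
atom_coords <- function(model, keys, atom_name = "CA") {
  at <- model$atoms
  at <- at[at$name == atom_name, , drop = FALSE]
  akey <- res_key(at$chain, at$resseq, at$icode)
  idx <- match(keys, akey)
  cbind(x = at$x[idx], y = at$y[idx], z = at$z[idx])
}

# All atoms of one residue key.
residue_atoms <- function(model, key) {
  at <- model$atoms
  at[res_key(at$chain, at$resseq, at$icode) == key, , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$hetero, "HETATM", "ATOM"),
    resno = at$resseq, resid = at$resname, chain = at$chain,
    insert = ifelse(at$icode == "", "", at$icode),
    elety = at$name, o = at$occupancy, b = at$bfactor, eleno = at$serial,
    elesy = at$element)
  invisible(path)
}

#' Extract a chain's amino-acid sequence
#'
#' @param model A `structure_model`.
#' @param chain_id Chain identifier.
#' @param source `"atom_records"` derives the sequence from observed
#'   residues (gaps in author numbering insert nothing); `"seqres"` uses the
#'   SEQRES records captured at parse time.
#' @return A `sequence_record`: list with `id`, `letters` (1-letter string,
#'   nonstandard residues as `X`) and `residue_keys` (parallel keys for
#'   atom-record sequences, NULL for seqres).
#' @export
extract_sequence <- function(model, chain_id,
                             source = c("atom_records", "seqres")) {
  source <- match.arg(source)
  if (source == "seqres") {
    if (is.null(model$seqres)) stop2("no SEQRES records in '%s'", model$id)
    sel <- names(model$seqres) == chain_id
    if (!any(sel)) stop2("chain '%s' not found in SEQRES", chain_id)
    letters <- paste(aa_one(model$seqres[sel]), collapse = "")
    return(new_sequence_record(paste0(model$id, "_", chain_id), letters))
  }
  at <- model$atoms
  at <- at[!at$hetero & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0) stop2("chain '%s' not found in '%s'", chain_id, model$id)
  key <- res_key(at$chain, at$resseq, at$icode)
  first <- !duplicated(key)
  resnames <- at$resname[first]
  std <- resnames %in% STANDARD_AA
  # nonstandard polymer residues (e.g. MSE) become X; true hetero ligands
  # are excluded above only when flagged, so filter by known backbone here
  letters <- aa_one(resnames)
  new_sequence_record(paste0(model$id, "_", chain_id),
                      paste(letters, collapse = ""), key[first])
}

new_sequence_record <- function(id, letters, residue_keys = NULL) {
  if (!is.null(residue_keys) && nchar(letters) != length(residue_keys)) {
    stop2("residue_keys length (%d) != sequence length (%d)",
          length(residue_keys), nchar(letters))
  }
  structure(list(id = id, letters = letters, residue_keys = residue_keys),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record '%s' (%d aa)\n%s\n", x$id, nchar(x$letters),
              x$letters))
  invisible(x)
}

#' Read a conformer ensemble from a multi-model PDB file
#'
#' Every MODEL block becomes one frame; all frames must share the atom
#' skeleton of MODEL 1 restricted to `selection`.
#'
#' @param path Multi-model PDB file.
#' @param selection Atom-name filter (default `"CA"`); `NULL` keeps all.
#' @param temperature Optional temperature label, degrees C.
#' @return An `ensemble`: list with `coords` (n_frames x n_atoms x 3 array,
#'   Angstrom), `atom_meta` (data frame: key, name, resname, chain, resseq,
#'   icode), `temperature`, `times`.
#' @export
read_ensemble <- function(path, selection = "CA", temperature = NA_real_) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    # single-model file: one frame
    m <- read_structure(path)
    return(ensemble_from_models(list(m), selection, temperature))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) stop2("unterminated MODEL block in %s", path)

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  frame_of <- findInterval(seq_along(lines), starts)
  sel_lines <- which(is_atom & frame_of >= 1)
  al <- lines[sel_lines]
  name <- trimws(substr(al, 13, 16))
  if (!is.null(selection)) {
    keep <- name %in% selection
    al <- al[keep]
    sel_lines <- sel_lines[keep]
    name <- name[keep]
  }
  fr <- findInterval(sel_lines, starts)
  counts <- tabulate(fr, nbins = length(starts))
  if (any(counts != counts[1])) {
    bad <- which(counts != counts[1])[1]
    stop2("frame %d has %d atoms matching selection; frame 1 has %d",
          bad, counts[bad], counts[1])
  }
  na <- counts[1]
  nf <- length(starts)
  # skeleton consistency beyond counts: atom names must align frame-wise
  nm <- matrix(name, nrow = na)
  mism <- which(colSums(nm != nm[, 1]) > 0)
  if (length(mism) > 0) {
    stop2("frame %d atom ordering differs from frame 1", mism[1])
  }
  xyz <- cbind(as.numeric(substr(al, 31, 38)),
               as.numeric(substr(al, 39, 46)),
               as.numeric(substr(al, 47, 54)))
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (k in 1:3) coords[, , k] <- t(matrix(xyz[, k], nrow = na))
  first <- al[seq_len(na)]
  meta <- data.frame(
    name = name[seq_len(na)],
    resname = trimws(substr(first, 18, 20)),
    chain = substr(first, 22, 22),
    resseq = as.integer(substr(first, 23, 26)),
    icode = trimws(substr(first, 27, 27)),
    stringsAsFactors = FALSE)
  meta$key <- res_key(meta$chain, meta$resseq, meta$icode)
  new_ensemble(coords, meta, temperature)
}

ensemble_from_models <- function(models, selection = "CA",
                                 temperature = NA_real_) {
  m1 <- models[[1]]
  at <- m1$atoms
  if (!is.null(selection)) at <- at[at$name %in% selection, , drop = FALSE]
  meta <- data.frame(name = at$name, resname = at$resname, chain = at$chain,
                     resseq = at$resseq, icode = at$icode,
                     stringsAsFactors = FALSE)
  meta$key <- res_key(meta$chain, meta$resseq, meta$icode)
  coords <- array(NA_real_, dim = c(length(models), nrow(at), 3))
  for (i in seq_along(models)) {
    ai <- models[[i]]$atoms
    if (!is.null(selection)) ai <- ai[ai$name %in% selection, , drop = FALSE]
    if (nrow(ai) != nrow(at)) {
      stop2("frame %d has %d atoms matching selection; frame 1 has %d",
            i, nrow(ai), nrow(at))
    }
    coords[i, , ] <- as.matrix(ai[, c("x", "y", "z")])
  }
  new_ensemble(coords, meta, temperature)
}

new_ensemble <- function(coords, atom_meta, temperature = NA_real_,
                         times = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(atom_meta), dim(coords)[1] >= 1)
  structure(list(coords = coords, atom_meta = atom_meta,
                 temperature = temperature, times = times),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frames x %d atoms%s\n", dim(x$coords)[1],
              dim(x$coords)[2],
              if (is.na(x$temperature)) "" else
                sprintf(" at %g degC", x$temperature)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens An `ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  nf <- dim(ens$coords)[1]
  na <- dim(ens$coords)[2]
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * na)
  xyz[, seq(1, 3 * na, 3)] <- ens$coords[, , 1]
  xyz[, seq(2, 3 * na, 3)] <- ens$coords[, , 2]
  xyz[, seq(3, 3 * na, 3)] <- ens$coords[, , 3]
  m <- ens$atom_meta
  bio3d::write.pdb(file = path, xyz = xyz, resno = m$resseq,
                   resid = m$resname, chain = m$chain, elety = m$name,
                   insert = ifelse(m$icode == "", "", m$icode))
  invisible(path)
}

#' Write a sequence record to FASTA
#' @param seq A `sequence_record` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path) {
  if (inherits(seq, "sequence_record")) seq <- list(seq)
  sets <- Biostrings::AAStringSet(vapply(seq, function(s) s$letters, ""))
  names(sets) <- vapply(seq, function(s) s$id, "")
  Biostrings::writeXStringSet(sets, filepath = path)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return List of `sequence_record`s.
#' @export
read_fasta <- function(path) {
  sets <- Biostrings::readAAStringSet(path)
  lapply(seq_along(sets), function(i) {
    new_sequence_record(names(sets)[i], as.character(sets[[i]]))
  })
}
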