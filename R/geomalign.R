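# Sequence alignment, residue pairing, Kabsch superposition, per-class RMSD
# and catalytic-triad geometry.

#' Global (Needleman-Wunsch) alignment of two protein sequences
#'
#' Optimal global alignment with affine gap penalties, computed with
#' [Biostrings::pairwiseAlignment()]. Identity is counted over aligned
#' columns excluding dual gaps; similarity counts columns with a positive
#' substitution score.
#'
#' @param seq_a,seq_b `sequence_record`s or plain strings.
#' @param substitution_matrix A scoring matrix, or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`). Ignored when `match` is given.
#' @param gap_open,gap_extend Gap opening/extension penalties (positive).
#' @param match,mismatch Optional simple scoring; builds a uniform
#'   match/mismatch matrix over the letters present.
#' @return An `alignment_result`: `aligned_a`, `aligned_b` (gapped strings),
#'   `identity_pct`, `similarity_pct`, `score`, plus the input records.
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         match = NULL, mismatch = 0) {
  rec_a <- as_sequence_record(seq_a, "seq_a")
  rec_b <- as_sequence_record(seq_b, "seq_b")
  if (nchar(rec_a$letters) == 0 || nchar(rec_b$letters) == 0) {
    stop2("cannot align empty sequence")
  }
  if (!is.null(match)) {
    alpha <- sort(unique(strsplit(paste0(rec_a$letters, rec_b$letters),
                                  "")[[1]]))
    substitution_matrix <- matrix(mismatch, length(alpha), length(alpha),
                                  dimnames = list(alpha, alpha))
    diag(substitution_matrix) <- match
  } else if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    substitution_matrix <- get(substitution_matrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(rec_a$letters), Biostrings::AAString(rec_b$letters),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  both <- ca != "-" & cb != "-"
  n_cols <- sum(ca != "-" | cb != "-")
  ident <- 100 * sum(ca == cb & both) / n_cols
  sim_pos <- vapply(which(both), function(i) {
    a <- ca[i]; b <- cb[i]
    a %in% rownames(substitution_matrix) && b %in% colnames(substitution_matrix) &&
      substitution_matrix[a, b] > 0
  }, logical(1))
  structure(list(aligned_a = ga, aligned_b = gb,
                 identity_pct = ident,
                 similarity_pct = 100 * sum(sim_pos) / n_cols,
                 score = Biostrings::score(pa),
                 record_a = rec_a, record_b = rec_b),
            class = "alignment_result")
}

as_sequence_record <- function(x, id) {
  if (inherits(x, "sequence_record")) return(x)
  if (is.character(x) && length(x) == 1) return(new_sequence_record(id, x))
  stop2("expected a sequence_record or a single string for %s", id)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: score %.1f, identity %.1f%%, similarity %.1f%%\n",
              x$score, x$identity_pct, x$similarity_pct))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Residue correspondence between two structures from an alignment
#'
#' One pair per aligned non-gap column whose residues both possess a
#' C-alpha atom. The alignment's sequence records must carry residue keys
#' (i.e. come from [extract_sequence()] on the two models).
#'
#' @param model_a,model_b `structure_model`s.
#' @param alignment An `alignment_result` whose records ungap to the two
#'   models' chain sequences.
#' @return A `correspondence`: data frame `pairs` (key_a, key_b) plus the
#'   pairing method.
#' @export
pair_residues <- function(model_a, model_b, alignment) {
  ka <- alignment$record_a$residue_keys
  kb <- alignment$record_b$residue_keys
  if (is.null(ka) || is.null(kb)) {
    stop2("alignment records carry no residue keys; extract sequences from the models first")
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  if (paste(ca[ca != "-"], collapse = "") != alignment$record_a$letters ||
      paste(cb[cb != "-"], collapse = "") != alignment$record_b$letters) {
    stop2("alignment does not ungap to its input sequences")
  }
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  sel <- ca != "-" & cb != "-"
  pairs <- data.frame(key_a = ka[ia[sel]], key_b = kb[ib[sel]],
                      stringsAsFactors = FALSE)
  has_ca_a <- !is.na(atom_coords(model_a, pairs$key_a, "CA")[, 1])
  has_ca_b <- !is.na(atom_coords(model_b, pairs$key_b, "CA")[, 1])
  pairs <- pairs[has_ca_a & has_ca_b, , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0) stop2("no alignable residue pairs with C-alpha atoms")
  structure(list(pairs = pairs, method = "alignment"),
            class = "correspondence")
}

#' @export
print.correspondence <- function(x, ...) {
  cat(sprintf("correspondence (%s): %d residue pairs\n", x$method,
              nrow(x$pairs)))
  invisible(x)
}

#' Least-squares (Kabsch) superposition of paired coordinates
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `coords_b` onto `coords_a`. Reflections are never returned: when the
#' determinant of the raw solution is negative, the axis of smallest
#' singular value is negated.
#'
#' @param coords_a,coords_b n x 3 matrices of paired positions (Angstrom).
#' @return A `superposition`: `rotation` (3 x 3, det +1; applied to row
#'   vectors as `x %*% rotation`), `translation` (length-3), `rmsd_all`
#'   (Angstrom), `n_pairs`, and the fitted coordinates.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  stopifnot(ncol(coords_a) == 3, ncol(coords_b) == 3)
  n <- nrow(coords_a)
  if (nrow(coords_b) != n) stop2("coordinate sets differ in size")
  if (n < 3) stop2("need at least 3 paired atoms, got %d", n)
  if (anyNA(coords_a) || anyNA(coords_b)) stop2("NA coordinates in input")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  ac <- sweep(coords_a, 2, ca); bc <- sweep(coords_b, 2, cb)
  if (svd(ac)$d[2] < 1e-8 || svd(bc)$d[2] < 1e-8) {
    stop2("degenerate geometry: paired atoms are collinear")
  }
  s <- svd(t(bc) %*% ac)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- bc %*% rot
  rmsd <- sqrt(mean(rowSums((ac - fitted)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(ca - cb %*% rot),
                 rmsd_all = rmsd, n_pairs = n,
                 coords_a = coords_a,
                 coords_b_fitted = sweep(fitted, 2, ca, FUN = "+"),
                 rmsd_by_class = NULL, pair_keys = NULL),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d pairs, RMSD %.3f A\n", x$n_pairs,
              x$rmsd_all))
  if (!is.null(x$rmsd_by_class)) {
    for (cl in names(x$rmsd_by_class)) {
      cat(sprintf("  %-6s %.3f A (%d)\n", cl, x$rmsd_by_class[[cl]]$rmsd,
                  x$rmsd_by_class[[cl]]$n))
    }
  }
  invisible(x)
}

#' Superpose two structures on corresponding C-alpha atoms
#'
#' Convenience wrapper: extracts paired C-alpha coordinates through a
#' `correspondence` and runs [kabsch_superpose()]. The returned object
#' carries the pair keys, enabling [classwise_rmsd()].
#'
#' @param model_a Reference `structure_model`.
#' @param model_b Mobile `structure_model`.
#' @param corr A `correspondence` between the two.
#' @return A `superposition` (see [kabsch_superpose()]).
#' @export
superpose_models <- function(model_a, model_b, corr) {
  xa <- atom_coords(model_a, corr$pairs$key_a, "CA")
  xb <- atom_coords(model_b, corr$pairs$key_b, "CA")
  ok <- !is.na(xa[, 1]) & !is.na(xb[, 1])
  sup <- kabsch_superpose(xa[ok, , drop = FALSE], xb[ok, , drop = FALSE])
  sup$pair_keys <- corr$pairs[ok, , drop = FALSE]
  sup
}

#' RMSD by secondary-structure class
#'
#' Restricts a superposition's deviations to the pairs whose reference
#' (model A) residue falls in each 3-state class of `sse_a`.
#'
#' @param sup A `superposition` from [superpose_models()].
#' @param corr The `correspondence` used (defaults to pairs stored in `sup`).
#' @param sse_a An `sse_assignment` for the reference structure.
#' @return The `superposition` with `rmsd_by_class` filled: named list
#'   (helix/strand/loop) of `list(rmsd, n)`; classes with no pairs absent.
#' @export
classwise_rmsd <- function(sup, corr = NULL, sse_a) {
  keys <- if (!is.null(corr)) corr$pairs else sup$pair_keys
  if (is.null(keys)) stop2("superposition carries no pair keys; pass corr")
  if (nrow(keys) != sup$n_pairs) stop2("correspondence size != n_pairs")
  cls3 <- sse_a$residues$sse3[match(keys$key_a, sse_a$residues$key)]
  dev2 <- rowSums((sup$coords_a - sup$coords_b_fitted)^2)
  out <- list()
  for (cl in c("helix", "strand", "loop")) {
    code <- c(helix = "H", strand = "E", loop = "C")[[cl]]
    sel <- !is.na(cls3) & cls3 == code
    if (any(sel)) {
      out[[cl]] <- list(rmsd = sqrt(mean(dev2[sel])), n = sum(sel))
    }
  }
  sup$rmsd_by_class <- out
  sup
}

#' Catalytic triad hydrogen-bond geometry
#'
#' Distances Ser OG - His NE2 and His ND1 - nearest of Asp OD1/OD2 (or Glu
#' OE1/OE2), the canonical charge-relay contacts of a Ser-His-Asp triad.
#'
#' @param model A `structure_model`.
#' @param triad Character vector of three residue keys, in order
#'   (Ser, His, Asp/Glu).
#' @return A `triad_geometry`: `ser_his_dist`, `his_asp_dist` (Angstrom),
#'   `triad_keys`.
#' @export
triad_distances <- function(model, triad) {
  stopifnot(length(triad) == 3)
  get_atom <- function(key, names_try) {
    at <- residue_atoms(model, key)
    if (nrow(at) == 0) stop2("residue %s not found", key)
    hit <- at[at$name %in% names_try, , drop = FALSE]
    if (nrow(hit) == 0) {
      stop2("residue %s (%s) lacks side-chain atom %s", key, at$resname[1],
            paste(names_try, collapse = "/"))
    }
    as.matrix(hit[, c("x", "y", "z")])
  }
  ser_og <- get_atom(triad[1], "OG")
  his_ne2 <- get_atom(triad[2], "NE2")
  his_nd1 <- get_atom(triad[2], "ND1")
  acid <- get_atom(triad[3], c("OD1", "OD2", "OE1", "OE2"))
  d_sh <- vnorm(ser_og[1, ] - his_ne2[1, ])
  d_ha <- min(sqrt(rowSums(sweep(acid, 2, his_nd1[1, ])^2)))
  structure(list(ser_his_dist = d_sh, his_asp_dist = d_ha,
                 triad_keys = triad),
            class = "triad_geometry")
}

#' @export
print.triad_geometry <- function(x, ...) {
  cat(sprintf("triad %s: Ser(OG)-His(NE2) %.1f A, His(ND1)-acid(ODx) %.1f A\n",
              paste(x$triad_keys, collapse = "/"), x$ser_his_dist,
              x$his_asp_dist))
  invisible(x)
}
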