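# Cross-homolog comparative analyses: salt-bridge conservation, amino-acid
# composition trends, deamidation motif scan, directional substitution-rule
# counting, and the candidate selection filter cascade.

#' Map salt-bridge conservation from a reference onto a homolog
#'
#' A reference ionic bridge counts as conserved when both partner residues
#' map through the correspondence AND the mapped pair still satisfies the
#' ionic criteria in the homolog structure. A partner aligned to a gap, or
#' a mapped pair that no longer carries the charged side-chain geometry,
#' makes the bridge lost.
#'
#' @param ref_bridges Ionic interaction records of the reference (from
#'   [detect_interactions()] with kind `"ionic"`).
#' @param homolog A `structure_model`.
#' @param corr A `correspondence` from reference to homolog.
#' @param criteria A `criteria_set`.
#' @return A `bridge_conservation` data frame: ref_a, ref_b, mapped_a,
#'   mapped_b (NA when unaligned), status (`conserved`/`lost`).
#' @export
map_bridge_conservation <- function(ref_bridges, homolog, corr,
                                    criteria = default_criteria()) {
  stopifnot(inherits(corr, "correspondence"))
  hom_res <- residue_table(homolog)
  unknown <- setdiff(corr$pairs$key_b, hom_res$key)
  if (length(unknown) > 0) {
    stop2("correspondence references unknown homolog residue %s", unknown[1])
  }
  hom_ionic <- detect_interactions(homolog, "ionic", criteria)
  hom_pairs <- paste(hom_ionic$key_a, hom_ionic$key_b)
  map <- stats::setNames(corr$pairs$key_b, corr$pairs$key_a)
  out <- data.frame(ref_a = ref_bridges$key_a, ref_b = ref_bridges$key_b,
                    mapped_a = unname(map[ref_bridges$key_a]),
                    mapped_b = unname(map[ref_bridges$key_b]),
                    stringsAsFactors = FALSE)
  satisfied <- !is.na(out$mapped_a) & !is.na(out$mapped_b) &
    (paste(out$mapped_a, out$mapped_b) %in% hom_pairs |
       paste(out$mapped_b, out$mapped_a) %in% hom_pairs)
  out$status <- ifelse(satisfied, "conserved", "lost")
  class(out) <- c("bridge_conservation", "data.frame")
  out
}

#' Amino-acid composition trends across a temperature ladder
#'
#' Per-residue-type counts for each sequence and the Spearman rank
#' correlation of count against host growth temperature. Direction is the
#' sign of rho when `|rho| >= 0.5`, else flat; with a handful of enzymes
#' this is descriptive, not inferential.
#'
#' @param seqs List of `sequence_record`s.
#' @param host_temps Numeric vector of host growth temperatures (degrees
#'   C), parallel to `seqs`.
#' @return A `composition_trend` data frame: one row per amino acid with
#'   counts per sequence, `rho` and `direction`.
#' @export
composition_trend <- function(seqs, host_temps) {
  if (length(seqs) < 3) stop2("need at least 3 sequences, got %d",
                              length(seqs))
  if (length(host_temps) != length(seqs)) {
    stop2("host_temps length (%d) != number of sequences (%d)",
          length(host_temps), length(seqs))
  }
  if (anyDuplicated(host_temps)) {
    warn2("duplicate host temperatures; Spearman rho uses midranks")
  }
  aas <- sort(unname(AA_3TO1))
  counts <- vapply(seqs, function(s) {
    ch <- strsplit(s$letters, "")[[1]]
    vapply(aas, function(a) sum(ch == a), integer(1))
  }, integer(length(aas)))
  colnames(counts) <- vapply(seqs, function(s) s$id, "")
  rho <- apply(counts, 1, function(x) {
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, host_temps, method = "spearman")
  })
  direction <- ifelse(abs(rho) < 0.5, "flat",
                      ifelse(rho > 0, "increasing", "decreasing"))
  out <- data.frame(aa = aas, counts, rho = rho, direction = direction,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("composition_trend", "data.frame")
  out
}

DEAMIDATION_FOLLOWERS <- c("G", "S", "H", "A", "D")

#' Scan a sequence for deamidation-prone Asn motifs
#'
#' Asparagine deamidation is accelerated when Asn is followed by Gly, Ser,
#' His, Ala or Asp. Reports every such N-X pair; positions are author
#' residue numbers when the record carries residue keys, else 1-based
#' sequence positions.
#'
#' @param seq A `sequence_record` or string.
#' @return Data frame: position (sequence index), key (residue key or NA),
#'   motif (e.g. `"ND"`).
#' @export
deamidation_scan <- function(seq) {
  rec <- as_sequence_record(seq, "seq")
  if (nchar(rec$letters) == 0) stop2("empty sequence")
  ch <- strsplit(rec$letters, "")[[1]]
  n <- length(ch)
  hits <- which(ch[-n] == "N" & ch[-1] %in% DEAMIDATION_FOLLOWERS)
  data.frame(position = hits,
             key = if (!is.null(rec$residue_keys)) rec$residue_keys[hits]
                   else rep(NA_character_, length(hits)),
             motif = paste0("N", ch[hits + 1]),
             stringsAsFactors = FALSE)
}

#' Count directional substitutions along an alignment
#'
#' For each rule `from -> to`, counts aligned columns carrying `from` in
#' sequence A and `to` in sequence B. Direction matters; gap columns never
#' count.
#'
#' @param alignment An `alignment_result`.
#' @param rules Data frame or list of 2-vectors with columns/elements
#'   (from, to), 1-letter codes.
#' @return Data frame: from, to, count.
#' @export
substitution_rule_count <- function(alignment, rules) {
  if (is.list(rules) && !is.data.frame(rules)) {
    rules <- data.frame(from = vapply(rules, `[`, "", 1),
                        to = vapply(rules, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  rules$count <- vapply(seq_len(nrow(rules)), function(r) {
    sum(both & ca == rules$from[r] & cb == rules$to[r])
  }, integer(1))
  rules
}

FILTER_CRITERIA <- c(
  a = "pathogenic organism",
  b = "membrane-bound",
  c = "resolution above 3 A",
  d = "no primary literature",
  e = "heteromultimeric",
  f = "structure not solved by X-ray crystallography",
  g = "sequence identity outside [35, 50]%",
  h = "sequence length not below 400 residues",
  i = "catalytic triad not conserved")

#' Filter candidate enzymes by the selection criteria cascade
#'
#' Rejects candidates that are (a) from pathogenic organisms, (b)
#' membrane-bound, (c) solved at resolution above 3 Angstrom, (d) without
#' primary literature, (e) heteromultimeric, or (f) solved by a method
#' other than X-ray crystallography. In homolog mode (reference structure
#' known) candidates must additionally have (g) sequence identity to the
#' reference within the closed band 35-50%, (h) length below 400 residues
#' and (i) a conserved catalytic triad. Every rejection lists all failed
#' criteria.
#'
#' @param records Data frame with columns id, pathogenic, membrane_bound,
#'   resolution (Angstrom, NA allowed), has_primary_literature,
#'   heteromultimeric, method (`"xray"` or other) and, in homolog mode,
#'   identity_to_ref, length, triad_conserved.
#' @param reference_known_structure Logical; TRUE enables criteria (g)-(i).
#' @return List with `kept` (data frame) and `rejected` (data frame with a
#'   `reasons` column of failed criterion letters).
#' @export
filter_candidates <- function(records, reference_known_structure = FALSE) {
  need <- c("id", "pathogenic", "membrane_bound", "resolution",
            "has_primary_literature", "heteromultimeric", "method")
  if (reference_known_structure) {
    need <- c(need, "identity_to_ref", "length", "triad_conserved")
  }
  missing <- setdiff(need, names(records))
  if (length(missing) > 0) stop2("missing required field: %s", missing[1])

  fails <- lapply(seq_len(nrow(records)), function(r) {
    x <- records[r, ]
    f <- character()
    if (isTRUE(x$pathogenic)) f <- c(f, "a")
    if (isTRUE(x$membrane_bound)) f <- c(f, "b")
    if (!is.na(x$resolution) && x$resolution > 3) f <- c(f, "c")
    if (!isTRUE(x$has_primary_literature)) f <- c(f, "d")
    if (isTRUE(x$heteromultimeric)) f <- c(f, "e")
    if (!identical(tolower(x$method), "xray")) f <- c(f, "f")
    if (reference_known_structure) {
      if (is.na(x$identity_to_ref) || x$identity_to_ref < 35 ||
          x$identity_to_ref > 50) f <- c(f, "g")
      if (is.na(x$length) || x$length >= 400) f <- c(f, "h")
      if (!isTRUE(x$triad_conserved)) f <- c(f, "i")
    }
    f
  })
  ok <- lengths(fails) == 0
  rejected <- records[!ok, , drop = FALSE]
  rejected$reasons <- vapply(fails[!ok], paste, "", collapse = ",")
  list(kept = records[ok, , drop = FALSE], rejected = rejected)
}
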