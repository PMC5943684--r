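# Kabsch-Sander secondary-structure assignment and loop segmentation.
#
# Re-implemented from the backbone hydrogen-bond energy model so that no
# external DSSP binary is required. Amide hydrogens are rebuilt from
# backbone geometry. The 8-state letters are retained internally and
# collapsed to 3 states as H,G,I -> helix; E,B -> strand; everything else
# (turns, bends, coil) -> loop, the convention under which turn/bend
# residues count as loop residues.

KS_Q <- 0.084 * 332  # electrostatic H-bond energy prefactor, kcal/mol * A
KS_EMAX <- -0.5      # bond iff E below this, kcal/mol

#' Assign secondary structure (Kabsch-Sander)
#'
#' Backbone H-bond energies are computed as
#' `E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN)` kcal/mol with the
#' amide H placed 1 Angstrom from N opposite the preceding carbonyl; a bond
#' exists when `E < -0.5` kcal/mol. N-turn and bridge patterns yield 8-state
#' labels (H,G,I,E,B,T and '-'), collapsed to 3 states.
#'
#' @param model A `structure_model`.
#' @return An `sse_assignment`: `residues` (data frame with key, chain,
#'   resseq, icode, resname, sse8, sse3, flagged) and `hbonds` (data frame:
#'   acceptor_key, donor_key, energy).
#' @export
assign_sse <- function(model) {
  res <- residue_table(model)
  n <- nrow(res)
  bb <- list(
    N = atom_coords(model, res$key, "N"),
    CA = atom_coords(model, res$key, "CA"),
    C = atom_coords(model, res$key, "C"),
    O = atom_coords(model, res$key, "O"))
  complete <- !Reduce(`|`, lapply(bb, function(m) is.na(m[, 1])))

  # chain segments: same chain, complete backbone, peptide bond intact
  seg <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    new_seg <- i == 1 || res$chain[i] != res$chain[i - 1] ||
      !complete[i] || !complete[i - 1] ||
      vnorm(bb$N[i, ] - bb$C[i - 1, ]) > 2.5
    if (new_seg) cur <- cur + 1L
    seg[i] <- cur
  }

  # rebuild amide H: h = n + (c_prev - o_prev)/|c_prev - o_prev|
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!complete[i] || res$resname[i] == "PRO") next
    if (i > 1 && seg[i] == seg[i - 1]) {
      H[i, ] <- bb$N[i, ] + unit(bb$C[i - 1, ] - bb$O[i - 1, ])
    }
  }

  # H-bond energies: acceptor i (C=O), donor j (N-H)
  hb <- matrix(FALSE, n, n)
  energies <- NULL
  if (any(complete)) {
    ca_ok <- which(complete)
    dmat <- as.matrix(stats::dist(bb$CA[ca_ok, , drop = FALSE]))
    cand <- which(dmat < 9, arr.ind = TRUE)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- ca_ok[cand[r, 1]]  # acceptor
      j <- ca_ok[cand[r, 2]]  # donor
      if (abs(i - j) < 2 && seg[i] == seg[j]) next
      if (is.na(H[j, 1])) next
      d_on <- vnorm(bb$O[i, ] - bb$N[j, ])
      d_ch <- vnorm(bb$C[i, ] - H[j, ])
      d_oh <- vnorm(bb$O[i, ] - H[j, ])
      d_cn <- vnorm(bb$C[i, ] - bb$N[j, ])
      if (min(d_on, d_oh) < 0.5) next  # clashing, treat as no bond
      e <- KS_Q * (1 / d_on + 1 / d_ch - 1 / d_oh - 1 / d_cn)
      if (e < KS_EMAX) {
        hb[i, j] <- TRUE
        energies <- rbind(energies, c(i, j, e))
      }
    }
  }

  # turns: turn_k(i) iff CO(i) accepts NH(i+k)
  turn <- list()
  for (k in 3:5) {
    t_k <- logical(n)
    idx <- seq_len(max(0, n - k))
    for (i in idx) {
      if (seg[i] == seg[i + k] && hb[i, i + k]) t_k[i] <- TRUE
    }
    turn[[as.character(k)]] <- t_k
  }

  helix_set <- function(k) {
    t_k <- turn[[as.character(k)]]
    lab <- logical(n)
    for (i in seq_len(n)) {
      if (i >= 2 && t_k[i] && t_k[i - 1]) {
        lab[i:min(n, i + k - 1)] <- TRUE
      }
    }
    lab
  }
  is_H <- helix_set(4)
  is_G <- helix_set(3)
  is_I <- helix_set(5)

  # bridges
  bridged <- logical(n)
  bridge_pairs <- NULL
  in_seg <- function(i) i >= 1 && i <= n
  HBs <- function(a, b) in_seg(a) && in_seg(b) && hb[a, b]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      par <- (HBs(i - 1, j) && HBs(j, i + 1)) || (HBs(j - 1, i) && HBs(i, j + 1))
      anti <- (HBs(i, j) && HBs(j, i)) || (HBs(i - 1, j + 1) && HBs(j - 1, i + 1))
      if (par || anti) {
        bridged[c(i, j)] <- TRUE
        bridge_pairs <- rbind(bridge_pairs, c(i, j))
      }
    }
  }
  is_E <- logical(n); is_B <- logical(n)
  if (!is.null(bridge_pairs)) {
    bp <- paste(bridge_pairs[, 1], bridge_pairs[, 2])
    has_neighbor <- function(i, j) {
      any(paste(c(i + 1, i + 1, i - 1, i - 1), c(j + 1, j - 1, j + 1, j - 1)) %in% bp)
    }
    for (r in seq_len(nrow(bridge_pairs))) {
      i <- bridge_pairs[r, 1]; j <- bridge_pairs[r, 2]
      if (has_neighbor(i, j)) is_E[c(i, j)] <- TRUE else is_B[c(i, j)] <- TRUE
    }
  }

  is_T <- logical(n)
  for (k in 3:5) {
    t_k <- turn[[as.character(k)]]
    for (i in which(t_k)) {
      span <- (i + 1):(i + k - 1)
      is_T[span[span <= n]] <- TRUE
    }
  }

  sse8 <- rep("-", n)
  sse8[is_T] <- "T"
  sse8[is_I] <- "I"
  sse8[is_G] <- "G"
  sse8[is_B & !is_E] <- "B"
  sse8[is_E] <- "E"
  sse8[is_H] <- "H"
  sse8[!complete] <- "-"

  sse3 <- rep("C", n)
  sse3[sse8 %in% c("H", "G", "I")] <- "H"
  sse3[sse8 %in% c("E", "B")] <- "E"

  if (n < 4) warn2("chain shorter than 4 residues; all residues labeled loop")

  hbonds <- if (is.null(energies)) {
    data.frame(acceptor_key = character(), donor_key = character(),
               energy = numeric())
  } else {
    data.frame(acceptor_key = res$key[energies[, 1]],
               donor_key = res$key[energies[, 2]],
               energy = energies[, 3], stringsAsFactors = FALSE)
  }
  residues <- cbind(res, sse8 = sse8, sse3 = sse3,
                    flagged = !complete, stringsAsFactors = FALSE)
  structure(list(residues = residues, hbonds = hbonds,
                 model_id = model$id),
            class = "sse_assignment")
}

#' @export
print.sse_assignment <- function(x, ...) {
  tab <- table(factor(x$residues$sse3, levels = c("H", "E", "C")))
  cat(sprintf("sse_assignment for '%s': %d residues (H %d, E %d, C %d), %d backbone H-bonds\n",
              x$model_id, nrow(x$residues), tab["H"], tab["E"], tab["C"],
              nrow(x$hbonds)))
  invisible(x)
}

#' Segment loop regions from a secondary-structure assignment
#'
#' Maximal runs of loop-class residues of length at least `min_len`, within
#' one chain, numbered L1..Ln from the N-terminus. Chain termini are
#' included.
#'
#' @param sse An `sse_assignment`.
#' @param min_len Minimum run length (default 2).
#' @return A `loop_regions` data frame: loop_id, chain, first_key, last_key,
#'   first_resseq, last_resseq, length, surface_exposed (NA until filled by
#'   a census).
#' @export
segment_loops <- function(sse, min_len = 2L) {
  res <- sse$residues
  is_c <- res$sse3 == "C"
  run_id <- cumsum(c(TRUE, diff(as.integer(is_c)) != 0 |
                       res$chain[-1] != res$chain[-nrow(res)]))
  out <- NULL
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    if (!is_c[idx[1]] || length(idx) < min_len) next
    out <- rbind(out, data.frame(
      chain = res$chain[idx[1]],
      first_key = res$key[idx[1]], last_key = res$key[idx[length(idx)]],
      first_resseq = res$resseq[idx[1]],
      last_resseq = res$resseq[idx[length(idx)]],
      length = length(idx), stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(loop_id = character(), chain = character(),
                      first_key = character(), last_key = character(),
                      first_resseq = integer(), last_resseq = integer(),
                      length = integer(), surface_exposed = logical())
    class(out) <- c("loop_regions", "data.frame")
    return(out)
  }
  out <- cbind(loop_id = paste0("L", seq_len(nrow(out))), out,
               surface_exposed = NA, stringsAsFactors = FALSE)
  class(out) <- c("loop_regions", "data.frame")
  out
}

#' Residue keys covered by loop regions
#' @param sse An `sse_assignment`.
#' @param loops A `loop_regions` table from [segment_loops()].
#' @return Character vector of residue keys inside the loop spans.
#' @export
loop_residue_keys <- function(sse, loops) {
  res <- sse$residues
  keys <- character()
  for (r in seq_len(nrow(loops))) {
    i1 <- match(loops$first_key[r], res$key)
    i2 <- match(loops$last_key[r], res$key)
    keys <- c(keys, res$key[i1:i2])
  }
  keys
}

#' Secondary-structure composition percentages
#'
#' Integer percentages of helix, strand and loop residues, rounded by the
#' largest-remainder rule so they always sum to exactly 100.
#'
#' @param sse An `sse_assignment`.
#' @return Named integer vector: helix_pct, strand_pct, loop_pct.
#' @export
sse_fractions <- function(sse) {
  counts <- table(factor(sse$residues$sse3, levels = c("H", "E", "C")))
  pct <- largest_remainder_pct(as.numeric(counts))
  stats::setNames(pct, c("helix_pct", "strand_pct", "loop_pct"))
}
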