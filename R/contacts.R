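# Geometric interaction detection, Shrake-Rupley SASA and the interaction
# census with loop/surface partitioning.

HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "PRO", "TYR")
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

AROMATIC_RING <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

CATION_ATOMS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                     HIS = c("ND1", "NE2"))
ANION_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

SC_DONORS <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                  HIS = c("ND1", "NE2"), TRP = "NE1", ASN = "ND2",
                  GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH")
SC_ACCEPTORS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                     TYR = "OH", HIS = "ND1")
ACCEPTOR_ANTECEDENT <- c(O = "C", OXT = "C", OD1 = "CG", OD2 = "CG",
                         OE1 = "CD", OE2 = "CD", OG = "CB", OG1 = "CB",
                         OH = "CZ", ND1 = "CG")

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
               SE = 1.90)

# Theoretical Gly-X-Gly maximum accessibilities (A^2), Tien et al. 2013.
MAX_SASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
              GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
              LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
              SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Default geometric interaction criteria
#'
#' Cutoffs mirroring the documented defaults of residue-level interaction
#' calculators: hydrophobic side-chain carbon contacts within 5 Angstrom,
#' aromatic ring centroids between 4.5 and 7 Angstrom, ionic side-chain N/O
#' pairs within 6 Angstrom, and heavy-atom hydrogen bonds within 3.5
#' Angstrom with a donor-acceptor-antecedent angle of at least 90 degrees.
#'
#' @param ... Named overrides of any default.
#' @return A `criteria_set` list.
#' @export
default_criteria <- function(...) {
  cr <- list(
    hydrophobic_cutoff = 5.0, hydrophobic_min_seqsep = 2L,
    aromatic_min = 4.5, aromatic_max = 7.0,
    ionic_cutoff = 6.0, ionic_include_his = TRUE,
    hbond_cutoff = 3.5, hbond_min_angle = 90,
    hbond_min_seqsep_sidechain = 1L, hbond_min_seqsep_backbone = 2L,
    surface_rel_sasa = 0.20, sasa_probe = 1.4, sasa_n_points = 960L)
  override <- list(...)
  unknown <- setdiff(names(override), names(cr))
  if (length(unknown) > 0) stop2("unknown criteria: %s",
                                 paste(unknown, collapse = ", "))
  cr[names(override)] <- override
  structure(cr, class = "criteria_set")
}

# side-chain atoms of one model as data frame with residue index
.sidechain_atoms <- function(model, res) {
  at <- model$atoms[!model$atoms$hetero, , drop = FALSE]
  at$key <- res_key(at$chain, at$resseq, at$icode)
  at$ridx <- match(at$key, res$key)
  at[!is.na(at$ridx) & !(at$name %in% BACKBONE_ATOMS), , drop = FALSE]
}

#' Detect residue interactions of one kind
#'
#' Geometric detection of hydrophobic, aromatic, ionic or hydrogen-bond
#' contacts. Hydrophobic, aromatic and ionic contacts are recorded once per
#' residue pair (with the minimal qualifying distance); hydrogen bonds once
#' per donor-acceptor atom pair.
#'
#' @param model A `structure_model`.
#' @param kind One of `"hydrophobic"`, `"aromatic"`, `"ionic"`, `"hbond"`.
#' @param criteria A `criteria_set` (see [default_criteria()]).
#' @return Data frame of interaction records: kind, key_a, key_b, res_a,
#'   res_b, atom_a, atom_b, distance, seq_sep; attribute `model_id`.
#' @export
detect_interactions <- function(model, kind = c("hydrophobic", "aromatic",
                                                "ionic", "hbond"),
                                criteria = default_criteria()) {
  kind <- match.arg(kind)
  res <- residue_table(model)
  out <- switch(kind,
    hydrophobic = .detect_hydrophobic(model, res, criteria),
    aromatic = .detect_aromatic(model, res, criteria),
    ionic = .detect_ionic(model, res, criteria),
    hbond = .detect_hbond(model, res, criteria))
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(kind = character(), key_a = character(),
                      key_b = character(), res_a = character(),
                      res_b = character(), atom_a = character(),
                      atom_b = character(), distance = numeric(),
                      seq_sep = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "model_id") <- model$id
  out
}

# one record per residue pair, ordered by residue index
.pair_records <- function(kind, res, ridx_a, ridx_b, atom_a, atom_b, dist) {
  swap <- ridx_a > ridx_b
  tmp <- ridx_a[swap]; ridx_a[swap] <- ridx_b[swap]; ridx_b[swap] <- tmp
  tmp <- atom_a[swap]; atom_a[swap] <- atom_b[swap]; atom_b[swap] <- tmp
  df <- data.frame(kind = kind, key_a = res$key[ridx_a],
                   key_b = res$key[ridx_b], res_a = res$resname[ridx_a],
                   res_b = res$resname[ridx_b], atom_a = atom_a,
                   atom_b = atom_b, distance = dist,
                   seq_sep = abs(ridx_b - ridx_a), stringsAsFactors = FALSE)
  df <- df[order(df$distance), , drop = FALSE]
  df <- df[!duplicated(paste(df$key_a, df$key_b)), , drop = FALSE]
  df[order(match(df$key_a, res$key), match(df$key_b, res$key)), ,
     drop = FALSE]
}

.detect_hydrophobic <- function(model, res, cr) {
  sc <- .sidechain_atoms(model, res)
  sc <- sc[sc$resname %in% HYDROPHOBIC_RES & sc$element == "C", , drop = FALSE]
  if (nrow(sc) < 2) return(NULL)
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cr$hydrophobic_cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  ra <- sc$ridx[hit[, 1]]; rb <- sc$ridx[hit[, 2]]
  keep <- abs(ra - rb) >= cr$hydrophobic_min_seqsep
  if (!any(keep)) return(NULL)
  .pair_records("hydrophobic", res, ra[keep], rb[keep],
                sc$name[hit[keep, 1]], sc$name[hit[keep, 2]],
                d[hit[keep, , drop = FALSE]])
}

.detect_aromatic <- function(model, res, cr) {
  sc <- .sidechain_atoms(model, res)
  cent <- NULL
  for (i in which(res$resname %in% names(AROMATIC_RING))) {
    ring <- AROMATIC_RING[[res$resname[i]]]
    at <- sc[sc$ridx == i & sc$name %in% ring, , drop = FALSE]
    if (nrow(at) < 3) next
    cent <- rbind(cent, data.frame(ridx = i,
                                   x = mean(at$x), y = mean(at$y),
                                   z = mean(at$z)))
  }
  if (is.null(cent) || nrow(cent) < 2) return(NULL)
  d <- as.matrix(stats::dist(as.matrix(cent[, c("x", "y", "z")])))
  hit <- which(d >= cr$aromatic_min & d <= cr$aromatic_max & upper.tri(d),
               arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  .pair_records("aromatic", res, cent$ridx[hit[, 1]], cent$ridx[hit[, 2]],
                "ring", "ring", d[hit])
}

.detect_ionic <- function(model, res, cr) {
  sc <- .sidechain_atoms(model, res)
  cat_atoms <- CATION_ATOMS
  if (!cr$ionic_include_his) cat_atoms$HIS <- NULL
  pick <- function(defs) {
    sel <- rep(FALSE, nrow(sc))
    for (rn in names(defs)) {
      sel <- sel | (sc$resname == rn & sc$name %in% defs[[rn]])
    }
    sc[sel, , drop = FALSE]
  }
  pos <- pick(cat_atoms)
  neg <- pick(ANION_ATOMS)
  if (nrow(pos) == 0 || nrow(neg) == 0) return(NULL)
  px <- as.matrix(pos[, c("x", "y", "z")])
  nx <- as.matrix(neg[, c("x", "y", "z")])
  d2 <- outer(rowSums(px^2), rowSums(nx^2), "+") - 2 * px %*% t(nx)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= cr$ionic_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  ra <- pos$ridx[hit[, 1]]; rb <- neg$ridx[hit[, 2]]
  keep <- ra != rb
  if (!any(keep)) return(NULL)
  .pair_records("ionic", res, ra[keep], rb[keep],
                pos$name[hit[keep, 1]], neg$name[hit[keep, 2]], d[hit][keep])
}

.detect_hbond <- function(model, res, cr) {
  at <- model$atoms[!model$atoms$hetero, , drop = FALSE]
  at$key <- res_key(at$chain, at$resseq, at$icode)
  at$ridx <- match(at$key, res$key)
  at <- at[!is.na(at$ridx), , drop = FALSE]

  don_sel <- (at$name == "N" & at$resname != "PRO")
  acc_sel <- at$name %in% c("O", "OXT")
  for (rn in names(SC_DONORS)) {
    don_sel <- don_sel | (at$resname == rn & at$name %in% SC_DONORS[[rn]])
  }
  for (rn in names(SC_ACCEPTORS)) {
    acc_sel <- acc_sel | (at$resname == rn & at$name %in% SC_ACCEPTORS[[rn]])
  }
  don <- at[don_sel, , drop = FALSE]
  acc <- at[acc_sel, , drop = FALSE]
  if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
  dx <- as.matrix(don[, c("x", "y", "z")])
  ax <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- outer(rowSums(dx^2), rowSums(ax^2), "+") - 2 * dx %*% t(ax)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= cr$hbond_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)

  recs <- NULL
  for (r in seq_len(nrow(hit))) {
    di <- hit[r, 1]; ai <- hit[r, 2]
    rd <- don$ridx[di]; ra <- acc$ridx[ai]
    sep <- abs(rd - ra)
    if (sep == 0) next
    bb_bb <- don$name[di] == "N" && acc$name[ai] %in% c("O", "OXT")
    min_sep <- if (bb_bb) cr$hbond_min_seqsep_backbone else
      cr$hbond_min_seqsep_sidechain
    if (sep < min_sep) next
    ante_name <- ACCEPTOR_ANTECEDENT[[acc$name[ai]]]
    if (!is.null(ante_name)) {
      ante <- at[at$ridx == ra & at$name == ante_name, , drop = FALSE]
      if (nrow(ante) == 1) {
        ang <- vangle(c(dx[di, 1], dx[di, 2], dx[di, 3]),
                      c(ax[ai, 1], ax[ai, 2], ax[ai, 3]),
                      c(ante$x[1], ante$y[1], ante$z[1]))
        if (ang < cr$hbond_min_angle) next
      }
    }
    recs <- rbind(recs, data.frame(
      kind = "hbond",
      key_a = res$key[min(rd, ra)], key_b = res$key[max(rd, ra)],
      res_a = res$resname[min(rd, ra)], res_b = res$resname[max(rd, ra)],
      atom_a = if (rd <= ra) don$name[di] else acc$name[ai],
      atom_b = if (rd <= ra) acc$name[ai] else don$name[di],
      distance = d[di, ai], seq_sep = sep, stringsAsFactors = FALSE))
  }
  if (is.null(recs)) return(NULL)
  recs[!duplicated(paste(recs$key_a, recs$key_b, recs$atom_a, recs$atom_b)), ,
       drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA with test points on a deterministic Fibonacci sphere
#' lattice. Relative SASA normalizes by theoretical Gly-X-Gly maxima;
#' residues with relative SASA at or above the surface threshold are
#' flagged exposed.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius, Angstrom (default 1.4).
#' @param n_points Sphere points per atom (default 960).
#' @param criteria Optional `criteria_set` supplying the surface threshold.
#' @return A `sasa_profile` data frame: key, resname, abs_sasa (A^2),
#'   rel_sasa, exposed; attributes probe, n_points, model_id.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960L,
                               criteria = default_criteria()) {
  at <- model$atoms
  at <- at[!(at$hetero & at$resname %in% WATER_RESNAMES), , drop = FALSE]
  elem <- toupper(at$element)
  radii <- VDW_RADII[elem]
  miss <- is.na(radii)
  if (any(miss)) {
    # fallback from the first letter of the atom name
    guess <- VDW_RADII[substr(gsub("[0-9]", "", at$name[miss]), 1, 1)]
    if (anyNA(guess)) {
      stop2("unknown element '%s' with no radius fallback",
            elem[miss][is.na(guess)][1])
    }
    radii[miss] <- guess
  }

  # Fibonacci sphere lattice (deterministic)
  i <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * i / n_points)
  theta <- pi * (1 + sqrt(5)) * i
  sphere <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))

  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  ext <- radii + probe
  area <- numeric(n)
  # neighbor lists from one pass over the distance matrix
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  maxr <- outer(ext, ext, "+")
  for (k in seq_len(n)) {
    nb <- which(d2[k, ] < maxr[k, ]^2)
    nb <- nb[nb != k]
    pts <- sweep(sphere * ext[k], 2, xyz[k, ], FUN = "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
          (pts[acc, 3] - xyz[j, 3])^2
        acc[acc] <- dj2 >= ext[j]^2
      }
      frac <- sum(acc) / n_points
    } else {
      frac <- 1
    }
    area[k] <- 4 * pi * ext[k]^2 * frac
  }

  key <- res_key(at$chain, at$resseq, at$icode)
  res <- residue_table(model)
  abs_sasa <- tapply(area, key, sum)
  prof <- data.frame(key = res$key, resname = res$resname,
                     abs_sasa = as.numeric(abs_sasa[res$key]),
                     stringsAsFactors = FALSE)
  prof$rel_sasa <- prof$abs_sasa / MAX_SASA[prof$resname]
  prof$exposed <- !is.na(prof$rel_sasa) &
    prof$rel_sasa >= criteria$surface_rel_sasa
  attr(prof, "probe") <- probe
  attr(prof, "n_points") <- n_points
  attr(prof, "model_id") <- model$id
  class(prof) <- c("sasa_profile", "data.frame")
  prof
}

#' Interaction census with loop/surface partitioning
#'
#' Counts interaction records per kind and, per kind, the percentage whose
#' residues touch a loop (at least one partner in loop class) or the
#' protein surface (at least one partner surface-exposed).
#'
#' @param records Data frame of interaction records of any kinds, e.g.
#'   row-bound results of [detect_interactions()].
#' @param sse An `sse_assignment` for the same model.
#' @param sasa A `sasa_profile` for the same model.
#' @return An `interaction_census`: counts per kind, total, pct_in_loops,
#'   pct_surface_exposed.
#' @export
interaction_census <- function(records, sse, sasa) {
  ids <- c(attr(records, "model_id"), sse$model_id, attr(sasa, "model_id"))
  ids <- ids[!is.null(ids) & !is.na(ids)]
  if (length(unique(ids)) > 1) {
    stop2("census inputs refer to different models: %s",
          paste(unique(ids), collapse = ", "))
  }
  kinds <- c("hydrophobic", "aromatic", "hbond", "ionic")
  counts <- stats::setNames(integer(4), kinds)
  in_loops <- stats::setNames(rep(NA_real_, 4), kinds)
  surf <- stats::setNames(rep(NA_real_, 4), kinds)
  loop_keys <- sse$residues$key[sse$residues$sse3 == "C"]
  exp_keys <- sasa$key[sasa$exposed]
  for (k in kinds) {
    rk <- records[records$kind == k, , drop = FALSE]
    counts[k] <- nrow(rk)
    if (nrow(rk) > 0) {
      lp <- rk$key_a %in% loop_keys | rk$key_b %in% loop_keys
      sf <- rk$key_a %in% exp_keys | rk$key_b %in% exp_keys
      in_loops[k] <- 100 * sum(lp) / nrow(rk)
      surf[k] <- 100 * sum(sf) / nrow(rk)
    }
  }
  structure(list(counts = counts, total = sum(counts),
                 pct_in_loops = in_loops, pct_surface_exposed = surf,
                 model_id = if (length(ids) > 0) ids[1] else NA_character_),
            class = "interaction_census")
}

#' @export
print.interaction_census <- function(x, ...) {
  cat(sprintf("interaction_census%s:\n",
              if (is.na(x$model_id)) "" else paste0(" for '", x$model_id, "'")))
  for (k in names(x$counts)) {
    extra <- if (!is.na(x$pct_in_loops[k])) {
      sprintf("  (loops %.0f%% / surface %.0f%%)", x$pct_in_loops[k],
              x$pct_surface_exposed[k])
    } else ""
    cat(sprintf("  %-12s %4d%s\n", k, x$counts[k], extra))
  }
  cat(sprintf("  %-12s %4d\n", "total", x$total))
  invisible(x)
}
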