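# Seeded generators for toy structures, homolog families and
# temperature-ladder conformer ensembles with planted ground truth.
#
# Backbones are built by natural-extension placement from ideal phi/psi
# blocks; pseudo side chains carry only the atoms the interaction criteria
# need, so planted censuses are exact by construction. Fluctuations are
# independent per-residue isotropic Gaussians (expected RMSF = sigma*sqrt(3)),
# not correlated elastic-network modes.

IDEAL_HELIX <- c(phi = -57, psi = -47)
IDEAL_STRAND <- c(phi = -139, psi = 135)
IDEAL_PPII <- c(phi = -75, psi = 145)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

euler_rotation <- function(deg) {
  a <- deg * pi / 180
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t),
                             0, sin(t), cos(t)), 3, 3, byrow = TRUE)
  rz(a[1]) %*% ry(a[2]) %*% rx(a[3])
}

# Backbone (N, CA, C, O) from per-residue phi/psi by NeRF chain extension.
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
    # carbonyl O in the peptide plane; torsion psi+180 places it trans to
    # the next N
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8,
                         psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.atoms_from_backbone <- function(bb, resnames, chain = "A",
                                 resseq = NULL) {
  n <- nrow(bb$N)
  resseq <- resseq %||% seq_len(n)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, altloc = "", resname = resnames[i],
        chain = chain, resseq = resseq[i], icode = "",
        x = bb[[nm]][i, 1], y = bb[[nm]][i, 2], z = bb[[nm]][i, 3],
        occupancy = 1, bfactor = 0,
        element = substr(nm, 1, 1), hetero = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic structure with planted interactions
#'
#' Builds a continuous single-chain backbone from ideal phi/psi blocks
#' (loop, helix, loop, helix, ...), then plants a Ser-His-Asp triad,
#' Arg-Asp salt bridges and Leu-Leu hydrophobic contacts at exact target
#' distances using pseudo side chains. Non-planted residues are glycine, so
#' the planted census is the whole census. Deterministic for a fixed seed.
#'
#' @param helix_lengths Integer vector of helix lengths (residues).
#' @param loop_lengths Integer vector of loop lengths; must be one longer
#'   than `helix_lengths` (loops flank and connect the helices).
#' @param n_bridges Number of Arg-Asp salt bridges to plant.
#' @param bridge_distance Planted N-O distance, Angstrom (default 3.5).
#' @param triad Plant a Ser-His-Asp triad (default FALSE).
#' @param triad_dists Target (Ser OG-His NE2, His ND1-Asp OD1) distances.
#' @param n_hydrophobic Number of Leu-Leu contacts to plant.
#' @param hydrophobic_distance Planted C-C distance, Angstrom (default 4.2).
#' @param loop_jitter Uniform phi/psi jitter amplitude in loops, degrees
#'   (seeded; makes structures differ across seeds).
#' @param seed Integer seed.
#' @return A `synth_structure`: list with `model` (a `structure_model`) and
#'   `truth` (intended per-residue classes, planted triad, bridges and
#'   hydrophobic pairs with their exact distances).
#' @export
synth_structure <- function(helix_lengths = c(14, 14),
                            loop_lengths = c(5, 6, 5),
                            n_bridges = 0, bridge_distance = 3.5,
                            triad = FALSE, triad_dists = c(3.0, 2.8),
                            n_hydrophobic = 0, hydrophobic_distance = 4.2,
                            loop_jitter = 10, seed = 1) {
  if (length(loop_lengths) != length(helix_lengths) + 1) {
    stop2("need length(loop_lengths) == length(helix_lengths) + 1")
  }
  if (any(helix_lengths < 4)) stop2("helices need >= 4 residues")
  with_seed(seed, {
    phi <- psi <- cls <- NULL
    for (k in seq_along(helix_lengths)) {
      ll <- loop_lengths[k]
      phi <- c(phi, IDEAL_PPII["phi"] + stats::runif(ll, -loop_jitter,
                                                     loop_jitter))
      psi <- c(psi, IDEAL_PPII["psi"] + stats::runif(ll, -loop_jitter,
                                                     loop_jitter))
      cls <- c(cls, rep("C", ll))
      hl <- helix_lengths[k]
      phi <- c(phi, rep(IDEAL_HELIX["phi"], hl))
      psi <- c(psi, rep(IDEAL_HELIX["psi"], hl))
      cls <- c(cls, rep("H", hl))
    }
    ll <- loop_lengths[length(loop_lengths)]
    phi <- c(phi, IDEAL_PPII["phi"] + stats::runif(ll, -loop_jitter,
                                                   loop_jitter))
    psi <- c(psi, IDEAL_PPII["psi"] + stats::runif(ll, -loop_jitter,
                                                   loop_jitter))
    cls <- c(cls, rep("C", ll))

    n <- length(phi)
    bb <- .build_backbone(unname(phi), unname(psi))
    ca <- bb$CA
    dmat <- as.matrix(stats::dist(ca))
    if (any(dmat[abs(row(dmat) - col(dmat)) > 2] < 3.0)) {
      stop2("generation error: backbone self-clash")
    }

    resnames <- rep("GLY", n)
    used <- logical(n)
    planted_xyz <- list()  # per feature: matrix of planted atom coords
    extra <- NULL

    # candidate pairs for a feature needing reach window [lo, hi] on d_CA
    find_pair <- function(target, reach = c(2.3, 4.6), exclude = used) {
      lo <- target + reach[1]; hi <- target + reach[2]
      cand <- which(dmat >= lo & dmat <= hi & upper.tri(dmat),
                    arr.ind = TRUE)
      cand <- cand[abs(cand[, 1] - cand[, 2]) >= 3, , drop = FALSE]
      cand <- cand[!exclude[cand[, 1]] & !exclude[cand[, 2]], ,
                   drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      # farthest from already-planted atoms, deterministic tie-break
      score <- vapply(seq_len(nrow(cand)), function(r) {
        pts <- rbind(ca[cand[r, 1], ], ca[cand[r, 2], ])
        if (length(planted_xyz) == 0) return(Inf)
        min(vapply(planted_xyz, function(m) {
          min(sqrt(outer(rowSums(pts^2), rowSums(m^2), "+") -
                     2 * pts %*% t(m)))
        }, numeric(1)))
      }, numeric(1))
      ord <- order(-score, cand[, 1], cand[, 2])
      cand[ord, , drop = FALSE]
    }
    ok_clearance <- function(pts, min_d = 6.5) {
      if (length(planted_xyz) == 0) return(TRUE)
      all(vapply(planted_xyz, function(m) {
        min(sqrt(pmax(outer(rowSums(pts^2), rowSums(m^2), "+") -
                        2 * pts %*% t(m), 0))) > min_d
      }, logical(1)))
    }

    truth <- list(sse = data.frame(key = res_key("A", seq_len(n)),
                                   class = cls, stringsAsFactors = FALSE),
                  triad = NULL, bridges = NULL, hydrophobic = NULL)

    plant_pair <- function(i, j, target, reach_a = 1.8) {
      u <- unit(ca[j, ] - ca[i, ])
      xa <- ca[i, ] + reach_a * u
      xb <- xa + target * u
      list(i = i, j = j, xa = xa, xb = xb)
    }

    if (triad) {
      placed <- FALSE
      cand <- find_pair(triad_dists[1])
      for (r in seq_len(nrow(cand) %||% 0)) {
        i <- cand[r, 1]; j <- cand[r, 2]
        # third residue within reach of His
        ks <- which(!used & dmat[j, ] >= triad_dists[2] + 2.3 &
                      dmat[j, ] <= triad_dists[2] + 4.6 &
                      abs(seq_len(n) - j) >= 3 & seq_len(n) != i)
        if (length(ks) == 0) next
        k <- ks[1]
        og <- ca[i, ] + 1.8 * unit(ca[j, ] - ca[i, ])
        ne2 <- og + triad_dists[1] * unit(ca[j, ] - og)
        nd1 <- ca[j, ] + 1.8 * unit(ca[k, ] - ca[j, ])
        od1 <- nd1 + triad_dists[2] * unit(ca[k, ] - nd1)
        w <- unit(vcross(od1 - nd1, c(0.3, 0.7, 0.64)))
        od2 <- od1 + 1.2 * w
        pts <- rbind(og, ne2, nd1, od1, od2)
        if (!ok_clearance(pts)) next
        resnames[c(i, j, k)] <- c("SER", "HIS", "ASP")
        used[c(i, j, k)] <- TRUE
        planted_xyz[[length(planted_xyz) + 1]] <- pts
        extra <- rbind(extra,
          .plant_rows(i, "OG", og, "O"), .plant_rows(j, "NE2", ne2, "N"),
          .plant_rows(j, "ND1", nd1, "N"), .plant_rows(k, "OD1", od1, "O"),
          .plant_rows(k, "OD2", od2, "O"))
        truth$triad <- list(keys = res_key("A", c(i, j, k)),
                             ser_his = triad_dists[1],
                             his_asp = triad_dists[2])
        placed <- TRUE
        break
      }
      if (!placed) stop2("generation error: cannot place triad")
    }

    for (b in seq_len(n_bridges)) {
      cand <- find_pair(bridge_distance)
      placed <- FALSE
      for (r in seq_len(nrow(cand) %||% 0)) {
        i <- cand[r, 1]; j <- cand[r, 2]
        p <- plant_pair(i, j, target = bridge_distance)
        w <- unit(vcross(p$xb - p$xa, c(0.3, 0.7, 0.64)))
        od2 <- p$xb + 1.2 * w
        pts <- rbind(p$xa, p$xb, od2)
        if (!ok_clearance(pts)) next
        resnames[c(i, j)] <- c("ARG", "ASP")
        used[c(i, j)] <- TRUE
        planted_xyz[[length(planted_xyz) + 1]] <- pts
        extra <- rbind(extra,
          .plant_rows(i, "NH1", p$xa, "N"), .plant_rows(j, "OD1", p$xb, "O"),
          .plant_rows(j, "OD2", od2, "O"))
        truth$bridges <- rbind(truth$bridges, data.frame(
          key_a = res_key("A", i), key_b = res_key("A", j),
          distance = bridge_distance, in_loop = cls[i] == "C" | cls[j] == "C",
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop2("generation error: cannot place bridge %d", b)
    }

    for (h in seq_len(n_hydrophobic)) {
      cand <- find_pair(hydrophobic_distance, reach = c(2.0, 4.2))
      placed <- FALSE
      for (r in seq_len(nrow(cand) %||% 0)) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (abs(i - j) < 2) next
        u <- unit(ca[j, ] - ca[i, ])
        cb_i <- ca[i, ] + 1.6 * u
        cb_j <- cb_i + hydrophobic_distance * u
        pts <- rbind(cb_i, cb_j)
        if (!ok_clearance(pts)) next
        resnames[c(i, j)] <- "LEU"
        used[c(i, j)] <- TRUE
        planted_xyz[[length(planted_xyz) + 1]] <- pts
        extra <- rbind(extra, .plant_rows(i, "CB", cb_i, "C"),
                        .plant_rows(j, "CB", cb_j, "C"))
        truth$hydrophobic <- rbind(truth$hydrophobic, data.frame(
          key_a = res_key("A", i), key_b = res_key("A", j),
          distance = hydrophobic_distance, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop2("generation error: cannot place hydrophobic pair %d", h)
    }

    # construction-derived census expectations: each planted bridge is one
    # ionic record; a planted triad adds one more (His ND1 is a potential
    # cation and sits at the His-Asp target distance from Asp OD1)
    truth$expected_counts <- c(
      ionic = n_bridges + as.integer(triad && triad_dists[2] <= 6),
      hydrophobic = n_hydrophobic,
      aromatic = 0L)

    atoms <- .atoms_from_backbone(bb, resnames)
    if (!is.null(extra)) {
      extra$resname <- resnames[match(extra$resseq, seq_len(n))]
      # keep atoms grouped by residue
      atoms <- rbind(atoms, extra)
      atoms <- atoms[order(atoms$resseq, atoms$serial), , drop = FALSE]
      atoms$serial <- seq_len(nrow(atoms))
    }
    model <- new_structure_model(sprintf("synth_s%d", seed), atoms,
                                 source = "synth_structure")
    structure(list(model = model, truth = truth, seed = seed),
              class = "synth_structure")
  })
}

# helper used inside synth_structure closures
.plant_rows <- function(resseq, name, xyz, element) {
  data.frame(serial = 0L, name = name, altloc = "", resname = "",
             chain = "A", resseq = resseq, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, bfactor = 0,
             element = element, hetero = FALSE, stringsAsFactors = FALSE)
}

#' Generate an ideal antiparallel two-stranded beta sheet
#'
#' Builds one extended strand and places a rigid copy by minimizing the
#' summed Kabsch-Sander energies of the intended antiparallel ladder
#' hydrogen bonds (pairs i and n+1-i between the strands) under a backbone
#' clash penalty, yielding a proper registry. The two strands are separate
#' chain segments (sequence-discontinuous residue numbering). Deterministic.
#'
#' @param n_res Residues per strand (default 8).
#' @return A `structure_model` with strands at residues 1..n and
#'   101..100+n.
#' @export
synth_sheet <- function(n_res = 8) {
  A <- .build_backbone(rep(IDEAL_STRAND["phi"], n_res),
                       rep(IDEAL_STRAND["psi"], n_res))
  ctr <- colMeans(A$CA)
  mk_b <- function(p) {
    R <- euler_rotation(p[1:3])
    lapply(A, function(m) {
      sweep(sweep(m, 2, ctr) %*% t(R), 2, ctr + p[4:6], FUN = "+")
    })
  }
  h_of <- function(S) {
    H <- matrix(NA_real_, n_res, 3)
    for (i in 2:n_res) H[i, ] <- S$N[i, ] + unit(S$C[i - 1, ] - S$O[i - 1, ])
    H
  }
  e1 <- function(Ci, Oi, Nj, Hj) {
    if (anyNA(Hj)) return(10)
    d <- c(vnorm(Oi - Nj), vnorm(Ci - Hj), vnorm(Oi - Hj), vnorm(Ci - Nj))
    if (min(d) < 1.0) return(10)
    KS_Q * (1 / d[1] + 1 / d[2] - 1 / d[3] - 1 / d[4])
  }
  hA <- h_of(A)
  obj <- function(p) {
    B <- mk_b(p)
    hB <- h_of(B)
    tot <- 0
    for (i in seq_len(n_res)) {
      j <- n_res + 1 - i
      if (j >= 2) tot <- tot + max(-3, min(5, e1(A$C[i, ], A$O[i, ],
                                                 B$N[j, ], hB[j, ])))
      if (i >= 2) tot <- tot + max(-3, min(5, e1(B$C[j, ], B$O[j, ],
                                                 A$N[i, ], hA[i, ])))
    }
    dca <- sqrt(pmax(outer(rowSums(A$CA^2), rowSums(B$CA^2), "+") -
                       2 * A$CA %*% t(B$CA), 0))
    tot + 100 * sum(dca < 3.8)
  }
  starts <- list(c(0, 180, 0, 0, 4.8, 0), c(180, 0, 0, 0, 4.8, 0),
                 c(0, 180, 0, 0, -4.8, 0), c(0, 180, 0, 0, 0, 4.8),
                 c(180, 0, 0, 0, 0, 4.8), c(0, 0, 180, 0, 4.8, 0))
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-10))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  B <- mk_b(best$par)
  bb2 <- list(N = rbind(A$N, B$N), CA = rbind(A$CA, B$CA),
              C = rbind(A$C, B$C), O = rbind(A$O, B$O))
  atoms <- .atoms_from_backbone(bb2, rep("GLY", 2 * n_res),
                                resseq = c(seq_len(n_res),
                                           100 + seq_len(n_res)))
  new_structure_model("synth_sheet", atoms, source = "synth_sheet")
}

#' Derive a homolog with known ground truth from a synthetic structure
#'
#' Applies residue substitutions, bridge-breaking mutations (the anionic
#' partner becomes alanine, losing its carboxylate atoms), residue
#' deletions, a rigid-body transform and isotropic coordinate noise.
#' Emits the true residue correspondence and the fate of every planted
#' bridge.
#'
#' @param base A `synth_structure` (or a `structure_model`; then `bridges`
#'   must be passed explicitly to break any).
#' @param break_bridges Integer indices (into the base truth's bridge
#'   table) of bridges to destroy by mutation.
#' @param n_deletions Number of unplanted residues to delete (seeded).
#' @param substitution_rate Fraction of unplanted residues renamed
#'   (sequence-level substitution, GLY -> SER).
#' @param rigid_rotation Euler angles, degrees (z, y, x).
#' @param rigid_translation Length-3 translation, Angstrom.
#' @param coord_noise_sigma Per-axis Gaussian noise, Angstrom.
#' @param seed Integer seed.
#' @return A `synth_homolog`: list with `model`, `correspondence`,
#'   `bridge_fates` (data frame: key_a, key_b, fate kept/broken),
#'   `deleted_keys`.
#' @export
synth_homolog <- function(base, break_bridges = integer(),
                          n_deletions = 0, substitution_rate = 0,
                          rigid_rotation = c(0, 0, 0),
                          rigid_translation = c(0, 0, 0),
                          coord_noise_sigma = 0, seed = 1) {
  truth_bridges <- if (inherits(base, "synth_structure")) {
    base$truth$bridges
  } else NULL
  base_model <- if (inherits(base, "synth_structure")) base$model else base
  if (length(break_bridges) > 0) {
    if (is.null(truth_bridges) || any(break_bridges > nrow(truth_bridges))) {
      stop2("break_bridges references a bridge the base does not have")
    }
  }
  with_seed(seed, {
    atoms <- base_model$atoms
    res <- residue_table(base_model)
    planted <- res$key[res$resname != "GLY"]

    fates <- NULL
    if (!is.null(truth_bridges)) {
      fates <- data.frame(key_a = truth_bridges$key_a,
                          key_b = truth_bridges$key_b,
                          fate = "kept", stringsAsFactors = FALSE)
      for (b in break_bridges) {
        victim <- truth_bridges$key_b[b]  # the Asp partner
        keym <- res_key(atoms$chain, atoms$resseq, atoms$icode)
        sel <- keym == victim
        atoms$resname[sel] <- "ALA"
        atoms <- atoms[!(sel & atoms$name %in% c("OD1", "OD2")), ,
                       drop = FALSE]
        fates$fate[b] <- "broken"
      }
    }

    free <- setdiff(res$key, planted)
    deleted <- character()
    if (n_deletions > 0) {
      if (n_deletions > length(free)) stop2("too many deletions requested")
      deleted <- sort(sample(free, n_deletions))
      keym <- res_key(atoms$chain, atoms$resseq, atoms$icode)
      atoms <- atoms[!(keym %in% deleted), , drop = FALSE]
    }
    if (substitution_rate > 0) {
      remaining <- setdiff(free, deleted)
      n_sub <- round(substitution_rate * length(remaining))
      subs <- sample(remaining, n_sub)
      keym <- res_key(atoms$chain, atoms$resseq, atoms$icode)
      atoms$resname[keym %in% subs & atoms$resname == "GLY"] <- "SER"
    }

    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    rot <- euler_rotation(rigid_rotation)
    xyz <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, ctr + rigid_translation,
                 FUN = "+")
    if (coord_noise_sigma > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, coord_noise_sigma),
                          ncol = 3)
    }
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
    atoms$serial <- seq_len(nrow(atoms))
    model <- new_structure_model(paste0(base_model$id, "_hom", seed), atoms,
                                 source = "synth_homolog")
    kept_keys <- setdiff(res$key, deleted)
    corr <- structure(list(pairs = data.frame(key_a = kept_keys,
                                              key_b = kept_keys,
                                              stringsAsFactors = FALSE),
                           method = "generator"),
                      class = "correspondence")
    structure(list(model = model, correspondence = corr,
                   bridge_fates = fates, deleted_keys = deleted,
                   seed = seed),
              class = "synth_homolog")
  })
}

#' Generate temperature-ladder conformer ensembles with known RMSF
#'
#' Each frame is the base C-alpha skeleton plus independent isotropic
#' Gaussian displacements (per-residue, per-temperature sigma), optionally
#' followed by a random rigid-body jitter. The expected RMSF of residue i
#' is `sigma_i * sqrt(3)`; rigid jitter is removed by frame fitting and
#' leaves the expectation unchanged.
#'
#' @param base A `structure_model` or `synth_structure`; its C-alpha atoms
#'   define the skeleton.
#' @param temperatures Numeric vector of temperature labels, degrees C.
#' @param sigma Per-axis fluctuation amplitude, Angstrom: a single number,
#'   a vector over residues, or a matrix (residues x temperatures).
#' @param n_frames Frames per temperature (default 1000).
#' @param jitter_rot Max random rigid rotation per frame, degrees.
#' @param jitter_trans Max random rigid translation per frame, Angstrom.
#' @param seed Integer seed.
#' @return A `synth_ensemble`: list with `ensembles` (named by
#'   temperature), `truth` (data frame: key, temperature, sigma,
#'   expected_rmsf).
#' @export
synth_ensemble <- function(base, temperatures = 25, sigma = 0.5,
                           n_frames = 1000, jitter_rot = 0,
                           jitter_trans = 0, seed = 1) {
  if (n_frames < 2) stop2("n_frames must be >= 2")
  model <- if (inherits(base, "synth_structure")) base$model else base
  res <- residue_table(model)
  ca <- atom_coords(model, res$key, "CA")
  nr <- nrow(ca)
  nt <- length(temperatures)
  sig <- if (is.matrix(sigma)) sigma else
    matrix(sigma, nrow = nr, ncol = nt)
  if (nrow(sig) != nr || ncol(sig) != nt) {
    stop2("sigma must be scalar, length-%d vector, or %d x %d matrix",
          nr, nr, nt)
  }
  if (any(sig <= 0)) stop2("sigma must be positive")
  meta <- data.frame(name = "CA", resname = res$resname, chain = res$chain,
                     resseq = res$resseq, icode = res$icode, key = res$key,
                     stringsAsFactors = FALSE)
  with_seed(seed, {
    ensembles <- list()
    truth <- NULL
    for (t in seq_len(nt)) {
      coords <- array(NA_real_, dim = c(n_frames, nr, 3))
      for (f in seq_len(n_frames)) {
        frame <- ca + matrix(stats::rnorm(nr * 3, 0, sig[, t]), nrow = nr)
        if (jitter_rot > 0 || jitter_trans > 0) {
          ang <- stats::runif(3, -jitter_rot, jitter_rot)
          tr <- stats::runif(3, -jitter_trans, jitter_trans)
          ctr <- colMeans(frame)
          frame <- sweep(sweep(frame, 2, ctr) %*% t(euler_rotation(ang)),
                         2, ctr + tr, FUN = "+")
        }
        coords[f, , ] <- frame
      }
      ensembles[[as.character(temperatures[t])]] <-
        new_ensemble(coords, meta, temperatures[t])
      truth <- rbind(truth, data.frame(
        key = res$key, temperature = temperatures[t], sigma = sig[, t],
        expected_rmsf = sig[, t] * sqrt(3), stringsAsFactors = FALSE))
    }
    structure(list(ensembles = ensembles, truth = truth, seed = seed),
              class = "synth_ensemble")
  })
}
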