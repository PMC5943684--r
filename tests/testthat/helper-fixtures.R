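# Shared fixtures, built in code.

# small structure with planted features, cached per test file
fixture_structure <- local({
  cache <- new.env()
  function(seed = 3, n_bridges = 2, triad = TRUE, n_hydrophobic = 2) {
    key <- paste(seed, n_bridges, triad, n_hydrophobic)
    if (is.null(cache[[key]])) {
      cache[[key]] <- synth_structure(
        helix_lengths = c(14, 14), loop_lengths = c(5, 6, 5),
        n_bridges = n_bridges, triad = triad,
        n_hydrophobic = n_hydrophobic, seed = seed)
    }
    cache[[key]]
  }
})

# minimal hand-built structure_model from a residue spec list:
# list(list(resname=, resseq=, atoms=list(name=c(x,y,z), ...)), ...)
toy_model <- function(res_spec, id = "toy", chain = "A") {
  rows <- list()
  serial <- 0L
  for (r in res_spec) {
    for (nm in names(r$atoms)) {
      serial <- serial + 1L
      xyz <- r$atoms[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = nm, altloc = "", resname = r$resname,
        chain = chain, resseq = r$resseq, icode = "",
        x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, bfactor = 0,
        element = substr(gsub("[0-9]", "", nm), 1, 1), hetero = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  thermadapt:::new_structure_model(id, do.call(rbind, rows))
}

# ideal poly-GLY helix as a structure_model
helix_model <- function(n = 12, id = "helix") {
  bb <- thermadapt:::.build_backbone(rep(-57, n), rep(-47, n))
  at <- thermadapt:::.atoms_from_backbone(bb, rep("GLY", n))
  thermadapt:::new_structure_model(id, at)
}

# brute-force global alignment score by recursive enumeration
# (linear gap penalty; match/mismatch scoring)
brute_force_nw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    memo[[key]] <- best
    best
  }
  rec(nchar(a), nchar(b))
}

# brute-force rotation search: best RMSD over a coarse Euler grid followed
# by Nelder-Mead refinement of the rotation angles (independent of the
# closed-form solution under test)
brute_force_min_rmsd <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  rmsd_of <- function(ang) {
    R <- thermadapt:::euler_rotation(ang)
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  best <- NULL
  grid <- seq(0, 300, by = 60)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- rmsd_of(c(a1, a2, a3))
    if (is.null(best) || v < best$v) best <- list(v = v, p = c(a1, a2, a3))
  }
  o <- stats::optim(best$p, rmsd_of, method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-14))
  o <- stats::optim(o$par, rmsd_of, method = "Nelder-Mead",
                    control = list(maxit = 4000, reltol = 1e-15))
  o$value
}
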