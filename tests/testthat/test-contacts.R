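# Interaction detection, SASA and census partitioning.

test_that("planted interactions are detected exactly, no more, no fewer", {
  s <- fixture_structure(seed = 3, n_bridges = 2, triad = TRUE,
                         n_hydrophobic = 2)
  ion <- detect_interactions(s$model, "ionic")
  expect_equal(nrow(ion), unname(s$truth$expected_counts["ionic"]))
  expect_true(all(s$truth$bridges$key_a %in% c(ion$key_a, ion$key_b)))
  hyd <- detect_interactions(s$model, "hydrophobic")
  expect_equal(nrow(hyd), unname(s$truth$expected_counts["hydrophobic"]))
  expect_equal(nrow(detect_interactions(s$model, "aromatic")), 0)
})

test_that("an Asp-Arg pair at 4 A is one ionic record; far Leu pairs none", {
  m <- toy_model(list(
    list(resname = "ARG", resseq = 1,
         atoms = list(N = c(0, 0, 0), CA = c(1.5, 0, 0),
                      NH1 = c(2.5, 1, 0))),
    list(resname = "ASP", resseq = 5,
         atoms = list(N = c(7, 0, 0), CA = c(8.5, 0, 0),
                      OD1 = c(2.5, 5, 0)))))
  ion <- detect_interactions(m, "ionic")
  expect_equal(nrow(ion), 1)
  expect_equal(ion$distance, 4, tolerance = 1e-6)
  m2 <- toy_model(list(
    list(resname = "LEU", resseq = 1,
         atoms = list(N = c(0, 0, 0), CA = c(1.5, 0, 0),
                      CB = c(2, 1, 0))),
    list(resname = "LEU", resseq = 5,
         atoms = list(N = c(9, 0, 0), CA = c(10.5, 0, 0),
                      CB = c(2, 9, 0)))))
  expect_equal(nrow(detect_interactions(m2, "hydrophobic")), 0)
})

test_that("every record's distance sits inside its kind's cutoff window", {
  s <- fixture_structure()
  cr <- default_criteria()
  for (kind in c("hydrophobic", "aromatic", "ionic", "hbond")) {
    recs <- detect_interactions(s$model, kind, cr)
    if (nrow(recs) == 0) next
    lim <- switch(kind, hydrophobic = cr$hydrophobic_cutoff,
                  aromatic = cr$aromatic_max, ionic = cr$ionic_cutoff,
                  hbond = cr$hbond_cutoff)
    expect_true(all(recs$distance <= lim))
  }
})

test_that("helix backbone hydrogen bonds appear in the hbond census", {
  recs <- detect_interactions(helix_model(12), "hbond")
  expect_gt(nrow(recs), 3)
  bb <- recs[recs$atom_a == "O" | recs$atom_b == "O", ]
  expect_true(all(bb$seq_sep >= 2))
})

test_that("tightening cutoffs never increases counts", {
  for (seed in 1:5) {
    s <- fixture_structure(seed = seed)
    tight <- default_criteria(hydrophobic_cutoff = 4.0, ionic_cutoff = 4.5,
                              hbond_cutoff = 3.0, aromatic_max = 6.0)
    for (kind in c("hydrophobic", "ionic", "hbond", "aromatic")) {
      n_def <- nrow(detect_interactions(s$model, kind))
      n_tight <- nrow(detect_interactions(s$model, kind, tight))
      expect_lte(n_tight, n_def)
    }
  }
})

test_that("census is invariant under atom-order permutation", {
  s <- fixture_structure()
  m2 <- s$model
  set.seed(99)
  m2$atoms <- m2$atoms[sample(nrow(m2$atoms)), ]
  for (kind in c("hydrophobic", "ionic")) {
    expect_equal(nrow(detect_interactions(m2, kind)),
                 nrow(detect_interactions(s$model, kind)))
  }
})

test_that("isolated atoms get full solvent-extended sphere areas", {
  # one-atom residue: exactly 4*pi*(r+probe)^2
  m <- toy_model(list(list(resname = "GLY", resseq = 1,
                           atoms = list(CA = c(0, 0, 0)))))
  prof <- shrake_rupley_sasa(m)
  expect_equal(prof$abs_sasa, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
  # well-separated atoms: sum of full spheres within 2%
  m2 <- toy_model(list(list(resname = "ALA", resseq = 1,
                            atoms = list(N = c(0, 0, 0), CA = c(20, 0, 0),
                                         C = c(40, 0, 0), O = c(60, 0, 0),
                                         CB = c(80, 0, 0)))))
  expected <- 4 * pi * ((1.55 + 1.4)^2 + 3 * (1.70 + 1.4)^2 +
                          (1.52 + 1.4)^2)
  expect_equal(shrake_rupley_sasa(m2)$abs_sasa, expected,
               tolerance = 0.02)
})

test_that("a caged atom has zero accessible area", {
  cage_dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  cage_dirs <- cage_dirs[rowSums(abs(cage_dirs)) > 0, ]
  cage_dirs <- sweep(cage_dirs, 1, sqrt(rowSums(cage_dirs^2)), FUN = "/")
  spec <- list(list(resname = "GLY", resseq = 1,
                    atoms = list(CA = c(0, 0, 0))))
  atoms2 <- stats::setNames(
    lapply(seq_len(nrow(cage_dirs)), function(i) 2.0 * cage_dirs[i, ]),
    paste0("C", seq_len(nrow(cage_dirs))))
  spec[[2]] <- list(resname = "GLY", resseq = 2, atoms = atoms2)
  prof <- shrake_rupley_sasa(toy_model(spec))
  expect_equal(prof$abs_sasa[prof$key == "A:1"], 0)
})

test_that("doubling sphere points leaves per-residue SASA converged", {
  s <- fixture_structure()
  a <- shrake_rupley_sasa(s$model, n_points = 960)
  b <- shrake_rupley_sasa(s$model, n_points = 1920)
  rel <- abs(a$abs_sasa - b$abs_sasa) / pmax(b$abs_sasa, 1)
  # point-count quantization leaves a small residue-level jitter; the
  # profile as a whole is converged below 1%
  expect_lt(mean(rel), 0.01)
  expect_lt(max(rel), 0.03)
})

test_that("census counts, totals and partition percentages are consistent", {
  s <- fixture_structure(seed = 5, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 1)
  recs <- do.call(rbind, lapply(c("hydrophobic", "aromatic", "ionic",
                                  "hbond"), function(k) {
    detect_interactions(s$model, k)
  }))
  attr(recs, "model_id") <- s$model$id
  sse <- assign_sse(s$model)
  sasa <- shrake_rupley_sasa(s$model)
  cen <- interaction_census(recs, sse, sasa)
  expect_equal(cen$total, sum(cen$counts))
  expect_equal(unname(cen$counts["ionic"]), 3)
  # exact agreement with per-record recomputation
  loop_keys <- sse$residues$key[sse$residues$sse3 == "C"]
  exp_keys <- sasa$key[sasa$exposed]
  for (k in names(cen$counts)) {
    rk <- recs[recs$kind == k, ]
    if (nrow(rk) == 0) next
    expect_identical(cen$pct_in_loops[[k]],
                     100 * sum(rk$key_a %in% loop_keys |
                                 rk$key_b %in% loop_keys) / nrow(rk))
    expect_identical(cen$pct_surface_exposed[[k]],
                     100 * sum(rk$key_a %in% exp_keys |
                                 rk$key_b %in% exp_keys) / nrow(rk))
  }
  # empty record set: zero counts
  cen0 <- interaction_census(recs[0, ], sse, sasa)
  expect_equal(cen0$total, 0)
})

test_that("planted loop bridges drive the loop percentage", {
  # find a seeded structure whose bridges split across loops
  s <- fixture_structure(seed = 5, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 1)
  sse <- assign_sse(s$model)
  loop_keys <- sse$residues$key[sse$residues$sse3 == "C"]
  n_in_loops <- sum(s$truth$bridges$key_a %in% loop_keys |
                      s$truth$bridges$key_b %in% loop_keys)
  recs <- detect_interactions(s$model, "ionic")
  sasa <- shrake_rupley_sasa(s$model)
  cen <- interaction_census(recs, sse, sasa)
  expect_equal(cen$pct_in_loops[["ionic"]], 100 * n_in_loops / 3)
})

test_that("mismatched model ids are a consistency error", {
  s <- fixture_structure()
  other <- synth_structure(seed = 8)
  recs <- detect_interactions(s$model, "ionic")
  sse <- assign_sse(other$model)
  sasa <- shrake_rupley_sasa(other$model)
  expect_error(interaction_census(recs, sse, sasa), "different models")
})
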