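# Alignment, pairing, Kabsch superposition and triad geometry.

test_that("identical sequences align at 100% identity", {
  s <- paste(rep("ACDEFGHIKL", 5), collapse = "")
  aln <- global_align(s, s)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$aligned_a, aln$aligned_b)
})

test_that("alignment scores equal exhaustive enumeration for short sequences", {
  aln <- global_align("GLSMG", "GASAG", match = 1, mismatch = 0,
                      gap_open = 0, gap_extend = 1)
  expect_equal(aln$score, brute_force_nw("GLSMG", "GASAG"))
  set.seed(42)
  alpha <- c("A", "C", "D", "E")
  for (i in 1:25) {
    a <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b, match = 1, mismatch = 0, gap_open = 0,
                              gap_extend = 1)$score,
                 brute_force_nw(a, b), info = paste(a, b))
  }
})

test_that("gapped strings ungap to the inputs and empty input errors", {
  aln <- global_align("ACDEF", "ACEF")
  expect_equal(gsub("-", "", aln$aligned_a), "ACDEF")
  expect_equal(gsub("-", "", aln$aligned_b), "ACEF")
  expect_error(global_align("", "ACDEF"), "empty")
})

test_that("residue pairing yields one pair per aligned non-gap column", {
  s <- fixture_structure()
  seq_a <- extract_sequence(s$model, "A")
  aln <- global_align(seq_a, seq_a)
  corr <- pair_residues(s$model, s$model, aln)
  expect_equal(nrow(corr$pairs), nrow(residue_table(s$model)))
  # planted deletions remove exactly that many pairs
  h <- synth_homolog(s, n_deletions = 5, seed = 9)
  seq_b <- extract_sequence(h$model, "A")
  aln2 <- global_align(seq_a, seq_b)
  corr2 <- pair_residues(s$model, h$model, aln2)
  expect_equal(nrow(corr2$pairs), nrow(residue_table(s$model)) - 5)
})

test_that("self-superposition gives identity rotation and zero RMSD", {
  set.seed(1)
  A <- matrix(rnorm(60), ncol = 3)
  sup <- kabsch_superpose(A, A)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)
  expect_lt(sup$rmsd_all, 1e-10)
})

test_that("a planted rigid transform is recovered to numerical precision", {
  set.seed(2)
  A <- matrix(rnorm(60), ncol = 3)
  R <- thermadapt:::euler_rotation(c(37, 0, 0))
  B <- sweep(A %*% t(R), 2, c(3, -1, 2), FUN = "+")
  sup <- kabsch_superpose(A, B)
  expect_lt(sup$rmsd_all, 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
})

test_that("rotations are always proper and never reflections", {
  set.seed(3)
  for (i in 1:10) {
    A <- matrix(rnorm(45), ncol = 3)
    B <- A %*% diag(c(1, 1, -1))  # mirrored cloud invites a reflection
    sup <- kabsch_superpose(A, B)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(sup$rotation) - diag(3))), 1e-8)
  }
})

test_that("fitted RMSD never exceeds the unfitted RMSD", {
  set.seed(4)
  for (i in 1:10) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- A + matrix(rnorm(30, sd = 0.5), ncol = 3)
    sup <- kabsch_superpose(A, B)
    expect_lte(sup$rmsd_all, sqrt(mean(rowSums((A - B)^2))) + 1e-12)
  }
})

test_that("closed-form RMSD matches a rotation-search oracle on noisy clouds", {
  set.seed(5)
  for (i in 1:3) {
    A <- matrix(rnorm(60), ncol = 3)
    B <- A + matrix(rnorm(60, sd = 0.3), ncol = 3)
    sup <- kabsch_superpose(A, B)
    expect_equal(sup$rmsd_all, brute_force_min_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("kabsch agrees with an independent library implementation", {
  set.seed(6)
  A <- matrix(rnorm(90), ncol = 3)
  B <- A + matrix(rnorm(90, sd = 0.4), ncol = 3)
  ours <- kabsch_superpose(A, B)$rmsd_all
  theirs <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("degenerate inputs raise geometry errors", {
  A <- matrix(rnorm(6), ncol = 3)
  expect_error(kabsch_superpose(A, A), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("per-class RMSD partitions the pairs and isolates loop noise", {
  s <- fixture_structure()
  sse <- assign_sse(s$model)
  # homolog with noise planted only on loop residues
  h <- synth_homolog(s, seed = 12)
  loop_keys <- sse$residues$key[sse$residues$sse3 == "C"]
  at <- h$model$atoms
  keym <- thermadapt:::res_key(at$chain, at$resseq, at$icode)
  sel <- keym %in% loop_keys
  set.seed(12)
  at$x[sel] <- at$x[sel] + rnorm(sum(sel), sd = 1.0)
  h$model$atoms <- at
  sup <- superpose_models(s$model, h$model, h$correspondence)
  sup <- classwise_rmsd(sup, sse_a = sse)
  by_class <- sup$rmsd_by_class
  expect_gt(by_class$loop$rmsd, by_class$helix$rmsd)
  expect_lt(by_class$helix$rmsd, 0.2)
  n_sum <- sum(vapply(by_class, function(x) x$n, numeric(1)))
  expect_equal(n_sum, sup$n_pairs)
  # identical structures: all classes at zero
  sup0 <- superpose_models(s$model, s$model,
                           synth_homolog(s, seed = 1)$correspondence)
  sup0 <- classwise_rmsd(sup0, sse_a = sse)
  for (cl in names(sup0$rmsd_by_class)) {
    expect_lt(sup0$rmsd_by_class[[cl]]$rmsd, 1e-10)
  }
})

test_that("triad distances use OG-NE2 and the nearest carboxylate oxygen", {
  s <- fixture_structure()
  td <- triad_distances(s$model, s$truth$triad$keys)
  expect_equal(td$ser_his_dist, s$truth$triad$ser_his, tolerance = 1e-6)
  expect_equal(td$his_asp_dist, s$truth$triad$his_asp, tolerance = 1e-6)
  # nearest-oxygen rule: OD2 closer than OD1
  m <- toy_model(list(
    list(resname = "SER", resseq = 1,
         atoms = list(N = c(0, 0, 0), CA = c(1.5, 0, 0),
                      OG = c(2, 1, 0))),
    list(resname = "HIS", resseq = 2,
         atoms = list(N = c(5, 0, 0), CA = c(6.5, 0, 0),
                      NE2 = c(5, 1, 0), ND1 = c(7, 1, 0))),
    list(resname = "ASP", resseq = 3,
         atoms = list(N = c(10, 0, 0), CA = c(11.5, 0, 0),
                      OD1 = c(11, 1, 0), OD2 = c(7, 1, 3.1)))))
  td2 <- triad_distances(m, c("A:1", "A:2", "A:3"))
  expect_equal(td2$his_asp_dist, 3.1, tolerance = 1e-6)
  # missing side-chain atom errors, naming the atom
  m2 <- toy_model(list(
    list(resname = "SER", resseq = 1,
         atoms = list(N = c(0, 0, 0), CA = c(1.5, 0, 0)))))
  expect_error(triad_distances(m2, c("A:1", "A:1", "A:1")), "OG")
})
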