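# RMSF profiles, RMSD series, ratios, delta-RMSF and region
# classification.

make_profile <- function(rmsf, temperature = 25) {
  prof <- data.frame(key = thermadapt:::res_key("A", seq_along(rmsf)),
                     resseq = seq_along(rmsf), rmsf = rmsf,
                     stringsAsFactors = FALSE)
  attr(prof, "temperature") <- temperature
  class(prof) <- c("flexibility_profile", "data.frame")
  prof
}

test_that("a static ensemble has zero RMSF and a flat RMSD series", {
  s <- fixture_structure()
  base <- synth_ensemble(s, temperatures = 25, sigma = 0.5, n_frames = 10,
                         seed = 1)$ensembles[[1]]
  static <- thermadapt:::new_ensemble(
    array(rep(base$coords[1, , ], each = 10), dim = dim(base$coords)),
    base$atom_meta, 25)
  prof <- rmsf_profile(static, window = c(0, 1))
  expect_true(all(prof$rmsf < 1e-10))
  rs <- rmsd_series(static)
  expect_true(all(rs$rmsd < 1e-10))
  expect_true(rs$plateau)
})

test_that("isotropic Gaussian fluctuations recover sigma * sqrt(3)", {
  s <- synth_structure(helix_lengths = rep(14, 5),
                       loop_lengths = rep(8, 6), seed = 21)
  se <- synth_ensemble(s, temperatures = 25, sigma = 1.0, n_frames = 3000,
                       seed = 7)
  prof <- rmsf_profile(se$ensembles[[1]], window = c(0.7, 1))
  expect_equal(mean(prof$rmsf), sqrt(3), tolerance = 0.02)
})

test_that("two-region ensembles reproduce the planted RMSF ratio", {
  s <- synth_structure(helix_lengths = rep(14, 4),
                       loop_lengths = rep(6, 5), seed = 22)
  nr <- nrow(residue_table(s$model))
  sig <- rep(0.2, nr)
  sig[1:30] <- 0.8
  se <- synth_ensemble(s, temperatures = 25, sigma = matrix(sig, ncol = 1),
                       n_frames = 4000, seed = 3)
  prof <- rmsf_profile(se$ensembles[[1]], window = c(0.7, 1))
  ratio <- mean(prof$rmsf[1:30]) / mean(prof$rmsf[31:nr])
  expect_equal(ratio, 4, tolerance = 0.05 * 4)
})

test_that("window selection and frame-count contracts hold", {
  s <- fixture_structure()
  se <- synth_ensemble(s, temperatures = 25, sigma = 0.5, n_frames = 100,
                       seed = 2)
  prof <- rmsf_profile(se$ensembles[[1]], window = c(0.7, 1))
  expect_equal(attr(prof, "n_frames_used"), 30)
  expect_error(rmsf_profile(se$ensembles[[1]], window = c(0.999, 1)),
               "need >= 2")
})

test_that("drifting coordinates fail the plateau check, stationary ones pass", {
  s <- fixture_structure()
  drift <- synth_ensemble(s, temperatures = 25, sigma = 0.3, n_frames = 60,
                          seed = 4)$ensembles[[1]]
  for (t in seq_len(60)) drift$coords[t, , 1] <-
    drift$coords[t, , 1] + 0.05 * t
  rs <- rmsd_series(drift)
  expect_false(rs$plateau)
  # a long stationary ensemble plateaus: slope noise shrinks with frames
  base <- synth_ensemble(s, temperatures = 25, sigma = 0.3,
                         n_frames = 2000, seed = 42)$ensembles[[1]]
  rs2 <- rmsd_series(base)
  expect_true(rs2$plateau)
})

test_that("flexibility ratio follows its closed form and is scale-invariant", {
  prof <- make_profile(rep(1, 20))
  expect_equal(flexibility_ratio(prof, prof$key[1:10])$ratio, 1)
  # loops twice as flexible, half the residues: (1.5 x)/(2 x) = 0.75
  prof2 <- make_profile(c(rep(1, 10), rep(2, 10)))
  r <- flexibility_ratio(prof2, prof2$key[11:20])
  expect_equal(r$ratio, 0.75)
  prof3 <- make_profile(c(rep(1, 10), rep(2, 10)) * 7)
  expect_equal(flexibility_ratio(prof3, prof3$key[11:20])$ratio, 0.75)
  expect_error(flexibility_ratio(prof, character(0)), "no loop residues")
})

test_that("delta profiles subtract exactly and smooth plateaus correctly", {
  p1 <- make_profile(rep(1, 20), 50)
  p2 <- make_profile(rep(1, 20), 35)
  expect_true(all(delta_rmsf(p1, p2)$delta == 0))
  # +0.5 step over a 10-residue run, window 3: interior deltas exactly 0.5
  p3 <- make_profile(c(rep(1, 5), rep(1.5, 10), rep(1, 5)), 50)
  d <- delta_rmsf(p3, p2, smoothing_window = 3)
  expect_equal(d$delta[7:13], rep(0.5, 7))
  # window 1 equals direct subtraction for arbitrary profiles
  set.seed(5)
  pa <- make_profile(runif(20), 50)
  pb <- make_profile(runif(20), 35)
  expect_equal(delta_rmsf(pa, pb, smoothing_window = 1)$delta,
               pa$rmsf - pb$rmsf)
  expect_error(delta_rmsf(pa, pb, smoothing_window = 2), "odd")
  expect_error(delta_rmsf(pa, make_profile(runif(19), 35)),
               "different residues")
})

test_that("the sign logic labels stability and activity regions", {
  n <- 40
  dh <- dl <- rep(0, n)
  dh[11:17] <- 0.69; dl[11:17] <- -0.35   # heats up, cools down: stability
  dl[25:31] <- 0.6                         # more mobile when cooled: activity
  d_high <- structure(data.frame(key = thermadapt:::res_key("A", 1:n),
                                 resseq = 1:n, delta = dh),
                      class = c("delta_flexibility", "data.frame"))
  d_low <- structure(data.frame(key = thermadapt:::res_key("A", 1:n),
                                resseq = 1:n, delta = dl),
                     class = c("delta_flexibility", "data.frame"))
  cls <- classify_thermal_regions(d_high, d_low, theta = 0.2, min_run = 3)
  expect_true(all(cls$labels[11:17] == "stability"))
  expect_true(all(cls$labels[25:31] == "activity"))
  expect_true(all(cls$labels[c(1:10, 18:24, 32:40)] == "neutral"))
  # runs shorter than min_run dissolve into neutral
  dh2 <- rep(0, n); dh2[5:6] <- 0.5
  dl2 <- rep(0, n); dl2[5:6] <- -0.5
  d_high2 <- d_high; d_high2$delta <- dh2
  d_low2 <- d_low; d_low2$delta <- dl2
  cls2 <- classify_thermal_regions(d_high2, d_low2, theta = 0.2,
                                   min_run = 3)
  expect_true(all(cls2$labels == "neutral"))
  expect_error(classify_thermal_regions(d_high, d_low, theta = 0),
               "positive")
})

test_that("flat sigma across temperatures classifies everything neutral", {
  s <- fixture_structure()
  se <- synth_ensemble(s, temperatures = c(15, 25, 50), sigma = 0.5,
                       n_frames = 800, seed = 6)
  profs <- lapply(se$ensembles, rmsf_profile, window = c(0.7, 1))
  d_high <- delta_rmsf(profs[["50"]], profs[["25"]], 1)
  d_low <- delta_rmsf(profs[["15"]], profs[["25"]], 1)
  cls <- classify_thermal_regions(d_high, d_low)
  expect_true(all(cls$labels == "neutral"))
})
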