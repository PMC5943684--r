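# Bridge conservation, composition trends, deamidation, substitution
# rules and the selection filter cascade.

test_that("an identical homolog conserves every bridge", {
  s <- fixture_structure(seed = 4, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 0)
  ref_ionic <- detect_interactions(s$model, "ionic")
  h <- synth_homolog(s, seed = 2)  # no changes
  bc <- map_bridge_conservation(ref_ionic, h$model, h$correspondence)
  expect_true(all(bc$status == "conserved"))
  expect_lte(sum(bc$status == "conserved"), nrow(ref_ionic))
})

test_that("broken bridges are reported lost, intact ones conserved", {
  s <- fixture_structure(seed = 4, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 0)
  ref_ionic <- detect_interactions(s$model, "ionic")
  h <- synth_homolog(s, break_bridges = c(1, 3), seed = 5)
  bc <- map_bridge_conservation(ref_ionic, h$model, h$correspondence)
  expect_equal(sum(bc$status == "conserved"), 1)
  expect_equal(sum(bc$status == "lost"), 2)
})

test_that("a bridge partner aligned to a gap means lost", {
  s <- fixture_structure(seed = 4, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 0)
  ref_ionic <- detect_interactions(s$model, "ionic")
  h <- synth_homolog(s, seed = 2)
  # drop the first bridge's Arg from the correspondence
  corr <- h$correspondence
  corr$pairs <- corr$pairs[corr$pairs$key_a != ref_ionic$key_a[1], ]
  bc <- map_bridge_conservation(ref_ionic, h$model, corr)
  expect_equal(bc$status[1], "lost")
  expect_true(is.na(bc$mapped_a[1]))
})

test_that("unknown homolog residues in the correspondence error out", {
  s <- fixture_structure(seed = 4, n_bridges = 3, triad = FALSE,
                         n_hydrophobic = 0)
  ref_ionic <- detect_interactions(s$model, "ionic")
  h <- synth_homolog(s, seed = 2)
  corr <- h$correspondence
  corr$pairs$key_b[1] <- "Z:999"
  expect_error(map_bridge_conservation(ref_ionic, h$model, corr),
               "unknown")
})

test_that("composition trends track planted monotone counts", {
  mk <- function(n_ala, id) {
    thermadapt:::new_sequence_record(id, paste(c(rep("A", n_ala),
                                                 rep("G", 10)),
                                               collapse = ""))
  }
  seqs <- list(mk(2, "p"), mk(4, "q"), mk(6, "r"), mk(8, "s"))
  tr <- composition_trend(seqs, c(10, 20, 37, 70))
  expect_equal(tr$rho[tr$aa == "A"], 1)
  expect_equal(tr$direction[tr$aa == "A"], "increasing")
  expect_equal(tr$direction[tr$aa == "G"], "flat")  # constant counts
  expect_true(all(tr$rho >= -1 & tr$rho <= 1))
  expect_error(composition_trend(seqs[1:2], c(10, 20)), "at least 3")
})

test_that("deamidation scan matches a regex oracle", {
  hits <- deamidation_scan("ANGA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 2)
  expect_equal(hits$motif, "NG")
  expect_equal(nrow(deamidation_scan("ANNA")), 1)  # only the second N
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "N", "G", "S", "H", "D", "K", "L"), 60,
                      replace = TRUE), collapse = "")
    m <- gregexpr("(?=N[GSHAD])", s, perl = TRUE)[[1]]
    oracle <- if (m[1] == -1) 0L else length(m)
    expect_equal(nrow(deamidation_scan(s)), oracle, info = s)
  }
})

test_that("deamidation positions use author numbering when keys exist", {
  rec <- thermadapt:::new_sequence_record("x", "ANG",
                                          c("A:10", "A:11", "A:12"))
  hits <- deamidation_scan(rec)
  expect_equal(hits$key, "A:11")
})

test_that("substitution counting is directional and skips gaps", {
  aln <- global_align("QGQ", "RGR", match = 1, mismatch = 0,
                      gap_open = 0, gap_extend = 1)
  rules <- data.frame(from = c("Q", "R"), to = c("R", "Q"))
  counts <- substitution_rule_count(aln, rules)
  expect_equal(counts$count[1], 2)  # Q -> R twice
  expect_equal(counts$count[2], 0)  # reverse never
  aln2 <- global_align("QA", "Q", match = 1, mismatch = 0, gap_open = 0,
                       gap_extend = 1)
  counts2 <- substitution_rule_count(aln2, list(c("A", "Q")))
  expect_equal(counts2$count, 0)    # gap column not counted
})

test_that("the candidate filter rejects on each criterion with reasons", {
  base <- data.frame(
    id = "x", pathogenic = FALSE, membrane_bound = FALSE, resolution = 2.0,
    has_primary_literature = TRUE, heteromultimeric = FALSE,
    method = "xray", identity_to_ref = 45, length = 310,
    triad_conserved = TRUE, stringsAsFactors = FALSE)
  res <- filter_candidates(base, reference_known_structure = TRUE)
  expect_equal(nrow(res$kept), 1)

  bad_res <- base; bad_res$resolution <- 3.2
  out <- filter_candidates(bad_res, TRUE)
  expect_equal(out$rejected$reasons, "c")

  bad_id <- base; bad_id$identity_to_ref <- 52
  expect_equal(filter_candidates(bad_id, TRUE)$rejected$reasons, "g")
  edge <- base; edge$identity_to_ref <- 50  # closed band includes 50
  expect_equal(nrow(filter_candidates(edge, TRUE)$kept), 1)

  multi <- base
  multi$pathogenic <- TRUE; multi$method <- "nmr"; multi$length <- 450
  expect_equal(filter_candidates(multi, TRUE)$rejected$reasons, "a,f,h")
})

test_that("filter output partitions the input and reasons are never empty", {
  set.seed(10)
  n <- 30
  recs <- data.frame(
    id = paste0("e", 1:n),
    pathogenic = sample(c(TRUE, FALSE), n, TRUE),
    membrane_bound = sample(c(TRUE, FALSE), n, TRUE),
    resolution = round(runif(n, 1, 4), 1),
    has_primary_literature = sample(c(TRUE, FALSE), n, TRUE),
    heteromultimeric = sample(c(TRUE, FALSE), n, TRUE),
    method = sample(c("xray", "nmr"), n, TRUE),
    identity_to_ref = round(runif(n, 20, 60)),
    length = sample(200:500, n),
    triad_conserved = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE)
  out <- filter_candidates(recs, TRUE)
  expect_equal(nrow(out$kept) + nrow(out$rejected), n)
  expect_true(all(nchar(out$rejected$reasons) > 0))
  expect_error(filter_candidates(recs[, -3], TRUE), "membrane_bound")
})
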