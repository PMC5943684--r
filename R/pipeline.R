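# Orchestration of the full comparative study: superposition table,
# interaction censuses, bridge conservation, composition trends and
# flexibility classification, with a reproducible manifest.

#' Assemble and validate a study configuration
#'
#' @param enzymes List of per-enzyme entries: `id`, `structure` (a
#'   `structure_model` or PDB path), optional `ensembles` (named list,
#'   temperature label -> `ensemble` or multi-model PDB path), `t_opt`,
#'   `t_high`, `t_low` (degrees C; required when ensembles are given) and
#'   `host_temp` (degrees C).
#' @param reference_id Id of the reference enzyme (the known structure).
#' @param criteria A `criteria_set`.
#' @param window Trailing RMSF window (fraction pair).
#' @param theta Classification threshold, Angstrom.
#' @param min_run Minimum classified run length, residues.
#' @param smoothing_window Delta-RMSF smoothing window (odd).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `study_config`.
#' @export
study_config <- function(enzymes, reference_id,
                         criteria = default_criteria(),
                         window = c(0.7, 1), theta = 0.2, min_run = 3L,
                         smoothing_window = 3L, seed = 1L) {
  ids <- vapply(enzymes, function(e) e$id, "")
  if (anyDuplicated(ids)) stop2("duplicate enzyme ids")
  if (!reference_id %in% ids) stop2("reference_id '%s' not among enzymes",
                                    reference_id)
  defaults_filled <- character()
  for (i in seq_along(enzymes)) {
    e <- enzymes[[i]]
    if (is.null(e$structure)) stop2("enzyme '%s' lacks a structure", e$id)
    if (!is.null(e$ensembles) && length(e$ensembles) > 0) {
      for (role in c("t_opt", "t_high", "t_low")) {
        if (is.null(e[[role]])) {
          stop2("enzyme '%s' has ensembles but no %s temperature", e$id, role)
        }
        if (!as.character(e[[role]]) %in% names(e$ensembles)) {
          stop2("enzyme '%s' lacks an ensemble for %s = %s degC", e$id,
                role, e[[role]])
        }
      }
    }
    if (is.null(e$host_temp)) {
      enzymes[[i]]$host_temp <- NA_real_
      defaults_filled <- c(defaults_filled,
                           sprintf("%s.host_temp = NA", e$id))
    }
  }
  structure(list(enzymes = enzymes, reference_id = reference_id,
                 criteria = criteria, window = window, theta = theta,
                 min_run = min_run, smoothing_window = smoothing_window,
                 seed = seed, defaults_filled = defaults_filled),
            class = "study_config")
}

.load_structure <- function(x, id) {
  if (inherits(x, "structure_model")) return(x)
  if (is.character(x)) return(read_structure(x))
  stop2("enzyme '%s': structure must be a structure_model or a path", id)
}

.load_ensemble <- function(x, temperature) {
  if (inherits(x, "ensemble")) return(x)
  if (is.character(x)) return(read_ensemble(x, temperature = temperature))
  stop2("ensemble must be an ensemble object or a path")
}

#' Run the full comparative study
#'
#' Executes, per enzyme against the reference: sequence alignment and
#' C-alpha superposition with per-class RMSD; secondary-structure
#' fractions and loop inventory; interaction census with loop/surface
#' partition; salt-bridge conservation; amino-acid composition trends; and
#' (where ensembles are configured) trailing-window RMSF, loop/overall
#' ratio, delta-RMSF versus T_opt and stability/activity region
#' classification. Deterministic given config and seed.
#'
#' @param config A `study_config`.
#' @param out_dir Optional directory; reports are written as TSV/JSON
#'   after the whole study succeeds (no partial output on failure).
#' @return A `study_report` (list of result tables; see the vignette).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  ids <- vapply(config$enzymes, function(e) e$id, "")
  models <- stage("load", {
    out <- lapply(config$enzymes, function(e) .load_structure(e$structure,
                                                              e$id))
    names(out) <- ids
    out
  })
  ref_id <- config$reference_id
  cr <- config$criteria

  sse <- stage("secondary_structure", lapply(models, assign_sse))
  loops <- lapply(sse, segment_loops)
  fractions <- lapply(sse, sse_fractions)

  seqs <- stage("sequences", lapply(models, function(m) {
    extract_sequence(m, residue_table(m)$chain[1])
  }))

  superposition <- stage("superposition", {
    out <- NULL
    for (id in setdiff(ids, ref_id)) {
      aln <- global_align(seqs[[ref_id]], seqs[[id]])
      corr <- pair_residues(models[[ref_id]], models[[id]], aln)
      sup <- superpose_models(models[[ref_id]], models[[id]], corr)
      sup <- classwise_rmsd(sup, sse_a = sse[[ref_id]])
      cls <- function(cl) {
        v <- sup$rmsd_by_class[[cl]]
        if (is.null(v)) c(NA_real_, 0) else c(v$rmsd, v$n)
      }
      h <- cls("helix"); s <- cls("strand"); l <- cls("loop")
      out <- rbind(out, data.frame(
        id = id, identity_pct = aln$identity_pct,
        rmsd_total = sup$rmsd_all, n_total = sup$n_pairs,
        rmsd_helix = h[1], n_helix = h[2],
        rmsd_strand = s[1], n_strand = s[2],
        rmsd_loop = l[1], n_loop = l[2], stringsAsFactors = FALSE))
    }
    out
  })

  census <- stage("interaction_census", {
    out <- list()
    for (id in ids) {
      recs <- do.call(rbind, lapply(c("hydrophobic", "aromatic", "ionic",
                                      "hbond"), function(k) {
        detect_interactions(models[[id]], k, cr)
      }))
      attr(recs, "model_id") <- models[[id]]$id
      sasa <- shrake_rupley_sasa(models[[id]], cr$sasa_probe,
                                 cr$sasa_n_points, cr)
      out[[id]] <- list(records = recs,
                        census = interaction_census(recs, sse[[id]], sasa),
                        sasa = sasa)
    }
    out
  })

  bridges <- stage("bridge_conservation", {
    ref_recs <- census[[ref_id]]$records
    ref_ionic <- ref_recs[ref_recs$kind == "ionic", , drop = FALSE]
    attr(ref_ionic, "model_id") <- models[[ref_id]]$id
    out <- list(reference = ref_ionic)
    for (id in setdiff(ids, ref_id)) {
      aln <- global_align(seqs[[ref_id]], seqs[[id]])
      corr <- pair_residues(models[[ref_id]], models[[id]], aln)
      out[[id]] <- map_bridge_conservation(ref_ionic, models[[id]], corr,
                                           cr)
    }
    out
  })

  host_temps <- vapply(config$enzymes, function(e) e$host_temp, numeric(1))
  composition <- if (length(ids) >= 3 && !anyNA(host_temps)) {
    stage("composition_trend", composition_trend(seqs, host_temps))
  } else NULL

  flexibility <- stage("flexibility", {
    out <- list()
    for (i in seq_along(config$enzymes)) {
      e <- config$enzymes[[i]]
      if (is.null(e$ensembles) || length(e$ensembles) == 0) next
      roles <- c(t_opt = e$t_opt, t_high = e$t_high, t_low = e$t_low)
      profs <- lapply(names(roles), function(role) {
        ens <- .load_ensemble(e$ensembles[[as.character(roles[[role]])]],
                              roles[[role]])
        rmsf_profile(ens, window = config$window)
      })
      names(profs) <- names(roles)
      loop_keys <- loop_residue_keys(sse[[e$id]], loops[[e$id]])
      ratio <- flexibility_ratio(profs$t_opt,
                                 intersect(loop_keys, profs$t_opt$key))
      d_high <- delta_rmsf(profs$t_high, profs$t_opt,
                           config$smoothing_window)
      d_low <- delta_rmsf(profs$t_low, profs$t_opt,
                          config$smoothing_window)
      cls <- classify_thermal_regions(d_high, d_low, config$theta,
                                      config$min_run)
      out[[e$id]] <- list(profiles = profs, ratio = ratio,
                          delta_high = d_high, delta_low = d_low,
                          classification = cls)
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermadapt")),
    r_version = R.version.string,
    seed = config$seed, reference_id = ref_id,
    parameters = list(window = config$window, theta = config$theta,
                      min_run = config$min_run,
                      smoothing_window = config$smoothing_window,
                      criteria = unclass(cr)),
    defaults_filled = config$defaults_filled,
    enzymes = ids)

  report <- structure(list(
    superposition = superposition, sse_fractions = fractions,
    loops = loops, census = census, bridges = bridges,
    composition = composition, flexibility = flexibility,
    manifest = manifest), class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' Write a study report bundle to disk
#'
#' Plain TSV/JSON files: superposition table, per-enzyme census JSON,
#' bridge conservation table, composition trends, per-residue flexibility
#' TSVs (RMSF in both Angstrom and nm) and the run manifest.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$superposition)) {
    tsv(report$superposition, "superposition.tsv")
  }
  census <- lapply(report$census, function(x) {
    c(as.list(x$census$counts), total = x$census$total,
      pct_in_loops = as.list(x$census$pct_in_loops),
      pct_surface_exposed = as.list(x$census$pct_surface_exposed))
  })
  jsonlite::write_json(census, file.path(out_dir, "census.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (id in names(report$bridges)) {
    if (id == "reference") next
    tsv(report$bridges[[id]], sprintf("bridges_%s.tsv", id))
  }
  if (!is.null(report$composition)) {
    tsv(report$composition, "composition.tsv")
  }
  for (id in names(report$flexibility)) {
    fx <- report$flexibility[[id]]
    prof <- fx$profiles$t_opt
    df <- data.frame(key = prof$key, resseq = prof$resseq,
                     rmsf_ang = prof$rmsf, rmsf_nm = prof$rmsf / 10,
                     delta_high = fx$delta_high$delta,
                     delta_low = fx$delta_low$delta,
                     label = unname(fx$classification$labels),
                     stringsAsFactors = FALSE)
    tsv(df, sprintf("flexibility_%s.tsv", id))
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  enzymes: %s (reference %s)\n",
              paste(x$manifest$enzymes, collapse = ", "),
              x$manifest$reference_id))
  if (!is.null(x$superposition)) {
    cat(sprintf("  superposition: %d homolog(s), total RMSD %s A\n",
                nrow(x$superposition),
                paste(sprintf("%.2f", x$superposition$rmsd_total),
                      collapse = "/")))
  }
  for (id in names(x$census)) {
    cat(sprintf("  %s: %d interactions\n", id, x$census[[id]]$census$total))
  }
  if (length(x$flexibility) > 0) {
    for (id in names(x$flexibility)) {
      cat(sprintf("  %s loop/overall RMSF ratio: %.2f\n", id,
                  x$flexibility[[id]]$ratio$ratio))
    }
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  print(object)
  if (!is.null(object$bridges)) {
    ref_n <- nrow(object$bridges$reference)
    for (id in setdiff(names(object$bridges), "reference")) {
      n_c <- sum(object$bridges[[id]]$status == "conserved")
      cat(sprintf("  bridges conserved in %s: %d of %d\n", id, n_c, ref_n))
    }
  }
  invisible(object)
}
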