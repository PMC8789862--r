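#' Load a clinical cohort table
#'
#' Reads a per-patient clinical CSV (patient, engel, followup_years,
#' defect_electrodes as a ';'-separated list, asm_withdrawn). The package
#' ships the study-style example table at
#' \code{system.file("extdata", "table1_cohort.csv", package = "scalphfo")}.
#'
#' @param path CSV path; default is the shipped example table.
#' @return data.frame.
#' @export
read_cohort_table <- function(path = system.file("extdata",
                                                 "table1_cohort.csv",
                                                 package = "scalphfo")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort arithmetic summary
#'
#' Derives the headline descriptive statistics of a clinical cohort table:
#' the seizure-free fraction, mean follow-up, seizure freedom off
#' anti-seizure medication, and skull-defect-electrode counts.
#'
#' @param tab data.frame from \code{\link{read_cohort_table}}.
#' @return list: \code{n_patients}, \code{n_engel1}, \code{pct_engel1}
#'   (whole percent), \code{mean_followup_years}, \code{n_szfree_off_asm},
#'   \code{n_szfree_off_asm_fu2y} (of those, follow-up >= 2 years),
#'   \code{n_no_defect_electrodes}, \code{n_with_defect_channels},
#'   \code{n_with_defect_channels_szfree}.
#' @export
cohort_summary <- function(tab) {
  szfree <- grepl("^I[a-d]?$", tab$engel)
  off_asm <- szfree & tolower(tab$asm_withdrawn) == "yes"
  no_defect <- tab$defect_electrodes %in% c("None", "none", "")
  list(n_patients = nrow(tab),
       n_engel1 = sum(szfree),
       pct_engel1 = round(100 * mean(szfree)),
       mean_followup_years = round(mean(tab$followup_years), 1),
       n_szfree_off_asm = sum(off_asm),
       n_szfree_off_asm_fu2y = sum(off_asm & tab$followup_years >= 2),
       n_no_defect_electrodes = sum(no_defect),
       n_with_defect_channels = sum(!no_defect),
       n_with_defect_channels_szfree = sum(!no_defect & szfree))
}

# mean HFO-area rate per session, from detector output or ground truth
session_rate_tables <- function(cohort, use_detector, params, montage,
                                channels = NULL) {
  lapply(cohort$sessions, function(pt) {
    lapply(pt, function(ses) {
      if (use_detector) {
        iv <- select_intervals(ses$recording, stages = "N3",
                               min_total_minutes = 0,
                               interval_s = cohort$config$interval_s)
        ev <- detect_hfo(ses$recording, montage, iv, params,
                         channels = channels)
        compute_rates(accepted_events(ev), iv, channels = montage$channel)
      } else {
        ground_truth_rates(ses, montage)
      }
    })
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate, detect (optionally bypassed in favor of the
#' generator's ground-truth events), rate estimation, the HFO area,
#' skull-defect geometry, channel grouping and the outcome statistics.
#' The detection stage sees only signals and intervals, never outcome
#' fields. When \code{out_dir} is given, per-stage artifacts (cohort CSV,
#' rate CSVs, area JSON, distances CSV, stats JSON) and a run manifest
#' with file digests are written.
#'
#' @param config a \code{sim_config}.
#' @param use_detector run the signal-level detector (TRUE) or use the
#'   generator's ground-truth event lists (FALSE; orders of magnitude
#'   faster, used for statistics-level studies).
#' @param params a \code{detector_params}.
#' @param montage a \code{bipolar_montage}.
#' @param cv_seed seed for the cross-validation shuffles.
#' @param out_dir optional output directory for artifacts.
#' @return list of class \code{hfo_pipeline_result}: \code{summaries}
#'   (per-recording data.frame: patient, session, engel, mean_area_rate,
#'   seizure_freq, epilepsy_active), \code{area}, \code{groups},
#'   \code{defect_electrodes}, \code{stats} (rho/p, paired tests,
#'   threshold, confusion, cv), \code{manifest} (when written).
#' @export
run_pipeline <- function(config = sim_config(), use_detector = FALSE,
                         params = detector_params(),
                         montage = default_montage(), cv_seed = config$seed,
                         out_dir = NULL) {
  cohort <- generate_cohort(config, signals = use_detector)
  tabs <- session_rate_tables(cohort, use_detector, params, montage)

  # geometry -> skull-defect channels (shared head model)
  defect_el <- classify_defect_electrodes(cohort$head, cutoff_cm = 1.0)
  defect_ch <- skull_defect_channels(montage, defect_el)

  ct <- cohort$cohort_table
  rows <- list(); areas <- list(); groups <- list()
  for (i in seq_len(nrow(ct))) {
    p <- ct$patient[i]
    area <- compute_hfo_area(tabs[[p]]$pre)
    areas[[p]] <- area
    groups[[p]] <- channel_groups(area, defect_ch, montage)
    for (ses in c("pre", "post")) {
      ch <- if (length(area$channels)) area$channels else montage$channel
      rows[[paste(p, ses)]] <- data.frame(
        patient = p, session = ses, engel = ct$engel[i],
        mean_area_rate = recording_summary(tabs[[p]][[ses]], ch),
        area_empty = length(area$channels) == 0L,
        seizure_freq = if (ses == "pre") ct$seizure_freq_pre[i]
                       else ct$seizure_freq_post[i],
        stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  summaries$epilepsy_active <- epilepsy_active(summaries$session,
                                               summaries$engel)

  stats <- cohort_stats(summaries, tabs, groups, cv_seed = cv_seed)

  res <- structure(list(summaries = summaries, areas = areas,
                        groups = groups, defect_electrodes = defect_el,
                        defect_channels = defect_ch, stats = stats,
                        cohort = cohort, rate_tables = tabs),
                   class = "hfo_pipeline_result")
  if (!is.null(out_dir)) res$manifest <- write_artifacts(res, out_dir)
  res
}

#' Outcome statistics of a per-recording summary table
#'
#' Computes the statistical layer on per-recording mean HFO-area rates:
#' Spearman correlation with seizure frequency, the Engel-I and Engel
#' II-IV paired pre/post signed-rank tests, the ROC operating-point
#' threshold with confusion counts, two-fold cross-validation, and the
#' skull-defect group comparisons when rate tables and groups are given.
#'
#' @param summaries data.frame with patient, session, engel,
#'   mean_area_rate, seizure_freq, epilepsy_active.
#' @param tabs optional per-patient list of pre/post rate tables (for the
#'   skull-defect group comparisons).
#' @param groups optional per-patient channel groups.
#' @param cv_seed seed for cross-validation.
#' @return list with elements \code{spearman}, \code{engel1_prepost},
#'   \code{engel24_prepost}, \code{threshold}, \code{confusion}, \code{cv},
#'   and (when available) \code{defect_in_area_prepost},
#'   \code{defect_outside_prepost}, \code{contralateral_post}.
#' @export
cohort_stats <- function(summaries, tabs = NULL, groups = NULL,
                         cv_seed = 1L) {
  sp <- spearman_rho(summaries$mean_area_rate, summaries$seizure_freq)
  paired <- function(engel_set) {
    pre <- summaries[summaries$session == "pre" &
                       summaries$engel %in% engel_set, ]
    post <- summaries[summaries$session == "post" &
                        summaries$engel %in% engel_set, ]
    post <- post[match(pre$patient, post$patient), ]
    tryCatch(signed_rank(pre$mean_area_rate, post$mean_area_rate),
             error = function(e) list(p = NA_real_, z = NA_real_,
                                      n_effective = 0L))
  }
  e1 <- paired(c("I", "Ia", "Ib", "Ic", "Id"))
  e24 <- paired(c("II", "III", "IV"))
  th <- roc_threshold(summaries$mean_area_rate, summaries$epilepsy_active)
  conf <- classify_and_score(summaries$mean_area_rate,
                             summaries$epilepsy_active, th$threshold)
  # class-degenerate cohorts (e.g. a single seizure-free recording) cannot
  # form balanced folds; the cv summary is NA then rather than an error
  cv <- tryCatch(twofold_cv(summaries$mean_area_rate,
                            summaries$epilepsy_active, seed = cv_seed),
                 error = function(e) list(folds = NULL,
                                          summary = NULL, error = conditionMessage(e)))
  out <- list(spearman = sp, engel1_prepost = e1, engel24_prepost = e24,
              threshold = th, confusion = conf, cv = cv)
  if (!is.null(tabs) && !is.null(groups)) {
    grp_mean <- function(p, ses, chans) {
      if (!length(chans)) return(NA_real_)
      recording_summary(tabs[[p]][[ses]], chans)
    }
    pts <- names(tabs)
    szfree <- vapply(pts, function(p)
      grepl("^I[a-d]?$", summaries$engel[summaries$patient == p][1]), TRUE)
    pair_test <- function(sel, chans_of) {
      pre <- vapply(pts[sel], function(p) grp_mean(p, "pre", chans_of(p)), 0)
      post <- vapply(pts[sel], function(p) grp_mean(p, "post", chans_of(p)), 0)
      keep <- is.finite(pre) & is.finite(post)
      if (sum(keep) < 2) return(list(p = NA_real_, z = NA_real_,
                                     n_effective = 0L))
      tryCatch(signed_rank(pre[keep], post[keep]),
               error = function(e) list(p = NA_real_, z = NA_real_,
                                        n_effective = 0L))
    }
    out$defect_in_area_prepost <- pair_test(szfree, function(p)
      groups[[p]]$area_defect)
    out$defect_outside_prepost <- pair_test(szfree, function(p)
      groups[[p]]$defect_outside_area)
    ipsi <- vapply(pts, function(p)
      grp_mean(p, "post", groups[[p]]$defect_outside_area), 0)
    contra <- vapply(pts, function(p)
      grp_mean(p, "post", groups[[p]]$contralateral), 0)
    keep <- is.finite(ipsi) & is.finite(contra)
    out$contralateral_post <- if (sum(keep) >= 2)
      tryCatch(signed_rank(ipsi[keep], contra[keep]),
               error = function(e) list(p = NA_real_, z = NA_real_,
                                        n_effective = 0L))
      else list(p = NA_real_, z = NA_real_, n_effective = 0L)
  }
  out
}

#' @export
print.hfo_pipeline_result <- function(x, ...) {
  s <- x$stats
  cat("HFO pipeline result:", nrow(x$summaries), "recordings\n")
  cat(sprintf("  Spearman rho(rate, seizure freq) = %.3f (p = %.2g)\n",
              s$spearman$rho, s$spearman$p))
  cat(sprintf("  Engel I pre vs post: p = %.3g (z = %.2f); Engel II-IV: p = %.3g\n",
              s$engel1_prepost$p, s$engel1_prepost$z, s$engel24_prepost$p))
  cat(sprintf("  ROC threshold %.3f HFO/min: ", s$threshold$threshold))
  print(s$confusion)
  invisible(x)
}

# write per-stage artifacts and a digest manifest; returns the manifest
write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  w <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  w("cohort.csv", function(p)
    utils::write.csv(res$cohort$cohort_table, p, row.names = FALSE))
  w("summaries.csv", function(p)
    utils::write.csv(res$summaries, p, row.names = FALSE))
  w("defect_distances.csv", function(p) {
    d <- electrode_defect_distances(res$cohort$head)
    utils::write.csv(data.frame(label = names(d), distance_cm = d), p,
                     row.names = FALSE)
  })
  w("electrodes.csv", function(p) {
    el <- res$cohort$head$electrodes
    utils::write.csv(data.frame(label = rownames(el), x_cm = el[, 1],
                                y_cm = el[, 2], z_cm = el[, 3]), p,
                     row.names = FALSE)
  })
  w("area.json", function(p)
    jsonlite::write_json(lapply(res$areas, function(a)
      list(channels = a$channels, rate_threshold = a$rate_threshold,
           occurrence_threshold = a$occurrence_threshold)), p,
      auto_unbox = TRUE, digits = NA))
  w("stats.json", function(p) {
    s <- res$stats
    jsonlite::write_json(list(
      spearman = s$spearman[c("rho", "p", "n")],
      engel1_prepost = s$engel1_prepost[c("p", "z", "n_effective")],
      engel24_prepost = s$engel24_prepost[c("p", "z", "n_effective")],
      threshold = s$threshold$threshold,
      confusion = unclass(s$confusion)[c("TP", "FP", "FN", "TN", "ppv",
                                         "npv", "accuracy")],
      cv_summary = s$cv$summary), p, auto_unbox = TRUE, digits = NA)
  })
  digests <- as.list(tools::md5sum(unlist(paths)))
  names(digests) <- names(paths)
  manifest <- list(seed = res$cohort$config$seed,
                   package_version =
                     as.character(utils::packageVersion("scalphfo")),
                   files = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Write a ground-truth event table to TSV
#' @param ground_truth event data.frame from a \code{synthetic_session}.
#' @param path output TSV path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a detector event table to TSV
#' @param events an \code{hfo_events} table.
#' @param path output TSV path.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
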