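# Pipeline orchestration: write a synthetic study to tidy CSV files, read it
# back, and run the full analysis chain to summary and effects tables.

write_channel_csv <- function(trace, path) {
  df <- data.frame(time_s = trace_time(trace), value = trace$values)
  write.csv(df, path, row.names = FALSE)
}

read_channel_csv <- function(path, channel = "signal", units = "",
                             site = "") {
  df <- read.csv(path)
  # reconstruct the sampling rate exactly despite decimal round-off
  fs <- round((nrow(df) - 1) / (df$time_s[nrow(df)] - df$time_s[1]) * 1000) / 1000
  channel_trace(df$value, fs = fs, channel = channel, units = units,
                site = site)
}

#' Write a synthetic study to disk
#'
#' Writes one directory per participant x condition containing tidy CSV
#' time-series (`time_s`, `value`; one file per channel), JSON sidecars for
#' stimulation markers and scalar endpoints, the ergometer timeline, a
#' study-level manifest CSV and a ground-truth JSON. Output is plain text
#' and byte-stable under a fixed seed.
#'
#' @param study A `bfr_study` from [generate_study()] (with signals).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "bfr_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in study$participants) {
    for (cond in as.character(study$conditions)) {
      cell <- study$cells[[i]][[cond]]
      if (is.null(cell$power)) stop("study was generated without signals")
      cdir <- file.path(dir, sprintf("participant_%02d", i),
                        sprintf("condition_%s", cond))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_channel_csv(cell$power, file.path(cdir, "power.csv"))
      write_channel_csv(cell$cadence, file.path(cdir, "cadence.csv"))
      for (st in c("muscle", "cerebral")) {
        nir <- if (st == "muscle") cell$nirs_muscle else cell$nirs_cerebral
        for (ch in c("o2hb", "hhb", "tsi"))
          write_channel_csv(nir[[ch]], file.path(cdir, sprintf("%s_%s.csv", st, ch)))
      }
      for (ph in c("pre", "post")) {
        nm <- if (ph == "pre") cell$nm_pre else cell$nm_post
        write_channel_csv(nm$force, file.path(cdir, sprintf("force_%s.csv", ph)))
        write_channel_csv(nm$emg, file.path(cdir, sprintf("emg_%s.csv", ph)))
        jsonlite::write_json(nm$markers,
                             file.path(cdir, sprintf("markers_%s.json", ph)),
                             digits = NA)
      }
      write.csv(cell$vo2, file.path(cdir, "vo2.csv"), row.names = FALSE)
      write_channel_csv(cell$hr, file.path(cdir, "hr.csv"))
      write_channel_csv(cell$spo2, file.path(cdir, "spo2.csv"))
      write.csv(as.data.frame(unclass(cell$timeline)),
                file.path(cdir, "timeline.csv"), row.names = FALSE)
      jsonlite::write_json(cell$scalars, file.path(cdir, "scalars.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest[[length(manifest) + 1L]] <-
        data.frame(participant = i, condition = cond,
                   path = file.path(sprintf("participant_%02d", i),
                                    sprintf("condition_%s", cond)))
    }
  }
  write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  jsonlite::write_json(list(seed = study$seed,
                            conditions = study$conditions,
                            n_participants = length(study$participants)),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Study directory containing `manifest.csv`.
#' @return A `bfr_study`-like list (without the stored clean components).
#' @export
read_study <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"),
                 colClasses = c(condition = "character"))
  meta <- jsonlite::read_json(file.path(dir, "study.json"))
  participants <- sort(unique(mf$participant))
  conds <- as.character(unlist(meta$conditions))
  cells <- vector("list", max(participants))
  for (r in seq_len(nrow(mf))) {
    i <- mf$participant[r]; cond <- mf$condition[r]
    cdir <- file.path(dir, mf$path[r])
    tl <- read.csv(file.path(cdir, "timeline.csv"))
    timeline <- sprint_timeline(tl$start, tl$end, tl$recovery_end)
    rd_nirs <- function(st, site) {
      setNames(lapply(c("o2hb", "hhb", "tsi"), function(ch)
        read_channel_csv(file.path(cdir, sprintf("%s_%s.csv", st, ch)),
                         channel = toupper(ch),
                         units = if (ch == "tsi") "%" else "uM",
                         site = site)),
        c("o2hb", "hhb", "tsi"))
    }
    rd_nm <- function(ph) {
      list(force = read_channel_csv(file.path(cdir, sprintf("force_%s.csv", ph)),
                                    "force", "N"),
           emg = read_channel_csv(file.path(cdir, sprintf("emg_%s.csv", ph)),
                                  "emg", "mV", "vastus_lateralis"),
           markers = as.data.frame(
             jsonlite::fromJSON(file.path(cdir, sprintf("markers_%s.json", ph)))))
    }
    if (is.null(cells[[i]])) cells[[i]] <- list()
    cells[[i]][[cond]] <- list(
      power = read_channel_csv(file.path(cdir, "power.csv"), "power", "W"),
      cadence = read_channel_csv(file.path(cdir, "cadence.csv"), "cadence", "rpm"),
      timeline = timeline,
      nirs_muscle = rd_nirs("muscle", "vastus_lateralis"),
      nirs_cerebral = rd_nirs("cerebral", "prefrontal_cortex"),
      nm_pre = rd_nm("pre"), nm_post = rd_nm("post"),
      vo2 = read.csv(file.path(cdir, "vo2.csv")),
      hr = read_channel_csv(file.path(cdir, "hr.csv"), "hr", "bpm"),
      spo2 = read_channel_csv(file.path(cdir, "spo2.csv"), "spo2", "%"),
      scalars = jsonlite::read_json(file.path(cdir, "scalars.json"),
                                    simplifyVector = TRUE)
    )
  }
  truth <- as.data.frame(jsonlite::fromJSON(file.path(dir, "ground_truth.json")))
  structure(list(participants = participants, conditions = conds,
                 cells = cells, truth = truth,
                 protocol = default_protocol(),
                 seed = meta$seed),
            class = "bfr_study")
}

#' Generate a synthetic study and write it to disk
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_participants Number of participants (default 11).
#' @param ... Passed to [generate_study()].
#' @return The generated `bfr_study`, invisibly.
#' @export
run_generate <- function(out_dir, seed = 1, n_participants = 11, ...) {
  study <- generate_study(n_participants = n_participants, seed = seed, ...)
  write_study(study, out_dir)
  invisible(study)
}

#' Run the full analysis chain on a study
#'
#' For every participant x condition cell: summarises sprint performance,
#' extracts per-sprint NIRS deltas for both sites and normalises them to
#' set-duration fractions, and analyses both neuromuscular assessments.
#' Then fits the study-level mixed models (participant random intercept)
#' and runs likelihood-ratio tests and Tukey-adjusted contrasts for the
#' condition effect on sprint count, the condition x phase effects on MVC
#' and voluntary activation, and the condition x set-duration effects on
#' the muscle NIRS deltas. Per-subject percent changes versus the
#' unoccluded condition are reported for sprint count and total work.
#'
#' @param study A `bfr_study` (from [generate_study()] or [read_study()]).
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV files.
#' @param skip_stats Only compute per-test summaries (default `FALSE`).
#' @return List of data frames: `performance`, `nirs`, `nirs_normalized`,
#'   `neuromuscular`, and (unless skipped) `effects`, `contrasts`,
#'   `percent_change`.
#' @export
run_analyze <- function(study, out_dir = NULL, skip_stats = FALSE) {
  stopifnot(inherits(study, "bfr_study"))
  perf <- nirs <- nirsn <- nm <- list()
  for (i in study$participants) {
    for (cond in as.character(study$conditions)) {
      cell <- study$cells[[i]][[cond]]
      if (is.null(cell$power)) stop("study has no signal traces")
      id <- data.frame(participant = i, condition = cond)
      perf[[length(perf) + 1L]] <- cbind(id, summarize_sprint_test(
        cell$power, cell$timeline, cadence = cell$cadence, vo2 = cell$vo2,
        hr = cell$hr, spo2 = cell$spo2, scalars = cell$scalars))
      for (st in c("muscle", "cerebral")) {
        nir <- if (st == "muscle") cell$nirs_muscle else cell$nirs_cerebral
        smry <- nirs_sprint_summary(nir$o2hb, nir$hhb, nir$tsi,
                                    timeline = cell$timeline)
        nirs[[length(nirs) + 1L]] <- cbind(id, site = st, smry)
        for (ch in c("delta_o2hb", "delta_hhb", "delta_thb", "tsi_max")) {
          vals <- normalize_set_duration(smry[[ch]])
          nirsn[[length(nirsn) + 1L]] <- cbind(
            id, data.frame(site = st, channel = ch,
                           fraction = c(0.2, 0.4, 0.6, 0.8, 1.0),
                           value = as.numeric(vals)))
        }
      }
      for (ph in c("pre", "post")) {
        rec <- if (ph == "pre") cell$nm_pre else cell$nm_post
        nm[[length(nm) + 1L]] <- cbind(id, analyze_neuromuscular(
          rec$force, rec$emg, rec$markers, phase = ph))
      }
    }
  }
  out <- list(performance = do.call(rbind, perf),
              nirs = do.call(rbind, nirs),
              nirs_normalized = do.call(rbind, nirsn),
              neuromuscular = do.call(rbind, nm))
  if (!skip_stats) {
    eff <- list(); ctr <- list()
    add_effect <- function(endpoint, tab, term, fixed, interaction = TRUE) {
      res <- lrt_term(tab, term, fixed = fixed, interaction = interaction)
      eff[[length(eff) + 1L]] <<- cbind(data.frame(endpoint = endpoint), res)
      m <- fit_mixed_model(tab, fixed, interaction = interaction)
      tc <- tukey_contrasts(m, term)
      ctr[[length(ctr) + 1L]] <<- cbind(data.frame(endpoint = endpoint),
                                        tc$contrasts)
    }
    ptab <- out$performance
    ptab$value <- ptab$n_sprints
    add_effect("n_sprints", ptab, "condition", "condition")
    ptab$value <- ptab$total_work_kj
    add_effect("total_work_kj", ptab, "condition", "condition")
    ptab$value <- ptab$fatigue_index_pct
    add_effect("fatigue_index_pct", ptab, "condition", "condition")
    ptab$value <- ptab$vo2_lmin
    add_effect("vo2_lmin", ptab, "condition", "condition")
    nmtab <- out$neuromuscular
    nmtab$value <- nmtab$mvc_n
    add_effect("mvc_n", nmtab, "condition", c("condition", "phase"))
    nmtab$value <- nmtab$val_pct
    add_effect("val_pct", nmtab, "condition", c("condition", "phase"))
    ntab <- out$nirs_normalized
    ntab <- ntab[ntab$site == "muscle" & ntab$channel == "delta_hhb", ]
    ntab$fraction <- factor(ntab$fraction)
    add_effect("muscle_delta_hhb", ntab, "condition",
               c("condition", "fraction"))
    pct <- out$performance
    pct$value <- pct$n_sprints
    pc1 <- cbind(endpoint = "n_sprints",
                 percent_change_summary(pct))
    pct$value <- pct$total_work_kj
    pc2 <- cbind(endpoint = "total_work_kj",
                 percent_change_summary(pct))
    out$effects <- do.call(rbind, eff)
    out$contrasts <- do.call(rbind, ctr)
    out$percent_change <- rbind(pc1, pc2)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm2 in names(out))
      write.csv(out[[nm2]], file.path(out_dir, paste0(nm2, ".csv")),
                row.names = FALSE)
  }
  out
}
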