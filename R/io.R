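## Dataset bundle: the tabular interchange layout.  Three tables mirror
## the three-sheet supplementary layout common for this assay family:
## gap detection, prepulse inhibition, ABR thresholds.  The canonical
## on-disk dialect is a CSV directory (gap.csv, ppi.csv, abr.csv plus a
## meta.json provenance sidecar); a three-sheet XLSX can be read when the
## readxl package is available.

GAP_COLS <- c("mouse_id", "group", "timepoint", "session", "band",
              "mean_sa", "mean_ga", "n_sa", "n_ga", "inhibition_pct")
PPI_COLS <- c("mouse_id", "group", "timepoint", "task", "prepulse_khz",
              "delta_f_pct", "mean_asr", "sd_asr", "n", "ppi_pct")
ABR_COLS <- c("mouse_id", "timepoint", "frequency_khz", "threshold_db")

#' Assemble a dataset bundle from tidy tables
#'
#' @param gap_table per-(mouse, timepoint, session, band) gap results.
#' @param ppi_table per-(mouse, timepoint, task, prepulse frequency) PPI
#'   summaries.
#' @param abr_table ABR thresholds (may be `NULL`).
#' @param provenance free-form provenance list.
#' @return An object of class `gpias_bundle`.
#' @export
dataset_bundle <- function(gap_table = NULL, ppi_table = NULL,
                           abr_table = NULL, provenance = list()) {
  check_tab <- function(tab, cols, keys, what) {
    if (is.null(tab)) return(NULL)
    missing <- setdiff(cols, names(tab))
    if (length(missing))
      stop_invalid(what, " is missing required columns: ",
                   paste(missing, collapse = ", "))
    key <- do.call(paste, tab[keys])
    if (anyDuplicated(key))
      stop_invalid(what, " has duplicate keys, e.g. ",
                   key[anyDuplicated(key)][1])
    tab
  }
  structure(list(
    gap_table = check_tab(gap_table, GAP_COLS,
                          c("mouse_id", "timepoint", "session", "band"),
                          "gap_table"),
    ppi_table = check_tab(ppi_table, PPI_COLS,
                          c("mouse_id", "timepoint", "task", "prepulse_khz"),
                          "ppi_table"),
    abr_table = check_tab(abr_table, ABR_COLS,
                          c("mouse_id", "timepoint", "frequency_khz"),
                          "abr_table"),
    provenance = provenance
  ), class = "gpias_bundle")
}

#' @export
print.gpias_bundle <- function(x, ...) {
  nr <- function(t) if (is.null(t)) "absent" else paste0(nrow(t), " rows")
  cat("gpias_bundle: gap", nr(x$gap_table), "| ppi", nr(x$ppi_table),
      "| abr", nr(x$abr_table), "\n")
  invisible(x)
}

#' Serialise a simulated cohort to tidy session-level tables
#'
#' Applies the movement-artifact exclusion rule to every session, then
#' reduces gap sessions to per-band SA/GA means and percent inhibition
#' and FD sessions to per-frequency ASR summaries and PPI.
#'
#' @param cohort a `gpias_cohort`.
#' @param exclusion apply [apply_exclusion_rule()] first (default TRUE).
#' @return A `gpias_bundle`.
#' @export
cohort_to_bundle <- function(cohort, exclusion = TRUE) {
  groups <- stats::setNames(vapply(cohort$mice, `[[`, character(1), "group"),
                            vapply(cohort$mice, `[[`, character(1), "mouse_id"))
  gap_rows <- list(); ppi_rows <- list()
  for (s in cohort$sessions) {
    ses <- if (exclusion) apply_exclusion_rule(s) else s
    idx <- if (is.null(ses$session_index)) 1L else ses$session_index
    if (ses$task == "GAP") {
      tab <- compute_gap_inhibition(ses)
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        mouse_id = ses$mouse_id, group = groups[[ses$mouse_id]],
        timepoint = ses$timepoint, session = idx,
        band = tab$band, mean_sa = tab$mean_sa, mean_ga = tab$mean_ga,
        n_sa = tab$n_sa, n_ga = tab$n_ga,
        inhibition_pct = tab$inhibition_pct, stringsAsFactors = FALSE)
    } else {
      tab <- compute_ppi(ses)
      ppi_rows[[length(ppi_rows) + 1L]] <- data.frame(
        mouse_id = ses$mouse_id, group = groups[[ses$mouse_id]],
        timepoint = ses$timepoint, task = ses$task,
        prepulse_khz = tab$prepulse_khz, delta_f_pct = tab$delta_f_pct,
        mean_asr = tab$mean_asr, sd_asr = tab$sd_asr, n = tab$n,
        ppi_pct = tab$ppi_pct, stringsAsFactors = FALSE)
    }
  }
  sort_tab <- function(t, keys) {
    if (length(t) == 0L) return(NULL)
    t <- do.call(rbind, t)
    t[do.call(order, t[keys]), , drop = FALSE]
  }
  gap <- sort_tab(gap_rows, c("mouse_id", "timepoint", "session", "band"))
  ppi <- sort_tab(ppi_rows, c("mouse_id", "timepoint", "task", "prepulse_khz"))
  if (!is.null(gap)) rownames(gap) <- NULL
  if (!is.null(ppi)) rownames(ppi) <- NULL
  abr <- cohort$abr
  abr <- abr[order(abr$mouse_id, abr$timepoint, abr$frequency_khz), ]
  rownames(abr) <- NULL
  dataset_bundle(gap, ppi, abr,
                 provenance = list(source = "simulate_cohort",
                                   seed = cohort$seed))
}

#' Write a dataset bundle to disk
#'
#' The `csv-dir` dialect writes `gap.csv`, `ppi.csv`, `abr.csv` and a
#' `meta.json` provenance sidecar into `path`, with deterministic column
#' order and row sort so identical bundles produce byte-identical files.
#'
#' @param bundle a `gpias_bundle`.
#' @param path output directory.
#' @param format only `"csv-dir"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(bundle, path, format = "csv-dir") {
  stopifnot(inherits(bundle, "gpias_bundle"))
  if (format != "csv-dir")
    stop_invalid("only the csv-dir dialect is writable")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tab, cols, file) {
    if (is.null(tab)) tab <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    extra <- setdiff(names(tab), cols)
    utils::write.csv(tab[c(cols, extra)], file.path(path, file),
                     row.names = FALSE)
  }
  wr(bundle$gap_table, GAP_COLS, "gap.csv")
  wr(bundle$ppi_table, PPI_COLS, "ppi.csv")
  wr(bundle$abr_table, ABR_COLS, "abr.csv")
  prov <- bundle$provenance
  prov$parser_version <- as.character(utils::packageVersion("gpias"))
  jsonlite::write_json(prov, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset bundle
#'
#' Reads either the package's CSV-directory dialect or a three-sheet
#' XLSX workbook (sheet 1 gap detection, sheet 2 prepulse inhibition,
#' sheet 3 ABR thresholds; requires the readxl package).  Column names
#' can be adapted to the canonical schema through `column_map`, so
#' external files can be ingested without code changes.  Missing
#' optional tables yield a partial bundle with a warning.
#'
#' @param path directory (`csv-dir`) or `.xlsx` file (`xlsx-3sheet`).
#' @param format dataset dialect.
#' @param column_map optional named list per table (`gap`, `ppi`, `abr`)
#'   mapping source column names to canonical ones.
#' @return A `gpias_bundle`.
#' @export
read_dataset <- function(path, format = c("csv-dir", "xlsx-3sheet"),
                         column_map = NULL) {
  format <- match.arg(format)
  remap <- function(tab, which) {
    if (is.null(tab)) return(NULL)
    cm <- column_map[[which]]
    if (!is.null(cm))
      names(tab)[match(names(cm), names(tab))] <- unlist(cm)
    tab
  }
  if (format == "csv-dir") {
    if (!dir.exists(path)) stop_invalid("no such dataset directory: ", path)
    rd <- function(file, what) {
      f <- file.path(path, file)
      if (!file.exists(f)) {
        warning("dataset has no ", what, " table (", file, " missing)")
        return(NULL)
      }
      tab <- utils::read.csv(f, stringsAsFactors = FALSE)
      if (nrow(tab) == 0L) NULL else tab
    }
    gap <- remap(rd("gap.csv", "gap"), "gap")
    ppi <- remap(rd("ppi.csv", "ppi"), "ppi")
    abr <- remap(rd("abr.csv", "abr"), "abr")
    prov <- list(source = normalizePath(path))
    mf <- file.path(path, "meta.json")
    if (file.exists(mf)) prov <- utils::modifyList(
      jsonlite::read_json(mf, simplifyVector = TRUE), prov)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_invalid("reading xlsx requires the readxl package")
    if (!file.exists(path)) stop_invalid("no such file: ", path)
    sheets <- readxl::excel_sheets(path)
    rd <- function(i, what) {
      if (length(sheets) < i) {
        warning("workbook has no ", what, " sheet")
        return(NULL)
      }
      as.data.frame(readxl::read_excel(path, sheet = i))
    }
    gap <- remap(rd(1, "gap"), "gap")
    ppi <- remap(rd(2, "ppi"), "ppi")
    abr <- remap(rd(3, "abr"), "abr")
    prov <- list(source = normalizePath(path))
  }
  dataset_bundle(gap, ppi, abr, provenance = prov)
}

## ---- pipeline -----------------------------------------------------------

classify_bundle <- function(bundle, alpha = 0.05) {
  gap <- bundle$gap_table
  exposed <- sort(unique(gap$mouse_id[gap$group == "EXPOSED"]))
  rows <- lapply(exposed, function(id) {
    b <- gap[gap$mouse_id == id & gap$timepoint == "baseline",
             c("band", "session", "inhibition_pct")]
    w <- gap[gap$mouse_id == id & gap$timepoint == "week4",
             c("band", "session", "inhibition_pct")]
    call <- classify_tinnitus(b, w, alpha = alpha)
    data.frame(mouse_id = id, label = call$label,
               t_statistic = call$t_statistic, p_value = call$p_value,
               n_pairs = call$n_pairs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Group-pooled PPI points for one (task, timepoint): per prepulse
## frequency, mean and SD of the per-mouse mean ASR.
pooled_ppi_points <- function(ppi, task, timepoint, mouse_ids) {
  sub <- ppi[ppi$task == task & ppi$timepoint == timepoint &
               ppi$mouse_id %in% mouse_ids, ]
  if (nrow(sub) == 0L) return(NULL)
  agg_m <- tapply(sub$mean_asr, sub$delta_f_pct, mean)
  agg_s <- tapply(sub$mean_asr, sub$delta_f_pct, stats::sd)
  agg_n <- tapply(sub$mean_asr, sub$delta_f_pct, length)
  dfp <- as.numeric(names(agg_m))
  agg_s[is.na(agg_s)] <- 0
  ppi_points(dfp, as.numeric(agg_m), as.numeric(agg_s),
             as.integer(agg_n))
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a dataset, then runs every analysis stage:
#' per-band gap inhibition, Tinnitus(+)/(-) classification of exposed
#' mice, the two-way repeated-measures ANOVA (timepoint x band) per
#' classified group, per-group psychometric fits and parametric-bootstrap
#' threshold comparisons per task and post timepoint, and ABR paired
#' comparisons.  Tidy CSV outputs, a JSON run log and a summary are
#' written under `out_dir`.
#'
#' @param config a [cohort_config()] (used when `dataset` is `NULL`).
#' @param dataset optional path to an existing dataset (`csv-dir`).
#' @param seed integer seed for simulation and bootstrap.
#' @param out_dir output directory.
#' @param n_boot bootstrap draws per threshold distribution.
#' @param alpha classification significance level.
#' @return Invisibly, a list with `bundle`, `classification`, `anova`,
#'   `fd_comparisons`, `abr`, `out_dir`.
#' @export
run_pipeline <- function(config = cohort_config(), dataset = NULL, seed = 1L,
                         out_dir, n_boot = 1000L, alpha = 0.05) {
  log <- list(seed = seed, started = "run")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bundle <- stage("ingest", {
    if (is.null(dataset)) cohort_to_bundle(simulate_cohort(config, seed))
    else read_dataset(dataset)
  })
  cls <- stage("classify", classify_bundle(bundle, alpha = alpha))
  gap <- bundle$gap_table
  ## per-mouse x timepoint x band means across sessions -> RM-ANOVA
  agg <- stats::aggregate(inhibition_pct ~ mouse_id + timepoint + band,
                          data = gap, FUN = mean)
  group_of <- function(ids) cls$label[match(ids, cls$mouse_id)]
  anovas <- stage("rm-anova", {
    out <- list()
    groups <- list(
      CONTROL = unique(gap$mouse_id[gap$group == "CONTROL"]),
      TINNITUS_POS = cls$mouse_id[cls$label == "TINNITUS_POS"],
      TINNITUS_NEG = cls$mouse_id[cls$label == "TINNITUS_NEG"])
    for (g in names(groups)) {
      ids <- groups[[g]]
      if (length(ids) >= 2L)
        out[[g]] <- rm_anova_two_way(agg[agg$mouse_id %in% ids, ],
                                     "inhibition_pct", "mouse_id",
                                     c("timepoint", "band"))
    }
    out
  })
  fd_cmp <- NULL
  if (!is.null(bundle$ppi_table)) {
    fd_cmp <- stage("fd-bootstrap", {
      ppi <- bundle$ppi_table
      cls_groups <- list(
        CONTROL = unique(ppi$mouse_id[ppi$group == "CONTROL"]),
        TINNITUS_POS = cls$mouse_id[cls$label == "TINNITUS_POS"],
        TINNITUS_NEG = cls$mouse_id[cls$label == "TINNITUS_NEG"])
      tps <- setdiff(unique(ppi$timepoint), "baseline")
      seeds <- derive_seeds(seed + 2L, 2L * length(cls_groups) *
                              (length(tps) + 1L) + 10L)
      si <- 0L
      rows <- list()
      for (task in sort(unique(ppi$task))) for (g in names(cls_groups)) {
        ids <- cls_groups[[g]]
        if (length(ids) == 0L) next
        base_pts <- pooled_ppi_points(ppi, task, "baseline", ids)
        if (is.null(base_pts)) next
        si <- si + 1L
        base_boot <- bootstrap_thresholds(base_pts, n_boot, seeds[si])
        for (tp in tps) {
          pts <- pooled_ppi_points(ppi, task, tp, ids)
          if (is.null(pts)) next
          si <- si + 1L
          boot <- bootstrap_thresholds(pts, n_boot, seeds[si])
          cmpr <- compare_threshold_to_baseline(base_boot, boot)
          rows[[length(rows) + 1L]] <- data.frame(
            task = task, group = g, timepoint = tp,
            th_baseline = cmpr$th_baseline_mean,
            th_baseline_sd = cmpr$th_baseline_sd,
            th_post = cmpr$th_post_mean,
            significant = cmpr$significant,
            unreliable = cmpr$unreliable, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }
  abr_cmp <- NULL
  if (!is.null(bundle$abr_table)) {
    abr_cmp <- stage("abr", {
      tps <- setdiff(unique(bundle$abr_table$timepoint), "baseline")
      do.call(rbind, lapply(tps, function(tp)
        cbind(timepoint = tp,
              compare_abr(bundle$abr_table, "baseline", tp))))
    })
  }
  stage("report", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(bundle, file.path(out_dir, "dataset"))
    utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    if (!is.null(fd_cmp))
      utils::write.csv(fd_cmp, file.path(out_dir, "fd_threshold_comparisons.csv"),
                       row.names = FALSE)
    if (!is.null(abr_cmp))
      utils::write.csv(abr_cmp, file.path(out_dir, "abr_comparisons.csv"),
                       row.names = FALSE)
    for (g in names(anovas))
      utils::write.csv(as.data.frame(anovas[[g]]),
                       file.path(out_dir, paste0("anova_", tolower(g), ".csv")),
                       row.names = FALSE)
    summary <- list(
      seed = seed,
      n_mice = length(unique(c(gap$mouse_id))),
      n_exposed = nrow(cls),
      n_tinnitus_pos = sum(cls$label == "TINNITUS_POS"),
      n_tinnitus_neg = sum(cls$label == "TINNITUS_NEG"),
      anova_effects = lapply(anovas, function(a)
        stats::setNames(as.list(a$f_statistic), a$effect)),
      fd_significant = if (!is.null(fd_cmp))
        fd_cmp[fd_cmp$significant, c("task", "group", "timepoint")])
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(list(bundle = bundle, classification = cls, anova = anovas,
                 fd_comparisons = fd_cmp, abr = abr_cmp, out_dir = out_dir))
}
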