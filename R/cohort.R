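#' Run the full per-animal pipeline
#'
#' Deterministic composition segment -> QC -> summarize on one trace; all
#' intermediates are returned so they can be written to disk.
#'
#' @param trace a `breath_trace`.
#' @param seg_params a [segmentation_params()].
#' @param qc_cfg a [qc_config()].
#' @return a list with `table` (flagged breath table), `reliable`,
#'   `report` (the `qc_report`), and `summary` (the `animal_summary`).
#' @export
run_pipeline <- function(trace, seg_params = segmentation_params(),
                         qc_cfg = qc_config()) {
  table <- segment_breaths(trace, seg_params)
  qc <- apply_qc(table, qc_cfg)
  summary <- summarize_animal(qc$reliable, qc$report)
  list(table = qc$flagged, reliable = qc$reliable, report = qc$report,
       summary = summary)
}

#' Read a cohort metadata table
#'
#' Tab-separated text with columns `animal_id`, `genotype`, `age_group`,
#' `trace_path`. Relative trace paths are resolved against the metadata
#' file's directory.
#'
#' @param path metadata TSV path.
#' @return a data frame with resolved `trace_path`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop("ingestion error: metadata file not found: ", path, call. = FALSE)
  }
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "genotype", "age_group", "trace_path")
  missing <- setdiff(need, names(md))
  if (length(missing)) {
    stop("ingestion error: metadata lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$animal_id)) {
    stop("ingestion error: duplicate animal_id in metadata", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", md$trace_path)
  md$trace_path[rel] <- file.path(dirname(path), md$trace_path[rel])
  md
}

#' Build a cohort table from metadata and trace files
#'
#' Runs [run_pipeline()] for every animal in the metadata table and binds
#' the per-animal summaries with genotype and age-group labels. Excluded
#' animals are retained in the table (with `animal_excluded = TRUE` and
#' missing metrics) but contribute to no downstream statistic.
#'
#' @param metadata data frame from [read_metadata()], or a list of
#'   simulated animals from [simulate_cohort()] (genotype labels are taken
#'   from the presets and `age_group` is set to `"simulated"`).
#' @param seg_params,qc_cfg pipeline settings.
#' @param invert passed to [read_trace_file()] for file-based cohorts.
#' @return a `cohort_table` data frame: one row per animal with columns
#'   `animal_id`, `genotype`, `age_group` plus the `animal_summary`
#'   columns.
#' @export
build_cohort <- function(metadata, seg_params = segmentation_params(),
                         qc_cfg = qc_config(), invert = FALSE) {
  if (is.data.frame(metadata)) {
    rows <- lapply(seq_len(nrow(metadata)), function(i) {
      trace <- read_trace_file(metadata$trace_path[i], invert = invert,
                               animal_id = metadata$animal_id[i])
      res <- run_pipeline(trace, seg_params, qc_cfg)
      cbind(metadata[i, c("animal_id", "genotype", "age_group")],
            res$summary[, -1L], row.names = NULL)
    })
  } else {
    rows <- lapply(metadata, function(an) {
      res <- run_pipeline(an$trace, seg_params, qc_cfg)
      cbind(data.frame(animal_id = an$animal_id, genotype = an$genotype,
                       age_group = "simulated", stringsAsFactors = FALSE),
            res$summary[, -1L], row.names = NULL)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' One-way ANOVA across genotype groups
#'
#' Compares one respiratory metric across the genotype groups of a cohort
#' with a one-way fixed-effects ANOVA. Excluded animals never enter the
#' statistic. The conventional 0.05 significance threshold is reported for
#' context only; no filtering is keyed to it, and no multiple-testing
#' correction is applied across metrics.
#'
#' @param cohort a `cohort_table` from [build_cohort()].
#' @param metric one of `"frequency"`, `"tidal_volume"`,
#'   `"minute_ventilation"`, `"ibii_mean"`.
#' @return a list of class `group_comparison`: `metric`, `groups` (data
#'   frame of n, mean, sem per group), `df_between`, `df_within`,
#'   `f_statistic`, `p_value`, `alpha = 0.05`.
#' @export
compare_groups <- function(cohort, metric = "minute_ventilation") {
  metric <- match.arg(metric, c("frequency", "tidal_volume",
                                "minute_ventilation", "ibii_mean"))
  keep <- !cohort$animal_excluded & !is.na(cohort[[metric]])
  dat <- cohort[keep, , drop = FALSE]
  sizes <- table(dat$genotype)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("insufficient group sizes for ANOVA: need >= 2 groups with ",
         ">= 2 non-excluded animals each (got ",
         paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "),
         ")", call. = FALSE)
  }
  y <- dat[[metric]]
  g <- factor(dat$genotype)
  fit <- stats::lm(y ~ g)
  # near-zero within-group variance triggers R's "essentially perfect fit"
  # warning; the F and p limits are still the ones we want to report
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  groups <- do.call(rbind, lapply(split(y, g), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  groups <- cbind(data.frame(group = rownames(groups),
                             stringsAsFactors = FALSE), groups)
  rownames(groups) <- NULL
  structure(list(metric = metric, groups = groups,
                 df_between = an$Df[1L], df_within = an$Df[2L],
                 f_statistic = an$`F value`[1L],
                 p_value = an$`Pr(>F)`[1L],
                 alpha = 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on %s\n", x$metric))
  print(x$groups, row.names = FALSE)
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g (alpha = %.2f)\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value, x$alpha))
  invisible(x)
}

# Parse the package's plain-text key-value config format: one `key = value`
# per line, `#` comments; values are numeric when they parse as numbers.
# Dotted keys (artifact_rates.sniff_burst) populate nested lists.
parse_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) {
      stop("config error: cannot parse line: ", ln, call. = FALSE)
    }
    key <- trimws(kv[1L])
    raw <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(raw))
    val <- if (!is.na(num)) num else raw
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) {
      out[[key]] <- val
    } else {
      sub_list <- out[[parts[1L]]]
      if (is.null(sub_list)) sub_list <- list()
      sub_list[[parts[2L]]] <- val
      out[[parts[1L]]] <- sub_list
    }
  }
  out
}
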