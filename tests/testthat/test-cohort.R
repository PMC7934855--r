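test_that("trace files round-trip through write/read", {
  sim <- simulate_trace(quick_config(duration = 5, seed = 2), "a1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_file(sim$trace, path)
  back <- read_trace_file(path, animal_id = "a1")
  expect_equal(back$samples, sim$trace$samples, tolerance = 1e-12)
  expect_equal(back$sampling_rate, sim$trace$sampling_rate, tolerance = 1e-9)
  expect_identical(back$animal_id, "a1")
})

test_that("ingestion rejects gaps, non-monotone time and junk", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 1, by = 0.001)
  df <- data.frame(time_s = t, flow_ml_s = sin(2 * pi * 5 * t))
  gap <- df
  gap$time_s[600:nrow(gap)] <- gap$time_s[600:nrow(gap)] + 0.01 # 10x step
  utils::write.csv(gap, path, row.names = FALSE)
  expect_error(read_trace_file(path), "gap.*599", perl = TRUE)

  rev_t <- df
  rev_t$time_s[100] <- rev_t$time_s[98]
  utils::write.csv(rev_t, path, row.names = FALSE)
  expect_error(read_trace_file(path), "non-monotone")

  writeLines(c("time_s,flow_ml_s", "0,0.1", "0.001,abc"), path)
  expect_error(read_trace_file(path), "ingestion error")
})

test_that("mild sampling jitter is resampled onto the median step", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(9)
  t <- seq(0, 1, by = 0.001) + c(0, runif(1000, 0, 2e-4))
  utils::write.csv(data.frame(time_s = t, flow_ml_s = sin(2 * pi * t)),
                   path, row.names = FALSE)
  expect_warning(tr <- read_trace_file(path), "resampling")
  expect_equal(tr$sampling_rate, 1000, tolerance = 0.01)
})

test_that("polarity inversion swaps inspiratory and expiratory volumes", {
  cfg <- sim_config(duration = 20, irregularity = 0, insp_fraction = 0.5,
                    seed = 7)
  sim <- simulate_trace(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_file(sim$trace, path)
  fwd <- segment_breaths(read_trace_file(path))
  inv <- segment_breaths(read_trace_file(path, invert = TRUE))
  n <- min(nrow(fwd), nrow(inv))
  expect_gt(n, 10)
  # symmetric breaths: inverted ingestion reproduces the same volumes with
  # the roles of the two phases exchanged
  expect_equal(mean(fwd$vti_ml[2:n]), mean(inv$vte_ml[2:n]),
               tolerance = 1e-3)
  expect_equal(mean(fwd$vte_ml[2:n]), mean(inv$vti_ml[2:n]),
               tolerance = 1e-3)
})

test_that("run_pipeline composes deterministically and handles silence", {
  sim <- simulate_trace(sim_config(duration = 60, irregularity = 0.1,
                                   seed = 14))
  a <- run_pipeline(sim$trace)
  b <- run_pipeline(sim$trace)
  expect_identical(a$summary, b$summary)
  expect_false(a$summary$animal_excluded)

  silent <- breath_trace(numeric(5000), 1000)
  suppressWarnings(res <- run_pipeline(silent))
  expect_identical(nrow(res$table), 0L)
  expect_true(res$summary$animal_excluded)
})

test_that("breath tables round-trip as TSV", {
  sim <- simulate_trace(quick_config(duration = 10, seed = 5))
  tab <- segment_breaths(sim$trace)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_breath_table(tab, path)
  back <- read_breath_table(path, animal_id = "sim", sampling_rate = 1000)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-10)
})

test_that("ANOVA matches hand-computed sums of squares to 1e-10", {
  # independent oracle: textbook one-way decomposition on a 3-group table
  y <- c(5.1, 4.8, 5.5, 6.0, 7.2, 7.0, 6.8, 4.0, 4.4, 3.9, 4.1)
  g <- rep(c("A", "B", "C"), c(4, 3, 4))
  cohort <- data.frame(animal_id = paste0("m", seq_along(y)), genotype = g,
                       age_group = "x", minute_ventilation = y,
                       animal_excluded = FALSE)
  cmp <- compare_groups(cohort, "minute_ventilation")

  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_b <- 3L - 1L
  df_w <- length(y) - 3L
  f_oracle <- (ss_between / df_b) / (ss_within / df_w)
  p_oracle <- stats::pf(f_oracle, df_b, df_w, lower.tail = FALSE)

  expect_equal(cmp$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-10)
  expect_identical(cmp$df_between, df_b)
  expect_identical(cmp$df_within, df_w)
  expect_equal(cmp$groups$mean, as.numeric(means[cmp$groups$group]))
})

test_that("zero within-group variance drives F large and p to zero", {
  cohort <- data.frame(animal_id = paste0("m", 1:6),
                       genotype = rep(c("A", "B"), each = 3),
                       age_group = "x",
                       minute_ventilation = rep(c(10, 20), each = 3) +
                         c(0, 1e-9, -1e-9),
                       animal_excluded = FALSE)
  cmp <- compare_groups(cohort, "minute_ventilation")
  expect_gt(cmp$f_statistic, 1e10)
  expect_lt(cmp$p_value, 1e-10)
})

test_that("excluded animals never influence the comparison", {
  set.seed(8)
  cohort <- data.frame(animal_id = paste0("m", 1:11),
                       genotype = rep(c("A", "B"), c(5, 6)),
                       age_group = "x",
                       frequency = c(rnorm(5, 250, 10), rnorm(6, 300, 10)),
                       animal_excluded = c(rep(FALSE, 10), TRUE))
  base <- compare_groups(cohort, "frequency")
  mutated <- cohort
  mutated$frequency[11] <- 1e6 # perturb the excluded animal only
  expect_identical(compare_groups(mutated, "frequency")[c("f_statistic",
                                                          "p_value",
                                                          "groups")],
                   base[c("f_statistic", "p_value", "groups")])
  expect_identical(base$groups$n, c(5L, 5L))
})

test_that("insufficient groups raise an explicit error", {
  cohort <- data.frame(animal_id = c("a", "b", "c"),
                       genotype = c("A", "A", "B"), age_group = "x",
                       frequency = c(1, 2, 3), animal_excluded = FALSE)
  expect_error(compare_groups(cohort, "frequency"), "insufficient group sizes")
})

test_that("file-based cohorts run end to end with genotype separation", {
  dir <- withr::local_tempdir()
  coh <- simulate_cohort(list(WT = 2, SCA1_late = 2),
                         sim_config(duration = 90), seed = 4)
  md <- data.frame(animal_id = names(coh),
                   genotype = sapply(coh, `[[`, "genotype"),
                   age_group = "late",
                   trace_path = paste0(names(coh), ".csv"))
  for (an in coh) {
    write_trace_file(an$trace, file.path(dir, paste0(an$animal_id, ".csv")))
  }
  utils::write.table(md, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cohort <- build_cohort(read_metadata(file.path(dir, "meta.tsv")))
  expect_identical(nrow(cohort), 4L)
  expect_false(any(cohort$animal_excluded))
  wt <- cohort$tidal_volume[cohort$genotype == "WT"]
  sca <- cohort$tidal_volume[cohort$genotype == "SCA1_late"]
  expect_gt(mean(wt), mean(sca))
})

test_that("the CLI drives simulate, segment, qc and summarize", {
  dir <- withr::local_tempdir()
  code <- breathkit_cli(c("simulate", "--preset", "WT", "--n", "1",
                          "--duration", "30", "--seed", "5",
                          "--out-dir", dir))
  expect_identical(code, 0L)
  trace_file <- file.path(dir, "WT_01.csv")
  expect_true(file.exists(trace_file))
  expect_true(file.exists(file.path(dir, "WT_01_truth.tsv")))

  breaths <- file.path(dir, "breaths.tsv")
  expect_identical(breathkit_cli(c("segment", "--in", trace_file,
                                   "--out", breaths)), 0L)
  flagged <- file.path(dir, "flagged.tsv")
  report <- file.path(dir, "qc.txt")
  expect_identical(breathkit_cli(c("qc", "--in", breaths, "--out", flagged,
                                   "--report", report)), 0L)
  expect_true(any(grepl("^n_reliable", readLines(report))))
  summary_file <- file.path(dir, "summary.tsv")
  expect_identical(breathkit_cli(c("summarize", "--in", flagged,
                                   "--out", summary_file)), 0L)
  s <- utils::read.delim(summary_file)
  expect_false(s$animal_excluded)
  expect_equal(s$minute_ventilation, s$frequency * s$tidal_volume,
               tolerance = 1e-9)

  expect_identical(
    suppressMessages(breathkit_cli(c("segment", "--in",
                                     file.path(dir, "nope.csv"),
                                     "--out", breaths))), 2L)
  expect_identical(suppressMessages(breathkit_cli("frobnicate")), 2L)
})

test_that("the cohort CLI writes summaries and comparisons", {
  dir <- withr::local_tempdir()
  for (p in c("WT", "SCA1_late")) {
    breathkit_cli(c("simulate", "--preset", p, "--n", "2", "--duration",
                    "60", "--seed", "6", "--out-dir", dir))
  }
  md <- rbind(utils::read.delim(file.path(dir, "metadata.tsv")))
  # merge the two per-preset metadata files (second overwrote the first)
  md <- data.frame(animal_id = c("WT_01", "WT_02", "SCA1_late_01",
                                 "SCA1_late_02"),
                   genotype = rep(c("WT", "SCA1_late"), each = 2),
                   age_group = "sim",
                   trace_path = c("WT_01.csv", "WT_02.csv",
                                  "SCA1_late_01.csv", "SCA1_late_02.csv"))
  utils::write.table(md, file.path(dir, "meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  out <- file.path(dir, "out")
  expect_identical(breathkit_cli(c("cohort", "--metadata",
                                   file.path(dir, "meta.tsv"),
                                   "--out-dir", out)), 0L)
  expect_true(file.exists(file.path(out, "cohort_summary.tsv")))
  expect_true(file.exists(file.path(out, "group_comparisons.tsv")))
  cmp <- utils::read.delim(file.path(out, "group_comparisons.tsv"))
  expect_true("minute_ventilation" %in% cmp$metric)
})

test_that("key-value config files parse into nested settings", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# simulator overrides", "base_rate = 300",
               "artifact_rates.sniff_burst = 0.5",
               "irregularity = 0.2"), path)
  cfg <- breathkit:::parse_config_file(path)
  expect_equal(cfg$base_rate, 300)
  expect_equal(cfg$artifact_rates$sniff_burst, 0.5)
  writeLines("this is not a key value line", path)
  expect_error(breathkit:::parse_config_file(path), "config error")
})
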