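#' Default run configuration
#'
#' One structured object drives the end-to-end `report` pipeline; it
#' round-trips losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param seed top-level seed; every stage derives its own sub-seed via
#'   [stage_seed()].
#' @param n_samples cohort size.
#' @param panel_size SNP panel size for the engine demonstration samples.
#' @param n_engine_samples number of samples scored end-to-end through the
#'   SNP-level engine (the cohort association stages use the generator's
#'   cohort table directly).
#' @param engine_purity,engine_depth purity and mean depth of the simulated
#'   engine samples.
#' @param cutoffs gLOH-high cutoffs to tabulate; the derived inflection
#'   cutoff is always added.
#' @param q_threshold,prevalence_threshold univariate screen candidate
#'   filter.
#' @param hr_genes HR-pathway gene list.
#' @param uterine_fraction,gloh_mean,gloh_sd cohort generator targets.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_samples = 1658L, panel_size = 3500L,
                       n_engine_samples = 2L, engine_purity = 0.7,
                       engine_depth = 250, cutoffs = c(14, 16),
                       q_threshold = 0.1, prevalence_threshold = 0.005,
                       hr_genes = default_hr_genes(),
                       uterine_fraction = 0.393, gloh_mean = 12.9,
                       gloh_sd = 6.9) {
  cfg <- structure(list(seed = as.integer(seed),
                        n_samples = as.integer(n_samples),
                        panel_size = as.integer(panel_size),
                        n_engine_samples = as.integer(n_engine_samples),
                        engine_purity = engine_purity,
                        engine_depth = engine_depth,
                        cutoffs = cutoffs, q_threshold = q_threshold,
                        prevalence_threshold = prevalence_threshold,
                        hr_genes = hr_genes,
                        uterine_fraction = uterine_fraction,
                        gloh_mean = gloh_mean, gloh_sd = gloh_sd),
                   class = "run_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_samples < 1L) stop_invalid("n_samples must be >= 1")
  if (cfg$panel_size < 22L) stop_invalid("panel_size must be >= 22")
  if (cfg$engine_purity <= 0 || cfg$engine_purity > 1)
    stop_invalid("engine_purity must be in (0, 1]")
  if (cfg$q_threshold <= 0 || cfg$q_threshold > 1)
    stop_invalid("q_threshold must be in (0, 1]")
  if (cfg$prevalence_threshold < 0 || cfg$prevalence_threshold > 1)
    stop_invalid("prevalence_threshold must be in [0, 1]")
  invisible(cfg)
}

#' Write / read a run configuration as JSON
#' @param cfg a `run_config`.
#' @param path JSON path.
#' @return the path (writer) or the configuration (reader).
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(run_config()), raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_samples <- as.integer(cfg$n_samples)
  cfg$panel_size <- as.integer(cfg$panel_size)
  cfg$n_engine_samples <- as.integer(cfg$n_engine_samples)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full synthetic pipeline and write a report bundle
#'
#' Chains simulate -> gLOH engine (on a few SNP-level samples) -> cohort
#' description -> association screens -> survival into one reproducible run
#' under a single seed, writing every artifact plus a manifest with file
#' checksums and per-stage wall-clock times.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_report <- function(config = run_config(), outdir) {
  validate_config(config)
  if (missing(outdir)) stop_invalid("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    on.exit(timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3))
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            "lohscape_error_stage", stage = name)
    })
  }
  out <- function(f) { p <- file.path(outdir, f); files <<- c(files, p); p }

  cfg_path <- out("config.json")
  write_config(config, cfg_path)

  cohort <- stage("simulate", {
    spec <- cohort_spec(n_samples = config$n_samples,
                        uterine_fraction = config$uterine_fraction,
                        gloh_mean = config$gloh_mean,
                        gloh_sd = config$gloh_sd,
                        seed = stage_seed(config$seed, "simulate"))
    co <- simulate_cohort(spec)
    write_cohort_tsv(co, out("cohort.tsv"))
    write_alteration_table(co, out("alterations.tsv"))
    co
  })

  engine <- stage("gloh", {
    genome <- default_genome()
    panel <- make_snp_panel(genome, config$panel_size,
                            seed = stage_seed(config$seed, "gloh"))
    runs <- lapply(seq_len(config$n_engine_samples), function(i) {
      sd_i <- stage_seed(config$seed, "gloh") + i
      planted <- plant_segments(genome, target_gloh = c(10, 25, 40)[
        (i - 1) %% 3 + 1], seed = sd_i)
      sm <- simulate_sample(genome, panel, planted,
                            purity = config$engine_purity,
                            depth_mean = config$engine_depth, seed = sd_i)
      r <- run_gloh(sm$snp_obs, genome,
                    sample_id = sprintf("ENG-%02d", i))
      write_seg(r$profile$segments, out(sprintf("segments_ENG-%02d.seg.tsv", i)),
                r$sample_id)
      list(sample = r$sample_id, gloh_true = sm$gloh_true,
           gloh_est = if (!is.null(r$result)) r$result$percent_gloh else NA,
           purity_true = sm$purity, purity_est = r$profile$purity,
           qc = r$profile$qc_reason)
    })
    json_out(runs, out("gloh_engine.json"))
    runs
  })

  described <- stage("cohort", {
    gloh <- cohort$samples$gloh
    infl <- find_inflection_point(gloh)
    cuts <- c(config$cutoffs, inflection = infl$cutoff_percent)
    cls <- lapply(seq_along(cuts), function(i) {
      cl <- classify_gloh_high(gloh, cuts[i])
      data.frame(cutoff_label = names(cuts)[i] %||% "",
                 cutoff = cl$cutoff, n_high = cl$n_high,
                 n_total = cl$n_total, fraction_high = cl$fraction_high)
    })
    write_tsv(do.call(rbind, cls), out("gloh_high.tsv"))
    ds <- summarize_distribution(gloh)
    sm <- cohort$samples
    summary <- list(
      n = nrow(sm),
      sex = as.list(table(sm$sex)),
      age_mean = mean(sm$age), age_sd = stats::sd(sm$age),
      uterine_n = sum(sm$uterine),
      uterine_pct = 100 * mean(sm$uterine),
      msi = as.list(table(sm$msi)),
      tmb_mean = mean(sm$tmb), tmb_sd = stats::sd(sm$tmb),
      tmb_high_n = sum(sm$tmb >= 10),
      gloh_mean = ds$mean, gloh_sd = ds$sd,
      inflection = infl$cutoff_percent)
    json_out(summary, out("cohort_summary.json"))
    json_out(ds, out("distribution.json"))
    list(inflection = infl)
  })

  assoc <- stage("associate", {
    grp <- suppressWarnings(assign_hr_groups(cohort, config$hr_genes))
    gc <- group_contrast(cohort$samples$gloh, grp)
    json_out(list(groups = gc$groups, anova_f = gc$anova_f,
                  anova_p = gc$anova_p, comparisons = gc$comparisons),
             out("group_contrast.json"))
    scr <- univariate_screen(cohort, q_threshold = config$q_threshold,
                             prevalence_threshold = config$prevalence_threshold)
    cand <- scr$key[scr$candidate]
    tab2 <- scr[, c("key", "prevalence", "estimate", "ci_low", "ci_high",
                    "p_value", "q_value", "candidate")]
    names(tab2) <- paste0("uni_", names(tab2))
    names(tab2)[1] <- "key"
    if (length(cand)) {
      mv <- suppressWarnings(multivariate_fit(cohort, keys = cand))
      mt <- mv[match(tab2$key, mv$term), ]
      tab2$multi_estimate <- mt$estimate
      tab2$multi_ci_low <- mt$ci_low
      tab2$multi_ci_high <- mt$ci_high
      tab2$multi_p <- mt$p_value
    }
    write_tsv(tab2, out("association.tsv"))
    dp <- suppressWarnings(differential_prevalence(cohort))
    write_tsv(dp, out("prevalence.tsv"))
    tab2
  })

  surv <- stage("survive", {
    sub_n <- min(cohort$spec$survival$n, nrow(cohort$samples))
    sub <- cohort$samples[seq_len(sub_n), , drop = FALSE]
    sv <- simulate_survival(sub, cohort$spec$survival,
                            seed = stage_seed(config$seed, "survive"))
    write_tsv(sv, out("survival.tsv"))
    km <- km_estimate(sv)
    write_tsv(km, out("km_curves.tsv"))
    lr <- logrank_test(sv)
    cx <- cox_fit(sv, "group")
    json_out(list(median_gloh = stats::median(sv$gloh),
                  logrank_chisq = lr$chisq, logrank_p = lr$p_value,
                  hr = cx$terms$hr[1], ci_low = cx$terms$ci_low[1],
                  ci_high = cx$terms$ci_high[1],
                  cox_p = cx$terms$p_value[1]),
             out("survival.json"))
    NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lohscape")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    timings_sec = timings,
    checksums = as.list(tools::md5sum(sort(files))))
  json_out(manifest, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
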