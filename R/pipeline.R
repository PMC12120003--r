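#' Build a run configuration
#'
#' @param cohort Either a [cohort_params()] object (a cohort will be
#'   simulated) or a path to a cohort CSV from [write_cohort()].
#' @param out_dir Output directory; created if absent.
#' @param region_names Ordered region labels.
#' @param k_max Largest candidate model size for BIC selection (`NULL` =
#'   automatic).
#' @param n_boot_pattern Bootstrap replicates for the pattern weight CIs.
#' @param n_boot_mediation Bootstrap replicates per mediation model.
#' @param tiers Covariate tiers to run (subset of `"base"`, `"vascular"`,
#'   `"depression"`).
#' @param outcomes Outcome labels; the full set is `srt_cltr`,
#'   `tmt_b_resid`, `wais_lns`, `scwt`, `tmt_a` (simple model only) and
#'   `gpt`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_params(), out_dir = "wmhsgm_run",
                       region_names = default_region_names(),
                       k_max = NULL, n_boot_pattern = 1000L,
                       n_boot_mediation = 1000L,
                       tiers = c("base", "vascular", "depression"),
                       outcomes = c("srt_cltr", "tmt_b", "wais_lns",
                                    "scwt", "tmt_a", "gpt"),
                       seed = 1L) {
  stopifnot(all(tiers %in% c("base", "vascular", "depression")))
  structure(list(cohort = cohort, out_dir = out_dir,
                 region_names = region_names, k_max = k_max,
                 n_boot_pattern = as.integer(n_boot_pattern),
                 n_boot_mediation = as.integer(n_boot_mediation),
                 tiers = tiers, outcomes = outcomes, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognizes the fields of [run_config()]; a `cohort_params` mapping is
#' converted into a [cohort_params()] object, a `cohort_csv` string is
#' used as an input path.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- if (!is.null(raw$cohort_csv)) {
    raw$cohort_csv
  } else if (!is.null(raw$cohort_params)) {
    cp <- raw$cohort_params
    scalar_args <- cp[setdiff(names(cp), c("region_names", "region_log_means",
                                           "planted_weights", "c_direct",
                                           "d_speed", "outcome_scales"))]
    args <- scalar_args
    for (f in c("region_names", "planted_weights")) {
      if (!is.null(cp[[f]])) args[[f]] <- unlist(cp[[f]])
    }
    for (f in c("region_log_means", "c_direct", "d_speed")) {
      if (!is.null(cp[[f]])) args[[f]] <- unlist(cp[[f]])
    }
    if (!is.null(cp$outcome_scales)) {
      args$outcome_scales <- lapply(cp$outcome_scales, unlist)
    }
    do.call(cohort_params, args)
  } else {
    cohort_params()
  }
  keep <- intersect(names(raw), c("out_dir", "region_names", "k_max",
                                  "n_boot_pattern", "n_boot_mediation",
                                  "tiers", "outcomes", "seed"))
  args <- raw[keep]
  if (!is.null(args$region_names)) args$region_names <- unlist(args$region_names)
  if (!is.null(args$tiers)) args$tiers <- unlist(args$tiers)
  if (!is.null(args$outcomes)) args$outcomes <- unlist(args$outcomes)
  do.call(run_config, c(list(cohort = cohort), args))
}

# outcome label -> analysis column; set shifting is the TMT-A-residualized
# TMT-B in simple models (speed not otherwise conditioned on) but the
# log-transformed TMT-B in serial models, where log TMT-A is a mediator
outcome_column <- function(outcome, serial = FALSE) {
  switch(outcome,
         tmt_a = "log_tmt_a",
         tmt_b = if (serial) "log_tmt_b" else "tmt_b_resid",
         tmt_b_resid = "tmt_b_resid",
         gpt = "log_gpt", srt_cltr = "srt_cltr", wais_lns = "wais_lns",
         scwt = "scwt",
         stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage from a single configuration: obtain the cohort
#' (simulate or load), derive cognition variables, build and decompose the
#' double-centered log-volume matrix, select the WMH-related pattern by
#' BIC, bootstrap the regional weight CIs, and fit the mediation suite
#' (simple model for the processing-speed outcome, serial models with
#' pattern expression then log TMT-A for the others) at each covariate
#' tier. All tables are written as CSV, fit summaries as JSON, and a
#' manifest with seeds and per-file MD5 checksums closes the run.
#' Rerunning an identical configuration reproduces every numeric output
#' bit for bit.
#'
#' @param config A [run_config()] object.
#' @return The manifest, invisibly (list with `files`, `checksums`,
#'   `seed`, `k_selected`, `r2`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[wmhsgm] stage %-10s done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_params")) {
      cc <- generate_cohort(config$cohort)
      write_cohort_params(config$cohort, out("cohort_params.yaml"))
      cc
    } else {
      read_cohort(config$cohort)
    }
  })
  write_cohort(cohort, out("cohort.csv"))

  data <- stage("cognition", preprocess_cognition(cohort))

  decomp <- stage("ssm", {
    cm <- double_center(log_volume_matrix(cohort, config$region_names))
    d <- ssm_decompose(cm)
    utils::write.csv(data.frame(region = d$region_names, d$loadings,
                                check.names = FALSE),
                     out("ssm_loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(subject_id = cohort$subject_id, d$scores,
                                check.names = FALSE),
                     out("ssm_scores.csv"), row.names = FALSE)
    jsonlite::write_json(list(eigenvalues = d$eigenvalues,
                              variance_fraction = d$variance_fraction,
                              sign_convention = "largest-|loading|-positive"),
                         out("ssm_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    d
  })

  pattern <- stage("select", {
    y <- log_wmh(cohort)
    pat <- select_pattern(decomp, y, k_max = config$k_max)
    utils::write.csv(data.frame(region = names(pat$weights),
                                weight = unname(pat$weights),
                                rank = rank(-abs(pat$weights))),
                     out("pattern_weights.csv"), row.names = FALSE)
    jsonlite::write_json(list(k_selected = pat$k_selected,
                              bic_path = pat$bic_path, r2 = pat$r2,
                              adj_r2 = pat$adj_r2, f_stat = pat$f_stat,
                              df = pat$df),
                         out("pattern_fit.json"), auto_unbox = TRUE,
                         digits = NA)
    utils::write.csv(data.frame(subject_id = cohort$subject_id,
                                expression = pat$expression,
                                log_wmh = y),
                     out("expression_vs_logwmh.csv"), row.names = FALSE)
    pat
  })
  data$pattern_expression <- pattern$expression

  stage("bootstrap", {
    bw <- bootstrap_pattern(cohort, k_fixed = pattern$k_selected,
                            n_boot = config$n_boot_pattern,
                            seed = config$seed + 1L,
                            region_names = config$region_names,
                            keep_replicates = FALSE)
    utils::write.csv(as.data.frame(bw), out("bootstrap_weights.csv"),
                     row.names = FALSE)
    bw
  })

  med_files <- character(0)
  stage("mediation", {
    i <- 0L
    for (tier in config$tiers) {
      for (outcome in config$outcomes) {
        i <- i + 1L
        serial <- outcome != "tmt_a"
        ycol <- outcome_column(outcome, serial = serial)
        meds <- if (serial) c("pattern_expression", "log_tmt_a")
                else "pattern_expression"
        spec <- mediation_spec(x = "age", mediators = meds, y = ycol,
                               covariates = covariate_set(tier),
                               n_boot = config$n_boot_mediation,
                               seed = config$seed + 100L + i)
        fit <- fit_mediation(data, spec)
        tidy <- rbind(
          data.frame(model = paste(tier, outcome, sep = "/"),
                     term = fit$paths$path, kind = "path",
                     estimate = fit$paths$estimate, se = fit$paths$se,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p = fit$paths$p, n_used = fit$n_used,
                     stringsAsFactors = FALSE),
          data.frame(model = paste(tier, outcome, sep = "/"),
                     term = fit$effects$effect, kind = "effect",
                     estimate = fit$effects$estimate,
                     se = fit$effects$boot_se,
                     ci_low = fit$effects$ci_low,
                     ci_high = fit$effects$ci_high, p = NA_real_,
                     n_used = fit$n_used, stringsAsFactors = FALSE))
        f <- out(sprintf("mediation_%s_%s.csv", tier, outcome))
        utils::write.csv(tidy, f, row.names = FALSE)
        med_files <- c(med_files, basename(f))
      }
    }
  })

  files <- c("cohort.csv", "ssm_loadings.csv", "ssm_scores.csv",
             "ssm_summary.json", "pattern_weights.csv", "pattern_fit.json",
             "expression_vs_logwmh.csv", "bootstrap_weights.csv", med_files)
  manifest <- list(package_version = as.character(utils::packageVersion("wmhsgm")),
                   seed = config$seed, tiers = config$tiers,
                   outcomes = config$outcomes,
                   k_selected = pattern$k_selected, r2 = pattern$r2,
                   files = files,
                   checksums = as.list(tools::md5sum(file.path(config$out_dir,
                                                               files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
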