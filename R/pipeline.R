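# End-to-end driver: simulation (or user cohort files) -> per-cohort
# associations -> pooling -> meta-regression -> multivariate pooling -> IV
# ratios and F statistics -> optional summary-statistic replication -> power
# grid.  Every number written to the report tables is produced by the stage
# functions; the driver only sequences them, logs decisions and hashes the
# outputs so a rerun can be checked for byte-identity.

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; drives the simulation and any other randomness.
#' @param specs List of [cohort_spec()] (default the bundled 21-cohort
#'   template); ignored when `cohort_files` is given.
#' @param truth A [true_model()] for simulation.
#' @param panel An `snp_panel`, or `NULL` to build the default panel from
#'   `seed`.
#' @param cohort_files Optional character vector of cohort TSV paths to
#'   analyse instead of simulating.
#' @param alpha_het Heterogeneity threshold for fixed/random selection.
#' @param metareg Logical: run study-level meta-regressions.
#' @param power_grid `data.frame` with columns `effect, n, instrument_r2,
#'   reps` (or `NULL` to skip the power stage).
#' @param summary_stats Optional per-SNP summary-statistic table (or TSV
#'   path) with columns `rsid, beta, se` or `rsid, beta, ci_low, ci_high`
#'   and optionally `weight`, for the summary-score replication stage.
#' @param write_cohorts Logical: also write the simulated cohort TSVs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 20130205,
                       specs = default_cohort_specs(),
                       truth = true_model(),
                       panel = NULL,
                       cohort_files = NULL,
                       alpha_het = 0.05,
                       metareg = TRUE,
                       power_grid = data.frame(
                         effect = c(0.02, 0.02, 0.02, 0.01, 0.01),
                         n = 40000,
                         instrument_r2 = c(0.0097, 0.0064, 0.0126,
                                           0.0064, 0.0126),
                         reps = 400),
                       summary_stats = NULL,
                       write_cohorts = FALSE) {
  if (!is.null(cohort_files) && !all(file.exists(cohort_files))) {
    stop("cohort file(s) not found: ",
         paste(cohort_files[!file.exists(cohort_files)], collapse = ", "))
  }
  seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = seed, specs = specs, truth = truth,
                 panel = panel, cohort_files = cohort_files,
                 alpha_het = alpha_het, metareg = metareg,
                 power_grid = power_grid, summary_stats = summary_stats,
                 write_cohorts = write_cohorts),
            class = "run_config")
}

# covariate sets used throughout: BMI models adjust for age, sex and PCs;
# 25(OH)D models additionally for month of blood draw (categorical).
# Single-sex cohorts omit the sex term rather than carrying a degenerate
# column through every model.
.covariate_sets <- function(table) {
  pcs <- grep("^pc[0-9]+$", names(table), value = TRUE)
  sex <- if (length(unique(table$sex)) > 1) "sex" else character()
  list(bmi = c("age", sex, pcs),
       vitd = c("age", sex, pcs, "month"))
}

#' Per-cohort association stage
#'
#' Builds the three allele scores in each cohort (honouring whole-SNP
#' missingness and the no-imputation rule for unweighted scores), then fits
#' the observational ln 25(OH)D ~ BMI model, the six score-trait and
#' score-cross-trait models, the joint bivariate vitamin D model, and the
#' pooled variance-explained fractions per instrument.
#'
#' @param tables Named list of cohort tables.
#' @param panel Instrument panel.
#' @return List with elements `observational`, `score_assoc` (both
#'   `data.frame`s of `assoc_estimate` rows), `bivariate` (list), `r2`
#'   (`data.frame` of instrument, r2, n).
#' @export
stage_associations <- function(tables, panel) {
  defs <- list(bmi_score = bmi_score_def(panel),
               synthesis_score = synthesis_score_def(panel),
               metabolism_score = metabolism_score_def(panel))
  obs <- list(); assoc <- list(); biv <- list()
  pooled <- list(bmi_score = NULL, synthesis_score = NULL,
                 metabolism_score = NULL)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(attr(tab, "cohort"))) attr(tab, "cohort") <- nm
    cs <- .covariate_sets(tab)
    obs[[nm]] <- adjusted_percent_association(tab, "vitd", "bmi",
                                              covariates = cs$vitd)
    scores <- list(
      bmi_score = allele_score(tab, defs$bmi_score),
      synthesis_score = suppressWarnings(allele_score(tab, defs$synthesis_score)),
      metabolism_score = suppressWarnings(allele_score(tab, defs$metabolism_score))
    )
    for (sc in names(scores)) {
      if (is.null(scores[[sc]])) next
      target <- if (sc == "bmi_score") "bmi" else "vitd"
      for (out_ph in c(target, setdiff(c("bmi", "vitd"), target))) {
        row <- adjusted_percent_association(tab, out_ph, scores[[sc]],
                                            covariates = cs[[out_ph]],
                                            exposure_label = sc)
        row$instrument <- sc
        assoc[[paste(nm, sc, out_ph)]] <- row
      }
      ln_target <- paste0("ln_", target)
      pooled[[sc]] <- rbind(pooled[[sc]],
                            data.frame(score = scores[[sc]],
                                       pheno = tab[[ln_target]]))
    }
    if (!is.null(scores$synthesis_score) && !is.null(scores$metabolism_score)) {
      biv[[nm]] <- joint_score_association(tab, "bmi",
                                           scores$synthesis_score,
                                           scores$metabolism_score,
                                           covariates = cs$bmi)
    }
  }
  r2 <- do.call(rbind, lapply(names(pooled), function(sc) {
    data.frame(instrument = sc,
               r2 = variance_explained(pooled[[sc]]$score, pooled[[sc]]$pheno),
               n = nrow(pooled[[sc]]))
  }))
  list(observational = do.call(rbind, obs),
       score_assoc = do.call(rbind, assoc),
       bivariate = biv, r2 = r2)
}

#' Pooling stage
#'
#' Pools the observational association and each (instrument, outcome) group
#' with heterogeneity-based fixed/random selection, and runs the bivariate
#' multivariate pooling of the joint vitamin D model.
#'
#' @param assoc Result of [stage_associations()].
#' @param alpha_het Heterogeneity threshold.
#' @return List with `meta` (`data.frame`, one row per pooled group),
#'   `mv` (the [multivariate_pool()] result or `NULL`).
#' @export
stage_meta <- function(assoc, alpha_het = 0.05) {
  groups <- split(assoc$score_assoc,
                  list(assoc$score_assoc$instrument, assoc$score_assoc$outcome),
                  drop = TRUE)
  meta <- list()
  meta[["observational.vitd"]] <- cbind(
    data.frame(instrument = "bmi_kg_m2", outcome = "vitd"),
    pool(assoc$observational, alpha_het))
  for (g in names(groups)) {
    meta[[g]] <- cbind(
      data.frame(instrument = groups[[g]]$instrument[1],
                 outcome = groups[[g]]$outcome[1]),
      pool(groups[[g]], alpha_het))
  }
  mv <- if (length(assoc$bivariate) >= 2) multivariate_pool(assoc$bivariate) else NULL
  list(meta = do.call(rbind, meta), mv = mv)
}

#' MR stage: IV ratios in both directions plus instrument F statistics
#'
#' @param meta Result of [stage_meta()].
#' @param r2 The `r2` table from [stage_associations()].
#' @return `data.frame` with one row per instrument: `direction, instrument,
#'   ratio, se, ci_low, ci_high, p, f_stat, model`.
#' @export
stage_mr <- function(meta, r2) {
  m <- meta$meta
  pick <- function(instr, outc) m[m$instrument == instr & m$outcome == outc, ]
  plan <- list(
    list(direction = "bmi_to_vitd", instrument = "bmi_score",
         num = c("bmi_score", "vitd"), den = c("bmi_score", "bmi")),
    list(direction = "vitd_to_bmi", instrument = "synthesis_score",
         num = c("synthesis_score", "bmi"), den = c("synthesis_score", "vitd")),
    list(direction = "vitd_to_bmi", instrument = "metabolism_score",
         num = c("metabolism_score", "bmi"), den = c("metabolism_score", "vitd"))
  )
  rows <- lapply(plan, function(p) {
    num <- pick(p$num[1], p$num[2]); den <- pick(p$den[1], p$den[2])
    if (nrow(num) == 0 || nrow(den) == 0) return(NULL)
    iv <- iv_ratio(num, den,
                   numerator_ref = paste(p$num, collapse = "->"),
                   denominator_ref = paste(p$den, collapse = "->"))
    f <- r2[r2$instrument == p$instrument, ]
    data.frame(direction = p$direction, instrument = p$instrument,
               ratio = iv$ratio, se = iv$se,
               ci_low = iv$ci_low, ci_high = iv$ci_high, p = iv$p,
               f_stat = instrument_f(f$r2, f$n),
               model = num$model, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Meta-regression stage over study-level factors
#'
#' Runs univariate meta-regressions of each pooled association group on the
#' configured study-level factors (continent, assay, mean age band, mean BMI
#' band, percent female), skipping factors without contrast in the available
#' studies.
#'
#' @param assoc Result of [stage_associations()].
#' @param specs The cohort specs (source of the study-level factors).
#' @param tables The cohort tables (for observed study means).
#' @return `data.frame` with columns `group, factor, term, slope, se,
#'   ci_low, ci_high, z, p`.
#' @export
stage_metareg <- function(assoc, specs, tables) {
  nm <- vapply(specs, function(s) s$name, "")
  fac <- data.frame(
    cohort = nm,
    continent = vapply(specs, function(s) s$continent, ""),
    assay = vapply(specs, function(s) s$assay, ""),
    age_band = cut(vapply(specs, function(s) s$age_mean, 1),
                   breaks = c(-Inf, 40, 60, Inf),
                   labels = c("le40", "41_60", "ge61")),
    bmi_band = ifelse(vapply(tables[nm], function(t) mean(t$bmi), 1) <= 25,
                      "le25", "gt25"),
    pct_female = vapply(specs, function(s) s$prop_female, 1),
    stringsAsFactors = FALSE
  )
  refs <- c(continent = "europe", assay = "RIA", age_band = "le40",
            bmi_band = "le25")
  groups <- c(list(observational.vitd = assoc$observational),
              split(assoc$score_assoc,
                    list(assoc$score_assoc$instrument,
                         assoc$score_assoc$outcome), drop = TRUE))
  out <- list()
  for (g in names(groups)) {
    est <- groups[[g]]
    f_here <- fac[match(est$cohort, fac$cohort), ]
    for (f in c("continent", "assay", "age_band", "bmi_band", "pct_female")) {
      v <- f_here[[f]]
      if (is.character(v) || is.factor(v)) v <- droplevels(factor(v))
      res <- tryCatch(
        meta_regression(est, v, reference = unname(refs[f])),
        error = function(e) NULL)
      if (is.null(res)) next
      res <- cbind(data.frame(group = g, factor = f), res)
      out[[paste(g, f)]] <- res
    }
  }
  do.call(rbind, out)
}

#' Power grid stage
#'
#' @param power_grid `data.frame` with `effect, n, instrument_r2, reps`.
#' @param seed Master seed; each grid row uses a derived child seed.
#' @return `data.frame` of [iv_power()] results, one row per grid entry.
#' @export
stage_power <- function(power_grid, seed) {
  rows <- lapply(seq_len(nrow(power_grid)), function(i) {
    g <- power_grid[i, ]
    pr <- iv_power(g$effect, g$n, g$instrument_r2, reps = g$reps,
                   seed = derive_seed(seed, 9000 + i))
    data.frame(effect = pr$effect, n = pr$n, instrument_r2 = pr$instrument_r2,
               alpha = pr$alpha, reps = pr$reps, power = pr$power,
               mc_se = pr$mc_se)
  })
  do.call(rbind, rows)
}

# forest-plot data: one row per study plus a pooled row, per group
.forest_table <- function(assoc, meta) {
  z <- stats::qnorm(0.975)
  groups <- c(list(observational.vitd = assoc$observational),
              split(assoc$score_assoc,
                    list(assoc$score_assoc$instrument,
                         assoc$score_assoc$outcome), drop = TRUE))
  out <- list()
  for (g in names(groups)) {
    est <- groups[[g]]
    w <- (1 / est$se^2) / sum(1 / est$se^2)
    rows <- data.frame(group = g, study = est$cohort, beta = est$beta,
                       se = est$se, ci_low = est$beta - z * est$se,
                       ci_high = est$beta + z * est$se,
                       weight_pct = 100 * w, stringsAsFactors = FALSE)
    key <- if (g == "observational.vitd") c("bmi_kg_m2", "vitd") else
      strsplit(g, ".", fixed = TRUE)[[1]]
    mrow <- meta$meta[meta$meta$instrument == key[1] &
                        meta$meta$outcome == key[2], ]
    rows <- rbind(rows, data.frame(
      group = g, study = paste0("pooled_", mrow$model), beta = mrow$beta,
      se = mrow$se, ci_low = mrow$ci_low, ci_high = mrow$ci_high,
      weight_pct = 100))
    out[[g]] <- rows
  }
  do.call(rbind, out)
}

#' Run the full bi-directional MR pipeline
#'
#' Executes simulation (or reads cohort files), per-cohort observational and
#' score associations, pooling with heterogeneity-based model selection,
#' meta-regression, bivariate multivariate pooling, IV ratios with
#' F-statistics, the optional summary-statistic replication stage, and the
#' power grid.  All stage tables are written as TSV into `config$out_dir`
#' together with a run log (seeds, versions, per-stage inputs/outputs,
#' fixed/random decisions) and `index.tsv`, a results index listing every
#' table with its MD5 content hash.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results and the index.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    paste0("scoremr version: ", as.character(utils::packageVersion("scoremr"))),
    paste0("master seed: ", config$seed),
    paste0("R version: ", R.version.string))
  written <- character()
  emit <- function(df, name, stage, reads) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    written[[name]] <<- path
    log_lines <<- c(log_lines, paste0("stage ", stage, " reads: ",
                                      paste(reads, collapse = ","),
                                      " writes: ", name))
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      log_lines <- c(log_lines, paste0("stage ", stage, " FAILED: ",
                                       conditionMessage(e)))
      writeLines(log_lines, log_path)
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # (1) inputs: simulate or read
  panel <- config$panel
  tables <- run_stage("simulate", {
    if (is.null(config$cohort_files)) {
      if (is.null(panel)) panel <- make_snp_panel(seed = config$seed)
      tabs <- simulate_collaboration(config$specs, panel, config$truth,
                                     seed = config$seed)
      write_truth(config$truth, file.path(config$out_dir, "truth.yaml"))
      tabs
    } else {
      if (is.null(panel)) stop("cohort_files input requires an explicit panel")
      tabs <- lapply(config$cohort_files, read_cohort_tsv)
      names(tabs) <- vapply(tabs, attr, "", "cohort")
      tabs
    }
  })
  emit(as.data.frame(panel), "panel.tsv", "simulate", "config")
  if (config$write_cohorts && is.null(config$cohort_files)) {
    for (nm in names(tables)) {
      write_cohort_tsv(tables[[nm]], file.path(config$out_dir,
                                               paste0(nm, ".tsv")))
    }
    log_lines <- c(log_lines, paste0("stage simulate writes: ",
                                     length(tables), " cohort TSVs"))
  }

  # (2-4) per-cohort associations and scores
  assoc <- run_stage("associate", stage_associations(tables, panel))
  emit(assoc$observational, "observational.tsv", "associate", "cohorts,panel.tsv")
  emit(assoc$score_assoc, "associations.tsv", "associate", "cohorts,panel.tsv")
  emit(assoc$r2, "r2.tsv", "associate", "cohorts,panel.tsv")

  # (5) pooling
  meta <- run_stage("meta", stage_meta(assoc, config$alpha_het))
  emit(meta$meta, "meta.tsv", "meta", "observational.tsv,associations.tsv")
  for (i in seq_len(nrow(meta$meta))) {
    log_lines <- c(log_lines, paste0(
      "heterogeneity decision [", meta$meta$instrument[i], " -> ",
      meta$meta$outcome[i], "]: model=", meta$meta$model[i],
      " (Q=", signif(meta$meta$Q[i], 4), ", p_Q=", signif(meta$meta$p_Q[i], 4), ")"))
  }
  emit(.forest_table(assoc, meta), "forest.tsv", "meta",
       "observational.tsv,associations.tsv,meta.tsv")
  if (!is.null(meta$mv)) {
    mv_tab <- cbind(data.frame(term = meta$mv$components$term,
                               joint_p = meta$mv$joint_p, k = meta$mv$k),
                    meta$mv$components[, c("beta", "se", "ci_low", "ci_high", "p")])
    emit(mv_tab, "multivariate.tsv", "meta", "associations.tsv")
  }

  # (6) meta-regression
  metareg <- NULL
  if (isTRUE(config$metareg)) {
    metareg <- run_stage("metareg",
                         stage_metareg(assoc, config$specs, tables))
    if (!is.null(metareg)) {
      emit(metareg, "metareg.tsv", "metareg", "observational.tsv,associations.tsv")
    }
  }

  # (8) IV ratios and instrument strength
  iv <- run_stage("mr", stage_mr(meta, assoc$r2))
  emit(iv, "iv.tsv", "mr", "meta.tsv,r2.tsv")

  # (9) optional summary-statistic replication
  summary_rep <- NULL
  if (!is.null(config$summary_stats)) {
    summary_rep <- run_stage("summary", {
      ss <- config$summary_stats
      if (is.character(ss)) ss <- utils::read.delim(ss)
      w <- if ("weight" %in% names(ss)) ss$weight else rep(1, nrow(ss))
      summary_score(ss, weights = w)
    })
    emit(summary_rep, "summary_score.tsv", "summary", "summary_stats")
  }

  # (10) power grid
  power <- NULL
  if (!is.null(config$power_grid)) {
    power <- run_stage("power", stage_power(config$power_grid, config$seed))
    emit(power, "power.tsv", "power", "config")
  }

  # results index with content hashes (basis of the determinism contract)
  idx <- data.frame(file = names(written),
                    md5 = unname(tools::md5sum(unlist(written))),
                    stringsAsFactors = FALSE)
  utils::write.table(idx, file.path(config$out_dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(log_lines, log_path)

  invisible(list(panel = panel, tables = tables, assoc = assoc, meta = meta,
                 metareg = metareg, iv = iv, summary_rep = summary_rep,
                 power = power, index = idx))
}
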