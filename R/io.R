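# 31-bit polynomial rolling hash (hex) of a character scalar; used to stamp
# outputs with a configuration fingerprint
sg_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

sg_config_hash <- function(config) {
  config <- unclass(config)
  # paths are excluded so that identical analyses in different directories
  # produce byte-identical tables
  config <- config[setdiff(names(config), c("out_dir", "cohort_path", "mesh_dir"))]
  sg_hash(paste(deparse(config[order(names(config))]), collapse = ""))
}

# write a TSV with a one-line provenance comment header
sg_write_table <- function(df, path, config_hash = NA, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# growmap config_hash=%s seed=%s", config_hash, seed), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort table
#'
#' Tab-separated, one scan per row, with a provenance comment header
#' (configuration hash and seed).
#'
#' @param records scan records.
#' @param path output file.
#' @param config optional generating configuration (hashed into the header).
#' @param seed optional seed recorded in the header.
#' @export
write_cohort <- function(records, path, config = NULL, seed = NA) {
  sg_write_table(records, path,
                 config_hash = if (is.null(config)) NA else sg_config_hash(config),
                 seed = seed)
}

#' Read and validate a cohort table
#'
#' Expects a delimited table (TSV by default; `#` comment lines skipped) with
#' mandatory columns `subject_id`, `age_days`, `sex`, `site`, `icv` plus any
#' per-structure volume, household and Mullen score columns. Ages are coerced
#' to integer days and must lie in \[0, 810\] unless `allow_extended`;
#' duplicate (subject, age) pairs and unknown sex levels are rejected.
#'
#' @param path cohort file.
#' @param allow_extended allow ages outside the 0-810 day study span.
#' @return validated data.frame of scan records.
#' @export
read_cohort <- function(path, allow_extended = FALSE) {
  if (!file.exists(path)) stop(sprintf("cohort file '%s' not found", path))
  df <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("no records in '%s'", path)))
  if (!nrow(df)) stop(sprintf("no records in '%s'", path))
  mandatory <- c("subject_id", "age_days", "sex", "site", "icv")
  for (m in mandatory) {
    if (!m %in% names(df)) stop(sprintf("missing mandatory column '%s'", m))
  }
  df$age_days <- as.integer(round(as.numeric(df$age_days)))
  if (!allow_extended && any(df$age_days < 0 | df$age_days > 810))
    stop("age_days outside the 0-810 day span (use allow_extended to accept)")
  if (anyDuplicated(df[c("subject_id", "age_days")]))
    stop("duplicate (subject_id, age_days) pair")
  if (!all(df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  df$subject_id <- as.character(df$subject_id)
  df$site <- as.character(df$site)
  df
}

#' Serialize / restore a growth truth object as JSON
#' @param truth a `growth_truth`.
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(structures = truth$structures, icv = truth$icv,
                            behavior = truth$behavior),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  beh <- as.matrix(x$behavior)
  dimnames(beh) <- list(SG_STRUCTURES, SG_SCORES)
  structure(list(structures = as.data.frame(x$structures),
                 icv = x$icv, behavior = beh),
            class = "growth_truth")
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end run. Per-stage seeds are derived from the
#' master seed by fixed offsets, so any stage is independently reproducible.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_subjects cohort size for the simulate stage.
#' @param cohort_path optional existing cohort table (skips simulation).
#' @param mesh_dir optional existing mesh directory.
#' @param structures structure-hemisphere responses to fit.
#' @param K,K_sex spline basis dimensions.
#' @param method `"ML"` or `"REML"`.
#' @param B bootstrap replicates for the growth tables.
#' @param B_vertex bootstrap replicates for region detection.
#' @param refit_lambda re-select smoothing parameters per replicate.
#' @param n_vertices mesh vertex count for the simulate stage.
#' @param detect_months months at which regions are detected.
#' @param q,alpha candidate fraction and FDR level for region detection.
#' @param fdr_grouping association FDR family (`"score"` or `"all"`).
#' @param join_window behavioral-visit join window (days).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, n_subjects = 231,
                            cohort_path = NULL, mesh_dir = NULL,
                            structures = sg_volume_cols(),
                            K = 10, K_sex = 5, method = "ML",
                            B = 1000, B_vertex = 200, refit_lambda = FALSE,
                            n_vertices = 42, detect_months = c(3, 6, 12, 24),
                            q = 0.20, alpha = 0.05,
                            fdr_grouping = "score", join_window = 45) {
  stopifnot(B >= 2, B_vertex >= 2, q > 0, q < 0.5, alpha > 0, alpha < 1)
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop(sprintf("cohort_path '%s' does not exist", cohort_path))
  if (!is.null(mesh_dir) && !dir.exists(mesh_dir))
    stop(sprintf("mesh_dir '%s' does not exist", mesh_dir))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

sg_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  cat(line, "\n", sep = "", file = state$log, append = TRUE)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: `simulate` (synthetic cohort, Mullen scores and
#' corresponded meshes, skipped when a cohort table is supplied),
#' `fit-volumes` (one trajectory model per structure-hemisphere, curve and
#' derivative exports), `growth-table` (stratified bootstrap and Bonferroni
#' Z-tests), `fit-surface` (per-vertex trajectories), `detect-regions`
#' (high-/low-growth labels per month) and `associate` (structure-score
#' mixed-model table plus nested-model F tests). Each stage writes its
#' outputs under `out_dir` and is skipped when they already exist, so an
#' interrupted run resumes where it stopped; outputs are deterministic given
#' the configuration seed.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run (default all, in order).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit-volumes", "growth-table",
                                    "fit-surface", "detect-regions",
                                    "associate")) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ch <- sg_config_hash(unclass(config))
  state <- list(log = file.path(out, "pipeline.log"))
  seed <- config$seed
  wt <- function(df, name) sg_write_table(df, file.path(out, name), ch, seed)
  path <- function(name) file.path(out, name)
  done <- function(name) file.exists(path(name))

  # --- simulate ------------------------------------------------------------
  if ("simulate" %in% stages && is.null(config$cohort_path) &&
      !done("cohort.tsv")) {
    cc <- cohort_config(n_subjects = config$n_subjects, seed = seed)
    g <- generate_cohort(cc)
    rec <- generate_mullen(g$records, g$truth, seed = seed + 1L)
    write_cohort(rec, path("cohort.tsv"), config = unclass(config), seed = seed)
    write_truth_json(g$truth, path("truth.json"))
    gm <- generate_meshes(rec, n_vertices = config$n_vertices, seed = seed + 2L)
    write_mesh_series(gm$series, path("meshes"))
    jsonlite::write_json(gm$mesh_truth[c("high", "low", "growth_total")],
                         path("mesh_truth.json"), auto_unbox = TRUE, digits = NA)
    sg_log(state, "simulate: %d scans, %d mesh vertices [seed %d]",
           nrow(rec), config$n_vertices, seed)
  }
  cohort_file <- if (!is.null(config$cohort_path)) config$cohort_path else path("cohort.tsv")
  records <- read_cohort(cohort_file)

  # --- fit-volumes ---------------------------------------------------------
  if ("fit-volumes" %in% stages && !done("curves.tsv")) {
    icv_ref <- fit_gamm(records, as.numeric(records$icv), with_sex = FALSE,
                        K = min(config$K, 8), include_icv = FALSE,
                        method = config$method, compute_cov = FALSE)
    grid <- seq(0, 810, by = 10)
    curves <- list(); models <- list()
    for (resp in config$structures) {
      m <- fit_gamm(records, resp, K = config$K, K_sex = config$K_sex,
                    method = config$method, icv_ref = icv_ref)
      sg_log(state, "fit-volumes: %s converged=%s logLik=%.2f", resp,
             m$convergence == 0, m$logLik)
      models[[resp]] <- m
      for (sx in c("male", "female", "pooled")) {
        pc <- predict_curve(m, grid, sx)
        dc <- derivative_curve(m, grid, sx)
        nc <- normalized_curve(m, grid, sx)
        curves[[paste(resp, sx)]] <- data.frame(
          structure = resp, stratum = sx, age_days = grid,
          estimate = pc$estimate, lower = pc$lower, upper = pc$upper,
          rate_per_month = dc$estimate, normalized = nc$estimate)
      }
    }
    saveRDS(models, path("models.rds"))
    jsonlite::write_json(lapply(models, gamm_to_list), path("models.json"),
                         digits = NA, auto_unbox = TRUE)
    wt(do.call(rbind, curves), "curves.tsv")
  }

  # --- growth-table --------------------------------------------------------
  if ("growth-table" %in% stages && !done("growth_table.tsv")) {
    models <- readRDS(path("models.rds"))
    n_struct <- length(config$structures)
    m_bonf <- n_struct / 2 * nrow(growth_intervals())  # per-hemisphere table
    tabs <- list(); sexdiff <- list()
    for (resp in config$structures) {
      mdl <- models[[resp]]
      bt <- suppressWarnings(
        stratified_bootstrap(mdl, B = config$B, seed = seed + 3L,
                             refit_lambda = config$refit_lambda))
      gt <- growth_table(mdl, bt, m = m_bonf)
      gt$structure <- resp
      tabs[[resp]] <- gt
      sd_t <- sex_effect_test(mdl, bt, seq(0, 810, by = 90))
      sd_t$structure <- resp
      sexdiff[[resp]] <- sd_t
      sg_log(state, "growth-table: %s B=%d", resp, bt$B)
    }
    long <- do.call(rbind, tabs)
    wt(long, "growth_table.tsv")
    wt(growth_table_wide(long), "growth_table_wide.tsv")
    wt(do.call(rbind, sexdiff), "sex_effects.tsv")
    # asymmetry-index trajectories per structure
    grid <- seq(0, 810, by = 30)
    ai <- list()
    for (s in unique(sub("_[LR]$", "", config$structures))) {
      lr <- paste0(s, c("_L", "_R"))
      if (all(lr %in% names(models))) {
        ai[[s]] <- cbind(structure = s,
                         asymmetry_index(predict_curve(models[[lr[1]]], grid),
                                         predict_curve(models[[lr[2]]], grid)))
      }
    }
    if (length(ai)) wt(do.call(rbind, ai), "asymmetry.tsv")
  }

  # --- fit-surface ---------------------------------------------------------
  mesh_dir <- if (!is.null(config$mesh_dir)) config$mesh_dir else path("meshes")
  if ("fit-surface" %in% stages && dir.exists(mesh_dir) &&
      !done("vertex_fit.rds")) {
    series <- read_mesh_series(mesh_dir, records)
    vf <- fit_vertex_trajectories(series, records, K = config$K,
                                  method = config$method)
    saveRDS(vf, path("vertex_fit.rds"))
    sg_log(state, "fit-surface: %d vertices, %d masked", vf$V, sum(vf$masked))
  }

  # --- detect-regions ------------------------------------------------------
  if ("detect-regions" %in% stages && file.exists(path("vertex_fit.rds")) &&
      !done("regions.tsv")) {
    vf <- readRDS(path("vertex_fit.rds"))
    regions <- list(); rates_tab <- list()
    for (mo in config$detect_months) {
      r <- expansion_rate_map(vf, mo)
      br <- bootstrap_expansion_rates(vf, mo, B = config$B_vertex,
                                      seed = seed + 4L)
      det <- detect_growth_regions(r, br, q = config$q, alpha = config$alpha)
      det$month <- mo
      regions[[as.character(mo)]] <- det
      # rate map and labels as per-vertex PLY scalars on the first mesh shape
      first <- read_mesh(list.files(mesh_dir, pattern = "\\.(ply|off)$",
                                    full.names = TRUE)[1])
      write_ply(first$vertices, first$faces,
                path(sprintf("rate_map_%02dM.ply", mo)),
                scalars = list(rate = ifelse(is.na(r), -1, r),
                               label = match(det$label,
                                             c("none", "low", "high")) - 2))
      rates_tab[[as.character(mo)]] <- data.frame(month = mo,
                                                  vertex = seq_along(r), rate = r)
      sg_log(state, "detect-regions: month %d, %d high / %d low", mo,
             sum(det$label == "high"), sum(det$label == "low"))
    }
    wt(do.call(rbind, rates_tab), "vertex_rates.tsv")
    reg <- do.call(rbind, regions)
    wt(reg, "regions.tsv")
    jsonlite::write_json(
      lapply(split(reg, reg$month), function(d)
        list(high = d$vertex[d$label == "high"], low = d$vertex[d$label == "low"])),
      path("regions.json"), digits = NA)
  }

  # --- associate -----------------------------------------------------------
  if ("associate" %in% stages && !done("associations.tsv")) {
    score_cols <- paste0("mullen_", SG_SCORES)
    if (all(score_cols %in% names(records))) {
      at <- association_table(records, fdr_grouping = config$fdr_grouping)
      wt(at, "associations.tsv")
      sig <- at[at$significant, , drop = FALSE]
      cmp <- list()
      for (sc in unique(sig$score)) {
        cmp[[sc]] <- compare_models(records, sc,
                                    sig$structure[sig$score == sc])
      }
      if (length(cmp)) wt(do.call(rbind, cmp), "model_comparison.tsv")
      sg_log(state, "associate: %d significant pairs", sum(at$significant))
    } else {
      sg_log(state, "associate: no Mullen score columns; stage skipped")
    }
  }
  invisible(out)
}
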