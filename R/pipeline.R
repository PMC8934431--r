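#' Run the full succession analysis pipeline
#'
#' Orchestrates simulate/read -> community metrics -> stage assignment ->
#' coupling -> multifunctionality -> inferential layer as one
#' reproducible run. Results are written as CSV tables plus a JSON run
#' manifest; a failure at any stage moves the partial outputs into a
#' `quarantine/` subdirectory and re-raises a stage-named error.
#'
#' The run seed fans out deterministically to the stochastic steps
#' (generator: `rng_seed`; Mantel permutations: `rng_seed + 1`), so each
#' module can be re-run in isolation with the seed recorded in the
#' manifest.
#'
#' @param config An [analysis_config()].
#' @param survey Either a `survey_table`, a path to a survey CSV, or
#'   `NULL` to generate one with `generator`.
#' @param generator A [generator_config()] used when `survey` is `NULL`;
#'   its `rng_seed` is overridden by `config$rng_seed`.
#' @param fg_map Species-to-group map; defaults to the map implied by
#'   `generator`'s templates.
#' @param out_dir Output directory.
#' @param layout CSV layout when `survey` is a path.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = analysis_config(),
                         survey = NULL,
                         generator = generator_config(),
                         fg_map = templates_fg_map(generator$templates),
                         out_dir,
                         layout = "wide") {
  t0 <- proc.time()[["elapsed"]]
  withCallingHandlers(
    run_pipeline_impl(config, survey, generator, fg_map, out_dir, layout, t0),
    error = function(e) quarantine_outputs(out_dir)
  )
}

run_pipeline_impl <- function(config, survey, generator, fg_map, out_dir,
                              layout, t0) {
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "meadowsucc_pipeline_error", parent = e)
    })
    res
  }

  table <- step("input", {
    if (is.null(survey)) {
      generator$rng_seed <- config$rng_seed
      tab <- generate_survey(generator)
      inform(paste0("stage input: generated ", nrow(tab), " quadrats, ",
                    length(species_universe(tab)), " species"))
      tab
    } else if (is.character(survey)) {
      tab <- read_survey_table(survey, layout = layout)
      inform(paste0("stage input: read ", nrow(tab), " quadrats from ", survey))
      tab
    } else {
      as_survey_table(survey)
    }
  })

  community <- step("community", {
    out <- community_summary(table, fg_map)
    inform(paste0("stage community: ", nrow(out), " quadrat summaries"))
    out
  })

  stages <- step("stages", {
    out <- assign_stages(table, fg_map, k = config$n_clusters)
    inform(paste0("stage stages: ", config$n_clusters, " clusters over ",
                  nrow(out), " quadrats"))
    out
  })

  coupling <- step("coupling", {
    out <- coupling_indices(table, config)
    inform(paste0("stage coupling: D in [",
                  signif(min(out$D), 3), ", ", signif(max(out$D), 3), "]"))
    out
  })

  emf <- step("multifunction", {
    out <- multifunctionality(table, config)
    inform(paste0("stage multifunction: ", length(config$emf_functions),
                  " functions averaged"))
    out
  })

  stats_tables <- step("inference", {
    run_inference(table, community, stages, coupling, emf, config)
  })

  manifest <- step("write", {
    tables <- c(
      list(survey = tibble::as_tibble(table), community = community,
           stages = stages, coupling = coupling, multifunction = emf),
      stats_tables
    )
    m <- write_results(tables, out_dir, config = config,
                       seed = config$rng_seed)
    m$stage_counts <- as.list(table(stages$stage))
    m$elapsed_seconds <- proc.time()[["elapsed"]] - t0
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    m
  })
  invisible(manifest)
}

# The inferential layer over assigned stages: stage contrasts with Tukey
# letters, the pooled and per-stage EC_SP ~ EMF regressions, toxic-share
# regressions, Mantel tests of the plant-vs-soil distance structure and
# of EMF distance vs EC_SP distance, a correlation matrix of the summary
# indices, and LMG relative importance for EC_SP and EMF.
run_inference <- function(table, community, stages, coupling, emf, config) {
  stage <- stages$stage[match(table$quadrat_id, stages$quadrat_id)]
  d <- coupling$D
  emf_v <- emf$emf

  contrast_vars <- list(
    sr = community$sr, ev = community$ev, toxic_share = community$toxic_share,
    agb = table$agb, ec_sp = d,
    pgi = emf$pgi, sci = emf$sci, sni = emf$sni, emf = emf_v
  )
  contrasts <- dplyr::bind_rows(lapply(names(contrast_vars), function(v) {
    res <- anova_tukey(contrast_vars[[v]], stage)
    dplyr::mutate(res$summary, variable = v, f_value = res$f_value,
                  p_value = res$p_value, .before = 1)
  }))

  regressions <- dplyr::bind_rows(
    dplyr::mutate(simple_regression(emf_v, d), scope = "pooled",
                  response = "ec_sp", predictor = "emf", .before = 1),
    dplyr::bind_rows(lapply(sort(unique(stage)), function(s) {
      idx <- stage == s
      dplyr::mutate(simple_regression(emf_v[idx], d[idx]),
                    scope = paste0("stage", s),
                    response = "ec_sp", predictor = "emf", .before = 1)
    })),
    dplyr::bind_rows(lapply(sort(unique(stage)), function(s) {
      idx <- stage == s
      dplyr::mutate(
        simple_regression(community$toxic_share[idx], emf_v[idx]),
        scope = paste0("stage", s),
        response = "emf", predictor = "toxic_share", .before = 1
      )
    }))
  )

  plant_z <- scale(cbind(agb = table$agb, bgb = table$bgb,
                         plant_density = table$plant_density,
                         plant_height = table$plant_height, sr = community$sr))
  soil_z <- scale(cbind(sbd = table$sbd, sm = table$sm, st = table$st,
                        stc = table$stc, stn = table$stn,
                        stp = table$stp, sts = table$sts))
  mantel_seed <- config$rng_seed + 1L
  m1 <- mantel_test(dist(plant_z), dist(soil_z),
                    n_perm = config$n_permutations, seed = mantel_seed)
  m2 <- mantel_test(dist(emf_v), dist(d),
                    n_perm = config$n_permutations, seed = mantel_seed)
  mantel <- tibble::tibble(
    comparison = c("plant_vs_soil", "emf_vs_ec_sp"),
    r = c(m1$r, m2$r), p = c(m1$p, m2$p),
    n_permutations = config$n_permutations, seed = mantel_seed
  )

  idx_cols <- data.frame(sr = community$sr, ev = community$ev,
                         pgi = emf$pgi, sci = emf$sci, sni = emf$sni,
                         emf = emf_v, ec_sp = d)
  cm <- correlation_matrix(idx_cols)
  correlations <- tibble::as_tibble(cm$r, rownames = "variable")

  predictors <- cbind(
    agb = table$agb, sr = community$sr, ev = community$ev,
    bgb = table$bgb, plant_density = table$plant_density,
    plant_height = table$plant_height, sbd = table$sbd, sm = table$sm,
    st = table$st, stc = table$stc, stn = table$stn, stp = table$stp
  )
  imp_ec <- lmg_importance(predictors, d)
  imp_emf <- lmg_importance(predictors, emf_v)
  importance <- tibble::tibble(
    predictor = names(imp_ec$shares),
    share_ec_sp = unname(imp_ec$shares),
    share_emf = unname(imp_emf$shares)
  )
  attr(importance, "r_squared") <- c(ec_sp = imp_ec$r_squared,
                                     emf = imp_emf$r_squared)

  list(contrasts = contrasts, regressions = regressions, mantel = mantel,
       correlations = correlations, importance = importance)
}

quarantine_outputs <- function(out_dir) {
  if (!dir.exists(out_dir)) return(invisible(NULL))
  files <- list.files(out_dir, full.names = TRUE, recursive = FALSE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) return(invisible(NULL))
  qdir <- file.path(out_dir, "quarantine")
  dir.create(qdir, showWarnings = FALSE)
  file.rename(files, file.path(qdir, basename(files)))
  warn(paste0("partial outputs moved to ", qdir))
  invisible(NULL)
}
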