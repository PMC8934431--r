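#' Stage templates for the synthetic survey generator
#'
#' A stage template fixes the data-generating conditions of one succession
#' stage: the expected biomass share of each plant functional group, the
#' stage species pool (with functional-group assignments and within-group
#' dominance weights), per-species detection probability, the Dirichlet
#' concentration controlling compositional noise, the expected total
#' aboveground biomass, and means/SDs of the plant and soil covariates.
#'
#' @param stage Stage number, 1-4.
#' @param fg_proportions Named numeric over
#'   `sedge, grass, desirable_forb, toxic_forb, shrub`, summing to 1.
#' @param species_pool Tibble with columns `species`, `group`, `weight`
#'   (relative within-group abundance weight).
#' @param soil_means,soil_sds Named numeric over the covariates
#'   `bgb, plant_density, plant_height, sbd, sm, st, stc, stn, stp, sts`.
#' @param agb_mean Expected total aboveground biomass, g per 0.25 m2.
#' @param agb_cv Lognormal coefficient of variation of total AGB.
#' @param detection_prob Per-species occurrence probability in (0, 1].
#' @param biomass_dispersion Dirichlet concentration (> 0); larger values
#'   give quadrat compositions closer to `fg_proportions`.
#' @return An object of class `stage_template`.
#' @export
stage_template <- function(stage, fg_proportions, species_pool,
                           soil_means, soil_sds,
                           agb_mean, agb_cv = 0.25,
                           detection_prob = 0.4,
                           biomass_dispersion = 60) {
  fg_proportions <- fg_proportions[.functional_groups]
  if (anyNA(fg_proportions) || abs(sum(fg_proportions) - 1) > 1e-8 ||
      any(fg_proportions < 0)) {
    abort_schema("fg_proportions must cover all five functional groups and sum to 1")
  }
  species_pool <- tibble::as_tibble(species_pool)
  if (!all(c("species", "group", "weight") %in% names(species_pool))) {
    abort_schema("species_pool needs columns species, group, weight")
  }
  if (!all(species_pool$group %in% .functional_groups)) {
    abort_schema("species_pool contains an unknown functional group")
  }
  if (anyDuplicated(species_pool$species)) {
    abort_schema("species_pool contains duplicated species")
  }
  cov_names <- setdiff(.covariate_cols, "agb")
  if (!all(cov_names %in% names(soil_means)) ||
      !all(cov_names %in% names(soil_sds))) {
    abort_schema(paste0(
      "soil_means and soil_sds must name all of: ",
      paste(cov_names, collapse = ", ")
    ))
  }
  if (any(soil_sds[cov_names] < 0)) abort_schema("soil_sds must be >= 0")
  if (detection_prob <= 0 || detection_prob > 1) {
    abort_schema("detection_prob must be in (0, 1]")
  }
  if (biomass_dispersion <= 0) abort_schema("biomass_dispersion must be > 0")
  structure(
    list(
      stage = as.integer(stage),
      fg_proportions = fg_proportions,
      species_pool = species_pool,
      pool_size = nrow(species_pool),
      soil_means = soil_means[cov_names],
      soil_sds = soil_sds[cov_names],
      agb_mean = agb_mean,
      agb_cv = agb_cv,
      detection_prob = detection_prob,
      biomass_dispersion = biomass_dispersion
    ),
    class = "stage_template"
  )
}

#' @rdname stage_template
#' @param templates List of 4 `stage_template`s.
#' @param n_quadrats_per_stage Quadrats drawn per stage (default 30).
#' @param rng_seed Integer seed; the whole survey is reproducible from it.
#' @export
generator_config <- function(templates = default_stage_templates(),
                             n_quadrats_per_stage = 30L,
                             rng_seed = 1L) {
  if (length(templates) != 4 ||
      !all(vapply(templates, inherits, logical(1), "stage_template"))) {
    abort_schema("'templates' must be a list of 4 stage_template objects")
  }
  if (n_quadrats_per_stage < 2) {
    abort_schema("n_quadrats_per_stage must be >= 2")
  }
  structure(
    list(
      templates = templates,
      n_quadrats_per_stage = as.integer(n_quadrats_per_stage),
      rng_seed = as.integer(rng_seed)
    ),
    class = "generator_config"
  )
}

# Master species lists per functional group. The leading names are the
# field-observed dominants of the alpine-meadow succession series; the
# numbered fillers are synthetic placeholder taxa that pad each stage pool
# to its gamma diversity.
master_species_pools <- function() {
  fill <- function(prefix, from, n) {
    sprintf("%s_sp%02d", prefix, seq(from, length.out = n))
  }
  list(
    sedge = c("Kobresia graminifolia", "Kobresia cristata", "Carex thibetica",
              "Scirpus pumilus", fill("sedge", 5, 8)),
    grass = c("Elymus nutans", "Poa pratensis", "Stipa aliena",
              "Festuca sinensis", "Agrostis clavata", fill("grass", 6, 7)),
    desirable_forb = c("Saussurea hieracioides", "Potentilla fragarioides",
                       "Pleurospermum camtschaticum", "Anaphalis lactea",
                       "Aster tataricus", "Tibetia himalaica",
                       fill("dforb", 7, 18)),
    toxic_forb = c("Gentiana macrophylla", "Anemone rivularis",
                   "Anemone trullifolia", "Oxytropis kansuensis",
                   "Euphorbia esula", fill("tforb", 6, 13)),
    shrub = c("Berberis wilsonii", "Potentilla fruticosa",
              fill("shrub", 3, 2))
  )
}

build_pool <- function(master, counts, dominants = character(0),
                       weight_decay = 0.65) {
  rows <- lapply(names(counts), function(g) {
    sp <- master[[g]]
    lead <- intersect(dominants, sp)
    sp <- c(lead, setdiff(sp, lead))[seq_len(counts[[g]])]
    tibble::tibble(
      species = sp,
      group = g,
      weight = weight_decay^(seq_along(sp) - 1)
    )
  })
  dplyr::bind_rows(rows)
}

#' Default stage templates for the grazing-succession series
#'
#' Encodes the four-community succession series of a grazed alpine meadow:
#' the expected functional-group biomass shares per stage (Stage 1 sedge
#' 46%, desirable forbs 28%, grasses 15%; Stage 2 36/25/24; Stage 3
#' desirable forbs 38%, toxic forbs 29%, sedges 23%; Stage 4 toxic forbs
#' 44%, desirable forbs 37%, grasses 11%; the remainder in each stage is
#' split between the minor groups and shrubs), stage species pools of
#' 61, 55, 47 and 49 species led by each stage's dominant taxa, and soil
#' and plant covariate means ordered so that soil bulk density and soil
#' temperature peak in Stage 4, total soil N is lowest in Stage 4, soil C
#' and N peak in Stage 3, and soil moisture is flat across stages. The
#' covariate magnitudes themselves are a synthetic calibration chosen to
#' be plausible for alpine meadow, not measured values.
#'
#' @return List of 4 [stage_template()] objects.
#' @export
default_stage_templates <- function() {
  master <- master_species_pools()
  fg <- function(sedge, grass, dforb, tforb, shrub) {
    c(sedge = sedge, grass = grass, desirable_forb = dforb,
      toxic_forb = tforb, shrub = shrub)
  }
  soil <- function(bgb, pd, ph, sbd, sm, st, stc, stn, stp, sts) {
    c(bgb = bgb, plant_density = pd, plant_height = ph, sbd = sbd, sm = sm,
      st = st, stc = stc, stn = stn, stp = stp, sts = sts)
  }
  sds <- soil(35, 18, 2.2, 0.08, 5, 1.0, 6, 0.5, 0.08, 0.08)

  list(
    stage_template(
      stage = 1,
      fg_proportions = fg(0.46, 0.15, 0.28, 0.06, 0.05),
      species_pool = build_pool(
        master,
        c(sedge = 12, grass = 11, desirable_forb = 22, toxic_forb = 12, shrub = 4),
        dominants = c("Kobresia graminifolia", "Elymus nutans", "Poa pratensis",
                      "Anemone rivularis", "Tibetia himalaica")
      ),
      soil_means = soil(260, 120, 18, 0.85, 32, 11.5, 55, 4.2, 0.90, 0.80),
      soil_sds = sds,
      agb_mean = 62, detection_prob = 0.40
    ),
    stage_template(
      stage = 2,
      fg_proportions = fg(0.24, 0.25, 0.36, 0.10, 0.05),
      species_pool = build_pool(
        master,
        c(sedge = 9, grass = 11, desirable_forb = 21, toxic_forb = 11, shrub = 3),
        dominants = c("Elymus nutans", "Scirpus pumilus",
                      "Pleurospermum camtschaticum", "Saussurea hieracioides",
                      "Potentilla fragarioides")
      ),
      soil_means = soil(240, 110, 15, 0.88, 31, 12.0, 52, 4.0, 0.85, 0.75),
      soil_sds = sds,
      agb_mean = 58, detection_prob = 0.38
    ),
    stage_template(
      stage = 3,
      fg_proportions = fg(0.23, 0.07, 0.38, 0.29, 0.03),
      species_pool = build_pool(
        master,
        c(sedge = 7, grass = 8, desirable_forb = 19, toxic_forb = 11, shrub = 2),
        dominants = c("Anaphalis lactea", "Saussurea hieracioides",
                      "Anemone trullifolia", "Aster tataricus")
      ),
      soil_means = soil(250, 100, 11, 0.92, 33, 12.5, 65, 4.8, 0.98, 0.88),
      soil_sds = sds,
      agb_mean = 60, detection_prob = 0.38
    ),
    stage_template(
      stage = 4,
      fg_proportions = fg(0.04, 0.11, 0.37, 0.44, 0.04),
      species_pool = build_pool(
        master,
        c(sedge = 4, grass = 7, desirable_forb = 20, toxic_forb = 16, shrub = 2),
        dominants = c("Gentiana macrophylla", "Anemone rivularis",
                      "Saussurea hieracioides", "Oxytropis kansuensis")
      ),
      soil_means = soil(170, 65, 6, 1.15, 30, 14.5, 38, 2.6, 0.68, 0.55),
      soil_sds = sds,
      agb_mean = 35, detection_prob = 0.30
    )
  )
}

#' Functional-group map implied by a set of stage templates
#'
#' @param templates List of `stage_template`s.
#' @return Named character vector species -> functional group covering the
#'   union of all stage pools.
#' @export
templates_fg_map <- function(templates = default_stage_templates()) {
  pools <- dplyr::bind_rows(lapply(templates, `[[`, "species_pool"))
  pools <- dplyr::distinct(pools, .data$species, .data$group)
  setNames(pools$group, pools$species)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  # rgamma underflows to exactly 0 at minute shapes; a present species must
  # keep a positive (trace) biomass, so floor at the smallest positive double
  g <- pmax(g, .Machine$double.xmin)
  g / sum(g)
}

rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf, max_tries = 1000) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- out < lower | out > upper
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(out, lower), upper)
}

#' Generate a stage-structured synthetic quadrat survey
#'
#' For each stage, draws `n_quadrats_per_stage` quadrats. Per quadrat:
#' species presence is Bernoulli with the stage detection probability;
#' biomass shares among present species follow a Dirichlet with
#' concentration `biomass_dispersion x` the species' target share (its
#' group's expected share split across the group's present members by
#' dominance weight); total AGB is lognormal with mean `agb_mean` and CV
#' `agb_cv`; soil and plant covariates are Gaussian at the template
#' means/SDs, truncated at physical bounds (non-negative; SM within
#' 0-100%). The true stage label is emitted in the `stage` column so
#' stage-recovery can be scored. Fully reproducible from `rng_seed`.
#'
#' @param config A [generator_config()].
#' @return A `survey_table` whose `stage` column holds the ground-truth
#'   stage of each quadrat.
#' @export
generate_survey <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    abort_schema("'config' must be a generator_config")
  }
  local_seed(config$rng_seed, {
    universe <- unique(unlist(lapply(config$templates,
                                     function(t) t$species_pool$species)))
    n <- config$n_quadrats_per_stage
    total <- 4L * n
    sp_mat <- matrix(0, nrow = total, ncol = length(universe),
                     dimnames = list(NULL, universe))
    cov_names <- setdiff(.covariate_cols, "agb")
    cov_mat <- matrix(NA_real_, nrow = total, ncol = length(cov_names),
                      dimnames = list(NULL, cov_names))
    quadrat_id <- character(total)
    transect_id <- character(total)
    stage <- integer(total)
    agb <- numeric(total)
    k <- 0
    for (tmpl in config$templates) {
      pool <- tmpl$species_pool
      for (q in seq_len(n)) {
        present <- draw_presence(nrow(pool), tmpl$detection_prob)
        biomass <- draw_biomass(pool, present, tmpl)
        k <- k + 1
        sp_mat[k, pool$species[present]] <- biomass
        cov_mat[k, ] <- draw_covariates(tmpl)
        quadrat_id[k] <- sprintf("S%d_Q%04d", tmpl$stage, q)
        transect_id[k] <- sprintf("S%d_T%02d", tmpl$stage, (q - 1) %/% 3 + 1)
        stage[k] <- tmpl$stage
        agb[k] <- sum(biomass)
      }
    }
    colnames(sp_mat) <- paste0(.species_prefix, universe)
    out <- dplyr::bind_cols(
      tibble::tibble(
        quadrat_id = quadrat_id, transect_id = transect_id,
        stage = stage, agb = agb
      ),
      tibble::as_tibble(cov_mat),
      tibble::as_tibble(sp_mat)
    )
    as_survey_table(out)
  })
}

draw_presence <- function(n_pool, detection_prob, max_retries = 100) {
  for (i in seq_len(max_retries)) {
    present <- rbinom(n_pool, 1, detection_prob) == 1
    if (any(present)) return(present)
  }
  abort_validation(paste0(
    "no species present after ", max_retries,
    " occurrence redraws; detection_prob is too small"
  ))
}

draw_biomass <- function(pool, present, tmpl) {
  sub <- pool[present, ]
  # target share per present species: the group's expected share split
  # across present group members by dominance weight
  target <- numeric(nrow(sub))
  for (g in unique(sub$group)) {
    idx <- sub$group == g
    w <- sub$weight[idx]
    target[idx] <- tmpl$fg_proportions[[g]] * w / sum(w)
  }
  if (sum(target) == 0) target <- rep(1, length(target))
  shares <- rdirichlet1(tmpl$biomass_dispersion * target / sum(target))
  sdlog <- sqrt(log(1 + tmpl$agb_cv^2))
  total <- rlnorm(1, meanlog = log(tmpl$agb_mean) - sdlog^2 / 2, sdlog = sdlog)
  shares * total
}

draw_covariates <- function(tmpl) {
  nm <- names(tmpl$soil_means)
  upper <- ifelse(nm == "sm", 100, Inf)
  vals <- vapply(seq_along(nm), function(i) {
    rnorm_trunc(1, tmpl$soil_means[[i]], tmpl$soil_sds[[i]],
                lower = 0, upper = upper[i])
  }, numeric(1))
  setNames(vals, nm)
}
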