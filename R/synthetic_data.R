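#' Generative model of segment-level endophyte colonization
#'
#' Defines the parameters of a synthetic colonization survey with the study's
#' factorial structure: `n_species` taxa whose base per-segment colonization
#' probabilities follow a geometric ranked-abundance series
#' `p_i = base_rate * abundance_shape^(i-1)`, modulated multiplicatively by
#' per-level season, site and tissue effects (and optional interaction
#' multipliers).  The defaults mirror the survey design — 24 species, 3
#' seasons x 6 sites x 3 tissues, 45 segments per replicate and 3 replicates
#' per cell (135 segments per cell) — with `base_rate` set so that a null
#' model yields on the order of 1.9e3 isolates in total, the scale of the
#' field data.
#'
#' @param n_species Number of species in the pool.
#' @param abundance_shape Geometric-series ratio `k` in (0, 1); smaller values
#'   concentrate colonization in a few dominant species.
#' @param base_rate Per-segment colonization probability of the top-ranked
#'   species before factor effects.
#' @param season_effects,site_effects,tissue_effects Positive multiplicative
#'   modifiers, one per factor level (named or positional).
#' @param interaction_effects Optional data frame with a `multiplier` column
#'   and any subset of `season`, `site`, `tissue` columns; each row multiplies
#'   the colonization probability of every matching cell.
#' @param segments_per_replicate,replicates_per_cell Segment design.
#' @return An object of class `community_model`.
#' @seealso [simulate_isolations()], [recovery_experiment()]
#' @export
community_model <- function(n_species = 24, abundance_shape = 0.75,
                            base_rate = 0.065,
                            season_effects = c(winter = 1, summer = 1, rainy = 1),
                            site_effects = rep(1, 6),
                            tissue_effects = c(leaf = 1, stem = 1, petiole = 1),
                            interaction_effects = NULL,
                            segments_per_replicate = 45,
                            replicates_per_cell = 3) {
  stopifnot(n_species >= 1,
            abundance_shape > 0, abundance_shape < 1,
            base_rate >= 0,
            segments_per_replicate >= 1, replicates_per_cell >= 1)
  if (any(c(season_effects, site_effects, tissue_effects) <= 0)) {
    stop("factor effect multipliers must be positive", call. = FALSE)
  }
  if (is.null(names(season_effects))) {
    names(season_effects) <- season_levels[seq_along(season_effects)]
  }
  if (is.null(names(site_effects))) {
    names(site_effects) <- seq_along(site_effects)
  }
  if (is.null(names(tissue_effects))) {
    names(tissue_effects) <- tissue_levels[seq_along(tissue_effects)]
  }
  if (!is.null(interaction_effects)) {
    stopifnot(is.data.frame(interaction_effects),
              "multiplier" %in% names(interaction_effects),
              all(interaction_effects$multiplier > 0))
  }
  structure(
    list(n_species = n_species, abundance_shape = abundance_shape,
         base_rate = base_rate,
         season_effects = season_effects, site_effects = site_effects,
         tissue_effects = tissue_effects,
         interaction_effects = interaction_effects,
         segments_per_replicate = segments_per_replicate,
         replicates_per_cell = replicates_per_cell),
    class = "community_model"
  )
}

#' @export
print.community_model <- function(x, ...) {
  cat(sprintf(
    "Community model: %d species (geometric k = %.2f, base rate = %.3f)\n",
    x$n_species, x$abundance_shape, x$base_rate))
  cat(sprintf("Design: %d seasons x %d sites x %d tissues, %d x %d segments/cell\n",
              length(x$season_effects), length(x$site_effects),
              length(x$tissue_effects), x$segments_per_replicate,
              x$replicates_per_cell))
  invisible(x)
}

# Per-(cell, species) colonization probabilities, clamped to [0, 1].
model_probabilities <- function(model) {
  sp <- sprintf("sp%02d", seq_len(model$n_species))
  base <- model$base_rate * model$abundance_shape^(seq_len(model$n_species) - 1)
  cells <- tidyr::expand_grid(
    season = factor(names(model$season_effects),
                    levels = names(model$season_effects)),
    site = as.integer(names(model$site_effects)),
    tissue = factor(names(model$tissue_effects),
                    levels = names(model$tissue_effects))
  )
  grid <- tidyr::expand_grid(cells, species = factor(sp, levels = sp))
  prob <- base[as.integer(grid$species)] *
    model$season_effects[as.character(grid$season)] *
    model$site_effects[as.character(grid$site)] *
    model$tissue_effects[as.character(grid$tissue)]
  if (!is.null(model$interaction_effects)) {
    ie <- model$interaction_effects
    keys <- intersect(c("season", "site", "tissue"), names(ie))
    for (k in seq_len(nrow(ie))) {
      hit <- rep(TRUE, nrow(grid))
      for (col in keys) {
        if (!is.na(ie[[col]][k])) {
          hit <- hit & as.character(grid[[col]]) == as.character(ie[[col]][k])
        }
      }
      prob[hit] <- prob[hit] * ie$multiplier[k]
    }
  }
  grid$prob <- pmin(prob, 1)
  grid$clamped <- prob > 1
  grid
}

#' Simulate a segment-level colonization survey
#'
#' Draws independent per-segment occupancy for every (cell, replicate,
#' segment, species) combination at the model's clamped probabilities, then
#' aggregates to per-replicate species counts, per-replicate isolate totals
#' (the ANOVA response) and a per-cell percent CF matrix.
#'
#' @param model A [community_model()].
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list of class `mycodiv_sim` with elements `observations`
#'   (species x replicate counts), `replicates` (per-replicate isolate totals
#'   and richness), `cf` (long CF tibble), `n_clamped` (number of
#'   probability-clamping events), `model` and `rng` (RNG metadata).
#' @examples
#' sim <- simulate_isolations(community_model(), seed = 7)
#' head(sim$replicates)
#' @export
simulate_isolations <- function(model, seed = NULL) {
  stopifnot(inherits(model, "community_model"))
  if (!is.null(seed)) set.seed(seed)
  pr <- model_probabilities(model)
  r <- model$replicates_per_cell
  nseg <- model$segments_per_replicate
  obs <- tidyr::expand_grid(pr, replicate = seq_len(r)) |>
    dplyr::mutate(isolates = rbinom(dplyr::n(), nseg, .data$prob)) |>
    dplyr::select("season", "site", "tissue", "replicate", "species",
                  "isolates")
  replicates <- obs |>
    dplyr::group_by(.data$season, .data$site, .data$tissue, .data$replicate) |>
    dplyr::summarise(count = sum(.data$isolates),
                     richness = sum(.data$isolates > 0), .groups = "drop")
  cf <- obs |>
    dplyr::group_by(.data$season, .data$site, .data$tissue, .data$species) |>
    dplyr::summarise(isolates = sum(.data$isolates), .groups = "drop") |>
    dplyr::mutate(cf = colonization_frequency(.data$isolates, nseg * r)) |>
    dplyr::select("species", "season", "site", "tissue", "cf")
  structure(
    list(observations = obs, replicates = replicates, cf = new_cf_tbl(cf),
         n_clamped = sum(pr$clamped) * r, model = model,
         rng = list(kind = RNGkind(), seed = seed)),
    class = "mycodiv_sim"
  )
}

#' @export
print.mycodiv_sim <- function(x, ...) {
  cat(sprintf("Simulated survey: %d observations, %d isolates total",
              nrow(x$observations), sum(x$observations$isolates)))
  if (x$n_clamped > 0) cat(sprintf(" (%d clamped draws)", x$n_clamped))
  cat("\n")
  invisible(x)
}

#' Estimator-recovery experiment over repeated simulations
#'
#' Repeatedly simulates surveys from a model and summarizes, per simulation,
#' how well the pipeline's estimators recover the generating community:
#' observed richness versus the species pool, Shannon and Simpson indices of
#' the pooled observed counts versus the indices of the generating
#' ranked-abundance distribution, and the three-way ANOVA p-value (and
#' rejection at `alpha`) for each source.
#'
#' @param model A [community_model()].
#' @param n_sims Number of simulated surveys.
#' @param alpha Rejection level for the ANOVA sources.
#' @param seed Optional integer seed for the whole experiment.
#' @return A tibble with one row per simulation: `sim`, `richness_obs`,
#'   `shannon_obs`, `simpson_obs`, the constant `shannon_gen`/`simpson_gen`
#'   of the generating distribution, `p_<source>` and `reject_<source>`
#'   columns for the seven ANOVA sources.
#' @examples
#' m <- community_model(n_species = 6, site_effects = rep(1, 2))
#' recovery_experiment(m, n_sims = 3, seed = 1)
#' @export
recovery_experiment <- function(model, n_sims, alpha = 0.05, seed = NULL) {
  stopifnot(n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  q <- model$abundance_shape^(seq_len(model$n_species) - 1)
  q <- q / sum(q)
  shannon_gen <- -sum(q * log(q))
  simpson_gen <- sum(q^2)
  sources <- c("season", "site", "tissue", "season:site", "season:tissue",
               "site:tissue", "season:site:tissue")
  rows <- purrr::map(seq_len(n_sims), function(i) {
    sim <- simulate_isolations(model)
    pooled <- tapply(sim$observations$isolates, sim$observations$species, sum)
    fit <- anova_three_way(sim$replicates, response = "count")
    p <- setNames(fit$table$p.value[1:7], fit$table$term[1:7])[sources]
    out <- tibble(sim = i,
                  richness_obs = sum(pooled > 0),
                  shannon_obs = shannon(pooled),
                  simpson_obs = simpson_dominance(pooled),
                  shannon_gen = shannon_gen, simpson_gen = simpson_gen)
    pt <- tibble::as_tibble_row(setNames(as.list(p), paste0("p_", sources)))
    rt <- tibble::as_tibble_row(setNames(as.list(p < alpha),
                                         paste0("reject_", sources)))
    dplyr::bind_cols(out, pt, rt)
  })
  purrr::list_rbind(rows)
}
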