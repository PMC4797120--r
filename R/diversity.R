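#' Percent colonization frequency
#'
#' CF is the percentage of incubated tissue segments from which a given
#' endophyte was cultured: `colonized / total * 100`.
#'
#' @param colonized Number of segments colonized by the taxon (vectorized).
#' @param total Total number of segments incubated.
#' @return Percent CF in \[0, 100\].
#' @examples
#' colonization_frequency(9, 45)
#' @export
colonization_frequency <- function(colonized, total) {
  if (any(total < 1)) stop("total segments must be >= 1", call. = FALSE)
  if (any(colonized < 0)) stop("colonized segments must be >= 0", call. = FALSE)
  if (any(colonized > total)) {
    stop("colonized segments exceed total segments", call. = FALSE)
  }
  colonized / total * 100
}

#' Species richness
#'
#' Number of species with a positive count in an abundance vector.
#'
#' @param counts Nonnegative numeric vector of per-species isolate counts.
#' @return Integer richness.
#' @export
species_richness <- function(counts) {
  stopifnot(is.numeric(counts))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  sum(counts > 0)
}

#' Gleason richness index
#'
#' `G = (Np - 1) / ln(S)`, a richness statistic only weakly dependent on the
#' number of isolates `S`.
#'
#' @param richness Species richness `Np` (>= 1).
#' @param n_isolates Total isolates `S` (>= 2, so that `ln(S) > 0`).
#' @return Dimensionless index.
#' @examples
#' gleason(17, 762)
#' @export
gleason <- function(richness, n_isolates) {
  stopifnot(richness >= 1)
  if (any(n_isolates < 2)) {
    stop("Gleason index needs n_isolates >= 2 (ln would be <= 0)",
         call. = FALSE)
  }
  (richness - 1) / log(n_isolates)
}

#' Relative Gleason index
#'
#' `GR = (Np - 1) / S`: richness per isolate, the ratio of species richness
#' over sampling effort.
#'
#' @inheritParams gleason
#' @export
relative_gleason <- function(richness, n_isolates) {
  stopifnot(richness >= 1)
  if (any(n_isolates < 1)) stop("n_isolates must be >= 1", call. = FALSE)
  (richness - 1) / n_isolates
}

#' Simpson dominance
#'
#' `D = sum(p_i^2)`: the probability that two isolates drawn at random belong
#' to the same species.  High values indicate dominance by one or two species.
#'
#' @inheritParams species_richness
#' @return `D` in \[1/Np, 1\].
#' @examples
#' simpson_dominance(c(1, 2, 3))
#' @export
simpson_dominance <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  p <- counts / total
  sum(p^2)
}

#' Simpson diversity (complement of dominance)
#'
#' @param D Simpson dominance in \[0, 1\].
#' @return `1 - D`.
#' @export
simpson_diversity <- function(D) {
  if (any(D < 0 | D > 1)) stop("D must lie in [0, 1]", call. = FALSE)
  1 - D
}

#' Shannon-Wiener index
#'
#' `H' = -sum(p_i * ln(p_i))` over species with positive counts, in nats.
#'
#' @inheritParams species_richness
#' @export
shannon <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `E = H' / ln(Np)`, the Shannon index normalized by its maximum for the
#' observed richness; 1 means a perfectly even community.  Values above 1
#' (possible only through rounding of the inputs) are clamped with a warning.
#'
#' @param H Shannon-Wiener index in nats.
#' @param richness Species richness (>= 2; for a single species the ratio is
#'   undefined).
#' @export
pielou <- function(H, richness) {
  if (any(richness < 2)) {
    stop("Pielou evenness is undefined for richness < 2", call. = FALSE)
  }
  if (any(H < 0)) stop("H must be nonnegative", call. = FALSE)
  E <- H / log(richness)
  if (any(E > 1)) {
    warning("evenness above 1 clamped (inconsistent H/richness inputs)")
    E <- pmin(E, 1)
  }
  E
}

#' Full diversity profile of one abundance vector
#'
#' Computes the complete index row used in survey summaries: isolate count
#' `S`, richness `Np`, Gleason `G`, relative Gleason `GR`, Simpson dominance
#' `D` and its complement, Shannon `H` (nats), and Pielou evenness `E`.
#' A degenerate single-species vector is reported with `E = 1` (trivially
#' even) alongside a warning.
#'
#' @inheritParams species_richness
#' @param label Name of the grouping this vector summarizes.
#' @return A one-row tibble with columns `label, S, Np, G, GR, D,
#'   one_minus_D, H, E`.
#' @examples
#' diversity_profile(c(1, 2, 3), "toy")
#' @export
diversity_profile <- function(counts, label = "") {
  S <- sum(counts)
  if (S <= 0) stop("total count must be positive", call. = FALSE)
  Np <- species_richness(counts)
  G <- if (Np == 1) 0 else gleason(Np, S)
  GR <- relative_gleason(Np, S)
  D <- simpson_dominance(counts)
  H <- shannon(counts)
  if (Np < 2) {
    warning("single-species community: evenness reported as 1 by convention")
    E <- 1
  } else {
    E <- pielou(H, Np)
  }
  tibble(label = label, S = S, Np = Np, G = G, GR = GR,
         D = D, one_minus_D = 1 - D, H = H, E = E)
}

#' Diversity table by season, site or tissue
#'
#' The full pipeline from a long CF tibble to a survey-style diversity table:
#' CF values are converted to isolate counts under the segment design,
#' marginalized to one abundance vector per level of `by`, and profiled with
#' [diversity_profile()].
#'
#' @param x A long CF tibble (see [read_cf_matrix()]).
#' @param by One of `"season"`, `"site"`, `"tissue"`.
#' @inheritParams cf_to_counts
#' @return A tibble with one diversity row per level, classed
#'   `mycodiv_diversity` for [autoplot()][ggplot2::autoplot].
#' @examples
#' load_survey_cf() |> diversity_table("season")
#' @export
diversity_table <- function(x, by, segments_per_replicate = 45,
                            replicates_per_cell = 3) {
  counts <- if ("count" %in% names(x)) x
  else cf_to_counts(x, segments_per_replicate, replicates_per_cell)
  marg <- marginalize(counts, by)
  levs <- split(marg, marg[[by]], drop = TRUE)
  out <- purrr::imap(levs, \(d, l) diversity_profile(d$count, as.character(l))) |>
    purrr::list_rbind()
  class(out) <- c("mycodiv_diversity", class(out))
  attr(out, "by") <- by
  out
}
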