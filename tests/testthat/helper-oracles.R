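# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own code paths: plain loops and a regression fit.

shannon_brute <- function(counts) {
  total <- 0
  for (c_i in counts) total <- total + c_i
  h <- 0
  for (c_i in counts) {
    if (c_i > 0) {
      p <- c_i / total
      h <- h - p * log(p)
    }
  }
  h
}

simpson_brute <- function(counts) {
  total <- 0
  for (c_i in counts) total <- total + c_i
  d <- 0
  for (c_i in counts) d <- d + (c_i / total)^2
  d
}

# bitmask-style intersection/union count over an explicit universe
jaccard_brute <- function(a, b, universe = union(a, b)) {
  in_a <- universe %in% a
  in_b <- universe %in% b
  n_union <- sum(in_a | in_b)
  if (n_union == 0) return(100)
  100 * sum(in_a & in_b) / n_union
}

# Least-squares oracle: sequential sums of squares from a full factorial
# regression (identical to any SS type in a balanced design).  Returns SS in
# the package's term order plus the residual.
anova_lm_oracle <- function(d, response = "count") {
  form <- stats::as.formula(paste(
    response, "~ factor(season) * factor(site) * factor(tissue)"))
  tab <- stats::anova(stats::lm(form, data = d))
  ss <- tab[["Sum Sq"]]
  names(ss) <- rownames(tab)
  ord <- c("factor(season)", "factor(site)", "factor(tissue)",
           "factor(season):factor(site)", "factor(season):factor(tissue)",
           "factor(site):factor(tissue)",
           "factor(season):factor(site):factor(tissue)", "Residuals")
  unname(ss[ord])
}

# random balanced factorial dataset in the package's long layout
random_balanced <- function(a = 3, b = 6, cc = 3, r = 3, mu = 20, sd = 3) {
  d <- expand.grid(season = seq_len(a), site = seq_len(b),
                   tissue = seq_len(cc), replicate = seq_len(r))
  d$count <- stats::rnorm(nrow(d), mu, sd)
  d
}

random_abundance <- function(n_species = NULL) {
  if (is.null(n_species)) n_species <- sample(1:30, 1)
  counts <- stats::rpois(n_species, lambda = stats::runif(1, 0.5, 30))
  if (sum(counts) == 0) counts[sample(n_species, 1)] <- 1L
  counts
}

toy_cf <- function() {
  tibble::tibble(
    species = factor(rep(c("a", "b"), each = 2)),
    season = factor(rep("winter", 4), levels = c("winter", "summer", "rainy")),
    site = rep(1:2, times = 2),
    tissue = factor(rep("leaf", 4), levels = c("leaf", "stem", "petiole")),
    cf = c(10, 0, 20, 40)
  )
}
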