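#' Jaccard similarity between two species sets
#'
#' `J = 100 * |A intersect B| / |A union B|`, the shared-species fraction in
#' percent.  Two empty communities are identical by convention (`J = 100`),
#' which keeps the coefficient reflexive and avoids 0/0.
#'
#' @param a,b Character vectors of species identifiers (duplicates ignored).
#' @return Percent similarity in \[0, 100\].
#' @examples
#' jaccard(c("a", "b", "c"), c("b", "c", "d"))
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0) return(100)
  100 * length(intersect(a, b)) / length(u)
}

#' Pairwise Jaccard similarity matrix
#'
#' Builds the full symmetric site-by-site similarity matrix from a presence
#' map (as returned by [presence_absence()]).  The diagonal is exactly 100.
#'
#' @param presence Named list mapping each label to its species set.
#' @param digits Digits to round to; the survey tables print whole percents
#'   (`digits = 0`).  Use `NULL` for full precision.
#' @return A symmetric numeric matrix classed `mycodiv_jaccard`.
#' @examples
#' load_survey_cf() |> presence_absence("site") |> pairwise_jaccard()
#' @export
pairwise_jaccard <- function(presence, digits = 0) {
  stopifnot(is.list(presence), length(presence) >= 1)
  n <- length(presence)
  labs <- names(presence)
  if (is.null(labs)) labs <- paste0("set", seq_len(n))
  m <- diag(100, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- jaccard(presence[[i]], presence[[j]])
      }
    }
  }
  if (!is.null(digits)) m <- round(m, digits)
  dimnames(m) <- list(labs, labs)
  class(m) <- c("mycodiv_jaccard", class(m))
  m
}

#' Tidy a Jaccard similarity matrix
#'
#' @param x A matrix from [pairwise_jaccard()].
#' @param lower_tri Keep only the lower triangle (including the diagonal),
#'   mirroring the printed layout of site-similarity tables.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `similarity`.
#' @method tidy mycodiv_jaccard
#' @export
tidy.mycodiv_jaccard <- function(x, lower_tri = FALSE, ...) {
  m <- unclass(x)
  out <- tibble(
    from = rep(rownames(m), times = ncol(m)),
    to = rep(colnames(m), each = nrow(m)),
    similarity = as.vector(m)
  )
  if (lower_tri) {
    keep <- rep(seq_len(nrow(m)), times = ncol(m)) >=
      rep(seq_len(ncol(m)), each = nrow(m))
    out <- out[keep, ]
  }
  out
}

#' @export
print.mycodiv_jaccard <- function(x, ...) {
  cat("Jaccard similarity (%), ", nrow(x), " communities\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
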