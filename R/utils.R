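#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest
#' @importFrom purrr map map_dbl map2 imap pmap
NULL

# internal argument checks ----------------------------------------------------

stop_invalid <- function(msg) abort(msg, class = "sorgal_invalid_argument")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_invalid(sprintf("`%s` must be a whole number >= %d", name, min))
  }
  as.integer(x)
}

check_prob_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop_invalid(sprintf("`%s` must lie strictly in (0, 1)", name))
  }
  x
}

check_cols <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(sprintf("`%s` is missing column(s): %s", name,
                         paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Haldane map function
#'
#' Converts a genetic map distance in centimorgans to a recombination
#' fraction assuming crossovers occur without interference.
#'
#' @param cm Map distance in centimorgans (non-negative).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
#' @examples
#' haldane(0)    # complete linkage
#' haldane(10)   # ~0.0906
haldane <- function(cm) {
  if (any(cm < 0)) stop_invalid("map distances must be non-negative")
  (1 - exp(-2 * cm / 100)) / 2
}

# Dirichlet draw: rows are independent draws for one shape vector each
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # guard all-zero rows (possible for tiny shapes): fall back to one-hot
  s <- rowSums(x)
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    for (i in which(bad)) {
      x[i, ] <- 0
      x[i, sample.int(k, 1)] <- 1
    }
    s <- rowSums(x)
  }
  x / s
}
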