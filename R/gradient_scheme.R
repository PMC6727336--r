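#' Build a diffusion gradient scheme
#'
#' Constructs the acquisition table for a multi-shell diffusion experiment:
#' one unweighted (b = 0) volume per zero entry of `b_values` and
#' `n_directions` diffusion-weighted volumes for every non-zero b-value. The
#' default reproduces a breast DTI protocol with six gradient directions and
#' b = 0, 100, 800 s/mm^2 (13 volumes in total).
#'
#' The default six-direction set is the balanced dual-gradient scheme
#' \{(1,1,0), (1,0,1), (0,1,1), (1,-1,0), (1,0,-1), (0,1,-1)\}/sqrt(2), whose
#' direction outer products sum to 2I, so the 7-parameter log-linear tensor
#' design is full rank. For `n_directions > 6` a deterministic spherical
#' Fibonacci point set is used.
#'
#' @param n_directions Number of diffusion-encoding directions (>= 6; fewer
#'   directions cannot determine the six unique tensor elements).
#' @param b_values Numeric vector of b-values in s/mm^2; must contain 0.
#' @param directions Optional `n_directions` x 3 matrix of directions
#'   (normalized to unit length if needed).
#' @return An object of class `gradient_scheme`: a list with `b` (length-n
#'   vector of b-values per volume) and `g` (n x 3 matrix of unit directions;
#'   zero rows for b = 0 volumes).
#' @examples
#' scheme <- make_gradient_scheme(6, c(0, 100, 800))
#' length(scheme$b)  # 13 volumes
#' @export
make_gradient_scheme <- function(n_directions = 6L,
                                 b_values = c(0, 100, 800),
                                 directions = NULL) {
  n_directions <- as.integer(n_directions)
  if (n_directions < 6L) {
    stopf("degenerate design: %d directions cannot determine the 6 unique tensor elements (need >= 6)",
          n_directions)
  }
  if (!any(b_values == 0)) {
    stopf("b_values must include 0 (an unweighted volume is required to estimate S0)")
  }
  if (is.null(directions)) {
    directions <- default_directions(n_directions)
  } else {
    directions <- as.matrix(directions)
    if (nrow(directions) != n_directions || ncol(directions) != 3L) {
      stopf("directions must be an %d x 3 matrix", n_directions)
    }
    nrm <- sqrt(rowSums(directions^2))
    if (any(nrm == 0)) stopf("zero-length gradient direction supplied")
    directions <- directions / nrm
  }

  b <- numeric(0)
  g <- matrix(numeric(0), ncol = 3)
  for (bv in b_values) {
    if (bv == 0) {
      b <- c(b, 0)
      g <- rbind(g, c(0, 0, 0))
    } else {
      b <- c(b, rep(bv, n_directions))
      g <- rbind(g, directions)
    }
  }
  structure(
    list(b = b, g = unname(g), n_directions = n_directions,
         b_values = sort(unique(b_values)), directions = unname(directions)),
    class = "gradient_scheme"
  )
}

# Balanced dual-gradient set for n = 6; spherical Fibonacci points otherwise.
default_directions <- function(n) {
  if (n == 6L) {
    d <- rbind(
      c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
      c(1, -1, 0), c(1, 0, -1), c(0, 1, -1)
    ) / sqrt(2)
    return(d)
  }
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}

#' @method print gradient_scheme
#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme: %d volumes (%d directions; b = %s s/mm^2)\n",
              length(x$b), x$n_directions,
              paste(x$b_values, collapse = ", ")))
  invisible(x)
}
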