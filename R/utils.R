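# internal argument checking helpers

stop_domain <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain("`", name, "` must be a single finite number")
  if (x < lower || x > upper)
    stop_domain("`", name, "` must be in [", lower, ", ", upper, "]")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for the weight function exp(-x^2), computed by the
#' Golub-Welsch eigen decomposition of the Hermite Jacobi matrix. Used
#' internally for the adaptive quadrature of the year random intercept.
#'
#' @param q number of nodes (q = 1 gives the Laplace approximation).
#' @return list with `nodes` and `weights`, each length `q`.
#' @examples
#' gh <- gauss_hermite(5)
#' sum(gh$weights)           # integrates exp(-x^2): sqrt(pi)
#' sum(gh$weights * gh$nodes^2)  # sqrt(pi)/2
#' @export
gauss_hermite <- function(q) {
  check_number(q, "q", lower = 1)
  q <- as.integer(q)
  if (q == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(q - 1L)
  J <- matrix(0, q, q)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}
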