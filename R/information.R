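#' Fisher information for Dallal's model and its closed-form inverse
#'
#' With parameter vector `beta = (gamma_1..gamma_g, pi_1..pi_g)` the expected
#' information (expected negative Hessian of the log-likelihood) is block
#' sparse: groups are independent, and within group `i`
#' \deqn{I_{\gamma\gamma} = m_i(p_{2i}/\gamma_i^2 + p_{1i}/(1-\gamma_i)^2 +
#'       \pi_i^2/p_{0i}),\quad
#'       I_{\gamma\pi} = -m_i/p_{0i},\quad
#'       I_{\pi\pi} = m_i\left[(2-\gamma_i)/\pi_i +
#'       (2-\gamma_i)^2/p_{0i}\right].}
#' Its inverse has the same sparsity with per-group entries
#' \deqn{a_i = \gamma_i(\gamma_i-1)(\gamma_i-2)/(2 m_i \pi_i), \quad
#'       b_i = \pi_i(1+\gamma_i-2\pi_i)/(2 m_i), \quad
#'       c_i = -\gamma_i(\gamma_i-1)/(2 m_i),}
#' where `a_i` sits in the gamma block, `b_i` in the pi block and `c_i` in
#' the cross blocks. The Wald-type statistic uses only the `a_i`.
#'
#' @param pi,gamma Length-`g` interior parameters: all three cell
#'   probabilities must be strictly positive, i.e. `0 < pi < 1` and
#'   `gamma_lower_bound(pi) < gamma < 1` with `gamma > 0`.
#' @param group_sizes Length-`g` positive group sizes `m_i`.
#' @return A `2g x 2g` symmetric matrix, ordered
#'   `(gamma_1..gamma_g, pi_1..pi_g)`.
#' @examples
#' I <- information_matrix(0.5, 0.5, 10)
#' Iinv <- information_inverse(0.5, 0.5, 10)
#' round(I %*% Iinv, 10)
#' @export
information_matrix <- function(pi, gamma, group_sizes) {
  p <- check_interior(pi, gamma, group_sizes)
  g <- length(pi)
  m <- group_sizes
  Igg <- m * (p$p2 / gamma^2 + p$p1 / (1 - gamma)^2 + pi^2 / p$p0)
  Igp <- -m / p$p0
  Ipp <- m * ((2 - gamma) / pi + (2 - gamma)^2 / p$p0)
  out <- matrix(0, 2 * g, 2 * g)
  idx <- seq_len(g)
  out[cbind(idx, idx)] <- Igg
  out[cbind(g + idx, g + idx)] <- Ipp
  out[cbind(idx, g + idx)] <- Igp
  out[cbind(g + idx, idx)] <- Igp
  dimnames(out) <- info_dimnames(g)
  out
}

#' @rdname information_matrix
#' @export
information_inverse <- function(pi, gamma, group_sizes) {
  check_interior(pi, gamma, group_sizes)
  g <- length(pi)
  m <- group_sizes
  a <- gamma * (gamma - 1) * (gamma - 2) / (2 * m * pi)
  b <- pi * (1 + gamma - 2 * pi) / (2 * m)
  cc <- -gamma * (gamma - 1) / (2 * m)
  out <- matrix(0, 2 * g, 2 * g)
  idx <- seq_len(g)
  out[cbind(idx, idx)] <- a
  out[cbind(g + idx, g + idx)] <- b
  out[cbind(idx, g + idx)] <- cc
  out[cbind(g + idx, idx)] <- cc
  dimnames(out) <- info_dimnames(g)
  out
}

info_dimnames <- function(g) {
  nm <- c(paste0("gamma", seq_len(g)), paste0("pi", seq_len(g)))
  list(nm, nm)
}

check_interior <- function(pi, gamma, group_sizes) {
  g <- length(pi)
  if (length(gamma) != g || length(group_sizes) != g) {
    stop("pi, gamma and group_sizes must have equal length", call. = FALSE)
  }
  if (any(group_sizes <= 0)) stop("group sizes must be positive",
                                  call. = FALSE)
  check_dallal_params(pi, gamma)
  p <- dallal_probs(pi, gamma)
  if (any(p$p0 <= 0) || any(p$p1 <= 0) || any(p$p2 <= 0) ||
      any(gamma %in% c(0, 1)) || any(pi %in% c(0, 1))) {
    stop("information matrix requires interior parameters ",
         "(all cell probabilities strictly positive); got a boundary point",
         call. = FALSE)
  }
  p
}
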