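#' Shannon entropy of a host-use profile
#'
#' Entropy in nats of the proportions `p_j = w_j / sum(w)` derived from a
#' non-negative weight vector (egg counts or survival values over hosts),
#' with the convention `0 * log(0) = 0` so unused hosts contribute nothing.
#'
#' @param weights non-negative numeric vector with at least one positive
#'   entry.
#' @return entropy H in nats.
#' @export
shannon_entropy <- function(weights) {
  w <- check_profile(weights)
  p <- w[w > 0] / sum(w)
  -sum(p * log(p))
}

check_profile <- function(weights) {
  if (!is.numeric(weights) || length(weights) == 0L)
    stop("profile must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(weights) || any(weights < 0))
    stop("profile weights must be non-negative and finite", call. = FALSE)
  if (sum(weights) <= 0)
    stop("profile has no positive weight; diversity is undefined", call. = FALSE)
  weights
}

#' Hill diversity (numbers equivalent) of a host-use profile
#'
#' The effective number of equally common hosts producing the same diversity
#' index value: `D = (sum p_j^q)^(1/(1-q))` for `q != 1`, and `D = exp(H)`
#' (the numbers equivalent of Shannon entropy) at `q = 1`. A species using
#' 10 hosts very unevenly with `D = 2.08` behaves as if it were spread over
#' 2.08 equally common hosts. D is invariant to rescaling the raw weights.
#'
#' @param weights non-negative weights over hosts (zeros allowed, dropped
#'   before exponentiation so `q < 1` is well defined).
#' @param q diversity order, `q >= 0`; default 1.
#' @return effective number of hosts, in `[1, number of hosts with positive
#'   weight]`.
#' @export
hill_diversity <- function(weights, q = 1) {
  w <- check_profile(weights)
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0)
  p <- w[w > 0] / sum(w)
  if (abs(q - 1) < 1e-9) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Per-species alpha diversity of host use
#'
#' Column-wise Hill diversity of an interaction matrix: each fly species'
#' host-use profile (its column) is converted to the effective number of
#' equally common host plants. This per-species numbers equivalent is the
#' continuous degree-of-specialisation covariate used downstream.
#'
#' @param matrix plants-by-species interaction matrix (see
#'   [build_interaction_matrix()]); `NA` cells (unobserved survival) are
#'   dropped from the profile.
#' @param q diversity order; default 1.
#' @return named numeric vector, one effective host number per species.
#' @export
species_alpha <- function(matrix, q = 1) {
  stopifnot(is.matrix(matrix))
  labels <- if (is.null(colnames(matrix))) as.character(seq_len(ncol(matrix)))
            else colnames(matrix)
  out <- vapply(seq_len(ncol(matrix)), function(j) {
    w <- matrix[, j]
    w <- w[!is.na(w)]
    if (length(w) == 0L || sum(w) <= 0)
      stop(sprintf("species '%s' has an all-zero host-use profile", labels[j]),
           call. = FALSE)
    hill_diversity(w, q)
  }, numeric(1))
  stats::setNames(out, labels)
}

#' Community-level alpha diversity (multiplicative partitioning)
#'
#' Alpha diversity of order `q` across the species' host-use profiles under
#' Jost's multiplicative partitioning, with species weights `w_i`:
#' at `q = 1`, `exp(sum_i w_i H_i)`; otherwise
#' `(sum_ij (w_i p_ij)^q / sum_i w_i^q)^(1/(1-q))`. With identical columns
#' it reduces to the shared per-species value. Provided as the community-level
#' companion of [species_alpha()]; the degree-of-specialisation covariate is
#' the per-species value.
#'
#' @param matrix plants-by-species interaction matrix.
#' @param q diversity order; default 1.
#' @param column_weights species weights summing to 1; default equal.
#' @return community alpha diversity (effective hosts).
#' @export
jost_community_alpha <- function(matrix, q = 1, column_weights = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1L)
  if (is.null(column_weights))
    column_weights <- rep(1 / ncol(matrix), ncol(matrix))
  stopifnot(length(column_weights) == ncol(matrix),
            all(column_weights >= 0),
            abs(sum(column_weights) - 1) < 1e-8)
  P <- vapply(seq_len(ncol(matrix)), function(i) {
    w <- matrix[, i]
    w[is.na(w)] <- 0
    check_profile(w)
    w / sum(w)
  }, numeric(nrow(matrix)))
  if (abs(q - 1) < 1e-9) {
    H <- vapply(seq_len(ncol(P)), function(i) {
      p <- P[, i][P[, i] > 0]
      -sum(p * log(p))
    }, numeric(1))
    exp(sum(column_weights * H))
  } else {
    wp <- sweep(P, 2, column_weights, `*`)
    (sum(wp[wp > 0]^q) / sum(column_weights[column_weights > 0]^q))^(1 / (1 - q))
  }
}
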