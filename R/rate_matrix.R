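# Rate matrix of the lineage-count / allele-count Markov chain.
#
# States are pairs (n, r): n ancestral lineages of which r carry the red
# allele, 0 <= r <= n <= M, including the placeholder (0, 0); a partial
# likelihood vector has l = (M + 1)(M + 2)/2 entries.  The index map is a
# triangular ranking (only the (n, r) semantics matter).

#' Number of (n, r) states for a maximum of M lineages
#' @param M maximum number of lineages.
#' @export
n_states <- function(M) ((M + 1L) * (M + 2L)) %/% 2L

#' Triangular index of state (n, r)
#'
#' 1-based position of state (n, r) in partial-likelihood vectors.
#' @param n,r lineage and red-lineage counts, 0 <= r <= n.
#' @export
state_index <- function(n, r) (n * (n + 1L)) %/% 2L + r + 1L

# inverse: matrix with columns n, r for indices 1..l
state_table <- function(M) {
  n <- rep.int(0:M, 1:(M + 1L))
  r <- sequence(1:(M + 1L)) - 1L
  cbind(n = n, r = r)
}

#' Transition rate matrix for a branch
#'
#' Builds the generator Q of the continuous-time Markov chain over (n, r)
#' states on a branch with population mutation rate `theta`: going up the
#' branch (backward in time) lineages coalesce at pairwise rate 2/theta
#' while alleles mutate at rates u (red -> green) and v (green -> red),
#' acting on partial-likelihood vectors as F exp(Qt).  Entries:
#' (n,r) -> (n,r-1): (n-r+1) v;  (n,r) -> (n,r+1): (r+1) u;
#' (n,r) -> (n-1,r): (n-1-r) n / theta;  (n,r) -> (n-1,r-1): (r-1) n / theta;
#' diagonal -n(n-1)/theta - (n-r) v - r u.  The (0,0) row is zero.
#'
#' @param theta positive population mutation rate of the branch.
#' @param model a [mutation_model()].
#' @param M maximum number of lineages (>= 1).
#' @return Dense l x l matrix, l = (M+1)(M+2)/2.
#' @export
build_rate_matrix <- function(theta, model, M) {
  if (theta <= 0) stop("theta must be positive")
  if (M < 1) stop("M must be at least 1")
  u <- model$u; v <- model$v
  l <- n_states(M)
  Q <- matrix(0, l, l)
  for (n in 1:M) for (r in 0:n) {
    i <- state_index(n, r)
    if (r - 1L >= 0L) Q[i, state_index(n, r - 1L)] <- (n - r + 1) * v
    if (r + 1L <= n) Q[i, state_index(n, r + 1L)] <- (r + 1) * u
    if (n - 1L >= r && n - 1L >= 0L && (n - 1 - r) > 0)
      Q[i, state_index(n - 1L, r)] <- (n - 1 - r) * n / theta
    if (r - 1L >= 0L && n - 1L >= r - 1L && (r - 1) > 0)
      Q[i, state_index(n - 1L, r - 1L)] <- (r - 1) * n / theta
    Q[i, i] <- -n * (n - 1) / theta - (n - r) * v - r * u
  }
  Q
}

#' Stationary distribution vector at the root
#'
#' Solves Q x = 0 (restricted to states with n >= 1, Q built with the
#' population mutation rate of the infinite branch above the root) and
#' normalizes so that x(1,0) + x(1,1) = 1.  Then x(n, r) = Pr[R = r | N = n]
#' for a sample from a single stationary population; the site likelihood is
#' the dot product of the summed partial likelihood at the root with x.
#'
#' @inheritParams build_rate_matrix
#' @return Numeric vector of length l (entry (0,0) is 0).
#' @export
root_stationary <- function(theta, model, M) {
  Q <- build_rate_matrix(theta, model, M)
  l <- n_states(M)
  sub <- Q[-1L, -1L, drop = FALSE]          # drop the (0,0) placeholder
  sv <- svd(sub)
  d <- sv$d
  if (d[length(d) - 1L] < 1e-8 * max(d))
    warning("root stationary null space is numerically degenerate (second singular value ",
            format(d[length(d) - 1L]), ")")
  x <- sv$v[, length(d)]
  x <- x / (x[state_index(1L, 0L) - 1L] + x[state_index(1L, 1L) - 1L])
  if (any(x < -1e-8)) warning("negative entries in the stationary vector")
  x[x < 0] <- 0
  c(0, x)
}
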