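# Labeled partial likelihoods (LPLs).
#
# An LPL is a pair (F, s): a partial-likelihood vector F over (n, r) states
# and an integer label vector s of length k (one coordinate per
# reticulation).  s[i] = 0 means "did not pass through a split at
# reticulation i"; split halves carry a shared fresh positive value so that
# they are recombined exactly once.  Two LPLs are compatible iff at every
# coordinate the labels are equal or at least one is 0.

#' Construct an LPL
#' @param F numeric partial-likelihood vector (length (M+1)(M+2)/2).
#' @param s integer label vector, one coordinate per reticulation.
#' @export
lpl <- function(F, s) structure(list(F = F, s = as.integer(s)), class = "lpl")

labels_compatible <- function(s1, s2) all(s1 == s2 | s1 == 0L | s2 == 0L)

merge_labels <- function(s1, s2) ifelse(s1 == 0L, s2, s1)

#' Leaf partial likelihoods
#'
#' Initial LPL at the bottom of an external branch: for co-dominant data,
#' F(n, r) = 1 exactly at the observed (n_x, r_x) (`leaf_partials`); for
#' dominant markers on diploids (`leaf_partials_dominant`), F is nonzero at
#' n = 2 n_x for r_x <= r <= 2 r_x with the probability of the observed
#' band pattern given r red among the 2 n_x lineages, where r - r_x
#' individuals are homozygous red, 2 r_x - r heterozygous and n_x - r_x
#' homozygous green:
#' F(2 n_x, r) = n_x! / ((r-r_x)! (2 r_x - r)! (n_x - r_x)!) *
#'               2^(2 r_x - r) / choose(2 n_x, r).
#'
#' @param n_x number of sampled lineages (haploid/co-dominant) or diploid
#'   individuals (dominant).
#' @param r_x observed red-lineage count (co-dominant) or number of
#'   band-present individuals (dominant).
#' @param k number of reticulations (label length).
#' @param M maximum total lineage count of the data set.
#' @param miss number of lineages with missing state; the leaf partial is
#'   summed over every red count consistent with the observed ones
#'   (co-dominant only).
#' @return A single [lpl()] with an all-zero label.
#' @export
leaf_partials <- function(n_x, r_x, k, M, miss = 0L) {
  if (r_x < 0 || r_x > n_x - miss) stop("red count r_x out of range 0..", n_x - miss)
  F <- numeric(n_states(M))
  for (r in r_x:(r_x + miss)) F[state_index(n_x, r)] <- 1
  lpl(F, integer(k))
}

#' @rdname leaf_partials
#' @export
leaf_partials_dominant <- function(n_x, r_x, k, M) {
  if (r_x < 0 || r_x > n_x) stop("band count r_x out of range 0..", n_x)
  if (2L * n_x > M) stop("2 * n_x exceeds M")
  F <- numeric(n_states(M))
  for (r in r_x:(2L * r_x)) {
    F[state_index(2L * n_x, r)] <-
      exp(lfactorial(n_x) - lfactorial(r - r_x) - lfactorial(2L * r_x - r) -
            lfactorial(n_x - r_x) + (2L * r_x - r) * log(2) -
            lchoose(2L * n_x, r))
  }
  lpl(F, integer(k))
}

#' Propagate LPLs from the bottom to the top of a branch
#'
#' Each (F, s) becomes (F exp(Q t), s); labels are unchanged.
#'
#' @param lpls list of [lpl()] objects at the bottom of the branch.
#' @param Q rate matrix of the branch (see [build_rate_matrix()]).
#' @param t branch length in expected mutations per site (>= 0).
#' @return List of LPLs at the top of the branch.
#' @export
propagate_top <- function(lpls, Q, t) {
  if (t < 0) stop("branch length must be nonnegative")
  if (t == 0) return(lpls)
  P <- as.matrix(Matrix::expm(Q * t))
  lapply(lpls, function(p) lpl(as.numeric(p$F %*% P), p$s))
}

#' Decompose-and-split at a reticulation node
#'
#' Implements the decompose-and-split operation: every LPL reaching the top
#' of the branch below a reticulation is decomposed into its single-support
#' components; each component with support (n_i, r_i) is split over all
#' bipartitions of its lineages between the two parent branches y and z.
#' The y-side carries delta = F(n_i, r_i) * choose(n_i, n_y) *
#' gamma^n_y (1-gamma)^(n_i - n_y) at (n_y, r_y), the z-side carries 1 at
#' (n_z, r_z) = (n_i - n_y, r_i - r_y), and both receive the same fresh
#' label value at the reticulation's coordinate.  Bipartitions that would
#' need more red lineages than a side has room for are skipped.
#'
#' @param lpls list of LPLs at the top of the branch below the reticulation.
#' @param gamma inheritance probability of parent branch y.
#' @param retic_id 0-based coordinate of the reticulation in label vectors.
#' @param counter current split counter o_j for this reticulation (fresh
#'   label values continue from it).
#' @return List with elements `y`, `z` (LPL lists for the bottoms of the two
#'   parent branches) and `counter` (updated o_j).
#' @export
split_at_reticulation <- function(lpls, gamma, retic_id, counter = 0L) {
  k <- if (length(lpls)) length(lpls[[1L]]$s) else 0L
  if (retic_id < 0L || retic_id >= k) stop("retic_id out of range 0..", k - 1L)
  M <- M_from_l(length(lpls[[1L]]$F))
  Py <- list(); Pz <- list()
  o <- as.integer(counter)
  for (p in lpls) {
    nz <- which(p$F != 0)
    if (!length(nz)) {            # empty support passes through unchanged
      Py[[length(Py) + 1L]] <- p
      Pz[[length(Pz) + 1L]] <- p
      next
    }
    st <- state_table(M)
    for (i in nz) {
      ni <- st[i, "n"]; ri <- st[i, "r"]
      val <- p$F[i]
      for (ny in 0:ni) {
        ry_lo <- max(0L, ri - (ni - ny))
        ry_hi <- min(ri, ny)
        if (ry_lo > ry_hi) next
        for (ry in ry_lo:ry_hi) {
          o <- o + 1L
          s2 <- p$s; s2[retic_id + 1L] <- o
          delta <- val * choose(ni, ny) * gamma^ny * (1 - gamma)^(ni - ny)
          Fy <- numeric(length(p$F)); Fy[state_index(ny, ry)] <- delta
          Fz <- numeric(length(p$F)); Fz[state_index(ni - ny, ri - ry)] <- 1
          Py[[length(Py) + 1L]] <- lpl(Fy, s2)
          Pz[[length(Pz) + 1L]] <- lpl(Fz, s2)
        }
      }
    }
  }
  list(y = Py, z = Pz, counter = o)
}

M_from_l <- function(l) {
  M <- as.integer(round((-3 + sqrt(1 + 8 * l)) / 2))
  stopifnot(n_states(M) == l)
  M
}

#' Merge LPL sets at a tree node
#'
#' For every compatible pair (F_y, s_y), (F_z, s_z) from the tops of the two
#' child branches, produces (F_x, s_x) at the bottom of the parent branch:
#' s_x takes the nonzero label coordinatewise, and F_x is the convolution
#' F_x(n, r) = sum F_y(n_y, r_y) F_z(n - n_y, r - r_y) *
#'   choose(r, r_y) choose(n - r, n_y - r_y) / choose(n, n_y),
#' the hypergeometric probability of the red lineages splitting between the
#' two sides.  Incompatible pairs contribute nothing.
#'
#' @param Py,Pz lists of LPLs at the tops of the two child branches.
#' @return List of LPLs for the bottom of the parent branch.
#' @export
merge_at_tree_node <- function(Py, Pz) {
  out <- list()
  for (py in Py) for (pz in Pz) {
    if (length(py$s) != length(pz$s)) stop("label-length mismatch")
    if (!labels_compatible(py$s, pz$s)) next
    out[[length(out) + 1L]] <- lpl(convolve_partials(py$F, pz$F),
                                   merge_labels(py$s, pz$s))
  }
  out
}

convolve_partials <- function(Fy, Fz) {
  l <- length(Fy)
  M <- M_from_l(l)
  st <- state_table(M)
  Fx <- numeric(l)
  iy <- which(Fy != 0)
  iz <- which(Fz != 0)
  for (a in iy) {
    ny <- st[a, "n"]; ry <- st[a, "r"]
    for (b in iz) {
      nzz <- st[b, "n"]; rz <- st[b, "r"]
      n <- ny + nzz
      if (n > M) next
      r <- ry + rz
      w <- choose(r, ry) * choose(n - r, ny - ry) / choose(n, ny)
      i <- state_index(n, r)
      Fx[i] <- Fx[i] + Fy[a] * Fz[b] * w
    }
  }
  Fx
}

#' Merge all LPLs at a lowest articulation node
#'
#' At a lowest articulation node every split initiated below has been
#' resolved, so the whole set collapses to a single LPL: the sum of the
#' partial-likelihood vectors with an all-zero (empty) label.
#'
#' @param lpls nonempty list of LPLs.
#' @return A list containing one LPL.
#' @export
merge_at_articulation <- function(lpls) {
  if (!length(lpls)) stop("empty LPL set")
  F <- Reduce(`+`, lapply(lpls, `[[`, "F"))
  list(lpl(F, integer(length(lpls[[1L]]$s))))
}
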