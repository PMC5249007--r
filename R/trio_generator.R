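## Seeded generators of random genomes and of genome trios with an exactly
## prescribed overlap structure (psi, omega12, omega13, omega23).

#' Uniform random genome
#'
#' Draws a genome uniformly at random over the perfect matchings of the 2n
#' gene ends: a random permutation of the ends paired off two by two.  The
#' result is always a valid genome, typically with several circular
#' chromosomes.  Randomness comes from R's global RNG; call
#' \code{set.seed} for reproducibility.
#'
#' @param n gene count, \code{n >= 1}.
#' @return a \code{"genome"} object.
#' @examples
#' set.seed(1)
#' random_genome(5)
#' @export
random_genome <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  validate_genome(matrix(sample.int(2L * n), ncol = 2L), n)
}

## round(n * p) as a nonnegative integer count
.prop_count <- function(n, p, what) {
  if (is.na(p) || p < 0 || p > 1)
    stop("proportion ", what, " must lie in [0, 1]")
  as.integer(round(n * p))
}

## uniform random matching of the given ends (0 or >=2 of them, even count)
.random_matching <- function(ends) {
  m <- length(ends)
  if (m == 0L) return(matrix(integer(0), ncol = 2L))
  matrix(ends[sample.int(m)], ncol = 2L)
}

#' Random genome trio with an exact overlap structure
#'
#' Generates three genomes on \code{n} genes such that the measured overlap
#' profile equals the request exactly: \code{round(n * psi)} adjacencies
#' common to all three, and \code{round(n * omega_ij)} common to exactly
#' each pair.  A random partial matching of the gene ends supplies the four
#' shared blocks (which are mutually end-disjoint), and each genome is then
#' completed independently by a uniform random matching of its remaining
#' free ends.  Accidental extra coincidences introduced by the completions
#' are detected and repaired by redrawing the completions (bounded retries),
#' so the profile contract is exact rather than in expectation.
#'
#' @param n gene count.
#' @param psi requested proportion of adjacencies common to all three.
#' @param omega12,omega13,omega23 requested proportions common to exactly
#'   each pair.
#' @param seed optional integer; if given, \code{set.seed(seed)} is called
#'   first so the trio is a pure function of its arguments.
#' @param max_retries maximum number of completion redraws before giving up
#'   (only tiny, near-saturated specs ever come close).
#' @return a list with elements \code{g1}, \code{g2}, \code{g3} (genomes)
#'   and \code{retries} (number of completion redraws that were needed).
#' @examples
#' trio <- random_trio(200, psi = 0.1, omega12 = 0.05, seed = 7)
#' overlap_profile(trio$g1, trio$g2, trio$g3)
#' @export
random_trio <- function(n, psi = 0, omega12 = 0, omega13 = 0, omega23 = 0,
                        seed = NULL, max_retries = 100L) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  kpsi <- .prop_count(n, psi, "psi")
  k12 <- .prop_count(n, omega12, "omega12")
  k13 <- .prop_count(n, omega13, "omega13")
  k23 <- .prop_count(n, omega23, "omega23")
  if (kpsi + k12 + k13 > n || kpsi + k12 + k23 > n || kpsi + k13 + k23 > n)
    stop("infeasible overlap spec: a genome's shared adjacencies exceed n")
  m <- kpsi + k12 + k13 + k23
  if (m > n)
    stop("infeasible overlap spec: the shared blocks are mutually ",
         "end-disjoint, so n*(psi + omega12 + omega13 + omega23) <= n ",
         "is required")

  ## shared backbone: one random partial matching, split into four blocks
  se <- sample.int(2L * n, 2L * m)
  pairs <- if (m > 0L) matrix(se, ncol = 2L) else matrix(integer(0), ncol = 2L)
  idx <- 0L
  take <- function(k) {
    block <- pairs[idx + seq_len(k), , drop = FALSE]
    idx <<- idx + k
    block
  }
  b_psi <- take(kpsi); b12 <- take(k12); b13 <- take(k13); b23 <- take(k23)

  shared <- list(g1 = rbind(b_psi, b12, b13),
                 g2 = rbind(b_psi, b12, b23),
                 g3 = rbind(b_psi, b13, b23))
  free <- lapply(shared, function(s) setdiff(seq_len(2L * n), as.vector(s)))

  target12 <- kpsi + k12; target13 <- kpsi + k13; target23 <- kpsi + k23
  for (retry in 0:max_retries) {
    gs <- mapply(function(s, f) validate_genome(rbind(s, .random_matching(f)), n),
                 shared, free, SIMPLIFY = FALSE)
    k1 <- .adj_keys(gs$g1$adj, n)
    k2 <- .adj_keys(gs$g2$adj, n)
    k3 <- .adj_keys(gs$g3$adj, n)
    in12 <- k1[k1 %in% k2]
    if (sum(k1 %in% k2) == target12 && sum(k1 %in% k3) == target13 &&
        sum(k2 %in% k3) == target23 && sum(in12 %in% k3) == kpsi)
      return(list(g1 = gs$g1, g2 = gs$g2, g3 = gs$g3, retries = retry))
  }
  stop("generation error: could not realize the exact overlap profile in ",
       max_retries, " completion redraws (spec too tight for this n)")
}
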