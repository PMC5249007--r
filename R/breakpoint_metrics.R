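## Breakpoint distance, distance sums, the normalized score, and the
## overlap structure (psi, omegas) of a genome trio.

#' Number of shared adjacencies between two genomes
#'
#' Counts the adjacencies (unordered pairs of gene ends) present in both
#' genomes.  Two independent random genomes on the same genes share only
#' O(1) adjacencies as n grows.
#'
#' @param g,h \code{"genome"} objects on the same \code{n} genes.
#' @return integer count \code{a}, with \code{0 <= a <= n}.
#' @seealso \code{\link{breakpoint_distance}}
#' @export
shared_adjacency_count <- function(g, h) {
  n <- .check_same_n(g, h)
  sum(.adj_keys(g$adj, n) %in% .adj_keys(h$adj, n))
}

#' Breakpoint distance between two genomes
#'
#' The breakpoint distance is \code{d = n - a}, where \code{a} is the number
#' of adjacencies the two genomes share.  It is a metric on genomes with
#' equal gene content: zero exactly on identical genomes, symmetric, and
#' satisfying the triangle inequality.
#'
#' @inheritParams shared_adjacency_count
#' @return integer distance in \code{0..n}.
#' @examples
#' g <- adjacencies_from_gene_order(c(1, 2, 3, 4))
#' h <- adjacencies_from_gene_order(c(1, 2, 4, 3))
#' breakpoint_distance(g, h)  # 3: only 1h-2t is shared
#' @export
breakpoint_distance <- function(g, h) {
  .check_same_n(g, h) - shared_adjacency_count(g, h)
}

#' Sum of breakpoint distances from one genome to a trio
#'
#' @param x a \code{"genome"}; the candidate whose distances are summed.
#' @param g1,g2,g3 the three input genomes.
#' @return integer \code{S = d(x,g1) + d(x,g2) + d(x,g3)}.
#' @seealso \code{\link{score}} for the normalized version.
#' @export
distance_sum <- function(x, g1, g2, g3) {
  .check_same_n(x, g1, g2, g3)
  breakpoint_distance(x, g1) + breakpoint_distance(x, g2) +
    breakpoint_distance(x, g3)
}

#' Normalized breakpoint score of a genome against a trio
#'
#' The score of \code{x} is the sum of its breakpoint distances to the three
#' input genomes divided by the gene count:
#' \code{s(x) = (1/n) * sum_i d(x, g_i)}, a value in \code{[0, 3]}.
#' A random genome scores close to 3; the anti-median construction attains
#' the maximal expected score among maximal samples.
#'
#' @inheritParams distance_sum
#' @return numeric score in \code{[0, 3]} (an exact multiple of \code{1/n}).
#' @export
score <- function(x, g1, g2, g3) {
  n <- .check_same_n(x, g1, g2, g3)
  distance_sum(x, g1, g2, g3) / n
}

#' Overlap structure of a genome trio
#'
#' Measures the proportions of shared adjacencies among three genomes:
#' \code{psi} is the proportion (of \code{n}) common to all three, and each
#' \code{omega_ij} the proportion common to exactly the pair \code{(i, j)}
#' (the three-way core is excluded, so psi and the omegas add without
#' double counting).
#'
#' @param g1,g2,g3 \code{"genome"} objects on the same \code{n} genes.
#' @return an object of class \code{"overlap_profile"}: a list with
#'   \code{n}, \code{psi}, \code{omega12}, \code{omega13}, \code{omega23}.
#' @export
overlap_profile <- function(g1, g2, g3) {
  n <- .check_same_n(g1, g2, g3)
  k1 <- .adj_keys(g1$adj, n)
  k2 <- .adj_keys(g2$adj, n)
  k3 <- .adj_keys(g3$adj, n)
  a12 <- sum(k1 %in% k2)
  a13 <- sum(k1 %in% k3)
  a23 <- sum(k2 %in% k3)
  a123 <- sum(k1[k1 %in% k2] %in% k3)
  structure(list(n = n,
                 psi = a123 / n,
                 omega12 = (a12 - a123) / n,
                 omega13 = (a13 - a123) / n,
                 omega23 = (a23 - a123) / n),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf(
    "Trio overlap profile (n = %d): psi = %.4f, omega12 = %.4f, omega13 = %.4f, omega23 = %.4f\n",
    x$n, x$psi, x$omega12, x$omega13, x$omega23))
  invisible(x)
}

.total_overlap <- function(psi, omega12, omega13, omega23) {
  psi + omega12 + omega13 + omega23
}
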