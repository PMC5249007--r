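## The anti-median construction: seed with all two- and three-way overlap
## adjacencies, sample compatible adjacencies from the exclusive parts of
## g1 and g2 at prescribed proportions, take every remaining compatible g3
## adjacency (the maximal third proportion), and complete the partial
## assembly to a full genome by a uniform random matching of the free ends.

#' Partial assembly of a genome
#'
#' A partial assembly on \code{n} genes is a set of at most \code{n}
#' adjacencies that pairwise share no gene end, together with the set of
#' "free" ends not yet used by any adjacency.  It is the intermediate state
#' of the anti-median construction.
#'
#' @param n gene count.
#' @param adj optional two-column matrix of initial adjacencies.
#' @return an object of class \code{"partial_assembly"} with elements
#'   \code{n}, \code{adj} and \code{used} (logical over the \code{2n} ends).
#' @export
partial_assembly <- function(n, adj = NULL) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  used <- logical(2L * n)
  if (is.null(adj) || nrow(adj) == 0L) {
    adj <- matrix(integer(0), ncol = 2L)
  } else {
    adj <- .as_adj_matrix(adj)
    if (any(adj < 1L) || any(adj > 2L * n))
      stop("gene-end codes must lie in 1..2n")
    ends <- as.vector(adj)
    dup <- ends[duplicated(ends)]
    if (length(dup) > 0L)
      stop("incompatible adjacency set: gene end ", end_label(dup[1L]),
           " is part of more than one adjacency")
    used[ends] <- TRUE
  }
  structure(list(n = n, adj = adj, used = used), class = "partial_assembly")
}

#' @param assembly a \code{"partial_assembly"}.
#' @rdname partial_assembly
#' @export
free_ends <- function(assembly) {
  stopifnot(inherits(assembly, "partial_assembly"))
  which(!assembly$used)
}

#' Sample compatible adjacencies from a source genome into an assembly
#'
#' The candidates are the adjacencies of \code{source} whose two ends are
#' both free in the assembly (such an adjacency cannot already be present).
#' With an explicit \code{theta}, a uniform random subset of
#' \code{round(n * theta)} candidates is added; the call fails, reporting
#' the achievable maximum, if fewer candidates exist.  With
#' \code{maximal = TRUE} every candidate is added: candidates are mutually
#' compatible (they come from one matching) and compatibility with the
#' assembly is per-adjacency, so greedy inclusion is exactly maximal.
#'
#' @param assembly a \code{"partial_assembly"}.
#' @param source a \code{"genome"} on the same genes.
#' @param theta proportion of \code{n} to sample, or \code{NULL} when
#'   \code{maximal}.
#' @param maximal logical; add all two-free-end candidates.
#' @return a list: \code{assembly} (enlarged), \code{n_added}, and
#'   \code{n_candidates} (the number of two-free-end candidates before
#'   sampling, the quantity whose expected proportion follows the
#'   \code{(1 - theta)^2} law for disjoint sources).
#' @export
sample_stage <- function(assembly, source, theta = NULL, maximal = FALSE) {
  stopifnot(inherits(assembly, "partial_assembly"))
  .check_genome(source)
  if (source$n != assembly$n)
    stop("structural error: source genome has a different gene count")
  if (maximal && !is.null(theta))
    stop("give either an explicit theta or maximal = TRUE, not both")
  cand <- source$adj[!assembly$used[source$adj[, 1L]] &
                     !assembly$used[source$adj[, 2L]], , drop = FALSE]
  n_cand <- nrow(cand)
  if (maximal) {
    pick <- cand
  } else {
    if (is.null(theta)) stop("theta is required unless maximal = TRUE")
    if (is.na(theta) || theta < 0 || theta > 1)
      stop("theta must lie in [0, 1]")
    k <- .prop_count(assembly$n, theta, "theta")
    if (k > n_cand)
      stop(sprintf(paste0(
        "infeasible sampling request: theta = %g needs %d adjacencies but ",
        "only %d candidates have two free ends (achievable maximum theta ",
        "= %.4f)"), theta, k, n_cand, n_cand / assembly$n))
    pick <- cand[sample.int(n_cand, k), , drop = FALSE]
  }
  assembly$adj <- rbind(assembly$adj, pick)
  assembly$used[as.vector(pick)] <- TRUE
  list(assembly = assembly, n_added = nrow(pick), n_candidates = n_cand)
}

#' Complete a partial assembly by a uniform random matching
#'
#' Pairs all free ends of the assembly by a uniform random matching (the
#' number of free ends is always even) and validates the result.  The
#' adjacencies already in the assembly are preserved verbatim; random
#' completion adds asymptotically no adjacencies shared with any given
#' genome.
#'
#' @param assembly a \code{"partial_assembly"}.
#' @return a \code{"genome"} object.
#' @export
random_completion <- function(assembly) {
  stopifnot(inherits(assembly, "partial_assembly"))
  validate_genome(rbind(assembly$adj, .random_matching(free_ends(assembly))),
                  assembly$n)
}

#' Construct a breakpoint anti-median of three genomes
#'
#' Runs the full construction pipeline: (i) seed a partial assembly with
#' every adjacency in the two-way and three-way overlaps of the trio (these
#' are mutually compatible because any two overlap sets lie inside a common
#' genome); (ii) sample a proportion \code{theta1} of \code{n} from the
#' adjacencies exclusive to \code{g1}; (iii) likewise \code{theta2} from
#' \code{g2}; (iv) take a proportion \code{theta3} from \code{g3}, or, by
#' default, every compatible \code{g3} adjacency (the maximal sample); and
#' (v) randomly complete to a full genome.  All theta proportions are
#' relative to \code{n}, not to the exclusive-block sizes.
#'
#' @param g1,g2,g3 the input \code{"genome"} objects (same genes).
#' @param theta1,theta2 sampling proportions for the first two stages.
#' @param theta3 explicit third proportion, or \code{NULL} (the default) to
#'   maximize it greedily.
#' @return an object of class \code{"antimedian_construction"}: a list with
#'   \code{genome} (the constructed anti-median), \code{realized_theta}
#'   (named numeric triple actually achieved), \code{overlaps} (the trio's
#'   \code{\link{overlap_profile}}, all of which is included),
#'   \code{n_random_completed}, \code{stage_candidates} (two-free-end
#'   candidate counts seen by each stage), and \code{score}.
#' @examples
#' trio <- random_trio(500, seed = 42)
#' res <- construct_antimedian(trio$g1, trio$g2, trio$g3, 0.25, 0.25)
#' res$realized_theta
#' @export
construct_antimedian <- function(g1, g2, g3, theta1, theta2, theta3 = NULL) {
  n <- .check_same_n(g1, g2, g3)
  prof <- overlap_profile(g1, g2, g3)
  k1 <- .adj_keys(g1$adj, n)
  k2 <- .adj_keys(g2$adj, n)
  k3 <- .adj_keys(g3$adj, n)
  overlap_adj <- rbind(g1$adj[k1 %in% k2 | k1 %in% k3, , drop = FALSE],
                       g2$adj[(k2 %in% k3) & !(k2 %in% k1), , drop = FALSE])
  assembly <- partial_assembly(n, overlap_adj)
  st1 <- sample_stage(assembly, g1, theta = theta1)
  st2 <- sample_stage(st1$assembly, g2, theta = theta2)
  st3 <- if (is.null(theta3)) {
    sample_stage(st2$assembly, g3, maximal = TRUE)
  } else {
    sample_stage(st2$assembly, g3, theta = theta3)
  }
  x <- random_completion(st3$assembly)
  structure(list(
    genome = x,
    realized_theta = c(theta1 = st1$n_added / n,
                       theta2 = st2$n_added / n,
                       theta3 = st3$n_added / n),
    overlaps = prof,
    n_random_completed = n - nrow(st3$assembly$adj),
    stage_candidates = c(g1 = st1$n_candidates, g2 = st2$n_candidates,
                         g3 = st3$n_candidates),
    score = score(x, g1, g2, g3)
  ), class = "antimedian_construction")
}

#' @export
print.antimedian_construction <- function(x, ...) {
  cat(sprintf(
    "Anti-median construction (n = %d)\n  realized theta: %.4f %.4f %.4f\n",
    x$genome$n, x$realized_theta[1L], x$realized_theta[2L],
    x$realized_theta[3L]))
  cat(sprintf("  randomly completed adjacencies: %d\n  score: %.4f\n",
              x$n_random_completed, x$score))
  invisible(x)
}

#' Simulate the maximal third sampling proportion
#'
#' Runs \code{\link{construct_antimedian}} with a maximal third stage over
#' several replicates and reports the realized third proportion and score,
#' for comparison with the closed-form expectations of
#' \code{\link{max_theta3}} and \code{\link{expected_score}}.
#'
#' @param g1,g2,g3 the input genomes.
#' @param theta1,theta2 sampling proportions for the first two stages.
#' @param replicates number of independent constructions.
#' @return a list with \code{theta3} (vector of realized proportions),
#'   \code{mean}, \code{sd}, \code{scores}, and \code{score_mean}.
#' @export
empirical_max_theta3 <- function(g1, g2, g3, theta1, theta2, replicates = 3L) {
  res <- replicate(replicates,
                   construct_antimedian(g1, g2, g3, theta1, theta2),
                   simplify = FALSE)
  t3 <- vapply(res, function(r) r$realized_theta[["theta3"]], numeric(1L))
  sc <- vapply(res, function(r) r$score, numeric(1L))
  list(theta3 = t3, mean = mean(t3), sd = stats::sd(t3),
       scores = sc, score_mean = mean(sc))
}
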