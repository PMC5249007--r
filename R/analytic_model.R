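## Closed-form expectations for the anti-median construction: the maximal
## third sampling proportion, the expected score surface, its gradient, the
## symmetric anti-median solution, and a grid sweep of the surface.

.check_props <- function(theta1, theta2, psi, omega12, omega13, omega23) {
  vals <- c(theta1 = theta1, theta2 = theta2, psi = psi,
            omega12 = omega12, omega13 = omega13, omega23 = omega23)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1))
    stop("all proportions must lie in [0, 1]")
  if (theta1 + theta2 + psi + omega12 + omega13 + omega23 > 1 + 1e-12)
    stop("infeasible arguments: theta1 + theta2 plus the overlap ",
         "proportions exceed 1")
  invisible(vals)
}

#' Maximal third sampling proportion
#'
#' Expected maximal proportion of adjacencies that can be sampled from the
#' third genome after including all overlaps and sampling \code{theta1} and
#' \code{theta2} from the exclusive parts of the first two.  The default
#' model is \code{(1 - psi - sum(omega) - theta1 - theta2)^2}, the form
#' consistent with the stationarity system solved by
#' \code{\link{antimedian_solution}}; at zero overlaps it reduces to
#' \code{(1 - theta1 - theta2)^2}.  An alternative model conditioning on
#' the third genome's own shared ends, which divides the same square by
#' \code{1 - psi - omega13 - omega23}, is available for comparison with
#' simulation (\code{\link{empirical_max_theta3}}).
#'
#' @param theta1,theta2 sampling proportions (of \code{n}).
#' @param psi,omega12,omega13,omega23 overlap proportions of the trio.
#' @param model \code{"stationary"} (default) or \code{"conditional"}.
#' @return the expected maximal third proportion.
#' @examples
#' max_theta3(0.15, 0.15)  # 0.49
#' @export
max_theta3 <- function(theta1, theta2, psi = 0, omega12 = 0, omega13 = 0,
                       omega23 = 0, model = c("stationary", "conditional")) {
  model <- match.arg(model)
  .check_props(theta1, theta2, psi, omega12, omega13, omega23)
  sq <- (1 - psi - omega12 - omega13 - omega23 - theta1 - theta2)^2
  switch(model,
         stationary = sq,
         conditional = sq / (1 - psi - omega13 - omega23))
}

#' Expected anti-median score
#'
#' Expected normalized breakpoint score of the constructed genome when the
#' third proportion is maximal:
#' \code{s = 3 - (theta1 + theta2 + max_theta3 + omega12 + omega13 +
#' omega23 + psi)}.  At zero overlaps this expands to
#' \code{3 - (theta1 + theta2 + (1 - theta1 - theta2)^2)}, maximized on the
#' line \code{theta1 + theta2 = 0.5}.
#'
#' @inheritParams max_theta3
#' @return the expected score, a value in \code{[0, 3]}.
#' @examples
#' expected_score(0.15, 0.15)  # 2.21
#' @export
expected_score <- function(theta1, theta2, psi = 0, omega12 = 0,
                           omega13 = 0, omega23 = 0,
                           model = c("stationary", "conditional")) {
  3 - (theta1 + theta2 +
         max_theta3(theta1, theta2, psi, omega12, omega13, omega23,
                    model = model) +
         omega12 + omega13 + omega23 + psi)
}

#' Gradient of the zero-overlap score surface
#'
#' Partial derivative of \code{\link{expected_score}} with respect to
#' either \code{theta1} or \code{theta2} in the zero-overlap case:
#' \code{1 - 2*theta1 - 2*theta2}.  It vanishes exactly on the ridge
#' \code{theta1 + theta2 = 0.5}; the second derivatives are negative, so
#' the surface attains its interior maximum there.
#'
#' @param theta1,theta2 sampling proportions.
#' @return the common partial derivative value.
#' @export
score_gradient <- function(theta1, theta2) {
  .check_props(theta1, theta2, 0, 0, 0, 0)
  1 - 2 * theta1 - 2 * theta2
}

#' Symmetric anti-median solution
#'
#' Solves the linear stationarity system in which each pair of sampling
#' proportions sums to \code{0.5 - omega12 - omega13 - omega23 - psi}:
#' \deqn{\theta_1+\theta_2 = \theta_2+\theta_3 = \theta_3+\theta_1 =
#'   0.5 - \omega_{1,2} - \omega_{1,3} - \omega_{2,3} - \psi.}
#' The unique solution is symmetric,
#' \code{theta_i = 0.25 - 0.5 * (omega12 + omega13 + omega23 + psi)}, and
#' maximizes the expected score over all maximal samples.  The system is
#' solved numerically (it is a 3x3 linear solve), not substituted.
#'
#' @inheritParams max_theta3
#' @return named numeric triple \code{(theta1, theta2, theta3)}.
#' @examples
#' antimedian_solution()                 # 0.25 0.25 0.25
#' antimedian_solution(psi = 0.1, omega12 = 0.05, omega13 = 0.05,
#'                     omega23 = 0.05)   # 0.125 each
#' @export
antimedian_solution <- function(psi = 0, omega12 = 0, omega13 = 0,
                                omega23 = 0) {
  .check_props(0, 0, psi, omega12, omega13, omega23)
  shared <- psi + omega12 + omega13 + omega23
  if (shared > 0.5)
    stop("infeasible overlaps: psi + sum(omega) = ", shared,
         " > 0.5, the symmetric solution would be negative")
  A <- rbind(c(1, 1, 0),
             c(0, 1, 1),
             c(1, 0, 1))
  theta <- solve(A, rep(0.5 - shared, 3L))
  names(theta) <- c("theta1", "theta2", "theta3")
  theta
}

#' Proportional-representation sampling scheme
#'
#' A seemingly "fairer" alternative in which each genome samples in
#' proportion to the adjacencies it already contributes through the
#' overlaps: the raw ratios are
#' \code{(omega12 + omega13)/2 + psi/3} and its two permutations.  The
#' triple is returned normalized to sum 1 for comparison only: except in
#' symmetric cases it does not satisfy the stationarity system solved by
#' \code{\link{antimedian_solution}}, so it is not a maximal-score scheme.
#'
#' @inheritParams max_theta3
#' @return named numeric triple of ratios summing to 1.
#' @export
proportional_scheme <- function(psi = 0, omega12 = 0, omega13 = 0,
                                omega23 = 0) {
  .check_props(0, 0, psi, omega12, omega13, omega23)
  raw <- c(theta1 = (omega12 + omega13) / 2 + psi / 3,
           theta2 = (omega12 + omega23) / 2 + psi / 3,
           theta3 = (omega13 + omega23) / 2 + psi / 3)
  if (sum(raw) == 0)
    stop("undefined ratios: all overlap proportions are zero")
  raw / sum(raw)
}

#' Sweep the expected score surface over a sampling grid
#'
#' Enumerates feasible \code{(theta1, theta2)} pairs on a regular grid,
#' fills in the maximal third proportion and the expected score, and
#' returns them as plain columns (barycentric coordinates over the
#' feasible simplex).
#'
#' @param grid_step grid spacing, in \code{(0, 0.25]}.
#' @inheritParams max_theta3
#' @return a data frame with columns \code{theta1}, \code{theta2},
#'   \code{theta3} (maximal) and \code{score}.
#' @examples
#' surf <- surface_sweep(0.05)
#' surf[which.max(surf$score), ]
#' @export
surface_sweep <- function(grid_step = 0.05, psi = 0, omega12 = 0,
                          omega13 = 0, omega23 = 0,
                          model = c("stationary", "conditional")) {
  model <- match.arg(model)
  if (is.na(grid_step) || grid_step <= 0 || grid_step > 0.25)
    stop("grid_step must lie in (0, 0.25]")
  shared <- psi + omega12 + omega13 + omega23
  ts <- seq(0, 1, by = grid_step)
  grid <- expand.grid(theta1 = ts, theta2 = ts, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$theta1 + grid$theta2 + shared <= 1 + 1e-12, , drop = FALSE]
  grid$theta3 <- mapply(max_theta3, grid$theta1, grid$theta2,
                        MoreArgs = list(psi = psi, omega12 = omega12,
                                        omega13 = omega13, omega23 = omega23,
                                        model = model))
  grid$score <- mapply(expected_score, grid$theta1, grid$theta2,
                       MoreArgs = list(psi = psi, omega12 = omega12,
                                       omega13 = omega13, omega23 = omega23,
                                       model = model))
  rownames(grid) <- NULL
  grid
}

## The published 25-cell reference grid of (theta1, theta2) with the
## maximal third proportion and the expected score, used by the CLI
## validation suite.
.reference_grid <- function() {
  g <- expand.grid(theta2 = seq(0.15, 0.35, by = 0.05),
                   theta1 = seq(0.15, 0.35, by = 0.05),
                   KEEP.OUT.ATTRS = FALSE)[, c("theta1", "theta2")]
  theta3 <- c(0.4900, 0.4225, 0.3600, 0.3025, 0.2500,
              0.4225, 0.3600, 0.3025, 0.2500, 0.2025,
              0.3600, 0.3025, 0.2500, 0.2025, 0.1600,
              0.3025, 0.2500, 0.2025, 0.1600, 0.1225,
              0.2500, 0.2025, 0.1600, 0.1225, 0.0900)
  s <- c(2.2100, 2.2275, 2.2400, 2.2475, 2.2500,
         2.2275, 2.2400, 2.2475, 2.2500, 2.2475,
         2.2400, 2.2475, 2.2500, 2.2475, 2.2400,
         2.2475, 2.2500, 2.2475, 2.2400, 2.2275,
         2.2500, 2.2475, 2.2400, 2.2275, 2.2100)
  cbind(g, theta3 = theta3, score = s)
}
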