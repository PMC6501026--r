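# Pairwise auto-logistic (Ising-like) binary mutation model.
#
# P(x) is proportional to exp(alpha' x + sum_{j<k} theta_jk x_j x_k) over
# x in {0,1}^m.  For m <= 16 drivers the joint is enumerated exactly, the
# field terms alpha are calibrated against the target marginals by fixed-point
# iteration, and samples are drawn from the exact joint distribution -- no
# Gibbs burn-in, fully deterministic under seed.

#' @noRd
.state_matrix <- function(m) {
  # all 2^m binary states, one per row
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), m), KEEP.OUT.ATTRS = FALSE))
  dimnames(states) <- NULL
  storage.mode(states) <- "double"
  states
}

#' @noRd
.autologistic_dist <- function(alpha, theta, states = NULL) {
  m <- length(alpha)
  if (is.null(states)) states <- .state_matrix(m)
  quad <- rowSums((states %*% theta) * states) / 2
  lw <- drop(states %*% alpha) + quad
  w <- exp(lw - max(lw))
  list(states = states, prob = w / sum(w))
}

#' @noRd
.calibrate_fields <- function(freqs, theta, tol = 1e-10, maxit = 500) {
  m <- length(freqs)
  states <- .state_matrix(m)
  target <- .logit(freqs)
  alpha <- target
  quad <- rowSums((states %*% theta) * states) / 2
  for (it in seq_len(maxit)) {
    lw <- drop(states %*% alpha) + quad
    w <- exp(lw - max(lw))
    p <- drop(crossprod(states, w)) / sum(w)
    if (any(p <= 0 | p >= 1)) {
      stop("infeasible pairwise mutation model: a marginal collapsed to 0/1 ",
           "during field calibration", call. = FALSE)
    }
    delta <- target - .logit(p)
    alpha <- alpha + delta
    if (max(abs(delta)) < tol) {
      return(list(alpha = alpha, states = states, quad = quad,
                  marginals = p, iterations = it))
    }
  }
  stop("infeasible frequency/interaction combination: field calibration did ",
       "not converge to the requested marginals", call. = FALSE)
}

#' Sample binary driver mutations from a pairwise auto-logistic model
#'
#' Draws a samples-by-drivers binary mutation matrix whose marginal
#' frequencies match `truth$mutation_freqs` and whose pairwise dependence is
#' governed by `truth$pair_log_odds` (positive interactions give
#' co-occurrence, negative ones mutual exclusivity, as seen between EGFR and
#' KRAS in lung adenocarcinoma).  The joint distribution over the `2^m`
#' genotype states is enumerated exactly and field terms are calibrated so
#' the model marginals equal the requested frequencies; samples are then
#' drawn from the exact joint.  Restricted to at most 16 drivers, which
#' covers the 15-driver screen this package models.
#'
#' @param n_samples number of tumors to draw (>= 2).
#' @param truth a [sim_truth()] object.
#' @return Binary matrix (`n_samples` x drivers) with sample identifiers as
#'   row names, of class `matrix`.  Attribute `calibration` records the
#'   calibrated field terms and achieved model marginals.
#' @export
#' @examples
#' tr <- default_truth(n_genes = 50)
#' mut <- generate_mutations(200, tr)
#' colMeans(mut)
generate_mutations <- function(n_samples, truth) {
  stopifnot(inherits(truth, "sim_truth"), n_samples >= 2)
  m <- length(truth$mutation_freqs)
  if (m > 16) {
    stop("exact pairwise sampling supports at most 16 driver genes",
         call. = FALSE)
  }
  cal <- .calibrate_fields(truth$mutation_freqs, truth$pair_log_odds)
  lw <- drop(cal$states %*% cal$alpha) + cal$quad
  w <- exp(lw - max(lw))
  prob <- w / sum(w)
  idx <- .with_seed(.stream_seed(truth$seed, "mutations"),
                    sample.int(length(prob), n_samples, replace = TRUE,
                               prob = prob))
  out <- cal$states[idx, , drop = FALSE]
  dimnames(out) <- list(sprintf("S%05d", seq_len(n_samples)),
                        names(truth$mutation_freqs))
  attr(out, "calibration") <- list(alpha = cal$alpha,
                                   marginals = cal$marginals,
                                   iterations = cal$iterations)
  out
}

#' Exact joint distribution of the pairwise mutation model
#'
#' Enumerates all genotype states of the calibrated auto-logistic model and
#' returns their probabilities; used to verify realized pairwise odds ratios
#' against the model they were drawn from.
#'
#' @inheritParams generate_mutations
#' @return List with `states` (binary matrix) and `prob`.
#' @export
mutation_model_distribution <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  cal <- .calibrate_fields(truth$mutation_freqs, truth$pair_log_odds)
  d <- .autologistic_dist(cal$alpha, truth$pair_log_odds, cal$states)
  colnames(d$states) <- names(truth$mutation_freqs)
  d
}
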