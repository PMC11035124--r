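#' EM settings
#'
#' Tuning knobs for the abundance EM. Defaults: convergence when the
#' largest per-reference abundance change falls below `tol = 1e-6`, at most
#' `max_iters = 1000` iterations, the set-cover filter applied after every
#' 10 iterations, and a removal support threshold of one read-equivalent
#' (a reference outside the greedy cover is dropped when its abundance
#' times the read count is below `min_class_support`).
#'
#' @param max_iters Maximum EM iterations.
#' @param tol Convergence threshold on `max |delta theta|`.
#' @param setcover_interval Apply the set-cover filter every this many
#'   iterations (default 10).
#' @param min_class_support Removal threshold in read-equivalents
#'   (`theta_j * M < min_class_support` deactivates an uncovered
#'   reference).
#' @return A list of class `em_settings`.
#' @export
em_settings <- function(max_iters = 1000L, tol = 1e-6,
                        setcover_interval = 10L, min_class_support = 1) {
  stopifnot(setcover_interval >= 1L, tol > 0, max_iters >= 1L,
            min_class_support >= 0)
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 setcover_interval = as.integer(setcover_interval),
                 min_class_support = min_class_support),
            class = "em_settings")
}

#' Log-likelihood of an abundance vector
#'
#' The observed-data log-likelihood of the mixture model in which a read
#' is generated by first drawing a reference with probability
#' \eqn{\theta_j} and then the read with conditional probability
#' \eqn{p_{ij}} (the score-normalized mapping probability):
#' \eqn{\ell(\theta) = \sum_i \log \sum_j \theta_j p_{ij}}.
#'
#' @param theta Abundance vector over `matrix$refs` (named or positional).
#' @param matrix A [build_mapping_matrix()] object.
#' @return The log-likelihood; `-Inf` if some read has zero probability
#'   under `theta`.
#' @export
mapping_loglik <- function(theta, matrix) {
  theta <- .align_theta(theta, matrix$refs)
  lik <- as.numeric(matrix$probs %*% theta)
  if (any(lik <= 0)) return(-Inf)
  sum(log(lik))
}

.align_theta <- function(theta, refs) {
  if (!is.null(names(theta))) {
    stopifnot(all(refs %in% names(theta)))
    theta <- theta[refs]
  }
  stopifnot(length(theta) == length(refs))
  as.numeric(theta)
}

#' One EM update of the abundance vector
#'
#' E-step responsibilities \eqn{\gamma_{ij} \propto \theta_j p_{ij}} and
#' M-step \eqn{\theta_j' = \sum_i \gamma_{ij} / M}, computed on
#' equivalence-class weight sums (exactly equivalent to the read-level
#' update). References with `theta_j = 0` stay at zero.
#'
#' @param theta Current abundance vector (sums to 1 over active refs).
#' @param classes An [build_equivalence_classes()] object.
#' @return Updated abundance vector (named by reference).
#' @export
em_step <- function(theta, classes) {
  theta <- .align_theta(theta, colnames(classes$W))
  denom <- as.numeric(classes$W %*% theta)
  if (any(denom <= 0)) {
    stop("equivalence class with zero probability under theta")
  }
  # theta'_j = (1/M) * sum_c n_c * theta_j w_cj / sum_l theta_l w_cl ;
  # with score-profile classes, w_c = n_c * p_c so the n_c factor cancels
  # inside the ratio and this is the read-level update
  contrib <- as.numeric(Matrix::crossprod(classes$W, classes$sizes / denom))
  new_theta <- theta * contrib / sum(classes$sizes)
  new_theta <- new_theta / sum(new_theta)
  names(new_theta) <- colnames(classes$W)
  new_theta
}

#' Set-cover filter of redundant low-abundance references
#'
#' Every few EM iterations, references that explain no equivalence class
#' uniquely and carry almost no reads are removed, which sharpens the
#' remaining estimates and speeds convergence. A greedy weighted set cover
#' is built over the classes: references are considered in order of
#' current abundance (descending), then number of classes covered
#' (descending), then reference id, and added to the cover while uncovered
#' classes remain. References outside the cover whose expected read count
#' `theta_j * M` falls below `min_class_support` are deactivated (theta
#' set to 0, permanently) and theta is renormalized over the survivors.
#'
#' @param theta Current abundance vector.
#' @param classes An [build_equivalence_classes()] object.
#' @param settings An [em_settings()] object.
#' @return Abundance vector with deactivated entries at 0, renormalized.
#' @export
set_cover_filter <- function(theta, classes, settings = em_settings()) {
  refs <- colnames(classes$W)
  theta <- .align_theta(theta, refs)
  M <- sum(classes$sizes)
  active <- which(theta > 0)
  if (length(active) <= 1L) {
    names(theta) <- refs
    return(theta)
  }
  # classes each active reference belongs to
  covers <- lapply(active, function(j) {
    which(classes$W[, j] > 0)
  })
  n_cover <- lengths(covers)
  ord <- active[order(-theta[active], -n_cover, refs[active])]
  covered <- logical(nrow(classes$W))
  in_cover <- integer(0)
  for (j in ord) {
    cl <- covers[[match(j, active)]]
    if (any(!covered[cl])) {
      in_cover <- c(in_cover, j)
      covered[cl] <- TRUE
      if (all(covered)) break
    }
  }
  drop <- setdiff(active, in_cover)
  drop <- drop[theta[drop] * M < settings$min_class_support]
  if (length(drop) > 0L) {
    theta[drop] <- 0
    theta <- theta / sum(theta)
  }
  names(theta) <- refs
  theta
}

#' Estimate reference abundances by EM
#'
#' Runs the expectation-maximization estimator of the reference abundance
#' vector from a uniform start, applying the set-cover filter after every
#' `setcover_interval` iterations and once more on the final estimate,
#' until the largest abundance change drops below `tol` or `max_iters` is
#' reached. The returned abundances are the \eqn{a_j} consumed by the
#' re-assignment stage.
#'
#' @param matrix A [build_mapping_matrix()] object.
#' @param classes Optional [build_equivalence_classes()] object (built
#'   from `matrix` when omitted).
#' @param settings An [em_settings()] object.
#' @return A list of class `abundance_em`:
#' \describe{
#'   \item{theta}{named abundance vector (zeros for deactivated refs).}
#'   \item{active}{named logical mask of references kept by the filter.}
#'   \item{iterations}{number of EM iterations performed.}
#'   \item{converged}{logical.}
#'   \item{loglik}{log-likelihood trace, one value per iteration
#'     (computed after the EM update, before any filter).}
#' }
#' @export
run_em <- function(matrix, classes = NULL, settings = em_settings()) {
  if (is.null(classes)) classes <- build_equivalence_classes(matrix)
  refs <- matrix$refs
  n <- length(refs)
  theta <- rep(1 / n, n)
  names(theta) <- refs
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < settings$max_iters) {
    iter <- iter + 1L
    new_theta <- em_step(theta, classes)
    loglik[iter] <- mapping_loglik(new_theta, matrix)
    delta <- max(abs(new_theta - theta))
    if (iter %% settings$setcover_interval == 0L) {
      new_theta <- set_cover_filter(new_theta, classes, settings)
    }
    theta <- new_theta
    if (delta < settings$tol) {
      converged <- TRUE
      break
    }
  }
  # final cleanup: convergence may land between filter intervals, but the
  # returned estimate should never carry redundant sub-support references
  theta <- set_cover_filter(theta, classes, settings)
  structure(
    list(theta = theta, active = theta > 0, iterations = iter,
         converged = converged, loglik = loglik),
    class = "abundance_em"
  )
}

#' @export
print.abundance_em <- function(x, ...) {
  cat("abundance_em:", sum(x$active), "active of", length(x$theta),
      "references;", x$iterations, "iterations",
      if (x$converged) "(converged)" else "(max iterations)", "\n")
  top <- sort(x$theta[x$active], decreasing = TRUE)
  print(utils::head(round(top, 4), 10))
  invisible(x)
}
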