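#' Construct a univariate Gaussian mixture model object
#'
#' Components are stored in canonical order: ascending standard deviation,
#' ties broken by ascending mean, so cluster indices are stable across runs.
#' For distance data the smallest-sigma component is the tight cluster
#' around the drug name where genuine adverse-reaction mentions concentrate.
#'
#' @param weights Mixing proportions (must sum to 1 within 1e-12).
#' @param means Component means, in words.
#' @param sds Component standard deviations, in words (all > 0).
#' @return An `adr_mixture` object.
#' @export
mixture_model <- function(weights, means, sds) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            length(weights) >= 1L, all(is.finite(c(weights, means, sds))),
            all(sds > 0), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("mixture weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  ord <- order(sds, means)
  structure(list(K = length(weights), weights = unname(weights[ord]),
                 means = unname(means[ord]), sds = unname(sds[ord])),
            class = "adr_mixture")
}

#' @export
print.adr_mixture <- function(x, ...) {
  cat(sprintf("<Gaussian mixture, K=%d (components in ascending sd)>\n", x$K))
  print(data.frame(cluster = seq_len(x$K), weight = round(x$weights, 4),
                   mean = round(x$means, 3), sd = round(x$sds, 3)),
        row.names = FALSE)
  invisible(x)
}

# n x K matrix of log(pi_k) + log phi(x; mu_k, sd_k)
log_weighted_dens <- function(model, x) {
  K <- model$K
  out <- matrix(0, nrow = length(x), ncol = K)
  for (k in seq_len(K)) {
    out[, k] <- log(model$weights[k]) +
      stats::dnorm(x, model$means[k], model$sds[k], log = TRUE)
  }
  out
}

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Mixture log-likelihood
#'
#' `sum_i log sum_k pi_k phi(x_i; mu_k, sd_k)`, computed with the
#' log-sum-exp trick so that points far in the tails do not underflow.
#'
#' @param model An `adr_mixture`.
#' @param x Numeric vector of signed distances.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, x) {
  stopifnot(inherits(model, "adr_mixture"), all(is.finite(x)))
  if (length(x) == 0L) return(0)
  sum(row_log_sum_exp(log_weighted_dens(model, x)))
}

#' Fit a univariate Gaussian mixture to signed distances by EM
#'
#' Standard expectation-maximization with free weights, means and variances.
#' Initialization is deterministic: the data are sorted and split into K
#' equal-count quantile blocks whose means, standard deviations and
#' proportions seed the first M-step (`init = "quantile"`); `init = "random"`
#' draws random responsibilities (seeded) and is intended for optional
#' restarts. Iteration stops when the relative change in log-likelihood
#' falls below `tol` or after `max_iter` iterations. Component variances are
#' clamped to `var_floor` (with a warning) to avoid degenerate spikes.
#'
#' @param x Numeric vector of signed distances (length >= 2K).
#' @param K Number of components (the distance filter fixes K = 3:
#'   near/mid/far co-occurrences).
#' @param seed Integer seed; only consumed when `init = "random"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param var_floor Variance floor, in words squared.
#' @param init `"quantile"` (deterministic, default) or `"random"`.
#' @return An `adr_mixture_fit`: list with `model` (canonical component
#'   order), `responsibilities` (n x K, columns matching the canonical
#'   order), `loglik_trace`, `n_iter`, `converged`.
#' @export
em_fit <- function(x, K = 3L, seed = NULL, tol = 1e-8, max_iter = 500L,
                   var_floor = 1e-6, init = c("quantile", "random")) {
  init <- match.arg(init)
  stopifnot(all(is.finite(x)), K >= 1L)
  n <- length(x)
  if (n < 2L * K) {
    stop("insufficient data: EM with K=", K, " needs at least ", 2L * K,
         " observations, got ", n, call. = FALSE)
  }
  x <- as.numeric(x)
  if (init == "quantile") {
    xs <- sort(x)
    block <- rep(seq_len(K), each = ceiling(n / K), length.out = n)
    pi_k <- as.numeric(tabulate(block, K)) / n
    mu_k <- vapply(seq_len(K), function(k) mean(xs[block == k]), numeric(1))
    var_k <- vapply(seq_len(K), function(k) {
      v <- stats::var(xs[block == k])
      if (!is.finite(v) || v <= 0) var_floor else v * (sum(block == k) - 1) / sum(block == k)
    }, numeric(1))
  } else {
    if (!is.null(seed)) set.seed(as.integer(seed))
    resp0 <- matrix(stats::rexp(n * K), n, K)
    resp0 <- resp0 / rowSums(resp0)
    nk <- colSums(resp0)
    pi_k <- nk / n
    mu_k <- colSums(resp0 * x) / nk
    var_k <- vapply(seq_len(K), function(k)
      sum(resp0[, k] * (x - mu_k[k])^2) / nk[k], numeric(1))
  }
  var_k <- pmax(var_k, var_floor)
  clamped <- FALSE
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  resp <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    m <- matrix(0, n, K)
    for (k in seq_len(K)) {
      m[, k] <- log(pi_k[k]) + stats::dnorm(x, mu_k[k], sqrt(var_k[k]), log = TRUE)
    }
    lse <- row_log_sum_exp(m)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(m - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.xmin)
    pi_k <- nk / n
    mu_k <- colSums(resp * x) / nk
    var_k <- vapply(seq_len(K), function(k)
      sum(resp[, k] * (x - mu_k[k])^2) / nk[k], numeric(1))
    if (any(var_k < var_floor)) clamped <- TRUE
    var_k <- pmax(var_k, var_floor)
  }
  if (clamped) {
    warning("degenerate component(s): variance clamped to floor ",
            format(var_floor), call. = FALSE)
  }
  model <- mixture_model(pi_k, mu_k, sqrt(var_k))
  # reorder responsibility columns to the canonical (ascending sd) order
  ord <- order(sqrt(var_k), mu_k)
  structure(list(model = model, responsibilities = resp[, ord, drop = FALSE],
                 loglik_trace = ll_trace, n_iter = iter,
                 converged = converged),
            class = "adr_mixture_fit")
}

#' @export
print.adr_mixture_fit <- function(x, ...) {
  cat(sprintf("<EM fit: %d iterations, %sconverged, loglik %.4f>\n",
              x$n_iter, if (x$converged) "" else "NOT ",
              x$loglik_trace[length(x$loglik_trace)]))
  print(x$model)
  invisible(x)
}

#' Per-class Gaussian fit using gold labels (sensitivity analysis)
#'
#' Fits one Gaussian per label class with weights equal to class
#' proportions. This is not the default route (the filter is unsupervised;
#' gold labels are reserved for evaluation) but supports sensitivity checks
#' of the unsupervised cluster structure.
#'
#' @param x Numeric distances.
#' @param labels Factor or character class per observation.
#' @return An `adr_mixture` with one component per class.
#' @export
fit_supervised <- function(x, labels) {
  stopifnot(length(x) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  w <- vapply(classes, function(cl) mean(labels == cl), numeric(1))
  mu <- vapply(classes, function(cl) mean(x[labels == cl]), numeric(1))
  sd_ <- vapply(classes, function(cl) {
    xi <- x[labels == cl]
    s <- sqrt(sum((xi - mean(xi))^2) / length(xi))
    max(s, 1e-3)
  }, numeric(1))
  mixture_model(w, mu, sd_)
}

#' Maximum-a-posteriori cluster assignment
#'
#' Assigns each distance to the component maximizing the weighted density
#' `pi_k phi(x; mu_k, sd_k)`; ties go to the lowest canonical index.
#'
#' @param model An `adr_mixture`.
#' @param x Numeric vector of signed distances.
#' @return Integer vector of cluster indices in 1..K.
#' @export
map_assign <- function(model, x) {
  stopifnot(inherits(model, "adr_mixture"))
  if (length(x) == 0L) return(integer(0))
  m <- log_weighted_dens(model, x)
  max.col(m, ties.method = "first")
}

#' Exact MAP assignment regions of a mixture over a domain
#'
#' Solves, for every component pair, the quadratic equation
#' `log pi_i phi_i(x) = log pi_j phi_j(x)` whose real roots are the only
#' points where the argmax component can change; the domain is cut at those
#' roots and the winning component on each segment is determined at its
#' midpoint. Adjacent segments with the same winner are merged, producing
#' for each cluster the union of intervals on which it attains the maximum
#' posterior — for equal-mean components with increasing spread this yields
#' the characteristic nested structure: an inner interval (tight cluster),
#' a two-interval union flanking it (middle cluster) and the outer tails.
#'
#' @param model An `adr_mixture`.
#' @param domain Numeric length-2: the interval to partition (should cover
#'   the data range).
#' @return A `cluster_regions` object: data.frame with columns `cluster`,
#'   `lower`, `upper`, one row per maximal interval, ordered by `lower`.
#' @export
assignment_regions <- function(model, domain) {
  stopifnot(inherits(model, "adr_mixture"), length(domain) == 2L,
            all(is.finite(domain)), domain[1] < domain[2])
  K <- model$K
  dup <- duplicated(round(cbind(model$weights, model$means, model$sds), 12L))
  if (any(dup)) {
    warning("identical mixture components: their shared region is attributed ",
            "to the lowest index", call. = FALSE)
  }
  cuts <- numeric(0)
  if (K > 1L) {
    for (i in 1:(K - 1L)) {
      for (j in (i + 1L):K) {
        si2 <- model$sds[i]^2; sj2 <- model$sds[j]^2
        a <- 1 / (2 * sj2) - 1 / (2 * si2)
        b <- model$means[i] / si2 - model$means[j] / sj2
        c0 <- model$means[j]^2 / (2 * sj2) - model$means[i]^2 / (2 * si2) +
          log(model$weights[i] / model$sds[i]) -
          log(model$weights[j] / model$sds[j])
        if (abs(a) < 1e-300) {
          if (abs(b) > 0) cuts <- c(cuts, -c0 / b)
        } else {
          disc <- b^2 - 4 * a * c0
          if (disc >= 0) {
            r <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
            cuts <- c(cuts, r)
          }
        }
      }
    }
  }
  cuts <- sort(unique(cuts[cuts > domain[1] & cuts < domain[2]]))
  edges <- c(domain[1], cuts, domain[2])
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  winner <- map_assign(model, mids)
  # merge adjacent segments with the same winning component
  keep <- c(TRUE, winner[-1] != winner[-length(winner)])
  starts <- which(keep)
  ends <- c(starts[-1] - 1L, length(winner))
  out <- data.frame(cluster = winner[starts],
                    lower = edges[starts],
                    upper = edges[ends + 1L])
  structure(out, class = c("cluster_regions", "data.frame"))
}

#' @export
print.cluster_regions <- function(x, digits = 0, ...) {
  cat("<MAP assignment regions>\n")
  for (k in sort(unique(x$cluster))) {
    xi <- x[x$cluster == k, , drop = FALSE]
    iv <- sprintf("(%+.*f, %+.*f)", digits, xi$lower, digits, xi$upper)
    cat(sprintf("  cluster %d: %s\n", k, paste(iv, collapse = " U ")))
  }
  invisible(x)
}

#' Look up the region-based cluster of a point
#'
#' @param regions A `cluster_regions` object.
#' @param x Numeric vector within the regions' domain.
#' @return Integer cluster indices.
#' @export
region_assign <- function(regions, x) {
  stopifnot(inherits(regions, "cluster_regions"))
  idx <- findInterval(x, regions$lower, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  as.integer(regions$cluster[idx])
}
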