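#' Fit a Gaussian-emission hidden Markov model by EM
#'
#' Fits a K-state HMM with Gaussian emissions to one or more observation
#' sequences using the Baum-Welch (EM) algorithm, restarted from several
#' random initialisations; the restart with the best (smallest) AIC is
#' returned. This is the segmentation engine behind both the two-state
#' CNE-density HMM used to call GRB-like enriched regions and the
#' three-state directionality-index HMM used to call TADs.
#'
#' The AIC is \code{2 p - 2 logLik} with \code{p = K} means \code{+ K}
#' variances \code{+ K(K-1)} free transition entries \code{+ (K-1)} free
#' initial-distribution entries (7 parameters for the two-state model).
#' Emission variances are floored at \code{1e-6} to keep the likelihood
#' finite on near-constant stretches.
#'
#' @param obs A numeric vector or a list of numeric vectors (one per
#'   chromosome); all sequences share one parameter set.
#' @param k Number of hidden states (default 2).
#' @param restarts Number of random EM restarts (default 10).
#' @param seed Integer seed controlling the restarts.
#' @param max_iter,tol EM stopping rule: stop when the relative change in
#'   log-likelihood falls below \code{tol} (default \code{1e-6}) or after
#'   \code{max_iter} iterations (default 500).
#' @return An object of class \code{gaussian_hmm}: a list with elements
#'   \code{means}, \code{vars}, \code{trans}, \code{init}, \code{loglik},
#'   \code{aic}, \code{n_params}, \code{k}, \code{degenerate}.
#' @examples
#' obs <- c(rnorm(50, 0, .1), rnorm(50, 5, .1))
#' m <- fit_gaussian_hmm(obs, k = 2, restarts = 4, seed = 1)
#' sort(m$means)
#' @export
fit_gaussian_hmm <- function(obs, k = 2, restarts = 10, seed = 1,
                             max_iter = 500, tol = 1e-6) {
  stopifnot(restarts >= 1, k >= 2)
  if (!is.list(obs)) obs <- list(obs)
  obs <- lapply(obs, as.numeric)
  obs <- obs[lengths(obs) > 0]
  if (length(obs) == 0) stop("empty observation track")
  all_obs <- unlist(obs, use.names = FALSE)
  n_params <- k + k + k * (k - 1) + (k - 1)

  if (stats::sd(all_obs) < 1e-12) {
    # constant track: no two-level structure to segment
    out <- list(means = rep(mean(all_obs), k), vars = rep(1e-6, k),
                trans = diag(k), init = rep(1 / k, k),
                loglik = NA_real_, aic = NA_real_, n_params = n_params,
                k = k, degenerate = TRUE)
    class(out) <- "gaussian_hmm"
    return(out)
  }

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- tryCatch(
        em_once(obs, k, init_params(all_obs, k), max_iter, tol),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$aic < best$aic)) best <- fit
    }
  })
  if (is.null(best)) stop("all EM restarts failed")
  best$n_params <- n_params
  best$k <- k
  best$degenerate <- FALSE
  class(best) <- "gaussian_hmm"
  best
}

# Random EM starting point: means drawn near spread quantiles of the data.
init_params <- function(x, k) {
  qs <- stats::quantile(x, probs = seq(0.1, 0.9, length.out = k), names = FALSE)
  means <- qs + stats::rnorm(k, 0, max(stats::sd(x) * 0.25, 1e-3))
  vars <- rep(max(stats::var(x) / k, 1e-4), k) * stats::runif(k, 0.5, 1.5)
  stay <- stats::runif(k, 0.8, 0.99)
  trans <- matrix((1 - stay) / (k - 1), k, k)
  diag(trans) <- stay
  list(means = means, vars = vars, trans = trans, init = rep(1 / k, k))
}

em_once <- function(obs, k, par, max_iter, tol) {
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    ll <- 0
    g_sum <- numeric(k); gx_sum <- numeric(k); gxx_sum <- numeric(k)
    xi_sum <- matrix(0, k, k); g1_sum <- numeric(k)
    for (s in obs) {
      fb <- hmm_forward_backward(s, par$means, par$vars, par$trans, par$init)
      ll <- ll + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * s)
      gxx_sum <- gxx_sum + colSums(g * s^2)
      xi_sum <- xi_sum + fb$xi_sum
      g1_sum <- g1_sum + g[1, ]
    }
    par$means <- gx_sum / pmax(g_sum, 1e-300)
    par$vars <- pmax(gxx_sum / pmax(g_sum, 1e-300) - par$means^2, 1e-6)
    rs <- rowSums(xi_sum)
    for (j in seq_len(k)) {
      par$trans[j, ] <- if (rs[j] > 0) xi_sum[j, ] / rs[j]
                        else rep(1 / k, k)
    }
    par$init <- g1_sum / sum(g1_sum)
    if (is.finite(prev_ll) &&
        abs(ll - prev_ll) < tol * (abs(prev_ll) + tol)) break
    prev_ll <- ll
  }
  n_params <- k + k + k * (k - 1) + (k - 1)
  c(par, list(loglik = ll, aic = 2 * n_params - 2 * ll))
}

#' Viterbi decoding of a fitted Gaussian HMM
#'
#' @param model A \code{gaussian_hmm} fit.
#' @param obs Numeric observation vector.
#' @return Integer vector of 1-based state indices, the single most
#'   probable state path.
#' @export
viterbi_path <- function(model, obs) {
  stopifnot(inherits(model, "gaussian_hmm"))
  if (isTRUE(model$degenerate)) return(rep(1L, length(obs)))
  hmm_viterbi(as.numeric(obs), model$means, model$vars, model$trans,
              model$init)
}

#' @export
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM (%d states)%s\n", x$k,
              if (isTRUE(x$degenerate)) " [degenerate: constant track]" else ""))
  if (!isTRUE(x$degenerate)) {
    cat("  means:", signif(x$means, 4), "\n")
    cat("  sds:  ", signif(sqrt(x$vars), 4), "\n")
    cat(sprintf("  logLik %.2f, AIC %.2f (%d params)\n",
                x$loglik, x$aic, x$n_params))
  }
  invisible(x)
}
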