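#' Build a time-reversible amino-acid substitution model
#'
#' The instantaneous rate matrix is assembled as `Q[a,b] = s[a,b] * pi[b]`
#' from symmetric exchangeabilities `s` and stationary frequencies `pi`, with
#' diagonal set so rows sum to zero, then calibrated so that the expected
#' number of substitutions per site per unit time at rate 1 is one
#' (`-sum(pi * diag(Q)) == 1`). Detailed balance `pi_a Q_ab = pi_b Q_ba`
#' holds by construction, which the likelihood code exploits through a
#' symmetric eigendecomposition.
#'
#' @param exchangeabilities 20x20 symmetric non-negative matrix (diagonal
#'   ignored), rows/cols in [AA_CODES] order, or the 190-element lower
#'   triangle in column order.
#' @param frequencies length-20 positive vector summing to 1, [AA_CODES]
#'   order.
#' @param name model name for display.
#' @return An object of class `subst_model`: list with `name`, `Q`, `pi` and
#'   a cached eigendecomposition used to form transition matrices.
#' @export
subst_model <- function(exchangeabilities, frequencies, name = "custom") {
  if (is.null(dim(exchangeabilities))) {
    if (length(exchangeabilities) != 190L)
      stop("expected 190 lower-triangle exchangeabilities")
    s <- matrix(0, 20, 20)
    s[lower.tri(s)] <- exchangeabilities
    s <- s + t(s)
  } else {
    s <- as.matrix(exchangeabilities)
    if (!all(dim(s) == c(20L, 20L))) stop("exchangeability matrix must be 20x20")
    if (max(abs(s - t(s))) > 1e-8) stop("exchangeabilities must be symmetric")
    diag(s) <- 0
  }
  pi <- as.numeric(frequencies)
  if (length(pi) != 20L) stop("frequencies must have length 20")
  if (any(pi <= 0)) stop("all stationary frequencies must be positive")
  pi <- pi / sum(pi)
  Q <- s * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix")
  Q <- Q / rate
  dimnames(Q) <- list(AA_CODES, AA_CODES)
  names(pi) <- AA_CODES
  # symmetric eigendecomposition of D^{1/2} Q D^{-1/2}
  sp <- sqrt(pi)
  sym <- Q * (sp %o% (1 / sp))
  sym <- (sym + t(sym)) / 2
  eig <- eigen(sym, symmetric = TRUE)
  left <- eig$vectors / sp           # D^{-1/2} U
  right <- t(eig$vectors * sp)       # U' D^{1/2}
  structure(list(name = name, Q = Q, pi = pi,
                 eig = list(values = eig$values, left = left, right = right)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model %s: 20-state reversible, 1 sub/site at rate 1>\n",
              x$name))
  invisible(x)
}

.model_cache <- new.env(parent = emptyenv())

#' The JTT amino-acid replacement model
#'
#' Jones-Taylor-Thornton exchangeabilities with their companion stationary
#' frequencies, taken from the tables shipped with the `phangorn` package and
#' calibrated by [subst_model()]. This is the package default; any
#' exchangeability table in the same layout (WAG, LG, ...) can be swapped in
#' through [subst_model()].
#'
#' @return A `subst_model`.
#' @export
jtt_model <- function() {
  if (is.null(.model_cache$jtt)) {
    tab <- getFromNamespace(".JTT", "phangorn")
    .model_cache$jtt <- subst_model(tab$Q, tab$bf, name = "JTT")
  }
  .model_cache$jtt
}

# Transition probability matrix P(t) = exp(Q t); tiny negative entries from
# the eigendecomposition are clamped and rows renormalized.
.prob_matrix <- function(model, t) {
  e <- model$eig
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discretize a gamma rate prior into equal-probability categories
#'
#' The prior over relative site rates is gamma with shape `alpha` and mean 1
#' (scale `1/alpha`). It is discretized into `K` categories of equal prior
#' weight `1/K`, each represented by the conditional mean of the distribution
#' over its quantile bin, so the category means average exactly to 1.
#'
#' @param alpha gamma shape parameter (> 0); small alpha means strong
#'   among-site rate variation.
#' @param K number of categories (>= 1), default 16.
#' @return An object of class `gamma_prior`: list with `alpha`, `K` and
#'   `rates` (strictly increasing, mean 1).
#' @export
discretize_gamma <- function(alpha, K = 16) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a positive number")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) {
    rates <- 1
  } else {
    qb <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
    # conditional means via the incomplete-gamma identity:
    # E[X; X in (a,b)] for gamma(shape,rate=shape) = F_{shape+1}(b) - F_{shape+1}(a)
    cm <- pgamma(qb, shape = alpha + 1, rate = alpha)
    rates <- K * diff(cm)
    rates <- rates / mean(rates)  # absorb quadrature round-off
  }
  if (any(diff(rates) <= 0) && K > 1L)
    stop("degenerate gamma discretization (alpha too extreme)")
  structure(list(alpha = alpha, K = K, rates = rates), class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("<gamma_prior alpha=%.4g, K=%d, rates %.3g..%.3g>\n",
              x$alpha, x$K, min(x$rates), max(x$rates)))
  invisible(x)
}
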