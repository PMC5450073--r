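#' @useDynLib supermatrix, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Amino-acid alphabet, PAML/phangorn ordering.  Characters outside this set
# ("-", "X", "?", "B", "Z", "J", "U", "O", "*") are treated as fully
# ambiguous throughout the package.
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid substitution models
#'
#' Constructs a reversible amino-acid substitution model from an empirical
#' exchangeability matrix and equilibrium frequencies, normalised so that
#' branch lengths are in expected substitutions per site.  `Poisson` is the
#' equal-rates, equal-frequency model; `JTT`, `WAG` and `LG` use the
#' published exchangeabilities and frequencies.
#'
#' @param name One of `"Poisson"`, `"JTT"`, `"WAG"`, `"LG"`.
#' @param freq Optional length-20 frequency vector overriding the model's
#'   equilibrium frequencies (order `ARNDCQEGHILKMFPSTWYV`).
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for a
#'   single rate class.
#' @param n_rate_categories Number of discrete gamma categories (default 4;
#'   category rates are conditional means).
#' @return An object of class `aa_model` holding the normalised rate matrix,
#'   its eigendecomposition, frequencies and rate categories.
#' @examples
#' m <- aa_model("WAG")
#' m$pi[1:5]
#' @export
aa_model <- function(name = c("Poisson", "JTT", "WAG", "LG"), freq = NULL,
                     alpha = NULL, n_rate_categories = 4L) {
  name <- match.arg(name)
  if (name == "Poisson") {
    S <- matrix(1, 20, 20)
    diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else {
    dat <- get(paste0(".", name), envir = environment(phangorn::pml))
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- dat$Q
    S <- S + t(S)
    pi <- unname(dat$bf)
  }
  if (!is.null(freq)) {
    stopifnot(length(freq) == 20, all(freq >= 0))
    pi <- freq / sum(freq)
  }
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)
  if (!is.null(alpha)) {
    stopifnot(is.numeric(alpha), alpha > 0)
    stopifnot(n_rate_categories >= 1)
  }
  obj <- structure(
    list(name = name, S = S, pi = pi, alpha = alpha,
         k = as.integer(n_rate_categories)),
    class = "aa_model"
  )
  obj <- model_decompose(obj)
  obj
}

# eigendecomposition of the normalised rate matrix; reused for all P(t)
model_decompose <- function(model) {
  S <- model$S
  pi <- model$pi
  Q <- S * rep(pi, each = 20)        # Q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))        # expected substitutions per unit length
  Q <- Q / scale
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))         # D^1/2 Q D^-1/2, symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  model$Q <- Q
  model$lambda <- eig$values
  model$V <- eig$vectors / sq        # row-scaled: D^-1/2 U
  model$Vinv <- t(eig$vectors) * rep(sq, each = 20)
  model
}

#' @export
print.aa_model <- function(x, ...) {
  cat("<aa_model>", x$name,
      if (is.null(x$alpha)) "(single rate)"
      else sprintf("(gamma alpha = %.4g, %d categories)", x$alpha, x$k),
      "\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' @param model An [aa_model()].
#' @param t Branch length (expected substitutions per site), `t >= 0`.
#' @return A 20 x 20 row-stochastic matrix (entries clamped to `[0, 1]`).
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "aa_model"), t >= 0)
  P <- model$V %*% (exp(model$lambda * t) * model$Vinv)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

# discrete-gamma category rates (conditional means), mean 1
discrete_gamma_rates <- function(alpha, k) {
  if (is.null(alpha) || k == 1L) return(list(rates = 1, weights = 1))
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  p <- c(0, stats::pgamma(q, shape = alpha + 1, rate = alpha), 1)
  list(rates = k * diff(p), weights = rep(1 / k, k))
}

model_rates <- function(model) {
  discrete_gamma_rates(model$alpha, model$k)
}
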