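# Independent oracles used to verify the package's estimators: Gauss-Hermite
# quadrature marginal maximum likelihood and EAP for one latent variable, and
# a tensor-product quadrature for expected scores under a 2-LV model. These
# deliberately share no code with the package's MHRM / Monte Carlo paths.

ghNodes <- function(n = 49) {
  gh <- pracma::gaussHermite(n)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# log-likelihood matrix (subjects x nodes) for a 1-LV model, direct formulas
gh1dLikMatrix <- function(responses, pars, nodes) {
  N <- nrow(responses)
  lik <- matrix(0, N, length(nodes))
  for (j in seq_along(pars)) {
    a <- pars[[j]]$a
    d <- pars[[j]]$d
    cum <- 1 / (1 + exp(-outer(nodes * a, d, "+")))
    pcat <- cbind(1, cum) - cbind(cum, 0)
    lik <- lik + log(pmax(t(pcat)[responses[, j] + 1L, , drop = FALSE], 1e-300))
  }
  lik
}

# marginal ML for a 1-LV model: BFGS over (a_j, d_j1, log gaps), quadrature
# integration over theta ~ N(0, 1)
ghMmlFit <- function(responses, nCat, start, nQuad = 49) {
  nd <- ghNodes(nQuad)
  J <- ncol(responses)
  pack <- function(pars) unlist(lapply(pars, function(p) {
    gaps <- if (length(p$d) > 1L) log(-diff(p$d)) else numeric(0)
    c(p$a, p$d[1L], gaps)
  }))
  unpack <- function(v) {
    out <- list(); i <- 1L
    for (j in seq_len(J)) {
      a <- v[i]; i <- i + 1L
      d <- v[i]; i <- i + 1L
      if (nCat[j] > 2L) for (k in seq_len(nCat[j] - 2L)) {
        d <- c(d, d[length(d)] - exp(v[i])); i <- i + 1L
      }
      out[[j]] <- list(a = a, d = d)
    }
    out
  }
  nll <- function(v) {
    lik <- gh1dLikMatrix(responses, unpack(v), nd$x)
    -sum(log(pmax(exp(lik) %*% nd$w, 1e-300)))
  }
  opt <- stats::optim(pack(start), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
  list(pars = unpack(opt$par), value = -opt$value, convergence = opt$convergence)
}

# EAP mean and variance for one subject under a 1-LV model, by quadrature
ghEap1d <- function(responses, pars, nQuad = 201) {
  nd <- ghNodes(nQuad)
  lik <- exp(gh1dLikMatrix(responses, pars, nd$x))
  post <- sweep(lik, 2L, nd$w, "*")
  post <- post / rowSums(post)
  m <- drop(post %*% nd$x)
  v <- drop(post %*% nd$x^2) - m^2
  list(mean = m, var = v)
}

# E[item score | theta ~ N(mu, Sg)] for a 2-LV model by tensor-product
# Gauss-Hermite quadrature (Cholesky transform of the nodes)
ghExpected2d <- function(item, mu, Sg, nQuad = 40) {
  nd <- ghNodes(nQuad)
  g <- expand.grid(i = seq_len(nQuad), j = seq_len(nQuad))
  Z <- cbind(nd$x[g$i], nd$x[g$j])
  W <- nd$w[g$i] * nd$w[g$j]
  Th <- sweep(Z %*% chol(Sg), 2L, mu, "+")
  a <- slopes(item)
  d <- intercepts(item)
  eta <- drop(Th %*% a)
  es <- rowSums(1 / (1 + exp(-outer(eta, d, "+"))))
  sum(W * es)
}
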