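#' @title Variational autoencoder embedding of methylation profiles
#'
#' @description
#' A multilayer-perceptron variational autoencoder mapping per-sample
#' beta-value profiles to a low-dimensional Gaussian posterior. The encoder
#' emits posterior means and log-variances; training maximizes the ELBO
#' (Bernoulli cross-entropy reconstruction of beta in \[0,1\] plus the
#' closed-form KL divergence from the standard-normal prior) by
#' reparameterized stochastic gradients with Adam. After training, the
#' embedding used downstream is the deterministic posterior mean.
#'
#' Implemented directly on BLAS matrix products with hand-derived gradients;
#' training is reproducible given a seed.
#'
#' @name embed
NULL

#' VAE training configuration
#'
#' @param latent_dim latent dimensionality d (>= 2; default 10).
#' @param hidden_sizes encoder hidden layer widths, mirrored in the decoder
#'   (default c(512, 64)).
#' @param activation "relu" or "tanh".
#' @param epochs,batch_size,learning_rate optimizer settings (defaults 200,
#'   8, 2e-3; small minibatches give enough gradient steps per epoch on
#'   cohort-sized sample counts).
#' @param val_fraction held-out fraction for the validation loss curve, in
#'   (0, 0.5] (default 0.2).
#' @param kl_warmup epochs over which the KL weight anneals linearly from 0
#'   to 1 (default a quarter of `epochs`); guards against posterior
#'   collapse on small cohorts.
#' @param seed integer RNG seed.
#' @return Configuration list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 10L, hidden_sizes = c(512L, 64L),
                       activation = "relu", epochs = 200L, batch_size = 8L,
                       learning_rate = 2e-3, val_fraction = 0.2,
                       kl_warmup = max(1L, epochs %/% 4L), seed = 1L) {
  if (latent_dim < 2) stop("latent_dim must be >= 2")
  if (val_fraction <= 0 || val_fraction > 0.5)
    stop("val_fraction must be in (0, 0.5]")
  if (!activation %in% c("relu", "tanh")) stop("unknown activation")
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 kl_warmup = as.integer(kl_warmup), seed = as.integer(seed)),
            class = "vae_config")
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' KL(N(mu, diag(sigma^2)) || N(0, I)) =
#' 0.5 * sum(sigma^2 + mu^2 - 1 - log sigma^2), summed over dimensions (and
#' rows, if matrices are given).
#'
#' @param mu,logvar numeric vectors or matrices of matching shape.
#' @return Non-negative scalar.
#' @export
kl_diag_gaussian <- function(mu, logvar) {
  stopifnot(all(is.finite(mu)), all(is.finite(logvar)))
  0.5 * sum(exp(logvar) + mu^2 - 1 - logvar)
}

act_fun <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)
act_grad <- function(a, kind) if (kind == "relu") (a > 0) * 1 else 1 - a^2

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(p, config) {
  h <- config$hidden_sizes
  d <- config$latent_dim
  enc_dims <- c(p, h)
  dec_dims <- c(d, rev(h))
  par <- list()
  for (i in seq_along(h)) {
    par[[paste0("We", i)]] <- glorot(enc_dims[i], enc_dims[i + 1])
    par[[paste0("be", i)]] <- numeric(enc_dims[i + 1])
  }
  par$Wmu <- glorot(h[length(h)], d); par$bmu <- numeric(d)
  par$Wlv <- glorot(h[length(h)], d); par$blv <- numeric(d)
  for (i in seq_along(h)) {
    par[[paste0("Wd", i)]] <- glorot(dec_dims[i], dec_dims[i + 1])
    par[[paste0("bd", i)]] <- numeric(dec_dims[i + 1])
  }
  par$Wout <- glorot(h[1], p); par$bout <- numeric(p)
  par
}

# forward pass; returns activations needed for the backward pass
vae_forward <- function(X, par, config, eps = NULL) {
  kind <- config$activation
  nh <- length(config$hidden_sizes)
  H <- vector("list", nh); A <- X
  for (i in seq_len(nh)) {
    A <- act_fun(sweep(A %*% par[[paste0("We", i)]], 2, -par[[paste0("be", i)]]),
                 kind)
    H[[i]] <- A
  }
  mu <- sweep(A %*% par$Wmu, 2, -par$bmu)
  lv <- sweep(A %*% par$Wlv, 2, -par$blv)
  lv <- pmin(pmax(lv, -10), 10)  # keep sigma^2 in a sane range
  z <- if (is.null(eps)) mu else mu + eps * exp(0.5 * lv)
  D <- vector("list", nh); B <- z
  for (i in seq_len(nh)) {
    B <- act_fun(sweep(B %*% par[[paste0("Wd", i)]], 2, -par[[paste0("bd", i)]]),
                 kind)
    D[[i]] <- B
  }
  logits <- sweep(B %*% par$Wout, 2, -par$bout)
  list(H = H, mu = mu, lv = lv, z = z, D = D, logits = logits)
}

# numerically stable Bernoulli cross-entropy from logits, summed over features
bce_from_logits <- function(logits, X) {
  sum(pmax(logits, 0) - logits * X + log1p(exp(-abs(logits))))
}

vae_losses <- function(X, par, config, eps = NULL) {
  fw <- vae_forward(X, par, config, eps)
  n <- nrow(X)
  recon <- bce_from_logits(fw$logits, X) / n
  kl <- kl_diag_gaussian(fw$mu, fw$lv) / n
  c(recon = recon, kl = kl, loss = recon + kl)
}

vae_backward <- function(X, par, config, fw, eps, kl_weight = 1) {
  kind <- config$activation
  nh <- length(config$hidden_sizes)
  n <- nrow(X)
  g <- list()
  # decoder
  dlogits <- (1 / (1 + exp(-fw$logits)) - X) / n
  g$Wout <- crossprod(fw$D[[nh]], dlogits)
  g$bout <- colSums(dlogits)
  dA <- dlogits %*% t(par$Wout)
  for (i in rev(seq_len(nh))) {
    dpre <- dA * act_grad(fw$D[[i]], kind)
    prev <- if (i == 1) fw$z else fw$D[[i - 1]]
    g[[paste0("Wd", i)]] <- crossprod(prev, dpre)
    g[[paste0("bd", i)]] <- colSums(dpre)
    dA <- dpre %*% t(par[[paste0("Wd", i)]])
  }
  dz <- dA
  # reparameterization + KL gradients
  sig <- exp(0.5 * fw$lv)
  dmu <- dz + kl_weight * fw$mu / n
  dlv <- dz * eps * 0.5 * sig + kl_weight * 0.5 * (exp(fw$lv) - 1) / n
  top <- fw$H[[nh]]
  g$Wmu <- crossprod(top, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(top, dlv); g$blv <- colSums(dlv)
  dA <- dmu %*% t(par$Wmu) + dlv %*% t(par$Wlv)
  for (i in rev(seq_len(nh))) {
    dpre <- dA * act_grad(fw$H[[i]], kind)
    prev <- if (i == 1) X else fw$H[[i - 1]]
    g[[paste0("We", i)]] <- crossprod(prev, dpre)
    g[[paste0("be", i)]] <- colSums(dpre)
    dA <- dpre %*% t(par[[paste0("We", i)]])
  }
  g
}

#' Train the variational autoencoder
#'
#' @param beta probes x samples beta matrix, complete, values in \[0,1\]
#'   (typically the batch-adjusted, QC-filtered matrix).
#' @param config a [vae_config()].
#' @return List with `model` (weights, config, probe ids) and `embedding`
#'   (list with `mu`, `logvar` for all samples, and `history` of per-epoch
#'   train/validation reconstruction, KL and total losses).
#' @export
train_vae <- function(beta, config = vae_config()) {
  check_beta_matrix(beta)
  if (anyNA(beta)) stop("train_vae requires a complete matrix")
  X <- t(beta)  # samples x probes
  n <- nrow(X)
  if (n < config$batch_size)
    stop("fewer samples (", n, ") than minibatch size (", config$batch_size, ")")
  set.seed(config$seed)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < config$batch_size)
    stop("training split smaller than minibatch size")
  Xtr <- X[tr_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]

  par <- init_params(ncol(X), config)
  mstate <- lapply(par, function(x) x * 0)
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t <- 0
  hist <- data.frame()

  for (epoch in seq_len(config$epochs)) {
    kl_w <- min(1, epoch / config$kl_warmup)
    ord <- sample(nrow(Xtr))
    starts <- seq(1, length(ord) - config$batch_size + 1, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:(s + config$batch_size - 1)]
      Xi <- Xtr[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(nrow(Xi) * config$latent_dim),
                    nrow(Xi), config$latent_dim)
      fw <- vae_forward(Xi, par, config, eps)
      g <- vae_backward(Xi, par, config, fw, eps, kl_weight = kl_w)
      t <- t + 1
      for (nm in names(par)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mstate[[nm]] / (1 - b1^t)
        vhat <- vstate[[nm]] / (1 - b2^t)
        par[[nm]] <- par[[nm]] - config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    # epoch losses at the posterior mean (deterministic; KL term unchanged)
    ltr <- vae_losses(Xtr, par, config)
    lval <- vae_losses(Xval, par, config)
    if (!all(is.finite(c(ltr, lval))))
      stop("non-finite loss at epoch ", epoch)
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_recon = ltr["recon"], train_kl = ltr["kl"],
      train_loss = ltr["loss"], val_recon = lval["recon"],
      val_kl = lval["kl"], val_loss = lval["loss"], row.names = NULL))
  }

  model <- list(par = par, config = config, probe_ids = rownames(beta))
  class(model) <- "methylotyper_vae"
  emb <- encode(model, beta)
  emb$history <- hist
  list(model = model, embedding = emb)
}

#' Encode samples with a trained VAE
#'
#' Returns the deterministic posterior means (no sampling), one row per
#' sample in input order.
#'
#' @param model trained model from [train_vae()].
#' @param beta probes x samples beta matrix on the model's probe set.
#' @return List with `mu` (samples x d) and `logvar` matrices.
#' @export
encode <- function(model, beta) {
  stopifnot(inherits(model, "methylotyper_vae"))
  missing_probes <- setdiff(model$probe_ids, rownames(beta))
  if (length(missing_probes))
    stop("probe set mismatch; missing probes: ",
         paste(utils::head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) " ..." else "")
  X <- t(beta[model$probe_ids, , drop = FALSE])
  fw <- vae_forward(X, model$par, model$config, eps = NULL)
  mu <- fw$mu
  lv <- fw$lv
  dimnames(mu) <- list(colnames(beta), paste0("z", seq_len(ncol(mu))))
  dimnames(lv) <- dimnames(mu)
  list(mu = mu, logvar = lv)
}
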