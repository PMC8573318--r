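#' Variational autoencoder for excitability fields
#'
#' A fully connected VAE with a 2-D latent space embeds per-node
#' excitability fields into coordinates `z` where the active-learning
#' search runs. Encoder and decoder each have two hidden layers of
#' softplus units (default 512 each, mirroring widths used for training
#' corpora of region-grown fields); the encoder outputs a mean and
#' log-variance per latent dimension, the decoder outputs the expectation
#' of a fixed-variance Gaussian likelihood through a sigmoid scaled to
#' [0, 0.5], so decoded fields always respect the physiological bounds.
#'
#' All forward/backward passes are plain BLAS matrix algebra; training uses
#' Adam with the reparameterization trick and is bit-reproducible under a
#' fixed seed (single-threaded BLAS).
#'
#' @name vae
#' @keywords internal
NULL

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize VAE parameters
#'
#' Glorot-uniform weight initialization.
#'
#' @param n_input field length (node count)
#' @param hidden hidden-layer widths (length 2)
#' @param latent_dim latent dimensionality (2 for this workflow)
#' @param obs_var decoder observation variance (Gaussian likelihood). The
#'   default 0.1^2 keeps the latent informative (a unit variance is too
#'   weak to pay the KL cost and collapses the posterior) while keeping the
#'   aggregate encoded posterior close to the standard-normal latent prior
#' @param seed RNG seed
#' @return a `vae_params` list of weight matrices and bias vectors
#' @export
vae_init <- function(n_input, hidden = c(512L, 512L), latent_dim = 2L,
                     obs_var = 0.01, seed = 1L) {
  rng <- local_rng(seed)
  glorot <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(rng$runif(nin * nout, -r, r), nin, nout)
  }
  p <- list(
    W1 = glorot(n_input, hidden[1]), b1 = rep(0, hidden[1]),
    W2 = glorot(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
    Wmu = glorot(hidden[2], latent_dim), bmu = rep(0, latent_dim),
    Wlv = glorot(hidden[2], latent_dim), blv = rep(0, latent_dim),
    V1 = glorot(latent_dim, hidden[2]), c1 = rep(0, hidden[2]),
    V2 = glorot(hidden[2], hidden[1]), c2 = rep(0, hidden[1]),
    V3 = glorot(hidden[1], n_input), c3 = rep(0, n_input)
  )
  attr(p, "n_input") <- as.integer(n_input)
  attr(p, "latent_dim") <- as.integer(latent_dim)
  attr(p, "hidden") <- as.integer(hidden)
  attr(p, "obs_var") <- obs_var
  class(p) <- "vae_params"
  p
}

# Encoder forward pass; X is batch x n_input. Returns activations needed
# for backprop.
vae_encode_fwd <- function(p, X) {
  a1 <- sweep(X %*% p$W1, 2, p$b1, `+`); h1 <- softplus(a1)
  a2 <- sweep(h1 %*% p$W2, 2, p$b2, `+`); h2 <- softplus(a2)
  mu <- sweep(h2 %*% p$Wmu, 2, p$bmu, `+`)
  lv <- sweep(h2 %*% p$Wlv, 2, p$blv, `+`)
  list(a1 = a1, h1 = h1, a2 = a2, h2 = h2, mu = mu, lv = lv)
}

# Decoder forward pass; Z is batch x latent_dim.
vae_decode_fwd <- function(p, Z) {
  b1 <- sweep(Z %*% p$V1, 2, p$c1, `+`); g1 <- softplus(b1)
  b2 <- sweep(g1 %*% p$V2, 2, p$c2, `+`); g2 <- softplus(b2)
  pre <- sweep(g2 %*% p$V3, 2, p$c3, `+`)
  list(b1 = b1, g1 = g1, b2 = b2, g2 = g2, pre = pre,
       mu_theta = 0.5 * sigmoid(pre))
}

#' Posterior encoding of a field
#'
#' @param params a trained `vae_params`
#' @param theta excitability field (vector) or batch matrix (rows = fields)
#' @return list with `mean` and `log_var` (each latent-dim columns)
#' @export
vae_encode <- function(params, theta) {
  X <- if (is.matrix(theta)) theta else matrix(theta, 1)
  enc <- vae_encode_fwd(params, X)
  list(mean = enc$mu, log_var = enc$lv)
}

#' Decoder expectation
#'
#' Deterministic generative map E[p(theta | z)]: the decoder mean, bounded
#' in [0, 0.5] by construction.
#'
#' @param params a trained `vae_params`
#' @param z latent point (length-2 vector) or matrix of rows
#' @return excitability field vector (or batch matrix for matrix input)
#' @export
vae_decode <- function(params, z) {
  Z <- if (is.matrix(z)) z else matrix(z, 1)
  out <- vae_decode_fwd(params, Z)$mu_theta
  if (is.matrix(z)) out else as.numeric(out)
}

#' Evidence lower bound for one field
#'
#' L = -KL(q(z|theta) || N(0, I)) + E_q[log p(theta|z)], the KL term in
#' closed form for diagonal Gaussians and the expectation by a single
#' reparameterized sample. The reconstruction term is the Gaussian
#' log-likelihood with observation variance `attr(params, "obs_var")`, up
#' to its additive constant: -0.5 * ||theta - mu_dec(z)||^2 / obs_var.
#'
#' @param params a `vae_params`
#' @param theta one excitability field
#' @param rng_seed seed for the reparameterized draw
#' @return list: `elbo`, `kl`, `recon` (elbo = recon - kl)
#' @export
vae_elbo <- function(params, theta, rng_seed = 1L) {
  if (length(theta) != attr(params, "n_input"))
    stop("field length does not match the decoder width")
  enc <- vae_encode_fwd(params, matrix(theta, 1))
  kl <- 0.5 * sum(enc$mu^2 + exp(enc$lv) - enc$lv - 1)
  rng <- local_rng(rng_seed)
  epsd <- rng$rnorm(length(enc$mu))
  z <- enc$mu + exp(0.5 * enc$lv) * matrix(epsd, 1)
  dec <- vae_decode_fwd(params, z)
  recon <- -0.5 * sum((theta - dec$mu_theta)^2) / attr(params, "obs_var")
  out <- list(elbo = recon - kl, kl = kl, recon = recon)
  if (!all(vapply(out, is.finite, TRUE)))
    stop(sprintf("non-finite ELBO (kl = %g, recon = %g)", kl, recon))
  out
}

# One minibatch forward+backward; returns loss and gradients.
# kl_beta scales the KL term's contribution to the *gradient* (warm-up
# annealing); reported losses always use the full ELBO (beta = 1).
vae_batch_grad <- function(p, X, eps, kl_beta = 1) {
  B <- nrow(X)
  ov <- attr(p, "obs_var")
  enc <- vae_encode_fwd(p, X)
  sd_z <- exp(0.5 * enc$lv)
  Z <- enc$mu + sd_z * eps
  dec <- vae_decode_fwd(p, Z)
  resid <- dec$mu_theta - X
  recon <- 0.5 * sum(resid^2) / ov / B
  kl <- 0.5 * sum(enc$mu^2 + exp(enc$lv) - enc$lv - 1) / B
  # backward: decoder
  dpre <- (resid / (ov * B)) * 0.5 * dec$mu_theta / 0.5 * (1 - dec$mu_theta / 0.5)
  # = resid/(obs_var*B) * 0.5 * s(1-s) with s = sigmoid(pre)
  gV3 <- crossprod(dec$g2, dpre); gc3 <- colSums(dpre)
  dg2 <- tcrossprod(dpre, p$V3) * sigmoid(dec$b2)
  gV2 <- crossprod(dec$g1, dg2); gc2 <- colSums(dg2)
  dg1 <- tcrossprod(dg2, p$V2) * sigmoid(dec$b1)
  gV1 <- crossprod(Z, dg1); gc1 <- colSums(dg1)
  dZ <- tcrossprod(dg1, p$V1)
  # latent + KL
  dmu <- dZ + kl_beta * enc$mu / B
  dlv <- dZ * eps * 0.5 * sd_z + kl_beta * 0.5 * (exp(enc$lv) - 1) / B
  # encoder
  gWmu <- crossprod(enc$h2, dmu); gbmu <- colSums(dmu)
  gWlv <- crossprod(enc$h2, dlv); gblv <- colSums(dlv)
  dh2 <- (tcrossprod(dmu, p$Wmu) + tcrossprod(dlv, p$Wlv)) * sigmoid(enc$a2)
  gW2 <- crossprod(enc$h1, dh2); gb2 <- colSums(dh2)
  dh1 <- tcrossprod(dh2, p$W2) * sigmoid(enc$a1)
  gW1 <- crossprod(X, dh1); gb1 <- colSums(dh1)
  list(loss = recon + kl, recon = recon, kl = kl,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    Wmu = gWmu, bmu = gbmu, Wlv = gWlv, blv = gblv,
                    V1 = gV1, c1 = gc1, V2 = gV2, c2 = gc2,
                    V3 = gV3, c3 = gc3))
}

#' Train the VAE on a corpus
#'
#' Adam optimization of the negative ELBO with minibatches, a validation
#' split for early stopping (the epoch with the best validation loss wins),
#' and a logged training curve. Identical seeds give identical parameters.
#'
#' @param corpus a `training_corpus` (or plain fields matrix)
#' @param hidden hidden widths (default c(512, 512))
#' @param latent_dim latent dimensionality (default 2)
#' @param batch_size minibatch size (default 64)
#' @param epochs maximum epochs (default 100)
#' @param lr Adam learning rate (default 1e-3)
#' @param val_frac validation fraction for early stopping (default 0.1)
#' @param obs_var decoder observation variance (see [vae_init()])
#' @param patience epochs without validation improvement before stopping
#' @param kl_warmup epochs over which the KL term's weight ramps linearly
#'   from 0 to 1 (warm-up annealing that prevents posterior collapse; the
#'   reported and early-stopped losses are always the full ELBO)
#' @param seed RNG seed controlling split, shuffling and reparameterization
#' @param verbose print per-epoch losses
#' @return a trained `vae_params` with attributes `history` (data frame of
#'   per-epoch train/validation loss) and `config`
#' @export
train_vae <- function(corpus, hidden = c(512L, 512L), latent_dim = 2L,
                      batch_size = 64L, epochs = 100L, lr = 1e-3,
                      val_frac = 0.1, patience = 10L, kl_warmup = 10L,
                      obs_var = 0.01, seed = 1L, verbose = FALSE) {
  X <- if (inherits(corpus, "training_corpus")) corpus$fields else corpus
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  rng <- local_rng(seed)
  p <- vae_init(ncol(X), hidden, latent_dim, obs_var = obs_var,
                seed = seed + 1L)
  n <- nrow(X)
  n_val <- max(1L, as.integer(round(val_frac * n)))
  perm <- rng$sample_int(n, n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xtr <- X[tr_idx, , drop = FALSE]; Xval <- X[val_idx, , drop = FALSE]
  adam_m <- lapply(p, function(w) w * 0)
  adam_v <- lapply(p, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
  nm <- names(p)
  val_loss <- function(pp) {
    eps <- matrix(rng$rnorm(nrow(Xval) * latent_dim), ncol = latent_dim)
    enc <- vae_encode_fwd(pp, Xval)
    Z <- enc$mu + exp(0.5 * enc$lv) * eps
    dec <- vae_decode_fwd(pp, Z)
    (0.5 * sum((dec$mu_theta - Xval)^2) / obs_var +
       0.5 * sum(enc$mu^2 + exp(enc$lv) - enc$lv - 1)) / nrow(Xval)
  }
  best <- list(loss = Inf, params = p, epoch = 0L)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  stall <- 0L
  for (ep in seq_len(epochs)) {
    kl_beta <- if (kl_warmup > 0) min(1, ep / kl_warmup) else 1
    ord <- rng$sample_int(nrow(Xtr), nrow(Xtr))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1, nrow(Xtr), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, nrow(Xtr))]
      Xb <- Xtr[idx, , drop = FALSE]
      eps <- matrix(rng$rnorm(length(idx) * latent_dim), ncol = latent_dim)
      bg <- vae_batch_grad(p, Xb, eps, kl_beta = kl_beta)
      t_step <- t_step + 1
      for (k in nm) {
        g <- bg$grads[[k]]
        adam_m[[k]] <- beta1 * adam_m[[k]] + (1 - beta1) * g
        adam_v[[k]] <- beta2 * adam_v[[k]] + (1 - beta2) * g^2
        mhat <- adam_m[[k]] / (1 - beta1^t_step)
        vhat <- adam_v[[k]] / (1 - beta2^t_step)
        p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
      ep_loss <- ep_loss + bg$loss; n_batches <- n_batches + 1L
    }
    vl <- val_loss(p)
    hist <- rbind(hist, data.frame(epoch = ep, train = ep_loss / n_batches,
                                   val = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      ep_loss / n_batches, vl))
    if (ep >= kl_warmup) {      # early stopping engages after warm-up
      if (vl < best$loss - 1e-8) {
        best <- list(loss = vl, params = p, epoch = ep); stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  out <- if (best$epoch > 0L) best$params else p
  attr(out, "history") <- hist
  attr(out, "config") <- list(hidden = hidden, latent_dim = latent_dim,
                              batch_size = batch_size, epochs = epochs,
                              lr = lr, val_frac = val_frac, seed = seed,
                              best_epoch = best$epoch)
  out
}

#' @export
print.vae_params <- function(x, ...) {
  cat(sprintf("vae_params: %d -> (%s) -> %d latent, softplus hidden units\n",
              attr(x, "n_input"), paste(attr(x, "hidden"), collapse = ", "),
              attr(x, "latent_dim")))
  invisible(x)
}

#' Resample a field between geometries by nearest node
#'
#' Cross-geometry transfer (train the VAE on one heart, infer on another)
#' maps fields through nearest-node lookup; node counts may differ.
#'
#' @param field excitability field on `from_geom`
#' @param from_geom,to_geom `cardiac_geometry` objects
#' @return field on `to_geom`'s nodes
#' @export
resample_field <- function(field, from_geom, to_geom) {
  stopifnot(length(field) == n_nodes(from_geom))
  A <- to_geom$node_coords; B <- from_geom$node_coords
  D2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  field[max.col(-D2)]
}

#' Save / load VAE parameters as a JSON checkpoint
#' @param params a `vae_params`
#' @param path file path (.json)
#' @return `path` invisibly; `read_vae` returns `vae_params`
#' @export
write_vae <- function(params, path) {
  payload <- list(
    weights = lapply(unclass(params)[names(params)], function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))),
    n_input = attr(params, "n_input"),
    latent_dim = attr(params, "latent_dim"),
    hidden = attr(params, "hidden"),
    obs_var = attr(params, "obs_var"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_vae
#' @export
read_vae <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(payload$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  attr(p, "n_input") <- as.integer(payload$n_input)
  attr(p, "latent_dim") <- as.integer(payload$latent_dim)
  attr(p, "hidden") <- as.integer(payload$hidden)
  attr(p, "obs_var") <- as.numeric(payload$obs_var)
  class(p) <- "vae_params"
  p
}
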