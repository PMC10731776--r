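#' Symmetrically normalized self-looped adjacency
#'
#' Adds a self-loop to every node of the weighted similarity graph and
#' applies the symmetric degree normalization
#' `D^(-1/2) (SM + I) D^(-1/2)` used by graph-convolution layers.
#'
#' @param SM Symmetric nonnegative matrix (fused similarity network).
#' @return Symmetric normalized adjacency of the same shape.
#' @export
normalize_adjacency <- function(SM) {
  SM <- as.matrix(SM)
  if (max(abs(SM - t(SM))) > 1e-9) abort("adjacency must be symmetric")
  if (min(SM) < 0) abort("adjacency must be nonnegative")
  Ab <- SM + diag(nrow(SM))
  dis <- 1 / sqrt(rowSums(Ab))
  An <- Ab * outer(dis, dis)
  (An + t(An)) / 2
}

# Glorot-uniform weight init
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize encoder/decoder parameters
#'
#' Weight layout: two shared graph-convolution layers (`W0`, `W1`), one
#' mean head and one log-variance head per latent scale, and two
#' single-hidden-layer perceptrons that reconstruct the first- and
#' second-layer activations from the concatenated latent code. All weights
#' are Glorot-uniform; biases start at zero. Uses the current RNG state.
#'
#' @param n_features Input feature dimension (columns of `X`).
#' @param cfg An [mdlink_config()]; `base_hidden_dims` and `scales` fix the
#'   shapes.
#' @param mlp_hidden Hidden width of the auxiliary perceptrons.
#' @return A list of parameter matrices/vectors.
#' @export
vgae_init <- function(n_features, cfg, mlp_hidden = 128L) {
  h <- cfg$base_hidden_dims
  dz <- sum(cfg$scales)
  params <- list(
    W0 = glorot(n_features, h[1]),
    W1 = glorot(h[1], h[2]),
    W_mu = lapply(cfg$scales, function(s) glorot(h[2], s)),
    W_sg = lapply(cfg$scales, function(s) glorot(h[2], s)),
    V1 = glorot(dz, mlp_hidden), c1 = rep(0, mlp_hidden),
    U1 = glorot(mlp_hidden, h[1]), d1 = rep(0, h[1]),
    V2 = glorot(dz, mlp_hidden), c2 = rep(0, mlp_hidden),
    U2 = glorot(mlp_hidden, h[2]), d2 = rep(0, h[2])
  )
  params
}

#' Encode node features into per-scale latent Gaussian parameters
#'
#' Two shared graph-convolution layers with ReLU activations feed one pair
#' of linear graph-convolution heads per scale, producing each node's
#' posterior mean and log standard deviation at that scale (heads carry no
#' activation).
#'
#' @param An Normalized adjacency from [normalize_adjacency()].
#' @param X Node feature matrix (rows = nodes).
#' @param params Parameters from [vgae_init()].
#' @return A list with pre-activations `A1`, `A2`, activations `H1`, `H2`,
#'   and per-scale lists `MU`, `LS` (means and log standard deviations).
#' @export
vgae_encode <- function(An, X, params) {
  A1 <- An %*% X %*% params$W0
  H1 <- pmax(A1, 0)
  A2 <- An %*% H1 %*% params$W1
  H2 <- pmax(A2, 0)
  AH2 <- An %*% H2
  MU <- lapply(params$W_mu, function(W) AH2 %*% W)
  LS <- lapply(params$W_sg, function(W) AH2 %*% W)
  if (any(!vapply(c(MU, LS), function(m) all(is.finite(m)), TRUE))) {
    abort("non-finite values in encoder activations")
  }
  list(A1 = A1, H1 = H1, A2 = A2, H2 = H2, MU = MU, LS = LS)
}

#' Draw latent samples by the reparameterization trick
#'
#' `Z_i = mu_i + exp(log_sigma_i) * eps` with independent standard-normal
#' draws per scale; the per-scale samples are concatenated column-wise. In
#' evaluation mode (`sample = FALSE`) the means are used directly.
#'
#' @param state Encoder output from [vgae_encode()].
#' @param sample Draw noise (`TRUE`) or return the means (`FALSE`).
#' @param eps Optional list of pre-drawn noise matrices (for testing);
#'   otherwise drawn from the current RNG state.
#' @return `state` extended with `E` (noise), `Z_list` and concatenated `Z`.
#' @export
vgae_reparameterize <- function(state, sample = TRUE, eps = NULL) {
  M <- length(state$MU)
  if (!sample) {
    state$E <- NULL
    state$Z_list <- state$MU
  } else {
    if (is.null(eps)) {
      eps <- lapply(state$MU, function(m) {
        matrix(rnorm(length(m)), nrow(m), ncol(m))
      })
    }
    state$E <- eps
    state$Z_list <- lapply(seq_len(M), function(m) {
      state$MU[[m]] + exp(state$LS[[m]]) * eps[[m]]
    })
  }
  state$Z <- do.call(cbind, state$Z_list)
  state
}

#' Inner-product adjacency decoder
#'
#' @param Z Latent matrix (rows = nodes).
#' @return `sigmoid(Z %*% t(Z))`: a symmetric matrix with entries in (0, 1).
#' @export
decode_adjacency <- function(Z) {
  L <- tcrossprod(Z)
  1 / (1 + exp(-L))
}

#' Auxiliary multi-order embedding reconstruction
#'
#' Two perceptrons project the concatenated latent code back to the widths
#' of the first- and second-layer activations, through a ReLU hidden layer
#' and a sigmoid output.
#'
#' @param Z Latent matrix.
#' @param params Parameters from [vgae_init()].
#' @return List with `X1_hat`, `X2_hat` and the hidden pre-activations
#'   (`B1`, `R1`, `B2`, `R2`) needed for backpropagation.
#' @export
decode_aux <- function(Z, params) {
  B1 <- sweep(Z %*% params$V1, 2, params$c1, "+")
  R1 <- pmax(B1, 0)
  O1 <- sweep(R1 %*% params$U1, 2, params$d1, "+")
  B2 <- sweep(Z %*% params$V2, 2, params$c2, "+")
  R2 <- pmax(B2, 0)
  O2 <- sweep(R2 %*% params$U2, 2, params$d2, "+")
  list(X1_hat = 1 / (1 + exp(-O1)), X2_hat = 1 / (1 + exp(-O2)),
       B1 = B1, R1 = R1, B2 = B2, R2 = R2)
}

# mean binary cross entropy with soft targets in [0, 1]
bce_mean <- function(target, prob) {
  if (min(target) < 0 || max(target) > 1) {
    abort("BCE target outside [0, 1]: normalize before the loss")
  }
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# column-wise min-max to [0, 1]; constant columns map to 0.5
col_minmax <- function(H) {
  lo <- apply(H, 2, min); hi <- apply(H, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  rng[flat] <- 1
  T <- sweep(sweep(H, 2, lo), 2, rng, "/")
  T[, flat] <- 0.5
  T
}

#' Train the multi-scale variational graph autoencoder
#'
#' Full-graph gradient training of the encoder/decoder with the Adam
#' optimizer and a step-decayed learning rate. The loss is the sum of (i)
#' binary cross entropy between the fused similarity network and its
#' inner-product reconstruction, (ii) the mean over scales of the
#' 2-Wasserstein distance between each scale's latent sample cloud and an
#' equal-size draw from the standard-normal prior (entropic Sinkhorn
#' estimate, with the transport plan held fixed for the gradient), and
#' (iii) half the summed binary cross entropies of the two auxiliary
#' embedding reconstructions against the column-rescaled layer activations
#' (targets detached from the gradient). With
#' `cfg$wd_mode = "gaussian"` the prior term is instead the per-node
#' closed-form diagonal-Gaussian 2-Wasserstein distance.
#'
#' Training is deterministic given `cfg$seed`.
#'
#' @param SM Fused `similarity_matrix` used as weighted adjacency (entries
#'   in \[0, 1\], unit diagonal).
#' @param X Node feature matrix aligned with `SM` rows (for association
#'   data: rows of `A` for microbes, rows of `t(A)` for diseases).
#' @param cfg An [mdlink_config()].
#' @param verbose Log one line every 50 epochs.
#' @return An object of class `mdlink_vgae`: parameters, the evaluation
#'   embedding (`embedding`), the per-epoch loss history tibble
#'   (`history`), and the reconstruction of the adjacency at convergence.
#' @export
vgae_train <- function(SM, X, cfg = mdlink_config(), verbose = FALSE) {
  SM <- as.matrix(SM); X <- as.matrix(X)
  if (nrow(SM) != nrow(X)) abort("SM and X must have the same number of rows")
  validate_config(cfg)
  n <- nrow(SM)
  M <- length(cfg$scales)
  An <- normalize_adjacency(SM)
  set.seed(cfg$seed)
  params <- vgae_init(ncol(X), cfg)
  opt <- adam_new(params)
  hist <- vector("list", cfg$epochs)
  last <- NULL

  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$learning_rate * cfg$lr_gamma ^ floor((epoch - 1) / cfg$lr_step)
    step <- vgae_step(params, An, X, SM, cfg)
    if (!is.finite(step$total)) {
      abort(sprintf("non-finite loss at epoch %d", epoch))
    }
    upd <- adam_step(opt, params, step$grads, lr)
    params <- upd$params; opt <- upd$opt
    hist[[epoch]] <- c(epoch = epoch, bce_adj = step$bce_adj,
                       wd_prior = step$wd_prior, aux_1 = step$aux_1,
                       aux_2 = step$aux_2, total = step$total, lr = lr)
    if (verbose && (epoch %% 50 == 0 || epoch == 1)) {
      log_stage("vgae", epoch = epoch, loss = sprintf("%.4f", step$total))
    }
  }

  eval_state <- vgae_reparameterize(vgae_encode(An, X, params), sample = FALSE)
  emb <- eval_state$Z
  rownames(emb) <- rownames(SM)
  structure(list(
    params = params,
    embedding = emb,
    history = tibble::as_tibble(do.call(rbind, hist)),
    SM_hat = decode_adjacency(emb),
    labels = rownames(SM),
    cfg = cfg,
    n_nodes = n,
    n_features = ncol(X)
  ), class = "mdlink_vgae")
}

# one full-graph loss + gradient evaluation; eps (reparameterization noise)
# and priors (standard-normal sample clouds) may be supplied for testing,
# otherwise they are drawn from the current RNG state; targets overrides
# the detached auxiliary targets (list(T1, T2)), again for testing
vgae_step <- function(params, An, X, SM, cfg, eps = NULL, priors = NULL,
                      targets = NULL) {
  n <- nrow(SM)
  M <- length(cfg$scales)
  {
    st <- vgae_encode(An, X, params)
    st <- vgae_reparameterize(st, sample = TRUE, eps = eps)
    Z <- st$Z
    SM_hat <- decode_adjacency(Z)
    aux <- decode_aux(Z, params)
    if (is.null(targets)) {
      T1 <- col_minmax(st$H1); T2 <- col_minmax(st$H2)
    } else {
      T1 <- targets[[1]]; T2 <- targets[[2]]
    }

    bce_adj <- bce_mean(SM, SM_hat)
    aux_1 <- bce_mean(T1, aux$X1_hat)
    aux_2 <- bce_mean(T2, aux$X2_hat)

    # ---- prior discrepancy per scale (and its gradient wrt Z / mu,logsig)
    dZ_wd <- lapply(st$Z_list, function(z) 0 * z)
    dMU_wd <- dZ_wd; dLS_wd <- dZ_wd
    wd_vals <- numeric(M)
    if (cfg$wd_mode == "sinkhorn") {
      for (m in seq_len(M)) {
        Zm <- st$Z_list[[m]]
        # per-dimension normalization keeps the scales (16/32/64 dims)
        # commensurable inside the 1/M average
        sc <- 1 / sqrt(ncol(Zm))
        Qm <- if (is.null(priors)) {
          matrix(rnorm(length(Zm)), n, ncol(Zm))
        } else priors[[m]]
        sk <- sinkhorn_w2(Zm, Qm, epsilon = cfg$sinkhorn_epsilon,
                          iters = cfg$sinkhorn_iters, return_plan = TRUE,
                          warn_nonconv = FALSE)
        wd_vals[m] <- sc * sk$distance
        # Danskin: differentiate the transported cost at the fixed plan
        dZ_wd[[m]] <- sc * (Zm / n - sk$plan %*% Qm) /
          (M * max(sk$distance, 1e-8))
      }
    } else {
      for (m in seq_len(M)) {
        MUm <- st$MU[[m]]; Sm <- exp(st$LS[[m]])
        sc <- 1 / sqrt(ncol(MUm))
        wi <- sqrt(rowSums(MUm ^ 2) + rowSums((Sm - 1) ^ 2))
        wd_vals[m] <- sc * mean(wi)
        wi_safe <- pmax(wi, 1e-8)
        dMU_wd[[m]] <- sc * MUm / (wi_safe * n * M)
        dLS_wd[[m]] <- sc * ((Sm - 1) / (wi_safe * n * M)) * Sm
      }
    }
    wd_prior <- mean(wd_vals)
    total <- bce_adj + wd_prior + 0.5 * (aux_1 + aux_2)

    # ---- backward pass
    grads <- rapply(params, function(p) 0 * p, how = "replace")

    G_adj <- (SM_hat - SM) / length(SM)
    dZ <- (G_adj + t(G_adj)) %*% Z

    G1 <- 0.5 * (aux$X1_hat - T1) / length(T1)
    grads$U1 <- crossprod(aux$R1, G1); grads$d1 <- colSums(G1)
    dB1 <- (G1 %*% t(params$U1)) * (aux$B1 > 0)
    grads$V1 <- crossprod(Z, dB1); grads$c1 <- colSums(dB1)
    dZ <- dZ + dB1 %*% t(params$V1)

    G2 <- 0.5 * (aux$X2_hat - T2) / length(T2)
    grads$U2 <- crossprod(aux$R2, G2); grads$d2 <- colSums(G2)
    dB2 <- (G2 %*% t(params$U2)) * (aux$B2 > 0)
    grads$V2 <- crossprod(Z, dB2); grads$c2 <- colSums(dB2)
    dZ <- dZ + dB2 %*% t(params$V2)

    # split dZ over scales, add the prior term, map to head gradients
    AH2 <- An %*% st$H2
    dH2 <- 0 * st$H2
    col0 <- 0L
    for (m in seq_len(M)) {
      idx <- (col0 + 1):(col0 + cfg$scales[m])
      col0 <- col0 + cfg$scales[m]
      dZm <- dZ[, idx, drop = FALSE] + dZ_wd[[m]]
      dMUm <- dZm + dMU_wd[[m]]
      Sm <- exp(st$LS[[m]])
      dLSm <- dZm * st$E[[m]] * Sm + dLS_wd[[m]]
      grads$W_mu[[m]] <- crossprod(AH2, dMUm)
      grads$W_sg[[m]] <- crossprod(AH2, dLSm)
      dH2 <- dH2 + An %*% (dMUm %*% t(params$W_mu[[m]]) +
                             dLSm %*% t(params$W_sg[[m]]))
    }
    dA2 <- dH2 * (st$A2 > 0)
    grads$W1 <- crossprod(An %*% st$H1, dA2)
    dH1 <- An %*% dA2 %*% t(params$W1)
    dA1 <- dH1 * (st$A1 > 0)
    grads$W0 <- crossprod(An %*% X, dA1)
  }
  list(bce_adj = bce_adj, wd_prior = wd_prior, aux_1 = aux_1, aux_2 = aux_2,
       total = total, grads = grads, state = st, SM_hat = SM_hat)
}

#' Evaluation-mode node embedding
#'
#' Concatenated per-scale posterior means (no sampling), rows ordered as
#' the training labels; deterministic across calls.
#'
#' @param model A fitted `mdlink_vgae`.
#' @return Numeric matrix, one row per node, `sum(scales)` columns.
#' @export
vgae_embed <- function(model) {
  stopifnot(inherits(model, "mdlink_vgae"))
  model$embedding
}

#' @export
print.mdlink_vgae <- function(x, ...) {
  cat(sprintf("<mdlink_vgae> %d nodes, %d features -> %d latent dims, %d epochs\n",
              x$n_nodes, x$n_features, ncol(x$embedding), nrow(x$history)))
  cat(sprintf("  final loss %.4f (bce %.4f, wd %.4f)\n",
              x$history$total[nrow(x$history)],
              x$history$bce_adj[nrow(x$history)],
              x$history$wd_prior[nrow(x$history)]))
  invisible(x)
}

#' @rdname tidy.mdlink_cv
#' @method tidy mdlink_vgae
#' @export
tidy.mdlink_vgae <- function(x, ...) x$history

#' @rdname glance.mdlink_cv
#' @method glance mdlink_vgae
#' @export
glance.mdlink_vgae <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  tibble::tibble(n_nodes = x$n_nodes, latent_dim = ncol(x$embedding),
                 epochs = nrow(x$history), final_loss = h$total,
                 final_bce = h$bce_adj, final_wd = h$wd_prior)
}

# ---- Adam optimizer over a nested parameter list ------------------------

adam_new <- function(params) {
  list(m = rapply(params, function(p) 0 * p, how = "replace"),
       v = rapply(params, function(p) 0 * p, how = "replace"),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  walk <- function(p, g, m, v) {
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g ^ 2
    mh <- m / (1 - opt$beta1 ^ opt$t)
    vh <- v / (1 - opt$beta2 ^ opt$t)
    list(p = p - lr * mh / (sqrt(vh) + opt$eps), m = m, v = v)
  }
  for (k in names(params)) {
    if (is.list(params[[k]])) {
      for (i in seq_along(params[[k]])) {
        r <- walk(params[[k]][[i]], grads[[k]][[i]], opt$m[[k]][[i]], opt$v[[k]][[i]])
        params[[k]][[i]] <- r$p; opt$m[[k]][[i]] <- r$m; opt$v[[k]][[i]] <- r$v
      }
    } else {
      r <- walk(params[[k]], grads[[k]], opt$m[[k]], opt$v[[k]])
      params[[k]] <- r$p; opt$m[[k]] <- r$m; opt$v[[k]] <- r$v
    }
  }
  list(params = params, opt = opt)
}
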