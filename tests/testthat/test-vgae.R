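# small dense fixture shared across blocks
fixture_graph <- function(n = 6, f = 4, seed = 9) {
  set.seed(seed)
  SM <- matrix(runif(n * n), n); SM <- (SM + t(SM)) / 2
  diag(SM) <- 1; SM <- SM / max(SM)
  dimnames(SM) <- list(paste0("v", 1:n), paste0("v", 1:n))
  X <- matrix(runif(n * f), n) * 2
  list(SM = SM, X = X, n = n, f = f)
}

test_that("adjacency normalization matches the symmetric degree formula", {
  Z <- matrix(0, 3, 3)
  expect_equal(normalize_adjacency(Z), diag(3))
  SM <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalize_adjacency(SM), matrix(0.5, 2, 2))  # degrees 2
  fx <- fixture_graph()
  An <- normalize_adjacency(fx$SM)
  expect_equal(An, t(An))
  # straight-line reference
  Ab <- fx$SM + diag(fx$n)
  D <- diag(1 / sqrt(rowSums(Ab)))
  expect_equal(unname(An), D %*% Ab %*% D, tolerance = 1e-12)
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("encoder and decoders agree with dense-algebra references", {
  fx <- fixture_graph()
  cfg <- mdlink_config(scales = c(2L, 3L), base_hidden_dims = c(5L, 4L))
  An <- normalize_adjacency(fx$SM)
  set.seed(12)
  p <- vgae_init(fx$f, cfg, mlp_hidden = 6)
  st <- vgae_encode(An, fx$X, p)
  relu <- function(m) pmax(m, 0)
  H1 <- relu(An %*% fx$X %*% p$W0)
  H2 <- relu(An %*% H1 %*% p$W1)
  expect_equal(st$H1, H1, tolerance = 1e-12)
  expect_equal(st$H2, H2, tolerance = 1e-12)
  expect_equal(st$MU[[2]], An %*% H2 %*% p$W_mu[[2]], tolerance = 1e-12)
  expect_equal(st$LS[[1]], An %*% H2 %*% p$W_sg[[1]], tolerance = 1e-12)

  # adjacency decoder: zero latent gives 0.5 everywhere; toy Z by hand
  expect_equal(decode_adjacency(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  Zt <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(decode_adjacency(Zt),
               1 / (1 + exp(-Zt %*% t(Zt))), tolerance = 1e-12)
  SMh <- decode_adjacency(matrix(rnorm(8), 4, 2))
  expect_equal(SMh, t(SMh))
  expect_true(all(SMh > 0 & SMh < 1))

  # auxiliary decoder dims and dense-algebra agreement
  st <- vgae_reparameterize(st, sample = FALSE)
  aux <- decode_aux(st$Z, p)
  expect_identical(dim(aux$X1_hat), dim(H1))
  expect_identical(dim(aux$X2_hat), dim(H2))
  R1 <- relu(sweep(st$Z %*% p$V1, 2, p$c1, "+"))
  expect_equal(aux$X1_hat,
               1 / (1 + exp(-sweep(R1 %*% p$U1, 2, p$d1, "+"))),
               tolerance = 1e-12)
})

test_that("reparameterization has the stated moments and determinism", {
  fx <- fixture_graph()
  cfg <- mdlink_config(scales = c(2L, 3L), base_hidden_dims = c(5L, 4L))
  An <- normalize_adjacency(fx$SM)
  set.seed(12)
  p <- vgae_init(fx$f, cfg, mlp_hidden = 6)
  st <- vgae_encode(An, fx$X, p)
  # sigma -> 0 collapses the sample onto the mean
  st0 <- st; st0$LS <- lapply(st0$LS, function(m) m * 0 - 50)
  z <- vgae_reparameterize(st0, sample = TRUE)
  expect_equal(z$Z, do.call(cbind, st$MU), tolerance = 1e-12)
  # fixed seed -> bit-identical draw
  set.seed(5); z1 <- vgae_reparameterize(st, sample = TRUE)
  set.seed(5); z2 <- vgae_reparameterize(st, sample = TRUE)
  expect_identical(z1$Z, z2$Z)
  # Monte-Carlo: sample mean approaches mu within 4 standard errors
  set.seed(6)
  draws <- replicate(2000, vgae_reparameterize(st, sample = TRUE)$Z[1, 1])
  mu <- st$MU[[1]][1, 1]; s <- exp(st$LS[[1]][1, 1])
  expect_lt(abs(mean(draws) - mu), 4 * s / sqrt(2000))
  # eval mode is the concatenated means, dims add up
  ze <- vgae_reparameterize(st, sample = FALSE)
  expect_identical(ncol(ze$Z), 5L)
  expect_equal(ze$Z, do.call(cbind, st$MU))
})

test_that("the loss decomposes as reconstruction + prior + half the aux terms", {
  fx <- fixture_graph()
  cfg <- mdlink_config(scales = c(2L, 3L), base_hidden_dims = c(5L, 4L),
                       wd_mode = "gaussian")
  An <- normalize_adjacency(fx$SM)
  set.seed(12)
  p <- vgae_init(fx$f, cfg, mlp_hidden = 6)
  eps <- lapply(cfg$scales, function(s) matrix(rnorm(fx$n * s), fx$n, s))
  step <- mdlink:::vgae_step(p, An, fx$X, fx$SM, cfg, eps = eps)
  expect_equal(step$total,
               step$bce_adj + step$wd_prior + 0.5 * (step$aux_1 + step$aux_2))
  expect_true(all(is.finite(unlist(
    step[c("bce_adj", "wd_prior", "aux_1", "aux_2")]))))
  # hand-computed two-entry binary cross entropy
  expect_equal(mdlink:::bce_mean(c(1, 0), c(0.8, 0.3)),
               mean(-c(log(0.8), log(0.7))))
  expect_error(mdlink:::bce_mean(c(1.2, 0), c(.5, .5)), "outside")
  # perfect reconstruction of a binary target drives the bce to ~0
  expect_lt(mdlink:::bce_mean(c(1, 0), c(1 - 1e-12, 1e-12)), 1e-10)
})

test_that("analytic gradients match central finite differences", {
  fx <- fixture_graph()
  cfg <- mdlink_config(scales = c(2L, 3L), base_hidden_dims = c(5L, 4L),
                       wd_mode = "gaussian")
  An <- normalize_adjacency(fx$SM)
  set.seed(12)
  p <- vgae_init(fx$f, cfg, mlp_hidden = 6)
  eps <- lapply(cfg$scales, function(s) matrix(rnorm(fx$n * s), fx$n, s))
  st <- vgae_reparameterize(vgae_encode(An, fx$X, p), eps = eps)
  tg <- list(mdlink:::col_minmax(st$H1), mdlink:::col_minmax(st$H2))
  loss_of <- function(pp) {
    mdlink:::vgae_step(pp, An, fx$X, fx$SM, cfg, eps = eps, targets = tg)$total
  }
  an <- mdlink:::vgae_step(p, An, fx$X, fx$SM, cfg, eps = eps, targets = tg)$grads
  h <- 1e-6
  for (nm in c("W0", "W1", "V1", "U2")) {
    idx <- sample(length(p[[nm]]), 4)
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_of(pp) - loss_of(pm)) / (2 * h)
      expect_equal(an[[nm]][i], num, tolerance = 1e-5)
    }
  }
  for (m in 1:2) {
    i <- sample(length(p$W_mu[[m]]), 3)
    for (j in i) {
      pp <- p; pp$W_mu[[m]][j] <- pp$W_mu[[m]][j] + h
      pm <- p; pm$W_mu[[m]][j] <- pm$W_mu[[m]][j] - h
      expect_equal(an$W_mu[[m]][j], (loss_of(pp) - loss_of(pm)) / (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("training descends, is seed-reproducible, and embeds deterministically", {
  set.seed(31)
  w <- make_planted_association(nm = 40, nd = 12, n_clusters = 3,
                                p_in = 0.5, p_out = 0.05, flip_noise = 0,
                                seed = 31)
  SM <- snf_fuse(list(gip_kernel(w$A, "microbe"),
                      suppressWarnings(functional_similarity(
                        unclass(w$A), gip_kernel(w$A, "disease")))),
                 K = 8, t = 10)
  cfg <- tiny_config(seed = 7)
  fit1 <- vgae_train(SM, unclass(w$A), cfg)
  expect_identical(nrow(fit1$history), 30L)
  # descent: median loss of the last 10 epochs below the first 10, 3 seeds
  descends <- vapply(c(7, 8, 9), function(s) {
    f <- vgae_train(SM, unclass(w$A), tiny_config(seed = s, epochs = 100L))
    median(tail(f$history$total, 10)) < median(head(f$history$total, 10))
  }, TRUE)
  expect_true(all(descends))
  # bit reproducibility
  fit2 <- vgae_train(SM, unclass(w$A), cfg)
  expect_identical(fit1$history$total, fit2$history$total)
  expect_identical(fit1$embedding, fit2$embedding)
  # embedding: labeled rows, sum-of-scales columns, permutation-equivariant
  expect_identical(rownames(fit1$embedding), rownames(SM))
  expect_identical(ncol(fit1$embedding), sum(cfg$scales))
  expect_identical(vgae_embed(fit1), fit1$embedding)
  # learning-rate schedule steps down by lr_gamma every lr_step epochs
  cfg2 <- tiny_config(seed = 7, lr_step = 10L)
  f2 <- vgae_train(SM, unclass(w$A), cfg2)
  expect_equal(unique(f2$history$lr),
               cfg2$learning_rate * cfg2$lr_gamma ^ (0:2))
  # broom-style accessors
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_identical(glance(fit1)$epochs, 30L)
})

test_that("latent dimension follows the configured scales", {
  # the default three scales give a 112-dimensional embedding
  cfg <- mdlink_config()
  expect_identical(sum(cfg$scales), 112L)
  set.seed(2)
  p <- vgae_init(10, cfg)
  expect_identical(ncol(p$W_mu[[3]]), 64L)
  expect_identical(length(p$W_mu), 3L)
})
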