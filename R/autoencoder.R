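#' Class-conditional training targets: "filter" transform
#'
#' Under the filter objective the autoencoder learns to reconstruct positive
#' elements and to output all-zeros for negative ones, so that after
#' training only positive-class information passes through the bottleneck.
#'
#' @param x numeric matrix with entries in [0, 1].
#' @param class 0 or 1.
#' @return `0*x` if `class == 0`, `x` unchanged if `class == 1`.
#' @export
delta_filter <- function(x, class) {
  check_class01(class)
  if (class == 0L) array(0, dim = dim(x), dimnames = dimnames(x)) else x
}

#' Class-conditional training targets: "inverse" transform
#'
#' Under the inverse objective the autoencoder reconstructs positives and
#' the elementwise complement `1 - x` of negatives, acting as a classifier
#' with a matrix-valued output.
#'
#' @inheritParams delta_filter
#' @return `1 - x` if `class == 0`, `x` if `class == 1`.
#' @export
delta_inverse <- function(x, class) {
  check_class01(class)
  if (class == 0L) 1 - x else x
}

check_class01 <- function(class) {
  if (length(class) != 1L || !(class %in% c(0, 1)))
    stop("class must be a single 0 or 1")
}

# batch version: X is n x p, classes length n, alpha "filter"/"inverse"
delta_targets <- function(X, classes, alpha) {
  T <- X
  neg <- classes == 0L
  if (alpha == "filter") T[neg, ] <- 0 else T[neg, ] <- 1 - T[neg, ]
  T
}

#' Summed binary cross entropy between a target and a decoded output
#'
#' The reconstruction loss is the elementwise binary cross entropy
#' `-sum(t*log(o) + (1-t)*log(1-o))` over all p cells, with outputs clipped
#' to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param target numeric matrix/vector with entries in [0, 1].
#' @param output decoded matrix/vector of the same shape, entries in (0, 1).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(target, output) {
  if (length(target) != length(output))
    stop("target and output have different shapes")
  target <- as.vector(target)
  o <- pmin(pmax(as.vector(output), 1e-7), 1 - 1e-7)
  -sum(target * log(o) + (1 - target) * log(1 - o))
}

#' Analytic KL divergence of a diagonal Gaussian posterior from N(0, I)
#'
#' `0.5 * sum(mu^2 + exp(logvar) - logvar - 1)`, summed over latent
#' dimensions and batch rows.
#'
#' @param mu,logvar numeric matrices (rows = batch) or vectors of posterior
#'   means and log-variances.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stop("mu and logvar have different shapes")
  0.5 * sum(mu^2 + exp(logvar) - logvar - 1)
}

#' Bit-flip corruption for denoising training
#'
#' Replaces exactly `round(noise_ratio * p)` uniformly chosen distinct cells
#' of `x` by their complement `1 - x`, leaving the original untouched.
#' Deterministic for a fixed seed. The case study used a 0.1% ratio.
#'
#' @param x numeric matrix with entries in [0, 1].
#' @param noise_ratio proportion of cells to invert, in [0, 1).
#' @param seed integer RNG seed.
#' @return The corrupted copy of `x`.
#' @export
corrupt <- function(x, noise_ratio, seed = 1L) {
  if (noise_ratio < 0 || noise_ratio >= 1) stop("noise_ratio must be in [0, 1)")
  m <- round(noise_ratio * length(x))
  if (m == 0) return(x)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(length(x), m)
  x[idx] <- 1 - x[idx]
  x
}

# corrupt each row of an n x p batch, consuming the current RNG stream
corrupt_rows <- function(X, noise_ratio) {
  m <- round(noise_ratio * ncol(X))
  if (m == 0) return(X)
  for (r in seq_len(nrow(X))) {
    idx <- sample.int(ncol(X), m)
    X[r, idx] <- 1 - X[r, idx]
  }
  X
}

sigmoid <- function(a) 1 / (1 + exp(-a))

# add a bias (row) vector to every row of an n x d matrix
addb <- function(M, b) M + rep(b, each = nrow(M))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained autoencoder
#'
#' Symmetric dense architecture: `flatten(l*w) -> dense(hidden_dim, tanh) ->
#' latent head -> dense(hidden_dim, tanh) -> dense(l*w, sigmoid)`. The VAE
#' latent head emits means and log-variances (2 * latent_dim values); AE and
#' DAE emit the latent vector directly. Weights are Glorot-initialised from
#' the seed.
#'
#' @param l,w input matrix dimensions (activities x time windows).
#' @param architecture `"ae"`, `"dae"` or `"vae"`.
#' @param latent_dim bottleneck width (case study: 8).
#' @param hidden_dim hidden layer width (case study: 32).
#' @param strategy objective the model is meant for: `"filter"` or
#'   `"inverse"` (stored; used by [predict.pathway_autoencoder()]).
#' @param noise_ratio DAE corruption ratio (stored).
#' @param seed integer seed for weight initialisation.
#' @return An object of class `pathway_autoencoder` with empty history.
#' @export
build_model <- function(l, w, architecture = c("ae", "dae", "vae"),
                        latent_dim = 8L, hidden_dim = 32L,
                        strategy = c("filter", "inverse"),
                        noise_ratio = 0.001, seed = 1L) {
  architecture <- match.arg(architecture)
  strategy <- match.arg(strategy)
  if (l < 1L || w < 1L) stop("l and w must be >= 1")
  if (latent_dim < 1L) stop("latent_dim must be >= 1")
  if (hidden_dim < latent_dim) stop("hidden_dim must be >= latent_dim")
  p <- as.integer(l) * as.integer(w)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pr <- list(W1 = glorot(p, hidden_dim), b1 = numeric(hidden_dim),
             Wmu = glorot(hidden_dim, latent_dim), bmu = numeric(latent_dim),
             W4 = glorot(latent_dim, hidden_dim), b4 = numeric(hidden_dim),
             W5 = glorot(hidden_dim, p), b5 = numeric(p))
  if (architecture == "vae") {
    pr$Wlv <- glorot(hidden_dim, latent_dim)
    pr$blv <- numeric(latent_dim)
  }
  structure(list(params = pr, strategy = strategy, architecture = architecture,
                 l = as.integer(l), w = as.integer(w), p = p,
                 latent_dim = as.integer(latent_dim),
                 hidden_dim = as.integer(hidden_dim),
                 noise_ratio = noise_ratio,
                 row_labels = NULL, rescale_factor = NA_real_,
                 history = data.frame(epoch = integer(), train_loss = numeric(),
                                      val_loss = numeric()),
                 best_epoch = NA_integer_, config = list(seed = seed)),
            class = "pathway_autoencoder")
}

# forward pass; eps = NULL -> deterministic (VAE uses posterior mean)
forward <- function(model, X, eps = NULL) {
  pr <- model$params
  A1 <- addb(X %*% pr$W1, pr$b1); H1 <- tanh(A1)
  Mu <- addb(H1 %*% pr$Wmu, pr$bmu)
  if (model$architecture == "vae") {
    Lv <- addb(H1 %*% pr$Wlv, pr$blv)
    Z <- if (is.null(eps)) Mu else Mu + exp(0.5 * Lv) * eps
  } else {
    Lv <- NULL; Z <- Mu
  }
  H2 <- tanh(addb(Z %*% pr$W4, pr$b4))
  O <- sigmoid(addb(H2 %*% pr$W5, pr$b5))
  list(H1 = H1, Mu = Mu, Lv = Lv, Z = Z, H2 = H2, O = O, eps = eps)
}

# coerce data argument to an n x p matrix (+ classes when available)
as_batch <- function(data, classes = NULL, model = NULL) {
  if (inherits(data, "matrix_dataset")) {
    X <- data$values
    if (is.null(classes)) classes <- data$classes
  } else if (is.matrix(data) && !is.null(model) && nrow(data) == model$l &&
             ncol(data) == model$w) {
    X <- matrix(as.vector(data), nrow = 1L)
  } else {
    X <- as.matrix(data)
  }
  if (!is.null(model) && ncol(X) != model$p)
    stop("data has ", ncol(X), " cells per element; model expects ", model$p)
  list(X = X, classes = classes)
}

#' Encode / decode / reconstruct with a trained autoencoder
#'
#' All three are deterministic: the VAE path uses the posterior mean, never
#' a sample.
#'
#' @param model a `pathway_autoencoder`.
#' @param data a `matrix_dataset`, an `n x p` matrix of flattened elements,
#'   or a single `l x w` matrix.
#' @return `encode`: `n x latent_dim` matrix of latent codes (posterior
#'   means for VAE); `reconstruct`: `n x p` matrix of decoded outputs in
#'   (0, 1).
#' @export
encode <- function(model, data) {
  X <- as_batch(data, model = model)$X
  forward(model, X)$Mu
}

#' @rdname encode
#' @param z latent matrix (`n x latent_dim`) or vector.
#' @export
decode <- function(model, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$latent_dim)
    stop("latent dimension mismatch: got ", ncol(z), ", expected ", model$latent_dim)
  pr <- model$params
  H2 <- tanh(addb(z %*% pr$W4, pr$b4))
  sigmoid(addb(H2 %*% pr$W5, pr$b5))
}

#' @rdname encode
#' @export
reconstruct <- function(model, data) {
  X <- as_batch(data, model = model)$X
  forward(model, X)$O
}

#' Strategy objective J over a batch (Eq-style sum)
#'
#' Sum over the batch of the binary cross entropy between the
#' class-conditional target (filter: zeros for negatives; inverse:
#' complement for negatives) and the deterministic reconstruction.
#'
#' @param model a `pathway_autoencoder`.
#' @param data batch (`matrix_dataset` or `n x p` matrix).
#' @param classes 0/1 vector (taken from `data` when it is a dataset).
#' @param alpha `"filter"` or `"inverse"`; defaults to the model's strategy.
#' @return Scalar loss.
#' @export
objective <- function(model, data, classes = NULL, alpha = model$strategy) {
  b <- as_batch(data, classes, model)
  if (is.null(b$classes)) stop("classes are required")
  Tg <- delta_targets(b$X, b$classes, alpha)
  reconstruction_loss(Tg, forward(model, b$X)$O)
}

#' VAE objective: strategy reconstruction term plus analytic KL
#'
#' The evidence lower bound is adapted by replacing the log-likelihood term
#' with the filter/inverse cross-entropy objective; maximising the ELBO
#' becomes minimising `J^alpha + KL`. One latent sample per element via the
#' reparameterisation trick; seeded for determinism.
#'
#' @inheritParams objective
#' @param seed RNG seed for the latent samples.
#' @return Scalar loss (summed over the batch).
#' @export
vae_objective <- function(model, data, classes = NULL,
                          alpha = model$strategy, seed = 1L) {
  if (model$architecture != "vae") stop("model is not a VAE")
  b <- as_batch(data, classes, model)
  if (is.null(b$classes)) stop("classes are required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- matrix(stats::rnorm(nrow(b$X) * model$latent_dim),
                nrow(b$X), model$latent_dim)
  fw <- forward(model, b$X, eps = eps)
  kl <- kl_divergence(fw$Mu, fw$Lv)
  if (!is.finite(kl)) stop("non-finite KL divergence in vae_objective")
  Tg <- delta_targets(b$X, b$classes, alpha)
  reconstruction_loss(Tg, fw$O) + kl
}

# loss (mean over batch) and parameter gradients; fw from forward()
backward <- function(model, X, Tg, fw) {
  pr <- model$params
  n <- nrow(X)
  dA3 <- (fw$O - Tg) / n                       # grad wrt output pre-activation
  g <- list()
  g$W5 <- crossprod(fw$H2, dA3); g$b5 <- colSums(dA3)
  dH2 <- tcrossprod(dA3, pr$W5)
  dA2 <- dH2 * (1 - fw$H2^2)
  g$W4 <- crossprod(fw$Z, dA2); g$b4 <- colSums(dA2)
  dZ <- tcrossprod(dA2, pr$W4)
  if (model$architecture == "vae") {
    dMu <- dZ + fw$Mu / n                      # + KL term
    dLv <- dZ * fw$eps * 0.5 * exp(0.5 * fw$Lv) + 0.5 * (exp(fw$Lv) - 1) / n
    g$Wmu <- crossprod(fw$H1, dMu); g$bmu <- colSums(dMu)
    g$Wlv <- crossprod(fw$H1, dLv); g$blv <- colSums(dLv)
    dH1 <- tcrossprod(dMu, pr$Wmu) + tcrossprod(dLv, pr$Wlv)
  } else {
    g$Wmu <- crossprod(fw$H1, dZ); g$bmu <- colSums(dZ)
    dH1 <- tcrossprod(dZ, pr$Wmu)
  }
  dA1 <- dH1 * (1 - fw$H1^2)
  g$W1 <- crossprod(X, dA1); g$b1 <- colSums(dA1)
  g
}

# mean-over-batch training loss for monitoring (deterministic path)
eval_loss <- function(model, X, classes, alpha) {
  fw <- forward(model, X)
  Tg <- delta_targets(X, classes, alpha)
  loss <- reconstruction_loss(Tg, fw$O)
  if (model$architecture == "vae") loss <- loss + kl_divergence(fw$Mu, fw$Lv)
  loss / nrow(X)
}

adam_init <- function(pr) list(m = lapply(pr, function(x) x * 0),
                               v = lapply(pr, function(x) x * 0), t = 0L)

adam_step <- function(pr, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    pr[[nm]] <- pr[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = pr, state = st)
}

#' Fit an explainable pathway autoencoder
#'
#' Trains a dense autoencoder on [0,1] activity-by-time matrices under the
#' "filter" or "inverse" class-conditional objective with Adam, early
#' stopping on a held-out validation loss, and returns the best-validation
#' weights. This is the package's central fitting function; downstream
#' scoring ([predict.pathway_autoencoder()]), explanation
#' ([explanation_element()]) and validation all consume its result.
#'
#' @param data training data: a `matrix_dataset` from [tensorize()] (which
#'   carries the classes), or an `n x p` matrix with `classes` given and
#'   `l`, `w` supplied.
#' @param classes optional 0/1 outcome vector overriding the dataset's.
#' @param strategy `"filter"` (reconstruct positives, zero out negatives;
#'   score = decoded mass) or `"inverse"` (reconstruct positives, complement
#'   negatives; score = inverse reconstruction error).
#' @param architecture `"ae"`, `"dae"` (bit-flip input corruption, resampled
#'   every epoch) or `"vae"` (diagonal-Gaussian latent, ELBO-style loss).
#' @param latent_dim,hidden_dim network widths; defaults 8 and 32.
#' @param noise_ratio DAE corruption ratio; default 0.001 (0.1%).
#' @param learning_rate Adam learning rate; default 1e-4.
#' @param max_epochs,patience early-stopping budget; defaults 5000 and 25.
#' @param batch_size minibatch size; default 64.
#' @param validation optional held-out `matrix_dataset` (or `n x p` matrix
#'   with classes attribute) monitored for early stopping; when `NULL`, a
#'   stratified `val_fraction` of the training rows is held out.
#' @param val_fraction fraction of training rows held out when `validation`
#'   is `NULL`; default 0.1.
#' @param l,w element dimensions, required only when `data` is a bare matrix.
#' @param seed integer seed controlling initialisation, shuffling, DAE
#'   corruption and VAE sampling; fits are bit-reproducible for a fixed seed.
#' @param verbose print a line every 25 epochs.
#' @return A `pathway_autoencoder` with best-validation `params`, a
#'   `history` data.frame (`epoch,train_loss,val_loss`, mean loss per
#'   element) and `best_epoch`.
#' @export
pathway_autoencoder <- function(data, classes = NULL,
                                strategy = c("filter", "inverse"),
                                architecture = c("ae", "dae", "vae"),
                                latent_dim = 8L, hidden_dim = 32L,
                                noise_ratio = 0.001, learning_rate = 1e-4,
                                max_epochs = 5000L, patience = 25L,
                                batch_size = 64L, validation = NULL,
                                val_fraction = 0.1, l = NULL, w = NULL,
                                seed = 1L, verbose = FALSE) {
  strategy <- match.arg(strategy)
  architecture <- match.arg(architecture)
  if (inherits(data, "matrix_dataset") && length(data$row_labels) > 0L &&
      !is.null(data$window)) {
    l <- length(data$row_labels); w <- data$window$n_windows
  }
  if (is.null(l) || is.null(w)) stop("l and w are required for bare-matrix data")
  b <- as_batch(data, classes)
  X <- b$X; cls <- as.integer(b$classes)
  if (is.null(cls)) stop("classes are required")
  if (length(unique(cls)) < 2L)
    stop("training data must contain both outcome classes")

  model <- build_model(l, w, architecture, latent_dim, hidden_dim,
                       strategy = strategy, noise_ratio = noise_ratio,
                       seed = seed)
  if (inherits(data, "matrix_dataset")) {
    model$row_labels <- data$row_labels
    model$rescale_factor <- data$rescale_factor
    model$systems <- data$systems
    model$window <- data$window
  }
  model$config <- list(strategy = strategy, architecture = architecture,
                       latent_dim = latent_dim, hidden_dim = hidden_dim,
                       noise_ratio = noise_ratio, learning_rate = learning_rate,
                       max_epochs = max_epochs, patience = patience,
                       batch_size = batch_size, val_fraction = val_fraction,
                       seed = seed)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # held-out validation split (stratified) unless one was supplied
  if (is.null(validation)) {
    val_idx <- integer(0)
    for (cl in c(0L, 1L)) {
      ids <- which(cls == cl)
      k <- max(1L, round(val_fraction * length(ids)))
      k <- min(k, length(ids) - 1L)
      val_idx <- c(val_idx, sample(ids, k))
    }
    Xval <- X[val_idx, , drop = FALSE]; cval <- cls[val_idx]
    X <- X[-val_idx, , drop = FALSE]; cls <- cls[-val_idx]
  } else {
    bv <- as_batch(validation)
    Xval <- bv$X; cval <- as.integer(bv$classes)
    if (is.null(cval)) stop("validation classes are required")
  }

  pr <- model$params
  st <- adam_init(pr)
  n <- nrow(X)
  best_val <- Inf; best_pr <- pr; best_epoch <- 0L; bad <- 0L
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)

  for (epoch in seq_len(max_epochs)) {
    Xin <- if (architecture == "dae") corrupt_rows(X, noise_ratio) else X
    perm <- sample.int(n)
    total <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      Xb <- Xin[idx, , drop = FALSE]
      Tb <- delta_targets(X[idx, , drop = FALSE], cls[idx], strategy)
      eps <- if (architecture == "vae")
        matrix(stats::rnorm(length(idx) * latent_dim), length(idx), latent_dim)
      else NULL
      model$params <- pr
      fw <- forward(model, Xb, eps = eps)
      loss <- reconstruction_loss(Tb, fw$O)
      if (architecture == "vae") {
        kl <- kl_divergence(fw$Mu, fw$Lv)
        if (!is.finite(kl))
          stop("non-finite KL at epoch ", epoch, "; training aborted")
        loss <- loss + kl
      }
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, "; training aborted")
      total <- total + loss
      upd <- adam_step(pr, backward(model, Xb, Tb, fw), st, learning_rate)
      pr <- upd$params; st <- upd$state
    }
    model$params <- pr
    train_loss <- total / n
    val_loss <- eval_loss(model, Xval, cval, strategy)
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, train_loss)
    hist_val <- c(hist_val, val_loss)
    if (verbose && epoch %% 25L == 0L)
      message(sprintf("epoch %4d  train %.4f  val %.4f", epoch, train_loss, val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss; best_pr <- pr; best_epoch <- epoch; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model$params <- best_pr
  model$best_epoch <- best_epoch
  model$history <- data.frame(epoch = hist_epoch, train_loss = hist_train,
                              val_loss = hist_val)
  model
}

#' Save / load a model checkpoint
#'
#' Single-file RDS archive holding weights, configuration, label order and
#' rescale factor; loading verifies shape compatibility.
#'
#' @param model a `pathway_autoencoder`.
#' @param path checkpoint file path.
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- structure(obj, class = "pathway_autoencoder")
  with(model, {
    stopifnot(nrow(params$W1) == p, ncol(params$W5) == p,
              ncol(params$Wmu) == latent_dim)
  })
  model
}
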