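#' @export
print.pathway_autoencoder <- function(x, ...) {
  cat(sprintf("Pathway autoencoder (%s, %s objective)\n",
              toupper(x$architecture), x$strategy))
  cat(sprintf("  input: l = %d activities x w = %d windows (p = %d)\n",
              x$l, x$w, x$p))
  cat(sprintf("  widths: hidden %d, latent %d%s\n", x$hidden_dim, x$latent_dim,
              if (x$architecture == "vae") " (mean + log-variance heads)" else ""))
  if (nrow(x$history) > 0L)
    cat(sprintf("  trained %d epochs; best validation loss %.4f at epoch %d\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.pathway_autoencoder <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, 1L))
  out <- list(architecture = object$architecture, strategy = object$strategy,
              l = object$l, w = object$w, p = object$p,
              n_parameters = n_par, epochs = nrow(object$history),
              best_epoch = object$best_epoch,
              best_val_loss = if (nrow(object$history) > 0L)
                min(object$history$val_loss) else NA_real_,
              config = object$config)
  class(out) <- "summary.pathway_autoencoder"
  out
}

#' @export
print.summary.pathway_autoencoder <- function(x, ...) {
  cat(sprintf("Pathway autoencoder summary: %s / %s\n",
              toupper(x$architecture), x$strategy))
  cat(sprintf("  %d x %d input, %d trainable parameters\n", x$l, x$w,
              x$n_parameters))
  cat(sprintf("  epochs run: %d; best epoch %s (val loss %.4f)\n",
              x$epochs, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict from a fitted pathway autoencoder
#'
#' `type = "score"` returns the strategy score per patient: decoded mass
#' `sum(x')` for filter models, inverse reconstruction error
#' `1 - mean((x - x')^2)` for inverse models — higher means more likely
#' positive either way. `type = "class"` thresholds the scores (threshold
#' from [gini_threshold()] on `newdata` when not supplied). `"decoded"` and
#' `"latent"` expose the reconstruction and the latent code (posterior mean
#' for VAE; inference is always deterministic).
#'
#' @param object a fitted `pathway_autoencoder`.
#' @param newdata a `matrix_dataset`, `n x p` matrix, or single `l x w`
#'   matrix.
#' @param type one of `"score"`, `"class"`, `"decoded"`, `"latent"`.
#' @param threshold decision threshold for `type = "class"`.
#' @param ... unused.
#' @return Numeric vector (scores/classes, named by patient id when known)
#'   or matrix (decoded/latent).
#' @export
predict.pathway_autoencoder <- function(object, newdata,
                                        type = c("score", "class", "decoded",
                                                 "latent"),
                                        threshold = NULL, ...) {
  type <- match.arg(type)
  b <- as_batch(newdata, model = object)
  fw <- forward(object, b$X)
  nm <- if (inherits(newdata, "matrix_dataset")) newdata$patient_ids else NULL
  if (type == "latent") return(structure(fw$Mu, dimnames = list(nm, NULL)))
  if (type == "decoded") return(structure(fw$O, dimnames = list(nm, NULL)))
  scores <- if (object$strategy == "filter") rowSums(fw$O)
            else 1 - rowMeans((b$X - fw$O)^2)
  names(scores) <- nm
  if (type == "score") return(scores)
  if (is.null(threshold)) {
    if (is.null(b$classes)) stop("type = \"class\" needs a threshold or a dataset with classes")
    threshold <- as.numeric(gini_threshold(scores, b$classes))
  }
  stats::setNames(as.integer(scores >= threshold), nm)
}

#' Training-history plot for a fitted autoencoder
#'
#' Train and validation mean loss per epoch, with the best epoch marked.
#'
#' @param x a fitted `pathway_autoencoder`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pathway_autoencoder <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0L) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "mean loss per element", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.pathway_autoencoder <- function(object, ...) object$params

#' Reconstruction residuals
#'
#' Difference `x - x'` between inputs and their deterministic
#' reconstruction, one row per element.
#'
#' @param object a fitted `pathway_autoencoder`.
#' @param newdata data to reconstruct (required; the model stores no data).
#' @param ... unused.
#' @return `n x p` residual matrix.
#' @export
residuals.pathway_autoencoder <- function(object, newdata, ...) {
  b <- as_batch(newdata, model = object)
  b$X - forward(object, b$X)$O
}
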