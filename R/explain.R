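#' Mean decoded element of one class
#'
#' Cell-wise mean of the deterministic reconstructions `g(f(x))` over all
#' elements of the requested class (VAE decodes the posterior mean).
#'
#' @param model a fitted `pathway_autoencoder`.
#' @param dataset a `matrix_dataset`.
#' @param class restrict to this outcome class (0 or 1); `NULL` averages
#'   over every element in `dataset`.
#' @return `l x w` matrix with label rownames.
#' @export
mean_element <- function(model, dataset, class = NULL) {
  X <- dataset$values
  if (!is.null(class)) {
    keep <- dataset$classes == class
    if (!any(keep)) stop("no elements of class ", class, " in dataset")
    X <- X[keep, , drop = FALSE]
  }
  if (nrow(X) == 0L) stop("empty dataset")
  unflatten(colMeans(reconstruct(model, X)), model$l, model$w,
            model$row_labels)
}

#' Global explanation element E
#'
#' The difference between the mean decoded positive and mean decoded
#' negative elements, `E = x_bar_1 - x_bar_0`. Because both training
#' objectives extract positive-class patterns, large cells of E mark
#' (activity, time-window) pairs that push the prediction towards the
#' positive class. Computed on training data by default in the pipeline;
#' pass any population explicitly here.
#'
#' @param model a fitted `pathway_autoencoder`.
#' @param dataset a `matrix_dataset` containing both classes.
#' @return Object of class `explanation_element`: list with `values`
#'   (`l x w`, entries in [-1, 1]), `x_bar0`, `x_bar1`, `row_labels`,
#'   `systems`.
#' @export
explanation_element <- function(model, dataset) {
  if (!any(dataset$classes == 0L)) stop("dataset has no negative elements")
  if (!any(dataset$classes == 1L)) stop("dataset has no positive elements")
  x0 <- mean_element(model, dataset, class = 0L)
  x1 <- mean_element(model, dataset, class = 1L)
  structure(list(values = x1 - x0, x_bar0 = x0, x_bar1 = x1,
                 row_labels = model$row_labels,
                 systems = model$systems,
                 strategy = model$strategy, architecture = model$architecture),
            class = "explanation_element")
}

#' @export
print.explanation_element <- function(x, ...) {
  cat(sprintf("Explanation element E: %d activities x %d windows (%s/%s)\n",
              nrow(x$values), ncol(x$values),
              toupper(x$architecture %||% "?"), x$strategy %||% "?"))
  cat(sprintf("  range [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_E <- function(E) if (inherits(E, "explanation_element")) E$values else E

#' Rank activities by explanation weight over the frequent-history windows
#'
#' Sorts activities by their E row sum over windows `1..w-1` — everything
#' strictly before the last pre-index window — descending; this surfaces
#' recurrent long-term factors. The companion `rank_last_window()` sorts by
#' the final window's column `E[, w]` alone, surfacing punctual events just
#' before the index date. Ties break lexicographically by label.
#'
#' @param E an `explanation_element` or bare `l x w` matrix with rownames.
#' @param k number of activities to return (top-100 in the case study).
#' @return data.frame `rank, label, score, scope`, scores non-increasing.
#' @export
rank_frequent <- function(E, k = 100L) {
  v <- as_E(E)
  if (ncol(v) < 2L) stop("rank_frequent needs w >= 2")
  rank_by(rowSums(v[, -ncol(v), drop = FALSE]), rownames(v), k, "frequent")
}

#' @rdname rank_frequent
#' @export
rank_last_window <- function(E, k = 100L) {
  v <- as_E(E)
  rank_by(v[, ncol(v)], rownames(v), k, "last-window")
}

rank_by <- function(score, labels, k, scope) {
  if (k < 1L) stop("k must be >= 1")
  if (is.null(labels)) labels <- as.character(seq_along(score))
  o <- order(-score, labels)
  o <- o[seq_len(min(k, length(o)))]
  data.frame(rank = seq_along(o), label = labels[o], score = unname(score[o]),
             scope = scope, stringsAsFactors = FALSE)
}

#' Minimal representation of E
#'
#' Zeroes every row of E outside the selected activities, leaving a sparse
#' interpretable image of the retained predictive factors (the case study
#' kept the top-15 validated ones).
#'
#' @param E an `explanation_element` or bare matrix.
#' @param labels selected activity labels (subset of the rownames).
#' @return `l x w` matrix with non-selected rows set to 0; selected labels
#'   kept in `attr(, "selected")`.
#' @export
minimal_representation <- function(E, labels) {
  v <- as_E(E)
  unknown <- setdiff(labels, rownames(v))
  if (length(unknown) > 0L)
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  out <- v
  out[!(rownames(v) %in% labels), ] <- 0
  structure(out, selected = labels)
}

#' Render an explanation element as an image
#'
#' Rows are activities (optionally restricted and ordered by a ranking),
#' columns run left = oldest window to right = the window adjacent to the
#' index date. Cell shade encodes |E|; when `systems` tags are available
#' each activity row label is coloured by its system (one colour per type
#' of medical activity).
#'
#' @param x an `explanation_element`.
#' @param labels optional labels to display (default: all, by E weight).
#' @param max_rows cap on displayed rows.
#' @param palette named colours per system tag; defaults supplied.
#' @param ... unused.
#' @export
plot.explanation_element <- function(x, labels = NULL, max_rows = 40L,
                                     palette = NULL, ...) {
  v <- x$values
  if (!is.null(labels)) v <- minimal_representation(x, labels)[labels, , drop = FALSE]
  o <- order(-rowSums(abs(v)))
  v <- v[o[seq_len(min(max_rows, nrow(v)))], , drop = FALSE]
  sys <- x$systems[rownames(v)]
  if (is.null(palette))
    palette <- c(DIAG = "firebrick", COM = "darkorange", PROC = "steelblue",
                 DEV = "seagreen", BIO = "purple", CONSULT = "grey30")
  col_rows <- ifelse(is.na(sys) | !(sys %in% names(palette)),
                     "black", palette[sys])
  graphics::image(t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0, length.out = 64)),
                  axes = FALSE, xlab = "time window (oldest -> index date)",
                  ylab = "")
  at <- seq(1, 0, length.out = nrow(v))
  graphics::axis(2, at = at, labels = rownames(v), las = 2, cex.axis = 0.6,
                 tick = FALSE)
  for (i in seq_len(nrow(v)))
    graphics::mtext(rownames(v)[i], side = 2, at = at[i], las = 2,
                    cex = 0.6, col = col_rows[i], line = 0.5)
  invisible(x)
}
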