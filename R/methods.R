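# S3 methods for the fitted model and classifier objects.

#' @export
print.edembed <- function(x, ...) {
  cat("Self-supervised disease-concept embedding model\n")
  cat(sprintf("  encoder: %d-layer Transformer, %d heads, hidden %d; text width %d (%s encoder)\n",
              x$config$n_layers, x$config$n_heads, x$config$d_hidden,
              x$config$d_text, x$encoder$kind))
  cat(sprintf("  trained on %d visits; pretrained: %s\n", x$n_visits,
              if (x$pretrained) sprintf("yes (DIM: %s, SimCLR: %s, %d steps)",
                                        x$train$use_dim, x$train$use_simclr,
                                        nrow(x$metrics)) else "no"))
  invisible(x)
}

#' @export
summary.edembed <- function(object, ...) {
  print(object)
  if (!is.null(object$metrics)) {
    m <- object$metrics
    first <- m[1, ]; last <- m[nrow(m), ]
    cat("  loss parts (first step -> last step):\n")
    for (p in c("dim_nce", "prior_gen", "prior_disc", "simclr", "total"))
      if (!all(is.na(m[[p]])))
        cat(sprintf("    %-10s %8.4f -> %8.4f\n", p, first[[p]], last[[p]]))
  }
  invisible(object)
}

#' Plot pretraining loss curves or an embedding map
#'
#' @param x a fitted `edembed` model.
#' @param which "loss" for the per-step loss parts, or "map" for a t-SNE
#'   map of embeddings of `newdata`.
#' @param newdata visit table for `which = "map"`.
#' @param colour_by covariate for the map colouring.
#' @param ... unused.
#' @export
plot.edembed <- function(x, which = c("loss", "map"), newdata = NULL,
                         colour_by = NULL, ...) {
  which <- match.arg(which)
  if (which == "loss") {
    if (is.null(x$metrics)) stop("model was not pretrained; no loss curve")
    m <- x$metrics
    graphics::plot(m$step, m$total, type = "l", xlab = "step", ylab = "loss",
                   main = "pretraining loss")
    graphics::lines(m$step, m$dim_nce, col = 2)
    if (!all(is.na(m$simclr))) graphics::lines(m$step, m$simclr, col = 4)
    graphics::legend("topright", c("total", "dim_nce", "simclr"),
                     col = c(1, 2, 4), lty = 1, cex = 0.8)
  } else {
    stopifnot(!is.null(newdata))
    eps <- stats::predict(x, newdata)
    Y <- tsne_project(eps)
    if (is.null(colour_by)) colour_by <- rep("visit", nrow(Y))
    plot_embedding_map(Y, colour_by, main = "embedding t-SNE")
  }
  invisible(x)
}

#' @export
print.edembed_classifier <- function(x, ...) {
  cat("Critical-care-outcome classifier (finetuned embedding model)\n")
  cat(sprintf("  encoder pretrained: %s; positive-class weight %.1f\n",
              x$pretrained, x$pos_weight))
  if (is.finite(x$val_auroc))
    cat(sprintf("  best validation AUROC: %.3f\n", x$val_auroc))
  invisible(x)
}

#' @export
print.ed_config <- function(x, ...) {
  cat(sprintf("model config: d_hidden=%d, layers=%d, heads=%d, d_text=%d, d_ff=%d\n",
              x$d_hidden, x$n_layers, x$n_heads, x$d_text, x$d_ff))
  cat(sprintf("  augmentation: noise_fraction=%.2f, history_mask_prob=%.2f; dropout=%.2f\n",
              x$noise_fraction, x$history_mask_prob, x$dropout))
  invisible(x)
}

#' @export
print.ed_loss_parts <- function(x, ...) {
  cat(sprintf("pretraining loss: total=%.4f (dim_nce=%.4f + %.2f*prior_gen=%.4f + simclr=%.4f)\n",
              x$total, x$dim_nce, x$gamma, x$prior_gen, x$simclr))
  invisible(x)
}
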