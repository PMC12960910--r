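#' @export
print.stamix <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("stamix fit: %d units, %d clusters\n",
              length(x$labels), cfg$cfg$k))
  cat(sprintf("  graph: %s KNN, k = %d; image loss: %s\n",
              cfg$graph_mode, cfg$k_spatial,
              if (cfg$use_image) "on" else "off"))
  cat(sprintf("  epochs: %d, seed: %d, final total loss: %.3f\n",
              cfg$epochs, cfg$seed,
              x$loss_history$total[nrow(x$loss_history)]))
  cat("  cluster sizes:", paste(tabulate(x$labels, cfg$cfg$k),
                                collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.stamix <- function(object, ...) {
  cfg <- object$config
  out <- list(
    n_units = length(object$labels),
    k_cluster = cfg$cfg$k,
    cluster_sizes = tabulate(object$labels, cfg$cfg$k),
    use_image = cfg$use_image,
    epochs = cfg$epochs,
    final_losses = object$loss_history[nrow(object$loss_history), ],
    mean_max_soft = mean(apply(object$soft, 1L, max)))
  class(out) <- "summary.stamix"
  out
}

#' @export
print.summary.stamix <- function(x, ...) {
  cat(sprintf("stamix fit: %d units in %d clusters (image loss %s)\n",
              x$n_units, x$k_cluster, if (x$use_image) "on" else "off"))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = " "), "\n")
  cat(sprintf("mean max soft assignment: %.3f\n", x$mean_max_soft))
  cat(sprintf("final losses after %d epochs:\n", x$epochs))
  print(x$final_losses, row.names = FALSE)
  invisible(x)
}

#' Mixture-prior parameters of a fitted model
#'
#' @param object a `"stamix"` fit.
#' @param ... unused.
#' @return list with `mu_prior` (`k x d_z`) and `sigma_prior` (`k x d_z`).
#' @export
coef.stamix <- function(object, ...) {
  cfg <- object$config$cfg
  list(mu_prior = object$params$mu_prior,
       sigma_prior = prior_sd(object$params, cfg))
}

#' @export
fitted.stamix <- function(object, ...) object$soft

#' @export
logLik.stamix <- function(object, ...) {
  ll <- object$loss_history$elbo[nrow(object$loss_history)]
  attr(ll, "df") <- sum(vapply(object$params, length, integer(1L)))
  attr(ll, "nobs") <- length(object$labels)
  class(ll) <- "logLik"
  ll
}

#' Plot a fitted clustering in space
#'
#' Scatter of unit coordinates coloured by hard cluster label (y axis
#' flipped so the layout matches image raster orientation).
#'
#' @param x a `"stamix"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stamix <- function(x, ...) {
  k <- x$config$cfg$k
  pal <- grDevices::hcl.colors(max(3L, k), "Dark 3")
  graphics::plot(x$coords[, 1L], -x$coords[, 2L],
                 col = pal[x$labels], pch = 16, cex = 0.5,
                 xlab = "x (px)", ylab = "-y (px)",
                 main = "stamix spatial clusters", ...)
  graphics::legend("topright", legend = seq_len(k), col = pal[seq_len(k)],
                   pch = 16, cex = 0.7, bty = "n")
  invisible(x)
}
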