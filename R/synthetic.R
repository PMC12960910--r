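## Seeded generator of synthetic spatial omics fixtures with matched toy
## images. Domains are spatially contiguous (Voronoi regions around seeded
## centres), expression is Poisson with planted domain markers, and the image
## encodes domain identity through per-domain base intensity, blended toward
## uninformative grey as image_signal -> 0.

#' Specification of a synthetic spatial omics fixture
#'
#' @param n_units number of units (spots/cells).
#' @param k_domains number of spatial domains (>= 2).
#' @param m_features number of features; must admit
#'   `markers_per_domain * k_domains` markers.
#' @param markers_per_domain planted marker features per domain (default 3).
#' @param marker_shift added Poisson rate for a domain's markers within that
#'   domain (default 3; with `base_rate = 1`, markers average 4x background).
#' @param base_rate background Poisson rate for all features (default 1).
#' @param noise_sd sd of the log-normal jitter multiplying each unit-feature
#'   rate (default 0.2), giving overdispersion beyond Poisson.
#' @param image_signal in `[0, 1]`: how strongly per-domain base intensity is
#'   expressed in the image (1 = fully informative, 0 = uniform grey).
#' @param patch_noise_sd sd of Gaussian pixel noise (default 0.05).
#' @param px_per_unit square pixels of image per unit on the grid layout
#'   (default 8).
#' @param layout `"grid"` (units on a near-square lattice) or `"random"`
#'   (uniform positions).
#' @param seed integer seed; the whole fixture is a deterministic function
#'   of the spec.
#' @return a `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_units = 2000L, k_domains = 4L,
                           m_features = 60L, markers_per_domain = 3L,
                           marker_shift = 3, base_rate = 1,
                           noise_sd = 0.2, image_signal = 1,
                           patch_noise_sd = 0.05, px_per_unit = 8L,
                           layout = c("grid", "random"), seed = 0L) {
  layout <- match.arg(layout)
  if (k_domains < 2L) stopf("k_domains must be >= 2")
  if (markers_per_domain * k_domains > m_features)
    stopf("markers_per_domain * k_domains exceeds m_features")
  if (image_signal < 0 || image_signal > 1)
    stopf("image_signal must be in [0, 1]")
  structure(list(n_units = as.integer(n_units),
                 k_domains = as.integer(k_domains),
                 m_features = as.integer(m_features),
                 markers_per_domain = as.integer(markers_per_domain),
                 marker_shift = marker_shift, base_rate = base_rate,
                 noise_sd = noise_sd, image_signal = image_signal,
                 patch_noise_sd = patch_noise_sd,
                 px_per_unit = as.integer(px_per_unit),
                 layout = layout, seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Reassign units in disconnected fragments of a domain to the neighbouring
## domain most common on the fragment border (grid layouts only), so each
## domain is one connected component under 4-adjacency.
repair_contiguity <- function(dom, rows, cols) {
  grid <- matrix(NA_integer_, rows, cols)
  grid[cbind(((seq_along(dom) - 1L) %/% cols) + 1L,
             ((seq_along(dom) - 1L) %% cols) + 1L)] <- dom
  for (pass in 1:5) {
    changed <- FALSE
    for (d in sort(unique(dom))) {
      cells <- which(grid == d)
      if (length(cells) == 0L) next
      comp <- rep(0L, length(cells))
      cmap <- match(seq_len(rows * cols), cells)   # grid cell -> local id
      nc <- 0L
      for (s in seq_along(cells)) {
        if (comp[s] > 0L) next
        nc <- nc + 1L
        queue <- s
        comp[s] <- nc
        while (length(queue)) {
          cur <- cells[queue[1L]]; queue <- queue[-1L]
          r <- ((cur - 1L) %% rows) + 1L; cc <- ((cur - 1L) %/% rows) + 1L
          for (nb in c(if (r > 1L) cur - 1L, if (r < rows) cur + 1L,
                       if (cc > 1L) cur - rows, if (cc < cols) cur + rows)) {
            li <- cmap[nb]
            if (!is.na(li) && comp[li] == 0L) {
              comp[li] <- nc; queue <- c(queue, li)
            }
          }
        }
      }
      if (nc <= 1L) next
      main <- which.max(tabulate(comp, nc))
      for (frag in setdiff(seq_len(nc), main)) {
        fcells <- cells[comp == frag]
        nbd <- integer(0L)
        for (cur in fcells) {
          r <- ((cur - 1L) %% rows) + 1L; cc <- ((cur - 1L) %/% rows) + 1L
          for (nb in c(if (r > 1L) cur - 1L, if (r < rows) cur + 1L,
                       if (cc > 1L) cur - rows, if (cc < cols) cur + rows))
            if (grid[nb] != d) nbd <- c(nbd, grid[nb])
        }
        grid[fcells] <- if (length(nbd))
          as.integer(names(which.max(table(nbd)))) else d
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(t(grid))[seq_along(dom)]
}

#' Generate a synthetic spatial omics dataset with a matched toy image
#'
#' Layout: units on a near-square grid (or uniform at random), partitioned
#' into `k_domains` contiguous Voronoi regions around seeded centres
#' (fragments are re-attached so grid domains are 4-connected). Expression:
#' unit `i` in domain `c` has `X[i, f] ~ Poisson(lambda)` with
#' `lambda = (base_rate + marker_shift * [f is a marker of c]) * exp(N(0,
#' noise_sd^2))`. Image: a single-channel raster where each domain region
#' carries a distinct base intensity `0.5 + image_signal * (b_c - 0.5)`
#' (`b_c` evenly spaced in `[0.15, 0.85]`) plus Gaussian pixel noise. All
#' randomness derives from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [spatial_dataset()] with ground-truth `labels` (domain ids),
#'   pixel-space coordinates, an in-memory image, and an attribute
#'   `"synthetic"` holding the spec, marker indices per domain and domain
#'   centres.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_units; k <- spec$k_domains; m <- spec$m_features
    px <- spec$px_per_unit
    rows <- max(2L, round(sqrt(n)))
    cols <- as.integer(ceiling(n / rows))
    H <- rows * px; W <- cols * px
    if (spec$layout == "grid") {
      idx <- seq_len(n) - 1L
      gr <- idx %/% cols + 1L; gc <- idx %% cols + 1L
      coords <- cbind(x = (gc - 0.5) * px, y = (gr - 0.5) * px)
    } else {
      coords <- cbind(x = stats::runif(n, 0, W), y = stats::runif(n, 0, H))
    }
    centers <- coords[sample.int(n, k), , drop = FALSE]
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * coords %*% t(centers)
    dom <- max.col(-d2, ties.method = "first")
    if (spec$layout == "grid" && n == rows * cols)
      dom <- repair_contiguity(dom, rows, cols)
    # ensure no empty domain: seed each missing domain at its centre's unit
    for (d in which(tabulate(dom, k) == 0L))
      dom[which.min(d2[, d])] <- d

    markers <- lapply(seq_len(k), function(c_)
      ((c_ - 1L) * spec$markers_per_domain + 1L):
        (c_ * spec$markers_per_domain))
    rate <- matrix(spec$base_rate, n, m)
    for (c_ in seq_len(k))
      rate[dom == c_, markers[[c_]]] <- spec$base_rate + spec$marker_shift
    if (spec$noise_sd > 0)
      rate <- rate * exp(matrix(stats::rnorm(n * m, sd = spec$noise_sd),
                                n, m))
    X <- matrix(stats::rpois(n * m, as.vector(rate)), n, m)

    # image: per-pixel domain intensity, blended toward 0.5 by image_signal.
    # On the grid layout each unit's pixel block carries the unit's (final,
    # contiguity-repaired) domain so image and labels agree exactly;
    # otherwise pixels take the domain of the nearest centre.
    base_int <- seq(0.15, 0.85, length.out = k)
    img <- matrix(0, H, W)
    if (spec$layout == "grid" && n == rows * cols) {
      dom_grid <- matrix(dom, rows, cols, byrow = TRUE)
      pix_dom <- dom_grid[rep(seq_len(rows), each = px),
                          rep(seq_len(cols), each = px)]
      img[] <- 0.5 + spec$image_signal * (base_int[pix_dom] - 0.5)
    } else {
      pcy <- seq_len(H) - 0.5
      cxs <- seq_len(W) - 0.5
      for (r in seq_len(H)) {
        d2r <- sapply(seq_len(k), function(c_)
          (cxs - centers[c_, 1L])^2 + (pcy[r] - centers[c_, 2L])^2)
        pdom <- max.col(-d2r, ties.method = "first")
        img[r, ] <- 0.5 + spec$image_signal * (base_int[pdom] - 0.5)
      }
    }
    if (spec$patch_noise_sd > 0)
      img <- img + matrix(stats::rnorm(H * W, sd = spec$patch_noise_sd),
                          H, W)
    img <- pmin(pmax(img, 0), 1)

    ds <- spatial_dataset(X, coords, image = array(img, c(H, W, 1L)),
                          labels = dom)
    attr(ds, "synthetic") <- list(spec = spec, markers = markers,
                                  centers = centers,
                                  grid = c(rows = rows, cols = cols))
    ds
  })
}

#' Weaken the expression signal of a random subset of units
#'
#' A seeded fraction of units have their expression rows replaced by Poisson
#' draws from the global (domain-free) mean rate profile, removing their
#' domain information from the expression modality while coordinates, labels
#' and the image stay untouched. Used for image-ablation experiments: with
#' `fraction = 1`, per-domain feature means are statistically
#' indistinguishable.
#'
#' @param ds a raw-count [spatial_dataset()] (typically from
#'   [generate_synthetic()]).
#' @param fraction share of units to degrade, in `[0, 1]`.
#' @param seed integer seed.
#' @return the dataset with degraded rows.
#' @export
degrade_expression <- function(ds, fraction, seed = 0L) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  if (fraction == 0) return(ds)
  n <- nrow(ds$X); m <- ncol(ds$X)
  with_seed(seed, {
    n_deg <- floor(fraction * n)
    pick <- sort(sample.int(n, n_deg))
    global_rate <- colMeans(ds$X)
    ds$X[pick, ] <- matrix(
      stats::rpois(n_deg * m, rep(global_rate, each = n_deg)), n_deg, m)
    attr(ds, "degraded_units") <- pick
    ds
  })
}
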